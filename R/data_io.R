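#' Read a vegetation survey table
#'
#' Reads a long-format survey CSV with one row per (site, plot, species,
#' height layer) occupancy record. Four height layers are distinguished
#' (L1: 0-10 cm, L2: 10-30 cm, L3: 30-50 cm, L4: 50-200 cm); the sampling
#' design uses `n_plots` plots of 35 x 35 cm along one transect per site.
#' A pre-aggregated dialect with columns `site, species, layer_count`
#' (total layers occupied across all plots) is also accepted.
#'
#' @param path Path to a CSV file. Expected columns: `site`, `plot`,
#'   `species`, `layer` (long dialect) or `site`, `species`, `layer_count`
#'   (aggregated dialect). Layers may be coded `1..n_layers` or
#'   `"L1".."L4"`.
#' @param n_plots Number of plots per transect (default 21).
#' @param n_layers Number of height layers per plot (default 4).
#' @return A data frame of class `forage_survey`. Long dialect: columns
#'   `site`, `plot`, `species`, `layer`; aggregated dialect: `site`,
#'   `species`, `layer_count`, with attribute `aggregated = TRUE`. Both
#'   carry attributes `n_plots` and `n_layers`.
#' @export
read_survey <- function(path, n_plots = 21L, n_layers = 4L) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_survey(raw, n_plots = n_plots, n_layers = n_layers)
}

#' Validate an in-memory survey table
#'
#' @param x A data frame in either survey dialect (see [read_survey()]).
#' @inheritParams read_survey
#' @return A validated `forage_survey` data frame.
#' @export
as_survey <- function(x, n_plots = 21L, n_layers = 4L) {
  x <- as.data.frame(x)
  if (all(c("site", "species", "layer_count") %in% names(x)) &&
      !"layer" %in% names(x)) {
    x$layer_count <- as.integer(x$layer_count)
    if (anyNA(x$layer_count) || any(x$layer_count < 1L))
      stop("layer_count must be a positive integer", call. = FALSE)
    if (any(x$layer_count > n_plots * n_layers))
      stop("layer_count exceeds plots x layers (", n_plots * n_layers, ")",
           call. = FALSE)
    key <- paste(x$site, x$species, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (site, species) rows in aggregated survey",
           call. = FALSE)
    out <- x[, c("site", "species", "layer_count")]
    attr(out, "aggregated") <- TRUE
  } else {
    need <- c("site", "plot", "species", "layer")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("survey is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x$plot <- as.integer(x$plot)
    if (anyNA(x$plot) || any(x$plot < 1L) || any(x$plot > n_plots))
      stop("plot index outside 1..", n_plots, call. = FALSE)
    x$layer <- parse_layer(x$layer, n_layers)
    key <- paste(x$site, x$plot, x$species, x$layer, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate (site, plot, species, layer) rows collapsed",
              call. = FALSE)
      x <- x[!duplicated(key), , drop = FALSE]
    }
    out <- x[, need]
    attr(out, "aggregated") <- FALSE
  }
  out$site <- as.character(out$site)
  out$species <- as.character(out$species)
  attr(out, "n_plots") <- as.integer(n_plots)
  attr(out, "n_layers") <- as.integer(n_layers)
  class(out) <- c("forage_survey", "data.frame")
  out
}

parse_layer <- function(layer, n_layers) {
  lv <- as.character(layer)
  lv <- sub("^[Ll]", "", lv)
  li <- suppressWarnings(as.integer(lv))
  if (anyNA(li) || any(li < 1L) || any(li > n_layers))
    stop("layer codes must be 1..", n_layers, " or L1..L", n_layers,
         call. = FALSE)
  li
}

#' Read a leaf chemistry table
#'
#' One pooled leaf sample per (site, species); element contents are percent
#' of dry mass. Accepts long format (`site, species, element, content`) or
#' wide format (`site, species` plus one column per element symbol).
#'
#' @param path Path to a CSV file.
#' @return Long data frame of class `forage_chemistry` with columns `site`,
#'   `species`, `element`, `content`.
#' @export
read_chemistry <- function(path) {
  if (!file.exists(path)) stop("chemistry file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_chemistry(raw)
}

#' Validate an in-memory chemistry table
#'
#' @param x A data frame in long or wide chemistry format (see
#'   [read_chemistry()]).
#' @return A validated long `forage_chemistry` data frame.
#' @export
as_chemistry <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("site", "species") %in% names(x)))
    stop("chemistry is missing column(s): site, species", call. = FALSE)
  if (!"element" %in% names(x)) {
    have <- intersect(FORAGE_ELEMENTS, names(x))
    if (!length(have))
      stop("chemistry has neither an 'element' column nor element columns",
           call. = FALSE)
    x <- stats::reshape(
      x[, c("site", "species", have)],
      direction = "long", varying = have, v.names = "content",
      times = have, timevar = "element", idvar = c("site", "species"))
    rownames(x) <- NULL
  }
  need <- c("site", "species", "element", "content")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("chemistry is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- x[!is.na(x$content), need, drop = FALSE]
  bad <- setdiff(unique(x$element), FORAGE_ELEMENTS)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  x$content <- as.numeric(x$content)
  if (any(x$content <= 0))
    stop("element contents must be > 0 (percent of dry mass)", call. = FALSE)
  key <- paste(x$site, x$species, x$element, sep = "\r")
  if (anyDuplicated(key))
    stop("more than one record per (site, species, element)", call. = FALSE)
  x$site <- as.character(x$site)
  x$species <- as.character(x$species)
  rownames(x) <- NULL
  class(x) <- c("forage_chemistry", "data.frame")
  x
}

#' Read a site environment table
#'
#' @param path Path to a CSV with columns `site` and `rainfall` (mean
#'   annual rainfall, mm per year).
#' @return Data frame of class `forage_environment`.
#' @export
read_environment <- function(path) {
  if (!file.exists(path))
    stop("environment file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_environment(raw)
}

#' Validate an in-memory environment table
#'
#' @param x A data frame with columns `site` and `rainfall`.
#' @return A validated `forage_environment` data frame.
#' @export
as_environment <- function(x) {
  x <- as.data.frame(x)
  miss <- setdiff(c("site", "rainfall"), names(x))
  if (length(miss))
    stop("environment is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$rainfall <- as.numeric(x$rainfall)
  if (anyNA(x$rainfall) || any(x$rainfall <= 0))
    stop("rainfall must be positive (mm per year)", call. = FALSE)
  if (anyDuplicated(x$site))
    stop("more than one environment record per site", call. = FALSE)
  x$site <- as.character(x$site)
  out <- x[, c("site", "rainfall")]
  class(out) <- c("forage_environment", "data.frame")
  out
}

#' Literature-derived herbivore nutrient requirements
#'
#' Loads the bundled requirement table: minimum forage contents (% dry
#' mass) of N, P, K, Ca, Mg and Na needed for daily maintenance of three
#' reference herbivores (cattle 600 kg, wildebeest 143 kg, sheep 75 kg) at
#' lactating and non-lactating stages, plus optimal intake ranges for the
#' N:P and K:Na ratios (lactating cattle) and the Ca:P ratio (lactating
#' wildebeest). Cells the source literature does not provide are `NA`.
#'
#' @param path Optional path to an alternative requirement CSV in the same
#'   layout as the bundled fixture.
#' @return Data frame of class `forage_requirements` with columns
#'   `herbivore`, `body_mass_kg`, `life_stage`, the six element columns and
#'   `<ratio>_low` / `<ratio>_high` range columns.
#' @seealso [requirement_min()], [requirement_range()]
#' @export
load_requirements <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "herbivore_requirements.csv",
                        package = "foragevar", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("herbivore", "body_mass_kg", "life_stage", FORAGE_ELEMENTS,
            paste0(rep(FORAGE_RATIOS, each = 2), c("_low", "_high")))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("requirement table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(x$life_stage %in% c("lactating", "non_lactating")))
    stop("life_stage must be lactating or non_lactating", call. = FALSE)
  for (r in FORAGE_RATIOS) {
    lo <- x[[paste0(r, "_low")]]; hi <- x[[paste0(r, "_high")]]
    if (any(!is.na(lo) & !is.na(hi) & lo > hi))
      stop("ratio range with low > high for ", r, call. = FALSE)
  }
  x <- x[, need]
  class(x) <- c("forage_requirements", "data.frame")
  x
}

#' Look up a minimum element requirement
#'
#' @param requirements A `forage_requirements` table.
#' @param herbivore,life_stage Row selectors.
#' @param element One of the six element symbols.
#' @return The minimum content (% dry mass), or `NA` where the literature
#'   gives none.
#' @export
requirement_min <- function(requirements, herbivore, life_stage, element) {
  element <- match.arg(element, FORAGE_ELEMENTS)
  row <- requirements$herbivore == herbivore &
    requirements$life_stage == life_stage
  if (!any(row)) stop("no requirement row for ", herbivore, "/", life_stage,
                      call. = FALSE)
  requirements[[element]][row][1]
}

#' Look up an optimal ratio range
#'
#' @inheritParams requirement_min
#' @param ratio One of `"N:P"`, `"Ca:P"`, `"K:Na"`.
#' @return Numeric `c(low, high)`, or `c(NA, NA)` where absent.
#' @export
requirement_range <- function(requirements, herbivore, life_stage, ratio) {
  ratio <- match.arg(ratio, FORAGE_RATIOS)
  row <- requirements$herbivore == herbivore &
    requirements$life_stage == life_stage
  if (!any(row)) stop("no requirement row for ", herbivore, "/", life_stage,
                      call. = FALSE)
  c(requirements[[paste0(ratio, "_low")]][row][1],
    requirements[[paste0(ratio, "_high")]][row][1])
}

#' Write and re-read result tables
#'
#' Plain-CSV persistence for any of the package's result data frames.
#' Numeric columns survive the round trip to full double precision.
#'
#' @param x A data frame.
#' @param path Output CSV path.
#' @return `write_result()` returns `path` invisibly; `read_result()`
#'   returns the data frame.
#' @export
write_result <- function(x, path) {
  x <- as.data.frame(x)
  out <- x
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (j in which(num))
    out[[j]] <- formatC(x[[j]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = "")
}
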