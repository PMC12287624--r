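#' Default per-element generator parameters
#'
#' Realistic wet-season leaf contents (% dry mass) for savanna herbaceous
#' vegetation: community means and the shape/spread of between-species
#' baseline variation. Ca, Mg and Na baselines are lognormal (forbs can
#' carry several-fold higher contents than grasses); N, P and K are
#' normal, truncated positive.
#'
#' @return Data frame with columns `element`, `mean`, `dist`
#'   (`"normal"`/`"lognormal"`), `cv` (normal) or `sdlog` (lognormal).
#' @export
element_defaults <- function() {
  data.frame(
    element = FORAGE_ELEMENTS,
    mean = c(2.0, 0.20, 1.5, 0.60, 0.30, 0.10),
    dist = c("normal", "normal", "normal",
             "lognormal", "lognormal", "lognormal"),
    spread = c(0.30, 0.30, 0.30, 0.50, 0.50, 0.50),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic community scenario
#'
#' Defines the ground-truth structure of a simulated survey-plus-chemistry
#' dataset: a rainfall gradient of `n_sites` sites, `n_species` species
#' whose occupancy of the `n_plots` x `n_layers` sampling grid follows
#' Gaussian niches along the gradient, and per-(site, species) leaf
#' chemistry built from species baselines, optional within-species linear
#' trends, optional rainfall-orthogonal site offsets, and sampling noise.
#'
#' The three coupling knobs map onto the mechanistic scenarios:
#' `coupling` ties species baselines (log-linearly) to their niche optima,
#' producing gradient-related turnover; `orthogonal_coupling` ties
#' baselines to a full-period cosine of the niche optimum over the
#' gradient span — a pattern whose exponentiated harmonics are all
#' orthogonal to a linear trend — producing strong turnover with no linear
#' relation to rainfall; `site_offset_sd` adds site-level offsets residualized
#' against rainfall, producing gradient-unrelated intraspecific variation.
#' `shared_composition = TRUE` replicates a single occupancy grid across
#' all sites, removing species turnover entirely.
#'
#' @param n_sites Number of sites (default 9).
#' @param rainfall_range Gradient endpoints in mm/yr, evenly spaced
#'   (default 681-999).
#' @param n_species,n_plots,n_layers Community and sampling-grid sizes
#'   (defaults 45, 21, 4).
#' @param shared_composition Replicate one survey across sites (no
#'   turnover).
#' @param niche_width Gaussian niche SD on the rainfall axis (mm); default
#'   0.2 x gradient span, narrow enough that most species occupy only a
#'   few adjacent sites, as observed in real transect data.
#' @param occ_max Peak per-cell occupancy probability (default 0.6).
#' @param layer_profile Relative occupancy of the four height layers.
#' @param coupling Log-linear baseline-optimum coupling strength
#'   (0 = none).
#' @param orthogonal_coupling Strength of the rainfall-orthogonal
#'   baseline pattern (0 = none).
#' @param slope_frac Within-species trend: total fractional change of
#'   content over the full gradient span (negative = decline); the slope
#'   per mm for element e is `slope_frac * mean_e / span`.
#' @param site_offset_sd Relative SD of multiplicative site offsets
#'   (residualized against rainfall).
#' @param noise_sd Relative sampling noise SD (additive for normal
#'   elements, multiplicative lognormal for the skewed ones).
#' @param elements Element table as in [element_defaults()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_sites = 9L, rainfall_range = c(681, 999),
                          n_species = 45L, n_plots = 21L, n_layers = 4L,
                          shared_composition = FALSE,
                          niche_width = NULL, occ_max = 0.6,
                          layer_profile = c(1, 0.7, 0.4, 0.15),
                          coupling = 0, orthogonal_coupling = 0,
                          slope_frac = 0, site_offset_sd = 0,
                          noise_sd = 0.05,
                          elements = element_defaults(), seed = 1L) {
  stopifnot(n_sites >= 3L, n_species >= 1L, n_plots >= 1L, n_layers >= 1L,
            length(rainfall_range) == 2L,
            rainfall_range[2] > rainfall_range[1],
            noise_sd >= 0, site_offset_sd >= 0, occ_max > 0,
            length(layer_profile) == n_layers)
  span <- diff(rainfall_range)
  if (is.null(niche_width)) niche_width <- 0.2 * span
  if (occ_max * max(layer_profile) > 1)
    stop("infeasible occupancy: probability above 1", call. = FALSE)
  structure(list(
    n_sites = as.integer(n_sites), rainfall_range = rainfall_range,
    n_species = as.integer(n_species), n_plots = as.integer(n_plots),
    n_layers = as.integer(n_layers),
    shared_composition = shared_composition,
    niche_width = niche_width, occ_max = occ_max,
    layer_profile = layer_profile,
    coupling = coupling, orthogonal_coupling = orthogonal_coupling,
    slope_frac = slope_frac, site_offset_sd = site_offset_sd,
    noise_sd = noise_sd, elements = elements, seed = as.integer(seed)),
    class = "scenario_spec")
}

#' Scenario presets for the four mechanistic hypotheses
#'
#' * `"a"` gradient-related species turnover: baselines coupled to niche
#'   optima, no within-species trend.
#' * `"b"` gradient-related intraspecific variation: identical composition
#'   across sites, negative within-species slope.
#' * `"c"` gradient-unrelated species turnover: distinct niches, baselines
#'   follow a pattern orthogonal to the linear gradient.
#' * `"d"` gradient-unrelated intraspecific variation: identical
#'   composition, site offsets residualized against rainfall.
#'
#' @param name One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param seed Seed passed through to [scenario_spec()].
#' @param noise_sd Relative sampling noise (default 0.05).
#' @return A `scenario_spec`.
#' @export
scenario_preset <- function(name, seed = 1L, noise_sd = 0.05) {
  switch(match.arg(name, c("a", "b", "c", "d")),
    a = scenario_spec(coupling = 0.8, seed = seed, noise_sd = noise_sd),
    b = scenario_spec(shared_composition = TRUE, slope_frac = -0.5,
                      seed = seed, noise_sd = noise_sd),
    c = scenario_spec(orthogonal_coupling = 0.8, seed = seed,
                      noise_sd = noise_sd),
    d = scenario_spec(shared_composition = TRUE, site_offset_sd = 0.25,
                      seed = seed, noise_sd = noise_sd))
}

# residualize y against x and rescale to unit SD (zero vector if degenerate)
orthogonalize <- function(y, x) {
  r <- stats::residuals(stats::lm(y ~ x))
  s <- stats::sd(r)
  if (s == 0) rep(0, length(y)) else r / s
}

#' Generate a synthetic community dataset
#'
#' Draws a layer-occupancy survey, per-(site, species) leaf chemistry and
#' a site environment table from a [scenario_spec()], together with the
#' generating ground truth. The same seed yields identical output.
#'
#' @param spec A `scenario_spec`.
#' @return A list with `survey` (a `forage_survey`), `chemistry`
#'   (`forage_chemistry`), `environment` (`forage_environment`) and
#'   `ground_truth` (parameters, species optima, baselines, slopes, site
#'   offsets, noise draws and seed).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  rainfall <- seq(spec$rainfall_range[1], spec$rainfall_range[2],
                  length.out = spec$n_sites)
  sites <- sprintf("S%d", seq_len(spec$n_sites))
  species <- sprintf("sp%02d", seq_len(spec$n_species))
  span <- diff(spec$rainfall_range)

  # niche optima along the gradient (slightly beyond the sampled range so
  # edge sites keep full communities)
  optima <- stats::runif(spec$n_species,
                         spec$rainfall_range[1] - 0.15 * span,
                         spec$rainfall_range[2] + 0.15 * span)

  # occupancy probabilities per (species, site)
  if (spec$shared_composition) {
    p_occ <- matrix(spec$occ_max, spec$n_species, spec$n_sites)
  } else {
    p_occ <- spec$occ_max * exp(-0.5 * outer(
      optima, rainfall, function(o, r) ((r - o) / spec$niche_width)^2))
  }

  # survey: thin each species into the n_plots x n_layers grid
  draw_grid <- function(p_sp) {
    # layer counts per (species, plot): independent Bernoulli cells
    counts <- matrix(0L, spec$n_species, spec$n_plots)
    for (l in seq_len(spec$n_layers)) {
      pl <- p_sp * spec$layer_profile[l]
      occ <- matrix(stats::rbinom(spec$n_species * spec$n_plots, 1L,
                                  rep(pl, spec$n_plots)),
                    spec$n_species, spec$n_plots)
      counts <- counts + occ
    }
    counts
  }
  survey_rows <- list()
  shared_counts <- if (spec$shared_composition) draw_grid(p_occ[, 1]) else NULL
  layer_counts <- matrix(0L, spec$n_species, spec$n_sites,
                         dimnames = list(species, sites))
  for (j in seq_len(spec$n_sites)) {
    counts <- if (spec$shared_composition) shared_counts
              else draw_grid(p_occ[, j])
    layer_counts[, j] <- rowSums(counts)
    idx <- which(counts > 0L, arr.ind = TRUE)
    if (nrow(idx)) {
      survey_rows[[j]] <- data.frame(
        site = sites[j], species = species[idx[, 1]],
        plot = idx[, 2], layers = counts[idx],
        stringsAsFactors = FALSE)
    }
  }
  sv <- do.call(rbind, survey_rows)
  if (is.null(sv) || !all(sites %in% sv$site))
    stop("generated survey left a site empty; increase occ_max", call. = FALSE)
  # expand to long (site, plot, species, layer) rows: a species occupying k
  # layers of a plot is recorded in layers 1..k
  long <- sv[rep(seq_len(nrow(sv)), sv$layers), c("site", "plot", "species")]
  long$layer <- unlist(lapply(sv$layers, seq_len), use.names = FALSE)
  survey <- as_survey(long, n_plots = spec$n_plots, n_layers = spec$n_layers)

  # species baselines per element
  el <- spec$elements
  opt_scaled <- 2 * (optima - mean(range(optima))) / diff(range(optima))
  q_pattern <- cos(2 * pi * (optima - spec$rainfall_range[1]) / span)
  baselines <- matrix(NA_real_, spec$n_species, nrow(el),
                      dimnames = list(species, el$element))
  for (k in seq_len(nrow(el))) {
    if (el$dist[k] == "lognormal") {
      b <- el$mean[k] * exp(el$spread[k] * stats::rnorm(spec$n_species) -
                              el$spread[k]^2 / 2)
    } else {
      b <- el$mean[k] * pmax(0.1, 1 + el$spread[k] *
                               stats::rnorm(spec$n_species))
    }
    b <- b * exp(-spec$coupling * opt_scaled +
                   spec$orthogonal_coupling * q_pattern)
    baselines[, k] <- b
  }

  # site offsets (multiplicative, exactly uncorrelated with rainfall)
  offsets <- matrix(1, spec$n_sites, nrow(el),
                    dimnames = list(sites, el$element))
  if (spec$site_offset_sd > 0) {
    for (k in seq_len(nrow(el))) {
      e <- orthogonalize(stats::rnorm(spec$n_sites), rainfall)
      offsets[, k] <- exp(spec$site_offset_sd * e -
                            spec$site_offset_sd^2 / 2)
    }
  }

  slopes <- stats::setNames(spec$slope_frac * el$mean / span, el$element)

  # chemistry: one pooled sample per (site, species present)
  rain_c <- rainfall - mean(rainfall)
  chem_rows <- list()
  noise_draws <- list()
  for (k in seq_len(nrow(el))) {
    elem <- el$element[k]
    z <- matrix(stats::rnorm(spec$n_species * spec$n_sites),
                spec$n_species, spec$n_sites)
    noise_draws[[elem]] <- z
    base_content <- outer(baselines[, k], rep(1, spec$n_sites)) +
      outer(rep(1, spec$n_species), slopes[elem] * rain_c)
    base_content <- sweep(base_content, 2, offsets[, k], `*`)
    if (el$dist[k] == "lognormal") {
      content <- base_content * exp(spec$noise_sd * z - spec$noise_sd^2 / 2)
    } else {
      content <- base_content + spec$noise_sd * el$mean[k] * z
    }
    content <- pmax(content, 1e-4 * el$mean[k])
    present <- layer_counts > 0L
    idx <- which(present, arr.ind = TRUE)
    chem_rows[[elem]] <- data.frame(
      site = sites[idx[, 2]], species = species[idx[, 1]],
      element = elem, content = content[idx],
      stringsAsFactors = FALSE)
  }
  chemistry <- as_chemistry(do.call(rbind, chem_rows))
  environment <- as_environment(data.frame(site = sites, rainfall = rainfall))

  ground_truth <- list(
    seed = spec$seed,
    parameters = spec[setdiff(names(spec), "elements")],
    rainfall = stats::setNames(rainfall, sites),
    optima = stats::setNames(optima, species),
    baselines = baselines, slopes = slopes, site_offsets = offsets,
    noise_draws = noise_draws)
  list(survey = survey, chemistry = chemistry, environment = environment,
       ground_truth = ground_truth)
}

#' Write a generated community to disk
#'
#' Writes `survey.csv`, `chemistry.csv` and `environment.csv` in the
#' dialects the readers accept, plus `ground_truth.json` with the
#' generating parameters (matrices of noise draws are kept only in the
#' in-memory object).
#'
#' @param community Output of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(community$survey),
                   file.path(dir, "survey.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(community$chemistry),
                   file.path(dir, "chemistry.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(community$environment),
                   file.path(dir, "environment.csv"), row.names = FALSE)
  gt <- community$ground_truth
  gt$noise_draws <- NULL
  gt$baselines <- as.data.frame(gt$baselines)
  gt$site_offsets <- as.data.frame(gt$site_offsets)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
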