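#' Layer abundance per site and species
#'
#' The abundance currency of the sampling design: the total number of
#' (plot x height layer) cells a species occupies along a site's transect,
#' at most `n_plots * n_layers` (84 for the default 21-plot, 4-layer
#' design).
#'
#' @param survey A `forage_survey` data frame (either dialect).
#' @return Data frame with columns `site`, `species`, `layer_count`.
#' @export
layer_abundance <- function(survey) {
  if (!inherits(survey, "forage_survey"))
    survey <- as_survey(survey)
  if (isTRUE(attr(survey, "aggregated"))) {
    out <- survey[, c("site", "species", "layer_count")]
    out <- as.data.frame(out)
  } else {
    agg <- stats::aggregate(
      list(layer_count = survey$layer),
      by = list(site = survey$site, species = survey$species),
      FUN = length)
    out <- agg
  }
  out <- out[order(out$site, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out$layer_count <- as.integer(out$layer_count)
  out
}

#' Relative abundance over the chemically sampled subset
#'
#' Computes each species' weight at a site as its layer count divided by
#' the total layer count of all species with leaf chemistry at that site
#' (the "collected" species of the weighted-mean definition). Species
#' without chemistry receive weight `NA` but still count towards the
#' coverage denominator.
#'
#' @param abundance Output of [layer_abundance()].
#' @param chemistry A `forage_chemistry` table; a species counts as sampled
#'   at a site if it has any element measured there.
#' @return The abundance table with an added `weight` column, plus an
#'   attribute `coverage`: a data frame (`site`, `coverage`) giving the
#'   fraction of total layer abundance represented by sampled species.
#' @export
relative_abundance <- function(abundance, chemistry) {
  chemistry <- if (inherits(chemistry, "forage_chemistry")) chemistry
               else as_chemistry(chemistry)
  sampled_key <- unique(paste(chemistry$site, chemistry$species, sep = "\r"))
  ab <- abundance
  ab$sampled <- paste(ab$site, ab$species, sep = "\r") %in% sampled_key
  sites <- unique(ab$site)
  ab$weight <- NA_real_
  cov <- numeric(length(sites))
  for (k in seq_along(sites)) {
    rows <- ab$site == sites[k]
    tot <- sum(ab$layer_count[rows])
    samp <- rows & ab$sampled
    if (!any(samp))
      stop("no chemically sampled species at site ", sites[k], call. = FALSE)
    denom <- sum(ab$layer_count[samp])
    ab$weight[samp] <- ab$layer_count[samp] / denom
    cov[k] <- denom / tot
  }
  out <- ab[, c("site", "species", "layer_count", "weight")]
  attr(out, "coverage") <- data.frame(site = sites, coverage = cov,
                                      stringsAsFactors = FALSE)
  out
}

#' Cross-site fixed mean content per species
#'
#' The "fixed" trait value of a species: the unweighted arithmetic mean of
#' its site-level contents over the sites where it was sampled. It is
#' constant across sites, so a weighted mean built from it varies only
#' through species composition.
#'
#' @param chemistry A `forage_chemistry` table.
#' @return Data frame with columns `species`, `element`, `fixed_content`,
#'   `n_sites`.
#' @export
species_fixed_means <- function(chemistry) {
  chemistry <- if (inherits(chemistry, "forage_chemistry")) chemistry
               else as_chemistry(chemistry)
  m <- stats::aggregate(
    list(fixed_content = chemistry$content),
    by = list(species = chemistry$species, element = chemistry$element),
    FUN = mean)
  n <- stats::aggregate(
    list(n_sites = chemistry$content),
    by = list(species = chemistry$species, element = chemistry$element),
    FUN = length)
  out <- merge(m, n, by = c("species", "element"), sort = TRUE)
  out$n_sites <- as.integer(out$n_sites)
  rownames(out) <- NULL
  out
}

#' Specific and fixed community-weighted means
#'
#' For every site and element, computes the specific weighted mean (each
#' species enters with its site-specific content), the fixed weighted mean
#' (each species enters with its cross-site fixed mean), and their
#' difference, the intraspecific deviation. Weights are layer-abundance
#' shares recomputed per element over the species having that element
#' measured at the site, so the weighted mean stays well defined under
#' partial chemistry.
#'
#' @param abundance Output of [layer_abundance()].
#' @param chemistry A `forage_chemistry` table.
#' @param elements Elements to compute; defaults to those present.
#' @return Data frame of class `forage_cwm` with columns `site`, `element`,
#'   `specific`, `fixed`, `intraspecific_dev`, `coverage`.
#' @export
cwm_table <- function(abundance, chemistry, elements = NULL) {
  chemistry <- if (inherits(chemistry, "forage_chemistry")) chemistry
               else as_chemistry(chemistry)
  if (is.null(elements))
    elements <- intersect(FORAGE_ELEMENTS, unique(chemistry$element))
  fixed <- species_fixed_means(chemistry)
  sites <- sort(unique(abundance$site))
  res <- list()
  for (el in elements) {
    chem_el <- chemistry[chemistry$element == el, , drop = FALSE]
    fix_el <- fixed[fixed$element == el, , drop = FALSE]
    fix_map <- stats::setNames(fix_el$fixed_content, fix_el$species)
    for (s in sites) {
      ab <- abundance[abundance$site == s, , drop = FALSE]
      ch <- chem_el[chem_el$site == s, , drop = FALSE]
      idx <- match(ab$species, ch$species)
      in_chem <- !is.na(idx)
      if (!any(in_chem))
        stop("no species with ", el, " measured at site ", s, call. = FALSE)
      denom <- sum(ab$layer_count[in_chem])
      w <- ab$layer_count[in_chem] / denom
      site_content <- ch$content[idx[in_chem]]
      fixed_content <- fix_map[ab$species[in_chem]]
      if (anyNA(fixed_content))
        stop("species without fixed mean for ", el, call. = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        site = s, element = el,
        specific = sum(w * site_content),
        fixed = sum(w * unname(fixed_content)),
        coverage = denom / sum(ab$layer_count),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$intraspecific_dev <- out$specific - out$fixed
  out <- out[, c("site", "element", "specific", "fixed",
                 "intraspecific_dev", "coverage")]
  rownames(out) <- NULL
  class(out) <- c("forage_cwm", "data.frame")
  out
}
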