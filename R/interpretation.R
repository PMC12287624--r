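#' Default interpretation thresholds
#'
#' * `theta_contrib` — minimum share of the total across-site SS for a
#'   component (turnover or intraspecific) to count as a contributing
#'   mechanism (default 0.15).
#' * `trend_p` — p-value below which a site-level trend counts as
#'   gradient-related (default 0.1, the solid-line convention).
#' * `mixed_p` — p-value below which a within-species slope counts as a
#'   directional intraspecific trend (default 0.05).
#' * `theta_outlier` — within-species max/min content ratio above which a
#'   species is flagged as an idiosyncratic outlier (default 5).
#' * `severe_cutoff` — a nutrient is severely limiting when at most this
#'   fraction of sites meets the requirement for every reference herbivore
#'   (default 0.2); sufficient requires all sites and all samples to meet
#'   every requirement; anything between is moderately limiting.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(theta_contrib = 0.15, trend_p = 0.1, mixed_p = 0.05,
       theta_outlier = 5, severe_cutoff = 0.2)
}

#' Classify an element into the mechanistic hypotheses
#'
#' Combines the variance decomposition with the site-level trend: the
#' contributing mechanisms are the components (species turnover and/or
#' intraspecific variation) whose total share of the across-site SS is at
#' least `theta_contrib`; the variation is gradient-related when the
#' site-trend p-value is below `trend_p`. The label maps
#' (turnover, related) to `"a"`, (intraspecific, related) to `"b"`,
#' (turnover, unrelated) to `"c"` and (intraspecific, unrelated) to
#' `"d"`; when both mechanisms contribute the combined form (`"a+b"` or
#' `"c+d"`) is used. If neither component reaches the threshold the larger
#' of the two is taken as the mechanism.
#'
#' @param decomposition A `forage_decomp` result for the target.
#' @param site_trend A `forage_regression` result for the same target.
#' @param theta_contrib,trend_p Thresholds (see [default_thresholds()]).
#' @return A list of class `forage_hypothesis`: `target`, `mechanisms`,
#'   `gradient_related`, `label`, and `evidence` (shares and p used).
#' @export
classify_hypothesis <- function(decomposition, site_trend,
                                theta_contrib = 0.15, trend_p = 0.1) {
  if (isTRUE(attr(decomposition, "degenerate")))
    return(structure(list(target = attr(decomposition, "target"),
                          mechanisms = character(0),
                          gradient_related = NA, label = "unclassifiable",
                          evidence = NULL),
                     class = "forage_hypothesis"))
  sh <- stats::setNames(decomposition$total_share, decomposition$component)
  candidates <- c("turnover", "intraspecific")
  mech <- candidates[sh[candidates] >= theta_contrib]
  if (!length(mech))
    mech <- candidates[which.max(sh[candidates])]
  related <- site_trend$p < trend_p
  letters_rel <- c(turnover = "a", intraspecific = "b")
  letters_unrel <- c(turnover = "c", intraspecific = "d")
  lab <- if (related) letters_rel[mech] else letters_unrel[mech]
  label <- paste(sort(lab), collapse = "+")
  structure(list(
    target = attr(decomposition, "target"),
    mechanisms = mech, gradient_related = related, label = label,
    evidence = list(turnover_share = unname(sh["turnover"]),
                    intraspecific_share = unname(sh["intraspecific"]),
                    covariation_share = unname(sh["covariation"]),
                    trend_p = site_trend$p)),
    class = "forage_hypothesis")
}

#' @export
print.forage_hypothesis <- function(x, ...) {
  cat(sprintf("Hypothesis%s: %s (mechanisms: %s; gradient-related: %s)\n",
              if (is.na(x$target) || is.null(x$target)) ""
              else paste0(" [", x$target, "]"),
              x$label, paste(x$mechanisms, collapse = ", "),
              x$gradient_related))
  invisible(x)
}

#' Label within-species variability
#'
#' A target is `"variable"` when intraspecific variation both contributes
#' materially to the across-site SS (share >= `theta_contrib`) and shows a
#' significant directional within-species trend (mixed-model p <
#' `mixed_p`); otherwise `"uniform"`. Independently, species whose
#' within-species max/min content ratio exceeds `theta_outlier` are listed
#' as idiosyncratic outliers (large non-directional variation).
#'
#' @param decomposition A `forage_decomp` result.
#' @param mixed_result A `forage_mixed` result for the same target.
#' @param chemistry Optional chemistry table restricted by `element` to
#'   scan for outlier species; omit to skip outlier detection.
#' @param element Element symbol used to filter `chemistry`.
#' @param theta_contrib,mixed_p,theta_outlier Thresholds.
#' @return List: `label` ("uniform"/"variable"), `outlier_species`
#'   (character vector), `intraspecific_share`, `mixed_p`.
#' @export
label_intraspecific_variability <- function(decomposition, mixed_result,
                                            chemistry = NULL, element = NULL,
                                            theta_contrib = 0.15,
                                            mixed_p = 0.05,
                                            theta_outlier = 5) {
  sh <- decomposition$total_share[
    decomposition$component == "intraspecific"]
  variable <- isTRUE(!is.na(sh) && sh >= theta_contrib &&
                       mixed_result$p < mixed_p)
  outliers <- character(0)
  if (!is.null(chemistry)) {
    ch <- chemistry
    if (!is.null(element)) ch <- ch[ch$element == element, , drop = FALSE]
    if (nrow(ch)) {
      spread <- tapply(ch$content, ch$species,
                       function(v) if (length(v) >= 2) max(v) / min(v) else NA_real_)
      outliers <- names(spread)[!is.na(spread) & spread > theta_outlier]
    }
  }
  list(label = if (variable) "variable" else "uniform",
       outlier_species = outliers,
       intraspecific_share = unname(sh), mixed_p = mixed_result$p)
}

#' Grade nutrient limitation against herbivore requirements
#'
#' For each element: the fraction of sites whose specific weighted mean
#' meets (is at least, ties meet) the minimum requirement of each
#' reference herbivore at the given life stage, and the fraction of
#' individual (site, species) samples doing so. Summary per element:
#' `"sufficient"` when every site and every sample meets every available
#' requirement; `"severely limiting"` when at most `severe_cutoff` of
#' sites meet the requirement for every herbivore; otherwise
#' `"moderately limiting"`. For ratios the position of each site and
#' sample relative to the optimal range (below / within / above) is
#' tallied per herbivore with a populated range; the summary reports the
#' dominant position.
#'
#' @param cwm A `forage_cwm` table.
#' @param chemistry A `forage_chemistry` table.
#' @param ratios Output of [build_ratios()] (may be `NULL` to grade
#'   elements only).
#' @param requirements A `forage_requirements` table.
#' @param life_stage `"lactating"` (default; sampling in the peak wet
#'   season coincides with most herbivores lactating) or
#'   `"non_lactating"`.
#' @param severe_cutoff See [default_thresholds()].
#' @return A list with `detail` (one row per target x herbivore with the
#'   underlying fractions) and `summary` (one row per target).
#' @export
grade_limitation <- function(cwm, chemistry, ratios = NULL, requirements,
                             life_stage = "lactating", severe_cutoff = 0.2) {
  req <- requirements[requirements$life_stage == life_stage, , drop = FALSE]
  detail <- list()
  summary_rows <- list()
  for (el in intersect(FORAGE_ELEMENTS, unique(cwm$element))) {
    site_vals <- cwm$specific[cwm$element == el]
    samp_vals <- chemistry$content[chemistry$element == el]
    fr_sites <- fr_samp <- c()
    for (i in seq_len(nrow(req))) {
      thr <- req[[el]][i]
      if (is.na(thr)) next
      fs <- mean(site_vals >= thr)
      fp <- mean(samp_vals >= thr)
      detail[[length(detail) + 1L]] <- data.frame(
        target = el, herbivore = req$herbivore[i], life_stage = life_stage,
        threshold = thr, frac_sites_meet = fs, frac_samples_meet = fp,
        stringsAsFactors = FALSE)
      fr_sites <- c(fr_sites, fs); fr_samp <- c(fr_samp, fp)
    }
    if (!length(fr_sites)) next
    grade <- if (all(fr_sites == 1) && all(fr_samp == 1)) "sufficient"
             else if (all(fr_sites <= severe_cutoff)) "severely limiting"
             else "moderately limiting"
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      target = el, grade = grade,
      min_frac_sites = min(fr_sites), min_frac_samples = min(fr_samp),
      stringsAsFactors = FALSE)
  }
  if (!is.null(ratios)) {
    for (r in intersect(FORAGE_RATIOS, unique(ratios$site$ratio))) {
      site_vals <- ratios$site$specific[ratios$site$ratio == r]
      samp_vals <- if (!is.null(ratios$sample))
        ratios$sample$value[ratios$sample$ratio == r] else numeric(0)
      for (i in seq_len(nrow(req))) {
        lo <- req[[paste0(r, "_low")]][i]; hi <- req[[paste0(r, "_high")]][i]
        if (is.na(lo) || is.na(hi)) next
        pos <- function(v) c(below = mean(v < lo),
                             within = mean(v >= lo & v <= hi),
                             above = mean(v > hi))
        ps <- pos(site_vals)
        pp <- if (length(samp_vals)) pos(samp_vals) else rep(NA_real_, 3)
        detail[[length(detail) + 1L]] <- data.frame(
          target = r, herbivore = req$herbivore[i], life_stage = life_stage,
          range_low = lo, range_high = hi,
          frac_sites_below = ps[1], frac_sites_within = ps[2],
          frac_sites_above = ps[3],
          frac_samples_below = pp[1], frac_samples_within = pp[2],
          frac_samples_above = pp[3],
          stringsAsFactors = FALSE)
        grade <- if (ps["within"] == 1) "within range everywhere"
                 else if (ps["above"] == 1) "too high everywhere"
                 else if (ps["below"] == 1) "too low everywhere"
                 else sprintf("mixed (below/within/above = %.2f/%.2f/%.2f)",
                              ps[1], ps[2], ps[3])
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          target = r, grade = grade,
          min_frac_sites = ps[["within"]],
          min_frac_samples = if (length(samp_vals)) pp[["within"]] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- if (length(detail)) {
    all_names <- unique(unlist(lapply(detail, names)))
    do.call(rbind, lapply(detail, function(d) {
      for (nm in setdiff(all_names, names(d))) d[[nm]] <- NA
      d[, all_names]
    }))
  } else NULL
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else NULL
  if (!is.null(detail)) rownames(detail) <- NULL
  if (!is.null(summary)) rownames(summary) <- NULL
  list(detail = detail, summary = summary)
}

#' Full interpretation report for a community dataset
#'
#' Runs the complete inference chain for every requested element and
#' ratio: site-level trend regression, within-species mixed model,
#' SS decomposition with the gradient split, hypothesis classification,
#' intraspecific-variability labelling and limitation grading, and
#' assembles one summary row per target.
#'
#' @param cwm A `forage_cwm` table.
#' @param chemistry A `forage_chemistry` table.
#' @param environment A `forage_environment` table.
#' @param requirements A `forage_requirements` table (default the bundled
#'   fixture).
#' @param targets Elements and ratios to interpret.
#' @param transforms Transform map (default [default_transforms()]).
#' @param thresholds Threshold list (default [default_thresholds()]).
#' @param life_stage Reference life stage for limitation grading.
#' @param df_rule Degrees-of-freedom rule for the mixed models.
#' @return A list with `report` (one row per target: trend, variability,
#'   hypothesis label, limitation grade), `decomposition`, `regressions`,
#'   `mixed_models`, `limitation` and `thresholds`.
#' @export
interpret_all <- function(cwm, chemistry, environment,
                          requirements = load_requirements(),
                          targets = c(FORAGE_ELEMENTS, FORAGE_RATIOS),
                          transforms = default_transforms(),
                          thresholds = default_thresholds(),
                          life_stage = "lactating",
                          df_rule = "n_minus_2") {
  environment <- if (inherits(environment, "forage_environment")) environment
                 else as_environment(environment)
  targets <- targets[targets %in% c(FORAGE_ELEMENTS, FORAGE_RATIOS)]
  elements <- targets[targets %in% FORAGE_ELEMENTS]
  ratio_targets <- targets[targets %in% FORAGE_RATIOS]
  ratios <- if (length(ratio_targets))
    build_ratios(cwm, chemistry, pairs = ratio_targets) else NULL
  decomp <- decompose_all(cwm, environment, chemistry,
                          targets = targets, transforms = transforms)
  rain_of <- function(sites) environment$rainfall[match(sites, environment$site)]
  regs <- list(); mixed <- list(); rows <- list()
  for (tg in targets) {
    tr <- if (tg %in% names(transforms)) transforms[[tg]] else "identity"
    if (tg %in% FORAGE_ELEMENTS) {
      sub <- cwm[cwm$element == tg, , drop = FALSE]
      ser_spec <- sub$specific; ser_fix <- sub$fixed
      rain <- rain_of(sub$site)
      ch <- chemistry[chemistry$element == tg, , drop = FALSE]
      samples <- data.frame(species = ch$species, content = ch$content,
                            rainfall = rain_of(ch$site))
    } else {
      sub <- ratios$site[ratios$site$ratio == tg, , drop = FALSE]
      ser_spec <- sub$specific; ser_fix <- sub$fixed
      rain <- rain_of(sub$site)
      sr <- ratios$sample[ratios$sample$ratio == tg, , drop = FALSE]
      samples <- data.frame(species = sr$species, content = sr$value,
                            rainfall = rain_of(sr$site))
    }
    reg <- site_regression(ser_spec, rain, transform = tr, target = tg)
    mm <- within_species_mixed(samples, transform = tr, df_rule = df_rule,
                               target = tg)
    d <- decompose_with_gradient(ser_spec, ser_fix, rain, transform = tr,
                                 target = tg)
    hyp <- classify_hypothesis(d, reg,
                               theta_contrib = thresholds$theta_contrib,
                               trend_p = thresholds$trend_p)
    ch_for_outliers <- if (tg %in% FORAGE_ELEMENTS) chemistry else NULL
    var_lab <- label_intraspecific_variability(
      d, mm, chemistry = ch_for_outliers, element = tg,
      theta_contrib = thresholds$theta_contrib,
      mixed_p = thresholds$mixed_p,
      theta_outlier = thresholds$theta_outlier)
    trend <- if (reg$p < thresholds$trend_p) {
      if (reg$slope < 0) "decreasing" else "increasing"
    } else "unresponsive"
    regs[[tg]] <- reg; mixed[[tg]] <- mm
    rows[[tg]] <- data.frame(
      target = tg, trend = trend,
      intraspecific_variability = var_lab$label,
      outlier_species = paste(var_lab$outlier_species, collapse = ";"),
      hypothesis = hyp$label,
      turnover_pct = 100 * hyp$evidence$turnover_share,
      intraspecific_pct = 100 * hyp$evidence$intraspecific_share,
      trend_p = reg$p, mixed_p = mm$p,
      stringsAsFactors = FALSE)
  }
  lim <- grade_limitation(cwm, chemistry, ratios, requirements,
                          life_stage = life_stage,
                          severe_cutoff = thresholds$severe_cutoff)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(lim$summary))
    report$limitation <- lim$summary$grade[match(report$target,
                                                 lim$summary$target)]
  list(report = report, decomposition = decomp, regressions = regs,
       mixed_models = mixed, limitation = lim, ratios = ratios,
       thresholds = thresholds)
}
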