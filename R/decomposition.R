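#' Partition across-site variation into turnover, intraspecific and
#' covariation sums of squares
#'
#' Given the specific weighted mean `S_j` and fixed weighted mean `F_j` of
#' a trait at each site `j`, with intraspecific deviation
#' `I_j = S_j - F_j`, the centred sums of squares satisfy the exact
#' identity
#'
#' \deqn{\sum (S_j-\bar S)^2 = \sum (F_j-\bar F)^2 + \sum (I_j-\bar I)^2 +
#'   2\sum (F_j-\bar F)(I_j-\bar I)}
#'
#' i.e. total = species turnover + intraspecific variation + covariation.
#' Positive covariation means sites whose composition favours trait-rich
#' species also host individuals richer than their species' averages;
#' negative covariation means the two sources oppose each other.
#'
#' @param specific,fixed Numeric vectors of site-level specific and fixed
#'   weighted means, aligned by site (length >= 3).
#' @param transform `"identity"` or `"log10"`; applied to both series
#'   before decomposition.
#' @param target Optional label (element or ratio) carried into the result.
#' @return A data frame of class `forage_decomp` with one row per
#'   component (`turnover`, `intraspecific`, `covariation`) and columns
#'   `total_ss` and `total_share` (share of the total SS, signed).
#'   Attributes: `ss_total`, `n_sites`, `target`, `transform`,
#'   `degenerate` (TRUE when the total SS is zero, in which case shares
#'   are `NA`).
#' @export
decompose_ss <- function(specific, fixed, transform = "identity",
                         target = NA_character_) {
  if (length(specific) != length(fixed))
    stop("specific and fixed series differ in length", call. = FALSE)
  n <- length(specific)
  if (n < 3L)
    stop("decomposition needs at least 3 sites", call. = FALSE)
  S <- apply_transform(specific, transform)
  F_ <- apply_transform(fixed, transform)
  I <- S - F_
  css <- function(x) sum((x - mean(x))^2)
  ss_total <- css(S)
  turnover <- css(F_)
  intra <- css(I)
  covar <- ss_total - turnover - intra
  degenerate <- ss_total <= 0
  out <- data.frame(
    component = c("turnover", "intraspecific", "covariation"),
    total_ss = c(turnover, intra, covar),
    stringsAsFactors = FALSE)
  out$total_share <- if (degenerate) NA_real_ else out$total_ss / ss_total
  structure(out, ss_total = ss_total, n_sites = n, target = target,
            transform = transform, degenerate = degenerate,
            class = c("forage_decomp", "data.frame"))
}

#' Decompose variation with a gradient-explained / residual split
#'
#' Extends [decompose_ss()] by regressing the specific series, the fixed
#' series and the intraspecific deviation each on a single environmental
#' predictor (mean annual rainfall) with ordinary least squares. For the
#' turnover and intraspecific components the explained SS is the centred
#' SS of the fitted values and the residual SS the SS of the residuals;
#' for covariation the explained part is twice the cross-product of the
#' centred fitted values and the residual part the remainder, so each row
#' still sums exactly to its total.
#'
#' @inheritParams decompose_ss
#' @param rainfall Numeric gradient values aligned with the series.
#' @return A `forage_decomp` data frame with columns `component`,
#'   `explained_ss`, `residual_ss`, `total_ss` and the corresponding
#'   `_share` columns (shares of the total SS). If the gradient is
#'   constant the split columns are `NA` and attribute `gradient_defined`
#'   is `FALSE`; totals are always returned.
#' @export
decompose_with_gradient <- function(specific, fixed, rainfall,
                                    transform = "identity",
                                    target = NA_character_) {
  base <- decompose_ss(specific, fixed, transform = transform,
                       target = target)
  n <- attr(base, "n_sites")
  if (length(rainfall) != n)
    stop("rainfall must be defined for every site", call. = FALSE)
  S <- apply_transform(specific, transform)
  F_ <- apply_transform(fixed, transform)
  I <- S - F_
  gradient_defined <- stats::var(rainfall) > 0
  if (gradient_defined) {
    expl <- function(y) {
      fit <- stats::lm(y ~ rainfall)
      f <- stats::fitted(fit)
      list(fitted = f, explained = sum((f - mean(f))^2),
           residual = sum(stats::residuals(fit)^2))
    }
    eS <- expl(S); eF <- expl(F_); eI <- expl(I)
    cov_total <- base$total_ss[base$component == "covariation"]
    cov_expl <- 2 * sum((eF$fitted - mean(eF$fitted)) *
                          (eI$fitted - mean(eI$fitted)))
    explained <- c(eF$explained, eI$explained, cov_expl)
    residual <- c(eF$residual, eI$residual, cov_total - cov_expl)
  } else {
    explained <- residual <- rep(NA_real_, 3)
  }
  out <- base
  out$explained_ss <- explained
  out$residual_ss <- residual
  ss_total <- attr(base, "ss_total")
  if (attr(base, "degenerate")) {
    out$explained_share <- out$residual_share <- NA_real_
  } else {
    out$explained_share <- explained / ss_total
    out$residual_share <- residual / ss_total
  }
  out <- out[, c("component", "explained_ss", "residual_ss", "total_ss",
                 "explained_share", "residual_share", "total_share")]
  attr(out, "ss_total") <- ss_total
  attr(out, "n_sites") <- n
  attr(out, "target") <- target
  attr(out, "transform") <- transform
  attr(out, "degenerate") <- attr(base, "degenerate")
  attr(out, "gradient_defined") <- gradient_defined
  class(out) <- c("forage_decomp", "data.frame")
  out
}

#' Decompose every element and ratio of a CWM table
#'
#' Builds the specific and fixed site series for each requested element
#' (from the CWM table) and ratio (ratios of the respective CWMs, via
#' [build_ratios()]), applies the per-target transform, and runs
#' [decompose_with_gradient()] against rainfall.
#'
#' @param cwm A `forage_cwm` table.
#' @param environment A `forage_environment` table.
#' @param chemistry The chemistry table (needed to build ratio series).
#' @param targets Character vector of elements and/or ratios.
#' @param transforms Named map of transforms per target; defaults to
#'   [default_transforms()].
#' @return A data frame with one row per (target, component) and columns
#'   `target`, `component`, `explained_ss`, `residual_ss`, `total_ss`,
#'   `explained_pct`, `residual_pct`, `total_pct` (percent of the target's
#'   total SS, signed), `transform`, `n_sites`.
#' @export
decompose_all <- function(cwm, environment, chemistry = NULL,
                          targets = c(FORAGE_ELEMENTS, FORAGE_RATIOS),
                          transforms = default_transforms()) {
  environment <- if (inherits(environment, "forage_environment")) environment
                 else as_environment(environment)
  ratio_targets <- targets[targets %in% FORAGE_RATIOS]
  ratios <- NULL
  if (length(ratio_targets)) {
    ratios <- build_ratios(cwm, chemistry, pairs = ratio_targets)
  }
  out <- list()
  for (tg in targets) {
    if (tg %in% FORAGE_ELEMENTS) {
      sub <- cwm[cwm$element == tg, , drop = FALSE]
      if (!nrow(sub)) next
      ser <- data.frame(site = sub$site, specific = sub$specific,
                        fixed = sub$fixed, stringsAsFactors = FALSE)
    } else {
      sub <- ratios$site[ratios$site$ratio == tg, , drop = FALSE]
      if (!nrow(sub)) next
      ser <- data.frame(site = sub$site, specific = sub$specific,
                        fixed = sub$fixed, stringsAsFactors = FALSE)
    }
    rain <- environment$rainfall[match(ser$site, environment$site)]
    if (anyNA(rain))
      stop("rainfall missing for site(s) in CWM table", call. = FALSE)
    tr <- if (tg %in% names(transforms)) transforms[[tg]] else "identity"
    d <- decompose_with_gradient(ser$specific, ser$fixed, rain,
                                 transform = tr, target = tg)
    out[[tg]] <- data.frame(
      target = tg, component = d$component,
      explained_ss = d$explained_ss, residual_ss = d$residual_ss,
      total_ss = d$total_ss,
      explained_pct = 100 * d$explained_share,
      residual_pct = 100 * d$residual_share,
      total_pct = 100 * d$total_share,
      transform = tr, n_sites = attr(d, "n_sites"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
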