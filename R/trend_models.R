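#' Site-level regression of a weighted mean on rainfall
#'
#' Ordinary least squares of a (possibly log10-transformed) site series on
#' mean annual rainfall. The reported coefficient of determination is the
#' adjusted R-squared, which can be negative for fits worse than the
#' intercept-only model.
#'
#' @param values Numeric site series (e.g. specific weighted means).
#' @param rainfall Numeric gradient values, same length (mm per year).
#' @param transform `"identity"` or `"log10"` applied to `values`.
#' @param target Optional label carried into the result.
#' @return A list of class `forage_regression`: `target`, `transform`,
#'   `slope` (per mm/yr, on the transformed scale), `intercept`,
#'   `r2_adjusted`, `F`, `df1`, `df2`, `p`, `n`.
#' @export
site_regression <- function(values, rainfall, transform = "identity",
                            target = NA_character_) {
  if (length(values) != length(rainfall))
    stop("values and rainfall differ in length", call. = FALSE)
  n <- length(values)
  if (n < 3L) stop("regression needs at least 3 sites", call. = FALSE)
  y <- apply_transform(values, transform)
  fit <- stats::lm(y ~ rainfall)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                 lower.tail = FALSE)
  structure(list(
    target = target, transform = transform,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    se = sm$coefficients[2, 2],
    r2_adjusted = sm$adj.r.squared,
    F = unname(fstat[["value"]]),
    df1 = unname(fstat[["numdf"]]), df2 = unname(fstat[["dendf"]]),
    p = unname(p), n = n),
    class = "forage_regression")
}

#' @export
print.forage_regression <- function(x, ...) {
  cat(sprintf(
    "Site regression%s (%s): slope = %.4g per mm/yr, adj. R2 = %.2f, F(%d,%d) = %.2f, p = %.3g\n",
    if (is.na(x$target)) "" else paste0(" [", x$target, "]"),
    x$transform, x$slope, x$r2_adjusted, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Within-species trend across the gradient (mixed model)
#'
#' Fits `content ~ rainfall` with a random intercept per species by REML
#' (lme4), restricted to species sampled at `min_sites` or more sites.
#' Inference on the common slope is Wald-type: `t = slope / se` with a
#' configurable residual degrees-of-freedom rule, and the 95% CI is
#' `slope +/- t_crit * se`. With a single qualifying species the model
#' collapses to ordinary least squares on that species.
#'
#' @param samples Data frame with columns `species`, `rainfall`, `content`
#'   (one row per (site, species) sample).
#' @param transform `"identity"` or `"log10"` applied to `content`.
#' @param min_sites Minimum number of sites a species must be sampled at to
#'   be included (default 3).
#' @param df_rule `"n_minus_2"` (residual df = n_obs - 2; intercept and
#'   slope) or `"n_minus_species"` (n_obs - 1 - n_species).
#' @param target Optional label.
#' @return A list of class `forage_mixed`: `slope`, `se`, `ci_low`,
#'   `ci_high`, `t`, `df`, `p`, `var_species`, `var_resid`, `n_obs`,
#'   `n_species`, `singular`, `method` ("reml" or "ols"), `transform`,
#'   `df_rule`, `target`.
#' @export
within_species_mixed <- function(samples, transform = "identity",
                                 min_sites = 3L,
                                 df_rule = c("n_minus_2", "n_minus_species"),
                                 target = NA_character_) {
  df_rule <- match.arg(df_rule)
  need <- c("species", "rainfall", "content")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep_sp <- names(which(table(samples$species) >= min_sites))
  d <- samples[samples$species %in% keep_sp, , drop = FALSE]
  if (!nrow(d))
    stop("no species sampled at >= ", min_sites, " sites", call. = FALSE)
  d$y <- apply_transform(d$content, transform)
  n_obs <- nrow(d)
  n_species <- length(unique(d$species))
  if (n_species == 1L) {
    fit <- stats::lm(y ~ rainfall, data = d)
    sm <- summary(fit)
    slope <- unname(stats::coef(fit)[2])
    se <- sm$coefficients[2, 2]
    var_species <- 0
    var_resid <- sm$sigma^2
    singular <- TRUE
    method <- "ols"
  } else {
    fit <- lme4::lmer(y ~ rainfall + (1 | species), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_species <- vc$vcov[vc$grp == "species"]
    var_resid <- vc$vcov[vc$grp == "Residual"]
    co <- summary(fit)$coefficients
    slope <- co["rainfall", "Estimate"]
    se <- co["rainfall", "Std. Error"]
    singular <- lme4::isSingular(fit)
    method <- "reml"
  }
  df <- switch(df_rule,
               n_minus_2 = n_obs - 2L,
               n_minus_species = n_obs - 1L - n_species)
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  structure(list(
    target = target, transform = transform, df_rule = df_rule,
    slope = slope, se = se,
    ci_low = slope - crit * se, ci_high = slope + crit * se,
    t = tval, df = df, p = p,
    var_species = var_species, var_resid = var_resid,
    n_obs = n_obs, n_species = n_species,
    singular = singular, method = method),
    class = "forage_mixed")
}

#' @export
print.forage_mixed <- function(x, ...) {
  cat(sprintf(
    "Within-species trend%s (%s, %s): slope = %.3g per mm/yr (95%% CI %.3g ~ %.3g), t(%d) = %.2f, p = %.3g\n  species var = %.3g, residual var = %.3g, n = %d obs / %d species%s\n",
    if (is.na(x$target)) "" else paste0(" [", x$target, "]"),
    x$method, x$transform, x$slope, x$ci_low, x$ci_high, x$df, x$t, x$p,
    x$var_species, x$var_resid, x$n_obs, x$n_species,
    if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' Stoichiometric ratio series
#'
#' Builds, for each requested element pair, (i) the site-level ratio
#' series: the specific weighted mean of the numerator element divided by
#' that of the denominator (and the same for the fixed weighted means,
#' used in the ratio decomposition), and (ii) per-sample ratios computed
#' within each (site, species) chemistry record. Note the ratio of fixed
#' CWMs is not the fixed CWM of per-species ratios; the former defines the
#' site series here.
#'
#' @param cwm A `forage_cwm` table.
#' @param chemistry A `forage_chemistry` table (may be `NULL` to skip the
#'   sample-level series).
#' @param pairs Ratio keys such as `"N:P"`.
#' @return A list with components `site` (columns `site`, `ratio`,
#'   `specific`, `fixed`, `intraspecific_dev`) and `sample` (columns
#'   `site`, `species`, `ratio`, `value`, `rainfall`-free).
#' @export
build_ratios <- function(cwm, chemistry = NULL, pairs = FORAGE_RATIOS) {
  site_rows <- list()
  sample_rows <- list()
  for (r in pairs) {
    parts <- ratio_parts(r)
    num <- cwm[cwm$element == parts[1], , drop = FALSE]
    den <- cwm[cwm$element == parts[2], , drop = FALSE]
    m <- merge(num, den, by = "site", suffixes = c(".num", ".den"))
    if (!nrow(m))
      stop("CWM table lacks elements for ratio ", r, call. = FALSE)
    if (any(m$specific.den == 0) || any(m$fixed.den == 0))
      stop("zero denominator in ratio ", r, call. = FALSE)
    site_rows[[r]] <- data.frame(
      site = m$site, ratio = r,
      specific = m$specific.num / m$specific.den,
      fixed = m$fixed.num / m$fixed.den,
      stringsAsFactors = FALSE)
    if (!is.null(chemistry)) {
      cn <- chemistry[chemistry$element == parts[1], , drop = FALSE]
      cd <- chemistry[chemistry$element == parts[2], , drop = FALSE]
      mm <- merge(cn[, c("site", "species", "content")],
                  cd[, c("site", "species", "content")],
                  by = c("site", "species"), suffixes = c(".num", ".den"))
      if (nrow(mm)) {
        if (any(mm$content.den == 0))
          stop("zero denominator in sample ratio ", r, call. = FALSE)
        sample_rows[[r]] <- data.frame(
          site = mm$site, species = mm$species, ratio = r,
          value = mm$content.num / mm$content.den,
          stringsAsFactors = FALSE)
      }
    }
  }
  site <- do.call(rbind, site_rows)
  site$intraspecific_dev <- site$specific - site$fixed
  rownames(site) <- NULL
  sample <- if (length(sample_rows)) {
    s <- do.call(rbind, sample_rows); rownames(s) <- NULL; s
  } else NULL
  list(site = site, sample = sample)
}
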