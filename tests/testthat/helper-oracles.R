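# Independent brute-force oracles: every quantity is computed with explicit
# per-site loops and textbook formulas, sharing no code with the package
# implementation.

# weighted means by explicit loops over one site's species
oracle_cwm_site <- function(species, layer_counts, site_contents,
                            fixed_contents) {
  denom <- 0
  for (i in seq_along(species)) denom <- denom + layer_counts[i]
  spec <- fix <- 0
  for (i in seq_along(species)) {
    w <- layer_counts[i] / denom
    spec <- spec + w * site_contents[i]
    fix <- fix + w * fixed_contents[i]
  }
  c(specific = unname(spec), fixed = unname(fix))
}

# full CWM series for one element via loops; abundance/chemistry are plain
# data frames (site, species, layer_count) and (site, species, content)
oracle_cwm_series <- function(abundance, chem_el) {
  sites <- sort(unique(abundance$site))
  # fixed mean per species: plain mean over its sampled sites
  fixed <- sapply(sort(unique(chem_el$species)), function(sp) {
    v <- chem_el$content[chem_el$species == sp]
    s <- 0
    for (x in v) s <- s + x
    s / length(v)
  })
  out <- data.frame(site = sites, specific = NA_real_, fixed = NA_real_)
  for (k in seq_along(sites)) {
    s <- sites[k]
    ab <- abundance[abundance$site == s, ]
    ch <- chem_el[chem_el$site == s, ]
    keep <- ab$species %in% ch$species
    sp <- ab$species[keep]
    lc <- ab$layer_count[keep]
    cont <- ch$content[match(sp, ch$species)]
    r <- oracle_cwm_site(sp, lc, cont, fixed[sp])
    out$specific[k] <- r["specific"]
    out$fixed[k] <- r["fixed"]
  }
  out
}

# sums of squares by loops; covariation via the explicit cross-product
oracle_decompose <- function(S, F_, rainfall = NULL) {
  n <- length(S)
  I <- S - F_
  m <- function(x) sum(x) / length(x)
  css <- function(x) {
    mu <- m(x); s <- 0
    for (v in x) s <- s + (v - mu)^2
    s
  }
  cross <- function(x, y) {
    mx <- m(x); my <- m(y); s <- 0
    for (i in seq_along(x)) s <- s + (x[i] - mx) * (y[i] - my)
    s
  }
  res <- list(ss_total = css(S), turnover = css(F_), intraspecific = css(I),
              covariation = 2 * cross(F_, I))
  if (!is.null(rainfall)) {
    ols2 <- function(y, x) {
      b <- cross(x, y) / css(x)
      a <- m(y) - b * m(x)
      fit <- a + b * x
      r <- 0
      for (i in seq_along(y)) r <- r + (y[i] - fit[i])^2
      list(fitted = fit, explained = css(fit), residual = r)
    }
    eF <- ols2(F_, rainfall); eI <- ols2(I, rainfall)
    res$turnover_explained <- eF$explained
    res$turnover_residual <- eF$residual
    res$intraspecific_explained <- eI$explained
    res$intraspecific_residual <- eI$residual
    res$covariation_explained <- 2 * cross(eF$fitted, eI$fitted)
    res$covariation_residual <- res$covariation - res$covariation_explained
  }
  res
}

# closed-form simple regression for 3+ points (hand formulas)
oracle_ols <- function(y, x) {
  n <- length(y)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  fit <- a + b * x
  sse <- sum((y - fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  list(slope = b, intercept = a, r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
}
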