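test_that("site regression matches closed-form hand calculation", {
  y <- c(2.3, 1.9, 1.1)
  x <- c(700, 850, 1000)
  r <- site_regression(y, x)
  o <- oracle_ols(y, x)
  expect_equal(r$slope, o$slope, tolerance = 1e-12)
  expect_equal(r$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(r$r2_adjusted, o$r2_adj, tolerance = 1e-12)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 1)
})

test_that("adjusted R2 obeys its single-predictor identity", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    x <- runif(n, 600, 1000)
    y <- 3 - 0.002 * x + rnorm(n, 0, 0.3)
    r <- site_regression(y, x)
    o <- oracle_ols(y, x)
    expect_equal(r$r2_adjusted, 1 - (1 - o$r2) * (n - 1) / (n - 2),
                 tolerance = 1e-10)
  }
})

test_that("perfect fits and null slopes behave sensibly", {
  x <- seq(700, 1000, length.out = 9)
  # summary.lm warns about the essentially perfect fit; that is the point here
  r <- suppressWarnings(site_regression(5 - 0.002 * x, x))
  expect_equal(r$r2_adjusted, 1, tolerance = 1e-8)
  expect_lt(r$p, 1e-10)

  # slope-zero truth: estimate within 3 SE of zero
  set.seed(21)
  ok <- replicate(20, {
    y <- rnorm(9, 2, 0.3)
    r0 <- site_regression(y, x)
    abs(r0$slope) < 3 * r0$se
  })
  expect_gte(mean(ok), 0.9)

  expect_error(site_regression(c(-1, 2, 3), x[1:3], transform = "log10"),
               "positive")
  expect_error(site_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("a single qualifying species collapses the mixed model to OLS", {
  set.seed(8)
  d <- data.frame(species = "A", rainfall = seq(700, 1000, length.out = 6),
                  content = 2 - 0.001 * seq(700, 1000, length.out = 6) +
                    rnorm(6, 0, 0.05))
  m <- within_species_mixed(d)
  ols <- stats::lm(content ~ rainfall, data = d)
  expect_equal(m$slope, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(m$method, "ols")
  expect_equal(m$var_species, 0)
})

test_that("mixed model recovers a common slope across species intercepts", {
  set.seed(99)
  rain <- seq(681, 999, length.out = 9)
  make <- function(slope) {
    sp <- rep(paste0("sp", 1:8), each = 9)
    b <- rep(rnorm(8, 2, 0.4), each = 9)
    r <- rep(rain, 8)
    data.frame(species = sp, rainfall = r,
               content = b + slope * (r - mean(r)) + rnorm(72, 0, 0.1))
  }
  # true slope zero: estimate within 3 SE
  ok <- replicate(10, {
    m <- within_species_mixed(make(0))
    abs(m$slope) < 3 * m$se
  })
  expect_gte(mean(ok), 0.9)
  # a clear negative slope is detected with a covering CI
  m1 <- within_species_mixed(make(-2e-3))
  expect_lt(m1$p, 0.01)
  expect_true(m1$ci_low <= -2e-3 + 3 * m1$se &&
                m1$ci_high >= -2e-3 - 3 * m1$se)
  expect_equal(m1$df, 72 - 2)
  m2 <- within_species_mixed(make(-2e-3), df_rule = "n_minus_species")
  expect_equal(m2$df, 72 - 1 - 8)
})

test_that("species below the site-count threshold are excluded", {
  d <- data.frame(
    species = c(rep("A", 4), rep("B", 2)),
    rainfall = c(700, 800, 900, 1000, 700, 1000),
    content = c(2, 1.9, 1.8, 1.7, 5, 4))
  # one retained species collapses to OLS on an exactly linear series, which
  # makes summary.lm warn about the perfect fit
  m <- suppressWarnings(within_species_mixed(d, min_sites = 3))
  expect_equal(m$n_species, 1L)
  expect_equal(m$n_obs, 4L)
})

test_that("zero between-species variance is flagged singular, not fatal", {
  set.seed(2)
  rain <- rep(seq(700, 1000, length.out = 5), 3)
  d <- data.frame(species = rep(c("A", "B", "C"), each = 5), rainfall = rain,
                  content = 2 + 0.001 * rain + rnorm(15, 0, 0.01))
  m <- suppressMessages(within_species_mixed(d))
  expect_true(is.finite(m$slope))
  if (m$singular) expect_equal(m$var_species, 0, tolerance = 1e-10)
})

test_that("ratio series divide the right quantities", {
  ab <- data.frame(site = "S1", species = c("A", "B"),
                   layer_count = c(1L, 1L))
  chem <- as_chemistry(data.frame(
    site = "S1", species = rep(c("A", "B"), each = 2),
    element = rep(c("N", "P"), 2), content = c(2.0, 0.25, 1.2, 0.15)))
  cwm <- cwm_table(ab, chem)
  rat <- build_ratios(cwm, chem, pairs = "N:P")
  expect_equal(rat$site$specific, 1.6 / 0.2)  # (2+1.2)/2 over (0.25+0.15)/2
  expect_equal(rat$sample$value, c(8, 8))

  chem_kna <- as_chemistry(data.frame(site = "S1", species = "A",
                                      element = c("K", "Na"),
                                      content = c(1.0, 0.1)))
  cwm2 <- cwm_table(ab[1, ], chem_kna)
  rat2 <- build_ratios(cwm2, chem_kna, pairs = "K:Na")
  expect_equal(rat2$sample$value, 10)
})

test_that("ratio of fixed CWMs differs from fixed CWM of ratios in general", {
  # 2 species, 2 sites with swapped dominance: the ratio of fixed weighted
  # means is not the weighted mean of per-species fixed ratios
  ab <- data.frame(site = rep(c("S1", "S2"), each = 2),
                   species = rep(c("A", "B"), 2),
                   layer_count = c(3L, 1L, 1L, 3L))
  chem <- as_chemistry(data.frame(
    site = rep(c("S1", "S2"), each = 4),
    species = rep(rep(c("A", "B"), each = 2), 2),
    element = rep(c("N", "P"), 4),
    content = c(2.0, 0.2, 1.0, 0.4, 2.4, 0.3, 1.2, 0.5)))
  cwm <- cwm_table(ab, chem)
  rat <- build_ratios(cwm, chem, pairs = "N:P")
  fm <- species_fixed_means(chem)
  fixed_ratio_by_species <- with(
    list(n = fm$fixed_content[fm$element == "N"],
         p = fm$fixed_content[fm$element == "P"]), n / p)
  w_s1 <- c(0.75, 0.25)
  cwm_of_ratios_s1 <- sum(w_s1 * fixed_ratio_by_species)
  ratio_of_cwms_s1 <- rat$site$fixed[rat$site$site == "S1"]
  expect_false(isTRUE(all.equal(cwm_of_ratios_s1, ratio_of_cwms_s1)))
})
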