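# build a forage_decomp carrying given component shares, for classifier tests
fake_decomp <- function(turnover, intraspecific, target = "N") {
  cov <- 1 - turnover - intraspecific
  structure(data.frame(
    component = c("turnover", "intraspecific", "covariation"),
    total_ss = c(turnover, intraspecific, cov),
    total_share = c(turnover, intraspecific, cov),
    stringsAsFactors = FALSE),
    ss_total = 1, n_sites = 9, target = target, transform = "identity",
    degenerate = FALSE, class = c("forage_decomp", "data.frame"))
}
fake_reg <- function(p, slope = -1) {
  structure(list(target = NA, transform = "identity", slope = slope,
                 intercept = 0, se = 1, r2_adjusted = 0.5, F = 1,
                 df1 = 1, df2 = 7, p = p, n = 9),
            class = "forage_regression")
}
fake_mixed <- function(p) list(p = p)

test_that("hypothesis labels follow the share/trend mapping", {
  # dominant turnover with a near-significant downward trend
  h1 <- classify_hypothesis(fake_decomp(0.64, 0.07), fake_reg(0.059))
  expect_equal(h1$label, "a")
  expect_equal(h1$mechanisms, "turnover")

  # both mechanisms above threshold, trend significant
  h2 <- classify_hypothesis(fake_decomp(0.35, 0.25), fake_reg(0.001))
  expect_equal(h2$label, "a+b")

  # dominant turnover, no trend
  h3 <- classify_hypothesis(fake_decomp(0.70, 0.05), fake_reg(0.85))
  expect_equal(h3$label, "c")

  # dominant intraspecific with / without trend
  expect_equal(classify_hypothesis(fake_decomp(0.05, 0.80),
                                   fake_reg(0.01))$label, "b")
  expect_equal(classify_hypothesis(fake_decomp(0.05, 0.80),
                                   fake_reg(0.5))$label, "d")
  expect_equal(classify_hypothesis(fake_decomp(0.2, 0.7),
                                   fake_reg(0.5))$label, "c+d")
})

test_that("label mapping is a bijection over (mechanisms, relatedness)", {
  mechs <- list("turnover", "intraspecific", c("turnover", "intraspecific"))
  shares <- list(c(0.8, 0.05), c(0.05, 0.8), c(0.4, 0.4))
  seen <- character(0)
  for (i in seq_along(mechs)) for (rel in c(TRUE, FALSE)) {
    h <- classify_hypothesis(fake_decomp(shares[[i]][1], shares[[i]][2]),
                             fake_reg(if (rel) 0.01 else 0.9))
    expect_setequal(h$mechanisms, mechs[[i]])
    expect_equal(h$gradient_related, rel)
    seen <- c(seen, h$label)
  }
  expect_equal(sort(seen), sort(c("a", "b", "a+b", "c", "d", "c+d")))
})

test_that("degenerate decompositions are unclassifiable; tiny shares fall back", {
  d <- decompose_ss(c(1, 1, 1), c(1, 1, 1))
  h <- classify_hypothesis(d, fake_reg(0.5))
  expect_equal(h$label, "unclassifiable")
  # neither component reaches the threshold: the larger one is taken
  h2 <- classify_hypothesis(fake_decomp(0.10, 0.05), fake_reg(0.5))
  expect_equal(h2$mechanisms, "turnover")
  expect_equal(h2$label, "c")
})

test_that("intraspecific variability labels combine share and trend gates", {
  # material share + significant slope: variable
  v1 <- label_intraspecific_variability(fake_decomp(0.35, 0.25),
                                        fake_mixed(1e-4))
  expect_equal(v1$label, "variable")
  # significant slope but negligible share: uniform
  v2 <- label_intraspecific_variability(fake_decomp(0.79, 0.07),
                                        fake_mixed(0.03))
  expect_equal(v2$label, "uniform")
  # outlier species flagged by max/min spread
  chem <- as_chemistry(data.frame(
    site = c("S1", "S2", "S1", "S2"),
    species = c("cen mez", "cen mez", "the tri", "the tri"),
    element = "Na", content = c(0.50, 0.03, 0.08, 0.10)))
  v3 <- label_intraspecific_variability(fake_decomp(0.8, 0.05),
                                        fake_mixed(0.13), chemistry = chem,
                                        element = "Na")
  expect_equal(v3$label, "uniform")
  expect_equal(v3$outlier_species, "cen mez")
})

test_that("limitation grades follow the site/sample fractions", {
  # a community whose K always clears every threshold but whose Na clears
  # the lowest threshold at a single site only
  sites <- paste0("S", 1:9)
  cwm <- structure(data.frame(
    site = rep(sites, 2), element = rep(c("K", "Na"), each = 9),
    specific = c(rep(2.0, 9), c(0.06, rep(0.02, 8))),
    fixed = 1, intraspecific_dev = 0, coverage = 1,
    stringsAsFactors = FALSE), class = c("forage_cwm", "data.frame"))
  chem <- as_chemistry(data.frame(
    site = rep(sites, 2), species = "A",
    element = rep(c("K", "Na"), each = 9),
    content = c(rep(2.0, 9), c(0.06, rep(0.02, 8)))))
  req <- load_requirements()
  g <- grade_limitation(cwm, chem, NULL, req)
  expect_equal(g$summary$grade[g$summary$target == "K"], "sufficient")
  expect_equal(g$summary$grade[g$summary$target == "Na"],
               "severely limiting")

  # exact ties meet the requirement
  cwm_tie <- cwm[cwm$element == "K", ]
  cwm_tie$specific <- 0.69  # lactating cattle K threshold
  chem_tie <- as_chemistry(data.frame(site = sites, species = "A",
                                      element = "K", content = 0.69))
  g2 <- grade_limitation(cwm_tie, chem_tie, NULL, req)
  expect_equal(g2$summary$grade[g2$summary$target == "K"], "sufficient")
})

test_that("raising every content never worsens the limitation grade", {
  rank_of <- c("severely limiting" = 1, "moderately limiting" = 2,
               "sufficient" = 3)
  toy <- make_toy_community(n_sites = 5, n_species = 4, seed = 17,
                            elements = c("N", "P", "K", "Ca", "Mg", "Na"))
  req <- load_requirements()
  cwm <- cwm_table(toy$abundance, toy$chemistry)
  g1 <- grade_limitation(cwm, toy$chemistry, NULL, req)
  up <- toy$chemistry; up$content <- up$content * 3
  up <- as_chemistry(as.data.frame(up))
  cwm_up <- cwm_table(toy$abundance, up)
  g2 <- grade_limitation(cwm_up, up, NULL, req)
  for (el in g1$summary$target) {
    expect_gte(rank_of[g2$summary$grade[g2$summary$target == el]],
               rank_of[g1$summary$grade[g1$summary$target == el]])
  }
})

test_that("ratio positions are tallied against the optimal ranges", {
  sites <- paste0("S", 1:3)
  cwm <- structure(data.frame(
    site = rep(sites, 2), element = rep(c("K", "Na"), each = 3),
    specific = c(2, 2, 2, 0.02, 0.02, 0.02),
    fixed = c(2, 2, 2, 0.02, 0.02, 0.02),
    intraspecific_dev = 0, coverage = 1, stringsAsFactors = FALSE),
    class = c("forage_cwm", "data.frame"))
  chem <- as_chemistry(data.frame(
    site = rep(sites, 2), species = "A",
    element = rep(c("K", "Na"), each = 3),
    content = c(2, 2, 2, 0.02, 0.02, 0.02)))
  ratios <- build_ratios(cwm, chem, pairs = "K:Na")
  req <- load_requirements()
  g <- grade_limitation(cwm, chem, ratios, req)
  row <- g$summary[g$summary$target == "K:Na", ]
  expect_equal(row$grade, "too high everywhere")  # 100 vs optimal 1-5
  det <- g$detail[g$detail$target == "K:Na", ]
  expect_equal(det$frac_sites_above, 1)
})
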