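test_that("trophic position identities hold exactly", {
  tp1 <- trophic_position(3.4, 0)
  expect_identical(tp1$tp, 1)
  expect_identical(tp1$sd, 0)
  expect_equal(trophic_position(11.0, 0)$tp, 2)
  # TP(Glx = Phe + beta) = 1 for any Phe
  for (phe in c(-3, 0, 4.7)) {
    expect_equal(trophic_position(phe + 3.4, phe)$tp, 1)
  }
  expect_error(trophic_position(1, 0, params = tp_params(delta_tef = 0)),
               "delta_tef")
})

test_that("trophic position is affine and monotone in its inputs", {
  glx <- seq(0, 20, by = 2.5)
  tps <- trophic_position(glx, 1.0)$tp
  expect_true(all(diff(tps) > 0))
  expect_equal(diff(tps), rep(2.5 / 7.6, length(glx) - 1))
  phe <- seq(-2, 6, by = 1)
  expect_true(all(diff(trophic_position(10, phe)$tp) < 0))
})

test_that("propagated TP uncertainty matches hand arithmetic and Monte Carlo", {
  expect_equal(trophic_position(10, 5, 0.3, 0.4)$sd, sqrt(0.09 + 0.16) / 7.6,
               tolerance = 1e-12)
  # full propagation incl. beta/delta uncertainty vs 1e6-draw oracle
  set.seed(42)
  n <- 1e6
  p <- tp_params(sd_beta = 0.2, sd_delta = 0.3)
  est <- trophic_position(12, 2, 0.3, 0.4, params = p)
  draws <- (rnorm(n, 12, 0.3) - rnorm(n, 2, 0.4) - rnorm(n, 3.4, 0.2)) /
    rnorm(n, 7.6, 0.3) + 1
  expect_equal(est$sd, sd(draws), tolerance = 0.02)
  expect_equal(est$tp, mean(draws), tolerance = 0.01)
})

test_that("weighted mean d15N is the inverse-variance estimator", {
  expect_equal(weighted_mean_d15n(c(5, 10), c(1, 1)), 7.5)
  expect_equal(weighted_mean_d15n(c(5, 10), c(1, 2)), 6.0)
  expect_equal(weighted_mean_d15n(4.2, 0.3), 4.2)
  expect_error(weighted_mean_d15n(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean_d15n(c(1, 2), c(0, 1)), "infinite weight")
  expect_equal(weighted_mean_d15n(c(1, 2), c(0, 1), zero_sd = "substitute"),
               1.5)
  # bounded by inputs; invariant to joint sd rescaling
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(5, 5, 3); s <- runif(5, 0.1, 2)
    wm <- weighted_mean_d15n(x, s)
    expect_gte(wm, min(x)); expect_lte(wm, max(x))
    expect_equal(weighted_mean_d15n(x, 3.7 * s), wm)
  }
})

test_that("Sum-V is the mean absolute deviation of trophic AA d15N", {
  tab <- make_fixture_table(ids = "h1")
  df <- as.data.frame(tab)
  set_n <- function(df, code, v) {
    df$delta[df$element == "N" & df$amino_acid == code] <- v; df
  }
  codes <- c("Ala", "Leu", "Pro", "Asp", "Glx")
  for (i in seq_along(codes)) df <- set_n(df, codes[i], i)
  tab2 <- aa_isotope_table(df)
  sv <- sum_v(tab2, "h1")
  expect_equal(sv$sum_v, (2 + 1 + 0 + 1 + 2) / 5)
  expect_equal(unname(sv$deviations), c(1, 2, 3, 4, 5) - 3)
  # all equal -> 0; translation invariance; |a|-homogeneity about the mean
  for (i in seq_along(codes)) df <- set_n(df, codes[i], 4.4)
  expect_equal(sum_v(aa_isotope_table(df), "h1")$sum_v, 0)
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(5, 3, 2); c0 <- rnorm(1); a <- runif(1, -2, 2)
    for (i in seq_along(codes)) df <- set_n(df, codes[i], x[i])
    base <- sum_v(aa_isotope_table(df), "h1")$sum_v
    for (i in seq_along(codes)) df <- set_n(df, codes[i], x[i] + c0)
    expect_equal(sum_v(aa_isotope_table(df), "h1")$sum_v, base)
    for (i in seq_along(codes)) {
      df <- set_n(df, codes[i], mean(x) + a * (x[i] - mean(x)))
    }
    expect_equal(sum_v(aa_isotope_table(df), "h1")$sum_v, abs(a) * base)
  }
  # variance mode and missing-AA error
  for (i in seq_along(codes)) df <- set_n(df, codes[i], i)
  expect_equal(sum_v(aa_isotope_table(df), "h1", mode = "variance")$sum_v,
               var(1:5))
  df2 <- df[!(df$amino_acid == "Pro" & df$element == "N"), ]
  expect_error(sum_v(aa_isotope_table(df2), "h1"), "Pro")
})

test_that("mixing fractions hit the end-members exactly and stay linear", {
  expect_equal(heterotrophy_fraction(2.0, tp_auto = 1, tp_het = 2)$fraction, 1)
  expect_equal(heterotrophy_fraction(1.0, tp_auto = 1, tp_het = 2)$fraction, 0)
  expect_equal(heterotrophy_fraction(1.5, tp_auto = 1, tp_het = 3)$fraction,
               0.25)
  expect_equal(heterotrophy_fraction(2.0, tp_auto = 1, tp_het = 2)$percent,
               100)
  # linear in tp_mix
  f <- vapply(seq(1, 2, by = 0.1), function(m)
    heterotrophy_fraction(m, tp_auto = 1, tp_het = 2)$fraction, numeric(1))
  expect_equal(f, seq(0, 1, by = 0.1))
  expect_error(heterotrophy_fraction(1.5, tp_auto = 2, tp_het = 2),
               "degenerate")
  expect_warning(out <- heterotrophy_fraction(2.5, tp_auto = 1, tp_het = 2),
                 "outside")
  expect_true(out$out_of_range)
  expect_equal(out$fraction, 1.5)  # unclamped
})

test_that("mixing variance follows first-order propagation and Monte Carlo", {
  expect_equal(heterotrophy_fraction(1.5, sd_mix = 0.2, tp_auto = 1,
                                     tp_het = 2)$sd, 0.2)
  set.seed(99)
  n <- 1e6
  est <- heterotrophy_fraction(1.6, sd_mix = 0.15, tp_auto = 1.0,
                               sd_auto = 0.1, tp_het = 3.0, sd_het = 0.2)
  # the autotrophic draw is shared between numerator and denominator
  a <- rnorm(n, 1.0, 0.1)
  draws <- (rnorm(n, 1.6, 0.15) - a) / (rnorm(n, 3.0, 0.2) - a)
  expect_equal(est$sd, sd(draws), tolerance = 0.02)
  expect_equal(est$fraction, mean(draws), tolerance = 0.01)
})

test_that("scenario grids cross samples with end-member scenarios", {
  tp_tab <- data.frame(sample_id = "s1", fraction = "host",
                       treatment = "L-NF", tp = 1.5, sd = 0.1)
  st <- scenario_table(tp_tab)
  expect_equal(nrow(st$estimates), 2)
  expect_setequal(st$estimates$scenario, c("detritivory", "zooplanktivory"))
  f_det <- st$estimates$fraction[st$estimates$scenario == "detritivory"]
  f_zoo <- st$estimates$fraction[st$estimates$scenario == "zooplanktivory"]
  expect_gt(f_det, f_zoo)  # smaller end-member span -> larger fraction
  expect_error(scenario_table(tp_tab[0, ]), "nonempty")
  # group summaries are mean +/- SD over samples
  tp_tab2 <- data.frame(sample_id = c("s1", "s2"),
                        fraction = "host", treatment = "L-NF",
                        tp = c(1.2, 1.4), sd = 0.1)
  st2 <- scenario_table(tp_tab2, tp_het = 2.0)
  expect_equal(st2$summary$percent_mean, mean(c(20, 40)))
  expect_equal(st2$summary$percent_sd, sd(c(20, 40)))
})

test_that("per-sample TP extraction propagates replicate uncertainty", {
  tab <- make_fixture_table(ids = c("h1", "h2"))
  out <- tp_by_sample(tab)
  expect_equal(nrow(out), 2)
  glx <- tab$delta[tab$sample_id == "h1" & tab$amino_acid == "Glx" &
                     tab$element == "N"]
  phe <- tab$delta[tab$sample_id == "h1" & tab$amino_acid == "Phe" &
                     tab$element == "N"]
  expect_equal(out$tp[out$sample_id == "h1"], (glx - phe - 3.4) / 7.6 + 1)
  expect_equal(out$sd, rep(sqrt(2 * 0.25^2) / 7.6, 2))
})
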