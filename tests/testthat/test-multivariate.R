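test_that("mean normalization removes per-sample baselines exactly", {
  m <- matrix(c(-10, -20, -30, -15, -15, -15), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("Ile", "Leu", "Val")))
  fp <- mean_normalize(m)
  expect_equal(unclass(fp)["a", ], c(Ile = 10, Leu = 0, Val = -10))
  expect_equal(unclass(fp)["b", ], c(Ile = 0, Leu = 0, Val = 0))
  expect_equal(rowSums(fp), c(a = 0, b = 0), tolerance = 1e-12)
  # idempotence and invariance to adding a per-sample constant
  expect_equal(unclass(mean_normalize(fp)), unclass(fp))
  shifted <- m + c(3.7, -1.2)  # per-row constants
  expect_equal(unclass(mean_normalize(shifted)), unclass(fp))
  m[1, 2] <- NA
  expect_error(mean_normalize(m), "masked")
})

test_that("PCA of the correlation matrix reconstructs and ranks variance", {
  set.seed(3)
  x <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("V", 1:5)))
  pc <- aa_pca(x)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(pc$variance_fraction >= 0))
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  # scores x loadings' reproduces the scaled, centered data
  scaled <- scale(x)
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(unname(recon), unname(scaled[, ]), tolerance = 1e-8)
  # two perfectly correlated variables -> rank-1 correlation matrix
  y <- cbind(a = 1:10, b = 2 * (1:10) + 5)
  expect_equal(aa_pca(y)$variance_fraction[1], 1, tolerance = 1e-12)
  z <- x; z[, 2] <- 4
  expect_error(aa_pca(z), "V2")
})

test_that("PCA correlation vectors flag significant variables", {
  set.seed(8)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("V", 1:4)))
  x[, 1] <- x[, 1] + 3 * rowMeans(x[, 2:3])  # force shared structure
  pc <- aa_pca(x)
  cv <- pc$correlation_vectors
  expect_setequal(unique(cv$component), c("PC1", "PC2"))
  expect_equal(cv$significant, cv$p < 0.05)
  r1 <- cv$r[cv$variable == "V1" & cv$component == "PC1"]
  expect_equal(abs(r1), abs(cor(x[, 1], pc$scores[, 1])))
})

test_that("univariate single-factor PERMANOVA equals classical ANOVA", {
  set.seed(21)
  for (i in 1:5) {
    y <- matrix(rnorm(12), 12, 1)
    g <- sample(rep(c("a", "b", "c"), 4))
    res <- aa_permanova(y, design = data.frame(fraction = g),
                        terms = "fraction", n_perm = 9, seed = 1)
    f_aov <- anova(lm(y ~ g))$`F value`[1]
    expect_equal(res$aov_table$pseudo_F[1], f_aov, tolerance = 1e-10)
  }
})

test_that("PERMANOVA partitions sums of squares exactly and matches vegan", {
  set.seed(4)
  m <- matrix(rnorm(12 * 6), 12, 6)
  des <- data.frame(fraction = rep(c("host", "symbiont"), each = 6),
                    treatment = rep(c("L-NF", "L-F", "D-F"), 4))
  res <- aa_permanova(m, design = des,
                      terms = c("fraction", "treatment",
                                "fraction:treatment"),
                      n_perm = 199, seed = 11)
  tab <- res$aov_table
  ss_terms <- sum(tab$SS[tab$term != "Total"])
  expect_equal(ss_terms, tab$SS[tab$term == "Total"], tolerance = 1e-6)
  expect_equal(sum(tab$R2[tab$term != "Total"]), 1, tolerance = 1e-9)
  expect_true(all(tab$p >= 1 / 200, na.rm = TRUE))
  # independent implementation: vegan::adonis2
  ad <- vegan::adonis2(dist(m) ~ fraction * treatment, data = des,
                       permutations = 199, by = "terms")
  expect_equal(tab$SS[1:3], ad$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(tab$pseudo_F[1:3], ad$F[1:3], tolerance = 1e-8)
  expect_equal(tab$df[1:4], ad$Df[1:4])
  # observed statistic invariant to sample reordering
  perm <- sample(12)
  res2 <- aa_permanova(m[perm, ], design = des[perm, ],
                       terms = c("fraction", "treatment",
                                 "fraction:treatment"),
                       n_perm = 9, seed = 1)
  expect_equal(res2$aov_table$pseudo_F[1:3], tab$pseudo_F[1:3],
               tolerance = 1e-10)
})

test_that("isotope transforms do not alter Euclidean PERMANOVA", {
  set.seed(9)
  m <- matrix(rnorm(10 * 4, mean = 8), 10, 4)  # positive "nitrogen" values
  des <- data.frame(fraction = rep(c("a", "b"), 5))
  f_none <- aa_permanova(m, des, terms = "fraction", n_perm = 9, seed = 1,
                         transform = "none")$aov_table$pseudo_F[1]
  f_shift <- aa_permanova(m, des, terms = "fraction", n_perm = 9, seed = 1,
                          transform = "shift_positive")$aov_table$pseudo_F[1]
  expect_equal(f_shift, f_none, tolerance = 1e-10)
  # all-negative carbon values: absolute value is a sign flip, distances keep
  neg <- -abs(matrix(rnorm(10 * 4, mean = 15), 10, 4))
  f_abs <- aa_permanova(neg, des, terms = "fraction", n_perm = 9, seed = 1,
                        transform = "abs")$aov_table$pseudo_F[1]
  f_raw <- aa_permanova(neg, des, terms = "fraction", n_perm = 9, seed = 1,
                        transform = "none")$aov_table$pseudo_F[1]
  expect_equal(f_abs, f_raw, tolerance = 1e-10)
})

test_that("exhaustive permutation matches a brute-force oracle", {
  set.seed(14)
  y <- matrix(rnorm(6), 6, 1)
  g <- rep(c("a", "b"), each = 3)
  res <- aa_permanova(y, design = data.frame(fraction = g),
                      terms = "fraction", n_perm = "exact")
  # oracle: classical one-way F over all 720 permutations of y
  f_stat <- function(yy) anova(lm(yy ~ g))$`F value`[1]
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  f_all <- apply(perms, 1, function(p) f_stat(y[p]))
  p_oracle <- mean(f_all >= f_stat(y) - 1e-12)
  expect_equal(res$aov_table$p[1], p_oracle, tolerance = 1e-12)
  expect_error(aa_permanova(matrix(rnorm(9), 9, 1),
                            design = data.frame(fraction = rep(c("a", "b",
                                                                 "c"), 3)),
                            terms = "fraction", n_perm = "exact"), "n <= 8")
})

test_that("PERMANOVA rejects degenerate designs and data", {
  m <- matrix(1, 6, 3)
  des <- data.frame(fraction = rep(c("a", "b"), each = 3))
  expect_error(aa_permanova(m, des, terms = "fraction", n_perm = 9, seed = 1),
               "degenerate")
  m2 <- matrix(rnorm(18), 6, 3)
  des2 <- data.frame(fraction = c("a", "a", "a", "a", "a", "b"))
  expect_error(aa_permanova(m2, des2, terms = "fraction", n_perm = 9,
                            seed = 1), "singleton")
  expect_error(aa_permanova(m2, des, terms = "fraction", n_perm = 9),
               "seed")
})

test_that("LDA separates classes and reports sign-invariant quantities", {
  tc <- make_two_class(n = 20, p = 4, sep = 10, seed = 5)
  fit <- lda_fit(tc$x, tc$labels)
  expect_equal(ncol(fit$scalings), 1)  # classes - 1
  expect_equal(fit$proportion_trace, 1)
  expect_equal(sum(fit$proportion_trace), 1)
  cv <- lda_loocv(tc$x, tc$labels)
  expect_equal(cv$overall, 1)
  expect_equal(unname(cv$per_class), c(1, 1))
  # duplicated variable column -> singularity unless ridged
  xdup <- cbind(tc$x, V5 = tc$x[, 1])
  expect_error(lda_fit(xdup, tc$labels), "singular")
  rfit <- lda_fit(xdup, tc$labels, ridge = 1e-3)
  expect_equal(rfit$proportion_trace[1], 1, tolerance = 1e-6)
  expect_equal(lda_loocv(xdup, tc$labels, ridge = 1e-3)$overall, 1)
  # class with a single member cannot be cross-validated
  expect_error(lda_fit(tc$x[1:21, ], c(rep("a", 20), "b")), "fewer than 2")
})

test_that("permuted labels drop LOOCV success to chance", {
  tc <- make_two_class(n = 20, p = 4, sep = 10, seed = 5)
  set.seed(77)
  shuffled <- sample(tc$labels)
  cv <- lda_loocv(tc$x, shuffled)
  # binomial reference: 40 trials at p = 0.5 -> within [0.25, 0.75] w.h.p.
  expect_gt(cv$overall, 0.25)
  expect_lt(cv$overall, 0.75)
})

test_that("LDA posteriors normalize and favor the nearest class mean", {
  tc <- make_two_class(n = 15, p = 3, sep = 6, seed = 2)
  fit <- lda_fit(tc$x, tc$labels, priors = "uniform")
  mu_a <- colMeans(tc$x[tc$labels == "a", ])
  pred <- lda_predict(fit, rbind(mu_a, tc$x[1:4, ]))
  post <- as.matrix(pred[, c("a", "b")])
  expect_equal(unname(rowSums(post)), rep(1, 5), tolerance = 1e-12)
  expect_equal(pred$class[1], "a")
  expect_gt(post[1, "a"], 0.5)
  # coarse group mapping and panel mismatch
  mapped <- lda_predict(fit, tc$x[1:2, ],
                        coarse_map = c(a = "autotrophy", b = "heterotrophy"))
  expect_equal(mapped$group, c("autotrophy", "autotrophy"))
  bad <- tc$x[1:2, 1:2]
  expect_error(lda_predict(fit, bad), "V3")
})

test_that("mean-normalized panels keep their expected rank deficiency usable", {
  # rows sum to zero after normalization; the standard fingerprint workflow
  # must still fit, cross-validate and predict
  tc <- make_two_class(n = 10, p = 5, sep = 0, sd = 0.5, seed = 31)
  x <- tc$x
  x[tc$labels == "b", 1] <- x[tc$labels == "b", 1] + 6  # pattern difference
  fp <- mean_normalize(x)
  fit <- lda_fit(fp, tc$labels)
  expect_equal(lda_loocv(fp, tc$labels)$overall, 1)
  expect_equal(lda_predict(fit, fp)$class, tc$labels)
})

test_that("SD ellipses follow the covariance eigenstructure", {
  set.seed(10)
  iso <- matrix(rnorm(4000), 2000, 2)
  ell <- sd_ellipse(iso, level = 0.90)
  expect_equal(ell$semi_axes[1] / ell$semi_axes[2], 1, tolerance = 0.1)
  expect_false(ell$degenerate)
  # level -> 0 collapses toward the centroid
  tiny <- sd_ellipse(iso, level = 1e-8)
  expect_true(all(tiny$semi_axes < 0.01))
  expect_equal(tiny$center, colMeans(iso))
  # empirical coverage at level 0.90 (Monte-Carlo oracle)
  pts <- matrix(rnorm(2e5), 1e5, 2) %*% chol(matrix(c(2, 0.8, 0.8, 1), 2))
  cov90 <- mean(point_in_ellipse(pts, sd_ellipse(pts, level = 0.90)))
  expect_equal(cov90, 0.90, tolerance = 0.01)
  expect_error(sd_ellipse(iso[1:2, ]), "3 points")
  degen <- cbind(1:5, 2 * (1:5))
  expect_true(sd_ellipse(degen)$degenerate)
})

test_that("two-factor linear models report terms and Tukey contrasts", {
  # identical group means, balanced design -> F = 0, p = 1
  fraction <- rep(c("host", "symbiont"), each = 6)
  treatment <- rep(rep(c("L-NF", "L-F", "D-F"), each = 2), 2)
  y <- rep(c(-1, 1), 6)  # every cell mean is 0
  out <- two_factor_anova(y, fraction, treatment)
  expect_equal(out$anova$F[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(out$anova$p[1:2], c(1, 1), tolerance = 1e-12)
  expect_equal(nrow(out$tukey), 3)  # three pairwise treatment contrasts
  expect_true(all(out$tukey$p_adj > 0.99))
  # saturated design
  expect_error(two_factor_anova(rnorm(6), rep(c("a", "b"), 3),
                                rep(c("x", "y", "z"), each = 2),
                                interaction = TRUE), "saturated")
})

test_that("two-factor model holds its nominal type-I error", {
  set.seed(123)
  fraction <- rep(c("host", "symbiont"), each = 6)
  treatment <- rep(rep(c("L-NF", "L-F", "D-F"), each = 2), 2)
  reps <- 1000
  p_frac <- numeric(reps)
  for (i in seq_len(reps)) {
    out <- two_factor_anova(rnorm(12), fraction, treatment)
    p_frac[i] <- out$anova$p[1]
  }
  expect_equal(mean(p_frac < 0.05), 0.05, tolerance = 0.025)
})
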