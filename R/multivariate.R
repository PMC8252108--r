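# Multivariate machinery: mean-normalized fingerprints, correlation-matrix
# PCA, Euclidean PERMANOVA with seeded or exhaustive permutation, linear
# discriminant classification with LOOCV, SD ellipses, and per-amino-acid
# two-factor linear models.

#' Mean-normalize a fingerprint matrix
#'
#' Subtracts each sample's (row) mean from its values, removing baseline
#' spatiotemporal variability so amino acid patterns can be compared across
#' studies and locations. Normalized rows sum to zero; the operation is
#' idempotent and absorbs any per-sample constant shift.
#'
#' @param matrix A `sample_matrix` (or plain numeric matrix) with no missing
#'   cells.
#' @return The matrix with class `fingerprint_matrix`, attributes
#'   `normalized = TRUE` and `panel` (the column codes).
#' @export
mean_normalize <- function(matrix) {
  m <- unclass(matrix)
  if (anyNA(m)) {
    stop("masked (missing) cells in the selected panel; drop or subset first",
         call. = FALSE)
  }
  out <- m - rowMeans(m)
  structure(out, element = attr(matrix, "element"),
            metadata = attr(matrix, "metadata"),
            normalized = TRUE, panel = colnames(m),
            class = c("fingerprint_matrix", "matrix", "array"))
}

#' Principal component analysis of scaled, centered values
#'
#' PCA of the correlation matrix: variables are centered and scaled to unit
#' variance before eigendecomposition (via [stats::prcomp()]). Per-variable
#' Pearson correlations with the first two components are reported together
#' with a significance flag from the correlation t-test at `alpha`
#' (uncorrected).
#'
#' @param matrix Samples x variables numeric matrix, no missing cells.
#' @param alpha Significance level for correlation-vector flags.
#' @return A list of class `aa_pca`: `scores`, `loadings`,
#'   `variance_fraction`, `correlation_vectors`, `sdev`, `center`, `scale`.
#' @export
aa_pca <- function(matrix, alpha = 0.05) {
  m <- unclass(matrix)
  if (anyNA(m)) stop("masked cells present; PCA needs a complete matrix",
                     call. = FALSE)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("PCA needs at least 2 samples and 2 variables", call. = FALSE)
  }
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance variable(s): ",
         paste(colnames(m)[v == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- min(2, ncol(pc$x))
  cv <- do.call(rbind, lapply(seq_len(ncomp), function(j) {
    r <- apply(m, 2, function(col) stats::cor(col, pc$x[, j]))
    p <- apply(m, 2, function(col) stats::cor.test(col, pc$x[, j])$p.value)
    data.frame(variable = colnames(m), component = paste0("PC", j),
               r = unname(r), p = unname(p), significant = unname(p < alpha),
               stringsAsFactors = FALSE)
  }))
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = var_frac, correlation_vectors = cv,
                 sdev = pc$sdev, center = pc$center, scale = pc$scale),
            class = "aa_pca")
}

#' @export
print.aa_pca <- function(x, ...) {
  cat("<aa_pca> ", nrow(x$scores), " samples, ",
      length(x$variance_fraction), " components; first two explain ",
      sprintf("%.1f%%", 100 * sum(x$variance_fraction[1:min(2,
              length(x$variance_fraction))])), " of variance\n", sep = "")
  invisible(x)
}

# all permutations of 1:n, rows = permutations (identity first)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# sequential (Type I) projection matrices for a list of model terms
.term_hats <- function(design, terms) {
  n <- nrow(design)
  hats <- list(matrix(1 / n, n, n))  # intercept-only
  f <- "~ 1"
  for (term in terms) {
    f <- paste(f, "+", term)
    X <- stats::model.matrix(stats::as.formula(f), data = design)
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[length(hats) + 1]] <- tcrossprod(Q)
  }
  hats
}

#' PERMANOVA on Euclidean distances
#'
#' Permutational multivariate analysis of variance of a samples x variables
#' matrix. The (optionally transformed) values are converted to a Euclidean
#' distance matrix, Gower-centered, and partitioned by sequential (Type I)
#' hat-matrix projections over the requested terms. Pseudo-F per term is
#' tested by free permutation of observations; the p-value is
#' `(#\{F_perm >= F_obs\} + 1) / (n_perm + 1)` (or an exhaustive-enumeration
#' proportion when `n_perm = "exact"`, available for n <= 8).
#'
#' @param matrix Samples x variables numeric matrix (a `sample_matrix`
#'   carries its own metadata).
#' @param design Data.frame of factors, one row per sample. Defaults to the
#'   matrix's `metadata` attribute.
#' @param terms Character vector of model terms fitted sequentially, e.g.
#'   `c("fraction", "treatment", "fraction:treatment")`.
#' @param n_perm Number of random permutations (default 999), or `"exact"`
#'   for complete enumeration.
#' @param seed Integer seed for the permutation generator (required unless
#'   exact).
#' @param transform `"none"`, `"abs"` (absolute values, the carbon
#'   convention), or `"shift_positive"` (adds `-min + 1`, the nitrogen
#'   convention; a no-op for Euclidean distances, kept for fidelity to the
#'   reported workflow).
#' @return A list of class `permanova_result` with `aov_table` (per-term df,
#'   SS, R2, pseudo-F, p), `n_perm`, `seed`, `transform`.
#' @export
aa_permanova <- function(matrix, design = NULL,
                         terms = c("fraction", "treatment",
                                   "fraction:treatment"),
                         n_perm = 999, seed = NULL,
                         transform = c("none", "abs", "shift_positive")) {
  transform <- match.arg(transform)
  m <- unclass(matrix)
  if (anyNA(m)) stop("masked cells present", call. = FALSE)
  if (is.null(design)) design <- attr(matrix, "metadata")
  if (is.null(design)) stop("no design: supply `design` or use a ",
                            "sample_matrix with metadata", call. = FALSE)
  design <- as.data.frame(design)
  if (nrow(design) != nrow(m)) {
    stop("design rows must match matrix rows", call. = FALSE)
  }
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) {
    if (!v %in% names(design)) {
      stop("design lacks factor '", v, "'", call. = FALSE)
    }
    design[[v]] <- factor(design[[v]])
    if (any(table(design[[v]]) < 2)) {
      stop("factor '", v, "' has singleton group(s): ",
           paste(names(which(table(design[[v]]) < 2)), collapse = ", "),
           call. = FALSE)
    }
  }
  m <- switch(transform, none = m, abs = abs(m),
              shift_positive = m - min(m) + 1)
  n <- nrow(m)
  d2 <- as.matrix(stats::dist(m))^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  G <- ctr %*% (-0.5 * d2) %*% ctr
  ss_total <- sum(diag(G))
  if (ss_total <= 1e-12) {
    stop("degenerate input: total sum of squares is zero", call. = FALSE)
  }

  hats <- .term_hats(design, terms)
  dfs <- vapply(seq_along(terms), function(j) {
    sum(diag(hats[[j + 1]])) - sum(diag(hats[[j]]))
  }, numeric(1))
  dfs <- round(dfs)
  if (any(dfs < 1)) {
    stop("term(s) with zero degrees of freedom: ",
         paste(terms[dfs < 1], collapse = ", "), call. = FALSE)
  }
  H_full <- hats[[length(hats)]]
  df_res <- n - round(sum(diag(H_full)))
  if (df_res < 1) stop("zero residual degrees of freedom", call. = FALSE)
  # per-term difference projectors; tr(P G) = sum(P * G) for symmetric P, G
  P_terms <- lapply(seq_along(terms), function(j) hats[[j + 1]] - hats[[j]])
  P_res <- diag(n) - H_full

  stat_fun <- function(Gp) {
    ss <- vapply(P_terms, function(P) sum(P * Gp), numeric(1))
    ss_res <- sum(P_res * Gp)
    f <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_fun(G)

  exact <- identical(n_perm, "exact")
  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- .all_perms(n)
    f_perm <- t(apply(perms, 1, function(p) stat_fun(G[p, p])$f))
    f_perm <- matrix(f_perm, ncol = length(terms))
    p_val <- colMeans(sweep(f_perm, 2, obs$f - 1e-12, ">="))
    n_used <- nrow(perms)
  } else {
    if (is.null(seed)) stop("seed is required for random permutation",
                            call. = FALSE)
    n_perm <- as.integer(n_perm)
    if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    hits <- numeric(length(terms))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      fp <- stat_fun(G[p, p])$f
      hits <- hits + (fp >= obs$f - 1e-12)
    }
    p_val <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_F = c(obs$f, NA, NA),
    p = c(p_val, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(aov_table = tab, n_perm = n_used,
                 seed = if (exact) NA_integer_ else seed,
                 transform = transform, exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (Euclidean, ", if (x$exact) "exact enumeration" else
      paste0(x$n_perm, " permutations, seed ", x$seed),
      ", transform = ", x$transform, ")\n", sep = "")
  print(x$aov_table, row.names = FALSE, digits = 4)
  invisible(x)
}

.lda_prior <- function(labels, priors) {
  k <- nlevels(labels)
  if (identical(priors, "uniform")) rep(1 / k, k)
  else as.numeric(table(labels)) / length(labels)
}

.check_lda_input <- function(m, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  small <- table(labels) < 2
  if (any(small)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(which(small)), collapse = ", "), call. = FALSE)
  }
  if (anyNA(m)) stop("masked cells present", call. = FALSE)
  labels
}

# ridge-regularized discriminant decomposition (equal-covariance Gaussian):
# pooled within covariance W is inflated to W + ridge*tr(W)/p*I, then the
# between-class scatter is diagonalized in the whitened space; scalings give
# unit pooled within-class variance along each discriminant.
.ridge_lda <- function(m, labels, prior, ridge) {
  p <- ncol(m)
  k <- nlevels(labels)
  mu_g <- t(vapply(levels(labels),
                   function(g) colMeans(m[labels == g, , drop = FALSE]),
                   numeric(p)))
  W <- matrix(0, p, p)
  for (g in levels(labels)) {
    xg <- sweep(m[labels == g, , drop = FALSE], 2,
                mu_g[match(g, levels(labels)), ])
    W <- W + crossprod(xg)
  }
  W <- W / (nrow(m) - k)
  Wr <- W + diag(ridge * sum(diag(W)) / p, p)
  ew <- eigen(Wr, symmetric = TRUE)
  if (min(ew$values) <= 1e-10 * max(ew$values)) {
    stop("pooled within-class covariance is singular even after ridge",
         call. = FALSE)
  }
  Wih <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  mu <- colSums(mu_g * prior)
  B <- crossprod(sweep(mu_g, 2, mu) * sqrt(prior))
  eb <- eigen(Wih %*% B %*% Wih, symmetric = TRUE)
  r <- min(k - 1, p)
  scalings <- Wih %*% eb$vectors[, seq_len(r), drop = FALSE]
  colnames(scalings) <- paste0("LD", seq_len(r))
  rownames(scalings) <- colnames(m)
  ev <- pmax(eb$values[seq_len(r)], 0)
  list(scalings = scalings, prop_trace = ev / sum(ev), means = mu_g,
       Wr = Wr)
}

#' Fit a linear discriminant classifier
#'
#' Linear discriminant analysis of a (typically mean-normalized) fingerprint
#' matrix. With `ridge = 0` (default) the fit is delegated to
#' [MASS::lda()]; collinear variables (singular pooled covariance) raise an
#' error. With `ridge > 0` the pooled within-class covariance is inflated by
#' `ridge * trace(W)/p` on the diagonal before the discriminant
#' decomposition.
#'
#' @param matrix Samples x variables numeric matrix.
#' @param labels Class label per sample.
#' @param priors `"proportional"` (class frequencies, default) or
#'   `"uniform"`.
#' @param ridge Nonnegative ridge coefficient; 0 disables regularization.
#'
#' @details Mean-normalized fingerprints are rank-deficient by construction
#'   (every row sums to zero, so the panel columns are linearly dependent);
#'   for input carrying the `normalized` attribute this expected null
#'   direction is tolerated and the discriminant analysis proceeds in the
#'   reduced space, exactly as the standard fingerprinting workflow does.
#'   Collinearity in raw (un-normalized) input is treated as an error.
#' @return A list of class `aa_lda`: `scalings`, `class_means` (discriminant
#'   space), `prior`, `proportion_trace`, `levels`, `panel`, and (when
#'   `ridge = 0`) the underlying `MASS::lda` fit.
#' @export
lda_fit <- function(matrix, labels, priors = c("proportional", "uniform"),
                    ridge = 0) {
  priors <- match.arg(priors)
  normalized <- isTRUE(attr(matrix, "normalized"))
  m <- unclass(matrix)
  labels <- .check_lda_input(m, labels)
  prior <- .lda_prior(labels, priors)
  if (ridge == 0) {
    fit <- withCallingHandlers(
      MASS::lda(m, grouping = labels, prior = prior),
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w)) && !normalized) {
          stop("singular pooled within-class covariance (collinear ",
               "variables); set ridge > 0 to regularize, or mean-normalize ",
               "the panel if this is fingerprint data", call. = FALSE)
        }
        invokeRestart("muffleWarning")
      })
    scalings <- fit$scaling
    prop_trace <- fit$svd^2 / sum(fit$svd^2)
    class_means <- fit$means %*% scalings
  } else {
    fit <- NULL
    rl <- .ridge_lda(m, labels, prior, ridge)
    scalings <- rl$scalings
    prop_trace <- rl$prop_trace
    class_means <- rl$means %*% scalings
    rownames(class_means) <- levels(labels)
  }
  structure(list(mass_fit = fit, scalings = scalings,
                 class_means = class_means, prior = prior,
                 proportion_trace = unname(prop_trace),
                 levels = levels(labels), panel = colnames(m),
                 ridge = ridge,
                 training = if (ridge > 0) list(m = m, labels = labels)
                            else NULL),
            class = "aa_lda")
}

#' @export
print.aa_lda <- function(x, ...) {
  cat("<aa_lda> classes: ", paste(x$levels, collapse = ", "),
      "; LD1 proportion of trace: ",
      sprintf("%.3f", x$proportion_trace[1]), "\n", sep = "")
  invisible(x)
}

#' Predict class membership from a fitted discriminant model
#'
#' Equal-covariance Gaussian posteriors per class; the hard label is the
#' posterior argmax. An optional coarse-group map collapses classes into
#' nutrition groups (e.g. symbiont -> autotrophy, plankton/POM ->
#' heterotrophy).
#'
#' @param model An `aa_lda` fit.
#' @param matrix New samples x variables matrix over the model's panel.
#' @param coarse_map Optional named character vector `class = group`.
#' @return A data.frame with `sample`, `class`, one posterior column per
#'   class, and `group` when `coarse_map` is given.
#' @export
lda_predict <- function(model, matrix, coarse_map = NULL) {
  stopifnot(inherits(model, "aa_lda"))
  m <- unclass(matrix)
  if (is.null(colnames(m)) || !identical(colnames(m), model$panel)) {
    missing_vars <- setdiff(model$panel, colnames(m))
    if (length(missing_vars) > 0) {
      stop("panel mismatch; missing variable(s): ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    m <- m[, model$panel, drop = FALSE]
  }
  if (model$ridge == 0) {
    pr <- stats::predict(model$mass_fit, newdata = m)
    cls <- as.character(pr$class)
    post <- pr$posterior
  } else {
    rl <- .ridge_lda(model$training$m, model$training$labels, model$prior,
                     model$ridge)
    Wi <- solve(rl$Wr)
    mu_g <- rl$means
    disc <- m %*% Wi %*% t(mu_g) -
      matrix(rep(0.5 * diag(mu_g %*% Wi %*% t(mu_g)), each = nrow(m)),
             nrow = nrow(m)) +
      matrix(rep(log(model$prior), each = nrow(m)), nrow = nrow(m))
    disc <- disc - apply(disc, 1, max)
    post <- exp(disc) / rowSums(exp(disc))
    colnames(post) <- model$levels
    cls <- model$levels[max.col(post)]
  }
  out <- data.frame(sample = if (!is.null(rownames(m))) rownames(m)
                             else as.character(seq_len(nrow(m))),
                    class = cls, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(post))
  if (!is.null(coarse_map)) {
    unmapped <- setdiff(unique(cls), names(coarse_map))
    if (length(unmapped) > 0) {
      stop("coarse_map lacks class(es): ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    out$group <- unname(coarse_map[cls])
  }
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validated classification summary
#'
#' Each sample is classified by a discriminant model trained on all other
#' samples; per-class and overall success rates and the full confusion
#' matrix are returned.
#'
#' @inheritParams lda_fit
#' @return A list of class `lda_loocv`: `confusion` (true x predicted
#'   counts), `per_class` success rates, `overall` rate, `predicted` labels.
#' @export
lda_loocv <- function(matrix, labels, priors = c("proportional", "uniform"),
                      ridge = 0) {
  priors <- match.arg(priors)
  normalized <- isTRUE(attr(matrix, "normalized"))
  m <- unclass(matrix)
  labels <- .check_lda_input(m, labels)
  n <- nrow(m)
  pred <- character(n)
  for (i in seq_len(n)) {
    lab_i <- droplevels(labels[-i])
    if (nlevels(lab_i) < nlevels(labels)) {
      stop("leave-one-out fold ", i, " removes class '", labels[i],
           "' entirely", call. = FALSE)
    }
    fold <- m[-i, , drop = FALSE]
    if (normalized) attr(fold, "normalized") <- TRUE
    fit <- lda_fit(fold, lab_i, priors = priors, ridge = ridge)
    pred[i] <- lda_predict(fit, m[i, , drop = FALSE])$class
  }
  pred <- factor(pred, levels = levels(labels))
  confusion <- table(true = labels, predicted = pred)
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, per_class = per_class,
                 overall = mean(pred == labels), predicted = pred),
            class = "lda_loocv")
}

#' @export
print.lda_loocv <- function(x, ...) {
  cat(sprintf("LOOCV overall success: %.1f%%\n", 100 * x$overall))
  print(x$confusion)
  invisible(x)
}

#' Standard-deviation / confidence ellipse of a 2D point cloud
#'
#' Ellipse parameters from the eigenstructure of a group's 2D covariance,
#' scaled by `sqrt(qchisq(level, df = 2))` — the data (SD) ellipse
#' convention. Setting `kind = "mean"` rescales the covariance by 1/n for a
#' confidence ellipse of the group mean.
#'
#' @param points n x 2 matrix of scores.
#' @param level Coverage probability in (0, 1).
#' @param kind `"data"` (default) or `"mean"`.
#' @return A list of class `ellipse_params`: `center`, `semi_axes`, `angle`
#'   (radians, first axis vs. x), `level`, `degenerate`.
#' @export
sd_ellipse <- function(points, level = 0.90, kind = c("data", "mean")) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be n x 2", call. = FALSE)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  S <- stats::cov(points)
  if (kind == "mean") S <- S / nrow(points)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  degenerate <- any(e$values <= 1e-12 * max(abs(e$values), 1e-300))
  r <- sqrt(stats::qchisq(level, df = 2))
  structure(list(center = colMeans(points),
                 semi_axes = r * sqrt(vals),
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 level = level, kind = kind, degenerate = degenerate),
            class = "ellipse_params")
}

#' Two-factor linear model with Tukey post hoc contrasts
#'
#' Fixed-effects linear model of a per-sample scalar (an isotope value or
#' derived index) on tissue fraction and nutrition treatment (no interaction
#' by default), with Tukey HSD pairwise treatment contrasts.
#'
#' @param values Numeric response, one per sample.
#' @param fraction,treatment Factors, one value per sample.
#' @param interaction Include the fraction x treatment term.
#' @return A list with `anova` (per-term df, F, p) and `tukey` (pairwise
#'   treatment contrasts: estimate, CI, adjusted p).
#' @export
two_factor_anova <- function(values, fraction, treatment,
                             interaction = FALSE) {
  df <- data.frame(y = values, fraction = factor(fraction),
                   treatment = factor(treatment))
  form <- if (interaction) y ~ fraction * treatment else y ~ fraction + treatment
  fit <- stats::aov(form, data = df)
  if (stats::df.residual(fit) < 1) {
    stop("saturated design: no residual degrees of freedom", call. = FALSE)
  }
  a <- stats::anova(fit)
  aov_tab <- data.frame(term = rownames(a), df = a$Df, F = a$`F value`,
                        p = a$`Pr(>F)`, stringsAsFactors = FALSE)
  tk <- stats::TukeyHSD(fit, which = "treatment")$treatment
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(anova = aov_tab, tukey = tukey)
}
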