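# Scalar AA-CSIA trophic statistics: Glx-Phe trophic position with
# first-order error propagation, inverse-variance weighted mean d15N, the
# Sum-V resynthesis index, and the two-end-member percent-heterotrophy
# mixing model.

#' Trophic position parameters
#'
#' `beta` is the d15N spacing between glutamic acid and phenylalanine in
#' primary producers (3.4 permil by convention); `delta_tef` the per-trophic
#' -step enrichment of that spacing (7.6 permil). Their uncertainties default
#' to zero, in which case the propagated TP uncertainty carries only the
#' analytical replicate SDs of Glx and Phe.
#'
#' @param beta Producer Glx-Phe offset (permil).
#' @param delta_tef Trophic enrichment factor (permil), must be > 0.
#' @param sd_beta,sd_delta Standard deviations of `beta` and `delta_tef`.
#' @return A list of class `tp_params`.
#' @export
tp_params <- function(beta = 3.4, delta_tef = 7.6, sd_beta = 0, sd_delta = 0) {
  if (!is.finite(delta_tef) || delta_tef <= 0) {
    stop("delta_tef (trophic enrichment factor) must be > 0", call. = FALSE)
  }
  if (sd_beta < 0 || sd_delta < 0) {
    stop("sd_beta and sd_delta must be >= 0", call. = FALSE)
  }
  structure(list(beta = beta, delta_tef = delta_tef,
                 sd_beta = sd_beta, sd_delta = sd_delta),
            class = "tp_params")
}

#' Glx-Phe trophic position with propagated uncertainty
#'
#' Computes `tp = (d15N_Glx - d15N_Phe - beta) / delta_tef + 1` and its
#' first-order (delta-method) standard deviation
#' `sd = sqrt(sd_glx^2 + sd_phe^2 + sd_beta^2 + ((tp - 1) * sd_delta)^2) /
#' delta_tef`. At the default zero parameter uncertainty this reduces to
#' `sqrt(sd_glx^2 + sd_phe^2) / delta_tef`.
#'
#' @param d15n_glx,d15n_phe d15N of glutamic acid and phenylalanine (permil).
#' @param sd_glx,sd_phe Analytical replicate standard deviations (permil).
#' @param params A [tp_params()] object.
#' @return A list of class `trophic_position` with elements `tp`, `sd`,
#'   `inputs`, `params`. Vector inputs give vector `tp`/`sd`.
#' @examples
#' trophic_position(3.4, 0)       # tp = 1 (producer)
#' trophic_position(11.0, 0)      # tp = 2 (one trophic transfer)
#' trophic_position(10, 5, sd_glx = 0.3, sd_phe = 0.4)
#' @export
trophic_position <- function(d15n_glx, d15n_phe, sd_glx = 0, sd_phe = 0,
                             params = tp_params()) {
  stopifnot(inherits(params, "tp_params"))
  if (any(!is.finite(d15n_glx)) || any(!is.finite(d15n_phe))) {
    stop("d15N inputs must be finite", call. = FALSE)
  }
  if (any(sd_glx < 0) || any(sd_phe < 0)) {
    stop("analytical sds must be >= 0", call. = FALSE)
  }
  tp <- (d15n_glx - d15n_phe - params$beta) / params$delta_tef + 1
  sd <- sqrt(sd_glx^2 + sd_phe^2 + params$sd_beta^2 +
               ((tp - 1) * params$sd_delta)^2) / params$delta_tef
  structure(list(tp = tp, sd = sd,
                 inputs = list(d15n_glx = d15n_glx, d15n_phe = d15n_phe,
                               sd_glx = sd_glx, sd_phe = sd_phe),
                 params = params),
            class = "trophic_position")
}

#' @export
print.trophic_position <- function(x, ...) {
  cat("Trophic position (Glx-Phe): ",
      paste(sprintf("%.3f +/- %.3f", x$tp, x$sd), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Per-sample trophic positions from an isotope table
#'
#' @param table An `aa_table` holding nitrogen rows for Glx and Phe.
#' @param params A [tp_params()] object.
#' @return A data.frame with one row per sample: metadata, `tp` and `sd`.
#' @export
tp_by_sample <- function(table, params = tp_params()) {
  stopifnot(inherits(table, "aa_table"))
  n <- table[table$element == "N" & table$amino_acid %in% c("Glx", "Phe"), ]
  meta <- sample_metadata(table)
  rows <- lapply(meta$sample_id, function(id) {
    glx <- n[n$sample_id == id & n$amino_acid == "Glx", ]
    phe <- n[n$sample_id == id & n$amino_acid == "Phe", ]
    if (nrow(glx) != 1 || nrow(phe) != 1) {
      stop("sample '", id, "' lacks nitrogen Glx and/or Phe rows",
           call. = FALSE)
    }
    est <- trophic_position(glx$delta, phe$delta, glx$sd, phe$sd, params)
    data.frame(sample_id = id, tp = est$tp, sd = est$sd,
               stringsAsFactors = FALSE)
  })
  out <- merge(meta, do.call(rbind, rows), by = "sample_id", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Inverse-variance weighted mean d15N
#'
#' `sum(x / s^2) / sum(1 / s^2)`, weighting each amino acid by the inverse
#' of its analytical replicate variance.
#'
#' @param values d15N values (permil).
#' @param sds Replicate standard deviations, same length; must be > 0 unless
#'   `zero_sd = "substitute"`, which replaces zeros with the smallest
#'   positive sd present.
#' @param zero_sd `"error"` (default) or `"substitute"`.
#' @return The weighted mean (permil).
#' @examples
#' weighted_mean_d15n(c(5, 10), c(1, 1))   # 7.5
#' weighted_mean_d15n(c(5, 10), c(1, 2))   # 6.0
#' @export
weighted_mean_d15n <- function(values, sds, zero_sd = c("error", "substitute")) {
  zero_sd <- match.arg(zero_sd)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (length(values) != length(sds)) {
    stop("values and sds must have equal length", call. = FALSE)
  }
  if (any(sds < 0)) stop("sds must be >= 0", call. = FALSE)
  if (any(sds == 0)) {
    if (zero_sd == "error") {
      stop("sd of 0 gives infinite weight; use zero_sd = \"substitute\" ",
           "to replace zeros with the smallest positive sd", call. = FALSE)
    }
    pos <- sds[sds > 0]
    if (length(pos) == 0) stop("all sds are zero", call. = FALSE)
    sds[sds == 0] <- min(pos)
  }
  w <- 1 / sds^2
  sum(values * w) / sum(w)
}

#' Summed variance (Sum-V) of trophic amino acid d15N
#'
#' A per-sample index of heterotrophic microbial resynthesis: the mean
#' absolute deviation of trophic amino acid d15N values about their mean,
#' `sum(|x_i - mean(x)|) / n` over Ala, Leu, Pro, Asp, Glx by default. A
#' plain-variance mode is available behind `mode = "variance"`.
#'
#' @param table An `aa_table`.
#' @param sample_id Sample to evaluate.
#' @param aa_set Trophic amino acids entering the index.
#' @param mode `"mad"` (mean absolute deviation, default) or `"variance"`.
#' @return A list of class `sumv_result`: `sum_v`, `aa_used`, `deviations`.
#' @export
sum_v <- function(table, sample_id,
                  aa_set = c("Ala", "Leu", "Pro", "Asp", "Glx"),
                  mode = c("mad", "variance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "aa_table"))
  registry <- attr(table, "registry")
  if (is.null(registry)) registry <- aa_registry()
  aa_set <- check_aa_codes(aa_set, registry)
  n <- table[table$element == "N" & table$sample_id == sample_id &
               table$amino_acid %in% aa_set, ]
  absent <- setdiff(aa_set, n$amino_acid)
  if (length(absent) > 0) {
    stop("sample '", sample_id, "' is missing d15N for: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- n$delta[match(aa_set, n$amino_acid)]
  chi <- x - mean(x)
  sv <- if (mode == "mad") mean(abs(chi)) else stats::var(x)
  structure(list(sum_v = sv, aa_used = aa_set,
                 deviations = stats::setNames(chi, aa_set), mode = mode),
            class = "sumv_result")
}

#' Two-end-member heterotrophy mixing fraction
#'
#' Linear mass-balance mixing of an autotrophic and a heterotrophic trophic
#' position end-member: `f = (tp_mix - tp_auto) / (tp_het - tp_auto)`, with
#' the first-order (Phillips-Gregg) propagated variance
#' `var(f) = (sd_mix^2 + f^2 sd_het^2 + (1-f)^2 sd_auto^2) /
#' (tp_het - tp_auto)^2`. Fractions outside `[0, 1]` are returned unclamped
#' with `out_of_range = TRUE` (they flag data/end-member inconsistency).
#'
#' @param tp_mix A [trophic_position()] object, or a numeric TP value.
#' @param sd_mix SD of `tp_mix` when given numerically (ignored otherwise).
#' @param tp_auto,sd_auto Autotrophic end-member TP and SD.
#' @param tp_het,sd_het Heterotrophic end-member TP and SD.
#' @param scenario Label recorded with the estimate (`"detritivory"` for
#'   TP_het 2.0, `"zooplanktivory"` for 3.0, else `"custom"`).
#' @return A list of class `heterotrophy_estimate` with `fraction`,
#'   `percent`, `sd` (fraction scale), `sd_percent`, `scenario`,
#'   `endmembers`, `out_of_range`.
#' @examples
#' heterotrophy_fraction(2.0, tp_auto = 1, tp_het = 2)   # f = 1 (100%)
#' heterotrophy_fraction(1.5, tp_auto = 1, tp_het = 3)   # f = 0.25
#' @export
heterotrophy_fraction <- function(tp_mix, sd_mix = 0, tp_auto = 1.0,
                                  sd_auto = 0, tp_het = 2.0, sd_het = 0,
                                  scenario = NULL) {
  if (inherits(tp_mix, "trophic_position")) {
    sd_mix <- tp_mix$sd
    tp_mix <- tp_mix$tp
  }
  if (length(tp_mix) != 1) stop("tp_mix must be scalar", call. = FALSE)
  if (tp_het == tp_auto) {
    stop("degenerate end-members: tp_het must differ from tp_auto",
         call. = FALSE)
  }
  span <- tp_het - tp_auto
  f <- (tp_mix - tp_auto) / span
  sd_f <- sqrt(sd_mix^2 + f^2 * sd_het^2 + (1 - f)^2 * sd_auto^2) / abs(span)
  oor <- f < 0 || f > 1
  if (oor) {
    warning("mixing fraction ", sprintf("%.3f", f),
            " falls outside [0, 1]; end-members may not bracket the mixture",
            call. = FALSE)
  }
  if (is.null(scenario)) {
    scenario <- if (isTRUE(all.equal(tp_het, 2.0))) "detritivory"
                else if (isTRUE(all.equal(tp_het, 3.0))) "zooplanktivory"
                else "custom"
  }
  structure(list(fraction = f, percent = 100 * f, sd = sd_f,
                 sd_percent = 100 * sd_f, scenario = scenario,
                 endmembers = list(tp_auto = tp_auto, sd_auto = sd_auto,
                                   tp_het = tp_het, sd_het = sd_het),
                 out_of_range = oor),
            class = "heterotrophy_estimate")
}

#' @export
print.heterotrophy_estimate <- function(x, ...) {
  cat(sprintf("Heterotrophy (%s): %.1f%% +/- %.1f%%%s\n", x$scenario,
              x$percent, x$sd_percent,
              if (x$out_of_range) " [outside 0-100%]" else ""))
  invisible(x)
}

#' Percent-heterotrophy scenario grid
#'
#' Crosses per-sample trophic positions with heterotrophic end-member
#' scenarios (detritivory TP 2.0 and zooplanktivory TP 3.0 by default) and
#' returns per-sample mixing fractions plus group mean +/- SD summaries by
#' fraction and treatment.
#'
#' @param tp_table Output of [tp_by_sample()] (columns `sample_id`, `tp`,
#'   `sd`, plus metadata).
#' @param tp_het Numeric vector of heterotrophic end-member TPs.
#' @param sd_het SDs for `tp_het` (recycled).
#' @param tp_auto,sd_auto Autotrophic end-member TP and SD.
#' @return A list with `estimates` (per sample x scenario data.frame) and
#'   `summary` (group mean +/- SD of percent heterotrophy).
#' @export
scenario_table <- function(tp_table, tp_het = c(2.0, 3.0), sd_het = 0,
                           tp_auto = 1.0, sd_auto = 0) {
  if (!is.data.frame(tp_table) || nrow(tp_table) == 0) {
    stop("tp_table must be a nonempty data.frame of per-sample TPs",
         call. = FALSE)
  }
  stopifnot(all(c("sample_id", "tp", "sd") %in% names(tp_table)))
  sd_het <- rep_len(sd_het, length(tp_het))
  grid <- expand.grid(i = seq_len(nrow(tp_table)), s = seq_along(tp_het))
  est <- lapply(seq_len(nrow(grid)), function(k) {
    i <- grid$i[k]; s <- grid$s[k]
    h <- suppressWarnings(
      heterotrophy_fraction(tp_table$tp[i], tp_table$sd[i],
                            tp_auto = tp_auto, sd_auto = sd_auto,
                            tp_het = tp_het[s], sd_het = sd_het[s]))
    data.frame(sample_id = tp_table$sample_id[i],
               scenario = h$scenario, tp_het = tp_het[s],
               fraction = h$fraction, percent = h$percent,
               sd_percent = h$sd_percent, out_of_range = h$out_of_range,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, est)
  meta_cols <- intersect(c("fraction", "treatment", "study", "genet"),
                         names(tp_table))
  if (length(meta_cols) > 0) {
    meta <- tp_table[, c("sample_id", meta_cols), drop = FALSE]
    names(meta)[names(meta) == "fraction"] <- "tissue_fraction"
    est <- merge(meta, est, by = "sample_id", sort = FALSE)
  }
  group_cols <- intersect(c("tissue_fraction", "treatment"), names(est))
  summary <- NULL
  if (length(group_cols) > 0) {
    summary <- stats::aggregate(
      est["percent"],
      by = c(est[group_cols], list(scenario = est$scenario)),
      FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    summary <- do.call(data.frame, summary)
    names(summary) <- sub("^percent\\.", "percent_", names(summary))
  }
  list(estimates = est, summary = summary)
}
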