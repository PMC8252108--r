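# Synthetic AA-isotope dataset generator. Emulates the statistical structure
# of a coral host / Symbiodiniaceae symbiont / plankton feeding experiment:
# producer-like Glx-Phe spacing (TP ~ 1) in host and symbiont, consumer-like
# spacing (TP ~ 2) in plankton, plankton offset ~ -5.5 permil in d13C and
# ~ +2.5 permil in d15N relative to the host, triplicate analytical noise.
# The noise model is independent Gaussian per amino acid per replicate, with
# an optional common per-sample baseline shift (what mean-normalization
# removes).

.validate_synthetic_config <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$groups) == 0) stop("config has no groups", call. = FALSE)
  if (any(unlist(config$analytical_sd) <= 0)) {
    stop("analytical_sd must be > 0", call. = FALSE)
  }
  if (config$baseline_sd < 0) stop("baseline_sd must be >= 0", call. = FALSE)
  if (config$n_rep < 2) {
    stop("n_rep must be >= 2 (replicate sd is otherwise undefined)",
         call. = FALSE)
  }
  if (any(config$tp < 0)) stop("TP targets must be >= 0", call. = FALSE)
  for (g in names(config$groups)) {
    for (el in c("d13c_means", "d15n_means")) {
      mu <- config[[el]][[g]]
      if (is.null(mu) || !identical(sort(names(mu)), sort(config$aa_codes))) {
        stop("group '", g, "' lacks complete ", el, " over the configured ",
             "amino acids", call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Construct a synthetic dataset configuration
#'
#' Low-level constructor; most users want [synthetic_preset()]. Group means
#' are per-amino-acid named vectors; groups listed in `groups` with a
#' `treatments` element are replicated as genet x treatment, others as `n`
#' independent samples.
#'
#' @param aa_codes Amino acid codes measured per sample.
#' @param d13c_means,d15n_means Named lists (per group) of named numeric
#'   vectors (per amino acid) of latent means (permil).
#' @param tp Named numeric of target trophic positions per group (encoded in
#'   the Glx-Phe spacing of `d15n_means`; carried as ground truth).
#' @param groups Named list; each element a list with `fraction` (tissue
#'   fraction label), `n` (samples, or genets per treatment), and optional
#'   `treatments` (character vector).
#' @param treatment_effects Data.frame with columns `treatment`, `element`,
#'   `amino_acid`, `shift` (permil) added to latent means.
#' @param analytical_sd Replicate (injection) SD, scalar or named per amino
#'   acid (permil); must be > 0.
#' @param n_rep Replicates per measurement (>= 2).
#' @param baseline_sd SD of an optional common per-sample shift applied to
#'   all amino acids of one element (permil); 0 disables it.
#' @param beta,delta_tef TP parameters the spacings were built from.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(aa_codes, d13c_means, d15n_means, tp, groups,
                             treatment_effects = NULL, analytical_sd = 0.3,
                             n_rep = 3, baseline_sd = 0, beta = 3.4,
                             delta_tef = 7.6) {
  if (is.null(treatment_effects)) {
    treatment_effects <- data.frame(treatment = character(),
                                    element = character(),
                                    amino_acid = character(),
                                    shift = numeric(),
                                    stringsAsFactors = FALSE)
  }
  cfg <- structure(list(aa_codes = check_aa_codes(aa_codes),
                        d13c_means = d13c_means, d15n_means = d15n_means,
                        tp = tp, groups = groups,
                        treatment_effects = treatment_effects,
                        analytical_sd = analytical_sd, n_rep = n_rep,
                        baseline_sd = baseline_sd, beta = beta,
                        delta_tef = delta_tef),
                   class = "synthetic_config")
  .validate_synthetic_config(cfg)
  cfg
}

#' Default synthetic configuration: coral-symbiont-plankton experiment
#'
#' Encodes the study conditions the rest of the package is exercised
#' against: 13 measured amino acids; host d13C_AA means spanning -24.3 to
#' -8.1 permil with symbiont values 0 to ~2.5 permil lower; plankton
#' d13C_AA on average 5.5 permil below the host with per-amino-acid
#' variation (so mean-normalized fingerprints differ in pattern, not just
#' baseline); host and symbiont at trophic position 1.0 (Glx - Phe = beta =
#' 3.4 permil) and plankton at 2.0 (spacing beta + delta = 11.0 permil) with
#' the remaining plankton d15N_AA + 2.5 permil above the host; three
#' nutrition treatments (L-NF, L-F, D-F) x two genets for host and symbiont;
#' one pooled plankton sample; triplicate analytical SD 0.3 permil.
#'
#' @param n_plankton Number of plankton samples (1 mirrors a pooled tow
#'   sample; raise it for analyses needing plankton replication).
#' @param analytical_sd,n_rep,baseline_sd See [synthetic_config()].
#' @return A `synthetic_config`.
#' @examples
#' cfg <- synthetic_preset()
#' cfg$d15n_means$host["Glx"] - cfg$d15n_means$host["Phe"]      # 3.4
#' cfg$d15n_means$plankton["Glx"] - cfg$d15n_means$plankton["Phe"] # 11.0
#' @export
synthetic_preset <- function(n_plankton = 1, analytical_sd = 0.3, n_rep = 3,
                             baseline_sd = 0) {
  aa <- aa_set("measured13")
  host_c <- c(Ala = -17.5, Asp = -15.5, Glx = -12.5, Gly = -9.0,
              Ile = -19.0, Leu = -24.0, Lys = -14.5, Phe = -22.0,
              Pro = -14.0, Ser = -10.5, Thr = -12.0, Tyr = -20.5,
              Val = -21.0)
  # host minus symbiont differences (host mostly higher)
  hs_diff <- c(Ala = 1.5, Asp = 1.0, Glx = 2.0, Gly = 2.5, Ile = 0.3,
               Leu = 0.2, Lys = -0.3, Phe = 0.1, Pro = 1.5, Ser = 0.4,
               Thr = 0.6, Tyr = -0.5, Val = 0.2)
  # plankton offsets below host, mean 5.5, per-AA pattern variation
  pk_off <- c(Ala = 6.5, Asp = 5.0, Glx = 4.5, Gly = 3.0, Ile = 7.5,
              Leu = 8.0, Lys = 6.0, Phe = 4.0, Pro = 5.5, Ser = 3.5,
              Thr = 7.0, Tyr = 5.0, Val = 6.0)
  host_n <- c(Ala = 4.0, Asp = 3.5, Glx = 4.4, Gly = 2.0, Ile = 3.0,
              Leu = 3.8, Lys = 0.5, Phe = 1.0, Pro = 4.2, Ser = 1.5,
              Thr = -0.5, Tyr = 2.5, Val = 3.6)
  sym_n_off <- c(Ala = 0, Asp = -0.4, Glx = 0, Gly = 0.5, Ile = 0,
                 Leu = -0.5, Lys = 0, Phe = 0, Pro = -0.6, Ser = 0,
                 Thr = 0.4, Tyr = 0.8, Val = 0)
  plank_n <- host_n + 2.5
  plank_n["Glx"] <- plank_n["Phe"] + 11.0  # TP 2: beta + delta
  synthetic_config(
    aa_codes = aa,
    d13c_means = list(host = host_c, symbiont = host_c - hs_diff,
                      plankton = host_c - pk_off),
    d15n_means = list(host = host_n, symbiont = host_n + sym_n_off,
                      plankton = plank_n),
    tp = c(host = 1.0, symbiont = 1.0, plankton = 2.0),
    groups = list(
      host = list(fraction = "host", n = 2,
                  treatments = c("L-NF", "L-F", "D-F")),
      symbiont = list(fraction = "symbiont", n = 2,
                      treatments = c("L-NF", "L-F", "D-F")),
      plankton = list(fraction = "plankton", n = n_plankton)
    ),
    analytical_sd = analytical_sd, n_rep = n_rep, baseline_sd = baseline_sd
  )
}

.aa_sd <- function(config, code) {
  s <- config$analytical_sd
  if (length(s) == 1 && is.null(names(s))) return(s)
  if (!code %in% names(s)) {
    stop("analytical_sd lacks amino acid '", code, "'", call. = FALSE)
  }
  s[[code]]
}

#' Generate a synthetic isotope dataset
#'
#' For every sample x amino acid x element, draws `n_rep` replicates from
#' `Normal(latent mean + treatment effect + baseline shift, analytical sd)`
#' and collapses them to the replicate mean and SD (what a GC-IRMS triplicate
#' report looks like). Deterministic given `seed`; the exact latent structure
#' is returned as ground truth.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed.
#' @return A list with `table` (an `aa_table`) and `truth` (latent per-sample
#'   means, group TPs, treatment effects, baseline shifts, seed).
#' @export
generate_dataset <- function(config, seed) {
  .validate_synthetic_config(config)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  # enumerate samples
  samples <- list()
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    if (!is.null(grp$treatments)) {
      for (tr in grp$treatments) {
        for (i in seq_len(grp$n)) {
          samples[[length(samples) + 1]] <- list(
            sample_id = paste(g, paste0("g", i), tr, sep = "_"),
            group = g, fraction = grp$fraction, treatment = tr,
            genet = paste0("g", i))
        }
      }
    } else {
      for (i in seq_len(grp$n)) {
        samples[[length(samples) + 1]] <- list(
          sample_id = paste(g, i, sep = "_"),
          group = g, fraction = grp$fraction, treatment = NA_character_,
          genet = NA_character_)
      }
    }
  }

  eff <- config$treatment_effects
  codes <- config$aa_codes
  n_codes <- length(codes)
  n_rep <- config$n_rep
  sd_vec <- vapply(codes, function(code) .aa_sd(config, code), numeric(1))
  block <- 2 * n_codes  # rows per sample (C and N)
  n_rows <- length(samples) * block
  col_sample <- col_fraction <- col_treatment <- col_genet <-
    col_aa <- col_el <- character(n_rows)
  col_delta <- col_sd <- numeric(n_rows)
  latent <- vector("list", length(samples))
  names(latent) <- vapply(samples, `[[`, "", "sample_id")
  at <- 0
  for (s in samples) {
    shift <- c(C = 0, N = 0)
    if (config$baseline_sd > 0) {
      shift <- c(C = stats::rnorm(1, 0, config$baseline_sd),
                 N = stats::rnorm(1, 0, config$baseline_sd))
    }
    lat <- list(baseline = shift)
    for (el in c("C", "N")) {
      mu <- (if (el == "C") config$d13c_means[[s$group]]
             else config$d15n_means[[s$group]])[codes] + shift[[el]]
      if (!is.na(s$treatment) && nrow(eff) > 0) {
        hit <- eff$treatment == s$treatment & eff$element == el
        if (any(hit)) {
          add <- tapply(eff$shift[hit], eff$amino_acid[hit], sum)
          idx <- match(names(add), codes)
          mu[idx[!is.na(idx)]] <- mu[idx[!is.na(idx)]] + add[!is.na(idx)]
        }
      }
      lat[[el]] <- mu
      reps <- matrix(stats::rnorm(n_rep * n_codes, rep(mu, each = n_rep),
                                  rep(sd_vec, each = n_rep)),
                     nrow = n_rep)
      idx <- at + seq_len(n_codes)
      col_sample[idx] <- s$sample_id
      col_fraction[idx] <- s$fraction
      col_treatment[idx] <- s$treatment
      col_genet[idx] <- s$genet
      col_aa[idx] <- codes
      col_el[idx] <- el
      col_delta[idx] <- colMeans(reps)
      col_sd[idx] <- apply(reps, 2, stats::sd)
      at <- at + n_codes
    }
    latent[[s$sample_id]] <- lat
  }
  table <- aa_isotope_table(data.frame(
    sample_id = col_sample, fraction = col_fraction,
    treatment = col_treatment, genet = col_genet, amino_acid = col_aa,
    element = col_el, delta = col_delta, sd = col_sd, n_rep = n_rep,
    stringsAsFactors = FALSE))
  truth <- list(tp = config$tp, latent_means = latent,
                treatment_effects = eff, analytical_sd = config$analytical_sd,
                n_rep = config$n_rep, baseline_sd = config$baseline_sd,
                beta = config$beta, delta_tef = config$delta_tef,
                seed = seed)
  list(table = table, truth = truth)
}

#' Shift one group's trophic position in a configuration
#'
#' Raises the group's latent Glx d15N mean by `delta_tp * delta_tef`,
#' leaving Phe untouched, so the group's Glx-Phe trophic position moves by
#' `delta_tp`; the recorded target TP is updated accordingly. Used to build
#' power and recovery tests of the mixing model.
#'
#' @param config A `synthetic_config`.
#' @param group Group name present in the config.
#' @param delta_tp Trophic position shift (may be 0 or negative).
#' @return The modified `synthetic_config`.
#' @export
inject_trophic_shift <- function(config, group, delta_tp) {
  .validate_synthetic_config(config)
  if (!group %in% names(config$groups)) {
    stop("unknown group '", group, "'; configured groups: ",
         paste(names(config$groups), collapse = ", "), call. = FALSE)
  }
  config$d15n_means[[group]]["Glx"] <-
    config$d15n_means[[group]][["Glx"]] + delta_tp * config$delta_tef
  config$tp[[group]] <- config$tp[[group]] + delta_tp
  config
}

#' Write a synthetic dataset to a directory
#'
#' Generates a dataset and writes the standard long-format CSV, the ground
#' truth as JSON, and the configuration used as YAML.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named list of file paths.
#' @export
simulate_to_dir <- function(config, seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_dataset(config, seed)
  paths <- list(table = file.path(dir, "isotope_table.csv"),
                truth = file.path(dir, "ground_truth.json"),
                config = file.path(dir, "config.yaml"))
  write_isotope_table(gen$table, paths$table)
  jsonlite::write_json(.named_to_list(gen$truth), paths$truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(.config_to_plain(config), paths$config)
  invisible(paths)
}

# named atomic vectors serialize as JSON objects, not arrays
.named_to_list <- function(x) {
  if (is.list(x)) lapply(x, .named_to_list)
  else if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else x
}

.config_to_plain <- function(config) {
  plain <- unclass(config)
  plain$d13c_means <- lapply(plain$d13c_means, as.list)
  plain$d15n_means <- lapply(plain$d15n_means, as.list)
  plain$tp <- as.list(plain$tp)
  plain
}
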