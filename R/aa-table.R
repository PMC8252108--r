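# Long-format isotope tables and sample x amino-acid matrices.

FRACTION_LEVELS <- c("host", "symbiont", "holobiont", "plankton", "POM",
                     "microalgae")

#' Construct a validated amino acid isotope table
#'
#' The table is long format: one row per (sample, amino acid, element), with
#' the replicate mean `delta` (permil vs V-PDB for carbon, vs Air for
#' nitrogen), the replicate standard deviation `sd`, and the replicate count
#' `n_rep`. Sample metadata (`fraction`, and optionally `treatment`, `study`,
#' `genet`) travel as columns and must be constant within a sample.
#'
#' @param df A data.frame with columns `sample_id`, `fraction`,
#'   `amino_acid`, `element`, `delta`, `sd`, `n_rep` and optionally
#'   `treatment`, `study`, `genet`.
#' @param registry Amino acid registry; see [aa_registry()].
#' @return A data.frame of class `aa_table`.
#' @export
aa_isotope_table <- function(df, registry = aa_registry()) {
  required <- c("sample_id", "fraction", "amino_acid", "element", "delta",
                "sd", "n_rep")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("isotope table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$fraction <- as.character(df$fraction)
  df$element <- toupper(as.character(df$element))
  df$amino_acid <- check_aa_codes(df$amino_acid, registry)

  bad_fraction <- setdiff(unique(df$fraction), FRACTION_LEVELS)
  if (length(bad_fraction) > 0) {
    stop("unknown tissue fraction(s): ", paste(bad_fraction, collapse = ", "),
         "; allowed: ", paste(FRACTION_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$element %in% c("C", "N"))) {
    stop("element must be 'C' or 'N'", call. = FALSE)
  }
  for (col in c("delta", "sd", "n_rep")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))
      if (length(bad) > 0) {
        stop("unparseable numeric in column '", col, "' at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  if (any(!is.finite(df$delta))) {
    stop("non-finite delta value(s) at row(s): ",
         paste(utils::head(which(!is.finite(df$delta)), 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$sd < 0, na.rm = TRUE)) {
    stop("replicate sd must be >= 0", call. = FALSE)
  }
  if (any(df$n_rep < 1, na.rm = TRUE)) {
    stop("n_rep must be >= 1", call. = FALSE)
  }
  key <- paste(df$sample_id, df$amino_acid, df$element, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("sample_id", "amino_acid", "element")]
    stop("duplicate (sample_id, amino_acid, element) key(s), e.g. ",
         paste(dup[1, ], collapse = "/"), call. = FALSE)
  }
  # metadata must be constant within a sample
  meta_cols <- intersect(c("fraction", "treatment", "study", "genet"),
                         names(df))
  for (col in meta_cols) {
    n_per <- tapply(df[[col]], df$sample_id,
                    function(x) length(unique(as.character(x))))
    if (any(n_per > 1)) {
      stop("metadata column '", col, "' varies within sample(s): ",
           paste(names(n_per)[n_per > 1], collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("aa_table", "data.frame")
  attr(df, "registry") <- registry
  df
}

#' @export
print.aa_table <- function(x, ...) {
  cat("<aa_table> ", length(unique(x$sample_id)), " samples, ",
      length(unique(x$amino_acid)), " amino acids, ",
      nrow(x), " rows\n", sep = "")
  NextMethod()
}

#' Per-sample metadata of an isotope table
#'
#' @param table An `aa_table`.
#' @return One row per sample with its metadata columns.
#' @export
sample_metadata <- function(table) {
  meta_cols <- intersect(c("sample_id", "fraction", "treatment", "study",
                           "genet"), names(table))
  meta <- unique(as.data.frame(table)[, meta_cols, drop = FALSE])
  rownames(meta) <- NULL
  meta[order(meta$sample_id), , drop = FALSE]
}

#' Read an isotope table from CSV
#'
#' Expects RFC-4180 CSV (UTF-8, header row) in long format. Column names can
#' be remapped through `dialect`, a named list/vector mapping the canonical
#' names (`sample_id`, `fraction`, `amino_acid`, `element`, `delta`, `sd`,
#' `n_rep`, optionally `treatment`, `study`, `genet`) to the names used in
#' the file. Amino acid codes are case-normalized and `Glu` is aliased to
#' `Glx`.
#'
#' @param source Path to a CSV file or a connection.
#' @param dialect Optional named list: `canonical = "file column"`.
#' @param registry Amino acid registry.
#' @return An `aa_table`.
#' @examples
#' tab <- synthetic_preset() |> generate_dataset(seed = 1)
#' path <- tempfile(fileext = ".csv")
#' write_isotope_table(tab$table, path)
#' identical_table <- read_isotope_table(path)
#' @export
read_isotope_table <- function(source, dialect = NULL,
                               registry = aa_registry()) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    for (canonical in names(dialect)) {
      file_col <- dialect[[canonical]]
      if (!file_col %in% names(df)) {
        stop("dialect maps '", canonical, "' to missing column '",
             file_col, "'", call. = FALSE)
      }
      names(df)[names(df) == file_col] <- canonical
    }
  }
  aa_isotope_table(df, registry = registry)
}

#' Write an isotope table to CSV
#'
#' @param table An `aa_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(table, path) {
  stopifnot(inherits(table, "aa_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract a samples x amino acids matrix for one element
#'
#' Pulls the `delta` values for one element into a dense matrix with samples
#' as rows (in first-appearance order) and amino acids as columns (in
#' `aa_set` order). Cells absent from the table are `NA` (the explicit
#' missing mask). With `drop_missing_aa = TRUE`, amino acids missing in any
#' retained sample are dropped — this is how a five-AA panel is formed when
#' one study lacks lysine.
#'
#' @param table An `aa_table`.
#' @param element `"C"` or `"N"`.
#' @param aa_set Character vector of amino acid codes (column order).
#' @param fractions Optional tissue fractions to retain.
#' @param samples Optional sample ids to retain.
#' @param drop_missing_aa Drop columns with any missing value instead of
#'   erroring on sparse columns.
#' @return A numeric matrix of class `sample_matrix` with attributes
#'   `element` and `metadata` (per-sample metadata rows).
#' @export
subset_matrix <- function(table, element = c("C", "N"),
                          aa_set = NULL, fractions = NULL, samples = NULL,
                          drop_missing_aa = FALSE) {
  stopifnot(inherits(table, "aa_table"))
  element <- match.arg(element)
  registry <- attr(table, "registry")
  if (is.null(registry)) registry <- aa_registry()
  if (is.null(aa_set)) {
    aa_set <- sort(unique(table$amino_acid[table$element == element]))
  }
  aa_set <- check_aa_codes(aa_set, registry)
  df <- table[table$element == element, , drop = FALSE]
  if (!is.null(fractions)) df <- df[df$fraction %in% fractions, , drop = FALSE]
  if (!is.null(samples)) df <- df[df$sample_id %in% samples, , drop = FALSE]
  df <- df[df$amino_acid %in% aa_set, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("empty selection: no rows match element/amino acid/fraction filter",
         call. = FALSE)
  }
  ids <- unique(df$sample_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(aa_set),
              dimnames = list(ids, aa_set))
  m[cbind(match(df$sample_id, ids), match(df$amino_acid, aa_set))] <- df$delta
  if (drop_missing_aa) {
    keep <- colSums(is.na(m)) == 0
    if (!any(keep)) stop("all amino acid columns have missing values",
                         call. = FALSE)
    m <- m[, keep, drop = FALSE]
  } else {
    frac_missing <- colMeans(is.na(m))
    if (any(frac_missing > 0.5)) {
      stop(">50% missing values in column(s): ",
           paste(colnames(m)[frac_missing > 0.5], collapse = ", "),
           "; use drop_missing_aa = TRUE to drop them", call. = FALSE)
    }
  }
  meta <- sample_metadata(table)
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(m, element = element, metadata = meta,
            class = c("sample_matrix", "matrix", "array"))
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat("<sample_matrix> element ", attr(x, "element"), ", ",
      nrow(x), " samples x ", ncol(x), " amino acids\n", sep = "")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}
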