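# Amino acid classification registry.
#
# Two classification axes are carried for every amino acid:
#   * carbon:   essential / nonessential (dietary routing of carbon skeletons)
#   * nitrogen: trophic / source (15N enrichment per trophic transfer vs.
#               near-conservative baseline recorders)
# Glu and Gln are reported jointly as Glx after acid hydrolysis; Asp likewise
# absorbs Asn. Amino acids whose nitrogen behaviour is limited, unknown or
# "source-like" (Gly, Ser, Thr, Tyr, Arg) are binned as source.

.aa_registry_default <- function() {
  data.frame(
    code = c("Ala", "Arg", "Asp", "Glx", "Gly", "Ile", "Leu", "Lys",
             "Met", "Phe", "Pro", "Ser", "Thr", "Tyr", "Val"),
    full_name = c("alanine", "arginine", "aspartic acid", "glutamic acid",
                  "glycine", "isoleucine", "leucine", "lysine", "methionine",
                  "phenylalanine", "proline", "serine", "threonine",
                  "tyrosine", "valine"),
    carbon_class = c("nonessential", "nonessential", "nonessential",
                     "nonessential", "nonessential", "essential", "essential",
                     "essential", "essential", "essential", "nonessential",
                     "nonessential", "essential", "nonessential", "essential"),
    nitrogen_class = c("trophic", "source", "trophic", "trophic", "source",
                       "trophic", "trophic", "source", "source", "source",
                       "trophic", "source", "source", "source", "trophic"),
    stringsAsFactors = FALSE
  )
}

#' Amino acid classification registry
#'
#' Returns the registry of amino acids accepted by the package, with their
#' carbon-axis (essential/nonessential) and nitrogen-axis (trophic/source)
#' classifications. The default registry holds the 15 protein amino acids
#' routinely resolved by GC-IRMS after acid hydrolysis (Glu/Gln collapse to
#' Glx). The registry can be extended or re-binned, e.g. to move threonine
#' out of the source bin under an alternative convention.
#'
#' @param extra Optional `data.frame` with columns `code`, `full_name`,
#'   `carbon_class`, `nitrogen_class` appended to (or, for existing codes,
#'   replacing rows of) the default registry.
#' @return A `data.frame` with columns `code`, `full_name`, `carbon_class`,
#'   `nitrogen_class`; one row per amino acid.
#' @examples
#' aa_registry()
#' aa_registry(extra = data.frame(code = "His", full_name = "histidine",
#'   carbon_class = "essential", nitrogen_class = "source"))
#' @export
aa_registry <- function(extra = NULL) {
  reg <- .aa_registry_default()
  if (!is.null(extra)) {
    need <- c("code", "full_name", "carbon_class", "nitrogen_class")
    if (!is.data.frame(extra) || !all(need %in% names(extra))) {
      stop("`extra` must be a data.frame with columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    extra <- extra[, need, drop = FALSE]
    reg <- reg[!reg$code %in% extra$code, , drop = FALSE]
    reg <- rbind(reg, extra)
    rownames(reg) <- NULL
  }
  bad_c <- !reg$carbon_class %in% c("essential", "nonessential")
  bad_n <- !reg$nitrogen_class %in% c("trophic", "source")
  if (any(bad_c) || any(bad_n)) {
    stop("registry classes must be essential/nonessential (carbon) and ",
         "trophic/source (nitrogen); offending codes: ",
         paste(unique(reg$code[bad_c | bad_n]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reg$code)) {
    stop("duplicate amino acid codes in registry", call. = FALSE)
  }
  reg
}

# Case-normalize codes and apply hydrolysis aliases. Gln is rejected rather
# than aliased: a table holding Gln separately was not acid-hydrolysed the
# way the rest of the pipeline assumes.
normalize_aa_code <- function(code) {
  code <- as.character(code)
  norm <- paste0(toupper(substr(code, 1, 1)), tolower(substring(code, 2)))
  if (any(norm == "Gln")) {
    stop("amino acid code 'Gln' is not accepted: glutamine is converted to ",
         "glutamic acid during acid hydrolysis and must be reported as Glx",
         call. = FALSE)
  }
  norm[norm == "Glu"] <- "Glx"
  norm[norm == "Asn"] <- "Asp"
  norm
}

check_aa_codes <- function(codes, registry = aa_registry()) {
  codes <- normalize_aa_code(codes)
  unknown <- setdiff(unique(codes), registry$code)
  if (length(unknown) > 0) {
    stop("unknown amino acid code(s): ", paste(unknown, collapse = ", "),
         "; accepted codes are: ", paste(registry$code, collapse = ", "),
         call. = FALSE)
  }
  codes
}

#' Classify an amino acid on the carbon or nitrogen axis
#'
#' @param code Three-letter amino acid code (case-insensitive; `Glu` is
#'   aliased to `Glx`). Vectorized.
#' @param axis `"carbon"` (essential/nonessential) or `"nitrogen"`
#'   (trophic/source).
#' @param registry Registry data.frame, see [aa_registry()].
#' @return Character vector of class labels.
#' @examples
#' classify_amino_acid("Phe", "carbon")    # essential
#' classify_amino_acid("Gly", "nitrogen")  # source
#' classify_amino_acid("Glx", "nitrogen")  # trophic
#' @export
classify_amino_acid <- function(code, axis = c("carbon", "nitrogen"),
                                registry = aa_registry()) {
  axis <- match.arg(axis)
  code <- check_aa_codes(code, registry)
  col <- if (axis == "carbon") "carbon_class" else "nitrogen_class"
  registry[[col]][match(code, registry$code)]
}

#' Amino acid sets used throughout the analysis
#'
#' Named convenience selectors over the registry: the essential and trophic /
#' source bins, the six-member essential panel used for delta-13C
#' fingerprinting (Ile, Leu, Lys, Phe, Thr, Val), its five-member variant
#' without lysine, the default trophic set of the Sum-V index, and the
#' trophic/source sets of the weighted-mean baseline proxy.
#'
#' @param which One of `"essential"`, `"nonessential"`, `"trophic"`,
#'   `"source"`, `"eaa6"`, `"eaa5"`, `"sumv"`, `"wm_trophic"`, `"wm_source"`,
#'   `"measured13"`.
#' @param registry Registry data.frame.
#' @return Character vector of amino acid codes.
#' @export
aa_set <- function(which = c("essential", "nonessential", "trophic", "source",
                             "eaa6", "eaa5", "sumv", "wm_trophic",
                             "wm_source", "measured13"),
                   registry = aa_registry()) {
  which <- match.arg(which)
  switch(which,
    essential    = registry$code[registry$carbon_class == "essential"],
    nonessential = registry$code[registry$carbon_class == "nonessential"],
    trophic      = registry$code[registry$nitrogen_class == "trophic"],
    source       = registry$code[registry$nitrogen_class == "source"],
    eaa6         = c("Ile", "Leu", "Lys", "Phe", "Thr", "Val"),
    eaa5         = c("Ile", "Leu", "Phe", "Thr", "Val"),
    sumv         = c("Ala", "Leu", "Pro", "Asp", "Glx"),
    wm_trophic   = c("Ala", "Leu", "Glx"),
    wm_source    = c("Lys", "Phe"),
    measured13   = c("Ala", "Asp", "Glx", "Gly", "Ile", "Leu", "Lys",
                     "Phe", "Pro", "Ser", "Thr", "Tyr", "Val")
  )
}

#' Dump the registry as JSON
#'
#' @param registry Registry data.frame.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
registry_to_json <- function(registry = aa_registry(), path = NULL) {
  js <- jsonlite::toJSON(registry, dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
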