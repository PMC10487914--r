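# Design triage: prediction-confidence parsing (pLDDT / PAE), Rosetta
# InterfaceAnalyzer score-table parsing with SASA normalisation
# (dG_separated / dSASA x 100), and the confidence + binding-energy filters
# used to select a design.

#' Read a prediction-confidence JSON file
#'
#' Expects a JSON object with a per-residue `plddt` array on the 0-100 scale
#' and optionally a square pairwise `pae` matrix in Angstrom (non-negative,
#' zero diagonal).
#'
#' @param file Path to a JSON file.
#' @return Object of class `"prediction_confidence"`: list with `plddt`
#'   (numeric vector) and `pae` (N x N matrix or `NULL`).
#' @export
read_confidence <- function(file) {
  js <- tryCatch(jsonlite::fromJSON(file),
                 error = function(e) cyc_abort("format_error",
                   paste("cannot parse confidence JSON:", conditionMessage(e))))
  if (is.null(js$plddt)) {
    cyc_abort("format_error", "confidence JSON lacks a 'plddt' array")
  }
  plddt <- as.numeric(js$plddt)
  if (anyNA(plddt) || length(plddt) == 0L) {
    cyc_abort("format_error", "'plddt' must be a non-empty numeric array")
  }
  if (any(plddt < 0 | plddt > 100)) {
    cyc_abort("range_error", "pLDDT values must lie in [0, 100]")
  }
  pae <- NULL
  if (!is.null(js$pae)) {
    pae <- as.matrix(js$pae)
    n <- length(plddt)
    if (!is.numeric(pae) || nrow(pae) != n || ncol(pae) != n) {
      cyc_abort("format_error",
                sprintf("'pae' must be a %d x %d numeric matrix", n, n))
    }
    if (any(pae < 0) || any(abs(diag(pae)) > 1e-6)) {
      cyc_abort("format_error", "'pae' must be non-negative with zero diagonal")
    }
  }
  structure(list(plddt = plddt, pae = pae), class = "prediction_confidence")
}

#' Mean pLDDT over the peptide residues
#'
#' Design quality is judged on the peptide region only: the arithmetic mean
#' of per-residue pLDDT over the peptide's residue interval within the
#' complex, excluding the target protein.
#'
#' @param conf A `"prediction_confidence"`.
#' @param peptide_range Integer vector `c(first, last)`, 1-based inclusive
#'   residue interval of the peptide within the complex.
#' @return Mean pLDDT in `[0, 100]`.
#' @export
peptide_mean_plddt <- function(conf, peptide_range) {
  if (!inherits(conf, "prediction_confidence")) {
    cyc_abort("invalid_input", "conf must be a prediction_confidence object")
  }
  peptide_range <- as_strict_int(peptide_range, "peptide_range")
  if (length(peptide_range) != 2L || peptide_range[1] > peptide_range[2]) {
    cyc_abort("invalid_input", "peptide_range must be c(first, last) with first <= last")
  }
  if (peptide_range[1] < 1L || peptide_range[2] > length(conf$plddt)) {
    cyc_abort("invalid_input", "peptide_range outside the pLDDT array")
  }
  mean(conf$plddt[peptide_range[1]:peptide_range[2]])
}

#' Parse a Rosetta InterfaceAnalyzer score table
#'
#' Reads a whitespace-delimited score table (`SCORE:`-prefixed lines, or a
#' bare table) whose header names at least `dG_separated` and `dSASA_int`,
#' and computes the SASA-normalised interface score
#' `dG_separated / dSASA_int * 100` per record. Records with
#' `dSASA_int <= 0` are flagged and carry an undefined (`NA`) normalised
#' score; duplicate descriptions keep the last occurrence with a warning.
#'
#' @param file Path to the score file.
#' @return Data frame with columns `description`, `dG_separated`, `dSASA`,
#'   `normalized`, `flagged`.
#' @export
read_rosetta_scorefile <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "SEQUENCE:")]
  score <- grepl("^SCORE:", lines)
  if (any(score)) lines <- sub("^SCORE:", "", lines[score])
  fields <- strsplit(trimws(lines), "\\s+")
  if (length(fields) < 2L) {
    cyc_abort("format_error", "score file has no data lines")
  }
  header <- fields[[1]]
  for (col in c("dG_separated", "dSASA_int")) {
    if (!col %in% header) {
      cyc_abort("format_error", paste("score table lacks required column", col))
    }
  }
  rows <- fields[-1]
  if (any(lengths(rows) != length(header))) {
    cyc_abort("format_error", "score line field count does not match header")
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- header
  desc <- if ("description" %in% header) tab$description else
    sprintf("record_%03d", seq_len(nrow(tab)))
  dG <- suppressWarnings(as.numeric(tab$dG_separated))
  dS <- suppressWarnings(as.numeric(tab$dSASA_int))
  if (anyNA(dG) || anyNA(dS)) {
    cyc_abort("format_error", "non-numeric dG_separated or dSASA_int value")
  }
  if (anyDuplicated(desc)) {
    warning("duplicate description(s) in score file; keeping last occurrence",
            call. = FALSE)
    keep <- !duplicated(desc, fromLast = TRUE)
    desc <- desc[keep]; dG <- dG[keep]; dS <- dS[keep]
  }
  flagged <- dS <= 0
  normalized <- ifelse(flagged, NA_real_, dG / dS * 100)
  data.frame(description = desc, dG_separated = dG, dSASA = dS,
             normalized = normalized, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Triage designed binders by confidence and interface energy
#'
#' A design passes when its peptide-region mean pLDDT is strictly above
#' `plddt_min` and its SASA-normalised interface score is strictly below the
#' reference: the native complex's normalised score under
#' `energy_rule = "below_native"`, or zero under `"below_zero"` (the fallback
#' used when no design beats the native). Among passing designs the selected
#' one minimises `rmsd_best` (similarity to the native binding pose) or
#' `normalized` (interface energy), with ties broken by `design_id`
#' lexicographic order. An empty passing set is a valid result, not an error.
#'
#' @param records Data frame with columns `design_id`, `peptide_mean_plddt`,
#'   `normalized`, and `rmsd_best` (the latter required only for
#'   `selector = "lowest_rmsd_best"`). Records with `NA` `normalized`
#'   (flagged interface scores) never pass.
#' @param native_normalized The native complex's normalised interface score;
#'   required for `energy_rule = "below_native"`.
#' @param plddt_min pLDDT threshold, strict (default 70).
#' @param energy_rule `"below_native"` or `"below_zero"`.
#' @param selector `"lowest_rmsd_best"` or `"lowest_energy"`.
#' @return List with `passing` (data frame subset, original order) and
#'   `selected` (single-row data frame, or `NULL` when nothing passes).
#' @export
triage_designs <- function(records, native_normalized = NULL, plddt_min = 70,
                           energy_rule = c("below_native", "below_zero"),
                           selector = c("lowest_rmsd_best", "lowest_energy")) {
  energy_rule <- match.arg(energy_rule)
  selector <- match.arg(selector)
  need <- c("design_id", "peptide_mean_plddt", "normalized")
  if (!is.data.frame(records) || !all(need %in% names(records)) ||
      nrow(records) == 0L) {
    cyc_abort("invalid_input",
              "records must be a non-empty data frame with design_id, peptide_mean_plddt, normalized")
  }
  threshold <- if (energy_rule == "below_native") {
    if (is.null(native_normalized) || !is.finite(native_normalized)) {
      cyc_abort("invalid_input",
                "native_normalized is required for energy_rule = 'below_native'")
    }
    native_normalized
  } else 0
  ok <- records$peptide_mean_plddt > plddt_min &
    !is.na(records$normalized) & records$normalized < threshold
  passing <- records[ok, , drop = FALSE]
  if (nrow(passing) == 0L) {
    return(list(passing = passing, selected = NULL))
  }
  metric_col <- if (selector == "lowest_rmsd_best") "rmsd_best" else "normalized"
  if (!metric_col %in% names(passing) || anyNA(passing[[metric_col]])) {
    cyc_abort("invalid_input",
              sprintf("selector metric '%s' missing on a passing record", metric_col))
  }
  ord <- order(passing[[metric_col]], passing$design_id)
  list(passing = passing, selected = passing[ord[1L], , drop = FALSE])
}
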