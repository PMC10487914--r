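# Logo preparation: project each design's best window onto native peptide
# positions (gap-filled), then summarise surviving rows as per-column
# amino-acid frequencies, occupancy, and information content in bits.

#' Project a design sequence onto native positions via its best window
#'
#' Places the `W` design letters of the best window — taken cyclically from
#' the design sequence — at the native positions the window matched; every
#' other native position becomes `'-'`. Only the windowed letters contribute:
#' flanking design residues are not projected onto adjacent native positions.
#'
#' @param result An [`rmsd_best()`] result.
#' @param design_sequence Design peptide sequence (length `L_design`).
#' @param design_id Optional identifier carried into the row.
#' @return Object of class `"alignment_row"`: list with `design_id` and
#'   `padded` (string of length `L_native` over the 20 letters plus `'-'`).
#' @export
align_for_logo <- function(result, design_sequence, design_id = NULL) {
  if (!inherits(result, "rmsd_best_result")) {
    cyc_abort("invalid_input", "result must be an rmsd_best_result")
  }
  design_sequence <- toupper(as.character(design_sequence))
  if (nchar(design_sequence) != result$L_design) {
    cyc_abort("invalid_input", sprintf(
      "design sequence length %d does not match structure length %d",
      nchar(design_sequence), result$L_design))
  }
  letters_vec <- strsplit(design_sequence, "")[[1]]
  bad <- setdiff(letters_vec, c(AA1, "X"))
  if (length(bad)) {
    cyc_abort("invalid_input",
              paste("invalid sequence letter(s):", paste(bad, collapse = ", ")))
  }
  row <- rep("-", result$L_native)
  row[result$mapping[, "native_pos"]] <- letters_vec[result$mapping[, "design_pos"]]
  structure(list(design_id = design_id, padded = paste(row, collapse = "")),
            class = "alignment_row")
}

#' Build a logo matrix from gapped alignment rows
#'
#' Rows whose `RMSD_best` exceeds `rmsd_threshold` are dropped; the rest are
#' summarised per native column as gap-excluded amino-acid frequencies,
#' occupancy (fraction of rows contributing a letter), and information
#' content `R = log2(20) - H` in bits, where `H` is the Shannon entropy of
#' the gap-excluded frequencies. A fully conserved, gap-free column scores
#' `log2(20)` (about 4.32) bits; a uniform column scores 0. Columns with zero
#' occupancy carry `NA` bits. No small-sample entropy correction is applied.
#'
#' @param rows List of `"alignment_row"` objects, or a character vector of
#'   equal-length padded sequences.
#' @param rmsd_threshold Inclusion threshold in Angstrom (`<=`, default
#'   `Inf`: keep all rows).
#' @param rmsds Numeric `RMSD_best` per row; required when `rmsd_threshold`
#'   is finite.
#' @return Object of class `"logo_matrix"`: list with `freq` (L x 20
#'   matrix), `occupancy`, `bits` (length-L vectors), `n_rows` (surviving
#'   rows) and `L`. With zero surviving rows, `n_rows` is 0 and the
#'   components are empty/`NA` — an explicit empty logo.
#' @export
build_logo_matrix <- function(rows, rmsd_threshold = Inf, rmsds = NULL) {
  padded <- vapply(rows, function(r) {
    if (inherits(r, "alignment_row")) r$padded else as.character(r)
  }, character(1))
  if (length(padded) == 0L) cyc_abort("invalid_input", "no alignment rows")
  if (is.finite(rmsd_threshold)) {
    if (is.null(rmsds) || length(rmsds) != length(padded)) {
      cyc_abort("invalid_input", "rmsds must be given, one per row")
    }
    padded <- padded[rmsds <= rmsd_threshold]
  }
  L <- unique(nchar(padded))
  if (length(padded) == 0L) {
    return(structure(list(freq = matrix(numeric(), 0, 20,
                                        dimnames = list(NULL, AA1)),
                          occupancy = numeric(), bits = numeric(),
                          n_rows = 0L, L = 0L),
                     class = "logo_matrix"))
  }
  if (length(L) != 1L) cyc_abort("invalid_input", "rows differ in length")
  chars <- do.call(rbind, strsplit(padded, ""))
  bad <- setdiff(unique(as.vector(chars)), c(AA1, "-", "X"))
  if (length(bad)) {
    cyc_abort("invalid_input",
              paste("invalid alignment letter(s):", paste(bad, collapse = ", ")))
  }
  n <- nrow(chars)
  freq <- matrix(0, L, 20, dimnames = list(NULL, AA1))
  occupancy <- numeric(L)
  bits <- rep(NA_real_, L)
  for (col in seq_len(L)) {
    letters_here <- chars[, col]
    nongap <- letters_here[letters_here %in% AA1]
    occupancy[col] <- length(nongap) / n
    if (length(nongap) > 0L) {
      counts <- table(factor(nongap, levels = AA1))
      p <- as.numeric(counts) / length(nongap)
      freq[col, ] <- p
      H <- -sum(p[p > 0] * log2(p[p > 0]))
      bits[col] <- log2(20) - H
    }
  }
  structure(list(freq = freq, occupancy = occupancy, bits = bits,
                 n_rows = n, L = L),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("Logo matrix: %d columns from %d rows\n", x$L, x$n_rows))
  if (x$n_rows > 0L) {
    cat(sprintf("  bits range %.3f .. %.3f (max %.3f)\n",
                min(x$bits, na.rm = TRUE), max(x$bits, na.rm = TRUE), log2(20)))
  }
  invisible(x)
}

#' Write / read a gapped alignment as FASTA
#'
#' The FASTA uses `'-'` gaps and is directly usable by external logo
#' renderers.
#'
#' @param rows List of `"alignment_row"` objects (or padded strings).
#' @param file Output / input path.
#' @return `write_alignment()` returns `file` invisibly; `read_alignment()`
#'   returns a named character vector of padded sequences.
#' @export
write_alignment <- function(rows, file) {
  padded <- vapply(rows, function(r) {
    if (inherits(r, "alignment_row")) r$padded else as.character(r)
  }, character(1))
  ids <- vapply(seq_along(rows), function(k) {
    r <- rows[[k]]
    if (inherits(r, "alignment_row") && !is.null(r$design_id)) r$design_id
    else sprintf("row_%03d", k)
  }, character(1))
  seqinr::write.fasta(as.list(padded), names = ids, file.out = file,
                      nbchar = 10000)
  invisible(file)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(file) {
  fa <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  out <- toupper(vapply(fa, function(s) as.character(s)[1], character(1)))
  names(out) <- names(fa)
  out
}

# Amino-acid classes as commonly rendered in logos (hydrophilic / neutral /
# hydrophobic); emitted as metadata alongside the matrix.
AA_CLASSES <- list(
  hydrophilic = c("R", "K", "D", "E", "N", "Q"),
  neutral = c("S", "G", "H", "T", "A", "P"),
  hydrophobic = c("Y", "V", "M", "C", "L", "F", "I", "W")
)

#' Write a logo matrix as annotated TSV
#'
#' One data line per native column: `position`, the 20 per-letter
#' frequencies, `occupancy` and `bits`, preceded by `#` metadata (row count
#' and amino-acid colour classes). Floating point is fixed to 6 decimals.
#'
#' @param matrix A `"logo_matrix"`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_logo_matrix <- function(matrix, file) {
  if (!inherits(matrix, "logo_matrix")) {
    cyc_abort("invalid_input", "matrix must be a logo_matrix object")
  }
  meta <- c(
    paste0("# n_rows: ", matrix$n_rows),
    vapply(names(AA_CLASSES), function(cl) paste0(
      "# class ", cl, ": ", paste(AA_CLASSES[[cl]], collapse = ",")),
      character(1))
  )
  header <- paste(c("position", AA1, "occupancy", "bits"), collapse = "\t")
  data <- vapply(seq_len(matrix$L), function(col) {
    paste(c(col, sprintf("%.6f", matrix$freq[col, ]),
            sprintf("%.6f", matrix$occupancy[col]),
            if (is.na(matrix$bits[col])) "NA" else
              sprintf("%.6f", matrix$bits[col])),
          collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, data), file)
  invisible(file)
}
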