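# Shared helpers: amino-acid tables, classed error conditions, seeded RNG scope.

#' Canonical amino-acid alphabets
#'
#' `AA1` is the 20 canonical one-letter codes in alphabetical order; `AA321`
#' maps three-letter residue names (upper case) to one-letter codes.
#'
#' @keywords internal
#' @name aa-tables
NULL

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA321 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
           GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
           MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
           SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

AA123 <- structure(names(AA321), names = unname(AA321))

# Raise a classed condition so callers can distinguish failure modes.
# `class` is one of: invalid_input, format_error, missing_chain,
# correspondence, degenerate, range_error, usage.
cyc_abort <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("cycbinder_", class), "cycbinder_error",
              "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring global RNG state after.
# Keeps fixture generation deterministic without touching the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Coerce to integer, erroring (not warning) on non-integral values.
as_strict_int <- function(x, what = "value") {
  xn <- suppressWarnings(as.numeric(x))
  if (any(is.na(xn)) || any(xn != round(xn))) {
    cyc_abort("invalid_input", sprintf("%s must be integer-valued", what))
  }
  as.integer(round(xn))
}
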