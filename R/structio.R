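# PDB reading: per-chain Calpha traces and one-letter sequences, with the
# conventions used throughout the package: unknown or coordinate-less
# residues become 'X', first altloc by label is kept, first MODEL only.

#' Read a structure model from a PDB file
#'
#' Parses ATOM records (via bio3d) into a per-chain model holding author
#' residue numbering (with insertion codes), one-letter sequences and Calpha
#' coordinates. Residues with a nonstandard three-letter code, and residues
#' lacking a Calpha atom, are recorded as `'X'`; the latter carry `NA`
#' coordinates and are listed in the parse report. When a Calpha has
#' alternate locations, the first by altloc label is retained. HETATM records
#' and all but the first MODEL are ignored.
#'
#' @param file Path to a PDB-format file.
#' @param chains Optional character vector restricting (and ordering) the
#'   chains returned; an absent chain is an error.
#' @return Object of class `"structure_model"`: list with `chains` (named
#'   list; each chain a list with `resno`, `insert`, `resid`, `aa`, `xyz`
#'   (n x 3 matrix, `NA` rows where no Calpha), `missing_ca`), and `report`
#'   (data frame of parse issues).
#' @export
read_pdb_model <- function(file, chains = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                     rm.insert = FALSE, verbose = FALSE)),
    error = function(e) cyc_abort("format_error",
                                  paste("cannot parse PDB:", conditionMessage(e)))
  )
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    cyc_abort("format_error", "no ATOM records in PDB input")
  }
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""

  present <- unique(atoms$chain)
  if (is.null(chains)) {
    chains <- present
  } else {
    absent <- setdiff(chains, present)
    if (length(absent)) {
      cyc_abort("missing_chain",
                paste("chain(s) not in PDB:", paste(absent, collapse = ", ")))
    }
  }

  report <- list()
  model_chains <- list()
  for (ch in chains) {
    ca <- atoms[atoms$chain == ch & atoms$elety == "CA", , drop = FALSE]
    all_ch <- atoms[atoms$chain == ch, , drop = FALSE]
    key_all <- paste(all_ch$resno, all_ch$insert, sep = "|")
    keys <- unique(key_all[order(all_ch$resno, all_ch$insert)])
    n <- length(keys)
    resno <- integer(n); insert <- character(n)
    resid <- character(n); aa <- character(n)
    xyz <- matrix(NA_real_, n, 3L)
    missing_ca <- logical(n)
    key_ca <- paste(ca$resno, ca$insert, sep = "|")
    for (r in seq_len(n)) {
      first <- match(keys[r], key_all)
      resno[r] <- all_ch$resno[first]
      insert[r] <- all_ch$insert[first]
      resid[r] <- all_ch$resid[first]
      aa[r] <- if (resid[r] %in% names(AA321)) AA321[[resid[r]]] else "X"
      hit <- which(key_ca == keys[r])
      if (length(hit) == 0L) {
        aa[r] <- "X"
        missing_ca[r] <- TRUE
        report[[length(report) + 1L]] <- data.frame(
          chain = ch, resno = resno[r], insert = insert[r],
          issue = "missing_ca", stringsAsFactors = FALSE)
      } else {
        if (length(hit) > 1L) hit <- hit[order(ca$alt[hit])][1L]
        xyz[r, ] <- as.numeric(ca[hit, c("x", "y", "z")])
      }
    }
    model_chains[[ch]] <- list(resno = resno, insert = insert, resid = resid,
                               aa = aa, xyz = xyz, missing_ca = missing_ca)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(chain = character(), resno = integer(), insert = character(),
               issue = character(), stringsAsFactors = FALSE)
  structure(list(chains = model_chains, report = report, source = file),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model:", length(x$chains), "chain(s)\n")
  for (ch in names(x$chains)) {
    s <- model_sequence(x, ch)
    if (nchar(s) > 40) s <- paste0(substr(s, 1, 40), "...")
    cat(sprintf("  chain %s: %d residues  %s\n",
                ch, length(x$chains[[ch]]$aa), s))
  }
  if (nrow(x$report)) cat("  parse issues:", nrow(x$report), "\n")
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' @param model A `"structure_model"`.
#' @param chain Chain id.
#' @return Character scalar over the 20 canonical letters plus `'X'`.
#' @export
model_sequence <- function(model, chain) {
  paste(chain_of(model, chain)$aa, collapse = "")
}

#' Calpha coordinates of a chain
#'
#' @inheritParams model_sequence
#' @param drop_na Drop residues without a Calpha coordinate (default keeps
#'   them as `NA` rows so positions stay aligned with the sequence).
#' @return n x 3 numeric matrix of coordinates in Angstrom.
#' @export
ca_coords <- function(model, chain, drop_na = FALSE) {
  xyz <- chain_of(model, chain)$xyz
  if (drop_na) xyz <- xyz[stats::complete.cases(xyz), , drop = FALSE]
  xyz
}

chain_of <- function(model, chain) {
  if (!inherits(model, "structure_model")) {
    cyc_abort("invalid_input", "expected a structure_model object")
  }
  if (!chain %in% names(model$chains)) {
    cyc_abort("missing_chain", paste("no chain", chain, "in model"))
  }
  model$chains[[chain]]
}

#' Write a model's Calpha trace back to PDB
#'
#' Emits one CA ATOM record per residue that has a coordinate, for visual
#' inspection of aligned or transformed traces.
#'
#' @param model A `"structure_model"`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_model_pdb <- function(model, file) {
  resno <- integer(); resid <- character(); chain <- character()
  xyz <- numeric()
  for (ch in names(model$chains)) {
    cc <- model$chains[[ch]]
    keep <- stats::complete.cases(cc$xyz)
    resno <- c(resno, cc$resno[keep])
    resid <- c(resid, ifelse(cc$aa[keep] %in% names(AA123),
                             AA123[cc$aa[keep]], "UNK"))
    chain <- c(chain, rep(ch, sum(keep)))
    xyz <- c(xyz, as.vector(t(cc$xyz[keep, , drop = FALSE])))
  }
  bio3d::write.pdb(file = file, xyz = xyz, resno = resno, resid = resid,
                   chain = chain, elety = rep("CA", length(resno)),
                   o = rep(1, length(resno)), b = rep(0, length(resno)))
  invisible(file)
}
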