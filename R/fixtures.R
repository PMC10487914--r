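# Synthetic complexes, confidence files and score tables with known ground
# truth. The geometry emulates what the evaluation machinery needs — a
# helical protein Calpha trace plus a head-to-tail peptide ring with
# consecutive Calpha spacing of ~3.8 Angstrom — not physical backbones.

#' Calpha coordinates of an ideal head-to-tail peptide ring
#'
#' `L` points evenly spaced on a circle whose radius is chosen so every
#' adjacent Calpha pair — including the ring-closing last-to-first pair —
#' sits exactly 3.8 Angstrom apart. The ring is given a seeded random
#' orientation and centre so fixtures are not axis-aligned.
#'
#' @param L Ring length (>= 3 residues).
#' @param seed RNG seed (default 0).
#' @return L x 3 coordinate matrix.
#' @export
make_cyclic_peptide_coords <- function(L, seed = 0L) {
  L <- as_strict_int(L, "L")
  if (L < 3L) cyc_abort("invalid_input", "a ring needs at least 3 residues")
  radius <- 3.8 / (2 * sin(pi / L))
  theta <- 2 * pi * (seq_len(L) - 1L) / L
  ring <- cbind(radius * cos(theta), radius * sin(theta), 0)
  with_seed(seed, {
    R <- random_rotation()
    center <- stats::runif(3, -5, 5)
    sweep(ring %*% t(R), 2L, center, "+")
  })
}

# Uniform-ish random proper rotation from the QR decomposition of a
# Gaussian matrix, sign-fixed to det +1.
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Ideal alpha-helix Calpha trace: 2.3 A radius, 1.5 A rise, 100 deg/residue
# (consecutive Calpha distance ~3.8 A).
helix_coords <- function(n) {
  t <- seq_len(n) * 100 * pi / 180
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * seq_len(n))
}

#' Generate a native / predicted complex pair with known ground truth
#'
#' The native complex is a helical protein chain `A` plus a peptide chain
#' `B` (a head-to-tail ring for `peptide_topology = "cyclic"`, a straight
#' strand otherwise) placed beside it. The predicted complex is the native
#' with an optional rigid displacement applied to the peptide, then
#' independent Gaussian noise of standard deviation `noise_sigma` added to
#' every Calpha coordinate. The truth record retains the exact displacement
#' and noise so every downstream metric can be recomputed independently.
#'
#' @param protein_length,peptide_length Chain lengths in residues.
#' @param peptide_topology `"cyclic"` or `"linear"`.
#' @param noise_sigma Root-mean-square Calpha displacement in Angstrom
#'   (>= 0); implemented as isotropic Gaussian noise with per-coordinate
#'   standard deviation `noise_sigma / sqrt(3)`.
#' @param seed RNG seed; identical seeds give byte-identical fixtures.
#' @param peptide_displacement Optional rigid displacement of the predicted
#'   peptide: a numeric length-3 translation, or a list with `rotation`
#'   (3 x 3) and `translation`.
#' @param peptide_rotate_labels Rotate the predicted peptide's residue
#'   *labels* by this many positions (coordinates and sequence rotate
#'   together; the ring is unchanged as a set). Exercises invariance of
#'   cyclic evaluation to the arbitrary ring start.
#' @return List with `native` and `predicted` (character vectors of PDB
#'   text lines) and `truth` (list: sequences, coordinates, displacement,
#'   noise matrices, parameters).
#' @export
make_complex_pair <- function(protein_length = 20L, peptide_length = 13L,
                              peptide_topology = c("cyclic", "linear"),
                              noise_sigma = 0, seed = 0L,
                              peptide_displacement = NULL,
                              peptide_rotate_labels = 0L) {
  peptide_topology <- match.arg(peptide_topology)
  protein_length <- as_strict_int(protein_length, "protein_length")
  peptide_length <- as_strict_int(peptide_length, "peptide_length")
  if (protein_length < 3L || peptide_length < 3L) {
    cyc_abort("invalid_input", "chains must have at least 3 residues")
  }
  if (noise_sigma < 0) cyc_abort("invalid_input", "noise_sigma must be >= 0")

  prot <- helix_coords(protein_length)
  pep <- if (peptide_topology == "cyclic") {
    make_cyclic_peptide_coords(peptide_length, seed = seed)
  } else {
    cbind(3.8 * seq_len(peptide_length), 0, 0)
  }
  # park the peptide beside the helix
  pep <- sweep(pep, 2L, colMeans(pep), "-")
  pep <- sweep(pep, 2L, colMeans(prot) + c(12, 0, 0), "+")

  disp <- normalize_displacement(peptide_displacement)
  truth_seed <- seed + 1000L  # separate stream from ring orientation
  out <- with_seed(truth_seed, {
    prot_seq <- sample(AA1, protein_length, replace = TRUE)
    pep_seq <- sample(AA1, peptide_length, replace = TRUE)
    sd3 <- noise_sigma / sqrt(3)  # so E||noise||^2 = noise_sigma^2 per atom
    prot_noise <- matrix(stats::rnorm(3 * protein_length, sd = sd3), ncol = 3)
    pep_noise <- matrix(stats::rnorm(3 * peptide_length, sd = sd3), ncol = 3)
    list(prot_seq = prot_seq, pep_seq = pep_seq,
         prot_noise = prot_noise, pep_noise = pep_noise)
  })

  pred_prot <- prot + out$prot_noise
  pred_pep <- apply_transform(disp, pep) + out$pep_noise
  pred_pep_seq <- out$pep_seq
  rot <- as_strict_int(peptide_rotate_labels, "peptide_rotate_labels") %%
    peptide_length
  if (rot != 0L) {
    ord <- ((seq_len(peptide_length) - 1L + rot) %% peptide_length) + 1L
    pred_pep <- pred_pep[ord, , drop = FALSE]
    pred_pep_seq <- pred_pep_seq[ord]
  }

  native_txt <- pdb_text(list(A = list(seq = out$prot_seq, xyz = prot),
                              B = list(seq = out$pep_seq, xyz = pep)))
  pred_txt <- pdb_text(list(A = list(seq = out$prot_seq, xyz = pred_prot),
                            B = list(seq = pred_pep_seq, xyz = pred_pep)))
  list(
    native = native_txt, predicted = pred_txt,
    truth = list(
      protein_seq = paste(out$prot_seq, collapse = ""),
      peptide_seq = paste(out$pep_seq, collapse = ""),
      native_protein = prot, native_peptide = pep,
      predicted_protein = pred_prot, predicted_peptide = pred_pep,
      displacement = disp, protein_noise = out$prot_noise,
      peptide_noise = out$pep_noise, label_rotation = rot,
      noise_sigma = noise_sigma, seed = seed,
      peptide_topology = peptide_topology
    )
  )
}

normalize_displacement <- function(d) {
  if (is.null(d)) {
    list(rotation = diag(3), translation = c(0, 0, 0))
  } else if (is.numeric(d) && length(d) == 3L) {
    list(rotation = diag(3), translation = as.numeric(d))
  } else if (is.list(d) && !is.null(d$rotation) && !is.null(d$translation)) {
    list(rotation = as.matrix(d$rotation), translation = as.numeric(d$translation))
  } else {
    cyc_abort("invalid_input",
              "peptide_displacement must be a length-3 translation or list(rotation, translation)")
  }
}

# Format chains (named list of seq letters + n x 3 xyz) as PDB ATOM text
# via the standard writer, returning the text lines.
pdb_text <- function(chains) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  resno <- integer(); resid <- character(); chain <- character()
  xyz <- numeric()
  for (ch in names(chains)) {
    n <- length(chains[[ch]]$seq)
    resno <- c(resno, seq_len(n))
    resid <- c(resid, AA123[chains[[ch]]$seq])
    chain <- c(chain, rep(ch, n))
    xyz <- c(xyz, as.vector(t(chains[[ch]]$xyz)))
  }
  bio3d::write.pdb(file = tmp, xyz = round(xyz, 3), resno = resno,
                   resid = resid, chain = chain,
                   elety = rep("CA", length(resno)),
                   o = rep(1, length(resno)), b = rep(0, length(resno)))
  readLines(tmp)
}

#' Generate confidence JSONs and a Rosetta-style score table with a planted
#' triage outcome
#'
#' Writes one confidence JSON per design plus a score table (native record
#' included) into `dir`, with metrics constructed so the triage outcome is
#' known by construction. Under `scenario = "native_beatable"` a unique
#' planted winner passes the pLDDT > 70 / below-native filters and has both
#' the lowest `rmsd_best` and the lowest normalised energy among passers.
#' Under `scenario = "fallback"` no design beats the native score but a
#' known subset is below zero (the fallback rule's territory).
#'
#' @param n_designs Number of designs (>= 1).
#' @param seed RNG seed.
#' @param dir Output directory (created if needed).
#' @param protein_length,peptide_length Complex dimensions for the pLDDT
#'   arrays.
#' @param scenario `"native_beatable"` or `"fallback"`.
#' @return List with `score_file`, `confidence_files`, `records` (data frame
#'   ready for [`triage_designs()`]), `native_normalized`, `peptide_range`,
#'   and `truth` (planted winner ids and expected passing sets).
#' @export
make_score_fixtures <- function(n_designs, seed = 0L, dir = tempfile("scorefix"),
                                protein_length = 20L, peptide_length = 13L,
                                scenario = c("native_beatable", "fallback")) {
  scenario <- match.arg(scenario)
  n_designs <- as_strict_int(n_designs, "n_designs")
  if (n_designs < 1L) cyc_abort("invalid_input", "n_designs must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- protein_length + peptide_length
  pep_range <- c(protein_length + 1L, N)

  vals <- with_seed(seed, {
    ids <- sprintf("design_%02d", seq_len(n_designs))
    pep_plddt_mean <- stats::runif(n_designs, 55, 95)
    dSASA <- stats::runif(n_designs, 300, 900)
    native_norm <- if (scenario == "native_beatable") -2.0 else -5.0
    norm <- if (scenario == "native_beatable") {
      stats::runif(n_designs, native_norm - 1.5, native_norm + 1.5)
    } else {
      # nothing beats the native, but some land below zero
      stats::runif(n_designs, native_norm + 1, 1.5)
    }
    rmsd <- stats::runif(n_designs, 0.5, 6)
    winner <- sample(n_designs, 1L)
    if (scenario == "native_beatable") {
      # plant a unique winner under both selectors
      pep_plddt_mean[winner] <- 88
      norm[winner] <- native_norm - 2
      rmsd[winner] <- 0.4
    } else {
      pep_plddt_mean[winner] <- 88
      norm[winner] <- -1.4
      rmsd[winner] <- 0.4
    }
    jitter <- lapply(seq_len(n_designs), function(k)
      stats::runif(peptide_length, -2, 2))
    list(ids = ids, pep_plddt_mean = pep_plddt_mean, dSASA = dSASA,
         native_norm = native_norm, norm = norm, rmsd = rmsd,
         winner = winner, jitter = jitter)
  })

  conf_files <- vapply(seq_len(n_designs), function(k) {
    # protein residues get a fixed high confidence; peptide residues jitter
    # around the target mean with the jitter centred so the mean is exact
    pep_j <- vals$jitter[[k]] - mean(vals$jitter[[k]])
    pep <- vals$pep_plddt_mean[k] + pep_j
    plddt <- c(rep(90, protein_length), round(pep, 4))
    path <- file.path(dir, paste0(vals$ids[k], ".json"))
    jsonlite::write_json(list(plddt = plddt), path, auto_unbox = TRUE,
                         digits = NA)
    path
  }, character(1))

  dG <- vals$norm * vals$dSASA / 100
  native_dSASA <- 800
  native_dG <- vals$native_norm * native_dSASA / 100
  score_file <- file.path(dir, "scores.sc")
  header <- "SCORE:     total_score dG_separated dSASA_int description"
  fmt <- function(dg, ds, id) sprintf("SCORE: %14.3f %12.3f %9.3f %s",
                                      dg - 10, dg, ds, id)
  writeLines(c("SEQUENCE:", header,
               fmt(native_dG, native_dSASA, "native"),
               vapply(seq_len(n_designs), function(k)
                 fmt(dG[k], vals$dSASA[k], vals$ids[k]), character(1))),
             score_file)

  records <- data.frame(
    design_id = vals$ids,
    peptide_mean_plddt = vals$pep_plddt_mean,
    normalized = vals$norm,
    rmsd_best = vals$rmsd,
    stringsAsFactors = FALSE
  )
  pass_native <- vals$pep_plddt_mean > 70 & vals$norm < vals$native_norm
  pass_zero <- vals$pep_plddt_mean > 70 & vals$norm < 0
  list(
    score_file = score_file, confidence_files = conf_files,
    records = records, native_normalized = vals$native_norm,
    peptide_range = pep_range,
    truth = list(
      winner = vals$ids[vals$winner], scenario = scenario,
      passing_below_native = vals$ids[pass_native],
      passing_below_zero = vals$ids[pass_zero]
    )
  )
}
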