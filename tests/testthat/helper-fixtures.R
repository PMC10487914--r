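# Shared test machinery: fixture-to-model plumbing and independent oracles.
# Oracles are deliberately written against other code paths (bio3d fits,
# naive loops) than the implementations they check.

# Write a make_complex_pair() fixture to temp PDBs and read both models.
model_pair <- function(fx) {
  tn <- tempfile(fileext = ".pdb")
  tp <- tempfile(fileext = ".pdb")
  writeLines(fx$native, tn)
  writeLines(fx$predicted, tp)
  out <- list(native = read_pdb_model(tn), predicted = read_pdb_model(tp))
  unlink(c(tn, tp))
  out
}

# Write a fixture's PDB pair into `dir`, returning the two paths.
model_pair_files <- function(fx, dir) {
  paths <- list(native = file.path(dir, "native.pdb"),
                predicted = file.path(dir, "predicted.pdb"))
  writeLines(fx$native, paths$native)
  writeLines(fx$predicted, paths$predicted)
  paths
}

# Exhaustive windowed-minimum oracle: superposition through bio3d's
# least-squares fit, window scan and RMSD by naive per-point loops.
oracle_rmsd_best <- function(nat, prd, W = 6L, topology = "cyclic") {
  npr <- ca_coords(nat, "A"); npep <- ca_coords(nat, "B")
  ppr <- ca_coords(prd, "A"); ppep <- ca_coords(prd, "B")
  fixed <- as.vector(t(rbind(npr, npep)))
  mobile <- as.vector(t(rbind(ppr, ppep)))
  inds <- seq_len(3L * nrow(npr))
  moved <- bio3d::fit.xyz(fixed, mobile, fixed.inds = inds, mobile.inds = inds)
  mpep <- matrix(moved[-inds], ncol = 3, byrow = TRUE)
  Ln <- nrow(npep); Ld <- nrow(mpep)
  if (Ln < W) W <- Ln
  best <- Inf
  ds_max <- if (topology == "cyclic") Ld else Ld - W + 1L
  for (ns in seq_len(N <- Ln - W + 1L)) {
    for (ds in seq_len(ds_max)) {
      ss <- 0
      for (k in seq_len(W)) {
        ni <- ns + k - 1L
        di <- if (topology == "cyclic") ((ds + k - 2L) %% Ld) + 1L else ds + k - 1L
        ss <- ss + sum((npep[ni, ] - mpep[di, ])^2)
      }
      best <- min(best, sqrt(ss / W))
    }
  }
  best
}

# A seeded random proper rotation for constructing rigid-motion cases.
test_rotation <- function(seed) {
  set.seed(seed)
  q <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Minimal hand-written PDB ATOM line (Calpha) for parser edge cases.
atom_line <- function(serial, resid, chain, resno, x, y, z, alt = " ",
                      icode = " ", elety = "CA") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, elety, alt, resid, chain, resno, icode, x, y, z)
}
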