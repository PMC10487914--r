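# Rigid-body superposition (Kabsch, via SVD) and in-place RMSD. All RMSDs in
# this package are over Calpha atoms.

#' Optimal rigid superposition of paired point sets
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `reference` (centroid subtraction, SVD of the covariance, sign
#' correction to exclude reflections).
#'
#' @param mobile,reference n x 3 coordinate matrices in 1:1 row
#'   correspondence, n >= 3.
#' @return Object of class `"rigid_transform"`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3) and `rmsd`, the minimised RMSD in
#'   Angstrom. The transform maps x to `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  A <- as_coords(mobile); B <- as_coords(reference)
  if (nrow(A) != nrow(B)) {
    cyc_abort("invalid_input", "point sets must have equal length")
  }
  n <- nrow(A)
  if (n < 3L) cyc_abort("degenerate", "at least 3 point pairs are required")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2L, cA); Bc <- sweep(B, 2L, cB)
  # collinear point sets leave the rotation underdetermined
  for (M in list(Ac, Bc)) {
    d <- svd(M, nu = 0, nv = 0)$d
    if (d[2] <= 1e-8 * max(d[1], 1e-12)) {
      cyc_abort("degenerate", "points are collinear; superposition is underdetermined")
    }
  }
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  if (s == 0) s <- 1
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  tr <- as.numeric(cB - R %*% cA)
  fitted <- apply_transform(list(rotation = R, translation = tr), A)
  structure(list(rotation = R, translation = tr,
                 rmsd = rmsd_inplace(fitted, B)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `"rigid_transform"` (or list with `rotation`,
#'   `translation`).
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  X <- as_coords(coords)
  sweep(X %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform, fitted RMSD", sprintf("%.4f", x$rmsd), "Angstrom\n")
  invisible(x)
}

#' In-place Calpha RMSD (no refitting)
#'
#' Root mean squared distance between corresponding rows, with no
#' superposition — the windowed comparison deliberately measures deviation in
#' the frame fixed by the protein superposition.
#'
#' @param A,B n x 3 coordinate matrices, n >= 1.
#' @return RMSD in Angstrom.
#' @export
rmsd_inplace <- function(A, B) {
  A <- as_coords(A); B <- as_coords(B)
  if (nrow(A) != nrow(B)) {
    cyc_abort("invalid_input", "point sets must have equal length")
  }
  if (nrow(A) < 1L) cyc_abort("invalid_input", "empty point sets")
  sqrt(mean(rowSums((A - B)^2)))
}

as_coords <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 3L || !is.numeric(m)) {
    cyc_abort("invalid_input", "coordinates must be an n x 3 numeric matrix")
  }
  if (anyNA(m)) cyc_abort("invalid_input", "coordinates contain NA")
  m
}
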