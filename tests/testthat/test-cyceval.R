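test_that("window enumeration counts match the closed form", {
  expect_equal(nrow(enumerate_windows(13, 13, 6, "cyclic")), 104L)
  expect_equal(nrow(enumerate_windows(6, 6, 6, "cyclic")), 6L)
  expect_equal(nrow(enumerate_windows(13, 13, 10, "linear")), 16L)

  # property sweep: n_pairs formula over lengths and widths
  set.seed(31)
  for (rep in 1:40) {
    Ln <- sample(1:20, 1)
    Ld <- sample(1:20, 1)
    W <- sample(seq_len(min(Ln, Ld)), 1)
    for (topo in c("cyclic", "linear")) {
      p <- enumerate_windows(Ln, Ld, W, topo)
      expected <- (Ln - W + 1) * if (topo == "cyclic") Ld else Ld - W + 1
      expect_equal(nrow(p), expected)
      expect_true(all(p$native_start >= 1 & p$native_start <= Ln - W + 1))
      expect_false(any(duplicated(p)))
    }
  }
  expect_error(enumerate_windows(5, 13, 6, "cyclic"),
               class = "cycbinder_invalid_input")
  expect_error(enumerate_windows(13, 5, 6, "linear"),
               class = "cycbinder_invalid_input")
})

test_that("identical structures give RMSD_best ~ 0 on a diagonal window", {
  fx <- make_complex_pair(seed = 3)
  mp <- model_pair(fx)
  res <- rmsd_best(mp$native, mp$predicted, c(A = "A"), c(B = "B"))
  expect_lt(res$best$rmsd, 1e-3)  # only PDB coordinate rounding remains
  expect_equal(res$best$native_start, res$best$design_start)
  expect_equal(res$n_pairs, 104L)
  expect_equal(res$mapping[, "native_pos"], res$mapping[, "design_pos"],
               ignore_attr = TRUE)
})

test_that("RMSD_best is invariant to the design ring's start residue", {
  set.seed(77)
  for (s in 1:20) {
    fx0 <- make_complex_pair(seed = s, noise_sigma = 0.4)
    rot <- sample(0:12, 1)
    fxr <- make_complex_pair(seed = s, noise_sigma = 0.4,
                             peptide_rotate_labels = rot)
    m0 <- model_pair(fx0)
    mr <- model_pair(fxr)
    r0 <- rmsd_best(m0$native, m0$predicted, c(A = "A"), c(B = "B"))
    rr <- rmsd_best(mr$native, mr$predicted, c(A = "A"), c(B = "B"))
    expect_equal(rr$best$rmsd, r0$best$rmsd, tolerance = 1e-9)
  }
})

test_that("RMSD_best equals the exhaustive brute-force minimum", {
  for (s in 1:25) {
    fx <- make_complex_pair(seed = s, noise_sigma = 0.5)
    mp <- model_pair(fx)
    res <- rmsd_best(mp$native, mp$predicted, c(A = "A"), c(B = "B"))
    expect_equal(res$best$rmsd, oracle_rmsd_best(mp$native, mp$predicted),
                 tolerance = 1e-9)
    # the minimum never exceeds any diagonal window pair
    diag_rmsds <- res$pairs$rmsd[res$pairs$native_start == res$pairs$design_start]
    expect_lte(res$best$rmsd, min(diag_rmsds) + 1e-12)
  }
})

test_that("short native peptides shrink the window to their length", {
  fx <- make_complex_pair(peptide_length = 13, seed = 5)
  # use a 4-residue native by truncating the native peptide chain
  mp <- model_pair(fx)
  mp$native$chains$B <- lapply(mp$native$chains$B, function(x)
    if (is.matrix(x)) x[1:4, , drop = FALSE] else x[1:4])
  res <- rmsd_best(mp$native, mp$predicted, c(A = "A"), c(B = "B"), W = 6)
  expect_equal(res$best$width, 4L)
  expect_equal(res$n_pairs, 13L)  # 1 native window x 13 design rotations
  expect_equal(nrow(res$mapping), 4L)
})

test_that("window ties break to the smallest native then design start", {
  # two exactly tied window pairs constructed by duplicating rows
  pairs <- enumerate_windows(6, 6, 6, "cyclic")
  expect_equal(pairs$native_start[1], 1L)
  expect_equal(pairs$design_start[1], 1L)
  # a symmetric ring vs itself: every rotation-by-0 window ties at 0
  fx <- make_complex_pair(seed = 8)
  mp <- model_pair(fx)
  res <- rmsd_best(mp$native, mp$predicted, c(A = "A"), c(B = "B"), W = 13)
  expect_equal(res$best$native_start, 1L)
})

test_that("protein-chain count mismatches are correspondence errors", {
  fx1 <- make_complex_pair(protein_length = 20, seed = 1)
  fx2 <- make_complex_pair(protein_length = 18, seed = 1)
  m1 <- model_pair(fx1)
  m2 <- model_pair(fx2)
  expect_error(rmsd_best(m1$native, m2$predicted, c(A = "A"), c(B = "B")),
               class = "cycbinder_correspondence")
})

test_that("peptide RMSD modes recover a planted rigid displacement", {
  fx <- make_complex_pair(seed = 4, peptide_displacement = c(3, 0, 0))
  mp <- model_pair(fx)
  pa <- peptide_rmsd(mp$native, mp$predicted, c(A = "A"), c(B = "B"),
                     mode = "protein_aligned")
  pp <- peptide_rmsd(mp$native, mp$predicted, c(A = "A"), c(B = "B"),
                     mode = "peptide_aligned")
  expect_equal(pa, 3.0, tolerance = 1e-6)
  expect_equal(pp, 0.0, tolerance = 1e-6)

  ident <- model_pair(make_complex_pair(seed = 4))
  expect_lt(peptide_rmsd(ident$native, ident$predicted, c(A = "A"),
                         c(B = "B"), "protein_aligned"), 1e-3)
})

test_that("peptide-aligned RMSD never exceeds protein-aligned RMSD", {
  set.seed(55)
  for (s in 1:15) {
    fx <- make_complex_pair(seed = s, noise_sigma = runif(1, 0, 1),
                            peptide_displacement = rnorm(3))
    mp <- model_pair(fx)
    pa <- peptide_rmsd(mp$native, mp$predicted, c(A = "A"), c(B = "B"),
                       "protein_aligned")
    pp <- peptide_rmsd(mp$native, mp$predicted, c(A = "A"), c(B = "B"),
                       "peptide_aligned")
    expect_lte(pp, pa + 1e-9)
  }
})

test_that("larger peptide noise does not decrease expected RMSD_best", {
  mean_best <- function(sigma) {
    mean(vapply(1:50, function(s) {
      mp <- model_pair(make_complex_pair(seed = s, noise_sigma = sigma))
      rmsd_best(mp$native, mp$predicted, c(A = "A"), c(B = "B"))$best$rmsd
    }, numeric(1)))
  }
  expect_lt(mean_best(0.2), mean_best(0.6))
})
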