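write_conf <- function(plddt, pae = NULL) {
  f <- tempfile(fileext = ".json")
  obj <- list(plddt = plddt)
  if (!is.null(pae)) obj$pae <- pae
  jsonlite::write_json(obj, f, digits = NA)
  f
}

test_that("confidence JSON parsing validates shape and range", {
  f <- write_conf(rep(80, 30))
  conf <- read_confidence(f)
  expect_length(conf$plddt, 30)
  expect_null(conf$pae)

  expect_error(read_confidence(write_conf(c(rep(80, 29), 120))),
               class = "cycbinder_range_error")

  pae_ok <- matrix(1, 30, 30); diag(pae_ok) <- 0
  expect_equal(dim(read_confidence(write_conf(rep(80, 30), pae_ok))$pae),
               c(30L, 30L))
  expect_error(read_confidence(write_conf(rep(80, 30), pae_ok[1:29, ])),
               class = "cycbinder_format_error")

  f2 <- tempfile(); jsonlite::write_json(list(pae = pae_ok), f2)
  expect_error(read_confidence(f2), class = "cycbinder_format_error")
})

test_that("peptide mean pLDDT averages the peptide region only", {
  conf <- read_confidence(write_conf(c(rep(90, 20), rep(70, 13))))
  expect_equal(peptide_mean_plddt(conf, c(21, 33)), 70)
  expect_equal(peptide_mean_plddt(conf, c(1, 33)),
               (90 * 20 + 70 * 13) / 33)

  vals <- c(60, 70, 80, 90, 100, 50, 65, 75, 85, 95, 55, 77, 88)
  conf2 <- read_confidence(write_conf(c(rep(90, 20), vals)))
  acc <- 0; for (v in vals) acc <- acc + v  # independent summation
  expect_equal(peptide_mean_plddt(conf2, c(21, 33)), acc / 13)

  expect_error(peptide_mean_plddt(conf, c(30, 21)),
               class = "cycbinder_invalid_input")
  expect_error(peptide_mean_plddt(conf, c(21, 40)),
               class = "cycbinder_invalid_input")
})

test_that("Rosetta score tables parse and normalize dG by interface area", {
  f <- tempfile(fileext = ".sc")
  writeLines(c(
    "SEQUENCE:",
    "SCORE: total_score dG_separated dSASA_int description",
    "SCORE:     -100.00        -2.40    100.00 design_01",
    "SCORE:      -90.00        -5.00    250.00 design_02",
    "SCORE:      -80.00         1.00      0.00 design_03"), f)
  tab <- read_rosetta_scorefile(f)
  expect_equal(tab$normalized[tab$description == "design_01"], -2.40)
  expect_equal(tab$normalized[tab$description == "design_02"], -2.00)
  d3 <- tab[tab$description == "design_03", ]
  expect_true(d3$flagged)
  expect_true(is.na(d3$normalized))

  writeLines(c("SCORE: total_score dG_separated dSASA_int description",
               "SCORE: -1 -2.0 100 dup", "SCORE: -1 -3.0 100 dup"), f)
  expect_warning(tab2 <- read_rosetta_scorefile(f), "duplicate")
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$dG_separated, -3.0)  # last occurrence wins

  writeLines(c("SCORE: total_score dSASA_int description",
               "SCORE: -1 100 x"), f)
  expect_error(read_rosetta_scorefile(f), class = "cycbinder_format_error")
  unlink(f)
})

test_that("normalized score is invariant to common scaling", {
  f <- tempfile(fileext = ".sc")
  writeLines(c("SCORE: dG_separated dSASA_int description",
               "SCORE: -2.4 100 a", "SCORE: -4.8 200 b"), f)
  tab <- read_rosetta_scorefile(f)
  expect_equal(tab$normalized[1], tab$normalized[2])
  unlink(f)
})

test_that("triage applies strict thresholds, fallback rule and selectors", {
  records <- data.frame(
    design_id = c("d1", "d2", "d3", "d4", "d5"),
    peptide_mean_plddt = c(95, 71, 70, 90, 85),
    normalized = c(-2.5, -3.0, -4.0, -1.0, -2.6),
    rmsd_best = c(1.2, 0.8, 0.3, 0.5, 2.0),
    stringsAsFactors = FALSE
  )
  native <- -2.0
  # below_native: d3 fails pLDDT (70 is not > 70), d4 fails energy
  res <- triage_designs(records, native)
  expect_setequal(res$passing$design_id, c("d1", "d2", "d5"))
  # exhaustive argmin oracle under both selectors
  pass <- records[records$peptide_mean_plddt > 70 & records$normalized < native, ]
  expect_equal(res$selected$design_id,
               pass$design_id[which.min(pass$rmsd_best)])
  res_e <- triage_designs(records, native, selector = "lowest_energy")
  expect_equal(res_e$selected$design_id,
               pass$design_id[which.min(pass$normalized)])

  # fallback: nothing beats a very low native score, below_zero still passes
  none <- triage_designs(records, -10)
  expect_equal(nrow(none$passing), 0)
  expect_null(none$selected)
  fb <- triage_designs(records, energy_rule = "below_zero")
  expect_setequal(fb$passing$design_id, c("d1", "d2", "d4", "d5"))

  # raising the pLDDT threshold shrinks the passing set
  hi <- triage_designs(records, native, plddt_min = 90)
  expect_true(all(hi$passing$design_id %in% res$passing$design_id))

  # ties on the metric break by design_id
  tie <- records
  tie$rmsd_best <- 1
  expect_equal(triage_designs(tie, native)$selected$design_id, "d1")

  # flagged (NA normalized) records never pass; NA metric on passer errors
  na_rec <- records
  na_rec$normalized[1] <- NA
  expect_false("d1" %in% triage_designs(na_rec, native)$passing$design_id)
  na_met <- records
  na_met$rmsd_best[2] <- NA
  expect_error(triage_designs(na_met, native),
               class = "cycbinder_invalid_input")
  expect_error(triage_designs(records, NULL, energy_rule = "below_native"),
               class = "cycbinder_invalid_input")
})

test_that("filter monotonicity holds over random record sets", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    rec <- data.frame(
      design_id = sprintf("d%02d", seq_len(n)),
      peptide_mean_plddt = runif(n, 40, 100),
      normalized = runif(n, -5, 2),
      rmsd_best = runif(n, 0.2, 8),
      stringsAsFactors = FALSE
    )
    t1 <- runif(1, 50, 80); t2 <- t1 + runif(1, 0, 20)
    p1 <- triage_designs(rec, 0.5, plddt_min = t1)$passing$design_id
    p2 <- triage_designs(rec, 0.5, plddt_min = t2)$passing$design_id
    expect_true(all(p2 %in% p1))
    e1 <- triage_designs(rec, 1)$passing$design_id
    e2 <- triage_designs(rec, -1)$passing$design_id
    expect_true(all(e2 %in% e1))
  }
})
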