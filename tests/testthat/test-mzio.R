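# Evidence parsing, peak-count optimization and envelope extraction.

write_evidence_fixture <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

evidence_rows <- function(n = 3) {
  if (n == 0)
    return(data.frame(Sequence = character(0), Charge = numeric(0),
                      `m/z` = numeric(0), `Retention time` = numeric(0),
                      `Raw file` = character(0), Proteins = character(0),
                      Intensity = numeric(0), check.names = FALSE))
  data.frame(Sequence = rep("GASK", n), Charge = 2,
             `m/z` = 180.6, `Retention time` = 20.0,
             `Raw file` = paste0("run", seq_len(n)), Proteins = "P1",
             Intensity = 1e6, check.names = FALSE)
}

test_that("well-formed evidence parses row for row", {
  ev <- read_evidence(write_evidence_fixture(evidence_rows(3)))
  expect_equal(nrow(ev), 3)
  expect_equal(attr(ev, "n_dropped"), 0)
})

test_that("rows with missing mandatory fields are dropped and counted", {
  rows <- evidence_rows(3)
  rows$Charge[2] <- NA
  expect_message(ev <- read_evidence(write_evidence_fixture(rows)),
                 "dropped 1")
  expect_equal(nrow(ev), 2)
  expect_equal(attr(ev, "n_dropped"), 1)
})

test_that("header-only tables give an empty record set, not an error", {
  ev <- read_evidence(write_evidence_fixture(evidence_rows(0)))
  expect_equal(nrow(ev), 0)
})

test_that("a missing mandatory column is rejected by name", {
  rows <- evidence_rows(2)
  rows[["Retention time"]] <- NULL
  expect_error(read_evidence(write_evidence_fixture(rows)),
               "Retention time")
})

test_that("m/z deviations beyond 25 ppm are flagged, not dropped", {
  rows <- evidence_rows(2)
  true_mz <- mono_mz(formula_of_peptide("GASK"), 2)
  rows[["m/z"]] <- c(true_mz, true_mz * (1 + 60e-6))
  ev <- validate_evidence_mz(read_evidence(write_evidence_fixture(rows)))
  expect_equal(ev$mz_flag, c(FALSE, TRUE))
  expect_equal(nrow(ev), 2)
})

test_that("peak count adds natural tail peaks per the cumulative oracle", {
  enrich <- c(G = 0.15, S = 0.15)
  seqc <- "GSGK"
  fo <- formula_of_peptide(seqc, fixed_mods = character(0))
  nl <- count_labelable_atoms(seqc, enrich = enrich)$n_labelable
  expect_equal(nl, 3)
  cutoff <- 0.999
  np <- optimal_peak_count(fo, nl, natural_tail_cutoff = cutoff)
  # independent oracle: cumulative sum of the non-labelable-part
  # distribution, directly
  nat <- natural_distribution(fo, n_peaks = 30, exclude = c(N = nl))
  n_nat <- which(cumsum(nat) >= cutoff)[1] - 1
  expect_equal(np, nl + n_nat + 1)
})

test_that("tiny unlabelable molecules need a single peak", {
  # H2: M0 mass fraction (1-0.000115)^2 > 0.9991
  np <- optimal_peak_count(elemental_formula(H = 2), n_labelable = 0,
                           natural_tail_cutoff = 0.9991)
  expect_equal(np, 1)
})

test_that("raising the cutoff never shrinks the peak count", {
  fo <- formula_of_peptide("GASPVTLNDEK")
  nl <- 4
  counts <- vapply(c(0.991, 0.995, 0.999, 0.9999),
                   function(ct) optimal_peak_count(fo, nl,
                                                   natural_tail_cutoff = ct),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

make_ms1 <- function(mz0, z, env, rt_apex = 10, scans = 5) {
  rows <- list()
  for (s in seq_len(scans)) {
    rows[[s]] <- data.frame(scan = s,
                            rt_min = rt_apex + (s - 3) * 0.1,
                            mz = mz0 + (seq_along(env) - 1) * 1.00335 / z,
                            intensity = env / scans)
  }
  do.call(rbind, rows)
}

test_that("a known envelope is recovered proportionally from spectra", {
  env <- c(100, 30, 5)
  ms1 <- make_ms1(500, 2, env)
  e <- extract_envelope(ms1, 500, 2, rt_apex = 10, n_peaks = 3)
  expect_false(e$not_found)
  expect_equal(e$intensity / sum(e$intensity), env / sum(env),
               tolerance = 1e-9)
})

test_that("absent peptides give a flagged zero envelope", {
  ms1 <- make_ms1(500, 2, c(100, 30, 5))
  e <- extract_envelope(ms1, 900, 2, rt_apex = 10, n_peaks = 3)
  expect_true(e$not_found)
  expect_equal(e$intensity, c(0, 0, 0))
  # no scan in the RT window at all
  e2 <- extract_envelope(ms1, 500, 2, rt_apex = 50, n_peaks = 3)
  expect_true(e2$not_found)
  expect_equal(e2$n_scans, 0L)
})

test_that("co-eluting peptides 50 ppm apart do not cross-contaminate", {
  mzA <- 500
  mzB <- 500 * (1 + 50e-6)
  ms1 <- rbind(make_ms1(mzA, 2, c(100, 30, 5)),
               make_ms1(mzB, 2, c(7, 11, 13)))
  eA <- extract_envelope(ms1, mzA, 2, 10, 3, ppm_tol = 10)
  eB <- extract_envelope(ms1, mzB, 2, 10, 3, ppm_tol = 10)
  expect_equal(eA$intensity / sum(eA$intensity),
               c(100, 30, 5) / 135, tolerance = 1e-9)
  expect_equal(eB$intensity / sum(eB$intensity),
               c(7, 11, 13) / 31, tolerance = 1e-9)
})

test_that("extraction is RT-translation equivariant and intensity-linear", {
  env <- c(50, 20, 10, 2)
  ms1 <- make_ms1(600, 2, env)
  base <- extract_envelope(ms1, 600, 2, 10, 4)
  shifted <- ms1
  shifted$rt_min <- shifted$rt_min + 7.3
  e2 <- extract_envelope(shifted, 600, 2, 10 + 7.3, 4)
  expect_equal(e2$intensity, base$intensity, tolerance = 1e-12)
  doubled <- ms1
  doubled$intensity <- doubled$intensity * 2
  e3 <- extract_envelope(doubled, 600, 2, 10, 4)
  expect_equal(e3$intensity, 2 * base$intensity, tolerance = 1e-12)
})

test_that("multiple evidence rows of one peptide sum their envelopes", {
  env <- c(100, 30, 5)
  ms1 <- rbind(make_ms1(500, 2, env, rt_apex = 10),
               make_ms1(500, 2, env, rt_apex = 30))
  ev <- data.frame(sequence = "GASK", charge = 2L, mz = 500,
                   rt_apex = c(10, 30), raw_file = "run1", proteins = "P1",
                   intensity = 1, condition = "cold", replicate = "b1",
                   labelled = TRUE, stringsAsFactors = FALSE)
  out <- extract_all_envelopes(ev, ms1, enrich = c(G = 0.15, S = 0.15),
                               natural_tail_cutoff = 0.995)
  expect_equal(nrow(out), 1)
  got <- out$envelope[[1]][1:3]
  expect_equal(got / sum(got), env / sum(env), tolerance = 1e-9)
  expect_equal(sum(out$envelope[[1]][1:3]), 2 * sum(env), tolerance = 1e-9)
})

test_that("envelope tables survive a TSV round trip", {
  ev <- data.frame(sequence = c("GASK", "GSK"), charge = 2L, raw_file = "r",
                   condition = "cold", replicate = "b1", labelled = TRUE,
                   n_labelable = c(2L, 2L), n_peaks = c(4L, 3L),
                   not_found = FALSE, stringsAsFactors = FALSE)
  ev$envelope <- list(c(10, 5, 2, 1), c(8, 3, 1))
  path <- tempfile(fileext = ".tsv")
  write_envelopes(ev, path)
  back <- read_envelopes(path)
  expect_equal(back$envelope, ev$envelope)
})
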