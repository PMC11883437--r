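# Amino-acid pool enrichment: fragment QC, baseline handling, selection,
# cross-treatment statistics.

# hand-built per-sample fragment enrichment rows for select_fragments
enr_rows <- function(fragment_id, labelled_vals, control_vals,
                     aa = "S", condition = "cold") {
  n_l <- length(labelled_vals); n_c <- length(control_vals)
  data.frame(amino_acid = aa, fragment_id = fragment_id,
             sample_id = paste0(fragment_id, "_s",
                                seq_len(n_l + n_c)),
             condition = condition,
             replicate = paste0("b", c(seq_len(n_l), seq_len(n_c))),
             tech_rep = 1L, labelled = rep(c(TRUE, FALSE), c(n_l, n_c)),
             enrichment = c(labelled_vals, control_vals),
             stringsAsFactors = FALSE)
}

test_that("proportional fragments correlate perfectly, permuted do not", {
  frag <- function(id, sums) {
    d <- data.frame(amino_acid = "S", fragment_id = id,
                    sample_id = paste0("s", seq_along(sums)),
                    stringsAsFactors = FALSE)
    d$envelope <- lapply(sums, function(s) c(0.8, 0.2) * s)
    d
  }
  sums <- c(1, 2, 3, 4, 6)
  f <- rbind(frag("f1", sums), frag("f2", 10 * sums),
             frag("f3", sums[c(3, 5, 1, 4, 2)]))
  res <- fragment_pair_consistency(f, threshold = 0.8)
  expect_equal(res$r["f1", "f2"], 1, tolerance = 1e-12)
  expect_lt(res$r["f1", "f3"], 0.5)
  expect_true(any(res$inconsistent$fragment1 == "f1" &
                    res$inconsistent$fragment2 == "f3" |
                    res$inconsistent$fragment1 == "f3" &
                    res$inconsistent$fragment2 == "f1"))
})

test_that("consistency check refuses single fragments or < 3 samples", {
  d <- data.frame(amino_acid = "S", fragment_id = "f1",
                  sample_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  d$envelope <- list(1, 2, 3)
  expect_error(fragment_pair_consistency(d), ">= 2 fragments")
  d2 <- rbind(d[1:2, ], within(d[1:2, ], fragment_id <- "f2"))
  expect_error(fragment_pair_consistency(d2), ">= 3 samples")
})

test_that("fragment enrichment recovers the forward-simulated truth", {
  cfg <- tiny_config()
  frag_tab <- simulate_pools(cfg, amino_acids = c("S", "Q"),
                             noiseless = TRUE)
  path <- tempfile(fileext = ".tsv")
  write.table(frag_tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  frags <- read_fragments(path)
  one <- frags[frags$fragment_id == "S_f1", ]
  fe <- fragment_enrichment(one)
  lab_cold <- fe$labelled & fe$condition == "cold"
  expect_equal(mean(fe$enrichment[lab_cold]), 0.15, tolerance = 1e-6)
  ctl <- !fe$labelled
  expect_equal(mean(fe$enrichment[ctl]), 0, tolerance = 1e-6)
})

test_that("nitrogen-free fragments are rejected on read", {
  tab <- data.frame(amino_acid = "S", fragment_id = "bad",
                    formula = "C6H12O2", sample_id = "s1",
                    condition = "cold", replicate = "b1", labelled = TRUE,
                    M0 = 1, M1 = 0.1, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_fragments(path), "without nitrogen")
})

test_that("pyroglutamate rows alias to glutamine", {
  tab <- data.frame(amino_acid = "pyroglutamate", fragment_id = "q1",
                    formula = "C5H8N2O2", sample_id = "s1",
                    condition = "cold", replicate = "b1", labelled = TRUE,
                    M0 = 1, M1 = 0.1, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_fragments(path)$amino_acid, "Q")
})

test_that("clean branch: contaminated fragment excluded, lowest RSD wins", {
  set.seed(31)
  sel <- select_fragments(rbind(
    enr_rows("A", 0.15 * (1 + rnorm(3, 0, 0.02)), c(0.0005, -0.0003, 0.0002)),
    enr_rows("B", 0.15 * (1 + rnorm(3, 0, 0.08)), c(0.0002, 0.0004, -0.0001)),
    enr_rows("C", 0.15 * (1 + rnorm(3, 0, 0.02)), c(0.015, 0.016, 0.014))))
  expect_equal(sel$fragment_id, "A")
  expect_false(sel$undetected)
  expect_false(any(grepl("baseline subtracted", sel$flags)))
})

test_that("all-biased branch subtracts the control baseline", {
  set.seed(32)
  mk <- function(id, rsd) enr_rows(id,
                                   0.155 * (1 + rnorm(3, 0, rsd)),
                                   0.005 + rnorm(3, 0, 0.0004))
  sel <- select_fragments(rbind(mk("A", 0.02), mk("B", 0.05), mk("C", 0.03)))
  expect_true(any(grepl("baseline subtracted", sel$flags)))
  # labelled enrichment corrected down towards the true 0.15
  expect_equal(sel$e_a, 0.15, tolerance = 0.01)
})

test_that("single clean fragment is chosen with a fragment-count warning", {
  sel <- select_fragments(enr_rows("only", c(0.1, 0.11, 0.09),
                                   c(0.0003, -0.0002, 0.0001)))
  expect_equal(sel$fragment_id, "only")
  expect_true(any(grepl("fewer than 3 fragments", sel$flags)))
})

test_that("negative post-subtraction enrichments are clipped and flagged", {
  set.seed(33)
  sel <- select_fragments(rbind(
    enr_rows("A", c(0.004, 0.0045, 0.0042), c(0.005, 0.0049, 0.0051)),
    enr_rows("B", c(0.004, 0.005, 0.0045), c(0.005, 0.005, 0.005))))
  expect_true(any(grepl("clipped", sel$flags)))
  expect_true(all(sel$enrichments$enrichment >= 0))
})

test_that("undetected amino acids come back as e_a = 0 with a flag", {
  # contaminated fragment with no labelled signal at all
  ctl_only <- enr_rows("A", numeric(0), c(0.015, 0.014, 0.016))
  sel <- select_fragments(ctl_only)
  expect_true(sel$undetected)
  expect_equal(sel$e_a, 0)
  expect_match(paste(sel$flags, collapse = " "), "undetected|no labelled")
})

test_that("full pools pipeline recovers enrichments within 0.01 at 5% CV", {
  cfg <- sim_config(seed = 9, n_bio = 3, n_tech = 3, noise_cv = 0.05)
  frag_tab <- simulate_pools(cfg, amino_acids = c("S", "G", "Q", "E"))
  path <- tempfile(fileext = ".tsv")
  write.table(frag_tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pools <- pool_table(read_fragments(path))
  for (cond in c("cold", "control")) {
    e_hat <- enrichment_vector(pools, cond)
    e_true <- cfg$pool_enrichments[[cond]]
    for (aa in c("S", "G", "Q", "E"))
      expect_lt(abs(e_hat[aa] - e_true[aa]), 0.01)
  }
  # enrichment_vector fills unmeasured amino acids with zero
  expect_equal(unname(enrichment_vector(pools, "cold")["H"]), 0)
})

test_that("contaminated fragments are excluded by the full pipeline", {
  cfg <- sim_config(seed = 10, n_bio = 3, n_tech = 2, noise_cv = 0.02)
  frag_tab <- simulate_pools(cfg, amino_acids = "S", contaminated = 0.015)
  path <- tempfile(fileext = ".tsv")
  write.table(frag_tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pools <- pool_table(read_fragments(path))
  chosen <- pools$table$fragment_id[pools$table$condition == "cold" &
                                      pools$table$amino_acid == "S"]
  expect_false(chosen == "S_f3")  # the contaminated fragment
})

test_that("treatment comparison separates labelled conditions, not controls", {
  cfg <- sim_config(seed = 11, n_bio = 3, n_tech = 3, noise_cv = 0.05)
  frag_tab <- simulate_pools(cfg, amino_acids = "S")
  path <- tempfile(fileext = ".tsv")
  write.table(frag_tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pools <- pool_table(read_fragments(path))
  res <- compare_pool_enrichments(pools)$S
  la <- strsplit(res$letters, "")
  # cold labelled (15%) vs control labelled (4%): different letters
  expect_equal(length(intersect(la[["cold.L"]], la[["control.L"]])), 0)
  # the two unlabelled groups are both at zero: shared letter
  expect_gt(length(intersect(la[["cold.NL"]], la[["control.NL"]])), 0)
})
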