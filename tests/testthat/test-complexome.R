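# Substoichiometry normalization, differential abundance, group
# classification and the LSU:SSU ratio.

sub_map <- function() {
  data.frame(protein = c("L1", "L2", "L3", "S1", "S2"),
             subunit_class = c("60S", "60S", "60S", "40S", "40S"),
             stringsAsFactors = FALSE)
}

mk_lfq <- function(m, conditions = NULL) {
  if (is.null(conditions))
    conditions <- sub("_.*", "", colnames(m))
  lfq_matrix(m, data.frame(sample = colnames(m), condition = conditions,
                           replicate = sub(".*_", "", colnames(m)),
                           stringsAsFactors = FALSE))
}

test_that("within-class substoichiometry values sum to one per sample", {
  m <- matrix(c(2, 6, 2, 3, 1,
                4, 4, 2, 1, 1), ncol = 2,
              dimnames = list(c("L1", "L2", "L3", "S1", "S2"),
                              c("cold_b1", "cold_b2")))
  s <- substoichiometry(mk_lfq(m), sub_map())
  expect_equal(s[c("L1", "L2", "L3"), "cold_b1"], c(L1 = 0.2, L2 = 0.6, L3 = 0.2))
  expect_equal(colSums(s[c("L1", "L2", "L3"), ]), c(cold_b1 = 1, cold_b2 = 1))
  expect_equal(colSums(s[c("S1", "S2"), ]), c(cold_b1 = 1, cold_b2 = 1))
})

test_that("single-member classes normalize to one, missing values stay out", {
  m <- matrix(c(5, 2, NA, 3), ncol = 2,
              dimnames = list(c("L1", "S1"), c("a_b1", "a_b2")))
  map <- data.frame(protein = c("L1", "S1"),
                    subunit_class = c("60S", "40S"))
  s <- substoichiometry(mk_lfq(m), map)
  expect_equal(unname(s["L1", ]), c(1, NA))
  expect_equal(unname(s["S1", ]), c(1, 1))
})

test_that("a two-fold shift is detected and the null stays quiet", {
  set.seed(41)
  n <- 60
  base <- rlnorm(n, log(1e8), 0.5)
  noise <- function(k) matrix(rlnorm(n * k, 0, sqrt(log(1 + 0.1^2))), n, k)
  m <- cbind(base * noise(3), base * noise(3))
  shifted <- 1:10
  m[shifted, 1:3] <- m[shifted, 1:3] * 2
  colnames(m) <- c(paste0("cold_b", 1:3), paste0("control_b", 1:3))
  rownames(m) <- paste0("P", 1:n)
  res <- differential_abundance(mk_lfq(m), c("cold", "control"))
  hits <- res$protein[!is.na(res$q) & res$q < 0.1 & res$log2fc > 0]
  expect_gt(length(intersect(hits, paste0("P", shifted))), 5)
  # unshifted proteins: raw type-I around the nominal level
  null_p <- res$p[-shifted]
  expect_lt(mean(null_p < 0.05, na.rm = TRUE), 0.15)
})

test_that("proteins with a single replicate are skipped with a reason", {
  m <- matrix(c(1, 2, NA, 1.1, 2.2, NA, 1.2, NA, NA, 1, 2, 3), nrow = 3,
              dimnames = list(c("A", "B", "C"),
                              c("x_b1", "x_b2", "x_b3", "y_b1")))
  res <- differential_abundance(mk_lfq(m), c("x", "y"))
  expect_true(all(res$reason == "insufficient replicates"))
})

test_that("the accumulation/synthesis truth table maps to groups 1-4", {
  expect_equal(classify_group(TRUE, TRUE), 1L)
  expect_equal(classify_group(TRUE, FALSE), 2L)
  expect_equal(classify_group(FALSE, TRUE), 3L)
  expect_equal(classify_group(FALSE, FALSE), 4L)
  g <- classify_group(NA, TRUE)
  expect_true(is.na(g))
  expect_match(attr(g, "reason"), "undefined")
})

# constructed complex fixtures: diff and synthesis tables built by hand
cdef <- list(complex = "test complex", go_id = "GO:0000001",
             members = list(c("A", "B", "C")))

synth_tab <- function(cold_syn, control_syn) {
  data.frame(protein = rep(c("A", "B", "C"), 2),
             condition = rep(c("cold", "control"), each = 3),
             synthesized = c(cold_syn, control_syn),
             stringsAsFactors = FALSE)
}

test_that("accumulated + labelled members give group 1 in cold, 4 in control", {
  diff <- data.frame(protein = c("A", "B", "C"), log2fc = 1,
                     q = 0.001, stringsAsFactors = FALSE)
  gc <- classify_complex(cdef, diff, synth_tab(rep(TRUE, 3), rep(FALSE, 3)),
                         conditions = c("cold", "control"))
  expect_equal(gc$group[gc$condition == "cold"], 1L)
  expect_equal(gc$group[gc$condition == "control"], 4L)
})

test_that("accumulation without labelling gives group 2", {
  diff <- data.frame(protein = c("A", "B", "C"), log2fc = 1, q = 0.001,
                     stringsAsFactors = FALSE)
  gc <- classify_complex(cdef, diff, synth_tab(rep(FALSE, 3), rep(FALSE, 3)),
                         conditions = c("cold", "control"))
  expect_equal(gc$group[gc$condition == "cold"], 2L)
})

test_that("flat abundance with labelling in both conditions gives group 3", {
  diff <- data.frame(protein = c("A", "B", "C"), log2fc = 0.01, q = 0.9,
                     stringsAsFactors = FALSE)
  gc <- classify_complex(cdef, diff, synth_tab(rep(TRUE, 3), rep(TRUE, 3)),
                         conditions = c("cold", "control"))
  expect_equal(gc$group, c(3L, 3L))
})

test_that("accumulation is direction-aware: never positive in both conditions", {
  set.seed(43)
  for (i in 1:10) {
    diff <- data.frame(protein = c("A", "B", "C"),
                       log2fc = rnorm(3), q = runif(3),
                       stringsAsFactors = FALSE)
    gc <- classify_complex(cdef, diff, synth_tab(rep(FALSE, 3), rep(FALSE, 3)),
                           conditions = c("cold", "control"))
    expect_false(all(gc$accumulated))
  }
})

test_that("undetected complexes are reported as such", {
  diff <- data.frame(protein = "Z", log2fc = 1, q = 0.001,
                     stringsAsFactors = FALSE)
  gc <- classify_complex(cdef, diff, synth_tab(rep(TRUE, 3), rep(TRUE, 3)),
                         conditions = c("cold", "control"))
  expect_true(all(is.na(gc$group)))
  expect_equal(gc$accumulated_members[1], "not detected")
})

test_that("complex definitions validate GO identifiers and members", {
  tab <- data.frame(complex = "ribosome LSU", go_id = "GO:0022625",
                    members = "L1;L2;L3", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cx <- read_complexes(path)
  expect_equal(cx$members[[1]], c("L1", "L2", "L3"))
  tab$go_id <- "GO:123"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_complexes(path), "malformed GO")
})

test_that("an exact 3:1 fixture returns ratio 3 with perfect correlation", {
  ssu <- c(1, 2, 3, 4)
  m <- rbind(L1 = 2 * 3 * ssu, L2 = 3 * ssu, S1 = 0.5 * ssu, S2 = 0.5 * ssu)
  colnames(m) <- paste0("s_b", 1:4)
  map <- data.frame(protein = c("L1", "L2", "S1", "S2"),
                    subunit_class = c("60S", "60S", "40S", "40S"))
  sr <- subunit_ratio(mk_lfq(m), map)
  expect_equal(unname(sr$ratio), rep(9, 4))  # (6+3)/(0.5+0.5) per unit
  expect_equal(sr$r2, 1, tolerance = 1e-12)
  # global sample scaling leaves the ratio unchanged
  m2 <- sweep(m, 2, c(1, 10, 100, 1000), `*`)
  sr2 <- subunit_ratio(mk_lfq(m2), map)
  expect_equal(sr2$ratio, sr$ratio)
})

test_that("noisy proportional subunit sums keep a high r-squared", {
  set.seed(44)
  ok <- 0
  for (i in 1:5) {
    ssu_tot <- rlnorm(8, log(1e8), 0.4)
    m <- rbind(L1 = 2 * ssu_tot, L2 = ssu_tot, S1 = 0.6 * ssu_tot,
               S2 = 0.4 * ssu_tot) *
      matrix(rlnorm(32, 0, sqrt(log(1 + 0.05^2))), 4, 8)
    colnames(m) <- paste0("s_b", 1:8)
    map <- data.frame(protein = c("L1", "L2", "S1", "S2"),
                      subunit_class = c("60S", "60S", "40S", "40S"))
    if (subunit_ratio(mk_lfq(m), map)$r2 > 0.95) ok <- ok + 1
  }
  expect_gte(ok, 4)
})
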