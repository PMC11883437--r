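# Shared fixtures: small study configurations and a direct envelope
# builder that bypasses MS1 extraction (for stages downstream of mzio).

tiny_config <- function(seed = 42, ...) {
  sim_config(seed = seed, n_proteins = 3, peptides_per_protein = 3, ...)
}

# random peptide sequence with at least one labelable residue
random_peptide <- function(len, alphabet = setdiff(residue_table()$aa, "K")) {
  paste0(paste(sample(alphabet, len, replace = TRUE), collapse = ""), "K")
}

# envelope table rows for one peptide across replicates, built directly
# from the forward model (A %*% x_true) with multiplicative noise
direct_envelopes <- function(sequence, f, enrich, n_bio = 3, cv = 0,
                             purity = 0.99, condition = "cold",
                             with_unlabelled = TRUE) {
  residues <- residue_table()
  policy <- isotope_policy()
  fo <- formula_of_peptide(sequence, residues)
  nl <- count_labelable_atoms(sequence, residues, enrich)$n_labelable
  np <- optimal_peak_count(fo, nl, policy)
  A <- correction_matrix(fo, policy, nl, np, purity)
  rows <- list()
  for (lab in if (with_unlabelled) c(TRUE, FALSE) else TRUE) {
    x <- true_label_fractions(sequence, if (lab) f else 0, enrich, residues)
    env <- as.numeric(unclass(A) %*% x)
    for (b in seq_len(n_bio)) {
      noise <- if (cv > 0) {
        s2 <- log(1 + cv^2)
        stats::rlnorm(np, -s2 / 2, sqrt(s2))
      } else 1
      r <- data.frame(sequence = sequence, charge = 2L,
                      raw_file = sprintf("%s_b%d_%s", condition, b,
                                         if (lab) "L" else "NL"),
                      condition = condition, replicate = paste0("b", b),
                      labelled = lab, n_labelable = nl, n_peaks = np,
                      not_found = FALSE, stringsAsFactors = FALSE)
      r$envelope <- list(env * 1e6 * noise)
      rows[[length(rows) + 1]] <- r
    }
  }
  do.call(rbind, rows)
}
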