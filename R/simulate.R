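# Forward generative model for every input the pipeline consumes, with
# known ground truth: peptide isotopologue envelopes in MS1 peak tables,
# GC-MS amino-acid fragment tables, weight time series and LFQ matrices.
#
# The envelope model mirrors the NIA correction basis exactly: a peptide
# sample is a mixture of old molecules (no deliberate label) and a
# fraction f of new molecules whose labelable N atoms are each drawn from
# the amino acid's pool (labelled with probability e_a; a labelled atom is
# heavy with the tracer purity, an unlabelled one at natural abundance).
# Under this model the observed mean enrichment is exactly f * E_max, so
# the noiseless pipeline must return corrected LPF = f.

#' Default per-amino-acid pool enrichments of the simulated study
#'
#' Emulates the measured soluble-pool landscape: the tracer amino acids
#' serine and glycine near 15% in the cold-shifted condition and 4% in the
#' control; secondary labelling of Gln/Glu/Asn/Pro/Val/Asp/Phe/Ile in the
#' cold (2.5-10%) and of Gln/Glu/Asn in the control (2.5-3%); histidine
#' and arginine undetected (0) everywhere.
#'
#' @param condition "cold" or "control"
#' @return named numeric vector over one-letter codes
#' @export
default_pool_enrichments <- function(condition = c("cold", "control")) {
  condition <- match.arg(condition)
  rt <- residue_table()
  e <- stats::setNames(numeric(nrow(rt)), rt$aa)
  if (condition == "cold") {
    e[c("S", "G")] <- 0.15
    e["Q"] <- 0.10; e["E"] <- 0.08; e["N"] <- 0.06; e["P"] <- 0.05
    e[c("V", "D")] <- 0.04; e["F"] <- 0.03; e["I"] <- 0.025
  } else {
    e[c("S", "G")] <- 0.04
    e["Q"] <- 0.03; e["E"] <- 0.03; e["N"] <- 0.025
  }
  e
}

#' Simulation configuration
#'
#' Bundles the study design: conditions, replicate structure (biological
#' by technical), the simulated proteome, per-protein true fraction-new,
#' pool enrichments, tracer purity, multiplicative noise level, growth
#' truth (average RGR per condition) and LFQ fold changes.
#'
#' @param seed mandatory integer seed
#' @param conditions condition labels
#' @param n_bio biological replicates per condition and labelling state
#' @param n_tech technical replicates (pools module)
#' @param n_proteins proteins in the simulated proteome
#' @param peptides_per_protein average Lys-C peptides per protein
#' @param fraction_new named list condition -> per-protein f (recycled);
#'   default 0.3 in cold, 0.15 in control
#' @param pool_enrichments named list condition -> named e_a vector
#' @param purity tracer isotopic purity
#' @param noise_cv multiplicative (log-normal) intensity noise CV
#' @param rgr_truth named list condition -> c(DW = ..., FW = ...) average
#'   RGR over the labelling window (h^-1); defaults are the published
#'   study's dry- and fresh-weight rates
#' @param t_f end of the labelling window (h)
#' @param charge peptide charge state
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(seed, conditions = c("cold", "control"), n_bio = 3,
                       n_tech = 3, n_proteins = 50,
                       peptides_per_protein = 10,
                       fraction_new = list(cold = 0.3, control = 0.15),
                       pool_enrichments = list(
                         cold = default_pool_enrichments("cold"),
                         control = default_pool_enrichments("control")),
                       purity = 0.99, noise_cv = 0.05,
                       rgr_truth = list(cold = c(DW = 0.017, FW = 0.011),
                                        control = c(DW = 0.008, FW = 0.008)),
                       t_f = 120, charge = 2L) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(purity > 0, purity <= 1, noise_cv >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# multiplicative log-normal noise factors with unit mean and given CV
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, -s2 / 2, sqrt(s2))
}

#' Simulate a Lys-C proteome
#'
#' Random protein sequences assembled from peptides that end in lysine
#' and contain none internally, so Lys-C digestion (cleavage C-terminal
#' of K) regenerates them exactly.
#'
#' @param n_proteins protein count
#' @param peptides_per_protein peptides per protein
#' @param min_len,max_len peptide length range (before the terminal K)
#' @return data.frame: protein, peptide
#' @export
simulate_proteome <- function(n_proteins = 50, peptides_per_protein = 10,
                              min_len = 7, max_len = 15) {
  rt <- residue_table()
  alphabet <- setdiff(rt$aa, "K")
  out <- NULL
  for (p in seq_len(n_proteins)) {
    npep <- max(2, stats::rpois(1, peptides_per_protein))
    peps <- vapply(seq_len(npep), function(i) {
      len <- sample(min_len:max_len, 1)
      paste0(paste(sample(alphabet, len, replace = TRUE), collapse = ""),
             "K")
    }, character(1))
    out <- rbind(out, data.frame(protein = sprintf("P%04d", p),
                                 peptide = peps,
                                 stringsAsFactors = FALSE))
  }
  unique(out)
}

#' True labelled-atom fraction vector of a peptide sample
#'
#' The ground-truth x (fractions of molecules with exactly j labelled
#' atoms): old molecules contribute to j = 0; new molecules draw each
#' labelable atom independently from its pool (Poisson-binomial over the
#' per-residue e_a).
#'
#' @param sequence peptide
#' @param f fraction of new molecules
#' @param enrich per-amino-acid pool enrichment vector
#' @param residues residue table
#' @return numeric x_0..x_n (n = labelable atoms)
#' @export
true_label_fractions <- function(sequence, f, enrich,
                                 residues = residue_table()) {
  cla <- count_labelable_atoms(sequence, residues, enrich)
  b <- cla$breakdown[cla$breakdown$labelable, ]
  n <- cla$n_labelable
  pb <- 1
  if (n > 0)
    for (i in seq_len(nrow(b)))
      for (k in seq_len(b$nN[i]))
        pb <- convolve_trunc(pb, c(1 - b$e_a[i], b$e_a[i]), n + 1)
  pb <- c(pb, numeric(n + 1 - length(pb)))
  x <- (1 - f) * c(1, numeric(n)) + f * pb
  x
}

#' Simulate evidence and MS1 peak tables
#'
#' For each peptide and sample, the isotopologue envelope is
#' \code{A x_true} (A the purity-aware correction basis, x_true from
#' [true_label_fractions()]; unlabelled samples have f = 0), scaled by a
#' log-normal peptide abundance, spread over a Gaussian elution profile
#' across MS1 scans and perturbed by multiplicative noise per peak.
#' Peaks are placed at mz0 + i * 1.00335 / z.
#'
#' @param config \code{sim_config}
#' @param proteome optional data.frame (protein, peptide); simulated from
#'   the config when absent
#' @param noiseless overrides the config noise to 0 when TRUE
#' @return list: \code{evidence} (data.frame in the evidence dialect plus
#'   Condition/Replicate/Labelled), \code{ms1} (named list of peak
#'   data.frames, one per raw file), \code{truth} (per peptide and
#'   condition: f, E_max, expected Ks), \code{proteome}
#' @export
simulate_envelopes <- function(config, proteome = NULL, noiseless = FALSE) {
  set.seed(config$seed)
  residues <- residue_table()
  policy <- isotope_policy()
  cv <- if (noiseless) 0 else config$noise_cv
  if (is.null(proteome))
    proteome <- simulate_proteome(config$n_proteins,
                                  config$peptides_per_protein)
  peps <- proteome$peptide
  z <- config$charge
  rt_apex <- 5 + (seq_along(peps) - 1) * 1.2
  scan_offsets <- seq(-0.4, 0.4, by = 0.1)
  scan_w <- stats::dnorm(scan_offsets, 0, 0.2)
  scan_w <- scan_w / sum(scan_w)
  ev_rows <- list()
  ms1 <- list()
  truth_rows <- list()
  # per-peptide chemistry is condition-independent; precompute
  pep_formula <- lapply(peps, formula_of_peptide, residues = residues)
  pep_mz0 <- vapply(pep_formula, mono_mz, numeric(1), z = z,
                    policy = policy)
  for (cond in config$conditions) {
    enrich <- config$pool_enrichments[[cond]]
    fvec <- rep_len(config$fraction_new[[cond]], length(peps))
    n_lab <- integer(length(peps))
    n_pk <- integer(length(peps))
    A_list <- x_lab <- x_unl <- vector("list", length(peps))
    for (i in seq_along(peps)) {
      cla <- count_labelable_atoms(peps[i], residues, enrich)
      n_lab[i] <- cla$n_labelable
      n_pk[i] <- optimal_peak_count(pep_formula[[i]], n_lab[i], policy)
      A_list[[i]] <- correction_matrix(pep_formula[[i]], policy, n_lab[i],
                                       n_pk[i], config$purity)
      x_lab[[i]] <- true_label_fractions(peps[i], fvec[i], enrich,
                                         residues)
      x_unl[[i]] <- c(1, numeric(n_lab[i]))
      e_max <- max_lpf(peps[i], enrich, residues)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        peptide = peps[i], protein = proteome$protein[i],
        condition = cond, f = fvec[i], e_max = as.numeric(e_max),
        ks = fvec[i] * config$rgr_truth[[cond]][["DW"]] * 100,
        stringsAsFactors = FALSE)
    }
    for (rep_i in seq_len(config$n_bio)) {
      for (lab in c(TRUE, FALSE)) {
        raw <- sprintf("%s_b%d_%s", cond, rep_i, if (lab) "L" else "NL")
        abund <- stats::rlnorm(length(peps), log(1e6), 0.5)
        peak_rows <- list()
        for (i in seq_along(peps)) {
          np <- n_pk[i]
          x <- if (lab) x_lab[[i]] else x_unl[[i]]
          env <- as.numeric(unclass(A_list[[i]]) %*% x)
          mzs <- pep_mz0[i] + (0:(np - 1)) * ISOTOPE_SPACING / z
          for (s in seq_along(scan_offsets)) {
            peak_rows[[length(peak_rows) + 1]] <- data.frame(
              scan = s + i * 100, rt_min = rt_apex[i] + scan_offsets[s],
              mz = mzs,
              intensity = abund[i] * env * scan_w[s] * noise_factor(np, cv))
          }
          ev_rows[[length(ev_rows) + 1]] <- data.frame(
            Sequence = peps[i], Charge = z, `m/z` = pep_mz0[i],
            `Retention time` = rt_apex[i], `Raw file` = raw,
            Proteins = proteome$protein[i],
            Intensity = abund[i] * sum(env), Condition = cond,
            Replicate = paste0("b", rep_i), Labelled = lab,
            check.names = FALSE, stringsAsFactors = FALSE)
        }
        ms1[[raw]] <- do.call(rbind, peak_rows)
      }
    }
  }
  list(evidence = do.call(rbind, ev_rows), ms1 = ms1,
       truth = do.call(rbind, truth_rows), proteome = proteome)
}

#' Simulate peptide envelope tables directly
#'
#' The same forward model as [simulate_envelopes()] but skipping the MS1
#' peak placement and recovery: returns the per-sample isotopologue
#' envelope table in the layout of [extract_all_envelopes()], for fast
#' simulation studies of the correction and rate stages.
#'
#' @inheritParams simulate_envelopes
#' @return list: \code{envelopes} (data.frame with envelope list-column),
#'   \code{truth}, \code{proteome}
#' @export
simulate_envelope_table <- function(config, proteome = NULL,
                                    noiseless = FALSE) {
  set.seed(config$seed)
  residues <- residue_table()
  policy <- isotope_policy()
  cv <- if (noiseless) 0 else config$noise_cv
  if (is.null(proteome))
    proteome <- simulate_proteome(config$n_proteins,
                                  config$peptides_per_protein)
  peps <- proteome$peptide
  rows <- list()
  truth_rows <- list()
  for (cond in config$conditions) {
    enrich <- config$pool_enrichments[[cond]]
    fvec <- rep_len(config$fraction_new[[cond]], length(peps))
    for (i in seq_along(peps)) {
      fo <- formula_of_peptide(peps[i], residues)
      nl <- count_labelable_atoms(peps[i], residues, enrich)$n_labelable
      np <- optimal_peak_count(fo, nl, policy)
      A <- correction_matrix(fo, policy, nl, np, config$purity)
      e_max <- max_lpf(peps[i], enrich, residues)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        peptide = peps[i], protein = proteome$protein[i],
        condition = cond, f = fvec[i], e_max = as.numeric(e_max),
        ks = fvec[i] * config$rgr_truth[[cond]][["DW"]] * 100,
        stringsAsFactors = FALSE)
      for (lab in c(TRUE, FALSE)) {
        x <- true_label_fractions(peps[i], if (lab) fvec[i] else 0,
                                  enrich, residues)
        env0 <- as.numeric(unclass(A) %*% x)
        for (b in seq_len(config$n_bio)) {
          r <- data.frame(sequence = peps[i], charge = config$charge,
                          raw_file = sprintf("%s_b%d_%s", cond, b,
                                             if (lab) "L" else "NL"),
                          condition = cond, replicate = paste0("b", b),
                          labelled = lab, n_labelable = nl, n_peaks = np,
                          not_found = FALSE, stringsAsFactors = FALSE)
          r$envelope <- list(env0 * 1e6 * noise_factor(np, cv))
          rows[[length(rows) + 1]] <- r
        }
      }
    }
  }
  list(envelopes = do.call(rbind, rows),
       truth = do.call(rbind, truth_rows), proteome = proteome)
}

#' Simulate a GC-MS amino-acid fragment table
#'
#' Three fragments per detected amino acid with distinct CHNOS formulas;
#' labelled-sample envelopes follow the binomial label model at the
#' condition's pool enrichment, control samples at zero (plus any
#' configured contamination). \code{contaminated} adds control-visible
#' enrichment to one fragment per amino acid; \code{all_biased} adds a
#' shared baseline to every fragment in every sample, exercising the
#' baseline-subtraction branch.
#'
#' @param config \code{sim_config}
#' @param amino_acids codes to simulate (default: those with e_a > 0 in
#'   any condition)
#' @param contaminated fraction_id-3 control contamination level (0 = off)
#' @param all_biased shared technical baseline added to all fragments (0 =
#'   off)
#' @param noiseless overrides noise to 0
#' @return data.frame in the fragment-table layout of [read_fragments()]
#'   (with envelope list-column already expanded to M0..Mk columns)
#' @export
simulate_pools <- function(config, amino_acids = NULL, contaminated = 0,
                           all_biased = 0, noiseless = FALSE) {
  set.seed(config$seed + 1)
  residues <- residue_table()
  policy <- isotope_policy()
  cv <- if (noiseless) 0 else config$noise_cv
  if (is.null(amino_acids)) {
    e_any <- Reduce(`+`, config$pool_enrichments)
    amino_acids <- names(e_any)[e_any > 0]
  }
  rows <- list()
  # common envelope length across amino acids so rows bind cleanly
  np <- max(residue_table()[amino_acids, "nN"]) + 4
  for (aa in amino_acids) {
    res_f <- do.call(elemental_formula,
                     as.list(stats::setNames(
                       as.numeric(residues[aa, ELEMENTS]), ELEMENTS)))
    # derivatized fragments: residue plus increasing carbon backbones
    frag_formulas <- list(res_f + elemental_formula(C = 2, H = 6),
                          res_f + elemental_formula(C = 5, H = 12),
                          res_f + elemental_formula(C = 8, H = 18, O = 1))
    nN <- unclass(res_f)[["N"]]
    for (fi in seq_along(frag_formulas)) {
      ff <- frag_formulas[[fi]]
      A <- correction_matrix(ff, policy, nN, np, config$purity)
      for (cond in config$conditions) {
        e_true <- config$pool_enrichments[[cond]][aa]
        for (rep_i in seq_len(config$n_bio)) {
          for (tech in seq_len(config$n_tech)) {
            for (lab in c(TRUE, FALSE)) {
              e_eff <- if (lab) e_true else 0
              if (fi == 3 && contaminated > 0) e_eff <- e_eff + contaminated
              if (all_biased > 0) e_eff <- e_eff + all_biased
              x <- stats::dbinom(0:nN, nN, min(e_eff, 1))
              env <- as.numeric(unclass(A) %*% x) * 1e5 *
                noise_factor(np, cv)
              row <- data.frame(
                amino_acid = aa, fragment_id = paste0(aa, "_f", fi),
                formula = format(ff),
                sample_id = sprintf("%s_b%d_t%d_%s", cond, rep_i, tech,
                                    if (lab) "L" else "NL"),
                condition = cond, replicate = paste0("b", rep_i),
                tech_rep = tech, labelled = lab,
                stringsAsFactors = FALSE)
              row[paste0("M", 0:(np - 1))] <- as.list(env)
              rows[[length(rows) + 1]] <- row
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

# solve the power-curve exponent so that the eq.-8.1 average RGR over the
# daily time points equals the target
solve_growth_exponent <- function(rgr_target, times, t_f) {
  obj <- function(a) mean(times^(a - 1) / t_f^a) - rgr_target
  stats::uniroot(obj, c(0.01, 10), tol = 1e-12)$root
}

#' Simulate weight time series
#'
#' Power-law accumulation curves W_t = W_f (t / t_f)^alpha per condition
#' and variable, with alpha solved so that the fraction-of-final-weight
#' average RGR over the daily time points equals the configured truth.
#'
#' @param config \code{sim_config}
#' @param times measurement times (h since treatment onset); default daily
#' @param w_f final weight (mg)
#' @param noiseless overrides noise to 0
#' @return data.frame: condition, replicate, time_h, variable, value
#' @export
simulate_growth <- function(config, times = seq(24, 120, by = 24),
                            w_f = 10, noiseless = FALSE) {
  set.seed(config$seed + 2)
  cv <- if (noiseless) 0 else config$noise_cv
  out <- NULL
  for (cond in config$conditions) {
    for (v in names(config$rgr_truth[[cond]])) {
      a <- solve_growth_exponent(config$rgr_truth[[cond]][[v]], times,
                                 config$t_f)
      w <- w_f * (times / config$t_f)^a
      for (rep_i in seq_len(config$n_bio)) {
        out <- rbind(out, data.frame(
          condition = cond, replicate = paste0("b", rep_i),
          time_h = c(0, times), variable = v,
          value = c(0, w * noise_factor(length(w), cv)),
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Simulate an LFQ matrix
#'
#' Log-normal protein abundances with per-protein, per-condition fold
#' changes and multiplicative noise.
#'
#' @param config \code{sim_config}
#' @param proteins protein IDs
#' @param log2fc named list condition -> per-protein log2 fold change
#'   relative to baseline (recycled); default 0
#' @param noise_cv noise CV (default 0.1)
#' @return \code{lfq_matrix}
#' @export
simulate_lfq <- function(config, proteins, log2fc = NULL, noise_cv = 0.1) {
  set.seed(config$seed + 3)
  base <- stats::rlnorm(length(proteins), log(1e8), 0.7)
  samples <- expand.grid(replicate = paste0("b", seq_len(config$n_bio)),
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  samples$sample <- paste(samples$condition, samples$replicate, sep = "_")
  m <- matrix(NA_real_, length(proteins), nrow(samples),
              dimnames = list(proteins, samples$sample))
  for (s in seq_len(nrow(samples))) {
    fc <- if (is.null(log2fc)) 0
          else rep_len(log2fc[[samples$condition[s]]], length(proteins))
    m[, s] <- base * 2^fc * noise_factor(length(proteins), noise_cv)
  }
  lfq_matrix(m, samples[c("sample", "condition", "replicate")])
}

#' Write a simulated dataset to a directory
#'
#' Writes evidence.tsv, one ms1_<rawfile>.tsv per run, pools.tsv,
#' weights.tsv and truth.json (the realized ground truth).
#'
#' @param config \code{sim_config}
#' @param dir output directory (created)
#' @param noiseless passed through to the generators
#' @return invisible list of generated objects
#' @export
simulate_dataset <- function(config, dir, noiseless = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env <- simulate_envelopes(config, noiseless = noiseless)
  utils::write.table(env$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (raw in names(env$ms1))
    utils::write.table(env$ms1[[raw]],
                       file.path(dir, paste0("ms1_", raw, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  pools <- simulate_pools(config, noiseless = noiseless)
  utils::write.table(pools, file.path(dir, "pools.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  weights <- simulate_growth(config, noiseless = noiseless)
  utils::write.table(weights, file.path(dir, "weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(truth = env$truth,
                            rgr_truth = config$rgr_truth,
                            pool_enrichments = config$pool_enrichments,
                            seed = config$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(envelopes = env, pools = pools, weights = weights))
}

#' Recovery report: pipeline estimates against simulation truth
#'
#' @param truth data.frame from [simulate_envelopes()] (peptide,
#'   condition, f, e_max, ks)
#' @param pep \code{peptide_synthesis} table
#' @return data.frame per condition: bias and RMSE of the recovered
#'   fraction-new and Ks over matched peptides
#' @export
recovery_report <- function(truth, pep) {
  key_t <- paste(truth$peptide, truth$condition, sep = "\r")
  key_p <- paste(pep$sequence, pep$condition, sep = "\r")
  m <- match(key_p, key_t)
  d <- data.frame(condition = pep$condition,
                  f_true = truth$f[m], f_hat = pep$corrected_lpf,
                  ks_true = truth$ks[m], ks_hat = pep$ks)
  d <- d[!is.na(d$f_hat) & !is.na(d$f_true), ]
  out <- NULL
  for (cond in unique(d$condition)) {
    s <- d[d$condition == cond, ]
    out <- rbind(out, data.frame(
      condition = cond, n = nrow(s),
      bias_f = mean(s$f_hat - s$f_true),
      rmse_f = sqrt(mean((s$f_hat - s$f_true)^2)),
      bias_ks = mean(s$ks_hat - s$ks_true),
      rmse_ks = sqrt(mean((s$ks_hat - s$ks_true)^2)),
      stringsAsFactors = FALSE))
  }
  out
}
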