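# From corrected peptide enrichments to physiology-normalized fractional
# protein synthesis rates: significance filtering, pool-dilution
# correction (LPF / E_max), Ks = corrected LPF x RGR x 100, and
# protein-level aggregation and differential statistics.

star_of <- function(q) {
  ifelse(is.na(q), "",
         ifelse(q < 0.01, "***",
                ifelse(q < 0.05, "**", ifelse(q < 0.1, "*", ""))))
}

#' Per-sample labelled-peptide fractions from an envelope table
#'
#' NIA-corrects every peptide envelope and reports both enrichment
#' statistics: the mean isotopic enrichment over the labelable atoms (the
#' default LPF) and 1 - x0 (the fraction of molecules carrying any
#' label). The labelable-atom count is taken from the pools of the row's
#' own condition, since conditions can label different amino-acid sets.
#'
#' @param envs envelope table from [extract_all_envelopes()] or
#'   [read_envelopes()] (needs sequence, charge, condition, replicate,
#'   labelled, envelope columns)
#' @param enrich_by_condition named list: condition -> per-amino-acid
#'   enrichment vector (see [enrichment_vector()])
#' @param residues residue table
#' @param policy isotope policy
#' @param purity tracer purity
#' @return input table with added columns lpf, one_minus_x0, residual,
#'   completeness (fraction of expected peaks observed), n_labelable,
#'   e_max
#' @export
peptide_lpf <- function(envs, enrich_by_condition,
                        residues = residue_table(),
                        policy = isotope_policy(), purity = 0.99) {
  n <- nrow(envs)
  out <- envs
  out$lpf <- out$one_minus_x0 <- out$residual <- out$completeness <-
    out$e_max <- NA_real_
  out$n_labelable <- NA_integer_
  # correction matrices are cached per (sequence, condition, n_peaks)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    cond <- envs$condition[i]
    enrich <- enrich_by_condition[[cond]]
    if (is.null(enrich)) stop("no pool enrichments for condition ", cond)
    m <- envs$envelope[[i]]
    out$completeness[i] <- mean(m > 0)
    if (sum(m) <= 0) next
    seqc <- envs$sequence[i]
    key <- paste(seqc, cond, length(m), sep = "\r")
    if (is.null(cache[[key]])) {
      f <- formula_of_peptide(seqc, residues)
      cla <- count_labelable_atoms(seqc, residues, enrich)
      A <- if (cla$n_labelable >= 1)
        correction_matrix(f, policy, cla$n_labelable, length(m), purity)
      else NULL
      cache[[key]] <- list(A = A, nl = cla$n_labelable,
                           e_max = max_lpf(seqc, enrich, residues))
    }
    cc <- cache[[key]]
    out$n_labelable[i] <- cc$nl
    out$e_max[i] <- cc$e_max
    if (is.null(cc$A)) next  # no labelable atoms: LPF undefined
    ce <- correct_envelope(m, cc$A)
    out$lpf[i] <- ce$enrichment
    out$one_minus_x0[i] <- ce$one_minus_x0
    out$residual[i] <- ce$residual
  }
  out
}

#' Maximum attainable labelled-peptide fraction
#'
#' The mean isotopic enrichment a fully newly synthesized peptide would
#' show over its labelable atoms:
#' \code{E_max = sum(nN(a) e_a) / sum(nN(a))} over residues with
#' \code{e_a > 0}. Residues from undetected pools contribute neither to
#' the numerator nor the denominator — the same labelable-atom convention
#' the NIA enrichment uses, so the ratio LPF / E_max is internally
#' consistent.
#'
#' @param sequence peptide string
#' @param enrich named per-amino-acid enrichment vector
#' @param residues residue table
#' @return E_max, or NA with a reason attribute when no atom is labelable
#' @export
max_lpf <- function(sequence, enrich, residues = residue_table()) {
  cla <- count_labelable_atoms(sequence, residues, enrich)
  b <- cla$breakdown[cla$breakdown$labelable, ]
  if (!nrow(b)) {
    out <- NA_real_
    attr(out, "reason") <- "no labelable atoms"
    return(out)
  }
  sum(b$nN * b$e_a) / sum(b$nN)
}

#' Significance filter for peptide labelling
#'
#' One-sided Welch t-test that the labelled-replicate LPFs exceed the
#' unlabelled baseline (or zero, whichever is larger; with no unlabelled
#' replicates the test is one-sample against zero). Returns the raw p;
#' multiple-testing adjustment happens across the whole peptide table in
#' [peptide_synthesis()].
#'
#' @param lpf_labelled numeric LPFs of labelled replicates
#' @param lpf_unlabelled numeric LPFs of unlabelled replicates (may be
#'   empty)
#' @return list: p, n_labelled, baseline, reason (non-NA on automatic
#'   fail)
#' @export
lpf_filter <- function(lpf_labelled, lpf_unlabelled = numeric(0)) {
  lpf_labelled <- lpf_labelled[!is.na(lpf_labelled)]
  lpf_unlabelled <- lpf_unlabelled[!is.na(lpf_unlabelled)]
  if (length(lpf_labelled) < 2)
    return(list(p = NA_real_, n_labelled = length(lpf_labelled),
                baseline = NA_real_, reason = "insufficient replicates"))
  baseline <- max(0, if (length(lpf_unlabelled)) mean(lpf_unlabelled) else 0)
  # essentially-constant data (e.g. noiseless input): call by ordering
  tol <- 1e-10 * max(1, abs(mean(lpf_labelled)))
  sd_lab <- stats::sd(lpf_labelled)
  sd_unl <- if (length(lpf_unlabelled) >= 2) stats::sd(lpf_unlabelled) else 0
  if (sd_lab < tol && sd_unl < tol) {
    p <- if (mean(lpf_labelled) > baseline + tol) 0 else 1
    return(list(p = p, n_labelled = length(lpf_labelled),
                baseline = baseline, reason = NA_character_))
  }
  p <- if (length(lpf_unlabelled) >= 2 && sd_unl >= tol) {
    stats::t.test(lpf_labelled, pmax(lpf_unlabelled, 0),
                  alternative = "greater")$p.value
  } else {
    stats::t.test(lpf_labelled, mu = baseline,
                  alternative = "greater")$p.value
  }
  list(p = p, n_labelled = length(lpf_labelled), baseline = baseline,
       reason = NA_character_)
}

#' Pool-dilution corrected labelled-peptide fraction
#'
#' \code{LPF / E_max}: the estimated fraction of the peptide's molecules
#' synthesized during the labelling window. Values above 1 indicate an
#' underestimated pool enrichment and are flagged, not truncated.
#'
#' @param lpf labelled-peptide fraction
#' @param e_max maximum attainable LPF
#' @return numeric with attribute \code{flag} when > 1
#' @export
corrected_lpf <- function(lpf, e_max) {
  if (is.na(e_max) || e_max <= 0) stop("E_max must be > 0")
  out <- lpf / e_max
  if (!is.na(out) && out > 1) attr(out, "flag") <- "pool underestimate"
  out
}

#' Fractional protein synthesis rate
#'
#' \code{Ks = corrected LPF x RGR x 100}, in percent per hour: the
#' fraction-new scaled by the tissue's relative growth rate over the
#' labelling window.
#'
#' @param clpf corrected LPF (fraction-new)
#' @param rgr_avg average relative growth rate over the labelling window
#'   (per hour), typically the dry-weight RGR
#' @export
ks_rate <- function(clpf, rgr_avg) {
  as.numeric(clpf) * rgr_avg * 100
}

#' Per-peptide synthesis table
#'
#' Aggregates per-sample LPFs to one row per (sequence, charge,
#' condition): labelling significance (BH-adjusted across the table),
#' E_max, corrected LPF and Ks, plus the quality gates — replicate count,
#' NNLS residual and envelope completeness. Gate counts are recorded in
#' the \code{funnel} attribute.
#'
#' @param lpf_tab output of [peptide_lpf()]
#' @param rgr_by_condition named numeric: condition -> average RGR (h^-1)
#' @param q_max BH q-value gate (default 0.05)
#' @param resid_max maximum mean NNLS relative residual (default 0.1)
#' @param completeness_min minimum mean fraction of expected envelope
#'   peaks observed (default 0.8)
#' @return data.frame of class \code{peptide_synthesis}; attribute
#'   \code{funnel} holds the filter-chain counts
#' @export
peptide_synthesis <- function(lpf_tab, rgr_by_condition, q_max = 0.05,
                              resid_max = 0.1, completeness_min = 0.8) {
  key <- paste(lpf_tab$sequence, lpf_tab$charge, lpf_tab$condition,
               sep = "\r")
  rows <- lapply(split(seq_len(nrow(lpf_tab)), key), function(idx) {
    d <- lpf_tab[idx, ]
    lab <- d[d$labelled %in% c(TRUE, "TRUE", "True", 1), ]
    unl <- d[!(d$labelled %in% c(TRUE, "TRUE", "True", 1)), ]
    ft <- lpf_filter(lab$lpf, unl$lpf)
    e_max <- d$e_max[1]
    lpf <- mean(lab$lpf, na.rm = TRUE)
    clpf <- if (!is.na(e_max) && e_max > 0 && !is.na(lpf))
      corrected_lpf(lpf, e_max) else NA_real_
    data.frame(sequence = d$sequence[1], charge = d$charge[1],
               condition = d$condition[1],
               n_labelled = ft$n_labelled,
               lpf = lpf,
               one_minus_x0 = mean(lab$one_minus_x0, na.rm = TRUE),
               e_max = e_max,
               corrected_lpf = as.numeric(clpf),
               clpf_flag = if (!is.null(attr(clpf, "flag")))
                 attr(clpf, "flag") else "",
               p = ft$p,
               residual = mean(lab$residual, na.rm = TRUE),
               completeness = mean(lab$completeness, na.rm = TRUE),
               fail_reason = if (is.na(ft$reason)) "" else ft$reason,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  gate_q <- !is.na(tab$q) & tab$q < q_max
  gate_rep <- tab$n_labelled >= 2
  gate_res <- !is.na(tab$residual) & tab$residual <= resid_max
  gate_cmp <- !is.na(tab$completeness) & tab$completeness >= completeness_min
  tab$pass <- gate_q & gate_rep & gate_res & gate_cmp
  tab$ks <- NA_real_
  for (cond in names(rgr_by_condition)) {
    sel <- tab$condition == cond
    tab$ks[sel] <- ks_rate(tab$corrected_lpf[sel], rgr_by_condition[[cond]])
  }
  funnel <- c(total = nrow(tab), replicates = sum(gate_rep),
              significant = sum(gate_q & gate_rep),
              residual = sum(gate_q & gate_rep & gate_res),
              complete = sum(tab$pass))
  structure(tab, class = c("peptide_synthesis", "data.frame"),
            funnel = funnel)
}

#' Map peptides to proteins and aggregate synthesis statistics
#'
#' Peptides mapping to more than one protein group are discarded (razor
#' assignment off): synthesis rates of paralogues must not be mixed in a
#' study of paralogue-specific synthesis. Per protein and condition the
#' median corrected LPF and Ks over passing peptides are reported; a
#' protein is flagged synthesized when at least \code{min_peptides}
#' peptides pass.
#'
#' @param pep \code{peptide_synthesis} table
#' @param protein_map named character: sequence -> protein group string
#'   (";"-separated when shared); typically from the evidence table
#' @param min_peptides passing peptides required to flag synthesis
#'   (default 1)
#' @return data.frame: protein, condition, n_peptides, n_passing,
#'   median_clpf, median_ks, dispersion (MAD of Ks), synthesized
#' @export
aggregate_protein <- function(pep, protein_map, min_peptides = 1) {
  prot <- protein_map[pep$sequence]
  shared <- !is.na(prot) & grepl(";", prot, fixed = TRUE)
  keep <- !is.na(prot) & !shared
  pep <- pep[keep, ]
  prot <- prot[keep]
  key <- paste(prot, pep$condition, sep = "\r")
  rows <- lapply(split(seq_len(nrow(pep)), key), function(idx) {
    d <- pep[idx, ]
    pass <- d[d$pass, ]
    data.frame(protein = prot[idx[1]], condition = d$condition[1],
               n_peptides = nrow(d), n_passing = nrow(pass),
               median_clpf = if (nrow(pass)) stats::median(pass$corrected_lpf)
                             else NA_real_,
               median_ks = if (nrow(pass)) stats::median(pass$ks)
                           else NA_real_,
               dispersion = if (nrow(pass)) stats::mad(pass$ks)
                            else NA_real_,
               synthesized = nrow(pass) >= min_peptides,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential synthesis between conditions
#'
#' Per protein: replicate-level corrected LPFs (median over the protein's
#' passing peptides within each replicate) are compared between two
#' conditions by a two-sided Welch t-test, BH-adjusted across proteins,
#' with significance stars at q < 0.1 (*), < 0.05 (**) and < 0.01 (***).
#'
#' @param rep_tab data.frame with columns protein, condition, replicate,
#'   value (replicate-level corrected LPF or Ks)
#' @param conditions length-2 character: conditions to compare (difference
#'   is condition 1 minus condition 2)
#' @return data.frame: protein, mean1, mean2, diff, p, q, star, skipped
#'   proteins carry a reason
#' @export
compare_ks <- function(rep_tab, conditions) {
  stopifnot(length(conditions) == 2)
  rows <- lapply(split(rep_tab, rep_tab$protein), function(d) {
    v1 <- d$value[d$condition == conditions[1]]
    v2 <- d$value[d$condition == conditions[2]]
    if (length(v1) < 2 || length(v2) < 2)
      return(data.frame(protein = d$protein[1], mean1 = NA_real_,
                        mean2 = NA_real_, diff = NA_real_, p = NA_real_,
                        reason = "missing condition or replicates",
                        stringsAsFactors = FALSE))
    p <- if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      if (mean(v1) == mean(v2)) 1 else 0
    } else stats::t.test(v1, v2)$p.value
    data.frame(protein = d$protein[1], mean1 = mean(v1), mean2 = mean(v2),
               diff = mean(v1) - mean(v2), p = p, reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$star <- star_of(out$q)
  out
}

#' Replicate-level corrected LPFs per protein
#'
#' Builds the input for [compare_ks()]: per protein, condition and
#' biological replicate, the median corrected LPF over the protein's
#' passing peptides in that replicate.
#'
#' @param lpf_tab output of [peptide_lpf()] (labelled samples only are
#'   used)
#' @param pep \code{peptide_synthesis} table (supplies the pass flags and
#'   E_max)
#' @param protein_map named character: sequence -> protein group
#' @return data.frame: protein, condition, replicate, value
#' @export
protein_replicate_clpf <- function(lpf_tab, pep, protein_map) {
  pass_key <- paste(pep$sequence, pep$charge, pep$condition, sep = "\r")
  pass <- stats::setNames(pep$pass, pass_key)
  lab <- lpf_tab[lpf_tab$labelled %in% c(TRUE, "TRUE", "True", 1), ]
  key <- paste(lab$sequence, lab$charge, lab$condition, sep = "\r")
  lab <- lab[!is.na(pass[key]) & pass[key], ]
  prot <- protein_map[lab$sequence]
  keep <- !is.na(prot) & !grepl(";", prot, fixed = TRUE)
  lab <- lab[keep, ]
  prot <- prot[keep]
  clpf <- lab$lpf / lab$e_max
  agg <- stats::aggregate(clpf,
                          by = list(protein = prot,
                                    condition = lab$condition,
                                    replicate = lab$replicate),
                          FUN = stats::median)
  names(agg)[4] <- "value"
  agg
}
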