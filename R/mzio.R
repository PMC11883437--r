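# IO for peptide evidence tables (MaxQuant dialect), MS1 peak data (mzML
# via mzR, or a plain peak-table TSV) and FASTA, plus per-peptide
# isotopologue envelope extraction with peak-count optimization.

EVIDENCE_COLS <- c("Sequence", "Charge", "m/z", "Retention time",
                   "Raw file", "Proteins", "Intensity")

#' Read a peptide evidence table
#'
#' Accepts the MaxQuant evidence.txt dialect: a TSV with at least the
#' columns Sequence, Charge, m/z, Retention time, Raw file, Proteins and
#' Intensity (extra columns ignored; optional Condition, Replicate and
#' Labelled columns are carried through). Rows with missing mandatory
#' fields are dropped with a message reporting the count.
#'
#' @param path TSV path
#' @return data.frame of class \code{evidence} with columns sequence,
#'   charge, mz, rt_apex, raw_file, proteins, intensity, condition,
#'   replicate, labelled; attribute \code{n_dropped}
#' @export
read_evidence <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(EVIDENCE_COLS, names(tab))
  if (length(miss))
    stop("evidence table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  opt <- function(col)
    if (col %in% names(tab)) tab[[col]] else rep(NA, nrow(tab))
  ev <- data.frame(sequence = as.character(tab$Sequence),
                   charge = suppressWarnings(as.integer(tab$Charge)),
                   mz = suppressWarnings(as.numeric(tab[["m/z"]])),
                   rt_apex = suppressWarnings(as.numeric(tab[["Retention time"]])),
                   raw_file = as.character(tab[["Raw file"]]),
                   proteins = as.character(tab$Proteins),
                   intensity = suppressWarnings(as.numeric(tab$Intensity)),
                   condition = as.character(opt("Condition")),
                   replicate = as.character(opt("Replicate")),
                   labelled = opt("Labelled"),
                   stringsAsFactors = FALSE)
  ok <- nzchar(ev$sequence) & !is.na(ev$charge) & !is.na(ev$mz) &
    !is.na(ev$rt_apex) & nzchar(ev$raw_file)
  ok[is.na(ok)] <- FALSE
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("read_evidence: dropped ", n_dropped,
            " row(s) with missing mandatory fields")
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) && any(ev$charge < 1 | ev$charge > 8, na.rm = TRUE))
    warning("charge states outside [1, 8] present")
  structure(ev, class = c("evidence", "data.frame"), n_dropped = n_dropped)
}

#' Flag evidence rows whose m/z disagrees with the peptide formula
#'
#' Computes the theoretical monoisotopic m/z from the peptide formula and
#' flags records deviating by more than \code{ppm_max} (they are kept, not
#' dropped).
#'
#' @param ev evidence data.frame from [read_evidence()]
#' @param residues residue table
#' @param policy isotope policy
#' @param ppm_max tolerance in ppm (default 25)
#' @export
validate_evidence_mz <- function(ev, residues = residue_table(),
                                 policy = isotope_policy(), ppm_max = 25) {
  theo <- vapply(seq_len(nrow(ev)), function(i) {
    mono_mz(formula_of_peptide(ev$sequence[i], residues), ev$charge[i],
            policy)
  }, numeric(1))
  ev$ppm_dev <- (ev$mz - theo) / theo * 1e6
  ev$mz_flag <- abs(ev$ppm_dev) > ppm_max
  ev
}

#' Read MS1 peak data
#'
#' Reads centroided MS1 peaks either from an mzML file (through the mzR
#' package) or from a plain peak-table TSV with columns scan, rt_min, mz,
#' intensity — the download-free interchange format also written by the
#' simulator.
#'
#' @param path .mzML or .tsv path
#' @return data.frame with columns scan, rt_min, mz, intensity
#' @export
read_ms1 <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    h <- NULL
    ms <- mzR::openMSfile(path)
    on.exit(mzR::close(ms))
    hd <- mzR::header(ms)
    ms1 <- which(hd$msLevel == 1)
    out <- lapply(ms1, function(i) {
      pk <- mzR::peaks(ms, i)
      data.frame(scan = hd$seqNum[i], rt_min = hd$retentionTime[i] / 60,
                 mz = pk[, 1], intensity = pk[, 2])
    })
    return(do.call(rbind, out))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scan", "rt_min", "mz", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("MS1 peak table missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Read protein sequences from FASTA
#' @param path FASTA path
#' @return named character vector (ID -> sequence); the ID is the first
#'   whitespace-delimited token of the header
#' @export
read_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  stats::setNames(toupper(unlist(fa)), names(fa))
}

# default isotopologue spacing: 13C - 12C mass difference divided by charge
# (MaxQuant convention); the 15N spacing difference is absorbed by the ppm
# tolerance at resolutions where C and N isotopologues are not resolved.
ISOTOPE_SPACING <- 1.00335

#' Optimal isotopologue peak count for a peptide
#'
#' The number of envelope peaks is the number of labelable atoms plus
#' however many natural-isotope peaks the non-labelled part of the
#' molecule needs to capture \code{natural_tail_cutoff} of its probability
#' mass, plus the monoisotopic peak.
#'
#' @param formula peptide \code{elemental_formula}
#' @param n_labelable labelable atom count (from
#'   [count_labelable_atoms()])
#' @param policy isotope policy
#' @param natural_tail_cutoff cumulative-mass cutoff in (0.99, 1)
#' @return integer peak count (k + 1, envelope M0..Mk)
#' @export
optimal_peak_count <- function(formula, n_labelable,
                               policy = isotope_policy(),
                               natural_tail_cutoff = 0.999) {
  stopifnot(natural_tail_cutoff > 0.99, natural_tail_cutoff < 1)
  f <- as_formula(formula)
  el <- policy$label_element
  # natural envelope of everything except the labelable atoms
  max_j <- 64L
  nat <- natural_distribution(f, policy, max_j,
                              exclude = stats::setNames(n_labelable, el))
  cum <- cumsum(nat)
  n_nat <- which(cum >= natural_tail_cutoff)[1] - 1L
  if (is.na(n_nat)) n_nat <- max_j - 1L
  as.integer(n_labelable + n_nat + 1L)
}

#' Extract an isotopologue envelope from MS1 peaks
#'
#' For each isotopologue i = 0..n_peaks-1, sums over all MS1 scans within
#' the retention-time window the most intense centroid within
#' \code{ppm_tol} of m/z0 + i * spacing / z. A missing peak contributes
#' zero intensity; if no MS1 scan falls in the window the envelope is all
#' zeros and flagged \code{not_found}.
#'
#' @param ms1 data.frame from [read_ms1()] (or a path)
#' @param mz0 monoisotopic m/z anchor
#' @param z charge
#' @param rt_apex retention-time apex in minutes
#' @param n_peaks envelope length
#' @param ppm_tol matching tolerance in ppm (default 10)
#' @param rt_halfwidth_min half-width of the integration window in minutes
#'   (default 0.5)
#' @param spacing isotopologue spacing in Da (default 1.00335, the 13C
#'   spacing)
#' @return list of class \code{envelope}: \code{intensity} (length
#'   n_peaks), \code{mz} (targets), \code{not_found}, \code{n_scans}
#' @export
extract_envelope <- function(ms1, mz0, z, rt_apex, n_peaks, ppm_tol = 10,
                             rt_halfwidth_min = 0.5,
                             spacing = ISOTOPE_SPACING) {
  if (is.character(ms1)) ms1 <- read_ms1(ms1)
  inwin <- abs(ms1$rt_min - rt_apex) <= rt_halfwidth_min
  sub <- ms1[inwin, , drop = FALSE]
  targets <- mz0 + (0:(n_peaks - 1)) * spacing / z
  intensity <- numeric(n_peaks)
  if (nrow(sub) == 0)
    return(structure(list(intensity = intensity, mz = targets,
                          not_found = TRUE, n_scans = 0L),
                     class = "envelope"))
  for (sc in unique(sub$scan)) {
    pk <- sub[sub$scan == sc, , drop = FALSE]
    for (i in seq_len(n_peaks)) {
      tol <- targets[i] * ppm_tol * 1e-6
      hit <- which(abs(pk$mz - targets[i]) <= tol)
      if (length(hit))
        intensity[i] <- intensity[i] + max(pk$intensity[hit])
    }
  }
  structure(list(intensity = intensity, mz = targets,
                 not_found = all(intensity == 0),
                 n_scans = length(unique(sub$scan))),
            class = "envelope")
}

#' Extract envelopes for every evidence record
#'
#' Convenience wrapper: groups evidence rows by (sequence, charge, raw
#' file), sums envelopes over multiple evidence rows of the same peptide
#' in the same run (the usual LFQ aggregation), and returns one row per
#' peptide/sample with the envelope columns M0..Mk.
#'
#' @param ev evidence data.frame
#' @param ms1 MS1 peak data.frame or path
#' @param enrich named per-amino-acid enrichment vector used for peak-count
#'   optimization (per the record's condition; a single vector applies to
#'   all records)
#' @param residues residue table
#' @param policy isotope policy
#' @inheritParams extract_envelope
#' @param natural_tail_cutoff see [optimal_peak_count()]
#' @return data.frame: sequence, charge, raw_file, condition, replicate,
#'   labelled, n_peaks, not_found, then M0..Mk (ragged envelopes padded
#'   with NA)
#' @export
extract_all_envelopes <- function(ev, ms1, enrich,
                                  residues = residue_table(),
                                  policy = isotope_policy(), ppm_tol = 10,
                                  rt_halfwidth_min = 0.5,
                                  spacing = ISOTOPE_SPACING,
                                  natural_tail_cutoff = 0.999) {
  if (is.character(ms1)) ms1 <- read_ms1(ms1)
  key <- paste(ev$sequence, ev$charge, ev$raw_file, sep = "\r")
  groups <- split(seq_len(nrow(ev)), key)
  rows <- lapply(groups, function(idx) {
    r <- ev[idx[1], ]
    f <- formula_of_peptide(r$sequence, residues)
    nl <- count_labelable_atoms(r$sequence, residues, enrich)$n_labelable
    np <- optimal_peak_count(f, nl, policy, natural_tail_cutoff)
    env <- numeric(np)
    found <- FALSE
    for (i in idx) {
      e <- extract_envelope(ms1, ev$mz[i], ev$charge[i], ev$rt_apex[i],
                            np, ppm_tol, rt_halfwidth_min, spacing)
      env <- env + e$intensity
      found <- found || !e$not_found
    }
    out <- data.frame(sequence = r$sequence, charge = r$charge,
                      raw_file = r$raw_file, condition = r$condition,
                      replicate = r$replicate, labelled = r$labelled,
                      n_labelable = nl, n_peaks = np,
                      not_found = !found, stringsAsFactors = FALSE)
    out$envelope <- list(env)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write an envelope table to TSV
#'
#' Flattens the list-column of envelopes into M0..Mk columns (padded with
#' NA for shorter envelopes).
#' @param envs output of [extract_all_envelopes()]
#' @param path output TSV path
#' @export
write_envelopes <- function(envs, path) {
  kmax <- max(vapply(envs$envelope, length, integer(1)))
  m <- t(vapply(envs$envelope, function(e) c(e, rep(NA, kmax - length(e))),
                numeric(kmax)))
  colnames(m) <- paste0("M", seq_len(kmax) - 1)
  flat <- cbind(envs[setdiff(names(envs), "envelope")], as.data.frame(m))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(flat)
}

#' Read an envelope table written by [write_envelopes()]
#' @param path TSV path
#' @export
read_envelopes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mcols <- grep("^M[0-9]+$", names(tab), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^M", "", mcols)))]
  tab$envelope <- lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, mcols])
    v[!is.na(v)]
  })
  tab[setdiff(names(tab), mcols)]
}
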