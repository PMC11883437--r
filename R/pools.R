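# Soluble amino-acid pool 15N enrichment from GC-MS fragment isotopologue
# tables: fragment consistency QC, NIA correction per fragment,
# control-baseline handling, fragment selection by relative standard
# deviation, and cross-treatment statistics.
#
# The pool enrichments are the proxy for the labelling of amino-acylated
# tRNAs and set the ceiling (E_max) any fully new peptide can reach.

# analyte aliases introduced by extraction/derivatization chemistry:
# glutamine is measured via its conversion product pyroglutamate
DEFAULT_AA_ALIASES <- c(pyroglutamate = "Q", pyroglutamic_acid = "Q")

#' Read a GC-MS fragment isotopologue table
#'
#' TSV with columns amino_acid (one-letter code or alias), fragment_id,
#' formula (Hill string, e.g. \code{"C5H10N2O2"}), sample_id, condition,
#' replicate (biological), labelled (logical), optional tech_rep, and
#' isotopologue intensity columns M0..Mk. Fragments without nitrogen are
#' rejected (they carry no label information).
#'
#' @param path TSV path
#' @param aliases named character: analyte name -> amino-acid code
#' @return data.frame with an \code{envelope} list-column and an
#'   \code{nN} column (fragment nitrogen count)
#' @export
read_fragments <- function(path, aliases = DEFAULT_AA_ALIASES) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("amino_acid", "fragment_id", "formula", "sample_id",
            "condition", "replicate", "labelled")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("fragment table missing column(s): ", paste(miss, collapse = ", "))
  if (!"tech_rep" %in% names(tab)) tab$tech_rep <- 1L
  al <- tab$amino_acid %in% names(aliases)
  tab$amino_acid[al] <- aliases[tab$amino_acid[al]]
  mcols <- grep("^M[0-9]+$", names(tab), value = TRUE)
  mcols <- mcols[order(as.integer(sub("^M", "", mcols)))]
  if (!length(mcols)) stop("no isotopologue columns M0..Mk found")
  tab$envelope <- lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, mcols])
    v[!is.na(v)]
  })
  tab$nN <- vapply(tab$formula,
                   function(s) unclass(parse_formula(s))[["N"]], numeric(1))
  if (any(tab$nN < 1))
    stop("fragment(s) without nitrogen rejected: ",
         paste(unique(tab$fragment_id[tab$nN < 1]), collapse = ", "))
  tab$labelled <- as.logical(tab$labelled)
  tab[setdiff(names(tab), mcols)]
}

#' Summed-isotopologue consistency between fragments of one amino acid
#'
#' Because labelling redistributes intensity across isotopologues, the
#' classical monoisotopic-abundance correlation is replaced by the Pearson
#' correlation of per-sample summed isotopologue abundances between each
#' fragment pair. Pairs below \code{threshold} are flagged inconsistent.
#'
#' @param frags fragment rows (one amino acid) from [read_fragments()]
#' @param threshold flagging threshold on r (default 0.8)
#' @return list: \code{r} (correlation matrix), \code{inconsistent}
#'   (data.frame of flagged pairs)
#' @export
fragment_pair_consistency <- function(frags, threshold = 0.8) {
  fr <- unique(frags$fragment_id)
  if (length(fr) < 2) stop("need >= 2 fragments")
  samples <- unique(frags$sample_id)
  if (length(samples) < 3) stop("need >= 3 samples")
  m <- matrix(NA_real_, length(samples), length(fr),
              dimnames = list(samples, fr))
  for (i in seq_len(nrow(frags)))
    m[frags$sample_id[i], frags$fragment_id[i]] <- sum(frags$envelope[[i]])
  r <- stats::cor(m, use = "pairwise.complete.obs")
  bad <- which(r < threshold & upper.tri(r), arr.ind = TRUE)
  inconsistent <- data.frame(fragment1 = rownames(r)[bad[, 1]],
                             fragment2 = colnames(r)[bad[, 2]],
                             r = r[bad], stringsAsFactors = FALSE)
  list(r = r, inconsistent = inconsistent)
}

#' Per-sample enrichment of one fragment
#'
#' NIA-corrects each sample's isotopologue envelope of the fragment and
#' returns the mean isotopic enrichment, with the fragment's nitrogen
#' count as the labelable-atom number.
#'
#' @param frags rows of one fragment from [read_fragments()]
#' @param policy isotope policy
#' @param purity tracer purity
#' @return input rows with added columns \code{enrichment},
#'   \code{residual}
#' @export
fragment_enrichment <- function(frags, policy = isotope_policy(),
                                purity = 0.99) {
  stopifnot(length(unique(frags$fragment_id)) == 1)
  f <- parse_formula(frags$formula[1])
  nN <- unclass(f)[["N"]]
  np <- length(frags$envelope[[1]])
  A <- correction_matrix(f, policy, n_label = nN, n_peaks = np,
                         purity = purity)
  res <- lapply(frags$envelope, function(m) {
    ce <- correct_envelope(m, A)
    c(ce$enrichment, ce$residual)
  })
  frags$enrichment <- vapply(res, `[`, numeric(1), 1)
  frags$residual <- vapply(res, `[`, numeric(1), 2)
  frags
}

# RSD across biological replicates, technical replicates pooled first
labelled_rsd <- function(d) {
  lab <- d[d$labelled, ]
  if (!nrow(lab)) return(NA_real_)
  bio <- tapply(lab$enrichment, lab$replicate, mean)
  if (mean(bio) == 0) return(Inf)
  stats::sd(bio) / abs(mean(bio))
}

#' Select the reporting fragment for each amino acid
#'
#' Implements the fragment QC cascade: (1) fragments showing non-null
#' enrichment in non-labelled control samples are discarded — unless every
#' fragment is contaminated, in which case the mean control "enrichment"
#' is subtracted from the labelled samples (technical-bias correction) and
#' fragments with minimal post-subtraction control variance are retained;
#' (2) among survivors the fragment with the lowest relative standard
#' deviation across replicates (technical replicates pooled within
#' biological replicates first) is chosen. Negative post-subtraction
#' enrichments are clipped to zero and flagged. Fewer than three candidate
#' fragments raises a QC warning, not a rejection.
#'
#' @param enr per-sample fragment enrichments of one amino acid and one
#'   condition pair (labelled + control samples), as returned by
#'   [fragment_enrichment()]
#' @param null_threshold absolute control-mean enrichment below which a
#'   fragment counts as clean (default 0.002)
#' @param var_slack clean post-subtraction fragments are those whose
#'   control s.d. is within this factor of the minimum (default 2)
#' @return list: \code{fragment_id}, \code{enrichments} (per labelled
#'   sample, baseline-subtracted if applicable), \code{e_a} (mean over
#'   biological replicates), \code{sd}, \code{flags} (character vector),
#'   \code{undetected}
#' @export
select_fragments <- function(enr, null_threshold = 0.002, var_slack = 2) {
  flags <- character(0)
  fr <- unique(enr$fragment_id)
  if (length(fr) < 3)
    flags <- c(flags, sprintf("fewer than 3 fragments (%d)", length(fr)))
  ctrl_mean <- vapply(fr, function(id) {
    d <- enr[enr$fragment_id == id & !enr$labelled, ]
    if (!nrow(d)) NA_real_ else mean(d$enrichment)
  }, numeric(1))
  clean <- fr[!is.na(ctrl_mean) & abs(ctrl_mean) < null_threshold]
  subtracted <- FALSE
  if (length(clean) == 0) {
    if (all(is.na(ctrl_mean)))
      return(list(fragment_id = NA_character_, enrichments = NULL,
                  e_a = 0, sd = NA_real_,
                  flags = c(flags, "undetected: no control samples"),
                  undetected = TRUE))
    # every fragment carries technical bias: subtract control baseline
    subtracted <- TRUE
    flags <- c(flags, "control baseline subtracted")
    enr$enrichment <- enr$enrichment - ctrl_mean[enr$fragment_id]
    ctrl_sd <- vapply(fr, function(id) {
      d <- enr[enr$fragment_id == id & !enr$labelled, ]
      stats::sd(d$enrichment)
    }, numeric(1))
    clean <- fr[!is.na(ctrl_sd) & ctrl_sd <= var_slack * min(ctrl_sd,
                                                             na.rm = TRUE)]
  }
  if (length(clean) == 0)
    return(list(fragment_id = NA_character_, enrichments = NULL, e_a = 0,
                sd = NA_real_,
                flags = c(flags, "undetected: no fragment passed QC"),
                undetected = TRUE))
  rsd <- vapply(clean, function(id) labelled_rsd(enr[enr$fragment_id == id, ]),
                numeric(1))
  if (all(!is.finite(rsd)))
    return(list(fragment_id = NA_character_, enrichments = NULL, e_a = 0,
                sd = NA_real_,
                flags = c(flags, "undetected: no labelled signal"),
                undetected = TRUE))
  chosen <- clean[which.min(rsd)]
  keep <- enr[enr$fragment_id == chosen, ]
  neg <- keep$enrichment < 0
  if (any(neg)) {
    flags <- c(flags, sprintf("%d negative enrichment(s) clipped to 0",
                              sum(neg)))
    keep$enrichment[neg] <- 0
  }
  lab <- keep[keep$labelled, ]
  bio <- tapply(lab$enrichment, lab$replicate, mean)
  list(fragment_id = chosen, enrichments = keep, e_a = mean(bio),
       sd = stats::sd(bio), flags = flags, undetected = FALSE)
}

#' Amino-acid pool enrichment table from a fragment table
#'
#' Runs the full pools pipeline: per-fragment NIA correction and
#' enrichment, then fragment selection per amino acid within each
#' condition (each condition's labelled samples are judged against that
#' condition's non-labelled controls).
#'
#' @param frags data.frame from [read_fragments()]
#' @param policy isotope policy
#' @param purity tracer purity
#' @param null_threshold see [select_fragments()]
#' @return list of class \code{pool_table}: \code{table} (condition,
#'   amino_acid, e_a, sd, fragment_id, flags), \code{replicates}
#'   (per-replicate enrichments of the chosen fragments, for statistics)
#' @export
pool_table <- function(frags, policy = isotope_policy(), purity = 0.99,
                       null_threshold = 0.002) {
  enr <- do.call(rbind, lapply(split(frags, frags$fragment_id),
                               fragment_enrichment, policy = policy,
                               purity = purity))
  tab <- NULL
  reps <- NULL
  for (cond in unique(enr$condition)) {
    sub_c <- enr[enr$condition == cond, ]
    for (aa in unique(sub_c$amino_acid)) {
      sel <- select_fragments(sub_c[sub_c$amino_acid == aa, ],
                              null_threshold = null_threshold)
      tab <- rbind(tab, data.frame(condition = cond, amino_acid = aa,
                                   e_a = sel$e_a, sd = sel$sd,
                                   fragment_id = sel$fragment_id,
                                   flags = paste(sel$flags, collapse = "; "),
                                   undetected = sel$undetected,
                                   stringsAsFactors = FALSE))
      if (!is.null(sel$enrichments))
        reps <- rbind(reps, sel$enrichments[c("amino_acid", "fragment_id",
                                              "sample_id", "condition",
                                              "replicate", "tech_rep",
                                              "labelled", "enrichment")])
    }
  }
  structure(list(table = tab, replicates = reps), class = "pool_table")
}

#' Per-amino-acid enrichment vector for one condition
#'
#' Amino acids absent from the pool table are returned as 0 (undetected:
#' their nitrogen atoms are excluded from the labelable set).
#'
#' @param pools \code{pool_table}
#' @param condition condition label
#' @return named numeric vector over the 20 one-letter codes
#' @export
enrichment_vector <- function(pools, condition) {
  rt <- residue_table()
  out <- stats::setNames(numeric(nrow(rt)), rt$aa)
  tab <- pools$table[pools$table$condition == condition, ]
  hit <- tab$amino_acid %in% names(out)
  out[tab$amino_acid[hit]] <- tab$e_a[hit]
  out
}

#' Compare pool enrichments across treatments
#'
#' Per amino acid: one-way ANOVA over the condition-by-labelled groups of
#' per-replicate enrichments, followed by Tukey HSD and a compact letter
#' display (shared letter = not significantly different at \code{alpha}).
#'
#' @param pools \code{pool_table}
#' @param alpha significance level (default 0.05)
#' @return named list per amino acid of [anova_tukey()] results
#' @export
compare_pool_enrichments <- function(pools, alpha = 0.05) {
  reps <- pools$replicates
  if (is.null(reps)) stop("pool table holds no per-replicate enrichments")
  out <- list()
  for (aa in unique(reps$amino_acid)) {
    d <- reps[reps$amino_acid == aa, ]
    grp <- paste(d$condition, ifelse(d$labelled, "L", "NL"), sep = ".")
    if (length(unique(grp)) < 2 || any(table(grp) < 2)) next
    out[[aa]] <- anova_tukey(d$enrichment, grp, alpha = alpha)
  }
  out
}
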