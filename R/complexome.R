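# Complex-ome statistics at the LFQ level: subunit substoichiometry
# normalization, differential abundance with BH stars, the LSU:SSU ratio
# check, and the four-way accumulation/synthesis group classification of
# macromolecular complexes.

#' Read a label-free quantification matrix
#'
#' proteinGroups-style TSV: a protein identifier column (\code{Protein
#' IDs} or \code{protein}) plus one \code{LFQ intensity <sample>} column
#' per sample. Zeros are treated as missing (not quantified), as is the
#' MaxQuant convention.
#'
#' @param path TSV path
#' @param samples optional data.frame (sample, condition, replicate); when
#'   absent, condition and replicate are parsed from sample names of the
#'   form \code{<condition>_<replicate>}
#' @return list of class \code{lfq_matrix}: \code{lfq} (protein x sample
#'   matrix, NA = missing), \code{samples}
#' @export
read_lfq <- function(path, samples = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  idcol <- intersect(c("Protein IDs", "protein"), names(tab))[1]
  if (is.na(idcol)) stop("no protein identifier column found")
  lfqcols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  if (!length(lfqcols)) stop("no 'LFQ intensity <sample>' columns found")
  m <- as.matrix(tab[lfqcols])
  mode(m) <- "numeric"
  m[m == 0] <- NA
  if (any(m < 0, na.rm = TRUE)) stop("negative LFQ intensity")
  rownames(m) <- tab[[idcol]]
  colnames(m) <- sub("^LFQ intensity ", "", lfqcols)
  if (is.null(samples)) {
    parts <- strsplit(colnames(m), "_")
    samples <- data.frame(sample = colnames(m),
                          condition = vapply(parts, `[`, "", 1),
                          replicate = vapply(parts, function(p)
                            paste(p[-1], collapse = "_"), ""),
                          stringsAsFactors = FALSE)
  }
  structure(list(lfq = m, samples = samples), class = "lfq_matrix")
}

#' Build an lfq_matrix from a matrix and sample metadata
#' @param m protein x sample numeric matrix (NA = missing)
#' @param samples data.frame (sample, condition, replicate)
#' @export
lfq_matrix <- function(m, samples) {
  stopifnot(all(colnames(m) == samples$sample))
  if (any(m < 0, na.rm = TRUE)) stop("negative LFQ intensity")
  structure(list(lfq = m, samples = samples), class = "lfq_matrix")
}

#' Subunit substoichiometry normalization
#'
#' Normalizes each protein's abundance by the summed abundance of its own
#' subunit class in the same sample (e.g. 40S proteins by the 40S sum,
#' 60S by the 60S sum), correcting for the number of assembled subunits
#' per sample. Within-class values sum to 1 in every sample. Proteins
#' missing in a sample are excluded from that sample's class sum.
#'
#' @param lfq \code{lfq_matrix}
#' @param subunit_map data.frame: protein, subunit_class
#' @return matrix of normalized values (NA where missing or where the
#'   class sum is zero, with flagged samples in the
#'   \code{flagged_samples} attribute)
#' @export
substoichiometry <- function(lfq, subunit_map) {
  m <- lfq$lfq
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  flagged <- character(0)
  for (cls in unique(subunit_map$subunit_class)) {
    members <- intersect(subunit_map$protein[subunit_map$subunit_class == cls],
                         rownames(m))
    if (!length(members)) next
    sub <- m[members, , drop = FALSE]
    sums <- colSums(sub, na.rm = TRUE)
    zero <- sums <= 0
    if (any(zero))
      flagged <- c(flagged, paste0(cls, ":", colnames(m)[zero]))
    sums[zero] <- NA
    out[members, ] <- sweep(sub, 2, sums, `/`)
  }
  structure(out, flagged_samples = flagged)
}

#' Differential protein abundance between two conditions
#'
#' Welch t-test per protein on log2-transformed intensities with a
#' pseudo-intensity floor at the per-sample 1st percentile (variance
#' stabilization), pairwise-complete (no imputation), BH adjustment across
#' the table and stars at q < 0.1 / 0.05 / 0.01. \code{diff > 0} means
#' higher in \code{conditions[1]}.
#'
#' @param lfq \code{lfq_matrix} (or a plain matrix with \code{samples})
#' @param conditions length-2 character
#' @param samples sample metadata when \code{lfq} is a plain matrix
#' @param log2_transform set FALSE to test already-normalized values (e.g.
#'   substoichiometries) on their own scale
#' @return data.frame: protein, log2fc (or mean difference), p, q, star;
#'   proteins without >= 2 values per condition are skipped with a reason
#' @export
differential_abundance <- function(lfq, conditions, samples = NULL,
                                   log2_transform = TRUE) {
  if (inherits(lfq, "lfq_matrix")) {
    m <- lfq$lfq
    samples <- lfq$samples
  } else m <- lfq
  stopifnot(length(conditions) == 2)
  if (log2_transform) {
    floors <- apply(m, 2, function(v)
      stats::quantile(v[v > 0], 0.01, na.rm = TRUE, names = FALSE))
    m <- log2(pmax(m, rep(floors, each = nrow(m))))
  }
  s1 <- samples$sample[samples$condition == conditions[1]]
  s2 <- samples$sample[samples$condition == conditions[2]]
  rows <- lapply(rownames(m), function(p) {
    v1 <- m[p, s1]; v1 <- v1[!is.na(v1)]
    v2 <- m[p, s2]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2)
      return(data.frame(protein = p, log2fc = NA_real_, p = NA_real_,
                        reason = "insufficient replicates",
                        stringsAsFactors = FALSE))
    pval <- if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      if (mean(v1) == mean(v2)) 1 else 0
    } else stats::t.test(v1, v2)$p.value
    data.frame(protein = p, log2fc = mean(v1) - mean(v2), p = pval,
               reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$star <- star_of(out$q)
  out
}

#' Classify a complex response from its accumulation and synthesis flags
#'
#' The four response groups: 1 = accumulated and newly synthesized, 2 =
#' accumulated and not degraded (no label), 3 = not accumulated but newly
#' synthesized (turnover), 4 = neither.
#'
#' @param accumulated logical
#' @param synthesized logical
#' @return integer group 1-4 (NA with a reason attribute on undefined
#'   input)
#' @export
classify_group <- function(accumulated, synthesized) {
  if (is.na(accumulated) || is.na(synthesized)) {
    out <- NA_integer_
    attr(out, "reason") <- "undefined accumulation or synthesis flag"
    return(out)
  }
  if (accumulated && synthesized) 1L
  else if (accumulated) 2L
  else if (synthesized) 3L
  else 4L
}

#' Read complex membership definitions
#' @param path TSV: complex, go_id, members (";"-separated protein IDs)
#' @return data.frame with a \code{members} list-column
#' @export
read_complexes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("complex", "go_id", "members")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("complex table missing column(s): ", paste(miss, collapse = ", "))
  bad <- !grepl("^GO:[0-9]{7}$", tab$go_id)
  if (any(bad))
    stop("malformed GO ID(s): ", paste(tab$go_id[bad], collapse = ", "))
  tab$members <- strsplit(tab$members, ";", fixed = TRUE)
  if (any(lengths(tab$members) < 1)) stop("complex without members")
  tab
}

#' Classify one complex per condition into response groups
#'
#' A member is accumulated in a condition when the member-wise
#' differential abundance test is significant in that condition's
#' direction; it is synthesized when it passes the labelling filter in
#' that condition. Member flags are aggregated to the complex by
#' \code{agg_rule} ("majority" = more than half the detected members;
#' also "any" or "all"); the supporting member subsets are reported so a
#' complex can be called on a subset, mirroring nested child terms.
#' Accumulation is direction-aware, so a complex can be
#' accumulation-positive in at most one of the two conditions.
#'
#' @param cdef one row of [read_complexes()] (or a list with
#'   \code{complex}, \code{go_id}, \code{members})
#' @param diff differential-abundance table from
#'   [differential_abundance()] computed as conditions[1] vs conditions[2]
#' @param synthesis protein synthesis table from [aggregate_protein()]
#'   (protein, condition, synthesized)
#' @param conditions length-2 character, same order as \code{diff}
#' @param q_acc significance gate on accumulation (default 0.1, the
#'   loosest star)
#' @param agg_rule "majority", "any" or "all"
#' @return data.frame: complex, go_id, condition, accumulated,
#'   synthesized, group, n_detected, n_accumulated, n_synthesized,
#'   accumulated_members, synthesized_members
#' @export
classify_complex <- function(cdef, diff, synthesis, conditions,
                             q_acc = 0.1, agg_rule = "majority") {
  members <- unlist(cdef$members)
  detected <- intersect(members, diff$protein)
  if (!length(detected))
    return(data.frame(complex = cdef$complex, go_id = cdef$go_id,
                      condition = conditions, accumulated = NA,
                      synthesized = NA, group = NA_integer_,
                      n_detected = 0L, n_accumulated = NA_integer_,
                      n_synthesized = NA_integer_,
                      accumulated_members = "not detected",
                      synthesized_members = "not detected",
                      stringsAsFactors = FALSE))
  agg <- switch(agg_rule,
                majority = function(f) sum(f) > length(detected) / 2,
                any = function(f) any(f),
                all = function(f) all(f),
                stop("unknown aggregation rule: ", agg_rule))
  d <- diff[match(detected, diff$protein), ]
  out <- NULL
  for (k in 1:2) {
    cond <- conditions[k]
    sgn <- if (k == 1) 1 else -1
    acc_m <- !is.na(d$q) & d$q < q_acc & sgn * d$log2fc > 0
    syn_tab <- synthesis[synthesis$condition == cond, ]
    syn_m <- detected %in% syn_tab$protein[syn_tab$synthesized]
    accumulated <- agg(acc_m)
    synthesized <- agg(syn_m)
    out <- rbind(out, data.frame(
      complex = cdef$complex, go_id = cdef$go_id, condition = cond,
      accumulated = accumulated, synthesized = synthesized,
      group = classify_group(accumulated, synthesized),
      n_detected = length(detected), n_accumulated = sum(acc_m),
      n_synthesized = sum(syn_m),
      accumulated_members = paste(detected[acc_m], collapse = ";"),
      synthesized_members = paste(detected[syn_m], collapse = ";"),
      stringsAsFactors = FALSE))
  }
  out
}

#' LSU:SSU summed-abundance ratio
#'
#' Per-sample ratio of summed large-subunit (60S) to summed small-subunit
#' (40S) r-protein abundances, and the Pearson r-squared of the two sums
#' across samples — a check that subunit numbers are co-regulated (the
#' study system maintains ~3 LSU : 1 SSU).
#'
#' @param lfq \code{lfq_matrix}
#' @param subunit_map data.frame: protein, subunit_class (classes "60S"
#'   and "40S")
#' @return list: \code{ratio} (per sample; NA where the SSU sum is zero),
#'   \code{r2}, \code{lsu_sum}, \code{ssu_sum}
#' @export
subunit_ratio <- function(lfq, subunit_map) {
  m <- lfq$lfq
  pick <- function(cls)
    intersect(subunit_map$protein[subunit_map$subunit_class == cls],
              rownames(m))
  lsu <- pick("60S"); ssu <- pick("40S")
  if (!length(lsu) || !length(ssu)) stop("need both 60S and 40S proteins")
  lsum <- colSums(m[lsu, , drop = FALSE], na.rm = TRUE)
  ssum <- colSums(m[ssu, , drop = FALSE], na.rm = TRUE)
  ratio <- ifelse(ssum > 0, lsum / ssum, NA_real_)
  r2 <- stats::cor(lsum, ssum)^2
  list(ratio = ratio, r2 = r2, lsu_sum = lsum, ssu_sum = ssum)
}
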