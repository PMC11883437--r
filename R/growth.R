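# Relative growth rates from destructive weight time series, and the
# shared ANOVA + Tukey HSD utility used for growth and pool comparisons.
#
# The RGR is a fraction-of-final-weight rate: RGR_t = dW_t / (W_f * dt)
# with the initial root weight taken as zero, so dW_t is the weight
# measured at t and dt the hours since treatment onset. It is not a
# log-slope; for these germinating-seedling series the log-linear model is
# rejected (r2 < 0.5), which is why this form is used.

#' Relative growth rate from a weight time series
#'
#' @param weights long data.frame with columns condition, replicate,
#'   time_h (hours since treatment onset), variable (e.g. "FW", "DW"),
#'   value (mg or stated unit)
#' @param window numeric length-2: labelling window in hours; the average
#'   RGR is the unweighted mean of RGR_t over time points inside it.
#'   Time point 0 is always excluded (dt = 0 leaves the rate undefined).
#' @return list of class \code{rgr_result}: \code{per_time} (condition,
#'   variable, time_h, rgr, flags) and \code{average} (condition,
#'   variable, rgr_avg, n_timepoints). Because weighing is destructive,
#'   replicates are not paired: weights are averaged within each day
#'   first, and W_f is the mean of final-day replicates per condition.
#' @export
rgr <- function(weights, window = NULL) {
  need <- c("condition", "replicate", "time_h", "variable", "value")
  miss <- setdiff(need, names(weights))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(weights$value < 0)) stop("negative weight")
  per_time <- NULL
  average <- NULL
  for (cond in unique(weights$condition)) {
    for (v in unique(weights$variable)) {
      w <- weights[weights$condition == cond & weights$variable == v, ]
      if (!nrow(w)) next
      # replicate-first averaging: mean within day, then across days
      daily <- stats::aggregate(value ~ time_h, data = w, FUN = mean)
      daily <- daily[order(daily$time_h), ]
      t_f <- max(daily$time_h)
      W_f <- daily$value[daily$time_h == t_f]
      if (W_f <= 0) stop("W_f is zero for ", cond, "/", v)
      use <- daily$time_h > 0
      rt <- daily$value[use] / (W_f * daily$time_h[use])
      flag <- ifelse(daily$value[use] < 0, "shrinkage", "")
      pt <- data.frame(condition = cond, variable = v,
                       time_h = daily$time_h[use], rgr = rt, flag = flag,
                       stringsAsFactors = FALSE)
      per_time <- rbind(per_time, pt)
      win <- if (is.null(window)) c(0, t_f) else window
      inwin <- pt$time_h > win[1] & pt$time_h <= win[2] & pt$time_h > 0
      average <- rbind(average,
                       data.frame(condition = cond, variable = v,
                                  rgr_avg = mean(pt$rgr[inwin]),
                                  n_timepoints = sum(inwin),
                                  stringsAsFactors = FALSE))
    }
  }
  structure(list(per_time = per_time, average = average),
            class = "rgr_result")
}

#' Read a weight time-series TSV
#' @param path TSV with columns condition, replicate, time_h, variable, value
#' @export
read_weights <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# ---- shared ANOVA + Tukey ----------------------------------------------

#' One-way ANOVA with post hoc Tukey HSD and compact letter display
#'
#' Standard one-way ANOVA at 95% confidence followed by Tukey's honest
#' significant difference test; group letters share a symbol when the
#' groups are not significantly different at \code{alpha}.
#'
#' @param values numeric vector
#' @param groups factor/character of the same length
#' @param alpha significance level for the letter display (default 0.05)
#' @return list: \code{anova_p}, \code{tukey} (pairwise data.frame with
#'   \code{p_adj}), \code{letters} (named character), \code{degenerate}
#'   (TRUE when residual variance is ~0 and letters come from exact ties)
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 values per group")
  gm <- tapply(values, groups, mean)
  resid_var <- sum(tapply(values, groups,
                          function(v) sum((v - mean(v))^2)))
  if (resid_var < 1e-24) {
    # degenerate: letters from exact ties of group means
    lev <- names(gm)
    pm <- outer(gm, gm, function(a, b) as.numeric(a == b))
    dimnames(pm) <- list(lev, lev)
    letters <- compact_letters(pm, alpha = 0.5)  # tie => p=1 > alpha
    return(list(anova_p = NA_real_, tukey = NULL, letters = letters,
                degenerate = TRUE))
  }
  d <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = d)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  lev <- levels(groups)
  pm <- matrix(1, nlevels(groups), nlevels(groups), dimnames = list(lev, lev))
  for (i in seq_len(nrow(tukey))) {
    pm[tukey$group1[i], tukey$group2[i]] <- tukey$p_adj[i]
    pm[tukey$group2[i], tukey$group1[i]] <- tukey$p_adj[i]
  }
  list(anova_p = p, tukey = tukey,
       letters = compact_letters(pm, alpha = alpha), degenerate = FALSE)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insertion-absorption algorithm: start from one set holding all groups;
#' every significant pair splits each set containing both; subset and
#' duplicate sets are absorbed. Groups sharing any letter are not
#' significantly different.
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames
#' @param alpha significance level
#' @return named character vector of letter strings, one per group
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  sets <- list(g)
  cmb <- utils::combn(length(g), 2)
  for (k in seq_len(ncol(cmb))) {
    i <- g[cmb[1, k]]; j <- g[cmb[2, k]]
    if (pmat[i, j] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        a <- setdiff(s, i); b <- setdiff(s, j)
        if (length(a)) new_sets <- c(new_sets, list(a))
        if (length(b)) new_sets <- c(new_sets, list(b))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb duplicates and subsets
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b))
        keep[a] <- FALSE
    }
    sets <- new_sets[keep]
  }
  # order sets by first member appearance, label a, b, c, ...
  ord <- order(vapply(sets, function(s) min(match(s, g)), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}
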