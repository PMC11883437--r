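# Natural-isotopic-abundance correction of isotopologue envelopes and mean
# isotopic enrichment. The correction basis expresses the envelope of a
# molecule carrying exactly j deliberately labelled atoms; observed
# envelopes are decomposed over that basis by non-negative least squares.

#' Natural-isotopic-abundance correction matrix
#'
#' Column j (j = 0..n_label) holds the isotopologue distribution of a
#' molecule in which exactly j of the labelable atoms carry the deliberate
#' label: the j labelled atoms each shift the envelope by one (thinned by
#' tracer purity), and all remaining atoms — including the other
#' n_label - j labelable atoms — follow natural abundance.
#'
#' @param formula \code{elemental_formula} of the analyte
#' @param policy \code{isotope_policy}
#' @param n_label number of labelable atoms of the label element
#' @param n_peaks number of isotopologue rows
#' @param purity tracer isotopic purity (fraction); each deliberately
#'   labelled atom is heavy with this probability. Default 0.99, the
#'   purity of the supplied tracer.
#' @return matrix (n_peaks x (n_label + 1)) of class
#'   \code{correction_matrix} with attributes \code{n_label},
#'   \code{formula}
#' @export
correction_matrix <- function(formula, policy = isotope_policy(),
                              n_label, n_peaks, purity = 0.99) {
  f <- as_formula(formula)
  el <- policy$label_element
  if (n_label > f[[el]])
    stop("n_label (", n_label, ") exceeds ", el, " count (", f[[el]], ")")
  stopifnot(n_peaks >= 1, purity > 0, purity <= 1)
  A <- matrix(0, n_peaks, n_label + 1)
  for (j in 0:n_label) {
    # natural envelope of the molecule minus its j labelled atoms
    nat <- natural_distribution(f, policy, n_peaks,
                                exclude = stats::setNames(j, el))
    # j labelled atoms: heavy with prob = purity each
    lab <- stats::dbinom(0:min(j, n_peaks - 1), j, purity)
    col <- convolve_trunc(nat, lab, n_peaks)
    A[, j + 1] <- col
  }
  structure(A, class = c("correction_matrix", "matrix", "array"),
            n_label = n_label, formula = format(f))
}

#' Correct an isotopologue envelope for natural abundance
#'
#' Solves \code{min ||A x - m||_2} subject to \code{x >= 0}
#' (Lawson-Hanson NNLS), then normalizes x to sum 1. The fractions
#' \code{x_j} estimate the proportion of molecules carrying exactly j
#' labelled atoms.
#'
#' @param m numeric envelope M0..Mk (intensities, length = nrow(A))
#' @param A \code{correction_matrix}
#' @param weighting \code{"relative"} (default) scales each residual by
#'   the inverse observed intensity (floored at 0.1% of the base peak),
#'   the correct weighting when intensity noise is multiplicative; it
#'   markedly reduces the small positive enrichment bias that unweighted
#'   fits show on noisy envelopes. \code{"uniform"} is the plain fit.
#' @return list of class \code{corrected_envelope}: \code{x} (fractions
#'   summing to 1), \code{residual} (relative L2 residual of the fit),
#'   \code{enrichment} (mean isotopic enrichment over the labelable atoms)
#' @export
correct_envelope <- function(m, A, weighting = c("relative", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(m) != nrow(A))
    stop("envelope length ", length(m), " != correction matrix rows ",
         nrow(A))
  if (any(m < 0)) stop("negative envelope intensity")
  s <- sum(m)
  if (s <= 0) stop("empty envelope: all intensities zero")
  mn <- m / s
  w <- if (weighting == "relative") 1 / pmax(mn, 1e-3 * max(mn)) else
    rep(1, length(mn))
  fit <- pracma::lsqnonneg(unclass(A) * w, mn * w)
  x <- fit$x
  if (sum(x) <= 0) stop("degenerate NNLS fit (all-zero solution)")
  residual <- sqrt(sum((unclass(A) %*% x - mn)^2)) / sqrt(sum(mn^2))
  x <- x / sum(x)
  n_label <- attr(A, "n_label")
  structure(list(x = x, residual = residual,
                 enrichment = mean_enrichment(x, n_label),
                 one_minus_x0 = 1 - x[1],
                 n_label = n_label),
            class = "corrected_envelope")
}

#' Mean isotopic enrichment from labelled-atom fractions
#'
#' \code{E = sum_j j x_j / n_label}: the average fraction of labelable
#' atoms that carry the label. Undefined (NA with a warning attribute)
#' when there are no labelable atoms — distinct from a measured zero.
#'
#' @param x fractions x_0..x_n (length n_label + 1)
#' @param n_label number of labelable atoms
#' @export
mean_enrichment <- function(x, n_label) {
  if (n_label == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no labelable atoms: enrichment undefined"
    return(out)
  }
  stopifnot(length(x) == n_label + 1)
  sum((seq_along(x) - 1) * x) / n_label
}
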