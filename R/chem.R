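# Elemental formulas, residue composition and isotopologue distribution math.
# Everything downstream (envelope sizing, NIA correction, the forward
# simulator) is built on these primitives.

ELEMENTS <- c("C", "H", "N", "O", "S")

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of atom counts over the
#' elements C, H, N, O, S. Absent elements count as zero.
#'
#' @param ... named atom counts, e.g. \code{formula(C = 2, H = 3, N = 1, O = 1)}
#' @return an object of class \code{elemental_formula}
#' @export
elemental_formula <- function(...) {
  x <- c(...)
  if (length(x) == 0) x <- stats::setNames(integer(0), character(0))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("atom counts must be named by element symbol")
  bad <- setdiff(names(x), ELEMENTS)
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (any(x < 0)) stop("negative atom count")
  counts <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  counts[names(x)] <- as.integer(x)
  structure(counts, class = "elemental_formula")
}

as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  do.call(elemental_formula, as.list(x))
}

#' @export
`+.elemental_formula` <- function(e1, e2) {
  structure(unclass(as_formula(e1)) + unclass(as_formula(e2)),
            class = "elemental_formula")
}

#' @export
`-.elemental_formula` <- function(e1, e2) {
  out <- unclass(as_formula(e1)) - unclass(as_formula(e2))
  if (any(out < 0))
    stop("formula subtraction below zero for element(s): ",
         paste(names(out)[out < 0], collapse = ", "))
  structure(out, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) return("(empty)")
  paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format(x), "\n")
  invisible(x)
}

#' Parse a Hill-style formula string
#'
#' Parses strings like \code{"C4H8N2O3"} over the supported elements
#' C, H, N, O, S.
#' @param s formula string
#' @return \code{elemental_formula}
#' @export
parse_formula <- function(s) {
  if (!grepl("^([CHNOS][0-9]*)+$", s))
    stop("cannot parse formula string: ", s)
  m <- gregexpr("[CHNOS][0-9]*", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  counts <- stats::setNames(integer(length(ELEMENTS)), ELEMENTS)
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L
    counts[el] <- counts[el] + n
  }
  do.call(elemental_formula, as.list(counts))
}

# ---- residue table -----------------------------------------------------

#' Residue composition table
#'
#' Peptide-bond residue formulas (free amino acid minus H2O) for the 20
#' standard amino acids, with nitrogen counts. Shipped as plain TSV under
#' \code{inst/extdata}; pass \code{path} to override.
#'
#' @param path optional TSV with columns aa, name, C, H, N, O, S
#' @return data.frame keyed by one-letter code, with an \code{nN} column
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residues.tsv", package = "protKs")
  rt <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", ELEMENTS) %in% names(rt)))
  rt$nN <- rt$N
  rownames(rt) <- rt$aa
  rt
}

#' Isotope policy: natural isotope masses and abundances
#'
#' Fixed, versioned isotope constants shipped with the package so that
#' corrections do not depend on the runtime environment. The label element
#' defaults to nitrogen (the 15N tracer).
#'
#' @param path optional TSV (element, shift, mass, abundance)
#' @param label_element element carrying the deliberate label
#' @return list of class \code{isotope_policy}: per-element data.frames,
#'   plus \code{label_element}
#' @export
isotope_policy <- function(path = NULL, label_element = "N") {
  if (is.null(path))
    path <- system.file("extdata", "isotopes.tsv", package = "protKs")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pol <- split(tab[c("shift", "mass", "abundance")], tab$element)
  for (el in names(pol)) {
    s <- sum(pol[[el]]$abundance)
    if (abs(s - 1) > 1e-9)
      stop("abundances for ", el, " sum to ", s, ", not 1")
  }
  if (!label_element %in% names(pol))
    stop("label element ", label_element, " not in isotope policy")
  structure(list(elements = pol, label_element = label_element),
            class = "isotope_policy")
}

# monoisotopic mass of a formula (lightest isotope per element)
#' Monoisotopic mass of an elemental formula
#' @param formula \code{elemental_formula}
#' @param policy \code{isotope_policy}
#' @return mass in Da
#' @export
mono_mass <- function(formula, policy = isotope_policy()) {
  f <- as_formula(formula)
  m <- 0
  for (el in names(f)[f > 0]) {
    iso <- policy$elements[[el]]
    m <- m + f[[el]] * iso$mass[which.min(iso$shift)]
  }
  m
}

PROTON_MASS <- 1.00727646688

#' Theoretical monoisotopic m/z for a charge state
#' @inheritParams mono_mass
#' @param z positive integer charge
#' @export
mono_mz <- function(formula, z, policy = isotope_policy()) {
  stopifnot(z >= 1)
  (mono_mass(formula, policy) + z * PROTON_MASS) / z
}

# ---- peptide formula ---------------------------------------------------

H2O <- function() elemental_formula(H = 2, O = 1)

# carbamidomethyl adduct (iodoacetamide alkylation of cysteine)
CAM <- function() elemental_formula(C = 2, H = 3, N = 1, O = 1)

#' Elemental formula of a peptide
#'
#' Sums residue formulas and adds the terminal H2O. The only modification
#' modelled is fixed carbamidomethylation of cysteine (the alkylation
#' chemistry of the underlying sample preparation); variable modifications
#' are rejected.
#'
#' @param sequence one-letter amino-acid string
#' @param residues residue table from [residue_table()]
#' @param fixed_mods character vector; only \code{"carbamidomethyl-C"}
#'   (default) or empty allowed
#' @return \code{elemental_formula}
#' @export
formula_of_peptide <- function(sequence, residues = residue_table(),
                               fixed_mods = "carbamidomethyl-C") {
  if (!nzchar(sequence)) stop("empty peptide sequence")
  if (length(fixed_mods) && !all(fixed_mods == "carbamidomethyl-C"))
    stop("unsupported modification(s): ",
         paste(setdiff(fixed_mods, "carbamidomethyl-C"), collapse = ", "),
         " (only fixed carbamidomethyl-C is modelled)")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, residues$aa)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  counts <- stats::setNames(numeric(length(ELEMENTS)), ELEMENTS)
  for (el in ELEMENTS)
    counts[el] <- sum(residues[aa, el])
  f <- do.call(elemental_formula, as.list(counts)) + H2O()
  if ("carbamidomethyl-C" %in% fixed_mods) {
    ncys <- sum(aa == "C")
    if (ncys > 0)
      for (i in seq_len(ncys)) f <- f + CAM()
  }
  f
}

# ---- isotopologue distributions ----------------------------------------

# distribution of extra-neutron shifts for n atoms of one element,
# truncated to n_peaks entries; exact polynomial exponentiation
element_shift_dist <- function(iso, n, n_peaks) {
  base <- numeric(n_peaks)
  keep <- iso$shift < n_peaks
  base[iso$shift[keep] + 1] <- iso$abundance[keep]
  out <- c(1, numeric(n_peaks - 1))  # identity for convolution
  p <- base
  k <- n
  while (k > 0) {  # fast exponentiation under truncated convolution
    if (k %% 2 == 1) out <- convolve_trunc(out, p, n_peaks)
    k <- k %/% 2
    if (k > 0) p <- convolve_trunc(p, p, n_peaks)
  }
  out
}

# truncated linear convolution of two probability prefixes
convolve_trunc <- function(a, b, n_peaks) {
  n <- min(n_peaks, length(a) + length(b) - 1)
  out <- numeric(n_peaks)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n_peaks - i + 1)
    if (jmax >= 1)
      out[i:(i + jmax - 1)] <- out[i:(i + jmax - 1)] + a[i] * b[1:jmax]
  }
  out
}

#' Natural isotopologue distribution of a formula
#'
#' Probability that a molecule carries 0, 1, ... extra neutrons at natural
#' isotopic abundance, computed by convolving per-element multinomial
#' distributions. The tail beyond \code{n_peaks} is truncated, so entries
#' sum to at most 1.
#'
#' @inheritParams mono_mass
#' @param n_peaks number of isotopologue entries to return (>= 1)
#' @param exclude named integer vector: atoms to exclude from the
#'   distribution (e.g. deliberately labelled N atoms)
#' @return numeric vector of length \code{n_peaks}
#' @export
natural_distribution <- function(formula, policy = isotope_policy(),
                                 n_peaks, exclude = NULL) {
  stopifnot(n_peaks >= 1)
  f <- unclass(as_formula(formula))
  if (!is.null(exclude)) {
    f[names(exclude)] <- f[names(exclude)] - exclude
    if (any(f < 0)) stop("exclusion exceeds atom count")
  }
  out <- c(1, numeric(n_peaks - 1))
  for (el in names(f)[f > 0])
    out <- convolve_trunc(out, element_shift_dist(policy$elements[[el]],
                                                  f[[el]], n_peaks),
                          n_peaks)
  out
}

# ---- labelable atoms ---------------------------------------------------

#' Count labelable nitrogen atoms of a peptide
#'
#' A residue's N atoms are labelable when its soluble amino-acid pool shows
#' non-zero tracer enrichment; residues whose pools are undetected (e.g.
#' His and Arg below the GC-MS detection limit) contribute no labelable
#' atoms, per the pool-constraint logic of the workflow.
#'
#' @param sequence peptide string
#' @param residues residue table
#' @param enrich named numeric vector: per-amino-acid pool enrichment
#'   fractions \code{e_a} for one condition (missing codes treated as 0)
#' @return list with \code{n_total_N}, \code{n_labelable}, and a
#'   per-residue \code{breakdown} data.frame
#' @export
count_labelable_atoms <- function(sequence, residues = residue_table(),
                                  enrich) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, residues$aa)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  e <- vapply(aa, function(a) {
    v <- unname(enrich[a])
    if (is.na(v) || is.null(v)) 0 else v
  }, numeric(1))
  nN <- residues[aa, "nN"]
  breakdown <- data.frame(position = seq_along(aa), aa = aa, nN = nN,
                          e_a = unname(e), labelable = e > 0,
                          row.names = NULL)
  list(n_total_N = sum(nN),
       n_labelable = sum(nN[e > 0]),
       breakdown = breakdown)
}
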