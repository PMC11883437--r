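---
title: "Measuring fractional protein synthesis rates from 15N labelling: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fractional protein synthesis rates from 15N labelling: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protKs)
```

## The problem

When a plant tissue is fed a stable-isotope tracer — here ¹⁵N supplied
through labelled serine and glycine — newly synthesized protein molecules
incorporate heavy nitrogen while pre-existing molecules retain the natural
isotope pattern. The isotopologue envelope of a peptide in an MS1 spectrum
is therefore a mixture of an "old" population at natural abundance and a
"new" population whose nitrogen atoms are drawn from partially labelled
amino-acid pools. protKs turns such envelopes into per-peptide and
per-protein fractional synthesis rates, comparable between physiological
states that differ in growth rate and in tracer dilution.

Three corrections make the rates comparable across conditions:

1. **Natural isotopic abundance (NIA)**: the naturally occurring heavy
   isotopes (¹³C, ¹⁵N, ²H, ¹⁷O/¹⁸O, ³³S/³⁴S/³⁶S) must be deconvolved out
   of the envelope before any labelling is quantified.
2. **Pool dilution**: the tracer never saturates the free amino-acid
   pools. A fully new peptide molecule can at most reach the enrichment of
   the pools its residues are drawn from, so the observed labelled-peptide
   fraction (LPF) is scaled by this peptide-specific ceiling,
   `E_max`.
3. **Growth**: a fraction-new number is converted to a rate by the
   tissue's relative growth rate (RGR) over the labelling window, because
   the same fraction-new means faster synthesis in faster-growing tissue.

The chain is:

```
LPF  =  mean isotopic enrichment of the peptide's labelable N atoms
E_max = sum(nN(a) * e_a) / sum(nN(a))   over residues with e_a > 0
corrected LPF = LPF / E_max             (the fraction of molecules that are new)
Ks = corrected LPF * RGR * 100          (% of the protein pool renewed per hour)
```

## Isotope model and the correction basis

Every analyte is reduced to a CHNOS elemental formula
(`formula_of_peptide()` sums residue compositions plus terminal water;
fixed carbamidomethylation of cysteine is the only modification modelled,
matching iodoacetamide alkylation chemistry). Natural isotopologue
distributions are exact multinomial convolutions over a fixed, versioned
isotope table shipped with the package (`inst/extdata/isotopes.tsv`), so
results do not depend on the runtime environment. The distribution is
computed per element by fast exponentiation under truncated convolution
and convolved across elements; truncation keeps a user-chosen number of
peaks and simply drops tail mass.

The NIA correction matrix `A` has one column per number of deliberately
labelled atoms `j = 0..n_label`. Column `j` is the envelope of a molecule
whose `j` labelled atoms each shift the pattern by one neutron — thinned
binomially by the tracer purity (default 0.99) — while *all* remaining
atoms, including the other `n_label − j` labelable nitrogens, follow
natural abundance. This is a "low-resolution" model: all heavy isotopes
are pooled by nominal mass shift, appropriate when ¹³C and ¹⁵N
isotopologues of peptides are not chromatographically or spectrally
resolved. Peaks are accordingly sought at a spacing of 1.00335 Da/z (the
¹³C spacing); the small ¹⁵N spacing difference is absorbed by the 10 ppm
matching tolerance for the first handful of isotopologues.

The observed envelope `m` is decomposed by non-negative least squares,
`min ||A x − m||, x ≥ 0`, then `x` is renormalized to sum to one. NNLS is
used rather than matrix inversion because envelopes are truncated (A is
not square) and intensities are noisy; non-negativity keeps the fractions
physical.

### Why the fit is weighted

Intensity noise in MS1 data is predominantly multiplicative: the standard
deviation of a peak scales with its intensity. An unweighted least-squares
fit therefore lets the base peak dominate and, combined with the
non-negativity constraint, produces a small *positive* bias in the
recovered enrichment of weakly labelled envelopes. That bias looks
negligible on the enrichment scale (a few 10⁻³) but the corrected LPF
divides by `E_max`, which is often below 0.1 under realistic pool
enrichments — amplifying the bias more than tenfold. `correct_envelope()`
therefore defaults to relative (inverse-intensity) weighting, with
observed intensities floored at 0.1% of the base peak so empty channels
cannot acquire infinite weight; simulations at 5% CV show this removes
most of the bias. The unweighted fit remains available
(`weighting = "uniform"`).

Two enrichment statistics are reported for every envelope, because
"labelled fraction" is genuinely ambiguous: the default **mean isotopic
enrichment** `E = Σ j·x_j / n_label` (the fraction of labelable atoms that
carry label, the quantity that equals `f · E_max` under the mixture
model), and **1 − x₀** (the fraction of molecules carrying *any* label).
The first is used for rate calculation; the second is carried alongside.

## Labelable atoms and `E_max`

A residue's nitrogen atoms count as labelable only when its free pool
shows non-zero tracer enrichment. Pools below the detection limit
(typically histidine and arginine in this kind of experiment) contribute
nothing — neither to the enrichment denominator nor to `E_max` — so both
quantities use the *same* atom set and their ratio is internally
consistent. This convention means a peptide's `corrected LPF` estimates
the fraction of new molecules regardless of how many of its residues were
measurable, at the cost of excluding peptides with no labelable atoms at
all (they are reported with an explicit reason rather than a zero rate).
`E_max` always uses the pool table of the peptide's own condition, since
conditions can differ strongly in which pools pick up label.

## Pool enrichments from GC-MS fragments

Free amino-acid enrichments are measured on GC-MS fragment isotopologue
envelopes, NIA-corrected exactly as peptides are (with the fragment's
nitrogen count as `n_label`). Because several fragments per amino acid are
measured, a QC cascade picks the reporting fragment:

1. Fragment consistency is screened by correlating per-sample *summed*
   isotopologue abundances between fragment pairs (plain monoisotopic
   correlation would be confounded by the labelling itself); pairs with
   r < 0.8 are flagged.
2. Fragments showing enrichment in non-labelled control samples carry
   contamination or interference and are discarded. "Null in the control"
   is operationalized as |mean control enrichment| < 0.002 — a
   configurable threshold chosen at roughly twice the repeatability of
   control-sample enrichments in simulation.
3. If *every* fragment is contaminated, the bias is treated as technical:
   the mean control "enrichment" is subtracted per fragment from the
   labelled samples, and fragments whose post-subtraction control spread
   is within twice the minimum are retained. Negative post-subtraction
   values are clipped to zero and flagged (enrichment is a physical
   fraction).
4. Among survivors, the fragment with the lowest relative standard
   deviation wins. RSD is computed respecting the replicate hierarchy:
   technical replicates are averaged within each biological replicate
   first, then the RSD is taken across biological replicates. Fewer than
   three candidate fragments raises a warning, not a rejection.

Pyroglutamate, an extraction/derivatization product of glutamine, is
mapped back to glutamine through a configurable alias table. Treatment
effects on pool enrichments are tested per amino acid by one-way ANOVA
with post hoc Tukey HSD at 95% confidence; group letters use an
insertion–absorption compact letter display (shared letter = not
significantly different). The letter routine is hand-written because base
R has none; its partitions are cross-checked against an independent
implementation in the test suite.

## Relative growth rate

The RGR here is a *fraction-of-final-weight* rate:
`RGR_t = dW_t / (W_f · dt)` with the initial weight taken as zero, so
`dW_t` is simply the weight at time `t` and `dt` the hours since
treatment onset. The average over the labelling window is the unweighted
mean across the daily time points, excluding `t = 0` where the rate is
undefined. This is deliberately *not* the slope of log-weight over time:
germinating-seedling series violate log-linearity badly (r² below 0.5),
and the fraction-of-final-weight form is the correct normalizer for a
fraction-new measured at the end of the window. A documented consequence
(and test) is that under exponential growth this RGR does not equal the
exponential rate constant.

Because weighing is destructive, replicates cannot be paired across
days: weights are averaged within each day first, and `W_f` is the mean
of the final-day replicates per condition. For the same reason, rates use
the condition-average RGR, not per-replicate RGRs. Dry-weight RGR is the
recommended normalizer for protein synthesis (protein mass is a major
component of dry weight); fresh-weight series are carried for comparison.

## Statistical filters and rate tables

A peptide counts as significantly labelled when a one-sided Welch t-test
of its labelled-replicate LPFs against the unlabelled baseline — or
against zero when no unlabelled samples exist, whichever is larger —
survives Benjamini–Hochberg adjustment at q < 0.05 across the peptide
table, with at least two labelled replicates, a mean NNLS relative
residual ≤ 0.1 and at least 80% of expected envelope peaks observed. The
counts at each gate are recorded as a funnel attribute so the filter
chain is auditable. Corrected LPFs above 1 indicate an underestimated
pool ceiling and are flagged, never silently truncated.

Peptides mapping to more than one protein group are discarded before
protein aggregation: in a study of paralogue-specific synthesis, razor
assignment would mix exactly the signals of interest. Protein tables take
medians over passing peptides; differential synthesis between conditions
uses two-sided Welch tests on replicate-level corrected LPFs with BH
adjustment *within each analysis table separately* (peptides, proteins,
complex members each form their own family), starred at q < 0.1, < 0.05,
< 0.01.

## Complex-ome statistics

LFQ differential abundance is tested per protein on log2 intensities with
a pseudo-intensity floor at the per-sample 1st percentile (variance
stabilization), pairwise-complete without imputation. Subunit
substoichiometry divides each ribosomal protein's abundance by its own
subunit's summed abundance per sample, so within-class values sum to one
and differences in assembled-subunit numbers cancel. The LSU:SSU summed
ratio and its cross-sample r² serve as a co-regulation check.

Each complex is classified per condition by two flags — *accumulated*
(member-wise differential abundance significant in that condition's
direction at q < 0.1) and *synthesized* (members passing the labelling
filter) — into four response groups: 1 = accumulated and newly
synthesized, 2 = accumulated without label (not degraded), 3 = labelled
without accumulation (turnover), 4 = neither. Member flags are aggregated
by a configurable rule, defaulting to majority (> 50% of detected
members); the supporting member subsets are always reported so a call can
rest on a named subset. Accumulation is direction-aware, so no complex
can be accumulation-positive in both conditions.

## The generator, and what passing tests mean

`simulate_*()` produces every input with known truth: evidence tables and
MS1 peak lists (Gaussian elution over centroided scans, peaks at the
configured spacing), GC-MS fragment tables exercising each QC branch,
weight series, and LFQ matrices. Its defaults are the study conditions
the package targets: two conditions (cold, control) × three biological
replicates × labelled/unlabelled, technical triplicates for pools, 99%
tracer purity, 5% multiplicative intensity noise, tracer amino acids near
15% (cold) and 4% (control) with secondary labelling of a plausible
amino-acid set, histidine and arginine undetected, average dry-weight
RGRs of 0.017 h⁻¹ (cold) and 0.008 h⁻¹ (control) over a 120 h window with
daily sampling, and a 50-protein proteome of Lys-C peptides (cleavage
after lysine only).

New molecules draw each labelable atom as a two-stage mixture: labelled
with probability `e_a`, then heavy with the tracer purity if labelled and
at natural ¹⁵N abundance if not. This is exactly the generative model the
correction basis inverts, which gives the pipeline's central correctness
theorem: composed with the noiseless generator, extraction and correction
return the configured fraction-new identically (asserted to 10⁻⁶ in the
acceptance suite). Growth curves are power laws `W_f (t/t_f)^α` with `α`
solved numerically so the averaged RGR equals the configured truth.

The generator deliberately omits several features of real data:
chromatographic peak-shape distortions and co-elution interference,
charge-state and missed-cleavage heterogeneity, missing peaks,
ionization competition, detector saturation, and time-varying pool
enrichments within the labelling window (the pipeline treats pools as a
window-average). Passing tests therefore demonstrate correctness of the
*computation* under the stated measurement model, not robustness to every
pathology of real chromatography; the quality funnel is the run-time
guard against such pathologies.

Test and simulation sizes (200 random peptides for round-trip and
recovery checks, 200 replications for null calibration, 20–50 protein
proteomes) were chosen as the smallest sets that make the Monte-Carlo
estimates stable to well within the asserted tolerances.

## Known limitations

- The uncertainty of a corrected LPF scales as `1/E_max`: peptides whose
  labelable residues sit in weakly enriched pools have intrinsically
  noisy fraction-new estimates. The significance and residual gates
  remove the worst cases, but rates near the detection floor should be
  read with their q-values.
- Pool enrichments of free amino acids proxy the charging of tRNAs; the
  package inherits that assumption and cannot check it.
- Only synthesis is estimated. Degradation and turnover require a
  steady-state assumption the targeted experiments do not meet.
- The low-resolution isotope model pools ¹³C and ¹⁵N isotopologues; fine
  isotope structure at very high resolving power is out of scope.
- Selenocysteine and residues outside the 20-letter alphabet are
  rejected rather than modelled.
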