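Package: protKs
Title: Physiology-Normalized Fractional Protein Synthesis Rates from 15N
    Kinetic Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts 15N-labelled peptide isotopologue envelopes, soluble
    amino-acid pool enrichments and growth measurements into fractional
    protein synthesis rates (Ks) normalized to relative growth rate.
    Implements peptide elemental-formula and isotope-distribution math,
    per-peptide isotopologue envelope extraction from MS1 data with
    peak-count optimization, natural-isotopic-abundance correction by
    non-negative least squares, GC-MS amino-acid pool enrichment with
    fragment quality control and baseline subtraction, relative growth
    rates from destructive weight series, statistical labelling filters,
    pool-dilution correction of labelled-peptide fractions, and downstream
    complex-ome statistics (subunit substoichiometry, differential
    abundance, accumulation/synthesis group classification). A forward
    generative model with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mzR,
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
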