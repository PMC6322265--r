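Package: condnds
Title: GC-Conservative dN/dS from Non-Stationary Codon Models and Substitution Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates lineage-specific selection efficacy free of GC-biased
    gene conversion (gBGC). Fits a non-stationary YN98 (F3X4) codon
    substitution model by maximum likelihood, maps expected substitution
    counts per branch split into weak-to-strong, strong-to-weak and
    GC-conservative categories, normalizes by a neutralized (omega = 1)
    model to obtain category-specific dN/dS - notably the GC-conservative
    dN/dS statistic robust to gBGC - computes equilibrium GC (GC*),
    ancestral GC and delta-GC per lineage, and correlates rates with
    life-history traits using phylogenetically independent contrasts.
    Includes an event-based codon sequence simulator with branch-specific
    selection and gBGC for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
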