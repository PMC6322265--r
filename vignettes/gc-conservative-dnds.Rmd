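---
title: "Measuring selection efficacy free of GC-biased gene conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection efficacy free of GC-biased gene conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The ratio of non-synonymous to synonymous substitution rates, dN/dS, is
the workhorse measure of the efficacy of purifying selection. Under the
nearly neutral theory it should rise in lineages with small effective
population size, which in practice is proxied by life-history traits:
body mass, maximum longevity, age of sexual maturity. In many clades the
expected correlation between dN/dS and these traits is noisy or absent.

One confounder is GC-biased gene conversion (gBGC): a
recombination-associated repair bias that favors fixation of G/C
("strong", S) alleles over A/T ("weak", W) alleles. It acts like
directional selection for GC, pushing weak-to-strong (WS) substitutions
to fix — including weakly deleterious non-synonymous ones — and
suppressing strong-to-weak (SW) ones. Because the boost gBGC gives a
mutation's fixation probability is proportionally larger for deleterious
mutations than for neutral ones, gBGC distorts dN/dS, and does so
heterogeneously across lineages wherever recombination or its genomic
targeting varies.

The package implements the remedy analyzed in this workflow: split
substitutions into WS, SW and GC-conservative (SS plus WW) categories and
estimate dN/dS separately per category. gBGC changes neither SS nor WW
fluxes, so the GC-conservative dN/dS is a selection-efficacy estimate
robust to gBGC.

## The estimation procedure

### Model fitting

`fit_model()` fits a non-stationary homogeneous YN98 (F3X4) codon model
by maximum likelihood: 61 sense-codon states, rates proportional to the
target codon's frequency, times `kappa` for transitions and `omega` for
non-synonymous changes, with equilibrium codon frequencies built from
three position-specific nucleotide frequency vectors. Non-stationarity
enters through a second, independent F3X4 parameterization of the codon
frequencies at the root; base composition can therefore drift along the
tree, which is essential when gBGC moves GC content. The generator is
normalized so branch lengths are expected substitutions per codon site
at the process equilibrium.

The likelihood is the standard pruning recursion with per-node scaling;
gaps and ambiguous codons are missing data (partial likelihood vectors
of ones), and codon columns containing an in-frame stop in any species
are masked alignment-wide. Optimization alternates a bounded
quasi-Newton step over the substitution parameters with Brent searches
on each branch length (bounded to [1e-6, 10]), against exact
outer/inner partials, until the round-to-round log-likelihood gain falls
below `tol`.

Two estimation variants are exposed because the choice is genuinely
open:

* `optimize_freqs`: the process F3X4 frequencies can be optimized by ML
  or (default) fixed at the observed position-specific frequencies, the
  usual empirical F3X4 convention. The default trades a negligible
  likelihood loss for a much smaller search space.
* `root_freqs`: `"free"` (default) optimizes the root F3X4 parameters by
  ML, matching the idea that root composition is retrieved from the
  data; `"observed"` and `"stationary"` are available for speed or for
  deliberately stationary fits.

### Substitution mapping and category rates

`map_counts()` computes, for every branch and each of the eight
categories (synonymous/non-synonymous crossed with WS/SW/SS/WW), the
posterior expected number of substitutions given the tip data — the
expectation over all substitution histories consistent with the fitted
model. The per-branch endpoint distributions come from combined
upward/downward passes; the per-history counts come from the closed-form
convolution integral of the labeled rate matrix, evaluated in the
generator's eigenbasis, with uniformization as the fallback when the
spectrum is too close to degenerate (eigenvalue gap below 1e-9;
truncation error below 1e-10).

`map_opportunities()` computes the denominator: the number of
substitutions of each category that a *neutralized* model — same kappa,
frequencies and time scale, omega set to 1 — would perform in the same
scenarios. Two details matter:

* The neutralized generator is **not** rescaled. Rescaling would
  silently redefine the clock and distort the opportunity counts; on the
  shared time scale, dN/dS equals omega exactly in the unconditional
  limit.
* "Same scenarios" is read as: start from the fitted model's marginal
  posterior state distribution at the branch's parent node, then run the
  neutral process along the branch unconditional on the child data. The
  fully endpoint-conditioned alternative would force dN/dS to 1 at
  omega = 1 tautologically; it is available via
  `conditioning = "joint"` for comparison.

`category_rates()` forms dN and dS per category as expected counts over
opportunities (ratios with zero opportunities are flagged, not dropped),
plus an all-categories total computed by summing numerators and
denominators first. `gc_conservative_combine()` merges SS and WW into
the GC-conservative statistic, weighting by the GC content at the
branch's parent node: rate = g * SS + (1 - g) * WW, applied to dN and dS
separately with the ratio taken afterwards. The weight defaults to the
GC of the reconstructed ancestral sequence over all codon positions
(switchable to 0-fold or 4-fold positions only).

### GC statistics

`gc_stats()` reports, per terminal branch: ancestral GC at the parent
node measured at 0-fold and 4-fold degenerate sites (proxies for
selected and neutral sites, classified from the node's own reconstructed
codons), current tip GC at the same site classes, the equilibrium GC
implied by current fluxes GC* = WS / (WS + SW) computed separately from
synonymous and non-synonymous normalized rates (raw counts are a
switch away), and delta-GC = GC* minus ancestral GC, pairing
non-synonymous GC* with 0-fold ancestral GC and synonymous GC* with
4-fold. Ancestral sequences are the argmax of the marginal posterior per
node and site, ties broken by the fixed alphabetical codon order and
counted in an attribute; a posterior-weighted GC variant would be easy
to add but the point-estimate mirrors standard ancestral-reconstruction
practice.

### Dataset assembly and aggregation

`filter_codon_coverage()` implements the coverage rule (keep codon
columns observed in at least a fraction — default 0.87, the 41-of-47
convention — of species), `apply_exclusions()` removes named genes and
species (e.g. sex-linked genes) before any fitting, and three binning
schemes assemble genes for estimation: seeded random bins dealt
round-robin after a shuffle (sizes differ by at most one), GC-ranked
bins whose low/high halves separate GC-poor from GC-rich genes, and the
chromosome-class split (micro < 16 Mb, macro > 100 Mb, intermediates
discarded). `aggregate_bins()` averages dN and dS across bins and takes
the ratio of the averages — not the average of ratios, which would be
biased upward by noisy small denominators; `aggregate_genes()` sums
expected counts and opportunities over genes per species before any
ratio, for gene-by-gene analyses with per-gene trees.

### Comparative statistics

Traits are log10-transformed. Correlations are Pearson's, either on
species values or through phylogenetically independent contrasts
(Felsenstein's recursion via `ape::pic`, both variables contrast-
transformed on the same pruned tree). Contrast correlations go through
the origin, the standard convention since contrast signs are arbitrary;
zero-length branches receive a 1e-8 floor before standardization.
Two-group comparisons report the relative difference of means as a
percentage of the second group's mean, with a Welch unequal-variance
t-test; "percent of the reference group's mean" is this package's
reading of a relative difference, and groups enter as (focal,
reference).

## The simulator

`simulate_alignment()` is an exact event-based (Gillespie) simulator per
codon site, so every substitution event is recorded, classified and
replayable — realized per-branch category counts are exact oracles for
the analytic mapping. Selection and gBGC vary per branch.

gBGC is simulated through Kimura fixation probabilities rather than a
flat multiplicative tilt of WS rates. A flat tilt (WS rates times gamma,
SW divided by gamma) scales the WS numerator and denominator of dN/dS
identically and therefore cannot distort dN/dS at all — it would miss
the very phenomenon under study. Instead, the branch's omega is read as
the relative fixation rate of a non-synonymous mutation with scaled
selection coefficient S (omega = S / (1 - exp(-S))), and a conversion
coefficient B = 2 log(gamma) is added to every WS mutation and
subtracted from every SW mutation: synonymous WS/SW rates are multiplied
by the fixation factor at +-B, non-synonymous ones by the factor at
S +- B relative to S. Because the boost is proportionally larger for
deleterious mutations, dN/dS in the WS category rises on gBGC branches
while GC-conservative rates are untouched — the distortion-and-
correction structure the statistic exists for. `gamma = 1` recovers the
plain YN98 process exactly. The simple tilt remains available as
`gbgc_tilt()` for generator-level experiments.

`generate_traits()` makes the three life-history traits as log10 values
linear in log omega of each tip's terminal branch plus Brownian noise
accumulated along the tree, so traits carry phylogenetic signal and the
contrast machinery's null assumptions hold. `make_gene_set()` draws
genes from a GC-poor and a GC-rich F3X4 regime (defaults near 0.40 and
0.60 GC) with chromosome sizes spanning micro, intermediate and macro
classes, so every binning scheme is exercised.

### What the simulator does and does not emulate

It reproduces the features the estimators are sensitive to:
non-stationary base composition, lineage-varying selection and gBGC,
gappy multi-gene data, trait-selection coupling with phylogenetic
signal. It does not emulate alignment error, rate variation across
sites, incomplete lineage sorting (per-gene trees are accepted as
inputs, not simulated), codon usage beyond F3X4, or saturation at deep
divergences. Passing tests therefore validate the inference machinery,
not the biological realism of any particular dataset.

## Numerical choices

* Transition probabilities and count integrals use a symmetric
  eigendecomposition for reversible generators (similarity transform by
  the square root of the stationary frequencies), a general
  eigendecomposition otherwise, and uniformization when eigenvalues are
  closer than 1e-9; negative probability entries below -1e-8 are an
  error, smaller ones are clipped to zero.
* Site patterns are collapsed and per-node partials rescaled by column
  sums, with the log scale accumulated per pattern.
* Branch lengths are clamped to [1e-6, 10]; frequency parameters are
  optimized on a multinomial-logit scale bounded at +-20.
* Ratios with zero denominators are flagged `NA` and excluded pairwise
  downstream; they are never silently replaced.

## Validation problem sizes

The test-suite experiments run at desk scale, chosen to keep the full
suite in the tens of minutes while leaving the statistical checks sharp:
8-taxon balanced trees with 0.08-substitution branches and 2000-codon
alignments for calibration and recovery checks (10 replicates each), a
20-taxon, 3000-codon trait-linked design for the contrast-correlation
property (10 replicates), 1e5 Monte-Carlo trajectories for the mapping
oracle, and 100-150-codon genes for pipeline determinism. The package
itself has no built-in size limits; the same code ran the statistics on
concatenations of hundreds of genes.

The trait-linked design mirrors the biology it emulates: both the
efficacy of selection and the strength of gBGC scale with effective
population size, so tip omega rises with the trait while the gBGC
coefficient falls with it (B from 4 down to 0, i.e. gamma from about 7
down to 1, along the omega ranking). This covariation is what lets gBGC
conceal the omega-trait correlation in total dN/dS while the
GC-conservative statistic recovers it; with gBGC orthogonal to the
trait the total correlation would merely gain a little noise and
nothing would be concealed. GC-conservative substitutions are
transversions only, so per-branch conservative rates carry the largest
sampling noise of all categories — hence the longer (0.2) terminal
branches and 3000-codon alignments in this design, and the choice to
keep the input tree's branch lengths fixed there (parameters are still
fitted), trading a branch-length re-estimation nobody needs in a
controlled simulation for a threefold larger alignment in the same
compute budget.

## Known limitations

* The fitted model is homogeneous (one omega, one kappa, one frequency
  set across branches); heterogeneity exists only in the simulator, and
  the mapping inherits whatever bias the homogeneous fit has under
  strongly heterogeneous truth.
* No rate variation across sites (no Gamma mixture), no codon-position
  model variants, no model selection.
* Category rates on very short branches are ratios of small expected
  counts and are noisy; aggregate before interpreting, as
  `aggregate_bins()`/`aggregate_genes()` do.
* GC* from normalized rates assumes the WS and SW opportunity sets are
  well populated; branches with no observed flux are flagged undefined.
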