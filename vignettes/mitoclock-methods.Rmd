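---
title: "Methods: lineage-aware clock dating of mtDNA haplogroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-aware clock dating of mtDNA haplogroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoclock)
```

## The problem

Coalescence dating of human mitochondrial haplogroups rests on the
molecular-clock assumption: mutations accrue along each maternal lineage
as rare, independent events, so the number of mutations separating a
present haplotype from a clade ancestor is Poisson in elapsed time. In
practice the accumulation is strikingly heterogeneous across clades of the
same phylogeny. Some haplogroups carry far fewer synonymous changes than
their sisters over the same time span; others carry a normal total load
but an inverted balance of amino-acid-changing versus silent changes,
the signature of selection rather than a slow clock. Either pattern breaks
a shared-clock date: a slow clade looks spuriously young, and a
selection-distorted clade under-counts the synonymous events that dating
relies on.

`mitoclock` implements the full diagnostic and dating chain for this
situation: classify every substitution by its coding effect, profile
per-haplotype distances on a mutation-annotated tree, test the Poisson
assumption, detect selection-distorted clades, and date clades with either
a shared anchored clock or a clade-specific recalibrated one — plus a
simulator that generates all of these inputs with known ground truth.

## Substitution classification

All counting rests on the vertebrate mitochondrial genetic code
(`Biostrings::getGeneticCode("2")`), in which ATA encodes Met, TGA Trp,
and AGA/AGG are stops. A substitution is classified against the
*ancestral* codon containing it: synonymous when the encoded residue is
unchanged, nonsense when a stop is gained or lost, nonsynonymous
otherwise; positions in rRNA/tRNA genes and outside annotated spans get
their own classes. Light-strand genes are handled by reverse-complementing
the codon context before translation. Indels inside coding spans are
flagged frame-disrupting and excluded from synonymous/nonsynonymous
counts, as is standard. An optional user-supplied exclusion list of
positions (e.g. known pathogenic sites) can be removed from every count;
it is empty by default.

Synonymous *site* counts use the Nei–Gojobori convention: each codon
contributes the fraction of its nine single-base neighbors that are
synonymous, and nonsynonymous sites are defined by the conservation
`N + S = 3 × codons` (changes to or from stop codons count on the
nonsynonymous side). Note that per-genome rates divided by an effective
synonymous-site count are sensitive to that convention; functions that
convert to per-site rates therefore take the site count as an explicit
argument (`site_count`) rather than assuming the fractional count, and
report both forms.

## Distance profiles and the rho statistic

A `haplotree` is a rooted tree whose branches carry explicit substitution
lists; tips are observed haplotypes and labelled internal nodes are clade
MRCAs. Distances are *event counts* along branch paths — recurrent and
back mutations count once per event, which is the natural convention when
the input is a mutation-annotated phylogeny rather than raw sequences.
The per-haplotype distance profile from a clade MRCA, restricted to
synonymous changes, is the dating currency: its clade mean is the rho
statistic, and `age = rho / rate` for a per-genome synonymous rate in
mutations per lineage-year.

Two calibrations are supported:

* **Anchored**: `rate = rho_ref / age_ref` from a reference clade with an
  independently estimated age. We treat this as canonical because
  published per-site literature rates are ambiguous about the exact site
  denominator; an anchored per-genome rate sidesteps the conversion
  entirely, and a literature rate is accepted only together with an
  explicit site count.
* **Recalibrated**: for a clade whose whole lineage runs slow, a
  clade-specific rate is the mean distance from the clade's tips to the
  *super-lineage* MRCA divided by that MRCA's age. Dating the clade's
  sublineages with this rate removes the shared-clock bias.

Dating error intervals use a star-phylogeny heuristic,
`sqrt(rho / n) / rate`: exact when every tip hangs directly from the MRCA
(independent Poisson counts), an underestimate on structured trees where
deep shared branches dominate the variance. The exact founder-analysis
variance `sum_b (n_b/n)^2 m_b` is available when branch structure is
supplied (`rho_sigma_exact()`), and the package labels the heuristic
intervals as such; they are not comparable to confidence intervals
computed from a specific tree topology.

Clades whose pooled nonsynonymous proportion exceeds a configurable
threshold (default 50%, roughly twice the ~28% background typical of
mtDNA coding variation) are flagged and reported as `ND` (not datable)
instead of being given a synonymous-clock date: their synonymous counts
demonstrably under-represent mutation events.

## Ancestral sequences and phylogenetic lifespan

An ancestral sequence (AS) is an extant haplotype identical — over all
coding polymorphisms — to the reconstructed ancestor of its clade. Its
phylogenetic lifespan compares `Da`, the mean synonymous distance from the
AS node to its diverged descendants, with `Db`, the synonymous distance
from the AS node up to the super-lineage MRCA. We define

`lifespan = Da / (Da + Db)`,

which is 1 when the AS *is* the super-lineage ancestor (`Db = 0`) and
small for a young ancestor with barely diverged descendants. The
orientation matters: the ratio could be written with either distance in
the numerator, and we fixed the orientation by requiring that the deepest,
longest-lived ancestors (large `Da`, small `Db`) score highest, which is
the ordering the statistic is meant to express. When several nested nodes
qualify with the same carrier set, the node closest to the root — the
oldest ancestor those carriers preserve — is reported.

## Distributional tests

* **Poisson accumulation**: a one-sample Kolmogorov–Smirnov statistic of
  the count distribution against Poisson with the rate estimated by the
  sample mean, with the sup-gap evaluated on the integer support and the
  asymptotic Kolmogorov p value. Because the rate is estimated from the
  data and the null is discrete, this p value is conservative — we keep it
  as the default for comparability with common practice, and provide a
  parametric-bootstrap variant (`method = "bootstrap"`, re-estimating the
  rate in each replicate) that is exact up to Monte-Carlo error. The
  conservativeness is asserted by test: under a true Poisson null the
  rejection rate at the 1% level stays below 2% across 1,000 simulated
  cohorts.
* **Group contrasts**: Welch two-sample t tests on clade distances, a
  group-by-distance-histogram chi-square with unit bins and right-tail
  pooling until every expected count reaches 1 (degrees of freedom are
  therefore data-dependent), and a paired t test across replicate sets for
  posterior root-to-tip distance comparisons. For the paired test both a
  95% confidence interval and the standard error of the mean difference
  are reported, since either may be wanted as the interval summary.

## Branch dN/dS by counting

Rather than maximum-likelihood codon models, per-branch dN/dS is computed
by counting: ancestral sequences are reconstructed by Fitch parsimony
(ambiguities resolved toward the parent state, alphabetical tie-break at
the root), each differing codon on a branch is decomposed into single-base
steps averaged over all minimal substitution orders with uniform weights
(pathways through intermediate stop codons excluded), and counts are
pooled per lineage class: `omega = (Nobs/Nsites) / (Sobs/Ssites)`. A class
with no synonymous substitutions has undefined omega and is reported with
a `*` note rather than a number. Counting-based omega is a robust
substitute for likelihood fitting at mtDNA-like divergences; the
quantities the package relies on are the *ordering* of class omegas and
the zero/undefined structure, not third-decimal agreement with any
particular ML implementation.

## HVS1 quality metrics

Control-region datasets are screened by splitting observed transitions in
the 16090–16383 window (1-based, endpoints inclusive) into "speedy"
(hotspot) and "weighty" (slow) sites and pooling transversions with
indels. The weighty-transitions to transversions-plus-indels ratio (WTTI)
is scale-free: values of roughly 2–5 characterize clean datasets, values
an order of magnitude larger indicate artefact-heavy ones. The
speedy/weighty partition is an external data file supplied by the user;
the package ships only a clearly labelled *synthetic* stand-in
(`synthetic_site_classes()`) for testing, which partitions the window with
a realistic 80/20 speedy fraction but does not reproduce any empirically
determined hotspot list. Counting is per variant occurrence by default
(`distinct = TRUE` collapses repeated observations of the same variant).

## The simulator: what it emulates, and what it does not

`sim_scenario()` defaults define the reference conditions used throughout
the package's tests: 500 haploid sequences of 3000 nt, mutation rate 1e-4
per site per generation, omega 1, exponential growth rate 1e-3, effective
population size 1000, no recombination. Genealogies are sampled from the
coalescent with exponential growth (inter-coalescence times by inversion
of the inhomogeneous exponential rate), and sequences evolve by per-branch
Poisson candidate mutations with JC-like base exchangeability and uniform
codon usage at the root. Selection acts by acceptance sampling: candidate
nonsynonymous changes are accepted with probability `min(1, omega)`,
synonymous ones with `min(1, 1/omega)`, so omega targets above and below 1
are both expressible; stop-gaining candidates are rejected and redrawn
(logged), so simulated coding sequences never carry internal stops.
Per-lineage-class clock multipliers scale the candidate rate on the
branches of a class.

The generator retains the complete per-branch event log as ground truth,
which the test-suite uses for conservation checks: per-tip true counts
equal path sums through the rebuilt haplotree, and reconstructed
branch-wise synonymous counts reconcile with tip profiles.

Ascertainment-biased sampling follows the classic haplogroup-panel
recipe: rank sites by allele-frequency variance (expected heterozygosity,
so a 50/50 split is maximal), split the population on the top-variance
sites until at least 5 groups of at least 20 members exist (if the
criterion is unreachable the best partition achieved is returned with an
explicit flag — never silently), then draw samples either uniformly or
proportionally to pseudo-haplogroup frequencies with largest-remainder
rounding (the rounding rule is our choice; "proportional" alone does not
determine one).

What the simulator does *not* emulate: recombination (absent in mtDNA
anyway), population structure and migration, indel evolution, rate
variation among sites within a class, transition/transversion bias, and
realistic codon usage. Passing tests on simulated bundles therefore
demonstrate internal consistency and statistical calibration of the
estimators under a clean neutral-with-modifiers model — not robustness to
every artefact of real sequence databases.

The slow-clade fixture (`r0_slow`) joins two independently simulated
subtrees at a common root, with the 0.5 clock multiplier applied to every
branch on the slow clade's root paths (stem included). This construction
makes the expected tip-to-root distance of the slow clade exactly half the
baseline — because coalescent genealogies are ultrametric in time — so
clade-rate recalibration has a sharp ground truth to recover. Generations
are converted to years at 25 y/generation in fixtures that need a calendar
scale; nothing in the analysis depends on that constant.

## Numerical and design choices

* Coordinates are 1-based inclusive; circularity of the reference is
  ignored for coding spans (no analyzed gene wraps the origin).
* Zero-length branches and polytomies are allowed throughout.
* `poisson_ks_test` requires n ≥ 8 and errors on an all-zero sample
  (degenerate rate).
* `paired_rate_test` returns t = ±Inf with p = 0 for a constant nonzero
  offset (zero-variance differences) rather than erroring — the
  mathematical limit of the closed form.
* Ages are computed in years and printed as ky to 2 decimals.
* The selection-flag threshold boundary is exclusive: exactly 50%
  nonsynonymous does not flag.
* Fitch root ambiguities resolve to the alphabetically first base; this
  only matters for the handful of sites whose root state is genuinely
  ambiguous and cancels in pooled counts.

## Problem sizes used by the test-suite

The packaged checks run the reference scenario at its default scale
(500 × 3000 nt) for the event-log conservation and ascertainment
experiments (10 replicate sets, samples of 40), 1,000 cohorts of n = 80
for KS calibration, 200 replicates for dating-interval coverage, and
reduced scales (tens of tips, hundreds of sites) for exact oracle
comparisons, where brute-force enumeration is feasible. These sizes were
chosen so that each property is measured with comfortable Monte-Carlo
margins while the whole suite stays quick to run.

## Known limitations

* Counting-based omega is downward-biased by a few percent under neutral
  simulation because stop-gaining candidates are redistributed while the
  Nei–Gojobori site count books stop changes as nonsynonymous sites; the
  bias is well inside the tolerance of every ordering-based conclusion.
* The heuristic dating interval understates the true uncertainty on
  strongly nested clades; use `rho_sigma_exact()` with branch structure
  when a defensible interval matters.
* Fitch reconstruction degrades on deep, saturated branches; the
  simulator's divergences (a few percent per site) are far below that
  regime.
* The lifespan statistic is undefined when an ancestral sequence has
  neither depth nor diverged descendants (`Da + Db = 0`); such records are
  reported as `NA`.
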