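---
title: "Clonal composition from allele-specific SNP-array data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal composition from allele-specific SNP-array data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneComp)
```

# The measurement and the model

Allele-specific SNP arrays report two signals at each polymorphic
locus: the log2 ratio of total copy signal against a diploid reference
(log2R) and the B-allele frequency (BAF). `cloneComp` treats a tumor
specimen as a two-population mixture: diploid normal cells plus tumor
cells, where a copy-number event with total copies $n_T$ (of which
$n_B$ minor-allele copies) is carried by an overall cellular fraction
$f \in (0, 1]$ of all cells — the product of tumor purity $\rho$ and
the cancer-cell fraction $c_k$ of the clone carrying it. The expected
signals are

$$\mathrm{log2R} = \log_2\!\frac{2(1-f) + f\,n_T}{2}, \qquad
\mathrm{BAF} = \frac{(1-f) + f\,n_B}{2(1-f) + f\,n_T}$$

(the BAF expression for a germline-heterozygous locus). Because allele
phase is unknown, the pipeline works with the *mirrored* BAF
$b = 0.5 + |\mathrm{BAF} - 0.5| \in [0.5, 1]$. Both equations invert
in closed form for $f$ given a candidate state:
$f = (2 \cdot 2^{\mathrm{log2R}} - 2)/(n_T - 2)$ for $n_T \neq 2$, and
$f = (2b - 1) / \big((n_T - n_B - 1) - b\,(n_T - 2)\big)$ from the
mirrored BAF when the denominator is positive
(`fractionFromLog2R()`, `fractionFromMBAF()`).

The **Clonal Composition (CC) number** is the count of distinct
cellular-fraction clusters formed by copy-number-aberrant segments,
restricted to clusters whose genomic footprint reaches a configurable
fraction of the analyzed genome. Tumors with CC = 0 are called
**Mono-CC** (no detectable subclonality), CC ≥ 1 **Poly-CC**. The Mono
cutoff is a configuration knob (`mono_if_cc_le`, default 0) because the
strictest definition — any detectable fraction cluster implies
heterogeneity — is the one most robust to footprint sensitivity, while
related work on other tumor types has drawn the line at CC ≤ 1.
Note that under the default the dominant ("truncal") aberrant clone
itself contributes a cluster like any other, so purity never needs to
be estimated separately.

# Pipeline stages

## Segmentation

`segmentGenome()` reduces probes to segments per chromosome by
recursive binary change-point splitting on the bivariate series
(log2R, mirrored BAF of informative probes). A split is accepted when
it reduces the pooled within-segment sum of squared deviations by more
than $\lambda \log n$ ($\lambda$ = `split_penalty`, default 10; $n$ =
probes on the chromosome), with each channel z-scaled by its
genome-wide median absolute deviation — a BIC-style rule. Adjacent
segments whose medians differ by less than 0.05 log2R *and* 0.02
mirrored BAF are re-merged, and only segments with at least
`min_probes` (default 50, about 0.02% of a 220k array — small enough
to keep the sub-1% footprint regime observable) are emitted.

Binary segmentation with a penalty was chosen over circular binary
segmentation deliberately: it is deterministic, transparent, a few
hundred lines rather than a dependency, and on arrays of this density
the change points of interest (tens of megabases) are found exactly in
the zero-noise limit and to within one probe spacing in practice.
Medians, not means, summarize segments, for robustness to FFPE
outliers. When the genome-wide MAD of a channel is numerically zero
(exact simulated data), a small floor keeps the z-scaling finite; the
split decisions are unaffected because in that regime cost reductions
at true change points dwarf the penalty.

BAF-informative probes are those with raw BAF inside
`informative_baf_window` (default [0.03, 0.97]); without a matched
normal these approximate germline heterozygotes. A segment carries a
mirrored-BAF summary only when at least `min_informative` (default 10)
informative probes contributed; otherwise it is flagged
BAF-uninformative and fitted on log2R alone.

## Aberrance call and fitting

A segment is **aberrant** when |median log2R| ≥ `tau_log2r` (default
0.15) or median mirrored BAF ≥ `tau_mbaf` (default 0.58)
(`isAberrant()`). The thresholds sit just below the weakest signals the
fit grid is expected to resolve: a one-copy change at $f = 0.2$ gives
|log2R| ≈ 0.15, and copy-neutral LOH at $f = 0.2$ gives mirrored BAF
0.60.

`fitSegment()` assigns each aberrant segment a state and fraction by
exhaustive search over all states with $n_T \le$ `max_total_copy`
(default 4), $0 \le n_B \le \lfloor n_T/2 \rfloor$, excluding the
normal (2, 1), crossed with $f \in \{0.01, \dots, 1.00\}$ in steps of
0.01 (matching the 1% granularity of the footprint rule). The residual
is $w_l\,(\hat\ell - \ell(f, n_T))^2 + w_b\,(\hat b - b(f, n_T,
n_B))^2$ with $w_l = 1$, $w_b = 4$: after median summarization over
hundreds of probes the BAF channel is the less noisy of the two and is
weighted accordingly. The (state, fraction) surface is genuinely
degenerate in places — a gain to 3 copies at fraction $f$ produces the
same log2R as a gain to 4 at roughly $f/2$ — which is why the grid is
capped at $n_T = 4$ and ties are broken toward the smaller $|n_T - 2|$,
then the larger $n_B$, then the smaller $f$ (prefer the most
parsimonious state, then the most balanced alleles, then the smaller
clone). Numerical ties within $10^{-12}$ are treated as exact.

## Clustering and the footprint

`clusterFractions()` sorts fitted fractions and merges sequentially: a
segment joins the running cluster while its fraction is within
`delta_f` (default 0.08) of the running length-weighted centroid,
otherwise a new cluster starts. The default is roughly three times the
empirical spread of fitted fractions for a 1%-footprint clone at
default noise, so clones separated by ≥ 2 × `delta_f` are reliably
resolved. Sorting plus tie-breaking on genomic position makes the
result independent of input row order.

A cluster is counted toward CC only when its aggregate span reaches
`footprint_fraction` (default 0.01; the 0.5% setting is the
sensitivity analysis) of the analyzed genome. The footprint is applied
**per cluster**, not per segment: several small same-fraction segments
scattered across the genome jointly constitute evidence for a clone,
and this aggregate reading reproduces the observed behavior where a
sub-1% cluster appears as an additional clone when the footprint is
relaxed to 0.5%. The denominator is the probe-covered autosomal span,
not the full genome length — it is the region the assay actually
interrogated — and is echoed in every report. Sex chromosomes are
excluded throughout: their BAF expectations depend on sex, which the
model does not carry.

# The simulator

`simulateSample()` renders a ground-truth `ClonalArchitecture` (purity,
clones with cancer-cell fractions, allele-specific events) into
probe-level data: 220,000 probes placed uniformly over GRCh37 autosome
lengths, Gaussian log2R noise (`sigmaLog2R`, default 0.25), Beta BAF
noise with precision `bafConcentration` (default 60) around the exact
mixture expectation with random allele phase, and a germline
heterozygosity rate of 0.35. The defaults emulate FFPE-grade OncoScan
arrays. Beta noise (bounded support) was preferred over truncated
Gaussians so that the zero-noise limit is exact: `exactNoiseModel()`
sets $\sigma = 0$, $\kappa = \infty$ and renders expectations
verbatim, which the recovery tests exploit. Homozygous loci are
rendered near 0.02/0.98 precisely so that the downstream informative
window has realistic material to exclude.

Truth CC is bookkept with the same counting semantics as the pipeline:
distinct event fractions (rounded to 0.01) whose aggregate span passes
the footprint. Events of different clones must be disjoint unless
`nested = TRUE` is requested explicitly; the fraction algebra of
nested events (a subclonal change on an already-aberrant background)
is *not* modeled — in nested mode the innermost event simply wins at
rendering time — so nesting is an opt-in for exploration, not an
analysis feature.

`simulateCohort()` generates clinical tables: Mono/Poly membership at
a configurable prevalence (default 59/74), CC values from the
empirical distribution of the motivating cohort, exponential EFS/OS
times with a group hazard ratio, and independent uniform censoring.

What the simulator does **not** emulate: GC waves and probe-level
systematic effects (noise is i.i.d.), mosaic or chromothriptic
rearrangement patterns, subclone phylogenies (fractions are free
parameters, not tree-constrained), and X/Y. Passing recovery tests
therefore demonstrates correctness of the inference chain under the
stated noise model, not performance on every real-array artifact.

# Cohort statistics

The statistical surface consists of thin, validated wrappers around
the standard implementations — `fisher.test` (two-sided
probability-mass rule for 2×2; Freeman–Halton for r×c),
`wilcox.test`, `kruskal.test`, `cor.test`, and the `survival` package
(`survfit`, `survdiff`, `coxph` with Efron tie handling, the default
of major survival software) — with the independent enumeration and
hand-computed oracles living in the test suite, where they
cross-check the wrappers exactly on small fixtures. Count summaries
report the standard deviation under both the $n-1$ and $n$
conventions, because printed clinical tables are frequently ambiguous
between the two. No multiple-testing correction is applied anywhere;
p < 0.05 is the declared significance convention of the analyses this
package reproduces. `minDetectableHR()` exposes the Schoenfeld
power formula
$\mathrm{HR} = \exp\!\big((z_{1-\alpha/2} + z_{\mathrm{power}}) /
\sqrt{d\,p(1-p)}\big)$ with every input explicit, since a detectable
effect size depends on an event count that published reports often
omit.

# Numerical choices and degenerate inputs

* Zero surviving probes, a missing required column, negative follow-up
  times, overlapping segments, or an empty contingency margin are
  errors, not warnings; all row drops in readers are counted and
  logged.
* Fewer than `min_probes` probes on every chromosome yields an empty
  segment set with a warning (not an error), so screening loops can
  continue.
* Raw fraction solutions outside [0.01, 1] are clipped and flagged
  rather than discarded; the fitting grid never produces them, but the
  inversion helpers are exposed and must be safe standalone.
* Cox fits with monotone likelihood (perfect separation) are flagged
  `converged = FALSE` instead of returning a silently enormous hazard
  ratio.
* JSON reports are written with a fixed key order and survive a
  read–rewrite cycle byte-identically, so they can be diffed.

# Problem sizes in the shipped tests

Unit tests run the simulator at 2,000–50,000 probes, where every
segmentation property already holds; full 220,000-probe arrays are
exercised in the acceptance suite: 50 noisy recovery runs over the
1–3-clone grid, an exhaustive 14-architecture zero-noise grid, 100
random samples for the footprint-monotonicity property (at 20,000
probes), and a 2000-patient cohort for hazard-ratio recovery. These
sizes give stable pass/fail behavior in a few minutes on one CPU and
were fixed before being wired into the acceptance checks.

# Known limitations

* **Homozygous leakage inflates mirrored BAF.** With Beta(κ = 60)
  noise, a tail of homozygous probes falls inside the default
  [0.03, 0.97] informative window; mirrored near 1, they bias segment
  mBAF medians upward by a few hundredths. Consequences: fitted
  fractions are slightly overestimated (the worked example recovers
  0.79/0.35 for truth 0.75/0.30), and occasional small segments on
  flat genomes cross `tau_mbaf` and form spurious low-fraction
  clusters — which the clone-calling footprint then rejects. A
  matched-normal genotype channel, if available, would remove this
  bias; the package deliberately works in the tumor-only regime.
* **State degeneracy.** High-copy states at low fraction can be
  signal-identical to low-copy states at higher fraction; the grid cap
  and parsimony tie-break resolve the call deterministically but
  cannot recover information the two channels do not contain.
* **No nested-clone deconvolution, no SNV integration, no global
  purity/ploidy optimization.** The method counts fraction clusters;
  it does not order clones phylogenetically.
* The CC number is footprint-dependent by construction; reports echo
  the footprint, and sensitivity analyses (1% vs 0.5%) should be read
  together.

# Interface note

The package is an R-library-first artifact: the functions documented
here, the test suite and `scripts/acceptance.R` are its operational
surface. File formats (probe TSV, SEG with an optional
`Segment_mBAF` column, clinical CSV, YAML config, JSON reports and
architectures) all use 1-based inclusive genomic coordinates, matching
the SEG convention.
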