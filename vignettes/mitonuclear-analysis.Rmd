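---
title: "Models and methods: mitonuclear hybrid analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mitonuclear hybrid analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoHeterosis)
```

## The biological design

In heterothallic basidiomycetes, haploid monokaryons act like gametes:
mating two compatible monokaryons produces a heterokaryon carrying both
nuclear genomes but — because mitochondria are inherited uniparentally —
only one of the two mitochondrial haplotypes. Crossing a set of bred-line
monokaryons against one common tester therefore yields *reciprocal
mitotype pairs*: hybrids with identical nuclear composition that differ
only in whether they carry the (n) or the (t) mitochondrial genome. Any
phenotypic difference within such a pair is attributable to mitonuclear
interaction.

The panel this package models has five parental monokaryons (two fast- and
two slow-growing bred-line monokaryons plus one tester), their two founder
heterokaryons, and eight F1 hybrids forming four reciprocal-mitotype
pairs. Growth rate, gene expression (ETC subunits, antioxidant enzymes,
substrate-colonisation genes), mushroom-production traits and ROS staining
are each analysed per trio: the two parental monokaryons and their hybrid.

## The inheritance model

For one trait, with parental means $P_1, P_2$ and hybrid mean $F_1$:

$$m = \frac{P_1 + P_2}{2}, \qquad a = \frac{|P_1 - P_2|}{2}, \qquad
d = F_1 - m .$$

The degree of dominance is $d/a$ and classifies the mode of inheritance:
$d/a = 0$ co-dominance; $0 < |d/a| < 1$ partial dominance of the higher-
or lower-value parent; $|d/a| = 1$ complete dominance; $|d/a| > 1$ over- or
underdominance (a transgressive hybrid). Mid-parent heterosis is
$\mathrm{MPH} = 100\,(F_1 - m)/m$.

Two conventions resolve ambiguities in that classical formulation:

* **$a$ is non-negative** (half the parental span, oriented to the
  higher-value parent). A positive $d/a$ then always means deviation
  toward the better parent, which is what the high/low labels of the bins
  require.
* **Tolerance $\varepsilon$ around the point bins.** With continuous data
  the events $d/a = 0$ and $|d/a| = 1$ have probability zero, so
  `classifyMode()` treats $|d/a| \le \varepsilon$ as co-dominance and
  $\bigl||d/a| - 1\bigr| \le \varepsilon$ as complete dominance. The
  default $\varepsilon = 0.1$ is small relative to the bin width 1;
  published point-estimate calls implicitly used $\varepsilon = 0$.

Two guards handle degeneracy: when $a$ falls below `a_min` (default: the
pooled standard error of the parental difference, on the $a$ scale) the
ratio is reported as undefined rather than exploding, and the mode falls
back on the sign of $d$; and MPH is undefined when $m = 0$, which is why
expression trios should not be centred exactly at zero.

At point estimates, $|d/a| > 1$ is *equivalent* to $F_1$ lying outside the
parental range — the test suite checks this identity on random trios. The
statistical transgressive call is stricter: `callTransgressive()` also
requires Welch tests against *both* parents to reject at $\alpha$ in the
same direction, so a hybrid marginally outside a noisy parental range is
not called transgressive.

### Uncertainty

`bootstrapTrio()` is a parametric bootstrap: member means are resampled
from $\mathcal N(\bar x,\, s/\sqrt n)$, and $d/a$, MPH and the mode are
recomputed per replicate, giving percentile intervals and a mode-stability
fraction. The plug-in $s$ treats the replicate SD as known; with $n = 3$
replicates the intervals are noticeably liberal (the SD estimate has two
degrees of freedom), which is why the coverage test in the suite runs at
$n = 10$, where coverage is near-nominal. Interpret $n = 3$ intervals as
descriptive.

### Scale for expression traits

Additivity of $m$, $a$, $d$ is scale-dependent. Expression trios are
analysed on the **log2 relative-expression scale** (the $\Delta\Delta$Ct
scale), where qPCR noise is approximately normal and "codominance" means
geometric intermediacy of fold changes — the natural null for
transcription. Fold changes $2^{-\Delta\Delta Ct}$ are computed for
display. The $d/a$ ratio is invariant to the additive shift introduced by
the choice of calibrator, so mode calls do not depend on it; MPH of
expression traits does depend on the chosen scale, which is recorded in
the output.

## qPCR model

`buildExpressionTable()` implements the 2^−ΔΔCt method with a fixed
amplification efficiency of 2 (100%), the assumption built into the
formula. ΔCt is computed *per biological replicate*: target Cq minus the
arithmetic mean of the three reference-gene Cq values of the same
replicate — arithmetic averaging of Cq equals geometric-mean normalisation
of the linear quantities, the standard multi-reference practice. Replicate
ΔCt values give the per-strain mean, SD and $n$; ΔΔCt subtracts the
calibrator strain's mean ΔCt, and its SD combines both terms as
$\sqrt{s^2 + s_\mathrm{cal}^2}$. The calibrator defaults to the
alphabetically first parental monokaryon so that a fixed panel always has
a deterministic reference point; any strain can be configured instead.
Two invariants pin the arithmetic down: adding a constant to every Cq of a
sample leaves its ΔCt values unchanged, and the calibrator's own fold
change is exactly 1.

## Group statistics

`anovaOneway()` is the classical fixed-effects one-way ANOVA (via
`stats::aov`). `anovaFromSummary()` reconstructs the identical
decomposition from per-group (mean, SD, $n$) —
$SS_B = \sum n_i(\bar x_i - \bar x)^2$, $SS_W = \sum (n_i - 1) s_i^2$ — so
published tables reporting mean ± SD can be re-analysed; the suite checks
exact agreement of the two routes on random data. Scheffé's criterion
declares pair $(i,j)$ different when
$|\bar x_i - \bar x_j| > \sqrt{(k-1)\,F_{\alpha;\,k-1,\,N-k}}\;
\sqrt{MS_W (1/n_i + 1/n_j)}$; it protects the whole contrast family, so it
is conservative and can never contradict a non-significant omnibus test.
The compact letter display uses insert-and-absorb: groups share a letter
iff their comparison is non-significant, with letters ordered by
descending mean (best-performing group = "a"; the ordering is
configurable since "best" is trait-dependent — for earliness smaller is
better).

Two caveats inherited from working with printed tables: SDs rounded to
zero are accepted at face value with a warning (they cannot be
un-rounded), and letter displays recomputed from rounded summaries can
differ from those computed on the raw data — flush counts printed as
1 ± 0 vs 3 ± 0 are the canonical example: their printed letters are not
recoverable from the rounded SDs, and the package documents rather than
patches this.

`selectionResponse()` reports $R = \bar x_\mathrm{advanced} -
\bar x_\mathrm{base}$ and a relative percentage with the
**advanced-generation mean as denominator**: with $R = 2.03$ and an
advanced mean of 4.07 mm/day this gives 49.9% ≈ 50, and with $R = -0.02$
against 1.12 mm/day it gives −1.8% — both matching the percentages this
breeding design reports, whereas a base-generation denominator
(2.03/2.04 ≈ 100%) does not. The choice is recorded in the result object.

## Marker calls

Fragment-size calls use relative tolerance matching against the reference
bands (nuclear chromosome VII: 0.4 kb fast-line, 3.6 kb slow-line, 0.3 kb
tester; mitochondrial *cox1*: 1.9 kb (n), 0.2 kb (t)). The default
tolerance of 15% reflects typical agarose sizing error while keeping the
closest pair of bands (0.3 vs 0.4 kb) separable, since
$0.4 \times 0.15 = 0.06 < 0.1$; gel-sizing precision is not standardised,
so the tolerance is an explicit argument. A fragment matching two bands is
an *error*, never a nearest-match guess — a miscalled genotype corrupts
every trio built on it. `validateCrossTrio()` enforces uniparental
mitochondrial inheritance: a hybrid mitotype matching neither parent
aborts the pipeline run by name.

## ROS imaging

Staining is quantified as the percentage of plug pixels above a threshold,
computed strictly inside the plug mask — background pixels can never
affect the number. The mask is either the known plug disc (recorded by the
generator, or supplied in the sidecar) or a centred disc covering 90% of
the image's shorter dimension. The default threshold is Otsu's criterion
on a 256-level histogram of the masked intensities; a fixed threshold is
available since manual imaging workflows often use one. A uniform masked
region is degenerate for Otsu and returns 0% with an `NA` threshold. For
the high-contrast staining the generator emulates, the percent area is
invariant under monotone intensity rescaling at 8-bit granularity (the
threshold moves with the histogram); low-contrast real images would not
enjoy that invariance, and no flat-field correction is applied — equal
exposures and dark unstained controls are assumed.

## The synthetic-data generator

`simulateStudy()` produces every input with ground truth attached, under
a single integer seed (identical seed ⇒ identical tables and images).
What it emulates, and the defaults chosen:

* **Growth** — cell means $\mu_\mathrm{strain} + \beta_\mathrm{env} +
  \gamma_{\mathrm{strain}\times\mathrm{env}}$ with Gaussian residual
  (SD 0.15 mm/day), 3 replicates; fast and slow line means 4.07 and
  1.12 mm/day; environments are temperature (15/24/32 °C on malt) and
  carbon source (glucose/sucrose/glycerol at 24 °C); an interaction term
  makes the slow (t)-mitotype hybrid outgrow its (n) counterpart,
  emulating mitochondria-dependent rescue.
* **Expression** — per trio and gene, true log2 levels are $P_1 = b + a$,
  $P_2 = b - a$, $F_1 = b + (d/a)\,a$ with baseline $b = 6$, parental
  span $a = 3$ log2 units (an 8-fold parental difference, in line with
  strongly differential ETC/antioxidant genes) and true $d/a$ cycled
  through $\{-1.5, -1, -0.5, 0, 0.5, 1, 1.5\}$ — one value per bin.
  Cq = 26 − log2 level + $\mathcal N(0, 0.2)$; three reference genes sit
  at Cq 20 with the same noise. With 3 replicates this gives a ratio
  estimation error of about 0.05, so the boundary bins (0, ±1) are
  recovered in ≈ 95% of trios at $\varepsilon = 0.1$ — the recovery rate
  the acceptance checks measure. A smaller span or larger noise degrades
  boundary-bin recovery first; interior bins are robust.
* **Production** — earliness and yield Normal with the published
  per-hybrid means/SDs as defaults; flush counts are shifted Poisson
  ($1 + \mathrm{Pois}(\lambda)$) because a fruiting strain has at least
  one flush.
* **Plug images** — a disc (radius 45% of a 128 px image) at background
  intensity 0.2 with bright blobs (intensity 0.8, SD 0.03, 8-bit
  quantised) grown until the target stained fraction is hit exactly in
  pixel count; the truth table records the achieved fraction.
* **Breeding** — truncation selection on a population of 200 line means
  (genetic SD 0.8, environmental SD 0.3, $h^2 = 0.5$, top/bottom 20%
  selected). Sibling monokaryons derived from one heterokaryon are
  gametes of a *single* genotype, so each intercross generation is
  selfing-equivalent and the inbreeding coefficient follows
  $F_t = 1 - (1/2)^t$, giving 0.969 after five generations — consistent
  with a reported coefficient of 0.97 at that precision. The diploid
  full-sib recurrence $F_t = (1 + 2F_{t-1} + F_{t-2})/4$ is also provided
  because the pedigree reading is genuinely ambiguous; the generation
  count behind any particular printed coefficient is a parameter, not an
  inference.

What the generator does *not* emulate: amplification-efficiency
variation, reference-gene instability, heavy-tailed or batch-structured
noise, low-contrast or unevenly illuminated staining, and linkage
structure behind the breeding response. Recovery tests passing on this
generator therefore validate the estimators' arithmetic and calibration
under clean Gaussian conditions, not robustness to those real-data
pathologies.

## Numerical and design choices

* Problem sizes in the test suite and acceptance script — 10,000 random
  trios for the algebraic identities, 200 trios for mode recovery, 10,000
  null simulations for ANOVA calibration, 120 bootstrap coverage runs at
  $B = 400$ — were chosen to keep each stochastic check's sampling error
  well below the margin it asserts while the full suite runs in about a
  minute.
* Seeds are fixed in tests; generator helpers save and restore the
  caller's RNG state so seeded simulation never perturbs user code.
* Ambiguous marker calls, missing calibrator genes, unknown mitotypes and
  insufficient replication are errors, not warnings: every one of them
  invalidates downstream inference.
* The pipeline treats partial inputs as skippable stages with explicit
  warnings, but validation failures (uniparental inheritance, marker/panel
  discordance) abort the run.

## Known limitations

Single-trait, single-locus decomposition only: no best-parent heterosis,
no epistasis or QTL partitioning, no efficiency-corrected qPCR, no
mixed-effects or two-way ANOVA (environments are analysed separately),
and no per-hypha image segmentation. Published figure-level values whose
raw inputs are not printed (per-gene MPH ranges, ROS panel percentages)
are validated through the property checks and synthetic recovery described
above, not reproduced numerically.
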