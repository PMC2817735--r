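---
title: "Positional confidence intervals for CIM-detected QTL: models and methods"
author: "qtlci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional confidence intervals for CIM-detected QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlci)
```

## The problem

A quantitative trait locus (QTL) scan produces, for every chromosome, a LOD
curve over a grid of test positions and a peak taken as the point estimate of
the QTL location. For positional cloning or tests of pleiotropy one needs an
interval, not a point: a set of map positions that contains the causal locus
with stated confidence. `qtlci` implements and compares three interval
procedures for QTL mapped by **composite interval mapping (CIM)** in
recombinant inbred line (RIL) populations:

* **SI** — the LOD support interval: follow the curve from the peak until it
  drops a fixed number of LOD units (2.0 by default) on each side.
* **NPCI** — a naive bootstrap percentile interval: resample individuals with
  replacement, rescan with the *original* dataset's background markers, and
  take the central 95% of the per-chromosome peak positions.
* **CIM-NPCI** — the CIM-tailored bootstrap: identical, except that the
  stepwise selection of background markers is *redone on every bootstrap
  replicate*, so the interval accounts for the procedural variability of CIM
  itself.

Because CIM LOD curve shapes respond strongly to the choice of background
markers and blockout window, curve-shape methods (SI) can be anti-conservative
exactly where mapping is most informative — dense marker regions. The
bootstrap that re-runs the whole CIM pipeline is the package's focus.

## Population and trait model

The simulator targets an RI1 population: fully inbred lines derived by
repeated selfing, so each locus has two homozygous classes, coded +1 and -1.
Genotypes are generated chromosome-by-chromosome as a first-order Markov
chain along the ordered loci: the first locus is ±1 with probability 1/2 and
adjacent loci at distance $d$ cM differ with probability

$$R = \frac{2r}{1+2r}, \qquad r = \tfrac12\left(1 - e^{-2d/100}\right),$$

the selfed-RIL expansion of the Haldane (no-interference) recombination
fraction. The exact multilocus RIL process is not Markov; the chain on
RIL-expanded fractions is the approximation used by mainstream simulators and
is accurate at these marker densities. Kosambi mapping is available as an
option but is not used by the benchmark.

The trait is purely additive, $y_i = a\sum_k q_{ik} + e_i$ with
$e_i \sim N(0, \sigma_e^2)$ and

$$\sigma_e^2 = K a^2 \frac{1-h^2}{h^2}$$

for $K$ QTL, which fixes the *expected* heritability at $h^2$ (each ±1 locus
with balanced classes contributes variance $a^2$). Realized per-dataset
heritability therefore fluctuates around $h^2$ — the behaviour of standard
trait simulators, and the reading we adopt where the alternative (rescaling to
the realized genetic variance) was also defensible. With $a = 0$ the residual
SD is set to 1 so null traits remain usable.

## The benchmark design

The benchmark map has four identical 165 cM chromosomes with 23 whole-cM
markers graded dense to sparse; each chromosome carries one assay interval —
(11,12), (23,26), (69,84), (114,134) cM, i.e. widths 1, 3, 15 and 20 cM —
housing Q1..Q4. A sub-simulation places every QTL at fractional distance $D
\in \{0, 0.10, 0.30, 0.50\}$ from its left flanking marker; all four effects
are equal (sharing a sign, which the design leaves open) and scaled so each
QTL explains 15% of the phenotypic variance at $h^2 = 0.6$ with $n = 200$
lines. Only some marker positions are constrained by the design (telomeres
at 0 and 165; the assay intervals; markers at 134 and 154 used by the
chromosome-end control), so the filler markers of `benchmarkMap()` —
`r paste(markerPositions(benchmarkMap(), 1), collapse = ", ")` — are a
documented default satisfying every constraint, not ground truth; results
that depend only on the constrained intervals are insensitive to them.

## The CIM engine

`cimScan()` is a Haley–Knott-style regression CIM. At each grid position $t$
(1 cM walk, both chromosome ends included, hence 166 positions per 165 cM
chromosome) the predictor is the conditional expectation of the putative QTL
genotype given the flanking markers,

$$E[q \mid m_L, m_R] = m_L(2p-1), \qquad
p = \begin{cases}
\frac{(1-R_1)(1-R_2)}{1-R_{12}} & m_L = m_R\\[2pt]
\frac{(1-R_1)R_2}{R_{12}} & m_L \ne m_R,
\end{cases}$$

with $R_1, R_2$ the RIL-expanded fractions of the two sub-intervals and
$R_{12} = R_1(1-R_2) + R_2(1-R_1)$ their Markov-chain composition — the same
law the simulator uses, so predictor and data-generating process are
consistent. (Composing instead via the Haldane distance of the flanking pair
gives slightly different values; we use the chain form throughout.) At an
exact marker position the marker column itself is the predictor. The LOD of
adding the predictor to the covariates is

$$\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1},$$

capped at 1000 for perfect fits; projections use a Cholesky solve of the
small covariate Gram matrix with a rank-revealing QR fallback, so exactly
collinear covariates (possible in bootstrap resamples) are handled without
failure.

**Cofactors.** Background markers are chosen by forward/backward stepwise
regression of the trait on all markers: each forward step admits the marker
with the smallest partial-F p-value when it is below 0.05 (ties broken
leftmost in genome order), backward elimination then removes any included
marker whose drop-one p-value exceeds 0.05 until stable, and the search stops
after at most 10 forward additions. The selected set is then ranked by
final-model strength (ascending drop-one p-value) and the scan uses at most
the five strongest — a surrogate for the cofactor ranking of the original
software, which is not fully specified. Ranking matters more than it looks:
truncating by *entry order* instead lets a noise marker that happened to
enter early displace a true QTL's marker from the top five in bootstrap
resamples, leaving that QTL's signal unblocked elsewhere on its chromosome
and producing spurious far-off peaks that wreck bootstrap interval widths;
strength ranking removes this failure mode.

**Blockout window.** At test position $t$, a cofactor is excluded if it lies
within 10 cM of $t$ *or* is one of the two markers flanking the test
interval; the window boundary is excluded too, and cofactors on other
chromosomes are never blocked. Always excluding the current interval's
flanking markers is the classic CIM formulation, and it matters: blocking on
a bare 10 cM radius leaves a wide marker interval with no position at which
both flanks are simultaneously blocked, so when both flanking markers are
cofactors the LOD curve collapses to a spike at the single equidistant grid
point and sparse-region coverage collapses with it. We adopted the
interval-aware rule after observing exactly that failure. At an exact marker
position the marker is treated as belonging to the interval it starts.

## Interval procedures and thresholds

**Support intervals** take the leftmost argmax as the peak and extend to the
furthest grid positions reachable without dropping more than 2.0 LOD below
the peak, truncated at chromosome ends; endpoints are reported at
walking-speed resolution with no sub-grid interpolation.

**Permutation threshold.** The trait is shuffled against the genotypes P
times; each permuted dataset gets the complete CIM analysis — including
cofactor re-selection, our resolution of a point the benchmark protocol leaves open
(a frozen-cofactor variant is available by flag) — and the genome-wide
maximum LOD is recorded. The threshold is the $\lceil P(1-\alpha)\rceil$-th
order statistic of the null maxima, an experiment-wise cutoff at
$\alpha = 0.05$.

**Bootstrap intervals.** Each of B replicates resamples the n individuals
with replacement (trait staying paired with its genotypes), re-runs CIM
(with re-selection for CIM-NPCI, with the original cofactor set for NPCI),
and records the leftmost per-chromosome peak. The *selective* variant keeps
only peaks exceeding the original dataset's threshold before taking the
central 95% by the order-statistic rule
$\left[x_{(\lceil B\alpha/2\rceil)}, x_{(\lceil B(1-\alpha/2)\rceil)}\right]$;
the non-selective variant orders all peaks. Chromosomes whose original peak
is not significant yield no interval and are reported as such. If selective
filtering retains fewer than 20% of replicates the non-selective interval is
returned with a warning and a `fallback` flag. Degenerate replicates
(constant resampled trait) are skipped and logged.

## Study driver, seeding, and accounting

`runFullStudy()` concatenates sub-simulations over D, summarising per
(D, QTL, method) cell the mean interval width (with its standard error) and
the coverage — the fraction of datasets whose interval contains the true
position, containment being inclusive on closed intervals. Datasets whose
bootstrap methods produce no interval are counted two ways, as non-covering
(the `coverage` column) and conditionally on an interval existing
(`coverageEffective`), since either
accounting it used. Every dataset runs in its own RNG stream derived from
the master seed by counter, so any single dataset is reproducible in
isolation and results are invariant to execution order. The chromosome-end
control (`runEndEffectStudy()`) relocates Q1 to 154/152/148/144 cM — 0/10/30/50%
of the way from the marker at 154 toward 134 — leaving Q2–Q4 unchanged, so
the 0% variant mirrors the original Q1's 11 cM distance from a telomere.

## Replication scale and tolerances

The full-scale benchmark study uses N = 1000 datasets per sub-simulation with
B = 1000 bootstraps and P = 1000 permutations. The package's acceptance
checks run the same pipeline at desk scale: N = 100 for support-interval
summaries; N = 50 (D = 0 and single-cell summaries) or 25 (remaining
sub-simulations) with B = 200 and P = 100 for bootstrap methods; 200 null
datasets with P = 200 for the type-I calibration. Cell-mean tolerances are
±3 reference standard errors inflated by $\sqrt{N_{full}/N_{reduced}}$, plus
an engine allowance of 20% of the printed value for width statistics. The
allowance covers the one deliberate substitution in the pipeline: the
original analyses used an ECM maximum-likelihood mixture engine, which we
replace by regression CIM by design. The two agree closely at and near
markers, but in wide marker intervals the regression predictor retains only
$(1-2R)^2$ of the QTL signal at the midpoint (≈ 48% on a 20 cM RIL interval),
flattening the peak relative to the likelihood engine; support intervals and
bootstrap peak scatter in the sparse mid-interval cells are therefore
systematically somewhat wider here, while dense-region and at-marker cells
reproduce closely.

The bootstrap percentile interval adds a second, subtler sensitivity: it is
driven by the 2.5% tails of the peak distribution. In a dataset that happens
to carry a modest spurious marker association elsewhere on a QTL's
chromosome, resampling occasionally makes that secondary mode the
per-chromosome argmax; once more than 2.5% of replicates land there, the
percentile interval jumps to the far mode and the dataset contributes a very
wide interval. Taller, sharper likelihood curves make the true peak win more
reliably, so a regression engine shows more of these tail datasets than a
mixture-likelihood engine on identical data — per-dataset *median* widths
agree while *means* in the affected cells run wider. Users comparing
CIM-NPCI summaries across engines should compare medians, or inspect the
per-dataset width distribution, before interpreting mean widths.

## What the generator does and does not emulate

Simulated data are complete (no missing genotypes), fully inbred (no residual
heterozygosity), free of genotyping error, segregation distortion and
epistasis or dominance, with exactly one QTL per chromosome and Gaussian
residuals. Passing tests therefore demonstrate correctness of the procedures
under the stated model, not robustness to the missing-data patterns, outliers
or polygenic backgrounds of real populations — on real data the relative
width of SI and CIM-NPCI intervals has been observed to differ from the
complete-data pattern. Within-chromosome multilocus dependence is Markov by
construction; true RIL populations deviate from this slightly.

## Numerical choices

* LOD values are clamped to $[0, 1000]$; a predictor lying in the span of
  the covariates scores 0.
* Stepwise F-tests use the rank of the design, so collinear candidates can
  never enter; drop-one p-values come from coefficient t-statistics of a
  single fit, with an explicit refit fallback under exact collinearity.
* Peak ties are broken leftmost everywhere (argmax, support intervals,
  bootstrap peaks).
* The scan grid always includes both chromosome ends; a final partial step
  is appended if the walk does not divide the chromosome length.
* Quantile rules are pure order statistics (no interpolation), matching the
  discrete bootstrap and permutation protocols.

## A small worked example

```{r example, eval = FALSE}
cross <- simulateCross(n = 200, D = 0.10, seed = 1)
cof   <- stepwiseCofactors(cross)
prof  <- cimScan(cross, cof)
supportInterval(prof)                       # 2.0-LOD support intervals
cimNPCI(cross, B = 200, P = 100)            # CIM-tailored bootstrap CIs
```

At study scale, `studyConfig(reduced = TRUE)` installs the desk-scale
replication counts and `runFullStudy()` returns the width and coverage
tables; `scripts/acceptance.R` in the source tree drives exactly this
pipeline end to end.
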