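---
title: "qpcrSEA: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qpcrSEA: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

qpcrSEA analyses two-condition qPCR miRNome panel experiments end to end:
raw amplification curves are reduced to quantification cycles (Cq),
normalized to relative expression, ranked between conditions, and scored
against annotated miRNA sets with a running-sum enrichment statistic and a
permutation null.  A final consensus step joins the enriched sets with
multi-tool target predictions to nominate candidate miRNAs.  This
vignette records the statistical model behind each stage, the tunable
parameters and their defaults, and the design decisions taken where more
than one reasonable convention exists.

```{r setup}
library(qpcrSEA)
```

## The panel and its simulator

The unit of input is a 384-well miRNome PCR plate: 372 miRNA assays,
three interplate calibrators, three reference-gene assays, five RNA
spike-in controls, and one blank well.  `makeDefaultLayout()` builds this
layout with a packaged, representative human miRNA assay list (the vendor
assay list is proprietary; the packaged list contains widely profiled
human miRNAs and every miRNA referenced by the packaged worked-example
tables).

Because raw panel data from real instruments are rarely shareable, the
simulator is a first-class module rather than a test fixture.
`simulateExperiment()` generates, for each sample, one plate of
amplification curves under a four-parameter logistic model

$$ f(c) = b + \frac{f_{\max}}{1 + e^{-k (c - m)}} + \varepsilon_c,
   \qquad \varepsilon_c \sim \mathcal N(0, \sigma^2), $$

with baseline $b$, plateau $f_{\max}$, slope $k$ (per cycle) and midpoint
$m$.  The logistic was chosen because it is the standard idealized qPCR
shape *and* has a closed-form second-derivative maximum,
$c_{SDM} = m - \ln(2 + \sqrt 3)/k$, which gives every downstream Cq
computation an exact oracle.  The simulator places $m$ so that the SDM
sits exactly at the requested true Cq.

Defaults (`defaultCurveParams()`, `simulationConfig()`), chosen once as
typical of a well-behaved LNA panel run and held fixed:

| parameter | default | meaning |
|---|---|---|
| `fmax` | 10 | plateau fluorescence (arbitrary units) |
| `k` | 1 | logistic slope per cycle |
| `baseline` | 1 | background fluorescence |
| `noiseSd` | 0.1 | additive Gaussian noise SD on fluorescence |
| `cycles` | 1..45 | cycle range |
| `nSamplesPerCondition` | 3 | biological replicates per condition |
| `deEffectSize` | 2 | Cq shift of differential miRNAs (cycles) |
| `interplateSd` | 0.2 | SD of the per-plate Cq offset |

Three replicates per condition is the common minimum for a two-condition
profiling experiment; the replicate count is an engineering default, not
a claim about any particular study.  Direction semantics follow qPCR
convention throughout: *up-regulated means lower Cq* (one cycle = one
log2 unit of expression), and a differential effect of 2 cycles is a
four-fold expression change.  Planted enriched sets receive the shift
coherently in their stated direction; reference genes, calibrators and
spike-ins are condition-invariant by construction; the blank well yields
a flat baseline-plus-noise trace that the Cq caller must refuse to call.

What the simulator deliberately does **not** model: PCR efficiency
chemistry, melt behaviour, probe-specific amplification differences,
cross-well contamination, or batch structure beyond a single per-plate
Cq offset.  Passing tests on simulated data therefore demonstrate that
the statistical chain is correct under its stated model, not that the
model captures every failure mode of real instruments.

## Cq calling by the second-derivative maximum

`callCqSdm()` reports the cycle at which the second derivative of the
amplification curve peaks — the standard SDM definition of Cq.  Two
numerical routes exist for locating that peak from discrete, noisy
fluorescence readings:

1. smooth the trace, take discrete second differences, and interpolate
   around the argmax; or
2. fit a parametric sigmoid and differentiate the fit.

We measured route 1 on noiseless logistic curves sampled at integer
cycles: the discrete second-difference operator displaces the peak by
0.13–0.43 cycles without smoothing and by up to 1.8 cycles with a
five-point moving average, because both the differencing stencil and the
smoothing kernel have widths comparable to the curvature scale of the
curve.  That bias is far above what interplate comparisons tolerate, so
the package uses route 2: a four-parameter logistic is fitted by
Levenberg–Marquardt least squares (with analytic Jacobian) and the Cq is
taken in closed form at $\hat m - \ln(2+\sqrt3)/\hat k$.  On noiseless
logistic curves this recovers the true SDM to machine precision, and at
the default noise level the error stays well below 0.1 cycles (both are
checked in the test suite across $k \in [0.5, 2]$, $m \in [15, 35]$).
The `smoothingWindow` parameter (default 5, centered moving average) is
used only for the amplification screen and the fit's starting values, so
it cannot bias the estimate.

A trace is reported *undetermined* (`NA`) when its smoothed amplitude
rise is below `detectionNoiseMult` (default 5) times a robust noise
estimate (the MAD of the first differences, scaled), when the fit fails
or yields a non-positive slope or an amplitude below the detection
level, or when the fitted SDM falls outside the observed cycle range.
Blank wells fall out naturally under this rule.

## Preprocessing conventions

**Interplate calibration.**  For each plate, the mean calibrator Cq
minus the global mean of the per-plate calibrator means is subtracted
from every Cq on that plate.  The operation is idempotent and leaves
single-plate experiments untouched.  A plate with no defined calibrator
Cq is a hard QC failure.

**Spike-in QC.**  Each sample's spike-in Cq values are compared with the
cross-sample location of the same spike-in assay.  Location and scale
are estimated with the median and MAD rather than mean and SD: with the
small sample counts typical of these experiments, a single strongly
deviant sample inflates a non-robust scale estimate enough to mask
itself.  Samples deviating by more than `toleranceSd` (default 3) robust
SD units, or with undetermined spike-in Cq, are flagged.

**Normalization.**  Relative expression is $2^{-\Delta Cq}$ with
$\Delta Cq = Cq_{\text{miRNA}} - \overline{Cq}_{\text{ref}}$, the
arithmetic mean over the sample's defined reference-gene Cq values
(arithmetic mean on the Cq scale is the standard $\Delta Cq$ practice;
it equals a geometric mean on the expression scale).  Undetermined Cq
propagates to `NA`, never to zero expression.  Per-sample constant
shifts cancel exactly.

**Detectability filter.**  Before ranking, miRNAs undetermined in more
than half of the samples of either condition are dropped
(`filterDetected()`, threshold configurable).

## Differential ranking

`rankDifferential()` scores each miRNA by the log2 fold change of
condition means on the expression scale (equivalently
$-\Delta\Delta Cq$), test condition over reference.  A signal-to-noise
option — mean difference over the sum of within-condition SDs, with each
SD floored at 20% of the corresponding mean magnitude — is provided
because the enrichment procedure descends from the GSEA lineage where
that metric is customary.  Log2 fold change is the default because with
typical replicate counts (2–3) per condition, within-condition SD
estimates are too unstable to be a denominator.

Zero condition means (possible after heavy dropout) would produce
infinite scores; they are clamped to one unit beyond the largest finite
score with a warning, keeping the ranked list total and finite.  Ties
are broken lexicographically by name so that the ranking — and
everything downstream — is deterministic.

## The enrichment statistic

For a ranked universe of $N$ miRNAs and a set with $G$ members inside
it, the running sum starts at zero and, walking from rank 1 to $N$,
gains $1/G$ at each member and loses $1/(N-G)$ at each non-member.  The
enrichment score (ES) is the signed value at the maximum absolute
deviation; the sum always returns to zero at rank $N$.  The increments
are unweighted (classic Kolmogorov–Smirnov style) — the procedure is a
pure "enhance if member, reduce if not" cumulative sum, with no
score-weighting.  Exact ties in the maximal deviation are resolved
toward the positive peak, then toward the earlier rank; both choices are
arbitrary but fixed, and are mirrored by the brute-force oracle in the
test suite.  Leading-edge members are those at or before the peak
(positive ES) or strictly after it (negative ES).

**Null model.**  The ES is a rank statistic, so its null distribution
depends only on $(N, G)$.  The null is generated by drawing random
$G$-subsets of the universe (set-label permutation) — not by permuting
sample labels, because the procedure operates on a single differential
ranking and typical replicate counts could not support sample
permutation anyway.  `permutationNull()` draws $B$ subsets (default
1000) or enumerates all $\binom N G$ subsets exhaustively when there are
at most 10,000, and the null per set size is computed once and shared by
all sets of that size.

**NES and nominal p.**  The NES divides the observed ES by the mean
magnitude of same-sign null ES values; the nominal p-value is the
add-one estimator $(1 + \#\{\text{same-sign null} \ge |ES|\}) / (1 +
\#\text{same-sign null})$.  The add-one form keeps p strictly positive
with a floor of $1/(B+1)$ — reported permutation p-values of exactly
0.05 at modest $B$ are a familiar signature of such floors.  If no null
value shares the observed sign (possible at tiny $B$), all null
magnitudes are used, with a warning.

**FDR.**  q-values follow the GSEA convention: the fraction of pooled
normalized null NES at least as extreme (same sign) over the fraction of
observed NES at least as extreme (same sign), clipped to $[0,1]$ and
made monotone within each sign class by a suffix-minimum along
decreasing $|NES|$ (the same correction style as Benjamini–Hochberg).
By default the pool is per category, mirroring reports that analyze one
category at a time; `fdrScope = "global"` pools everything.

**Report shape.**  Results are grouped by category and ordered by
decreasing $|NES|$, ties by set name.  `significancePlotData()` (NES vs
nominal p and FDR) and `esPlotData()` (ES vs within-category rank, from
positively to negatively correlated) expose the plot tables behind the
two standard figures of such analyses.

## Set collections

Collections use the GMT dialect with the set category carried in the
description field (`target`, `regulator`, `cluster`, `family`, `tissue`,
`function`), optionally extended as `tissue|tsi=0.85` for
tissue-specificity indices and `|src=` for provenance.  Member names are
normalized to lower-case `hsa-mir-*` form so that capitalization
variants collapse.  Tissue sets require an index and are filtered at
`tsi >= 0.7` by default (inclusive, matching the usual "index of tissue
specificity ≥ 0.7" convention).  Before scoring, every set is
intersected with the ranked universe and sets below `minSize = 2`
members are dropped — 2 because curated miRNA set collections routinely
contain informative two-member sets (the smallest sets in the packaged
worked-example tables have two members).

## Candidate selection

`consensusTargets()` keeps miRNAs predicted to target the gene of
interest by at least `minTools = 2` distinct tools — the usual guard
against the high false-positive rates of individual prediction
algorithms.  `annotateCandidates()` then joins the filtered enrichment
report with the consensus: one row per miRNA in any retained set, with
its sets, its predicted-regulator flag and the supporting tools.
Because set collections use panel-level names (`hsa-mir-182`) while
prediction tools emit mature-arm names (`miR-182-5p`), the join matches
at base-name level by default (arm suffix and letter variants stripped);
this can be disabled for strictly mature-level work.  Candidates are
ordered by predicted-regulator status, then number of enriched sets,
then name — no canonical final ranking exists for this step, so the
order simply puts the most corroborated candidates first.

Report filters default to nominal $p \le 0.05$ and $|ES| \ge 0.25$,
both inclusive — the packaged worked-example tables retain a set at
exactly $ES = -0.25$, fixing the boundary convention.

## Determinism and problem sizes

Every random stage funnels through one integer seed: the simulator seeds
its own RNG locally (restoring the caller's state), and `mirnaSEA()`
accepts a `seed` that scopes the permutation draws.  `runPipeline()`
writes a manifest with package and R versions, seed, thresholds and MD5
digests of all inputs and outputs; identical configuration and seed give
byte-identical artifacts.

The validation suite exercises: exhaustive oracle equivalence of the ES
on all subsets of universes up to $N = 12$; null calibration with 1000
replicates of $B = 1000$ permutations at $N = 372$; and planted-set
recovery through the full curve-to-report chain over 100 simulated
panel experiments (five-member sets, two-cycle effect, fluorescence
noise 0.1).  These sizes were chosen to give stable rates while keeping
the suite comfortably runnable on a laptop.

## Known limitations

* The Cq caller assumes a sigmoid amplification shape; curves with
  drifting baselines or biphasic amplification are fitted as best the
  4PL allows, and badly non-sigmoidal traces should be caught upstream.
* The enrichment null assumes exchangeable set labels; correlated
  miRNA families on real panels violate this mildly, as they do for all
  set-permutation GSEA variants.
* Expression-scale means with 2–3 replicates make the default ranking
  sensitive to single outlying samples; the spike-in QC and the
  signal-to-noise option mitigate but do not remove this.
* Tissue-specificity indices and prediction evidence arrive as curated
  files; the package performs no live database queries.
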