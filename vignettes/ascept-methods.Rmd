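---
title: "Two-stage changepoint selection for mHealth time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage changepoint selection for mHealth time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascept)
```

## The problem

Population-level summaries of wearable-device data — say, the daily median
deep sleep across a study cohort — mix two kinds of abrupt change.
*Technological* changepoints arise when a vendor silently revises the
algorithm that turns raw sensor data into minutes of deep sleep: the whole
cohort's values jump on one day. *Behavioral* changes, by contrast, tend to
unfold as linear or seasonal trends (training programs, summer vs winter).
An analysis that treats a firmware jump as biology, or vice versa, is
wrong in a way that no amount of downstream modelling can repair.

`ascept` selects mean-shift changepoints in a univariate, regularly spaced,
complete series and then removes ("trims") those that merely track an
ongoing trend, leaving the sudden shifts plus the start and end points of
trends. A final, optional step adjusts the series for the selected
changepoints so that downstream analyses see a single consistent location
and scale.

## Stage 1: significance-tested accumulation of PELT solutions

Within a segment, observations are modelled as i.i.d. Normal; each segment
has its own mean and variance. The segment cost is minus twice the
*constrained* maximum of the Gaussian log-likelihood, with the variance
maximized over $[\,\sigma_{\min}^2, \infty)$:

$$C(y_{a:b}) = n\left(\log 2\pi + \log \hat\sigma_e^2 +
  \hat\sigma^2/\hat\sigma_e^2\right), \qquad
  \hat\sigma_e^2 = \max(\hat\sigma^2, \sigma_{\min}^2),$$

where $\hat\sigma^2$ is the maximum-likelihood (divide-by-$n$) variance.
Above the floor this is the familiar $n(\log 2\pi + \log\hat\sigma^2 + 1)$.
Two properties motivated the constrained form over simply plugging a
floored $\hat\sigma$ into the unconstrained formula:

* it is exactly $-2\sum_i \log \phi(y_i;\hat\mu,\hat\sigma_e)$ for *every*
  segment, degenerate or not, so the likelihood used by the significance
  tests and the cost minimized by the optimizer are the same object; and
* a constrained maximum likelihood can only increase when a segment is
  split (the unsplit fit is feasible for both halves), so total cost is
  subadditive and PELT's pruning inequality holds with $K = 0$ — the
  dynamic program stays *exact* for any floor. The plug-in form provably
  loses this guarantee when a non-constant sub-segment falls below the
  floor.

`pelt()` minimizes total cost plus $\beta$ per changepoint, exactly, with
deterministic tie-breaking (fewer changepoints, then the smaller last
position). `crops_sweep()` exploits the fact that the optimal penalized
cost is piecewise linear in $\beta$ with slope equal to the changepoint
count: bisection on crossing penalties recovers every distinct solution in
a penalty range with one PELT run per solution discovered.
`build_candidate_path()` orders these solutions by decreasing penalty into
$T_0 = \emptyset, T_1, \dots, T_K$.

The walk along the path is a fixed-sequence multiple-testing procedure.
For each consecutive pair, the observed statistic is the gain in
log-likelihood $\ell(y; T_{k+1}) - \ell(y; T_k)$. Its null distribution is
approximated by a parametric bootstrap: draw each segment of $T_k$ from
$\mathcal N(\hat\mu_s, \hat\sigma_{e,s}^2)$, impose *both* fixed
changepoint sets on the draw (detection is not re-run), and record the
gain. With $N$ draws the empirical P-value is the add-one estimate
$p = (1 + \#\{\Delta_{\text{null}} \ge \Delta_{\text{obs}}\})/(N+1)$,
which is conservative and never zero. The walk adopts $T_{k+1}$ while
$p \le \alpha$ and stops at the first non-rejection; because later tests
are only reached after earlier rejections, the family-wise error rate of
the adopted sequence is controlled at $\alpha$. If the path is exhausted
the last set is returned with a warning suggesting a smaller `beta_min`.

Draws for one comparison are generated as a single seeded $n \times N$
block (vectorized), with each comparison's seed derived deterministically
from the run seed and the path index; results are bit-reproducible and do
not depend on any parallel backend.

### The variance floor

$\sigma_{\min} = \max(10^{-8},\ 10^{-4}\,\mathrm{sd}(y))$. The floor's
nominal job is to give length-1 and constant segments a finite cost and a
samplable null. It has a second, less obvious role: a length-1 segment's
likelihood improves on its surroundings by roughly
$\tfrac12\log(\hat\sigma^2/\sigma_{\min}^2)$, so the floor sets the
"bonus" that degenerate segments earn in the penalized optimization. With
the default (tiny) floor this bonus is large, which means the first
candidate sets proposed on structureless noise are degenerate carvings —
boundary singletons and short runs of length-1 segments — rather than the
best interior mean split. That matters for error control: the bonus
appears identically in the observed statistic and in its bootstrap null,
so tests of such sets are close to honest, whereas the null of the *best
interior split* is anti-conservative (the observed statistic is maximized
over positions, the null is evaluated at fixed positions — the price of
not re-running detection on every draw). Raising the floor to the noise
scale was evaluated during development and rejected: it exposes exactly
that maximized-split comparison on noise and the false-positive rate
deteriorates sharply.

The flip side, a real limitation, is that a *single-point* shift of
moderate size (about $5\sigma$) produces a per-changepoint gain comparable
to the degenerate-segment bonus itself, so the fixed-sequence walk usually
meets (and stops on) an insignificant noise carving before reaching the
solution that isolates the true one-point segment. Single-point shifts
need to be substantially larger than $5\sigma$ to be recovered reliably;
multi-point shifts of $5\sigma$ are recovered with ease. The companion
acceptance script measures both behaviors.

## Stage 2: trimming changepoints inside trends

A changepoint that lives inside a linear or seasonal trend is "nuisance":
the trend, not the device, explains it. For a changepoint at $j$, two
fits are compared:

* *piecewise*: the best of {linear, harmonic} on the left segment and,
  independently, on the right segment (per-side SSE minimization also
  minimizes the pooled value below);
* *cross-segment*: the best of {linear, harmonic} on the merged segment,
  ignoring $j$.

All regressions use the global 1-based index as the regressor, so phase
and slope line up across segments. The harmonic model is an intercept plus
one sine/cosine pair at a period estimated from the peak of the raw
periodogram of the mean-centered segment (no taper, no detrending). The
periodogram is evaluated on a frequency grid oversampled eightfold by
zero-padding, restricted to $[1/n, 1/2]$ so the period fits inside the
segment. Oversampling is load-bearing: on the plain Fourier grid $k/n$, a
merged segment holding a non-integer number of seasonal cycles (72 points
of a period-50 cycle, say) estimates a badly wrong period, the
cross-segment harmonic fit collapses, and trimming stalls with seasonal
interiors still in the set. Periods are always re-estimated on the merged
segment; a feasible period must exceed 2 (the Nyquist limit) and needs at
least 4 points and non-degenerate variance.

The trim statistic is the ratio of cross-segment RMSE to pooled piecewise
RMSE $\sqrt{(SSE_L + SSE_R)/(n_L + n_R)}$, with exact fits defining
RMSE 0 and the conventions $0/0 \to 1$ and $x/0 \to \infty$. Since the
merged model restricted to either side is feasible for that side's fit,
the ratio is always $\ge 1$ under pooling. Greedily, the smallest ratio
below the trimming threshold (default 1.2, i.e. a cross fit within 20% of
the piecewise fit) is removed — ties broken at the smallest position —
and ratios are recomputed; only segments adjacent to a merge change, so
unaffected ratios are cached (provably identical to full recomputation,
and tested). The loop stops when no ratio is below the threshold.

Pooling dilutes the evidence of a very short segment against a long
neighbor: a one-point $5\sigma$ spike next to a 100-point segment yields a
ratio near $\sqrt{1 + 25/100} \approx 1.12$, below the default threshold.
This is the second reason single-point shifts of that size are not
retained; retention at threshold 1.2 requires roughly a $6.6\sigma$
one-point spike against 100-point neighbors. The $\infty$ convention
protects such shifts only while one side remains exactly fit.

## Segment correction

After selection, each induced segment gets the best of
{constant, linear, feasible harmonic}: the non-constant fit is adopted
only if the constant fit's RMSE exceeds the best non-constant RMSE by more
than the fitting threshold (default 1.75). Trended/seasonal segments are
replaced by their residuals plus the original segment mean, so "location"
remains the pre-correction mean. Every segment is then mapped onto a
chosen reference segment,

$$z = \frac{v - \mathrm{loc}_s}{\mathrm{scale}_s}\,
      \mathrm{scale}_{\mathrm{ref}} + \mathrm{loc}_{\mathrm{ref}},$$

with location the pre-correction segment mean and scale the residual
standard error $\sqrt{SSE/(n-p)}$ of the chosen model ($p = 1, 2, 3$).
The degrees-of-freedom divisor here (vs the MLE divisor in detection) is
deliberate: "residual standard error" is the conventional regression
quantity, and the correction is a regression adjustment, not a likelihood.
The reference segment passes through the same formula (a near-identity for
itself, exact when its model is constant). Segments with $n \le p$ or with
degenerate scale are shifted but not rescaled, with a warning. The same
definitions are applied to every segment, which is the only reading that
makes the transform well-defined for non-reference segments.

## The synthetic benchmark

`generate_benchmark()` builds an 800-point series: Gaussian noise
($\sigma = 1$) around a skeleton with $\pm 5\sigma$ mean shifts at
positions 49, 60, 600, 699 and 700 (the segment {700} is a single point),
a linear ramp rising $8\sigma$ across indices 201–400, and a period-50
sinusoid of amplitude $3\sigma$ across 401–600. The shift positions and
trend intervals are the benchmark's; the effect sizes are this package's
defaults, chosen once so that multi-point structure is recovered
unambiguously at desk scale. The ramp leaves the baseline at slope
$0.04\sigma$/point, so its detected onset naturally lags the nominal start
by a couple dozen points — matching how such a shallow onset behaves in
practice. `generate_noise()` provides the i.i.d. null fixture.

What the generator does *not* emulate: missing days, varying cohort size
(and hence heteroskedastic medians), non-Gaussian tails, multiple
overlapping trends. Passing tests on these fixtures demonstrates the
machinery, not robustness to those real-data features.

## Scale of the shipped checks

The test-suite and acceptance-script problem sizes are chosen for a
desk-scale run: Monte-Carlo tests use $N$ between 499 and 1999 (one
reference run at the default $N = 10000$), false-positive control uses 50
noise series of length 200, recovery uses 10 fixture seeds, and the
exactness oracle enumerates all segmentations of 100 series of length at
most 12. The method itself is $O(K\,n)$ per PELT sweep entry and
$O(N\,n)$ per significance test.

## Known limitations

* P-values are approximate: because detection is not re-run on null
  draws, a comparison whose observed set was *chosen* by the optimizer on
  the observed data is anti-conservative. On pure noise a minority of
  runs therefore select changepoints (subsequent trimming removes most of
  them); the acceptance script measures the stage-1 rate directly.
* Single-point shifts of moderate size are not reliably recovered, for
  the two structural reasons above.
* One harmonic only: sharp or multi-frequency seasonality is approximated
  by its dominant frequency.
* Variance-change-only changepoints are detectable in principle (the cost
  has a variance term) but trimming and correction reason about means and
  trends.
* The series must be complete and regular; missing values are a hard
  error by design, since silent imputation would distort both the
  likelihood and the periodogram.
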