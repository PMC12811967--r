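---
title: "Growth-curve modeling from cortical growth mark series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve modeling from cortical growth mark series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmgrowth)
```

## The estimation problem

Skeletochronology reads a bone's cortical growth marks (CGM) — lines of
arrested growth and annuli laid down during annual pauses in periosteal
apposition — as a longitudinal record: the circumference of the $i$-th mark
is the diaphyseal size of the animal in year $i$ of its preserved record.
Two censoring mechanisms spoil the record. Medullary expansion erases an
unknown number of inner (earliest) marks, so a specimen's first preserved
mark sits at an unknown age; and death truncates the record at the outer
cortex. A single specimen therefore carries only a window of the growth
trajectory, and a population-level curve must be assembled from several
specimens whose windows overlap in size but are unregistered in age.

The package models the pooled data
$\{(\mathrm{cgmc}_{ij},\,\mathrm{circ}_{ij})\}$, $j = 1,\dots,M$ series,
with a shared sigmoid $f(a, b, c; t)$ and per-series nuisance start ages
$s_j$:

$$\mathrm{OLS}(a,b,c,s) \;=\; \sum_{j=1}^{M}\sum_{i=1}^{N_j}
 \bigl(f(a,b,c;\ \mathrm{cgmc}_{ij} + s_j) - \mathrm{circ}_{ij}\bigr)^2 ,$$

minimized *jointly* over the curve parameters and the starts
(`joint_fit()`). The reference series — the one containing the smallest
measured circumference — has its start pinned to 0, which fixes the
translation freedom of the age axis; all reported ages are relative to that
specimen's first preserved mark. Starts are continuous by default
(an integer-rounding mode exists but is off): there is no reason the
first preserved mark of one specimen should align to whole years of
another's. The conventional two-step estimator (register first, then fit
with frozen starts) is available via `freeze_starts = TRUE`; the joint
optimum can only match or improve on it, which the test suite checks.

## Candidate curves

`model_registry()` provides nine sigmoids in location–scale CDF form
$a\,F\!\bigl((t-b)/c\bigr)$ — logistic, Gompertz (Gumbel-max kernel),
extreme-value (Gumbel-min), arctangent, Laplace, Gaussian, hyperbolic
tangent, monomolecular (von Bertalanffy), and a two-parameter
monomolecular with $b = 0$ — plus linear and quadratic diagnostics and an
optional four-parameter Richards form. In every sigmoid, $a$ is the
asymptotic circumference (mm), $b$ a location (years) and $c$ a scale
(years). The exact algebraic families behind historically used curve
names vary across the literature; the registry fixes these canonical CDF
forms and treats the names as configuration, and custom models can be
registered from an (evaluate, derivative, asymptote) triple. Richards is
flagged `fragile`: it contains several of the others as limits, but its
exponent interacts badly with local least squares and it is excluded from
the default selection set.

Model selection is by AICc with the least-squares Gaussian convention:
$\widehat{L}$ is the likelihood at plug-in variance $\mathrm{rss}/n$
(constants included) and the variance is *not* counted in $k$, so
$k = p + (M-1)$ for a $p$-parameter sigmoid. This is the only convention
consistent with a 20.1-point penalty difference between $k=12$ and $k=3$
at $n = 152$ together with $-2\ln\widehat{L}$ magnitudes near 1,300 for
residual sums of squares in the tens of thousands of mm². AICc values
from log-scale fits (circumferences natural-log transformed before
fitting) are on the log-data likelihood and are never compared with
arithmetic-scale values.

## Start-age initialization

Joint optimization needs a sensible starting point. `cluster_starts()`
projects every measured point of each series onto every series whose
circumference range overlaps it (piecewise-linear interpolation of age as
a function of circumference) and minimizes the summed squared *age*
residuals. Because starts shift series only horizontally, these residuals
are linear in the starts and the minimizer is a closed-form linear
least-squares solution — no grid search, no iteration. Two declared
choices: residuals are measured on the age axis (the direction in which
the decision variables act), and both directions of every overlapping
pair contribute, making the objective symmetric in series order. The
procedure is defined only when the overlap graph is connected; a
disconnected graph is an error naming the isolated components, because no
data tie those series to a common age axis.

## Simultaneous confidence bands

Uncertainty is summarized by a 95% *simultaneous* band: a region
containing the entire true curve with the stated probability, which is
the right object when inference concerns the trajectory rather than a
pointwise value. The package uses a fractional-random-weight (FRW)
bootstrap: each resample draws independent unit-mean exponential weights
on the squared residuals and refits the joint model from the base
solution. FRW resampling avoids the data loss of case resampling in small
samples (dropping a whole series can disconnect the overlap graph); a
case-resampling mode is retained behind a flag for sensitivity analysis.
The weight stream attaches to observations in a canonical order
(circumference, then count), making the band invariant to series ordering
and uid relabeling.

The band itself is the max-deviation construction: with pointwise
bootstrap spread $s(t)$ (standard deviation across refitted curves), find
the smallest $q$ such that a fraction $\ge 0.95$ of bootstrap curves
satisfies $|\hat f_b(t) - \hat f(t)| \le q\,s(t)$ at *every* grid age,
and report $\hat f \pm q\,s$. Whether a published simultaneous band of
this kind is best ± q·s or a direct envelope is generally ambiguous; the
construction used here is declared in the band's JSON metadata. The grid
is 512 equally spaced ages over the pooled relative-age extent of the
fitted points; the band *length* is that extent, *area* is the trapezoid
integral of the width, and area/length is the headline compatibility
metric (area alone rewards shorter datasets). Default resamples
$B = 2048$; the test suite runs $B = 64$–256 with correspondingly widened
tolerances, and the simulated whole-curve coverage check uses 50
replicates at $B = 256$.

## Dataset variants

Each series carries per-mark annotations: `xpl_only` (annuli visible only
under cross-polarized light) and `multiplet_group` (labels tying together
tightly spaced mark runs). Four readings of the same sections are then
derived mechanically (`derive_variant()`): variant A counts every mark as
one annual hiatus; NoX drops XPL-only marks; NoM collapses each multiplet
group to a single mark; NoXM applies both. Two declared rules close gaps
the histological definitions leave open:

* **Collapse keeps the outermost member.** A multiplet group records one
  hiatus event whose final periosteal position is its outermost line, so
  the member with the largest circumference (equivalently, largest count)
  represents the group. Innermost or averaged alternatives would be
  defensible; the choice is fixed and documented rather than configurable.
* **The collapse ignores XPL-flagged members.** A mark that is both
  XPL-only and inside a multiplet group is governed by the X rule alone.
  This keeps the dropped-by-X and dropped-by-M sets disjoint, so the set
  identities A = NoM ∪ NoX and NoXM = NoM ∩ NoX hold exactly on record
  uids — `variant_family()` verifies them on every construction.

Dropped marks do not count as years: each retained mark's count is
decremented by the number of dropped marks beneath it, which preserves
genuine counted-but-unmeasured gaps while removing dropped years from the
age axis. Record uids survive derivation, which is what makes
*same-points* comparisons across variants well defined.

## Comparing variants fairly

Overall AICc cannot rank fits made to different point sets — the variant
with the fewest points wins on residual sum alone. `same_points_aicc()`
therefore re-scores an existing fit (its own parameters and starts, no
refitting) on exactly the points shared with another variant, with $n$
set to the subset size. `dominance_check()` then evaluates the full
condition set under which the all-marks reading is preferred: best on the
NoXM-shared points with the remaining variants ordered NoM < NoX < NoXM,
and best on the NoM- and NoX-shared subsets too.

`mc_null_test()` calibrates those conditions against the null that the
flagged marks are extraneous. Each trial manufactures fictitious marks:
allocated across series in proportion to the observed per-series flag
counts, each placed in a uniformly chosen inter-mark interval with a
circumference uniform between the bounding measured circumferences, and
shifting subsequent counts by one year. A fictitious multiplet member
shares a group with the real mark bounding its interval, so the NoM
collapse retains the real mark. The interval-insertion scheme is a
declared construction (uniform placement "within the range" of the
unflagged points admits several readings); it keeps every augmented
series monotone by construction and is recorded in output metadata. Per
trial, all four variants are rebuilt, refitted (by default with the
variant-selected family from the real data; full per-trial selection is a
flag) and the dominance conditions evaluated; the p-value is the fraction
of trials meeting all of them.

## Compatibility screening

`leave_one_out()` removes one candidate at a time — by default all
elements of a specimen jointly, since a femur and tibia of one individual
stand or fall together — and tabulates band area/length per variant plus
the row total; the minimizing removal is the least compatible member.
Screening iterates: a second round excludes the first round's removal.
Removals that disconnect the overlap graph are marked unusable, never
silently dropped. `linear_probe()` asks the complementary question:
what constant growth rate *would* be compatible? It appends idealized
flag-free linear series of varying slope and finds the slopes minimizing
band area and area/length. `mean_slope()` (OLS slope of circumference on
count) locates real series against that optimum.

## Mass conversion and growth-rate metrics

Circumference converts to body mass through the bipedal stylopodial
power law $\log_{10} m(\mathrm{g}) = 2.754\,\log_{10} C(\mathrm{mm}) -
0.683$. The coefficients were back-calibrated by log-log regression on
published circumference–mass pairs (`mass_calibration_pairs()`,
`calibrate_mass_conversion()`), and the fixed form is required to
reproduce every pair within 0.5%. Because the transform is convex and
increasing, it moves the inflection (maximum-rate age) later: the
mass-rate peak of a fitted curve falls after the circumference-rate peak.
`max_growth_rate()` reports four metrics — absolute circumference and
mass rates, and their percentage counterparts — maximized over a window
floored at the first-CGM relative age; percentage rates of sigmoids are
decreasing there, so their maxima sit on that boundary and are reported
at it, as is the monomolecular family's absolute-rate maximum. The
inflection search uses a 2,048-point grid refined by golden-section,
robust for boundary-maximum models. `maturity_threshold()` computes the
theoretical $W^{0.3}$ maturity mass so that its implausibly small
predictions can be exhibited directly rather than taken on authority.

## The synthetic generator

`generate_cgm_dataset()` produces datasets with exactly the structure the
estimators assume, plus ground truth for recovery tests: a shared sigmoid;
one mark per year; Poisson-distributed erasure of inner marks (the true
start-age offsets); truncation at a uniform integer death age; bad-year
runs (entered with a per-year probability, lasting 2–4 years, increments
scaled by a factor ≤ 0.25) whose marks share a multiplet-group label;
independent faint-mark (XPL) flags; additive Gaussian noise; optional
linear outlier specimens. Two generative worlds are switchable: in
`"annual"` each bad-year mark is a real year (the A reading is true),
while in `"single_year"` a run's marks all form within one calendar year
(the NoM reading is true), letting the dominance machinery be validated
in both directions.

One numerical choice deserves emphasis. Adding Gaussian noise to a
monotone truth can violate monotonicity, and the repair matters: a
running maximum biases late-age sizes upward (where true increments are
near zero, the running max of noise drifts up), which in early testing
depressed whole-curve band coverage badly. The generator instead projects
noisy values onto the monotone cone by least-squares isotonic regression
— the maximum-likelihood monotone repair under Gaussian noise — which
removes the systematic bias.

What the generator does *not* emulate: histological realism (mark
visibility, remodeling, sectioning error structure), heteroskedastic or
autocorrelated measurement error, element-specific scaling between femora
and tibiae, and individual-level deviation from the shared curve beyond
the bad-year mechanism. Passing recovery and coverage tests therefore
demonstrates that the estimators are correct under their own assumptions,
not that those assumptions hold for any particular fossil dataset.

## Numerical choices

* Optimizer: Levenberg–Marquardt on the residual vector
  (`minpack.lm::nls.lm`), relative tolerances $10^{-12}$, up to 500
  iterations; 1 + 8 jittered restarts (starts ± 2 yr uniform, parameters
  ± 10% log-uniform) fixed by the seed. Bootstrap refits restart from the
  base solution with no jitter, keeping resamples in the same basin.
* Initial sigmoid parameters from the clustered composite: $a_0 = 1.05
  \max(\mathrm{circ})$, $b_0$ the median age, $c_0$ a quarter of the age
  range (monomolecular forms use their own heuristics).
* Non-finite residuals during optimization are replaced by a large
  constant ($10^6$), which steers the optimizer away from degenerate
  parameter regions rather than aborting.
* Degenerate spread: if the bootstrap curves collapse onto the base curve
  (noise-free data) the band has zero width by construction; a collapsed
  spread with non-collapsed curves is an error.
* Counted-unmeasured records contribute to age numbering only, never to
  objectives or point counts.
* Problem sizes in the test suite were chosen to exercise the estimators
  at realistic scale while keeping the suite quick: recovery replicates
  use 8–9 specimens (~130–150 measured marks), coverage runs 50
  replicates at $B=256$, screening runs 20 replicates at $B=64$.

## Known limitations

* Absolute ages are unknowable from these data: every age is relative to
  the reference specimen's first preserved mark, and any marks it lost to
  medullary expansion shift the whole axis. The package deliberately
  provides no neonate-extrapolation route.
* The clustering initializer weights series pairs by their overlap size;
  heavily overlapping pairs dominate the initial registration. The joint
  fit's restarts are the guard against a poor basin.
* Richards fits are offered but not trusted by default.
* Same-points AICc compares fits made to nested readings of the *same*
  sections; it says nothing about datasets that differ in specimens.
* The Monte Carlo null fixes the fitted model family per variant by
  default; enabling full per-trial selection is slower and can only make
  the null more permissive.
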