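---
title: "Hydraulic trait derivation and variance partitioning in tree provenance trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic trait derivation and variance partitioning in tree provenance trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provtraits)
```

## The scientific problem

Common-garden provenance trials grow seed sources ("provenances") from
contrasting climates side by side under one environment. Any systematic
trait difference that survives this transplantation reflects genetic
differentiation rather than plasticity. `provtraits` implements the
quantitative machinery such a trial needs for branch hydraulic traits in a
broadleaf tree such as European beech:

1. derive wood-anatomical and hydraulic traits from vessel-level
   measurements,
2. fit xylem vulnerability curves and extract cavitation thresholds,
3. compute growth allometry and climate-of-origin aridity indices,
4. partition each trait's variance into inter-provenance, block and
   residual components with restricted maximum likelihood (REML), testing
   provenance differentiation with a boundary-corrected likelihood-ratio
   test.

A seeded simulator generates complete virtual trials from the same additive
model the statistics assume, so every stage is testable without field data.

## Trait derivation

### Vessel anatomy and theoretical conductivity

Vessel lumina are digitised as ellipses with major radius $a$ and minor
radius $b$ (µm). The idealized diameter of the hydraulically equivalent
circular conduit is

$$D = \left(\frac{32\,(ab)^3}{a^2 + b^2}\right)^{1/4},$$

which reduces to $2a$ for circles and decreases as the lumen flattens at
constant size. From the diameter population of one cross-section the
package derives vessel density (n mm⁻²), the lumen-to-sapwood area ratio
(%), the hydraulically weighted diameter $D_h = \sum D^5 / \sum D^4$ — the
diameter at which vessels contribute in proportion to their conductance —
and the theoretical sapwood-area-specific conductivity from the
Hagen–Poiseuille law

$$K_{S,\mathrm{theo}} = \frac{\pi \sum D^4}{128\,\eta}\,
\frac{\rho}{A_\mathrm{xylem}},$$

with water viscosity $\eta = 1.002\times10^{-9}$ MPa s and density
$\rho = 998.2$ kg m⁻³ at 20 °C. Radii are stored in µm and areas in mm²
(the units of routine anatomy reporting); conversion to SI happens only
inside the conductivity computation, keeping the law dimensionally exact.
Dividing the same numerator by distal leaf area instead gives the
leaf-specific variant $K_{L,\mathrm{theo}}$.

Two conventions were genuinely open. First, the lumen area of a vessel can
be taken as $\pi (D/2)^2$ from the idealized diameter or as the ellipse
area $\pi a b$; the idealized-circle form is the default because the
derived traits are all defined through $D$, and the ellipse form remains
available via `lumen_area = "ellipse"`. Second, digitisation tools do not
guarantee axis order, so `a < b` inputs are swapped with a warning rather
than rejected. Sapwood area, where not delineated directly, comes from the
branch-level regression $A_\mathrm{xylem} = -3.715 + 0.770\,A_\mathrm{cross}$,
which is only valid above its positivity root (≈ 4.825 mm²); inputs at or
below it are an error, not a silent zero.

### Vulnerability curves

Percent loss of conductivity follows the two-parameter sigmoid

$$\mathrm{PLC} = \frac{100}{1 + \exp\!\big(\tfrac{s}{25}(P - P_{50})\big)},$$

where $P_{50}$ (MPa, negative = tension) is the pressure at half loss and
$s$ (% MPa⁻¹) the slope at the inflexion. `fit_vulnerability_curve()`
minimises raw least squares on the PLC scale (points at exactly 0 or 100
retained, unweighted) with multi-start initialisation: $P_{50}$ starts at
the measured pressure nearest 50% loss, $s$ at the central
finite-difference slope rescaled by the inflexion-point derivative, both
perturbed over a coarse grid, with Nelder–Mead search and a BFGS polish.
$P_{12}$ and $P_{88}$ come from the analytic inverse
$P = P_{50} + (25/s)\ln((100-t)/t)$, so
$|P_{50}-P_{12}| = |P_{88}-P_{50}|$ exactly under this model. Quality
control mirrors measurement practice: a fit passes only if the series
spans PLC below 30 and above 70 and reaches at least 90% loss (the
stopping rule of the centrifuge protocol); thresholds are arguments, the
defaults are those values. Degenerate series (constant PLC, too few
points) return a flagged, non-converged fit rather than an exception.
Pressures are stored as negative MPa; data recorded as positive tensions
must be declared via `tension_positive = TRUE`.

### Growth and climate indices

Stem volume uses a breast-height cylinder times an empirical beech form
factor; the form factor's printed small-diameter term behaves as
$-118.188/D^3$, so the function refuses inputs it would drive non-positive
and `growth_increments()` reports volume only for stems of timber
dimension (≥ 7 cm DBH). The quadratic term's coefficient is taken as
$4.2\times10^{-6}$: the alternative reading $4.2\times10^{6}$ would give
form factors of order $10^8$, while $10^{-6}$ reproduces realistic beech
values near 0.5. Aboveground biomass is the power law
$0.00523\,D^{2.12}H^{0.655}$ (kg). ABI divides final biomass by the time
since planting (default 19 years, sapling biomass neglected); BAI differs
two inventories' basal areas over exact day counts / 365.25 and uses
endpoint surveys only.

Climate of origin is summarised per provenance as MAT, MAP, April–June
precipitation (MSP), Ellenberg's quotient
$EQ = 1000\,T_{Jul}/P_{annual}$, and the forest aridity index

$$\mathrm{FAI} = \frac{100\,T_{Jul\text{–}Aug}}
{P_{May\text{–}Jul} + P_{Jul\text{–}Aug}},$$

in which July precipitation enters twice, reflecting peak evaporative
demand. The interval temperature is the July–August mean by default
(sums would break the index's published scale of roughly 2–9 across
European beech origins); a July-only switch exists because the original
definition is ambiguous on this point. The global aridity index is a
database product: it is echoed through from the input, never computed.

## The statistical core

Each trait is modelled as

$$Y_{ijk} = \mu + P_i + b_j + \varepsilon_{ijk},$$

with crossed random intercepts for provenance ($\sigma^2_\mathrm{inter}$)
and block ($\sigma^2_\mathrm{block}$) and residual
$\sigma^2_\mathrm{intra}$ — crossed, not nested, because every provenance
is replicated in every block. The restricted likelihood is evaluated
through the Woodbury identity and the matrix determinant lemma on the
low-rank-plus-diagonal covariance, so an evaluation costs
$O(n q^2)$ with $q$ the number of grouping levels; the implementation is
verified against an explicit dense-covariance computation in the tests.

Optimisation runs on the log-variance scale, and every zero-variance
boundary face (either or both grouping variances pinned at 0) is evaluated
explicitly. This matters: in trait tables of this kind many components are
estimated at exactly zero, and log-scale optimisation alone would only
approach the boundary asymptotically. When the interior search and a
boundary face tie in likelihood the face wins, giving exact zeros.

Provenance differentiation is tested by an LRT against the model without
the provenance component. Under the null the parameter lies on the
boundary, so the statistic follows the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ and the $\chi^2_1$ tail probability
is halved; at $LR = 0$ the corrected p-value is exactly 0.5, its maximum.
The AIC difference is reported as $\Delta_i = LR - 2$ (one extra
parameter), defined unambiguously with this sign throughout.

Descriptive variability is reported as `cv_inter` (SD of provenance means
over the grand mean) and `cv_intra`; since "within-provenance CV" admits
two natural readings, the default is the mean of per-provenance SDs over
the grand mean, with the pooled-within-SD variant as an option. Variance
components are also expressed as percentages summing to 100.

Climate sensitivity adds the origin's FAI as a fixed effect,
$Y_{ijk} = \alpha + \beta\,\mathrm{FAI}_i + P_i + b_j + \varepsilon_{ijk}$,
fitted and tested by maximum likelihood (the LRT compares models differing
in a fixed effect, where REML likelihoods are not comparable).
Right-skewed ratio traits — the leaf-specific conductivities and the Huber
value — are natural-log transformed before fitting; the set is an
argument. Missing trait values are dropped per trait (complete-case within
column), so each trait reports its own $n$.

Trait inter-relationships use pairwise-complete Pearson correlations with
two-sided t-tests, at tree level or between provenance means. Tree-level
correlations on pooled data mix variance sources and inflate degrees of
freedom; the result object carries this caveat explicitly. No
multiple-testing correction is applied by default (matching exploratory
reporting practice); a Holm option exists.

## The simulator and what it does (not) show

`simulate_trial()` draws trait values exactly under the additive
random-effects model above — the generator and the estimator share the
model by construction, which is what makes exact recovery and calibration
checks meaningful. The default design is balanced 10 provenances × 3
blocks × 4 trees; real trials allocate unevenly, but the balanced default
enables the closed-form expected-mean-squares oracle used in testing, and
the allocation is a parameter. Default trait scales are those of a
two-decade beech common garden (DBH ≈ 13 cm, branch $P_{50}$ ≈ −3 MPa,
vessel diameters ≈ 24 µm, foliar chemistry at typical beech values), and
the climate generator spans MAT 3.4–15.3 °C and MAP 575–1080 mm, the range
of European beech seed origins.

Vessel diameters are lognormal (strictly positive, right-skewed like real
xylem); PLC noise is additive Gaussian truncated to [0, 100], the simplest
error model consistent with bounded measurements; monthly climate is a
sinusoid plus noise rescaled to hit annual targets exactly. Every
generator takes a mandatory seed and is bit-reproducible.

What passing tests on these synthetic data do *not* show: robustness to
non-Gaussian trait distributions, unbalanced allocation, spatial
autocorrelation within blocks, open-vessel artefacts in vulnerability
curves, or measurement error in the anatomical inputs. The simulator
emulates the design and the assumed error model, not those complications.

## Worked example

```{r example, eval = FALSE}
res <- run_full_analysis("trial-output", seed = 7)
head(res$varcomp[, c("trait", "vc_inter", "vc_block", "vc_intra",
                     "lr", "p_corrected")])
```

`run_full_analysis()` simulates the full trial, derives all traits, fits
every vulnerability curve, partitions variance per trait and writes all
stage outputs plus a JSON manifest (seed, row counts, file checksums);
rerunning with the same seed reproduces every file byte-identically. This
package is used from R, so the pipeline surface is this function plus the
per-stage exported functions rather than a shell executable.

## Problem sizes and numerical choices

The validation suite works at deliberately modest sizes chosen as adequate
for their purpose: dense-oracle comparisons at ≤ 30 observations
(tolerance 10⁻⁸ on the log-likelihood), P50 recovery over 200 simulated
curves (17-point ramp, noise SD 3 PLC), and null calibration of the
boundary-corrected LRT over 500 replicates of the default 120-tree design.
Vulnerability fits treat non-convergence as data (flagged fits), never as
an exception; likelihood evaluations that encounter a singular system
return a guard value so the optimiser retreats rather than aborts.

## Known limitations

- The variance engine covers exactly two crossed random intercepts;
  deeper or nested structures are out of scope.
- The halved-p boundary correction is asymptotic; with only ten provenance
  levels it is approximate (its finite-sample calibration is itself
  checked by simulation in the tests).
- Only the logistic vulnerability-curve family is implemented; Weibull or
  exponential alternatives are not.
- The published provenance-level tables bundled in `inst/extdata` are
  summaries; the underlying tree-level field data were never deposited, so
  table-level reproduction, worked-ratio examples and property-based
  validation are the attainable checks.
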