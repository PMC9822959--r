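---
title: "Diagnosing regime shifts in exploited fish stocks with fishshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing regime shifts in exploited fish stocks with fishshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishshift)
```

## The problem

A heavily fished stock can cross a tipping point: spawning stock biomass
(SSB) drops abruptly to a depleted quasi-stable state and fails to recover
even when fishing mortality (F) is cut back to, or below, the level that
once sustained a healthy stock. `fishshift` screens an annual assessment
series — SSB (tonnes), recruitment (R, thousands at a stated age) and F
(per year), in the layout of the ICES Stock Assessment Database extracts —
for three statistical signatures of such regime-shift dynamics, plus an
optional sea-surface-temperature (SST) flag. The flags never gate one
another; each is computed on every run and reported with its evidence.

All data enter through `read_stock_csv()` / `read_sst_csv()` or the
constructors `stock_series()` / `env_series()` / `srr_data()`. Missing
values stay as explicit `NA`s and are excluded pairwise per analysis, never
imputed, and units are taken as given in the file. Recruitment reported at
age *a* in assessment year *y* is attributed to spawn year *y − a*
(`align_srr()`), so stock–recruitment pairs relate recruitment to the
parent biomass that produced it.

## Flag 1 — abrupt shifts in SSB

Two detectors run independently on the SSB series.

**Bayesian product-partition sampler** (`bcp_posterior()`). The series is a
sequence of constant-mean blocks; each interior boundary carries a change
indicator with uniform prior on $(0, p_0)$ for the boundary probability and
$(0, w_0)$ for the signal-to-noise ratio $w$ (defaults $p_0 = w_0 = 0.2$).
A Gibbs sweep resamples every indicator from its full conditional — the
marginal odds integrate the block means and the two hyperparameters, the
$w$-integral evaluated by 24-node Gauss–Legendre quadrature in log space —
and the posterior change probability of a year is the fraction of
post-burn-in sweeps in which its boundary was active (defaults: 5000
sweeps, 500 burn-in, candidates declared at posterior ≥ 0.5). The sweep is
implemented in C++ and is deterministic given a seed.

**Binary segmentation** (`binseg_changepoints()`). Greedy recursive
splitting for changes in mean under a Gaussian cost: a split is accepted
when its likelihood-ratio gain $(\mathrm{RSS}_{parent} -
\mathrm{RSS}_{left} - \mathrm{RSS}_{right})/\hat\sigma^2$ exceeds an
MBIC-style penalty ($3\log n$ by default), both children have at least
`min_segment` = 5 observations, and at most five changes are sought. The
noise scale $\hat\sigma^2$ is estimated robustly from the median absolute
deviation of first differences, so the steps themselves do not inflate it —
re-estimating the variance per proposed segment instead would leave any
remaining step inside a child segment masking further splits. The gain is
invariant to shifting or positively rescaling the series.

**Consensus** (`consensus_changepoints()`). A change year is retained when
the two methods agree within ±1 year (the deterministic binseg year is
reported); matching is greedy and one-to-one in year order, unmatched
candidates are discarded, and of two consensus years closer than five years
the one with the higher Bayesian posterior survives. The surviving years
tile the observed range into quasi-stable periods of at least five years.
Both raw candidate lists are always exposed, since a method can detect
changes the consensus discards.

## Flag 2 — hysteresis in the F → SSB relationship

Because fishing does not depress biomass instantaneously,
`select_lag()` first picks the lag $n$ of $F_{t-n}$ against $\mathrm{SSB}_t$
with the maximal absolute cross-correlation (searched over 0–10 years, ties
to the smaller lag). `baiperron_breakpoints()` then fits piecewise linear
regressions of SSB on lagged F in temporal order: an exact dynamic program
minimises the total RSS for every break count $m$ up to 3, and BIC selects
$m$ (pure RSS cannot select $m$, being non-increasing in it); segments with
a degenerate predictor fall back to intercept-only fits and are flagged.
The minimum segment is 15% of the observations and never fewer than three.

`classify_hysteresis()` makes the visual "loop" diagnosis explicit. The
trajectory is split at the year of maximum (3-year smoothed) F into an
ascending-pressure and a descending-pressure branch; over the F range both
branches visit, SSB is compared inside five equal-width F bins. A loop
requires *both* a significant paired test across the matched bins (α =
0.05) *and* a branch gap of at least 25% of the observed SSB range. The gap
guard is a practical-significance requirement calibrated on reversible
(no-depensation) simulations: across the calibration runs their transient
branch gaps never exceeded ≈18% of the SSB range, while genuine fold-
bifurcation loops never fell below ≈36%, so 25% separates the two regimes
with margin on both sides. A significant loop is *closed* when the final
five years' mean SSB re-enters the pre-collapse range, and *open* when it
stays below the pre-collapse minimum although final F is at or below the
level that previously sustained that biomass; the pre-collapse period ends
when SSB first fell under half of its running maximum.

One subtlety is deliberate: the cross-correlation lag is by construction
the shift that makes SSB most nearly a single-valued function of F, so it
can "shear" a genuine loop flat. With `lag = NULL` the classifier therefore
assesses both the selected lag and lag 0 and reports whichever shows the
larger absolute branch gap. When the true pressure-response lag is known —
as in simulations — passing it explicitly is preferable.

## Flag 3 — non-stationary stock–recruitment relationships

`loocv_compare()` competes six candidates on the spawn-year pairs:

* Beverton–Holt $R = \alpha S / (1 + \beta S)$, fitted by nonlinear least
  squares on $\log R$ (multiplicative lognormal error, the fisheries
  standard; the comparison RMSE is always computed on the raw scale so all
  models stay commensurate), started from the OLS linearisation
  $1/R = (1/\alpha)(1/S) + \beta/\alpha$ with a restart grid;
* Ricker $R = S e^{\alpha - \beta S}$, the exact OLS solution of
  $\log(R/S) = \alpha - \beta S$;
* linear and log-log linear OLS;
* a one-breakpoint segmented GLM via Muggeo's iterative linearisation,
  started at mean SSB, with the slope-difference Wald test deciding whether
  the break is supported ("no supported break" is flagged at p ≥ 0.05);
* a breakpoint regression over spawn years (the structural-break dynamic
  program with recruitment on SSB), whose periods each get their own linear
  SRR.

Every candidate is refitted on each leave-one-out subset; the winner is the
candidate with the lowest *training* RMSE, the package's stated selection
rule, with test RMSE always reported beside it. Because the discontinuous
candidates are the most flexible, they win that rule almost tautologically
on noisy data; the non-stationarity flag of the pipeline therefore fires
only when the discontinuous winner's break is itself supported (significant
slope change, or at least one BIC-selected break). `choose_glm_family()`
maps the qualitative notion of residual over/underdispersion onto explicit
Pearson-dispersion bands (Poisson within [0.8, 1.2], quasi-Poisson up to 5,
negative binomial beyond; Gaussian when recruitment has been rescaled away
from count magnitudes).

## Flag 4 — the temperature threshold GAM

`fit_pspline_gam()` implements the smoother underneath: a B-spline basis of
dimension $k$ on equally spaced knots (cubic for $k \ge 4$; at $k = 3$ the
degree drops to quadratic, since no cubic basis of dimension 3 exists) with
a second-difference coefficient penalty, the smoothing parameter chosen by
minimising $\mathrm{GCV} = n\,\mathrm{RSS}/(n - \mathrm{tr})^2$ over a
log-spaced grid. The penalty's null space is the linear functions, so the
smooth tends to the OLS line as $\lambda \to \infty$; GCV ties resolve to
the smoothest fit. Effective degrees of freedom are reported excluding the
intercept, so edf = 1 is a linear relationship, edf in (1, 2] weakly
non-linear, edf > 2 strongly non-linear.

`fit_threshold_gam()` searches 20 evenly spaced candidate SST thresholds
between the 0.2 and 0.8 SST quantiles. For each candidate the observations
split into an SST-below and an SST-above regime, and recruitment is
modelled by a separate penalized smooth of SSB (k = 4) per regime — each
regime's block spans its own level, mirroring how indicator-`by` smooths
behave in the standard GAM machinery — with the two smoothing parameters
minimising the overall GCV. Candidates leaving a regime with fewer than
five observations are skipped. The returned threshold attains the minimum
of the GCV profile.

The decision for a *true* threshold (`evaluate_threshold_criteria()`)
requires the leave-one-out comparison (`loocv_tgam_vs_gam()`, threshold and
smoothing re-selected in every fold, against a plain k = 3 GAM) to prefer
the threshold model, and three criteria: the regimes' edf differ by at
least 0.5; at least one regime trend is significant at p < 0.05 — a smooth
has no single slope, so the trend is operationalized as the Wald test of
the best-fit line through the regime's predictions with its variance
propagated through the smoother matrix; and the GCV profile shows a deep
valley, its minimum at least 5% below the profile median. The valley depth
was calibrated on no-threshold null simulations so that the full decision
accepts in well under 10% of null runs. The lag-1 autocorrelation of the
residuals is reported as a diagnostic but never gates the verdict.

## The synthetic generators and what they emulate

`simulate_stepped_series()` produces piecewise-constant means (each period
at least five years) plus stationary AR(1) noise — the quasi-stable-period
structure the consensus detector is built for.

`simulate_hysteretic_stock()` is the tipping-dynamics workhorse: a
depensatory (Holling-type) discrete logistic under harvest,
$B_{t+1} = B_t + r B_t \tfrac{B_t}{B_t+A}(1 - B_t/K) - f_t B_t$, times
lognormal process noise, floored at a quasi-extinction biomass. At $A = 0$
it reduces exactly to the reversible logistic. With depensation the
harvested map has a fold: `collapse_F` and `recovery_F` are computed by
numerical continuation of the noise-free map over an F grid (resolution
10⁻³, recorded in the truth object) and always satisfy
`recovery_F < collapse_F`. A strong-Allee form ($B/A - 1$ in place of
$B/(B+A)$) was rejected because it makes the depleted state absorbing at
every F ≥ 0, which would leave no recovery level to verify against. The
quasi-extinction floor defaults to 5% of K — a conventional depleted-stock
threshold — because a numerically tiny floor would stretch recovery over
centuries (per-capita depensatory growth vanishes with B) and make
closed-loop dynamics untestable on assessment-length series. Default
demographic parameters (r = 0.9 yr⁻¹, K = 10⁵ t, A = 0.2K) give a fold at
F ≈ 0.38 and recovery at F ≈ 0.17, comfortably inside the F ranges real
assessments span. `loop_scenario()` freezes the three canonical experiments
(closed loop, open loop, reversible control) with multi-decade ramp/dwell
F paths shaped like observed exploitation histories.

`simulate_srr_regimes()` switches Ricker parameters at known years;
`simulate_sst_threshold_srr()` draws SST uniformly and switches the
recruitment-SSB slope at a planted threshold (additive Gaussian noise, 40
(thousand) recruits by default — roughly a 10% CV at mid-range — floored
just above zero to keep pairs valid). `pipeline_scenario("all_effects")`
composes everything into one stock: the closed-loop collapse/recovery
trajectory, a dome-shaped SRR before the collapse versus a weak linear SRR
after it, and an SST warming step coincident with the collapse so the
recruitment regimes split at ≈11.9 °C; `pipeline_scenario("null")` is the
matching no-effect control.

What passing these simulations does *not* show: real assessment series are
shorter and autocorrelated in ways the generators only partially mimic
(AR(1) noise, lognormal process error), observation error of the assessment
model itself is not emulated, SST acts through a clean threshold rather
than a gradual driver, and no age structure exists. Recovery of planted
parameters here demonstrates the statistical machinery, not oceanography.

## Numerical choices and degenerate inputs

* Change-point costs floor RSS at a relative epsilon so exact fits do not
  produce infinities; a constant series yields no splits, and a
  zero-variance series gives the Bayesian sampler an all-zero posterior
  with a warning rather than an error.
* BIC for the structural-break program counts two coefficients per segment
  plus one per break; exact piecewise data tie at zero RSS and resolve to
  the smallest break count.
* The Beverton–Holt optimiser bounds $\beta > -0.99/\max(S)$ so the
  denominator stays positive over the data; a negative $\beta$ is reported
  and flagged rather than hidden.
* The segmented iteration clamps an escaping breakpoint to the interior
  5–95% SSB quantiles (flagged), and a vanishing slope-change coefficient
  ends the iteration with "no supported break".
* Threshold-GAM leave-one-out folds re-select the threshold from the
  full-data candidate grid (quantile bounds are not recomputed per fold);
  folds whose every candidate leaves a regime under-populated are dropped,
  and more than 10% such folds is an error.
* All report serialization uses full double precision and stable key order,
  so identical inputs, configuration and seed give byte-identical JSON.

## Problem sizes used in the checks

The packaged verification (test suite and `scripts/acceptance.R`) runs on
series of 24–80 years and stock–recruitment datasets of 40–80 pairs —
assessment-realistic sizes — with replicate counts of 50–100 for the
simulation-based recovery rates and exhaustive enumeration oracles applied
up to n = 30. The acceptance script reports slightly smaller replicate
counts (25–50) per quantity so a full from-scratch rerun stays inexpensive.

## Known limitations

* The consensus rule inherits the paper-world convention of reporting the
  deterministic binseg year when the two methods disagree within tolerance;
  the Bayesian year is retained in the provenance table.
* The posterior level at which the Bayesian method "detects" a change is a
  declared threshold (0.5), not an inference.
* The hysteresis classifier is an explicit operationalization of a visual
  diagnosis; its gap guard and bin count are calibrated on the package's
  own generators and should be revisited for stocks with strongly trending
  carrying capacity.
* The breakpoint count of the structural-break program is capped (default
  3) and the segmented GLM fits exactly one breakpoint, per the package's
  scope; multi-break SRR structure is delegated to the breakpoint
  regression.
* Threshold-GAM smooths are univariate in SSB; tensor-product or
  multi-covariate smooths, thin-plate bases and REML selection are out of
  scope.
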