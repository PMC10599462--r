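---
title: "Bisubstrate kinetics and mechanism diagnostics with slakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bisubstrate kinetics and mechanism diagnostics with slakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slakin)
```

## The scientific problem

Sulfolactaldehyde (SLA) dehydrogenase is an NAD(P)⁺-dependent aldehyde
dehydrogenase that oxidizes SLA to sulfolactate, the final step of several
sulfoglycolytic pathways. Like every two-substrate/two-product
("Bi–Bi") enzyme, its steady-state initial rates can arise from
qualitatively different binding orders: a ping-pong (substituted-enzyme)
mechanism, a steady-state ordered or random sequential mechanism, or a
rapid-equilibrium ordered (REO) mechanism in which one substrate — here the
nucleotide — must bind first and binding equilibrates fast relative to
turnover. `slakin` turns the classical graphical workflow for
distinguishing these mechanisms into explicit, seeded, testable statistics,
and surrounds it with the supporting analyses such a study needs: apparent
Michaelis–Menten fits with substrate-inhibition windowing, IC50 fits for
cofactor-analogue inhibitors, and progress-curve endpoint analysis for
stereospecificity on racemic substrate.

## Rate laws and their reciprocal geometry

All rate laws use the Cleland convention, with A the leading substrate, and
fixed units: concentrations in mM, rates in the units of `V`
(mM s⁻¹, or s⁻¹ when normalized by enzyme concentration):

* Michaelis–Menten: $v = V S / (K_M + S)$
* uncompetitive substrate inhibition: $v = V S / (K_M + S + S^2/K_{si})$
* ping-pong: $v = V A B / (K_b A + K_a B + A B)$
* ordered steady state: $v = V A B / (K_{ia} K_b + K_a B + K_b A + A B)$
* rapid equilibrium ordered: $v = V A B / (K_{ia} K_b + K_b A + A B)$
* rapid equilibrium random: $v = V A B / (\alpha K_a K_b + \alpha K_b A + \alpha K_a B + A B)$

Each Bi–Bi law is linear in the reciprocal of either substrate at a fixed
level of the other, and `reciprocal_coefficients()` returns the exact slope
and intercept of that line. Three geometric facts drive the classifier:

* ping-pong: the varied-A slope $K_a/V$ is independent of B — parallel
  lines;
* REO, varied second substrate: every line has intercept $1/V$ — the family
  intersects *on* the y axis;
* REO, varied leading substrate: slopes are $K_{ia} K_b/(V B)$, so the
  secondary replot of slopes against $1/B$ passes through the origin, and
  the lines intersect at $x = -1/K_{ia}$, $y = 1/V$.

The ordered steady-state law adds a $K_a B$ term which displaces both
diagnostics (secondary intercept $K_a/V > 0$; intersection left of the
axis), and the random law displaces them in both orientations. These exact
forms serve double duty as the simulator core and as the analytical oracle
the test suite checks the fitted line families against.

## The classification procedure

`classify_mechanism()` runs, at a single significance level
(`alpha = 0.05`):

1. **Parallelism** — an extra-sum-of-squares F-test of a common-slope line
   family against free slopes, per orientation. Both families parallel ⇒
   ping-pong.
2. **On-axis intersection** — the least-squares common point of all lines,
   with a residual-bootstrap confidence interval (default 1000 resamples,
   seeded), plus a nested F-test of the common-intercept family. A family
   is "on-axis" when the test is not rejected *and* the bootstrap CI of the
   intersection abscissa contains zero.
3. **Origin test** — a t-test on the intercept of the secondary replot of
   primary slopes against the reciprocal fixed concentration.
4. **Decision** — for exactly one leading-substrate assignment, an
   origin-passing secondary replot together with an on-axis partner family
   gives a clear REO verdict. If only the origin test supports an
   assignment the verdict is downgraded to REO "indicative": the
   secondary-replot pattern outranks the intersection position, which is
   the harder quantity to judge (its estimator degenerates as families
   approach parallelism). Otherwise the verdict is a sequential mechanism
   with order undetermined — initial rates alone cannot separate
   steady-state ordered from random binding, and the package never claims
   an order without REO evidence.
5. **AICc cross-check** — every candidate law is also fitted directly to
   the untransformed rates (both substrate orders for the ordered models)
   and ranked by corrected AIC; ties within ΔAICc < 2 are reported
   unresolved. When the graphical path is inconclusive but the AICc
   ranking selects an REO fit decisively, the verdict is upgraded to REO
   "indicative". The full evidence record travels with every verdict.

Exact (noise-free) data are recognized by a vanishing weighted residual sum
and short-circuit the F/t machinery with direct coefficient comparisons at
1e-6/1e-8 relative tolerance; without this, zero-variance denominators
would make the tests ill-defined.

### Weighting

Primary reciprocal fits default to weights proportional to $\hat v^4$, the
delta-method inverse variance of $1/v$ under homoscedastic rate noise; the
unweighted option reproduces classical Lineweaver–Burk plots. Secondary
replots are fitted unweighted, as they are in the classical workflow, and
support an explicit point subset (`use =`) for the traditional practice of
dropping a doubtful extreme point — subsetting is never automatic.

### Numerical choices

The global fits use multi-start Levenberg–Marquardt (binding-constant
starts rescaled by 0.2/1/5), because single starts occasionally land in
local optima on exact random-mechanism data and would break the agreement
between the graphical classifier and the AICc ranking. AICc counts the
error variance as a parameter. Near-parallel families are flagged
`unstable` rather than silently reporting a divergent intersection.

## Apparent Michaelis–Menten fitting

`fit_mm()` fits the hyperbola by Levenberg–Marquardt with a
Lineweaver–Burk start. Two design decisions matter:

* **Windowing.** The default window keeps points at or below 0.25 mM, the
  empirical substrate-inhibition onset for both SLA and
  glyceraldehyde 3-phosphate in this assay family; `window_max = "auto"`
  instead runs `detect_substrate_inhibition()` — an AICc comparison of the
  plain and inhibited laws, fitted in the $1/K_{si}$ parameterization so
  the inhibited law reduces smoothly to the plain one — and truncates at
  the estimated onset $\sqrt{K_M K_{si}}$. Windowed-out points are counted
  and reported, never silently dropped.
* **Weighting and intervals.** The default estimator iteratively reweights
  by $1/\hat v^2$, the correct error model for the roughly constant-CV
  scatter of spectrophotometric initial rates; confidence intervals are
  profile-likelihood with a Wald fallback. With unweighted least squares
  the nominal 95% intervals undercover at exactly the noise level the
  generators emulate, which is why the weighted estimator is the default
  rather than an option.

Catalytic efficiency is reported as the ratio of the point estimates with a
delta-method standard error. `check_efficiency_consistency()` recomputes
$k_{cat}/K_M$ from a table of printed estimates and flags rows whose
reported efficiency disagrees with the ratio — published tables sometimes
carry independently fitted efficiencies, and the package surfaces the
discrepancy rather than reconciling it.

IC50 curves are fitted with the Hill coefficient fixed at 1 (simple
reversible binding) unless freed explicitly, on a log-IC50 scale to keep
profiling stable, and require a bracketing design: at least one rate on
each side of half the uninhibited rate.

## The synthetic-data generators

The generators emulate the experimental designs of a spectrophotometric
SLA dehydrogenase study:

* `reference_bisubstrate_design()` — NAD⁺ at 0.05–0.25 mM (4 levels)
  crossed with D-SLA at 0.0125–0.25 mM (5 levels), duplicate
  measurements; all levels below the substrate-inhibition onset.
* `generate_initial_rates()` — any rate law plus a noise model; the
  realistic default is 5% CV with an absolute floor of 1e-6 rate units
  (`default_noise()`), typical initial-rate scatter, with negative draws
  clipped to zero and the clipping recorded in provenance.
* `generate_progress_curve()` — irreversible Michaelis–Menten depletion
  integrated with lsoda, converted to 340 nm absorbance via
  ε = 6.22 mM⁻¹ cm⁻¹ and a 1 cm path (the universal NAD(P)H assay
  constants, both configurable); `reactive_fraction = 0.5` models a
  racemate of which one enantiomer is turned over. The closed-form
  integrated-MM solution (Lambert-W form, `integrated_mm_substrate()`)
  is kept as an independent cross-check of the integrator, not as a
  user-facing estimator.
* `generate_dose_response()` — logistic inhibition curves in µM.

Every generator is a pure function of its parameters and seed; the
caller's RNG stream is never disturbed. The generators emulate design and
noise *level* only: they do not model inner-filter effects, product
inhibition, enzyme inactivation over the trace, pipetting covariance
between replicates, or non-Gaussian outliers. Passing tests therefore
demonstrate correctness of the estimators under the declared error model,
not robustness to every pathology of real cuvette data.

The replicate count (2) and the noise structure are explicit stand-ins:
typical values for duplicate spectrophotometric assays, fixed once and used
everywhere, since the true per-point error structure of any given
instrument is not something a simulator should quietly optimize over.

## Progress-curve endpoint analysis

`endpoint_fraction_consumed()` uses the mean of the terminal 20% of the
trace, so the fraction is invariant to baseline offsets. The plateau
criterion accepts either a statistically zero terminal slope (t-test at
alpha 0.05) or a practically negligible one (projected further rise under
1% of the observed rise) — the second branch exists because a noise-free
asymptotic trace has a tiny slope with an even tinier standard error and
would otherwise always "fail" the statistical test. A non-plateaued trace
is a hard error ("add enzyme or extend trace") unless explicitly
overridden, mirroring the experimental control of adding more enzyme and
observing no further conversion.

A consumed fraction within 0.05 of 0.5 on a declared racemate is called
stereospecific; within 0.05 of 1.0, both enantiomers are substrates. The
tolerance is deliberately wider than typical endpoint uncertainty, so a
47 ± 2% endpoint yields a clean single-enantiomer call. For a
stereospecific enzyme, `effective_substrate_concentration()` halves nominal
racemate concentrations, and `read_rates()` applies this automatically when
a substrate is flagged racemic.

## Problem sizes

The test suite and the acceptance script exercise: the exact-oracle
equivalence on 100 random parameter draws; the noise-free classifier on
40 draws spanning all four mechanisms and both substrate orders; the noisy
classifier on 200 seeded replicates of the reference grid at 5% CV
(300-resample bootstrap per replicate); and interval calibration on 200
seeded saturation-series fits. These sizes were chosen to estimate the
Monte-Carlo proportions to a few percent, which is the precision at which
the pass thresholds (100% exact, ≥90% noisy) are meaningful.

## Known limitations

* Initial rates only: no product-inhibition patterns, isotope exchange, or
  dead-end-inhibitor probes, which is why a sequential verdict never
  asserts binding order without REO evidence.
* Irreversible forward rate laws; no Theorell–Chance discrimination.
* The substrate-inhibition form is the single-site uncompetitive law — the
  simplest standard choice; the detector and windowing only need it to
  locate an onset, not to be mechanistically exact.
* IC50 fits report IC50 only; no Cheng–Prusoff conversion to $K_i$,
  which would require an inhibition mechanism the dose–response design
  cannot identify.
* Progress curves are simulated and summarized at their endpoint; full
  progress-curve parameter estimation is out of scope.
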