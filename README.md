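# slakin

Bisubstrate enzyme kinetics and mechanism diagnostics, built around the
kinetic characterization of sulfolactaldehyde (SLA) dehydrogenase — an
NAD(P)⁺-dependent aldehyde dehydrogenase that oxidizes SLA to sulfolactate,
the last step of several sulfoglycolytic pathways.

## What it does

For a two-substrate/two-product ("Bi–Bi") enzyme, initial-rate data can
distinguish a ping-pong (substituted-enzyme) mechanism from sequential
ones, and — in favorable cases — identify a rapid-equilibrium ordered
(REO) mechanism together with which substrate binds first. The classical
workflow reads this off double-reciprocal plots: ping-pong gives parallel
lines (constant slope $K_a/V$); sequential mechanisms give lines
intersecting left of the y axis; REO places the intersection *on* the
y axis when the second substrate is varied (common intercept $1/V$, since
$1/v = \frac{K_b}{V}\bigl(1 + \frac{K_{ia}}{A}\bigr)\frac{1}{B} + \frac{1}{V}$),
and sends the secondary replot of varied-leading-substrate slopes against
the reciprocal co-substrate concentration through the origin (slope
$K_{ia}K_b/V$, intercept 0).

`slakin` implements that workflow as explicit statistics — an
extra-sum-of-squares parallelism F-test, a least-squares common-point
estimator with bootstrap CI and an on-axis test, origin t-tests on
secondary replots, and an AICc cross-check by direct nonlinear fits of all
candidate rate laws — plus the supporting analyses of such a study:

* closed-form Bi–Bi rate laws and their exact reciprocal coefficients
  (simulator core and analytical oracle),
* apparent Michaelis–Menten fitting with substrate-inhibition windowing
  (default window ≤ 0.25 mM, the empirical onset for this assay family)
  and AICc-based inhibition detection,
* IC50 dose–response fitting with profile-likelihood intervals,
* progress-curve endpoint analysis: fraction consumed from the 340 nm
  absorbance rise, stereospecificity inference on racemic substrate, and
  the racemate concentration correction ([S]/2),
* seeded synthetic-data generators emulating the bisubstrate grid,
  saturation series, progress curves and dose–response designs.

## Worked example

Simulate the reference bisubstrate experiment — NAD⁺ (0.05–0.25 mM)
crossed with D-SLA (0.0125–0.25 mM), duplicates, 5% CV noise — under a
rapid-equilibrium ordered truth with the nucleotide leading, and classify:

```r
library(slakin)

p <- kinetic_params(V = 17.8, Kia = 0.081, Kb = 0.13)
m <- mechanism_model("RAPID_EQ_ORDERED", leading_substrate = "NAD+")
d <- generate_initial_rates(m, p, reference_bisubstrate_design(),
                            noise = default_noise(), seed = 42)
classify_mechanism(d, bootstrap_n = 1000, seed = 42)
#> <mechanism_verdict> RAPID_EQ_ORDERED (leading substrate: NAD+) [clear]
#>   parallelism p: varied-A 0.000414, varied-B 6.43e-05
#>   intersection x*: varied-A -13.16 (on-axis: FALSE), varied-B 1.194 (on-axis: TRUE)
#>   secondary origin p: varied-A 0.881, varied-B 0.00258
#>   AICc best: RAPID_EQ_ORDERED[NAD+] (dAICc to next: 2.65)
```

Reading the verdict: both line families are decisively non-parallel (so
the mechanism is sequential, not ping-pong); the varied-SLA family
intersects on the y axis while the varied-NAD⁺ family does not (its
intersection sits at x* ≈ −13 mM⁻¹ ≈ −1/K_ia); the varied-NAD⁺ secondary
replot passes through the origin (p = 0.88) while the varied-SLA one does
not — together the REO signature with NAD⁺ binding first, corroborated by
the AICc ranking.

Apparent Michaelis–Menten parameters from a simulated NAD⁺ saturation
series at 0.25 mM D-SLA (truth: kcat 17.7 s⁻¹, KM 0.081 mM):

```r
sat <- design_grid(a_levels = c(0.0125, 0.025, 0.05, 0.075, 0.1,
                                0.15, 0.2, 0.25),
                   b_levels = 0.25, replicates = 2,
                   a_label = "NAD+", b_label = "D-SLA")
d_sat <- generate_initial_rates(mechanism_model("MM"),
                                kinetic_params(V = 17.7, KM = 0.081),
                                sat, noise = default_noise(), seed = 42)
fit_mm(data.frame(S = d_sat$A, v = d_sat$v))
#> <mm_fit> (nls)
#>   V  = 18.07 +/- 0.59
#>   KM = 0.08039 +/- 0.0048 mM
#>   V/KM = 224.7 +/- 7.1
#>   window <= 0.25 mM: 16 used, 0 excluded; R^2 = 0.98253
```

The bundled apparent-parameter table for RlGabD
(`rlgabd_kinetics()`) and `check_efficiency_consistency()` recompute
kcat/KM from the point estimates and flag rows whose reported efficiency
disagrees with the ratio (the two GAP rows carry independently fitted
efficiencies):

```r
check_efficiency_consistency(rlgabd_kinetics())[, c(1, 2, 7, 8, 9)]
#>   varied_substrate fixed_substrate efficiency_mM_s      ratio consistent
#> 1             NAD+           D-SLA           210.0 218.518519       TRUE
#> 2            NADP+           D-SLA           240.0 241.176471       TRUE
#> 3            D-SLA            NAD+           137.0 136.923077       TRUE
#> 4            D-SLA           NADP+            30.0  29.375000       TRUE
#> 5              GAP            NAD+             4.2   2.517241      FALSE
#> 6              GAP           NADP+            10.5  17.647059      FALSE
```

Progress-curve stereospecificity on a racemate (one reactive enantiomer):

```r
pc <- generate_progress_curve(kcat = 17.7, KM = 0.081, E0 = 1e-4,
                              S_total = 1, reactive_fraction = 0.5,
                              t_end = 1500, dt = 3)
ef <- endpoint_fraction_consumed(pc)
sprintf("fraction consumed: %.3f -> %s", ef$fraction,
        infer_stereospecificity(ef$fraction)$verdict)
#> [1] "fraction consumed: 0.500 -> stereospecific"
```

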