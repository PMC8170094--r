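---
title: "From spin densities to superoxide production rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spin densities to superoxide production rates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxleak)
```

## The problem

At the Q_o-site of the cytochrome bc1 complex, a bound semiquinone radical
(Q•−) and a transiently trapped O2 molecule can undergo an electron
transfer that produces superoxide. Two donors are conceivable: the
semiquinone itself (model I) and the reduced iron-sulfur cluster (model
II). `redoxleak` takes the *outputs* of quantum-chemistry and
molecular-dynamics sampling of this site — tables of fragment spin
densities, ligand distance traces, energy-gap samples, and alchemical work
samples — and carries them through a chain of classical inference steps to
electron-transfer and superoxide production rates. No electronic-structure
or dynamics calculation happens inside the package.

## Spin-density classification

A snapshot's O2 fragment carries local spin density of magnitude near 2
(triplet O2) or near 1 (superoxide formed). We classify on the midpoint:

* `spin_threshold = 1.5` (dimensionless): |s| above it is "no transfer",
  between `anomaly_band = 0.5` and 1.5 is "transfer". The observed
  outcomes are discrete (2 vs 1), so any threshold between them works;
  the midpoint maximizes the margin to both.
* Magnitudes below 0.5, or signs inconsistent with the declared O2 spin
  orientation, are anomalies; the pipeline routes them to the outlier
  class rather than guessing.

Donor attribution uses the spin difference of every fragment against the
mean over no-transfer snapshots *of the same spin orientation* (the iron
spins differ in sign between the two orientations, so a pooled reference
would be biased). The transferred electron is assigned to whichever pool —
{SQ} or {Fe1, Fe2, S1, S2} — has the larger summed |Δs|, with normalized
|Δs| shares as donor weights. An exact tie goes to the cluster pool
(model II): arbitrary, but deterministic and documented. If the winning
pool's summed |Δs| is below `min_pool = 0.5`, no donor can honestly be
named and the snapshot is labeled unattributable (outlier downstream).

Energy outliers are snapshots whose total energy deviates from their
(orientation, label) group *median* by more than
`outlier_threshold = 50` kcal/mol. The median keeps the rule robust to the
outliers themselves. The class energy spreads are of order 11–15 kcal/mol,
so 50 kcal/mol sits 3–4 standard deviations out; the threshold is a free
parameter of the analysis and is exposed as such. All standard deviations
are sample (n−1) statistics — the snapshot ensembles are small. Gaussian
curves drawn over class histograms are moment-matched, never free-fitted:
with N of order 10–100 per class a two-parameter fit adds nothing but
fragility.

## Binding-event detection and residence times

Events in a distance trace are segmented with a hysteresis rule on three
radii (defaults 9, 13, 20 Å): an event opens when the ligand comes within
9 Å of the cluster, tolerates excursions beyond 13 Å as long as it
returns, and closes — retroactively at the last frame within 13 Å — once
20 Å is reached. Boundary semantics are fixed deterministically: "within
9" is `d < 9`, "within 13" is `d <= 13`, "reaching 20" is `d >= 20`.
A trace that starts below 9 Å opens an event at frame 0 (product-state
simulations begin bound), and an event still open at the end of the trace
is kept but flagged unresolved.

Residence times come from the survival count `N_b(t)`, the number of
events with duration at least `t`. Two estimators are provided:

* `lsq` (default): nonlinear least squares of `N0 * exp(-t/tau)` on the
  survival histogram with both parameters free (Levenberg–Marquardt via
  `minpack.lm`, initialized at the event count and the mean duration).
  This matches how such survival histograms are usually presented and
  lets the fitted `N0` absorb early-time artifacts.
* `mle`: the closed-form exponential maximum-likelihood estimate — the
  sample mean of the durations — which is the statistically efficient
  choice when the exponential model is trusted.

Durations and τ are reported in ns; input frame spacing is in ps.

Escape-side classification looks at the membrane-normal coordinate after a
resolved event and takes the sign of z when |z| first exceeds
`shell_A = 20` Å (positive z = intermembrane space). If the trace ends
first, the escape is unresolved rather than guessed.

## Energy-gap linear response

The reaction coordinate is the potential-energy gap
`ΔU = U_product − U_reactant` at fixed nuclear coordinates; negative
ΔG⁰ means a favorable forward reaction. Under Gaussian gap fluctuations
the free-energy curve of each state is the parabola

`G(ΔU) = kBT/(2σ²) (ΔU − ⟨ΔU⟩)² + G₀`,

and the package also builds the empirical curve
`G = −kBT ln(density)` from the histogram for the sampled range (thick
vs thin curves in `autoplot()`). Binning is Freedman–Diaconis by default
(bin count overridable); empty bins are dropped, and a histogram of
identical values is rejected as degenerate. A skewness check (adjusted
Fisher–Pearson, warning above |0.5|) guards the Gaussian assumption.

The product curve is shifted vertically so the two curves agree at
ΔU = 0 — the crossing condition for electron transfer — and then:

* ΔG⁰ = difference of the curve minima,
* Λ_p = product curvature × (vertex separation)², the energy to
  reorganize the relaxed product geometry into the reactant equilibrium,
* Λ_r = the mirror image on the reactant curve.

Both reorganization energies are computed from parabola *geometry*, not
from the identity σ² = 2ΛkBT: that identity holds only in the
equal-curvature case, and the unequal-variance case (Λ_p ≠ Λ_r) is
precisely the empirically relevant one. The identity is used in the test
suite as an independent oracle on equal-variance synthetic data. One
sign-convention remark: with this package's ΔU orientation, the aligned
curves intersect at the *product* vertex exactly when ΔG⁰ = Λ_p, a
magnitude relation |Λ_p| = |ΔG⁰| (statements of it with a minus sign
correspond to the opposite ΔG⁰ sign convention).

Temperature defaults to 300 K everywhere and is configurable; kB =
0.0019872 kcal/mol/K, 1 eV = 23.0609 kcal/mol, kB = 8.6173e-5 eV/K and
ħ = 6.5821e-16 eV·s are the constants used, quoted to the precision they
carry.

## Alchemical estimators

Per λ-window, the exponential (Zwanzig) estimator
`ΔΔG_i = −kBT ln⟨e^{−ΔU_i/kBT}⟩` is evaluated with a log-sum-exp
contract, exact for |ΔU|/kBT up to several hundred. The Bennett
acceptance ratio solves

`mean_F f((W − C)/kBT) = mean_B f((W + C)/kBT)`, `C = ΔG + kBT ln(n_b/n_f)`

with `f` the Fermi function; the left-minus-right difference is monotone
increasing in ΔG, so a bracketed `uniroot` starting from the interval
spanned by the two exponential estimates (extended upward if needed)
converges reliably; tolerance 1e-8 kcal/mol. The asymptotic variance is
the standard expression in the Fermi weights. BAR is the default method;
exponential averaging remains for initialization and for the
forward/backward hysteresis diagnostic
`|ΔG_exp,fwd + ΔG_exp,bwd|` (the backward total estimates −ΔG).

Sample-wise, the BAR estimate is *not* guaranteed to lie inside the
interval spanned by the two exponential estimates — finite-sample noise
moves it past the bracket in a sizeable fraction of replicates — so the
test suite asserts the bracketing with the combined estimator
uncertainties and, separately, the expectation-level ordering over many
seeds. Work samples are always stored in the forward direction of their
own transformation; backward totals are negated where a reaction-frame
quantity is needed. The two legs (discharging the reactant, charging the
product) add into the reaction ΔG⁰ with quadrature uncertainties.
Restraint corrections for the ligand-confinement spheres used during such
simulations are out of scope; the work samples are consumed as given.

## Rates

The default rate route is the empirical tunneling ruler

`log10 k_et = 15 − 0.6 R − 3.1 (ΔG + Λ)² / Λ`

with energies in eV and the edge-to-edge distance R in Å; inputs in
kcal/mol are converted internally, and computing in either unit system
agrees to 1e-12 relative (tested). The Marcus expression is available
when an electronic coupling |T_AB| is supplied; since no coupling is
derivable from the free-energy chain, it is excluded from the default
pipeline. The denominator of the Marcus exponent is 4ΛkBT, the standard
form.

Λ defaults to the product-state value Λ_p: the aligned curves intersect
at the product equilibrium when Λ_p matches |ΔG⁰|, the configuration of
maximal overlap between donor and acceptor vibronic states. Using Λ_r
instead is supported (`lambda_state = "reactant"`) and lowers the model I
rate by roughly two orders of magnitude — a useful sensitivity check.

Snapshot averaging over a distance series is the arithmetic mean of
per-snapshot rates (not of log-rates): the quantity of interest is the
expected number of transfer events per unit time, which is linear in the
rate. Because the ruler is convex in R, close-approach snapshots dominate
and the mean exceeds the rate at the mean distance (Jensen; tested).

The superoxide production rate while the enzyme holds a semiquinone is
`k = k_bind · k_et / (k_et + k_unbind)`; it saturates at `k_bind` and
halves when `k_et = k_unbind`. Binding kinetics are configuration inputs,
not estimated from trajectories. An optional occupancy fraction `x_sq`
scales to a per-complex rate.

## Synthetic data: what it does and does not emulate

Every pipeline input has a seeded generator with attached ground truth:

* `sim_gap_samples()` draws Gaussian gaps with reactant mean ΔG⁰ + Λ,
  product mean ΔG⁰ − Λ, reactant σ = √(2ΛkBT), and a configurable
  product/reactant σ ratio. σ ratio 1 gives the analytic equal-curvature
  case; ratio ≠ 1 reproduces the Λ_p ≠ Λ_r regime.
* `sim_fep_windows()` draws per-window Gaussian work with mean
  ±ΔG_i + σ²/(2kBT), which satisfies the Crooks relation exactly — the
  empirical log-density ratio is linear in work with slope 1/kBT (tested
  by binned regression).
* `sim_dwell_times()` is i.i.d. exponential.
* `sim_distance_trace()` builds a two-level (bound/unbound) trace from a
  non-overlapping event schedule plus zero-mean noise truncated at its
  amplitude (default 0.5 Å, Gaussian sd = amplitude/2) so that no noise
  excursion can cross the detection thresholds; the ground truth is the
  detector's segmentation of the noiseless trace. A membrane-normal
  coordinate ramps to the configured escape side after each event.
* `sim_spin_tables()` populates the four outcome classes with the
  baseline spin pattern (O2 ±2, SQ ∓1, antiparallel iron spins), the
  one-unit spin rearrangements of the two transfer models (cluster
  compensation split 0.5/0.25/0.25 over Fe2/S1/S2, total spin conserved),
  per-class Gaussian energies, and outliers displaced 150 kcal/mol from
  the no-transfer mean. Default class counts (77/0/44/6, spin up) mirror
  the reference snapshot ensemble.

These generators emulate the *distributional* structure the estimators
assume: Gaussian gaps, Crooks-consistent work, exponential dwells, clean
two-level traces, discrete spin outcomes. They do not emulate correlated
MD noise, anharmonic gap tails, multi-exponential unbinding, partial
charge transfer, or geometry-dependent couplings. Green tests therefore
certify the inference chain — that each stage recovers known truth from
data obeying its model — not the validity of those models for any given
simulation.

A master seed feeds each generator through an independent substream
derived from (seed, generator name), so changing one stage's draw does
not perturb another's.

## Problem sizes and numerical checks

The test suite exercises the estimators at the scales where their
asymptotic guarantees bite while staying quick on a laptop: gap-parameter
recovery at n = 1e5 with 100 bootstrap replicates of the geometric
estimator; BAR recovery over 100 seeded 16-window transformations at
1e4 samples per side; residence-time recovery at n = 1e4 plus a 100-seed
unbiasedness check; detector equivalence against an independently coded
brute-force segmentation on 1000 random traces; classification accuracy
on ~800-snapshot tables, exact at zero noise and ≥99% at spin noise
sd 0.1. Stochastic assertions use 3-standard-error bounds under fixed
seeds.

## Limitations

* The pipeline consumes extracted tables; it neither parses trajectory
  formats nor validates that the supplied energies/spins were computed
  consistently.
* The spin classifier presumes the discrete 2-vs-1 dichotomy; genuinely
  fractional charge-transfer states would all land in the anomaly band.
* The linear-response route extrapolates parabolas far beyond the sampled
  gap ranges when the two distributions do not overlap; the FEP route is
  the intended remedy, and the package reports both so the discrepancy is
  visible rather than hidden.
* The distance ruler is an order-of-magnitude tool; its 0.6/Å slope and
  3.1 curvature are empirical constants, and no attempt is made to refine
  them.
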