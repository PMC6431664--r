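---
title: "Models and methods: fluorometry, ITC partitioning, and bilayer structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fluorometry, ITC partitioning, and bilayer structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprobe)
```

memprobe reduces three classic membrane-biophysics measurements to their
standard observables. This vignette documents the underlying models, the
assumptions they carry, the parameters a user may want to move, and the
numerical and design choices made where more than one defensible convention
exists.

## Laurdan generalized polarization

Laurdan partitions at the hydrophilic/hydrophobic interface of a bilayer
and red-shifts its emission as the surrounding lipids melt and hydrate.
The generalized polarization

$$\mathrm{GP} = \frac{I_{440} - I_{490}}{I_{440} + I_{490}}$$

condenses the two-band emission into one number in $[-1, 1]$: high in the
gel phase, low in the fluid phase. Intensities must be blank-subtracted;
`blank_subtract()` permits negative results (an over-subtracted blank is
real information about the measurement), and `generalized_polarization()`
rejects, with a classed degenerate-signal error, any pair whose sum is not
positive. Surfacing instrument problems was preferred over silently
clipping them.

**Averaging order.** An instrument protocol records a dozen or more shots
per temperature. Whether GP should be the ratio of mean intensities or the
mean of per-shot ratios is a genuine convention choice; the two differ for
asymmetric noise. `build_gp_curve()` averages intensities first (ratio of
means), consistent with blank subtraction operating at the intensity level,
and exposes `average = "per_shot"` for the alternative. The reported `sd`
is the dispersion of per-shot GP values.

**Tm estimation.** Melting curves are summarized by the midpoint of a
descending four-parameter logistic

$$\mathrm{GP}(T) = \mathrm{GP}_{\mathrm{fluid}} +
  \frac{\mathrm{GP}_{\mathrm{gel}} - \mathrm{GP}_{\mathrm{fluid}}}
       {1 + e^{(T - T_m)/w}},$$

fitted by Levenberg–Marquardt (`minpack.lm::nlsLM`) with starting values
taken from the data (plateaus from the GP range, $T_m$ from the steepest
finite-difference descent, $w$ from the slope there). This functional form
is the standard choice for GP melting curves and is verifiable by
round-trip against the synthetic generator. A model-free fallback
(`method = "derivative"`) reports the steepest-descent temperature without
fitting. A curve whose GP range does not exceed `range_threshold`
(default 0.2, about a quarter of a full gel-to-fluid excursion) carries no
usable transition and raises a no-transition error rather than an
extrapolated estimate.

## DPH anisotropy

DPH sits in the acyl-chain region and reports its rotational freedom
through the polarization-resolved emission ratio

$$r = \frac{I_{VV} - G\,I_{VH}}{I_{VV} + 2\,G\,I_{VH}},
\qquad G = \frac{I_{HV}}{I_{HH}}.$$

The G-factor corrects the emission channel's polarization bias and is
computed from the same sample's horizontally excited pair — no global
instrument constant is assumed, because all four orientations are measured
per sample. Replicate shots are averaged per channel before the ratios are
formed, mirroring the GP convention. Both GP and $r$ are invariant under
uniform intensity rescaling, which the test suite asserts as a property.

## ITC partition model

In a lipid-into-solute titration the cumulative heat after $i$ injections
follows

$$\sum_{k=1}^{i} \delta h_k = \Delta H \, V_{\mathrm{cell}}\,
  C_A^0(i)\, \frac{K\, C_L^0(i)}{1 + K\, C_L^0(i)},$$

with $K$ the partition constant (mM$^{-1}$) and $\Delta H$ the molar
water-to-bilayer transfer enthalpy. The model saturates at
$\Delta H\, V_{\mathrm{cell}}\, C_A^0$ and is half-saturated at
$C_L^0 = 1/K$; both limits are asserted to machine precision in the tests.

**Concentration bookkeeping.** The model needs the total solute and lipid
concentrations in the cell after each injection. Three modes are provided
(`concentration_series()`):

* `naive` — injected volume ignored in the denominator;
* `dilution` (default) — the cell is treated as volume-additive, both
  concentrations scaled by $V/(V + \Sigma v)$;
* `overfill` — perfusion-cell displacement, each injection expelling
  premixed content with the per-injection factor $(1 - v/2V)/(1 + v/2V)$.

The default schedule injects 282 µL into a 1.4565 mL cell (about 19 %),
too much to ignore, which is why `dilution` is the default rather than
`naive`; the choice is a visible argument, not a hidden constant, because
published fits rarely state how (or whether) they correct for it. A
warning fires when the cumulative injected volume exceeds 25 % of the
cell, where the single-site isotherm itself becomes doubtful.

**Fitting.** `fit_partition()` fits cumulative heats — the form in which
the model is written — not per-injection heats, which would correlate the
noise differently; per-injection residuals remain available for
diagnostics. $K$ is kept positive by fitting $\log K$. Weights default to
unity, matching the common practice of vendor software; per-point inverse
variances may be supplied. The first (purge) injection's heat is excluded
from the fit while its volume still counts toward the concentrations, so
the model curve is referenced to the cumulative heat already evolved at
the end of the discarded injection. Initialization is data-driven:
$\Delta H_0$ from the final plateau, $K_0$ as the reciprocal of the lipid
concentration nearest half-plateau. Degenerate inputs (all-zero heats)
return a flagged non-convergent fit instead of an error or a silent
answer. A data-quality warning fires when an injection heat falls more
than 4 standard deviations below the fitted curve on the increment scale —
judged against the model rather than against raw monotonicity, because a
high-affinity titration under dilution bookkeeping legitimately tails
downward once binding saturates.

**Standard state.** Converting $K$ to a free energy requires a
dimensionless argument for the logarithm. The package uses the
mole-fraction convention,

$$\Delta G = -RT \ln\!\left(55.5 \cdot K[\mathrm{M}^{-1}]\right),
\qquad T\Delta S = \Delta H - \Delta G,$$

with the molarity of water (55.5 M) as the default
`standard_state_factor`. Among the common conventions this is the one that
makes partition free energies of small amphiphiles at different molar
scales comparable, and it reproduces published decompositions of exactly
this experiment type; the factor is an explicit parameter so any other
convention is one argument away. Heat units are µcal internally for raw
thermograms (the VP-ITC convention) with explicit, tested conversion to
joules (1 cal = 4.184 J); molar quantities are kJ/mol.

**Peak integration.** `integrate_peaks()` turns a raw power trace into
per-injection heats by baseline-subtracted trapezoid integration over each
inter-injection window. Two baselines are offered: the window median
(robust when the peak occupies a minority of the window) and a line
through the first and last 10 % of the window's samples. Windows without
at least two samples raise a missing-data error — a trace shorter than its
schedule is an acquisition fault, not a fitting nuisance.

## Bilayer structural observables

The analysis operates on coordinate frames (nm) with a topology map naming
each species' chain carbons, phosphorus, glycerol, and solute polar/terminal
atoms, plus per-atom masses. Fixed-width GRO and a minimal XYZ-plus-JSON
dialect are supported; binary trajectory formats are out of scope.

**Bilayer normal and centre of mass.** The membrane normal is taken as the
fixed z axis, appropriate for semi-isotropically coupled planar bilayers;
no director fitting is attempted. The bilayer centre of mass along z is
computed under periodic boundaries by placing the midpoint of the largest
unoccupied z-gap at the box boundary and taking a linear mass-weighted mean
— exact whenever the bilayer does not fill the box, and anchored at the gap
midpoint so that atoms sitting numerically on the cut cannot alias to the
far side. All observables are invariant under re-wrapping of periodic
images, asserted as a property test.

**Leaflets.** Each lipid is assigned to a leaflet by the sign of its
phosphorus atom's z relative to the bilayer centre of mass (other species
by their molecular centre of mass); molecules exactly at the midplane are
excluded from that frame with a logged count rather than arbitrarily
assigned.

**Order parameters.** For united-atom chains the hydrogens are not
present; at each internal carbon $C_i$ both C–H unit vectors are
reconstructed from the local frame of $C_{i-1}, C_i, C_{i+1}$ assuming
tetrahedral geometry: the two hydrogens lie in the plane perpendicular to
the $C_{i-1}$–$C_i$–$C_{i+1}$ plane, symmetric about the inverted angle
bisector, separated by 109.47°. Then

$$S_{CD}(i) = \left\langle \tfrac{1}{2}\left(3\cos^2\theta - 1\right)
\right\rangle$$

is averaged over both hydrogens, molecules, leaflets and production
frames, with $\theta$ the angle to z. The profile is reported as $-S_{CD}$
(positive for ordered chains, maximum 0.5), the standard deuterium-NMR
sign convention; `convention = "magnitude"` and `"signed"` are available
because plotted "order parameters" in the literature are frequently
ambiguous about sign. Terminal carbons have no reconstruction frame and
are reported `NA`; carbons whose backbone is locally collinear (degenerate
frame) are dropped from that frame's average. The reconstruction is
validated against analytic cases: an all-trans chain along z gives exactly
0.5 at every internal carbon; a rigid chain tilted at the magic angle
(54.7356°), averaged over its own azimuth, gives 0; isotropic orientations
give 0; and $|S_{CD}| \le 0.5$ holds for arbitrary geometry.

**z-profiles and thickness.** `z_profile()` reports, per atomic group, the
time- and leaflet-averaged $|z_{\mathrm{group}} - z_{\mathrm{COM}}|$ with
a standard error over frames — absolute-value folding of the two leaflets,
the usual way such insertion-depth profiles are drawn. Bilayer thickness
is twice the mean phosphorus distance from the centre of mass, i.e. the
inter-leaflet P–P separation; a frame with all P atoms on one side is
rejected as not being a two-leaflet bilayer.

**Equilibration.** Trajectories carry an `equilibration_fraction`
(default 0.6, as when the first 150 ns of a 250 ns run are discarded);
analyses operate on the trailing fraction of the time span.

## The synthetic-data generators

Each generator emits data in exactly the dialect its analysis stage reads
and is the stage's exact inverse in the noiseless limit — the round-trip
identities are asserted in the test suite, and identical seeds give
byte-identical output.

* `gen_gp_curve()` draws per-shot GP noise on the GP scale (then converts
  to a 440/490 intensity pair of fixed total intensity) — additive
  Gaussian noise being the simplest defensible model for averaged photon
  counts; defaults emulate a DPPC melting curve (Tm 41.5 °C, width 0.7 °C,
  plateaus 0.6 and −0.2, 12 replicates, the grid stepping finer near the
  transition).
* `gen_polarized_quad()` inverts the anisotropy equations exactly for any
  feasible $(r, G)$, additive intensity noise optional.
* `gen_itc_thermogram()` takes first differences of the cumulative
  isotherm under the chosen bookkeeping; noise is multiplicative per
  injection (instrument scatter scales with peak size). The default
  schedule is the 2 µL + 28 × 10 µL, 600 s protocol in a 1.4565 mL cell.
  Optionally the heats are rendered as Gaussian peaks (width 15 s, lag
  60 s) on a flat baseline for exercising `integrate_peaks()`.
* `gen_bilayer_frames()` is a *geometric* stand-in, not a physics engine:
  it places mirrored leaflets of zig-zag bead chains whose orientations
  realize a target order level. In `"sampled"` mode a chain is all-trans
  along z with probability $s$ and otherwise tilted uniformly in
  $\cos\tau$ over the leaflet hemisphere, giving an expected
  $-S_{CD} = s/2$ that is strictly monotone in $s$; exact `"all_trans"`,
  `"magic_angle"`, `"isotropic"` and `"fixed"`-tilt ensembles provide the
  analytic fixtures. Headgroup height follows each chain's own z-extent,
  so ordered ensembles are genuinely thicker — the qualitative
  order-thickness coupling seen in real bilayers emerges from the
  construction rather than being imposed.

What the generators deliberately do not emulate: photophysics (lifetimes,
wobbling-in-cone, inner-filter effects), heats of dilution beyond a
constant offset, force-field energetics, inter-molecular packing
correlations, or time correlation between frames. Passing round-trip tests
therefore demonstrates that the *estimators* are correct and unbiased
under their stated noise models — not that real instruments or simulations
satisfy those models.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run entirely on synthetic
data: titrations of 28 retained injections (200 noisy replicates for the
recovery statistics), melting curves of 11 temperatures × 12 shots,
bilayers of 140 lipids (+28 herbicides) over up to 100 frames, and
10⁴-chain ensembles for the Monte-Carlo order-parameter fixtures. These
sizes were chosen to make every statistical tolerance comfortably
resolvable while keeping a full run in seconds. Full-length production
trajectories and real instrument exports are read through the same code
paths; nothing in the implementation is specific to the synthetic sizes.

Known limitations: single-site partitioning only (no aggregation or
permeation models); no spectral deconvolution or scattering corrections;
fixed z as the bilayer normal; united-atom H-reconstruction assumes ideal
tetrahedral geometry, which differs from all-atom hydrogen positions by a
few degrees of bond-angle distortion; and uncertainties reported by
`fit_partition()` are fit covariances, which understate across-replicate
variability when instrument drift dominates.
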