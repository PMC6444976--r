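---
title: "Continuous-flow DNA deflection under orthogonal pulsed fields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-flow DNA deflection under orthogonal pulsed fields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsegel)
```

## The separation problem

In a gel-filled chamber driven by two alternately applied transverse electric
fields — a strong field $E_1$ at angle $\theta_1$ from the x axis and a weak
field $E_2$ at $\theta_2$, switched at frequency $f$ — DNA fragments injected
continuously at one edge migrate along length-dependent trajectories and
arrive at the opposite (collection) edge sorted into discrete streams. Two
physical mechanisms make the trajectory angle depend on fragment length:

1. **Field-dependent mobility.** A reptating chain aligns with the field; its
   mobility $\mu(E, L)$ increases with $E$ and decreases with contour length
   $L$. The *gain* between the two fields,
   $\Delta\mu = \frac{d\mu}{dE}(E_1 - E_2)$, grows with $L$, so in the
   quasi-static limit (low $f$) longer fragments lean more toward the
   strong-field direction.
2. **Reorientation lag ("switchback").** After each field switch a chain
   needs $t_{or} = L/(\mu E)$ to pull itself into a tube along the new field;
   above the reorientation frequency $f_{or} = \mu E/(2L)$ it cannot follow
   that field at all. Since $f_{or}$ falls with length, intermediate switching
   frequencies leave long fragments following only the strong field while
   short fragments still average both.

Both mechanisms are combined in the migration angle
$$\Phi = \operatorname{atan2}\!\big(v_1\sin\theta_1 + v_2\sin\theta_2,\;
v_1\cos\theta_1 + v_2\cos\theta_2\big),\qquad
v_i = \max(\mu_i E_i - 2 f L,\, 0),$$
where the $-2fL$ term is the per-half-period displacement lost to
reorientation and the clamp at zero encodes a field the chain can no longer
follow. Non-reptating ions have no reorientation loss and field-independent
mobility, so their angle reduces to
$\Phi_0 = \operatorname{atan2}(E_1\sin\theta_1 + E_2\sin\theta_2,\,
E_1\cos\theta_1 + E_2\cos\theta_2)$ — always steeper than the DNA streams,
which is why the device simultaneously purifies DNA from small ionic species.

### The sign convention of the angle formula

The historical single-argument arctangent form of the migration-angle formula
carries a minus sign in its denominator that is inconsistent with its own
ion limit: setting $f = 0$ and $\mu_1 = \mu_2$ must recover $\Phi_0$, which
has a plus sign. We therefore implement the physical time-weighted
displacement vector sum (plus sign, two-argument arctangent), which satisfies
that reduction exactly — this identity is property-tested over random
protocols. The as-printed variant remains available via
`migration_angle(..., convention = "as_printed")` for comparison.

### Regimes, duty cycle and degenerate cases

* `classify_regime()` splits frequencies at the two reorientation
  frequencies: `field_dependent_mobility` below $f_{or,2}$, the
  `switchback_window` between them (boundary inclusive upward), and
  `no_reorientation` above $f_{or,1}$.
* Duty cycles other than one half generalize the displacement weights to
  $\max(d_i \mu_i E_i - fL, 0)$ with $d_1 = \mathrm{duty}$,
  $d_2 = 1 - \mathrm{duty}$; at duty 0.5 this is algebraically identical to
  the symmetric form. This is an extension beyond the symmetric alternation
  used in the experiments it models.
* When the weak-field displacement clamps to zero, $\Phi = \theta_1$ is
  returned exactly (not via the arctangent), matching the contract used by
  downstream tests.
* When *both* displacements clamp, the dead-time model predicts no motion at
  all, yet a never-reorienting coil still responds to the time-averaged
  Coulomb force. The result is flagged `no_net_motion` and falls back to the
  ion-limit direction computed with the per-field mobilities.

## Mobility models

`mobility_model_parametric()` implements the biased-reptation form
$\mu(E, N) = \mu_0\,[1/(3N) + \beta E^2/(1 + \gamma E^2)]$ with $N$ the chain
length in Kuhn segments. The Kuhn conversion defaults to 300 bp per segment
(about 100 nm at 0.34 nm/bp) and is configurable; only qualitative trends
depend on it. The form is monotone by construction (non-decreasing in $E$,
non-increasing in length), which is property-tested over random parameter
draws.

`mobility_model_table()` wraps a measured calibration of
$(E, L, \mu)$ triples. Interpolation is bilinear in $(E, \log L)$: exact at
grid points, bounded by the neighbouring grid values between them, and
monotone-preserving. Extrapolation is off by default (out-of-range queries
raise an error naming the offending axis) and clamps to the grid edge when
explicitly enabled. The field derivative uses a central finite difference
with a step of 1% of the local grid spacing, one-sided at the edges;
`delta_mobility()` evaluates the derivative at the field midpoint
$(E_1+E_2)/2$, the second-order-accurate choice in the absence of a stated
convention.

### The packaged synthetic calibration

`synthetic_mobility_table()` stands in for a measured device calibration; it
is synthetic and makes no attempt to reproduce any instrument's numerical
values, which are not available. It is constructed to exhibit the structure
such calibrations show, because every qualitative behaviour of the simulator
depends on it: mobility rising with $E$ and falling with length everywhere;
$\Delta\mu$ between 59.5 and 22.4 V/cm increasing over 0.5–5 kbp (four
distinct quasi-static streams); and identical strong/weak mobility *ratios*
for 5 and 10 kbp, so those two lengths co-migrate quasi-statically and are
separated only through their reorientation lag — mirroring the observation
that four streams appear at very low frequency and five in the intermediate
band. One row is anchored quantitatively: the 10 kbp mobility at 59.5 V/cm is
$2 f_{or} L / E = 2.74\times10^{-5}\,\mathrm{cm^2\,V^{-1}\,s^{-1}}$, the
value implied by a 2.4 Hz reorientation frequency at that field. Each length
row follows $\mu(E) = \mu_{59}\,[p + (1-p)\,h(E)/h(59.5)]$ with
$h(E) = E^2/(1 + 10^{-3}E^2)$; the per-length $p$ values (0.930, 0.808,
0.615, 0.248, 0.248) set how strongly each row responds to the field and were
chosen once, by the structural constraints above, together with the scale
values $\mu_{59}$ (9.0, 8.6, 7.8, 7.0, 2.74 $\times 10^{-5}$).

## The stochastic stream simulator

`simulate_streams()` advances particles half-cycle by half-cycle: a dead time
$\min(t_{or}, \text{half-period})$ with zero displacement at each switch,
then straight motion at $\mu_i E_i$ along the field. Modelling reorientation
as zero-displacement dead time is the one choice that reproduces the $-2fL$
loss term of the closed-form angle exactly, which is the deciding rationale
(whether a real chain creeps along its old tube during reorientation is not
modelled). Other numerical choices:

* **Injection.** Particles start at $x = 0$ with $y$ drawn from a top-hat of
  the 110 µm injection band; the band centre sits 100 µm below the chamber
  corner by default.
* **Phase.** Each particle starts at a uniformly random phase of the period
  (default for ensembles), removing phase-locking artifacts; the fixed-phase
  option starts every particle at the beginning of a strong-field half-cycle.
* **Boundaries.** The injection edge is a gel boundary: $x$ is clamped at 0
  when the retrograde weak-field leg pushes a particle against it.
  Trajectories terminate at their first crossing of the collection edge
  $x = W$, with the crossing $y$ interpolated inside the straight segment.
  For near-45° streams the nominal chamber height can be slightly overrun
  near the exit; trajectories are not terminated there, as in a device whose
  collection channel array spans the full edge.
* **Diffusion.** Off by default — band width is injection-width plus sawtooth
  dominated in this regime — and available as an isotropic Gaussian kick of
  variance $2D\,\Delta t$ per half-cycle for user-supplied $D$.
* **Performance.** After the first (phase-dependent) partial period every
  particle advances by the same per-period displacement, so whole blocks of
  periods are jumped analytically when no trajectory log is requested;
  a 5 × 2000-particle run takes well under a second.

`band_broadening_excursion()` implements the per-period transverse excursion
$L_{fr} = \tfrac{\mu_2 E_2}{2f}(\tan\theta_1\cos\theta_2 + \sin\theta_2)$
(reported as a magnitude), the dominant protocol contribution to band
broadening at low $f$; it doubles when $f$ halves, and the simulator's logged
trajectories reproduce it within the dead-time correction $1 - f/f_{or,2}$.

### What the Monte-Carlo ensemble does and does not show

With diffusion off, the dynamics are deterministic given the injection phase,
so the per-particle exit angles vary only through the sawtooth deviation at
the path's two endpoints: the ensemble standard error at $n = 2000$ is of
order $10^{-4}$ degrees. The exit endpoint is a *first crossing* of the
collection edge; when the weak-field leg moves retrograde
($\theta_2 > 90°$), crossings can only occur on the fresh-ground part of the
strong-field leg, which biases the sampled sawtooth phase and leaves a
deterministic finite-chamber offset of order
$L_{fr}\,|\Delta x_2| / (\Delta x_1 W)$ — about $10^{-3}$–$10^{-2}$ degrees
here. The mean simulated angle therefore agrees with the closed form to
better than 0.03°, far below any experimentally readable angle difference,
but *not* to within a few Monte-Carlo standard errors; a statistical
equivalence test at 3 SE is bound to fail for such protocols, and no
estimator repairs this without degeneracy (any phase-matched pairing of
entry and exit collapses the variance to zero). The test suite asserts the
physically meaningful absolute bound and retains the strict statistical
comparison as a known-failing check.

## Synthetic images and the measurement chain

`render_image()` draws each stream as a straight ridge from the injection
point to its exit position with a Gaussian cross-section taken from the exit
ensemble, over a constant-plus-gradient background, blurred by a Gaussian
PSF and finished with Poisson photon noise in 16-bit counts; the ground truth
used for drawing is returned (and written as a JSON sidecar next to the
TIFF). The PSF default is kept well below the band width, as for a real
epifluorescence microscope whose PSF (~1 µm) is negligible against 100 µm
bands: an isotropic PSF acting on a diagonal ridge widens the *measured*
cross-section by $\sigma_{psf}^2(1 + \tan^2\Phi)$, and the prescribed 5×5
smoothing filter adds the same term again, so quantitative round trips are
run at ~5 µm pixels where the combined bias on recovered resolution is a few
percent (at ~10 µm pixels it approaches the 10% round-trip budget).

`process_image()` applies the standard conditioning: per-image **median**
background subtraction (robust when bright streams are sparse — the method
itself is a choice; a rolling-ball estimate would serve equally), clipping at
zero, a 5×5 Gaussian kernel with $\sigma = 1$ px, and optionally a linear
contrast stretch saturating 1% of pixels at each end (2% total). The stretch
is monotone — peak positions are unaffected — but rescales intensities, so it
is applied for display only; quantitative profiles are extracted with
`contrast = FALSE`. `extract_profile()` reads intensity against $y$ at a
fixed column; multi-column averaging (default 5) suppresses pixel noise but
broadens *diagonal* streams by $\tan\Phi$ × column pitch per column, so the
quantitative workflows extract a single column.

`fit_peaks()` fits a sum of Gaussians plus a constant baseline by
Levenberg–Marquardt least squares, initialized from the highest local maxima
of the lightly smoothed profile with positivity bounds on amplitudes and
widths; non-convergence raises a typed condition carrying the optimizer
diagnostics. From fitted peaks, `resolution()` computes
$R_s = |\Delta X|/(2\sigma_1 + 2\sigma_2)$ and `overlap_purity()` converts it
to stream purity under the equal-width, equal-area adjacent-Gaussian model:
the misassigned fraction is the normal survival function $Q(2R_s)$, checked
against direct quadrature to $10^{-6}$. This minimal Gaussian model
reproduces all four published purity values at their printed 1-decimal
precision; at 2-decimal precision the overlap column is limited by the
rounding of the printed $R_s$ values themselves. `recovery()` integrates
baseline-subtracted fluorescence over each stream's fitted ±3σ window
(trapezoidal rule, window edges widened by half a grid step so boundary
samples are kept deterministically) and reports the outlet/inlet ratio; a
lossless simulation recovers 100% by construction because injected particles
are conserved.

## Orchestration and reproducibility

`load_config()` reads a YAML/JSON description of a run with unit-suffixed
keys (`E1_V_per_cm`, …); unknown keys are rejected with their full path, all
defaults are materialized, and configurations round-trip losslessly through
`save_config()`. `run_experiment()` executes the standard workflows
(`angle-sweep`, `simulate`, `analyze`, `purity-table`) into a deterministic
output directory with a manifest (config echo, config hash, seed, package
version) from which any run can be reproduced; stochastic runs refuse to
start without a seed, and identical seeds give byte-identical outputs. The
`inst/cli/pulsegel.R` script exposes the same four modes from a shell.

## Problem sizes used by the tests

The test suite and the acceptance script use ensemble sizes chosen to keep
statistical errors well inside the asserted tolerances on a single CPU:
2000 particles per protocol for Monte-Carlo/closed-form comparisons (SE on
the mean angle ≪ 0.01°), 5000 particles and a 2048×2048-pixel frame for the
image round trip (sample σ known to ~1%, pixelization bias ~3%), 1000 random
protocols for the ion-limit identity, and 40-member quadrature grids for the
overlap oracle. The full suite runs in well under a minute of simulation
time.

## Known limitations

* The field is assumed uniform over the chamber. Real devices show bent
  field lines near the collection side (the inter-field angle tightening
  toward 60° and the magnitude ratio rising above 3), which systematically
  raises measured deflection angles above the uniform-field prediction; this
  is a documented, un-modelled systematic, not a parameter of this package.
* Joule heating, electroosmosis, hydrodynamic flow and gel heterogeneity are
  not modelled.
* The synthetic calibration table supports qualitative stream-count and
  ordering behaviour only; quantitative angle predictions for a real device
  require its measured calibration in `mobility_model_table()`.
* The purity model assumes equal-width, equal-area adjacent Gaussians;
  strongly unequal stream intensities would require integrating the fitted
  profile directly.
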