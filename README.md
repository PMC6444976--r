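# pulsegel

Physical model and simulator for **continuous-flow fractionation of
sub-10-kbp DNA in agarose under orthogonal pulsed electric fields**, with the
complete downstream measurement chain (image conditioning, line profiles,
Gaussian peak fitting, resolution, purity and recovery).

It is aimed at microfluidic-separation researchers who want to explore
voltage/frequency protocols for a gel-filled deflection chamber before (or
alongside) running a device: given a mobility calibration
$\mu(E, L)$ and a field protocol, the package predicts where each fragment
stream lands on the collection edge, how broad it is, and how clean the
collected fractions are.

## The model

Two alternating transverse fields — a strong field $E_1$ at angle $\theta_1$
from the x axis and a weak field $E_2$ at $\theta_2$, switched at frequency
$f$ — drive DNA through the gel. A reptating chain of contour length $L$
needs $t_{or} = L/(\mu E)$ to realign after each switch (reorientation
frequency $f_{or} = \mu E / 2L$), which removes $2fL$ from its displacement
per unit time in each field. The migration angle is the time-weighted vector
sum

$$\Phi = \operatorname{atan2}\big(v_1 \sin\theta_1 + v_2 \sin\theta_2,\;
v_1 \cos\theta_1 + v_2 \cos\theta_2\big), \qquad
v_i = \max(\mu_i E_i - 2 f L,\ 0),$$

which separates fragments by length through two mechanisms: the
length-dependent mobility gain $\Delta\mu = \frac{d\mu}{dE}(E_1 - E_2)$ at
low $f$, and the length-dependent reorientation clamp ($v_2 \to 0$) at
intermediate $f$. Non-reptating ions follow the mobility-free limit
$\Phi_0 = \operatorname{atan2}(E_1\sin\theta_1 + E_2\sin\theta_2,\,
E_1\cos\theta_1 + E_2\cos\theta_2) > \Phi$, so small ionic species stream
away from all DNA fractions. Separation quality is quantified by
$R_s = |\Delta X| / (2\sigma_1 + 2\sigma_2)$ between adjacent streams, stream
purity $100 - 100\,Q(2R_s)$ under a Gaussian overlap model, and recovery as
the outlet/inlet ratio of integrated, baseline-subtracted fluorescence.

A stochastic sawtooth simulator propagates particle ensembles through the
chamber (dead time at each switch, straight migration between, optional
diffusion), renders synthetic 16-bit fluorescence micrographs with known
ground truth, and the analysis chain recovers stream positions and widths
from those images. See the vignette
(`vignettes/pulsed-field-deflection.Rmd`) for the full account of the model,
its numerical choices and its limitations.

## Worked example

Five fragment sizes under the high-resolution protocol (59.5 and
22.4 V cm⁻¹, 25°/115°, 2 Hz), using the packaged synthetic mobility
calibration:

```r
library(pulsegel)
model    <- builtin_mobility_model()
chamber  <- chamber_spec()
protocol <- field_protocol(59.5, 22.4, theta1_deg = 25, theta2_deg = 115,
                           f_Hz = 2)

for (L in c(500, 1000, 2000, 5000, 10000)) {
  d <- migration_angle(protocol, fragment_spec(L), model = model)
  cat(sprintf("%-8s phi = %5.2f deg  [%s]\n",
              fragment_spec(L)$label, d$phi_deg, d$regime))
}
cat(sprintf("fluorescein (ion) angle: %.2f deg\n", ion_angle(protocol)))
```

```
0.5 kbp  phi = 44.45 deg  [field_dependent_mobility]
1 kbp    phi = 42.58 deg  [field_dependent_mobility]
2 kbp    phi = 39.02 deg  [field_dependent_mobility]
5 kbp    phi = 28.51 deg  [field_dependent_mobility]
10 kbp   phi = 25.00 deg  [switchback_window]
fluorescein (ion) angle: 45.63 deg
```

Five distinct streams: the 0.5–2 kbp fragments are spread by their
field-dependent mobility, while the 10 kbp fragment sits in the switchback
window and is clamped onto the strong-field direction (25°). The ion angle
is steeper than every DNA stream, i.e. the contaminant fraction separates
cleanly. Simulating 2000 particles per fragment and analysing a rendered
micrograph of the run:

```r
sim <- simulate_streams(protocol, c(500, 1000, 2000, 5000, 10000),
                        chamber, model, n_particles = 2000, seed = 1)
print(sim)

img   <- render_image(sim, chamber = chamber, noise_seed = 2)
proc  <- process_image(img$image, contrast = FALSE)
prof  <- extract_profile(proc, line_position_px = ncol(proc) - 1L,
                         averaging_width_px = 1, um_per_px = img$um_per_px_y)
peaks <- fit_peaks(prof, n_peaks = 5)
separation_report(peaks, chamber = chamber)
```

```
<stream_simulation> 5 fragment(s) x 2000 particles, f = 2 Hz, seed = 1
  0.5 kbp  exit y =   9910.1 +/-  32.2 um   angle =  44.45 deg   collected 2000/2000
  1 kbp    exit y =   9290.9 +/-  31.5 um   angle =  42.58 deg   collected 2000/2000
  2 kbp    exit y =   8202.9 +/-  32.0 um   angle =  39.02 deg   collected 2000/2000
  5 kbp    exit y =   5531.2 +/-  32.1 um   angle =  28.51 deg   collected 2000/2000
  10 kbp   exit y =   4762.0 +/-  31.6 um   angle =  25.00 deg   collected 2000/2000
<separation_report>
   pair   Rs overlap_pct purity_pct
 1 vs 2  5.6           0        100
 2 vs 3 19.2           0        100
 3 vs 4  7.8           0        100
 4 vs 5  4.4           0        100
deflection angles (deg): 24.96, 28.47, 38.97, 42.54, 44.41
```

Exit-band widths (~32 µm s.d.) stay at the injection-band value
(110 µm top-hat, s.d. 31.8 µm): band broadening at 2 Hz is negligible, so
the streams are baseline-resolved ($R_s > 4$) under this synthetic
calibration. The Monte-Carlo mean angles match the closed-form predictions
to better than 0.01°.

## Command line

```sh
Rscript inst/cli/pulsegel.R --config run.yaml --mode simulate --out results/
```

Modes: `angle-sweep` (deflection spectra over a frequency grid), `simulate`
(particle ensembles, exit samples and profiles), `analyze` (adds the
rendered image and the separation report), `purity-table` (resolution →
overlap/purity table). Configurations are YAML with unit-suffixed keys; a
minimal one:

```yaml
protocol:
  E1_V_per_cm: 59.5
  E2_V_per_cm: 22.4
  theta1_deg: 25
  theta2_deg: 115
  f_Hz: 2
fragments: [500, 1000, 2000, 5000, 10000]
simulation:
  seed: 42
```

Every run writes a `manifest.json` (configuration echo, hash, seed, package
version) from which it can be reproduced exactly.

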