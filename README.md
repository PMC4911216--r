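# cortexmap

Tools for modelling and analysing the joint layout of orientation
preference (OP) and ocular dominance (OD) maps in primary visual cortex.

In cats and monkeys, neurons in V1 are selective both for stimulus
orientation and for the eye of origin, and both preferences are laid out
as smooth, quasi-periodic cortical maps with a stereotyped relationship:
OP pinwheels — point singularities where all orientations meet — normally
sit near the centres of OD columns. Dimension-reduction models predict
that this relationship is experience-dependent: if each eye is exposed
predominantly to one orientation (orthogonal between the eyes,
"cross-rearing"), pinwheels should shift towards the OD borders. This
package implements the computational machinery for studying that
prediction end to end:

- an annealed **elastic-net simulator** of joint OP/OD development. Each
  cortical node carries a 5-vector y (retinotopy, ocularity, orientation
  double-angle vector); training features x form a grid (20×20 positions ×
  ocularity ±0.05 × 6 orientations of radius 0.08, i.e. 4800 points); the
  energy at annealing scale K is

      E = −K Σᵢ αᵢ log Σⱼ exp(−‖xᵢ−yⱼ‖²/2K²) + (β/2) Σ⟨jk⟩ ‖yⱼ−yₖ‖²

  with β = 10 and K annealed from 0.2 by ×0.9925 per iteration down to
  0.0358 (229 iterations). Cross-rearing is a coverage weight α > 1 on the
  (left eye, 0°) and (right eye, 90°) features.
- **map statistics**: pinwheel detection by ±180° winding number, map
  wavelength Λ from the Fourier spectrum, the dimensionless pinwheel
  density ρ = (pinwheels/pixel)·Λ² (theory: π), a 5-bin OD quintile
  histogram of pinwheel positions (column centre → border), orientation
  proportions with fixed-period (90°/180°) sine fits, and OP/OD contour
  crossing angles (sine-distributed null).
- **ESD map extraction** from intrinsic-signal imaging stacks: frame
  alignment, condition averaging, band-pass filtering, composition of
  OP/OD map stacks, single-shift extended spatial decorrelation
  (whitening + shifted-cross-covariance rotation, Δr = (5,5) px), and
  template-based source selection — plus the classical vector-average
  readout as a baseline.
- **single-unit tuning models**: von Mises orientation tuning, skewed
  log-Gaussian spatial/temporal frequency tuning, Naka–Rushton contrast
  response, monocularity index, interocular orientation difference.
- seed-deterministic **synthetic generators** for ground-truth maps,
  imaging stacks (hemodynamic kernel, vessel artifacts, drift, noise) and
  unit populations, so every stage is tested against known answers.

## Worked example

```r
library(cortexmap)

## control map development at the reference configuration (~45 s)
maps <- extract_maps(run_simulation(sim_config(seed = 1, alpha_over = 1)))
st <- map_statistics(maps$op, maps$od)
cat(sprintf("pinwheels %d | wavelength %.2f px | density %.3f\n",
            st$n_pinwheels, st$wavelength, st$pinwheel_density))
cat("pinwheel OD-bin proportions (centre -> border):",
    sprintf("%.2f", st$od_bin_proportions), "\n")

## cross-reared development from the same seed
maps5 <- extract_maps(run_simulation(sim_config(seed = 1, alpha_over = 5)))
st5 <- map_statistics(maps5$op, maps5$od)
cat("alpha = 5 OD-bin proportions:",
    sprintf("%.2f", st5$od_bin_proportions), "\n")
d <- pinwheel_displacement(attr(st5, "pinwheels"), attr(st, "pinwheels"),
                           st$wavelength)
cat(sprintf("matched pinwheel displacement: %.2f wavelengths\n",
            d$mean_displacement))
```

prints

```
pinwheels 112 | wavelength 21.76 px | density 3.236
pinwheel OD-bin proportions (centre -> border): 0.48 0.17 0.12 0.12 0.11
alpha = 5 OD-bin proportions: 0.10 0.30 0.22 0.18 0.19
matched pinwheel displacement: 0.27 wavelengths
```

Under normal rearing the density is close to the predicted π ≈ 3.14 and
nearly half the pinwheels lie in the OD-column-centre bin (0.2 would be
chance). With the over-representation at α = 5, the centre bin collapses
(0.48 → 0.10) and matched pinwheels have moved about a quarter of a map
wavelength: the modelled signature of cross-rearing.

The imaging side runs the same way from synthetic ground truth:

```r
truth <- synth_maps("parametric", seed = 5, size = 96, wavelength = 24)
stack <- synth_stack(truth, stack_recipe(), seed = 7)  # 30-trial protocol
rec <- esd_extract_maps(stack, final_lp_sigma = 3)
map_cor(rec$op$field[21:76, 21:76], truth$op$field[21:76, 21:76])
```

which recovers the planted OP map with |r| ≈ 0.99 despite 10% per-trial
pixel noise, vessel artifacts and illumination drift.

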