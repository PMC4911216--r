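---
title: "Modelling and measuring OP/OD map relationships"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring OP/OD map relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
elastic-net model of joint orientation-preference (OP) and
ocular-dominance (OD) map development, the statistics that quantify the
spatial relationship between the two maps, the blind-source-separation
pipeline that recovers maps from intrinsic-signal imaging stacks, the
single-unit tuning models, and the synthetic-data generators that give
every stage a test bed with known answers.

## The elastic net as a model of map development

Primary visual cortex lays out at least five stimulus dimensions on a
two-dimensional sheet: retinotopic position (2), ocularity (1), and
orientation preference encoded as a double-angle vector (2). The elastic
net treats development as a trade-off between *coverage* (every stimulus
feature should have cortex responding to it) and *continuity* (neighbouring
cortical points should prefer similar features). Each cortical node $j$
carries a 5-vector $\mathbf{y}_j$; each training feature $i$ is a 5-point
$\mathbf{x}_i$ on a Cartesian grid: $n_x \times n_y$ retinotopic positions
in the unit square $\times$ two ocularity values $\pm d$ $\times$ $n_\theta$
orientations at angles $\theta$ spaced evenly on $[0^\circ, 180^\circ)$,
encoded as $(r\cos 2\theta, r\sin 2\theta)$. The reference configuration is
$20 \times 20 \times 2 \times 6 = 4800$ features, $d = 0.05$, $r = 0.08$,
on a $128 \times 128$ sheet.

The energy at annealing scale $K$ is

$$E = -K \sum_i \alpha_i \log \sum_j
      e^{-\|\mathbf{x}_i-\mathbf{y}_j\|^2 / 2K^2}
      + \frac{\beta}{2} \sum_{\langle jk \rangle}
      \|\mathbf{y}_j-\mathbf{y}_k\|^2,$$

with $\beta = 10$, the edge sum over the non-periodic 4-neighbour lattice
(free boundary: missing neighbours are simply absent), and per-feature
coverage weights $\alpha_i$. **Cross-rearing** — rearing through
cylindrical lenses that expose the left eye mostly to horizontal and the
right eye mostly to vertical contours — is modelled by
$\alpha_i = \alpha > 1$ for the (left eye, $0^\circ$) and (right eye,
$90^\circ$) features and $\alpha_i = 1$ otherwise.

### The update step

Differentiating $E$ with responsibilities
$p_{ij} = \operatorname{softmax}_j(-\|\mathbf{x}_i-\mathbf{y}_j\|^2/2K^2)$
held fixed gives the stationarity condition

$$\bigl(\operatorname{diag}(w) + \beta K L^+\bigr)\,Y^{\text{new}}
  = P^{\top}\operatorname{diag}(\alpha)X, \qquad
  w_j = \textstyle\sum_i \alpha_i p_{ij},$$

where $L^+$ is the positive-semidefinite graph Laplacian. One call to
`elastic_net_step()` recomputes the responsibilities (with a per-feature
log-sum-exp shift, since $K$ shrinks 5.6-fold over a run) and jumps to the
solution of this SPD system (Jacobi-preconditioned conjugate gradients on
the 5-point stencil, warm-started, relative residual $10^{-12}$). This
implicit fixed-point step is the form used by the established cortical-map
elastic-net implementations. The textbook explicit step
$y \mathrel{+}= \Delta y$ is *not* usable at these parameters: the
continuity term alone has explicit-Euler amplification factor
$|1 - \beta K \lambda_{\max}(L^+)| \approx 15$ at $K_0$, and the checkerboard
mode diverges. The implicit step has the same fixed points, decreases $E$
monotonically (the EM/majorise–minimise argument; the suite verifies this
against a direct implementation of the energy), and is unconditionally
stable. Because responsibilities factorise over the feature grid's
Cartesian structure (the Gaussian separates over the retinotopic and
ocularity/orientation blocks), the package evaluates them by an exact
Kronecker factorisation — identical to the dense computation to machine
precision (also under test) and about five times faster.

### Annealing, symmetry breaking, and perturbation maintenance

`run_simulation()` performs one step per $K$ value, starting at
$K_0 = 0.2$ and multiplying by $0.9925$ each iteration until
$K \le 0.0358$ — 229 iterations. Map formation is a sequence of
symmetry-breaking bifurcations: above a critical $K$ the ocularity and
orientation components of the symmetric (unformed) state are linearly
stable and any perturbation decays; below it they grow to saturation. At
$128 \times 128$ both the OP and the OD instabilities switch on within the
last third of the schedule (we verified growth of seeded finite kicks at
$K = 0.045$ and $K = 0.0358$), so the run terminates *shortly after the
maps have formed* — the property the termination point was chosen for.

Numerically, however, a double-precision simulation that merely seeds
noise at $t = 0$ never forms maps: the pre-bifurcation contraction squashes
the $0.005$/$0.008$-amplitude initial perturbations to the $10^{-18}$
round-off floor, and the $\sim\!70$ post-bifurcation iterations cannot
amplify 16 orders of magnitude. `run_simulation()` therefore *maintains*
the perturbation: after each step, any component (ocularity; orientation)
whose rms is still below the rms of its seeded injection gets a fresh
seeded uniform perturbation. While a component is pinned to the symmetric
saddle this keeps it at constant small amplitude; the moment the
instability lifts it off, its rms exceeds the threshold and injection
stops for good. This is the standard deterministic-annealing remedy for
saddle points; it is seed-deterministic, and it leaves the formed maps
untouched (injection is inert after liftoff).

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 0.05 | ocularity half-separation (feature units) |
| `r` | 0.08 | orientation vector radius; sets saturated selectivity |
| `beta` | 10 | continuity weight |
| `K0`, `decay`, `K_end` | 0.2, 0.9925, 0.0358 | annealing schedule (229 steps) |
| `alpha_over` | 1 | coverage over-representation; 1 = control, 3–5 = cross-reared |
| `od_noise`, `op_noise` | 0.005, 0.008 | seeded perturbation amplitudes |
| `width`, `height` | 128 | cortical sheet size |

The schedule, grid sizes, $d$, $r$, $\beta$ and the $\alpha$ convention are
the reference study conditions; the perturbation amplitudes are the
conventional "small symmetric noise" choice (a few per-cent of $d$, $r$).

## Map statistics

**Pinwheels** are point singularities of the OP field. For every interior
pixel the orientation difference between consecutive pixels of its closed
8-neighbour loop is wrapped into $(-90^\circ, 90^\circ]$ and summed; the
total is $\pm 180^\circ$ exactly when the loop encloses a field zero
(winding number $\pm\tfrac12$), and 8-connected clusters of flagged pixels
are merged into one pinwheel at their centre of mass. The statistic is
topological, so detection is exact up to zeros sitting on pixel borders.

**Map wavelength** $\Lambda$ is the power-weighted mean wavelength of the
mean-subtracted complex field: each Fourier component contributes its
wavelength $1/|f|$ weighted by its power, pooling all directions (DC and
super-Nyquist frequencies excluded). A plane wave returns its exact
wavelength; an equal-power mixture of 8 px and 12 px waves returns 10 px.
We note the alternative reading — the reciprocal of the power-weighted
mean *frequency* — gives systematically shorter wavelengths on broadband
maps; the mean-wavelength form is the one under which control simulations
reproduce the theoretically predicted pinwheel density (below).

**Pinwheel density** $\rho = (n_{\text{pw}} / n_{\text{px}})\,\Lambda^2$
is dimensionless; for quasi-periodic orientation maps theory predicts
$\rho = \pi$. Control simulations here give $\rho \approx 3.0$ (three
seeds), within 5% of $\pi$.

**OD quintile localisation.** The positive and negative OD pixels are
*separately* ranked by $|OD|$ and split into five equal-count bins, then
pooled: bin 1 = strongest fifth of each eye (column centres), bin 5 =
closest to the border. Treating the eyes separately respects OD borders
and tolerates a contralateral bias. Bins are equal-area within one pixel,
so uniformly placed pinwheels land 0.2 in each bin — the null the suite
checks by $\chi^2$ at $n = 10^4$. Under control rearing pinwheels pile
into bin 1 (proportion $\approx 0.5$); with $\alpha = 5$ the centre bin
drops below the control value while matched pinwheels move by
$\sim 0.25\,\Lambda$ — the modelled signature of cross-rearing.

**Orientation proportions and sine fits.** Preferred orientations are
binned into eight $22.5^\circ$ bins (edges at $0, 22.5, \dots$;
left-closed; $180^\circ \equiv 0^\circ$). Fixed-period sine curves
$A\sin(2\pi(\theta-\phi)/P) + C$ with $P = 90^\circ$ (cardinal bias,
normal rearing) or $P = 180^\circ$ (single-orientation bias per eye,
cross-rearing) are linear in a sin/cos basis and fitted by least squares;
$r^2$ is the squared correlation of data and fit, and reporting both
periods supports the model comparison used for populations of units.

**Crossing angles.** The OD zero contour and the OP iso-orientation
contours at $0, 22.5, \dots, 157.5^\circ$ are extracted by marching
squares on the doubled-angle field (avoiding the $0/180$ wrap); at every
polyline intersection the absolute tangent-orientation difference is
folded into $[0^\circ, 90^\circ]$. For unrelated maps transversal
crossings are length-biased by the sine of the angle, so the null density
is $\propto \sin$ — verified by $\chi^2$ over pooled synthetic map pairs.
Tangents are taken from adjacent polyline vertices without smoothing.

## Recovering maps from imaging stacks

The imaging protocol acquires 50 frames at 5 Hz per trial (10 s), with the
grating visible during frames 11–35 (2–7 s); 16 drift directions per eye
plus blanks, each presented at least 30 times. The pipeline:

1. **Alignment** — exhaustive integer-shift search (±10 px) maximising
   correlation with a reference frame; vacated pixels take the frame mean.
2. **Condition averaging** — opposite drift directions pooled
   ($\theta = $ direction mod $180^\circ$), trials averaged pixel-wise:
   50-frame stacks for 8 orientations × 2 eyes.
3. **Band-pass** — subtract a $\sigma = 20$ px Gaussian blur (illumination
   changes), apply a $\sigma = 2$ px blur (the decorrelation step needs
   smooth sources), flip sign (reflectance decrease = activity). The blur
   renormalises its truncated kernel at the image boundary, so constants
   high-pass to exactly zero; away from edges this matches zero-padding,
   and analyses crop the boundary zone anyway.
4. **Composition** — frame-wise
   $\mathrm{re}(OP) = \sum_\theta \bar R_\theta \cos 2\theta$,
   $\mathrm{im}(OP) = \sum_\theta \bar R_\theta \sin 2\theta$,
   $OD = \sum_\theta (R_{\theta,R} - R_{\theta,L})$, with $\bar R_\theta$
   the two-eye mean (binocular) or a single eye's response (monocular).
5. **Single-shift spatial decorrelation** — frames centred, whitened by
   eigendecomposition of the frame covariance, then rotated by the
   eigenvectors of the symmetrised cross-covariance between the whitened
   frames and their copies shifted by $\Delta r = (5,5)$ px (computed over
   the overlap region only). Sources with distinct spatial autocorrelation
   at that lag separate; the rotation is orthogonal and the result is
   deterministic up to per-source sign.
6. **Selection and readout** — each source's coefficient time series
   (pre-stimulus mean over frames 1–10 subtracted) is scored by
   correlation with a rise-to-plateau template (ramp over frames 11–20,
   plateau to frame 35, linear decay after). A dominant stimulus-locked
   signal leaks its time course weakly into every source's
   coefficients, and a single spatial shift cannot resolve rotations
   within a subspace of sources sharing one shifted autocorrelation —
   so rather than betting on a single best score, the map is
   reconstructed from *all* sources passing the 0.6 threshold, each
   weighted by its coefficient plateau (mean over frames 31–35). The
   weighting is invariant to the arbitrary per-source signs, reduces to
   the classical single-source readout when only one source qualifies,
   and made planted-map recovery robust across seeds where
   single-source selection was erratic. If no source passes, a manual
   index is requested. The reconstruction is averaged over the final
   stimulus frames and low-pass filtered.

One numerical guard matters: whitening amplifies *every* retained
covariance component to unit variance. Components that merely sample the
flat noise floor of the eigenvalue spectrum carry no source structure,
and the finite-sample rotation mixes them straight into the signal source
(in our experiments recovery fell from $|r| = 0.99$ to $0.2$ without the
guard). `esd_unmix()` therefore drops components below 10× the median
eigenvalue before rotating, reporting how many. The final low-pass is a
denoiser ("remove remaining high-frequency noise, minimise distortion"):
round-trip checks use $\sigma = 0$ on noiseless stacks and $\sigma = 3$ px
at the synthetic 24 px map wavelength — the analogue of $\sigma = 12$ px
at the experimental scale.

The classical vector-average readout (`vector_average_baseline()`) is kept
as the comparison baseline: without source separation, structured
artifacts map straight into its estimates, and the suite checks that its
recovery degrades faster than ESD's as vessel-artifact amplitude grows.

## Single-unit tuning models

Responses to opposite drift directions are averaged before fitting.

- Orientation: $R(\theta) = R_p e^{k(\cos 2(\theta-\theta_p) - 1)} + R_0$,
  bandwidth = FWHM, numerically; $\theta_p$ identified by multi-start over
  eight phase offsets (the model is $180^\circ$-periodic in $\theta_p$).
- Spatial/temporal frequency:
  $R(f) = R_p \exp\!\bigl(-(\log(f/f_p)/(k + \lambda\log(f/f_p)))^2\bigr) + R_0$
  — a log-Gaussian skewed by $\lambda$ (symmetric at $\lambda = 0$);
  the same code path serves cycles/degree and Hz; bandwidth in octaves,
  numerically. $\lambda$ is bounded to $\pm 0.55$ so the denominator stays
  positive across the tested frequency range.
- Contrast: $R(c) = R_m c^n/(c^n + \sigma^n) + R_0$; fits with
  $\sigma$ beyond the largest tested contrast are flagged non-saturating
  for exclusion.
- $MI = |R_R - R_L|/(R_R + R_L)$; $\Delta OP$ = right minus left preferred
  orientation wrapped to $(-90^\circ, 90^\circ]$.

All fits are bounded nonlinear least squares (`minpack.lm::nlsLM`,
multi-start, `ftol` $10^{-10}$); noiseless synthetic
curves are recovered to at least four digits, and at 10% response noise
the median preferred-orientation error over 200 replicates is well under
$3^\circ$.

## Synthetic data: what it emulates, and what it does not

`synth_maps()` (parametric mode) builds OP maps as complex Gaussian noise
band-pass filtered on an annular spectrum at $1/\Lambda$ — smooth,
quasi-periodic, pinwheel-rich fields — and OD maps as independent real
band-pass noise. A coupling parameter adds a constant-phase complex bias
whose amplitude depends on $|OD|$: zeros of the field survive where the
bias vanishes, steering pinwheels towards OD centres (coupling > 0) or
borders (< 0) for validating the localisation statistic. `synth_stack()`
inverts the composition: each pixel responds with an untuned plus a
selectivity-weighted tuned component,
$\tfrac12(1 + s\cos 2(\theta - OP))$, scaled by a smooth ocularity weight
$(1 \pm \tanh(g\,OD))/2$; reflectance decreases by gain × amplitude × a
piecewise-linear hemodynamic kernel (0.6 s latency, 2 s rise, plateau to
offset, exponential decay); dark curvilinear vessel artifacts (Gaussian
profile along random walks) jitter independently per frame; a slow
sinusoidal illumination drift and white pixel noise complete the frame.
`synth_units()` draws preferred orientations from sine-modulated
densities (period $90^\circ$ for control, $180^\circ$ per eye for
cross-rearing), monocularity from Beta distributions matched to the
reported medians (0.24 control, 0.38 cross-reared), and emits noisy
curves on the standard stimulus grids.

What passing tests therefore show: the estimators are unbiased and
mutually consistent on data generated *by these models*. What they do not
show: robustness to anatomy-realistic vasculature, non-stationary
hemodynamics, eye movements beyond rigid translation, or electrode
sampling biases — none of which the generators attempt.

## Numerical choices and degenerate inputs

- Responsibilities via log-sum-exp shifts; never a division by zero.
- CG solves to relative residual $10^{-12}$, warm-started; $\beta = 0$
  reduces to an exact diagonal solve.
- Winding tolerance $10^{-6}$ degrees on the $\pm 180^\circ$ total;
  matching ties broken by distance then index; displacement matching
  capped at $\Lambda/2$, same-sign pairs preferred.
- Quintile ties broken by first occurrence (bins stay equal-area).
- Flat tuning curves return $k \to 0$ flagged unselective; all-zero
  stacks, one-signed OD maps, empty masks and missing conditions raise
  informative errors.
- Maps are stored as plain TSV matrices plus JSON metadata
  (`write_maps()`/`read_maps()`).

## Problem sizes in the test suite

The suite runs the elastic net at the full reference configuration
(128 × 128, 4800 features, 229 iterations) for three control seeds and two
cross-reared strengths, imaging round trips at 96 px with 30-trial
averaged stacks, 200-replicate tuning recovery, and $10^4$-placement
nulls. These sizes were chosen so the whole battery completes in minutes
while every quantitative claim above is exercised at the conditions it
refers to.

## Known limitations

- The perturbation-maintenance schedule makes formation timing (hence the
  degree of post-formation maturation) depend mildly on the injection
  amplitudes; pinwheel density is stable across seeds but sits a few
  per-cent below $\pi$, as expected for maps annealed briefly past
  formation.
- Crossing-angle tangents are unsmoothed; on coarse grids individual
  angles quantise.
- The ESD noise-floor guard assumes a flat eigenvalue bulk; pathological
  spectra (e.g. strongly coloured pixel noise) may require setting
  `bulk_factor` manually.
- Monocular OP modes reuse the binocular OD composition; truly monocular
  OD stacks are out of scope.
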