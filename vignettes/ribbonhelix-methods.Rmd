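---
title: "Models and methods behind ribbonhelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribbonhelix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonhelix)
```

`ribbonhelix` analyses twisted-ribbon (nanohelix) assemblies of short
amphiphilic peptoids: a width-selection free-energy model, a coordinate
builder and twist order parameter, synthetic trajectory and AFM-like
image generators, morphometric estimators, and lamellar-spacing
bookkeeping. This vignette records the science and the design decisions
in one place.

## The width-selection model

A ribbon is a bilayer of parallel peptoid chains, `N` columns across its
width. Two opposing contributions set the preferred `N`:

* burying hydrophobic faces between adjacent columns is favourable and
  proportional to the buried fraction, giving an interfacial term
  $-\kappa\,(1 - 1/N)$ per monomer (a lone column buries nothing; the
  buried fraction saturates as $N \to \infty$);
* a uniform twist shears the stacking between columns by an angle that
  grows linearly with distance from the mid-line, and a harmonic
  dispersion penalty averaged across the width gives
  $+(\phi^2/24)(N^2 - 1)$ per monomer, where $\phi$ is the shear angle
  accumulated per inter-column spacing.

So, in units of the dispersion energy $\varepsilon$,

$$ e(N) = -\kappa\left(1 - \frac{1}{N}\right) +
   \frac{\phi^2}{24}\left(N^2 - 1\right), \qquad
   \kappa = \frac{\gamma\, l\, \delta}{\varepsilon}. $$

This is the classic tape/ribbon balance for chiral amphiphile stacks:
interfacial tension drives ribbons wide, twist-frustrated dispersion
drives them narrow. `e(1) = 0` identically, `e` is strictly convex
(`e'' = 2κ/N³ + φ²/12 > 0`), and the continuous optimum solves
`e'(N) = 0`:

$$ N^\ast = \left(\frac{12\,\kappa}{\phi^2}\right)^{1/3}. $$

The observable is the relative probability of each width,
$\tilde P(N) \propto \exp[-\beta\varepsilon\, e(N)]$, evaluated on
integers `1..n_max` and rescaled to unit maximum (only the shape and the
mode carry information; the rescaling is the conventional presentation).
Ties in the argmax go to the smallest `N`, and no continuous
interpolation is applied to outputs.

Assumptions worth keeping in mind: the model is per-monomer (equivalent
to a fixed-size cooperative segment), achiral in width selection (no term
distinguishes left from right), and it treats $\phi$ as
width-independent — it selects a width given a twist, it does not predict
the twist.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `kappa` | 1 | — | interfacial / dispersion balance; the control parameter |
| `phi` | 0.0314 | rad | twist shear per inter-column spacing |
| `beta_eps` | 50 | — | dispersion depth in thermal units; curve sharpness |
| `n_max` | 60 | columns | largest width evaluated |
| `delta` | 0.46 | nm | inter-column spacing; converts `N` to width `D` |

`phi` is calibrated once so that `kappa = 1` puts the continuous optimum
near 23 columns, i.e. `D = N delta ≈ 10.6 nm`, commensurate with the
measured 10.7 nm ribbon width; it is exposed and overridable. `beta_eps`
only sharpens or flattens the displayed curves (interpretable as the
cooperative segment size in monomers); the mode and its ordering in
`kappa` do not depend on it. Width output uses `D = N * delta` — the
physical width spans `N` inter-column spacings — rather than `N * l`.

### pH dependence

The Dig head group is a carboxylic acid in dynamic -COOH/-COO⁻
equilibrium. With protonated fraction
$f = 1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})$, the effective interfacial
tension is the population average
$\gamma(\mathrm{pH}) = f\,\gamma_{HA} + (1-f)\,\gamma_{A}$, and
$\kappa = \gamma l \delta / \varepsilon$ follows. The aqueous pKa of a
carboxylic acid is about 3.5, but inside the assembly the equilibrium is
substantially shifted (partial protonation is evident even at pH 7), so
the default *apparent* pKa is 5.5 — a deliberately phenomenological
choice, exposed as `pka_app`. The default tensions put the kappa
saturation limits at 10 (fully protonated) and 0.1 (fully deprotonated),
spanning the range over which the mode moves from a few columns to tens
of columns; `kappa_from_ph` is monotone non-increasing in pH by
construction.

## Ribbon geometry and the twist dihedral

`build_ribbon()` places one pseudo-point per residue on the
diffraction-derived lattice: residues repeat at 0.29 nm along a chain,
chains run along the ribbon long axis tiled end-to-end, adjacent chains
sit 0.46 nm apart across the width, the two leaflets' backbone planes at
±0.68 nm, polar termini on the outer surfaces at ±1.23 nm. A uniform
twist rotates each cross-section about the long axis by
`360° · x / pitch`, signed by the handedness (right-handed = positive
rotation about +x with increasing x).

The global twist dihedral is defined through
$\vec v_u \cdot \vec v_l = |\vec v_u||\vec v_l| \cos\theta$ where
$\vec v_u$ and $\vec v_l$ are the best-fit vectors through the monomer
centres of mass of the ribbon's two *end* cross-sections, ordered by
column index. For a uniformly twisted ribbon the angle between the end
cross-section directions is exactly the accumulated twist, whatever the
ribbon's width-to-length ratio — which is why the ends, not the long
edges, define the order parameter: best-fit lines along the long edges
of a narrow ribbon are dominated by the axial component and underreport
the twist badly. Implementation details:

* the long axis is the first principal direction of the monomer centres
  of mass, oriented by increasing segment index; cross-section directions
  are least-squares fits of position against column index (sign by
  increasing column), which is insensitive to the leaflet offset;
* the sign is the triple product $(\vec v_l \times \vec v_u)\cdot\hat a$;
  mirroring a structure through any plane flips it exactly;
* $\theta$ is reported wrapped to (−180°, 180°]: the relation is blind to
  whole turns, so the builder refuses to build more than a half-turn
  rather than silently alias;
* beyond the two ends, the per-segment cross-section azimuth is
  regressed (after unwrapping) against axial position, giving a twist
  *rate* in deg/nm that uses every segment. `pitch = 360 L / |θ|`
  extrapolates a partial twist to a full turn, and
  `twist_at_contour(result, L_ref)` evaluates the dihedral across any
  reference contour from the measured rate — the same extrapolation, in
  the other direction. This matters because the chain period quantises
  realisable contour lengths to multiples of 1.45 nm: a pitch-87 nm
  ribbon of 17 chains spans 23.20 nm and twists 96.0° end to end, and its
  measured rate (4.138 deg/nm) puts 98.1° across the 23.7 nm reference
  contour.

Handedness is `right`/`left` when |θ| exceeds a 1° tolerance, `flat`
below it (a flat ribbon has no finite pitch, and the code says so with a
typed error rather than an infinity).

## Synthetic data

### Twist relaxation

`simulate_twist_relaxation()` emulates replicate relaxation runs of an
initially flat ribbon:
$\theta_r(t) = \theta_{eq}(1 - e^{-t/\tau}) + x_r(t)$ with $x_r$ a
discrete Ornstein–Uhlenbeck process. Defaults: plateau 98°, τ = 5 ns (so
the twist is > 98 % adopted by 20 ns), fluctuation sd σ = 3°, 100 ns at
0.2 ns steps, four runs. The fluctuations get their own correlation time
(`tau_noise`, default 1 ns): thermal twist fluctuations decorrelate much
faster than the structural relaxation, and the separation also governs
how many effectively independent samples a fit sees. Each run derives its
own stream from the base seed, so outputs are bit-identical for identical
seeds. `fit_relaxation()` refits the saturating exponential by nonlinear
least squares (explicit starting values; a convergence scale offset so
noise-free, zero-residual series converge cleanly) and exposes
broom-style `tidy()`/`glance()`.

### Height maps

`render_heightmap()` models AFM of a rigid twisted ribbon resting on a
flat substrate: at axial position `x` the cross-section (a `W × T`
rectangle) is rotated by `360° x / pitch`, and the map records the upper
envelope of the rotated rectangle. The height profile therefore
oscillates between the thickness (face-on) and about the width (edge-on)
with period `pitch/2` — the two-fold symmetry of a ribbon — and the
lateral footprint oscillates in antiphase.

Measured apparent heights of soft assemblies do not follow that rigid
envelope: the pH 7 helices read 5.2 nm — between the 2.46 nm bilayer and
the 10.7 nm width — and the pH 4 stacks read 15.6 nm, more than the
width. The generator therefore applies an *apparent-height mapping*: the
rigid relief is rescaled so the requested apparent height sits at
`plateau_frac` (default 0.55) of the rigid maximum, then capped there.
Every half-turn then presents a wide flat crest at exactly the apparent
height — emulating substrate flattening (low caps) or multilayer
stacking (tall caps) — which is the feature an AFM height measurement
actually reads, and which survives tip blur. The drawn apparent height is
the generator's ground truth for height recovery; the rigid-envelope
option (`apparent_height_nm = NULL`) remains for geometric tests.

Instrument effects: Gaussian tip blur of sd `tip_sigma_nm` (separable
convolution, background-padded) and additive Gaussian height noise,
seeded. Each map also draws a sub-pixel lateral offset and a random twist
phase from its seed — a physical specimen is never registered to the
pixel grid, and without these draws the pixel-coverage quantisation of
every map in a population falls on the same side and biases width
recovery by a systematic fraction of a pixel.

The population presets carry the measured cohort statistics as the study
conditions: `ph7` = pitch 86.4 ± 6.7 nm, height 5.2 ± 0.4 nm, width
10.7 ± 1.7 nm; `ph4` = pitch 110.1 ± 20.3 nm, height 15.6 ± 2.4 nm,
width 10.7 ± 1.7 nm (heights are the quantity the pH 4 experiments
quantify; no separate width statistic is reported for the stacks, so the
single published width distribution is used). Both are racemic
(`handedness_fraction_right = 0.5`). Per-helix parameters are drawn from
zero-truncated normals; map length is 2.6 pitches (five to six visible
profile periods). Imaging defaults, chosen once as realistic for
well-corrected, high-resolution AFM: 1 nm pixels, tip blur σ = 0.5 nm,
height noise 0.1 nm RMS.

What the generator does *not* emulate: tip–sample dilation (a true tip
convolves as a morphological maximum, not a Gaussian), scanner drift and
line noise, stain granularity, overlapping or curved helices, and any
mechanical deformation model beyond the apparent-height cap. Parameter
recovery on these synthetics therefore demonstrates estimator
correctness under the stated imaging model, not performance on raw
experimental micrographs.

## Estimators

All estimators first segment the footprint with an Otsu threshold (256
bins, with a minimum-relief guard of 0.1 nm so a featureless map raises a
detection error rather than measuring noise), then align the helix axis
to the image columns using the height-weighted principal direction of the
footprint (bilinear resampling; maps already within 0.25° are left
untouched).

* **Pitch.** The axial maximum-height profile is lightly smoothed (3 px
  running mean); its period is initialised at the *strongest*
  autocorrelation peak — the first local peak can sit on a secondary
  modulation such as the shallow edge-on sags tip blur creates — and the
  face-on dips (local minima below the mid-line, separated by at least
  0.6 of that period, boundary dips discarded) are refined to sub-pixel
  by parabolic interpolation. Successive spacings outside ±30 % of their
  median are discarded as clipped periods. The pitch is **twice** the
  mean dip spacing: a twisted ribbon's height profile repeats every half
  turn, so the raw profile period would silently halve the pitch. The
  spacing sd and period count are reported; fewer than two usable
  periods is a typed error.
* **Width** is read where the ribbon lies face-on (the profile dips) and
  presents its full width. Each face-on column is reduced to its
  equivalent-rectangle width — integrated excess height over background
  divided by the plateau level (interior mean of the half-maximum span).
  The integral and a wide plateau's level are both invariant under
  symmetric tip blur, whereas a plain half-maximum crossing is pushed
  outward by axial bleed from the taller neighbouring sections; the
  moment readout keeps the residual bias at the sub-percent level at the
  preset blur (it grows roughly with the square of the tip sd — see
  Limitations). Untwisted stripes fall back to the median over sampled
  columns.
* **Height** is the mean, over profile periods, of the crest level: the
  median of all pixels within 7 % of the period's maximum. The median of
  the broad flat crest is insensitive both to noise spikes (which bias a
  plain maximum upward) and to blur sag at the crest edges (which biases
  it downward), and it is stable under the resampling smoothing of
  rotated maps.
* **Handedness.** The screw sense appears as a consistent oblique drift
  of the edge-on ridge: over each half-period the crest's lateral
  position drifts one way and snaps back — a sawtooth, which is chiral
  (its mirror is not a translate of itself). On the aligned footprint the
  net obliquity is the sign of the structure-tensor off-diagonal
  $\sum I_x I_y$ (central differences); symmetric features — footprint
  edges, face-on dips — contribute zero by parity, so only the chiral
  texture survives the sum. The sign chain back to the 3-D builder
  convention is anchored by the generated reference pair that
  `make_fixtures()` ships. Confidence is $|2 S_{xy}|/(S_{xx}+S_{yy})$ in
  [0, 1]; below 0.002 the label is `indeterminate`. Mirroring a map flips
  the label and preserves the confidence exactly (the mirrored sums
  contain identical terms).

`summarize_population()` reports means, n−1 standard deviations, counts
and `mean ± sd (n = k)` strings, plus the right-handed fraction. Because
"counts" can mean period-level or helix-level measurements, both are
carried: per-helix rows keep `n_periods`, and the summary exposes the
helix count and the total period count.

## Numerical choices and degenerate inputs

Zero-twist ribbons report `handedness = "flat"` and no pitch; a flat
height profile raises `no_periodicity`; fewer than two edge monomers or
coincident centres of mass raise typed `insufficient_data` /
`degenerate_geometry` errors; builds beyond a half-turn are refused
(aliasing); `pitch = 0`, negative noise, empty peak lists and
non-positive `q` are domain errors. Boltzmann weights are computed
relative to the minimum energy before exponentiation; for extreme
`beta_eps * kappa` the scaled probabilities can underflow to exactly 0 in
double precision, which the tests acknowledge (the analytic statement is
strict positivity). Peak assignment uses relative error against the
nearest reference spacing with a 5 % default tolerance and no harmonic
indexing; assignments are order-invariant and tightening the tolerance
can only unassign.

## Problem sizes in the tests

The suite validates parameter recovery on populations of 50 helices per
preset and handedness balance on a racemic population of 200, each map
2.6 pitches long at 1 nm pixels; the noise-free ideal-case checks use
0.25 nm pixels so that estimator accuracy is tested apart from pixel
quantisation. Relaxation checks use the default 4 × 100 ns series, and
the model property grids span kappa from 0.01 to 100. These sizes give
sampling errors comfortably inside the asserted tolerances while keeping
the full suite around half a minute.

## Limitations

* The free energy is a phenomenological balance; it has no chiral term,
  no width-dependent twist, and no fitting of `kappa`, `phi` or `gamma`
  to images. `beta_eps` is a presentation parameter.
* The twist dihedral is a half-turn-wrapped quantity; cumulative twists
  beyond 180° require tracking the rate, not the end-to-end angle.
* Contour lengths of built ribbons are quantised by the 1.45 nm chain
  period; dihedrals at arbitrary reference contours are rate
  extrapolations.
* Width estimates degrade quadratically with tip blur (about +4 % at
  σ = 1 nm against +1 % at the preset 0.5 nm); with no tip deconvolution
  in scope, widths from heavily broadened imagery should be treated as
  upper bounds.
* The mapping from true ribbon geometry to AFM apparent height is not
  modelled mechanistically; estimator validation uses the generator's
  drawn apparent heights as truth, not the experimental height values.
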