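---
title: "Simulating brain resection cavities: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating brain resection cavities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectr)
```

## The problem

After resective neurosurgery — most prominently for refractory focal
epilepsy — the resection cavity (RC) fills with cerebrospinal fluid (CSF)
and appears on postoperative T1-weighted MRI as a dark, irregular hole in
the brain. Segmenting that cavity is the first step of most postoperative
analyses, but annotated postoperative datasets are scarce. `resectr`
implements the generative route around this bottleneck: it *simulates*
resections on preoperative scans, producing image/label pairs
`(X_sim, Y_sim)` that can train a segmentation network without any manual
annotation. The package covers the simulator itself, the anatomy masks it
needs, a head phantom so everything is testable without patient data, a
declarative reconstruction of the downstream compact 3D U-Net, and the
evaluation statistics used to compare models.

## The generative model

One draw of the simulator `simulate_resection()` composes these stages:

1. **Initial shape.** A geodesic sphere of frequency $f$ is built by
   subdividing an icosahedron's edges $f$ times and projecting onto the unit
   sphere, giving $10f^2 + 2$ vertices and $20f^2$ faces. Real cavities have
   non-smooth boundaries, so each vertex $v$ is displaced radially by fractal
   simplex noise,
   $\delta(v) = \eta\!\left((v + \mu)/\zeta,\ \omega,\ \gamma\right)$,
   where $\eta \in [-1, 1]$ sums $\omega$ octaves with geometrically decaying
   weights $\gamma^{n-1}$, $\zeta$ controls smoothness and the shift $\mu$
   acts as a continuous random seed.
2. **Size and orientation.** The perturbed sphere is rotated about x, y, z
   and scaled by ellipsoid semiaxes $(r, \lambda r, r/\lambda)$ chosen for a
   target cavity volume $v$.
3. **Placement.** A hemisphere is drawn with equal probability; the mesh is
   centred on a voxel drawn uniformly from that hemisphere's cortical gray
   matter (cavities originate at the cortex).
4. **Label.** The mesh is voxelized (a voxel is inside if its centre passes
   the even-odd parity test) and intersected with the *resectable hemisphere
   mask*: everything except background, brainstem, cerebellum and the
   contralateral hemisphere, smoothed by binary closing then opening. The
   intersection is the ground-truth label `Y_sim` — cavities never cross the
   midline or leave the brain.
5. **Texture.** CSF intensity is modelled as a Gaussian whose mean and
   population standard deviation are measured inside the ventricles of the
   input image itself (this adapts to any scanner calibration). A full
   volume of i.i.d. CSF noise is alpha-blended into the image,
   `X_sim = alpha * X_csf + (1 - alpha) * X_pre`, where the alpha channel is
   the label convolved with a truncated Gaussian; a positive blur width
   mimics partial-volume effects at the cavity border, and tissue where the
   alpha channel is exactly zero is provably untouched.

```{r example}
set.seed(7)
phantom <- make_phantom(phantom_spec(shape = c(64L, 64L, 64L), spacing = 3))
res <- simulate_resection(phantom$image, phantom$parcellation,
                          simulation_spec(seed = 42))
res
```

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `volume_range` (mm³) | cavity volume $v$ | [500, 50000] | spans small focal resections to lobectomies |
| `ratio_range` | semiaxis ratio $\lambda$ | [1, 2] | mild anisotropy; 1 keeps spheres |
| `angle_range` (rad) | rotations $\theta$ | [0, 2π) | orientation should be uninformative |
| `frequency` | geodesic frequency $f$ | 16 | 2562 vertices resolve the noise without slowing voxelization |
| `octaves`, `persistence` | noise structure $\omega$, $\gamma$ | 4, 0.5 | standard fractal roughness |
| `zeta` | noise smoothness | 0.5 | half the *unit* sphere radius; see below |
| `sigma_range` (mm) | alpha blur | [0.5, 2] | visible partial-volume border without smearing |
| `smooth_radius` (voxels) | mask morphology | 3 | fills sulcal gaps, removes spurs |

These defaults are engineering choices: they are deliberately labelled as
not validated against any trained model, and the ranges are the natural
dials for sensitivity studies.

Because the surface is perturbed *before* scaling (matching the pipeline
order above), the noise acts in unit-sphere coordinates: `zeta = 0.5` means
"features at half the sphere radius" at any cavity volume, which keeps
perceived roughness scale-free. Equivalently one may think of it as half
the mean semiaxis after scaling.

## The phantom, and what passing tests do not show

`make_phantom()` emulates exactly the anatomy the simulator consumes: two
mirror-symmetric hemispheres with a cortical gray-matter shell over white
matter, ellipsoidal ventricles, a brainstem and cerebellum, and Gaussian
per-tissue intensities with the T1 ordering WM > GM > CSF. That is enough
to exercise every code path (roles, hemisphere logic, CSF statistics,
containment) and to close parameter-recovery loops, e.g.
`csf_statistics()` recovering the phantom's CSF mean within its CLT band.

The phantom deliberately has no sulci, no partial-volume mixture at tissue
borders, no bias field, no real cortical geometry and no inter-subject
variability. Green tests therefore certify the *algorithmic* contracts
(containment, determinism, convexity, exact arithmetic), not realism of the
simulated images on clinical data.

Default test problem sizes are a 64³ phantom at 3 mm spacing (draws,
containment, recovery) and the canonical 193×229×193 grid only where the
target grid itself is the property under test; these sizes were chosen so
each property suite settles in seconds while keeping several thousand
voxels in every structure of interest.

## Numerical choices

- **Coordinates.** RAS+ millimetres; voxel indices 0-based; a voxel's
  physical position is its centre. One convention shared by mesh and volume
  code.
- **Semiaxes.** The printed formula for the sphere radius, $r = (3v/4)^{1/3}$,
  omits the factor $\pi$; under it the enclosed ellipsoid volume works out
  to $\pi v$ rather than $v$. The default `"volume-exact"` mode uses
  $r = (3v/(4\pi))^{1/3}$, under which the enclosed ellipsoid volume equals
  $v$ exactly (and the $f{=}8$ discretized mesh encloses it within 1%);
  `"paper-literal"` retains the printed constant for comparison.
- **Transform order.** The scaling-after-rotation composition
  $T_S \circ T_R$ is read right-to-left (rotate, then scale along fixed
  axes); `shape_transform(order = "scale-then-rotate")` flips it for
  sensitivity checks. Cuboid-mode ablation shapes are axis-aligned boxes
  with edges $(2r_1, 2r_2, 2r_3)$, never rotated and never perturbed.
- **Voxelization.** Even-odd parity of ray crossings, with rays offset from
  the lattice by ~10⁻⁶ voxel so they never graze mesh edges of meshes in
  general position; this matches a brute-force generalized-winding-number
  oracle voxel-for-voxel on randomized meshes.
- **Morphology.** Closing then opening with a digital spherical element
  (radius 3 voxels). Note that opening with a *ball* is not the identity on
  a digital cuboid — it rounds edges and corners; closing alone is the
  identity on convex solids. The tests assert exactly these properties.
- **Resampling.** Windowed sinc = Lanczos, radius 4 voxels, weights
  renormalised to unit sum over in-bounds taps, so constants are preserved
  and exact lattice coordinates reproduce the input. Masks and labels use
  nearest-neighbour, which can introduce no new label values. Registration
  is out of scope: the physical map to MNI space is supplied by the caller
  (identity for phantoms).
- **Gaussian alpha kernel.** Truncated at 4σ per axis, renormalised,
  zero-padded: the alpha channel stays within [0, 1] everywhere, so blending
  is always a convex combination.
- **CSF statistics.** Population (1/n) standard deviation; the divisor is a
  documented convention, not derivable from the source description.
- **Blur sigma.** Drawn per axis, uniform in [0.5, 2] mm. Whether the
  original drew one sigma per axis or one shared value is unknown;
  per-axis is the more general choice and degenerates to shared when the
  range is pinned.
- **Randomness.** All stochastic functions use R's global RNG so `set.seed()`
  reproduces any draw; `simulation_spec(seed = )` seeds one master stream
  for the whole pipeline, making draws bit-reproducible.

## The reference network reconstruction

The downstream segmentation network is reconstructed declaratively — an
ordered layer table (`architecture_spec`) with closed-form trainable
parameter counting and the standard receptive-field recursion
(RF += (k−1)·dilation·jump; jump ×= stride). The published description
fixes: two contractive and two expansive blocks, max-pool downsampling,
trilinear upsampling, one quarter of the original filter widths (base 8),
dilations starting at one and changing by one per block, batch
normalisation and PReLU after convolutions, and the headline pair
246,156 trainable parameters / 88 mm receptive field. It leaves open the
convolutions per block, the exact decrement timing of the dilation
schedule, and the bias/activation bookkeeping.

`scripts/search_architecture.R` enumerates that space. The natural fully
symmetric composition (two convolutions per block everywhere, schedule
1,2,3,2,1, one PReLU slope per convolution) lands close but not on the
published pair: 246,164 parameters and receptive field 92. The *unique*
structure reproducing both numbers simultaneously has convolutions per
block (2, 1, 1, 3, 3) for (enc1, enc2, bottleneck, dec1, dec2) and the
dilation schedule (1, 2, 3, 3, 2) — the decrement applied after each
expansive block completes — with PyTorch-conventional bookkeeping (no
convolution bias under affine batch norm, one shared PReLU slope per
network path, a biased two-class 1×1×1 classifier). That structure is
frozen in `inst/extdata/unet_reference_manifest.txt`; a pinned test breaks
if the manifest drifts. No tensors are ever instantiated and no training is
performed — the module exists to verify the architecture constants and to
document the network unambiguously.

## Evaluation statistics

`dice()` implements 2|A∩B|/(|A|+|B|) (two empty masks score 1, with a
warning). `threshold_prediction()` binarizes at 0.5 with ties positive;
`keep_largest_component()` uses 26-connectivity with ties broken at the
lowest voxel index — both conventions documented and configurable.
`mann_whitney_one_tailed()` requires an explicit direction (the sided-ness
of a comparison should never be implicit); it is exact by enumeration of
the null U distribution when $n_1 n_2 \le 400$ with no ties, and otherwise
uses the tie-corrected normal approximation with continuity correction.
`bonferroni_alpha()` divides by $n(n-1)$ — the count of ordered experiment
pairs, as used in the source protocol — with the conventional unordered
denominator behind a flag. `median_iqr()` uses linear-interpolation
quantiles (R type 7).

## Known limitations

- Cavities are placed and clipped by label geometry only; there is no brain
  shift, tissue collapse or biomechanical deformation, so large resections
  look "punched out" rather than sagging.
- CSF texture is i.i.d. Gaussian: no spatial correlation, no Rician
  magnitude bias, no interaction with a bias field.
- Brain extraction and registration to MNI space are consumed, not
  performed.
- The phantom's anatomy is schematic (see above); realism claims require
  real preoperative MRI with a real parcellation.
- The original training values of $\omega, \gamma, \zeta, \mu, f$ are
  unpublished; the defaults here are flagged as unvalidated against the
  original model.
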