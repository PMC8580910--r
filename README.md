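# resectr

Simulation of brain resection cavities on preoperative MRI, in R.

## Why

After resective neurosurgery (epilepsy surgery, tumour resection) the
cavity left in the brain fills with cerebrospinal fluid (CSF). Segmenting
that cavity on postoperative T1-weighted MRI is needed to relate resected
structures to outcome, but annotated postoperative scans are scarce and
expensive to label. A practical alternative is *self-supervision*:
synthesize realistic cavities on plentiful **pre**operative scans, so that
an image/label pair `(X_sim, Y_sim)` is available for free for every draw,
and train a segmentation CNN on those. `resectr` implements that generative
simulator and its supporting machinery for R users: anatomy-aware masks, a
synthetic head phantom (so everything runs without patient data), a
declarative reconstruction of the downstream compact 3D U-Net, and the
evaluation statistics used to compare segmentation models.

## The model in brief

One simulator draw maps a preoperative image and its brain parcellation to
a simulated postoperative image and ground-truth cavity label:

1. **Shape** — a geodesic sphere (frequency *f*: 10f²+2 vertices, 20f²
   faces) perturbed radially by fractal simplex noise,
   δ(v) = η((v + μ)/ζ; ω octaves, persistence γ), η ∈ [−1, 1];
2. **Size/pose** — rotations about x, y, z and scaling by ellipsoid
   semiaxes (r, λr, r/λ) sized so the ellipsoid encloses the drawn volume v;
3. **Placement** — hemisphere drawn with equal probability, mesh centred on
   a uniformly drawn cortical gray-matter voxel;
4. **Label** — parity voxelization intersected with the resectable
   hemisphere mask (no background, brainstem, cerebellum, or contralateral
   hemisphere; morphologically smoothed): `Y_sim`;
5. **Texture** — CSF intensity N(μ_CSF, σ_CSF) estimated from the subject's
   own ventricles, blended in through a Gaussian-blurred alpha channel:
   `X_sim = A ⊙ X_CSF + (1 − A) ⊙ X_pre`.

Ablation modes generate plain ellipsoids (no noise) and axis-aligned
cuboids (no noise, no rotation) for shape-complexity experiments.

## Worked example

```r
library(resectr)

set.seed(7)
phantom <- make_phantom(phantom_spec(shape = c(64L, 64L, 64L), spacing = 3))
res <- simulate_resection(phantom$image, phantom$parcellation,
                          simulation_spec(seed = 42))
res
#> <simulation_result> cavity 11097 mm^3 (411 voxels), right hemisphere
res$params
#> <drawn_params> right hemisphere, v = 14664 mm^3, lambda = 1.83, f = 16
```

The drawn target volume was 14 664 mm³; the realized cavity is 11 097 mm³
because the voxelized shape is clipped by the resectable-hemisphere mask —
the label can only shrink, never leak across the midline or outside the
brain. The CSF texture pasted into the cavity was estimated from the
phantom's own ventricles:

```r
csf_statistics(phantom$image, ventricle_mask(phantom$parcellation))
#> CSF model: mean 30.1, sd 5.1     (the phantom was built with CSF 30 ± 5)
```

The reconstructed compact 3D U-Net and the evaluation statistics:

```r
reference_architecture()
#> <architecture_spec> 17 layers, 246156 trainable parameters, receptive field 88
median_iqr(c(80.1, 85.3, 77.2, 90.0, 82.4))   # 'median (IQR)' DSC convention
#> 82.4 (5.2)
```

NIfTI I/O (`read_nifti()`, `write_nifti()`), resampling onto the canonical
1 mm 193×229×193 MNI-style grid (`resample_to_mni()`, Lanczos sinc for
images, nearest-neighbour for labels), and shell wrappers (`inst/cli/`:
`resect`, `resect-phantom`, `resect-eval`, `resect-netspec`) round out the
tool. See the vignette `vignettes/resection-simulation.Rmd` for the full
account of the model, parameters, and numerical choices.

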