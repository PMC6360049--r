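# petkem

Anatomically guided kernel EM reconstruction for image-derived input
functions (IDIF) in dynamic PET — with a fully synthetic evaluation study.

## The problem

Kinetic modelling of dynamic PET needs the arterial input function. Reading
it off the images (an IDIF from a blood-pool ROI) avoids arterial sampling,
but in preclinical work the available blood pool — an aorta of about 5 mm —
is the size of the scanner resolution, so the partial volume effect (PVE)
biases the ROI mean, and the very short early frames are too noisy for
reliable vessel delineation with plain OSEM. Gaussian postfiltering trades
the noise for even more PVE.

`petkem` implements the reconstruction-side remedy: **kernelised EM**
guided by an anatomical image, in its fixed-kernel (KEM) and hybrid (HKEM)
forms, combined with **fractional-maximum ROI extraction**. The image is
represented as `lambda = K alpha` and the coefficients are estimated by the
ordered-subsets EM update

    alpha <- alpha / (K' A' 1) * K' A' ( y / (A K alpha + s) )

where the kernel weight between neighbouring voxels f and j is a product of
Gaussians in intensity difference and spatial distance,

    k_fj = exp(-(v_f - v_j)^2 / 2 sigma_m^2) * exp(-|x_f - x_j|^2 / 2 sigma_dm^2)
         * exp(-(z_f - z_j)^2 / 2 sigma_p^2) * exp(-|x_f - x_j|^2 / 2 sigma_dp^2)

with `v` the (standardised) anatomical features and `z` the features of the
current PET estimate, rebuilt every subiteration (HKEM only). The ROI is
the anatomical vessel segment intersected with the voxels at or above 75%
of the segmented PET maximum, taken at the peak-activity frame.

The package ships every stage as tested, composable functions:

| stage | functions |
|---|---|
| synthetic phantom & kinetics | `make_phantom()`, `default_tac_table()`, `make_frame_scheme()`, `sample_activity_image()` |
| projector | `pet_geometry()`, `forward_project()`, `back_project()`, `attenuation_factors()` |
| acquisition simulation | `simulate_frame()`, `scatter_surrogate()`, `simulate_study()` |
| kernel | `kernel_params()`, `build_mr_kernel()`, `build_pet_kernel()`, `hybrid_kernel()` |
| reconstruction | `recon_settings()`, `make_em_system()`, `reconstruct()`, `gaussian_postfilter()` |
| IDIF metrics | `extract_roi()`, `compute_idif()`, `percent_bias()`, `percent_cov()`, `summarise_study()` |
| pipeline | `run_study()`, `read_study_config()`, NIfTI / study-container I/O |

A thin CLI (`inst/cli/petkem`) wraps the pipeline for shell use.

## Worked example

```r
library(petkem)

ph     <- make_phantom()                       # 96x96, 5 mm aorta
scheme <- make_frame_scheme()                  # 45 dynamic frames
tacs   <- default_tac_table()
geom   <- pet_geometry(dim(ph$labels), ph$spacing[1:3])
att    <- attenuation_factors(ph$mu, geom)
sys    <- make_em_system(geom, att, n_subsets = 21)

act <- sample_activity_image(ph, tacs, scheme[5, ])      # 24-30 s frame
frame <- simulate_frame(act, att, geom, scheme$duration[5], seed = 1)
img <- reconstruct(frame, sys, recon_settings("hkem"),
                   guidance = ph$guidance, body_mask = ph$body_mask)

seg <- ph$labels == ph$label_names[["aorta"]]
roi <- extract_roi(seg, img, 0.75)
roi_mean(roi, img)                              # 49.59 kBq/mL
frame_average_tac(tacs$aorta, scheme$start[5], scheme$duration[5])
                                                # true value 50.43 kBq/mL
```

The full comparison study — 10 Poisson noise realisations of all 45 frames,
reconstructed with OSEM, OSEM + 3 mm Gaussian postfilter, KEM and HKEM at
21 subsets x 10 iterations — runs in about ten minutes:

```r
report <- run_study()
report$metrics
#>   algorithm mean_bias max_bias min_bias mean_cov max_cov min_cov
#> 1      osem      7.90    24.22    0.006    18.78   64.51    3.00
#> 2    osem_g     19.68    40.94    0.015     9.19   18.56    0.68
#> 3       kem      4.87    21.30    0.003     4.13   19.24    0.22
#> 4      hkem      4.87    21.32    0.009     4.36   23.43    0.22
```

Columns are mean / max / min of the absolute percent bias of the per-frame
aorta IDIF against the true blood curve, and of the percent CoV over ROI
voxels, pooled over the 45 frames x 10 realisations. Read it as: the
postfilter suppresses noise but quadruples the mean bias through extra PVE;
plain OSEM is accurate on average but noisy; the anatomically guided
kernels cut both the bias of the filtered method and the noise of the
unfiltered one — with HKEM retaining PET contrast information that a pure
anatomical kernel lacks.

## Notes

See the methods vignette (`vignettes/hkem-idif-methods.Rmd`) for the model,
the synthetic-data design, numerical choices (including why kernel rows are
normalised by default) and known limitations.
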