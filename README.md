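# melanoct

Multi-contrast polarization-sensitive OCT (PS-OCT) simulation and
RPE-melanin quantification in R.

Melanin in the retinal pigment epithelium (RPE) scrambles the polarization
of backscattered light. PS-OCT quantifies this with the degree of
polarization uniformity (DOPU in [0, 1]; 1 = uniform state, low =
depolarization), but DOPU alone cannot separate RPE melanin from choroidal
melanin. The package implements the melanin-specific index

```
F_RPE = mu_norm x (1 - DOPU) x (1 - binarized OCT angiography signal)
```

which keeps only voxels that attenuate strongly (`mu_norm`, the depth-
resolved attenuation coefficient normalized by a reference of 10 mm^-1),
depolarize, and carry no flow. Counting voxels with `F_RPE >= 0.15` along
each A-line times the axial pitch gives an en-face RPE-melanin thickness
map; thresholding at 70 um yields thickened-lesion areas; PED volumes come
from segmented surfaces via the Cavalieri principle. A small U-Net-style
network (implemented from scratch in R, trained with per-pixel binary
cross-entropy) synthesizes DOPU from standard OCT intensity so the same
melanin pipeline can run without polarization-sensitive hardware.

All inputs can be simulated: a digital retinal phantom generates
dual-polarization repeated B-scan tomograms of a layered retina with a
depolarizing RPE band, serous PED, choroidal vessels, speckle and detector
noise — together with ground-truth masks, surfaces and attenuation maps for
every quantity the pipeline estimates.

## Worked example

```r
library(melanoct)

# an eye with a serous PED: 6 x 6 mm scan, 250 um detachment, 72 um RPE band
cfg <- phantom_config(rpe_thickness_um = 72, snr_db = 20, seed = 11,
                      ped = list(center_xy = c(0, 0), radius_mm = 1.5,
                                 height_um = 250, shape = "spherical-cap"))
vol <- generate_phantom(cfg)

bundle <- run_pipeline(vol, config = run_config(), keep_volumes = FALSE)
cat(sprintf("mean RPE-melanin thickness: %.1f um (truth %.1f um)\n",
            bundle$mean_thickness_um, bundle$truth_mean_thickness_um))
cat(sprintf("thickened lesion area (>= 70 um, PED region): %.3f mm^2\n",
            bundle$lesion$area_mm2))
cat(sprintf("PED volume (Cavalieri): %.4f mm^3\n", bundle$ped$volume_mm3))
```

prints (exact values are seed-reproducible):

```
mean RPE-melanin thickness: 75.1 um (truth 72.0 um)
thickened lesion area (>= 70 um, PED region): 4.047 mm^2
PED volume (Cavalieri): 0.8922 mm^3
```

The recovered thickness sits within one axial pixel (4 um) of truth, and the
PED volume is within 0.1% of the closed-form spherical-cap volume
`pi h (3 a^2 + h^2) / 6 = 0.8918 mm^3` for this geometry. For the synthesis
route, train on a phantom cohort and rerun with synthesized DOPU:

```r
cohort <- generate_cohort(12, list(rpe_thickness_um = c(30, 90)), seed = 42)
ds     <- build_patches(cohort, patch_size = 64, seed = 1)
model  <- train_synth(synth_model(seed = 1), ds, epochs = 8, lr = 2e-3)
synth  <- run_pipeline(vol, dopu_source = "synthesized", model = model)
```

`cohort_report()` aggregates per-eye bundles into group statistics, paired
measured-versus-synthesized comparisons (Wilcoxon signed-rank, Pearson) and
the lesion-area-versus-PED-volume correlation.

A thin command-line wrapper over these functions is installed at
`inst/cli/melanoct` (subcommands `phantom`, `process`, `maps`, `quantify`,
`synth`, `cohort`).

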