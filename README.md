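# dectmix

Dual-energy micro-CT material decomposition for contrast-agent staining
studies of soft tissue.

Micro-CT of unmineralised organs depends on contrast staining — immersing
the fixed sample in an iodine-in-ethanol solution (I2E) or an aqueous
gadolinium agent (Gadobutrol) and letting it diffuse in from the surface.
A single tomogram cannot tell agent concentration apart from tissue
density. Scanning the sample with two X-ray spectra can: the heavy staining
element and soft tissue respond to energy very differently, so each voxel's
pair of effective polychromatic attenuation coefficients
(µ<sub>LE</sub>, µ<sub>HE</sub>, in mm⁻¹) can be unmixed into fractions of
calibration materials. `dectmix` is for researchers running such staining
experiments: it turns registered dual-energy volume pairs plus a phantom
calibration into per-voxel staining maps and the downstream numbers a
staining-protocol study reports.

## The model

Per voxel, with basis coefficients measured from a calibration phantom
(PMMA rod + tube of the staining solution, air from phantom-free regions):

    µ_LE = µ_stain,LE·F_stain + µ_PMMA,LE·F_PMMA + µ_air,LE·F_air
    µ_HE = µ_stain,HE·F_stain + µ_PMMA,HE·F_PMMA + µ_air,HE·F_air
      1  =          F_stain +           F_PMMA +          F_air

solved voxel-wise under non-negativity constraints on the fractions
(support-enumeration NNLS, exact for ≤ 3 unknowns and vectorised across the
volume). `F_stain` is the fraction of the *calibration staining solution*:
values above 1 mean local accumulation beyond the bath concentration. The
sum-to-one row is a weighted least-squares row by default (`soft` mode), so
such super-unity fractions survive; an exact-simplex `hard` mode and a
two-material mode are also provided.

Around the core decomposition the package covers the full chain: synthetic
dual-energy phantoms with exact ground truth (diffusion-from-surface
staining profiles, shrinkage, noise, cupping, misalignment), rigid NCC
registration of the two energy volumes, median-filter denoising,
slice-annotation mask interpolation, phantom calibration with a spectral
separation check, and quantification — voxel-counting volumetry with
cavity inclusion, relative-volume and mean-attenuation time courses, 2D
correlation histograms, and per-tissue uptake summaries. File formats:
NRRD and TIFF-stack volumes, YAML calibrations/transforms, CSV tables.

## Worked example

Simulate a stained organ (heart/lung compartments, heart programmed to
accumulate up to 1.3× the bath concentration), decompose it, and summarise
uptake:

```r
library(dectmix)
cs   <- default_calibration_set("iodine")   # synthetic µ values, mm⁻¹
spec <- organ_phantom_spec(shape = c(32, 32, 32),
                           organ_semiaxes = c(12, 10, 8))
ph   <- make_organ_phantom(spec, cs, t_min = 60,
                           noise = noise_spec(sigma = 0.005, seed = 1))
fm   <- decompose_volume(median_filter(ph$le, 1), median_filter(ph$he, 1),
                         cs, mode = "three_material_soft",
                         mask = ph$truth$organ_mask)
fm
#> <fraction_map> 32 x 32 x 32 voxels, 4032 computed, mode three_material_soft
#>   F_stain range [0.0000, 1.2859], mean residual 0.00282 mm^-1

uptake_summary(fm, list(heart = ph$truth$heart_mask,
                        lung  = ph$truth$lung_mask), t_min = 60)
#> # A tibble: 2 × 5
#>   tissue time_min mean_f_stain max_f_stain n_voxels
#>   <chr>     <dbl>        <dbl>       <dbl>    <int>
#> 1 heart        60        1.19        1.29      1276
#> 2 lung         60        0.707       0.904     2756
```

After 60 min of simulated staining the fast-diffusing heart compartment
sits near its programmed 1.3× cap (recovered max 1.29 despite 1% noise)
while the slow compartment is still filling (mean 0.71) — the
differential-uptake readout the analysis exists to produce.
`sample_volume(ph$le, threshold = 0.05)` gives 32,256,000 µm³ for the same
phantom; shrinking the spec with `apply_shrinkage(spec, 0.8)` and
re-measuring recovers a relative volume of 0.80 ± 0.02.

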