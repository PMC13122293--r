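# scqsm — quantitative susceptibility mapping of the cervical spinal cord

`scqsm` reconstructs voxelwise magnetic susceptibility (QSM) of the cervical
spinal cord from dual in-phase / out-of-phase (IP/OOP) multi-echo
gradient-echo acquisitions, and classifies multiple-sclerosis lesions by
their susceptibility. The cord is a hard target for QSM: it is a few
millimetres across, sits next to strong background sources (vertebral bone,
marrow fat, air), and its tissue contrasts are an order of magnitude weaker
than in the brain. The package implements the full chain for a 3T protocol
built around two bipolar 12-echo series — one on the water-fat in-phase
times (first echo 2.64 ms, partially in phase), one out-of-phase (from
3.69 ms) — merged into a single 24-echo train with 2.46 ms spacing per
series.

The pipeline stages, each an exported function:

1. **Echo schedules** — `build_schedule()`, `merge_schedules()`: the
   24-echo interleaved grid with per-echo provenance.
2. **Registration & bipolar offsets** — `register_translation()` (subvoxel
   phase correlation, applied to real/imaginary channels separately),
   `correct_bipolar_offsets()` (triplet-based alternating phase offset).
3. **Total field** — without fat modelling, `fit_field_optimum_weights()`:
   Laplacian-unwrapped successive phase differences combined with
   inverse-variance weights; with fat-water separation, `ideal_fit()`:
   voxelwise R2\*-IDEAL

   s(TEₙ) = e^(−R₂\*TEₙ) (ρ_W + ρ_F Σₖ αₖ e^(−i2πΔfₖTEₙ)) e^(−i2πΔB TEₙ)

   solved by variable projection with Levenberg-Marquardt updates,
   initialised by the null field map, ARLO R2\* (`arlo_r2star()`) and
   phase-corrected two-point Dixon (`dixon_init()`), with per-echo SNR
   weights (`compute_echo_weights()`).
4. **Background removal** — `pdf_remove()`: projection onto dipole fields
   (PDF) by conjugate gradient, external sources supported outside the
   measured spinal canal; SMV radius 0.
5. **Dipole inversion** — `medi_invert()`: morphology-enabled L1
   gradient-regularised inversion (MEDI) with the IP/OOP l2-norm anatomical
   image (`build_anatomical()`, `edge_mask()`), then global-mean
   referencing (`reference_map()`).
6. **Analysis** — `region_stats()`, `compare_pipelines()` (per-tissue
   regression, Shapiro-Wilk, paired t-test), `classify_lesion()` /
   `lesion_records()` (hyper / iso / hypointense against a −0.7 ppb WM
   reference with ±1 ppb margin, i.e. cutoffs at 0.3 and −1.7 ppb),
   `build_report()`.

A numerical phantom (`phantom_spec()`, `build_phantom()`,
`simulate_signal()`) generates cord geometry with a gray-matter H-shape,
CSF ring, fat-bearing vertebral body, lesions, and the complex multi-echo
signal through the forward dipole + multi-peak fat model — so every stage
is testable with known ground truth and no data download.

## Worked example

Simulate the default noisy phantom (SNR 50) with two lesions and run the
no-FWS reconstruction:

```r
library(scqsm)
p  <- default_protocols()
ph <- build_phantom(phantom_spec(
  lesion_specs = list(list(center = c(2, 0, 0),  radius = 1,   pattern = "hyper"),
                      list(center = c(-2, 1, 2), radius = 0.9, pattern = "hypo"))))
ip  <- simulate_signal(ph, build_schedule(p$ip),  seed = 11)
oop <- simulate_signal(ph, build_schedule(p$oop), seed = 12)
res <- sc_qsm_pipeline(ip, oop, ph$masks$cord, method = "optw",
                       measured_mask = ph$masks$cord | ph$masks$CSF,
                       noise_region  = ph$masks$noise)
res$chi
#> <susceptibility_map> 5056 voxels, mean 3.65e-16 ppb, ref = global_mean

region_stats(res$chi, ph$masks[c("GM", "WM")])
#>  tissue       mean       sd n_voxels
#>      GM  2.8044963 12.06305     1184
#>      WM -0.8575733 10.46844     3872

lesion_records(res$chi, list(L1 = ph$chi == 1.5  & ph$masks$lesion,
                             L2 = ph$chi == -3.6 & ph$masks$lesion))
#>  id   mean_chi n_voxels     category
#>  L1  0.9305997       32 hyperintense
#>  L2 -3.4689238       24  hypointense
```

The reconstructed gray/white-matter means (2.80 / −0.86 ppb here) recover
the generator truth (+3.1 / −0.7 ppb) up to regularisation shrinkage and
noise; the per-voxel standard deviations reflect single-voxel noise at
SNR 50, not the uncertainty of the means. Both painted lesions are
classified correctly against the 0.3 / −1.7 ppb cutoffs. Swapping
`method = "ideal"` reruns the same chain with R2\*-IDEAL fat-water
separation.

A thin command-line front end over the same functions lives at
`inst/cli/scqsm.R` (subcommands `phantom`, `fit-field`,
`remove-background`, `invert`, `analyze`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/scqsm.R", package="scqsm"))')" \
    phantom --out phantom_dir --seed 1
```

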