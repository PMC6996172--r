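# deepangio

Quantification and quality control of **deep capillary plexus (DCP)
OCT-angiography** images in diabetic eyes, with the downstream
reliability and association statistics that clinical OCT-A studies
need.

OCT angiography resolves the retinal vasculature layer by layer, and in
diabetes the deep plexus is damaged earliest — but DCP en-face images
are plagued by artifacts, above all *projection* of the overlying
superficial (SCP) large vessels into the deep slab. `deepangio`
implements the full analysis chain for 3 mm × 3 mm, 320 × 320 en-face
angiograms:

1. **Quality control** — automated analogues of a reading-center
   grader: projection artifacts (SCP large-vessel co-elevation plus
   continuous, non-vortex morphology on the DCP image), blur (focus
   measure), motion (row discontinuity and residual motion lines),
   signal loss (dark row bands), poor foveal centration, a device
   quality score below 40, and a segmentation-error metadata flag.
   Exclusions carry a single primary reason in a fixed priority order.
2. **DCP metrics** — after edge-preserving (bilateral) denoising and
   locally adaptive binarization:
   * **FAZ area** (mm²): pixels of the central avascular component
     times the pixel area;
   * **vessel density** (%): share of the parafoveal annulus (outer
     diameter 3 mm, inner 1 mm) not covered by non-perfusion, where a
     non-perfusion region is a dark connected component larger than
     0.02 mm²;
   * **fractal dimension**: box-counting slope
     `FD = -d log N(s) / d log s` of the skeletonized vessel network.
3. **Reliability** — intra-/inter-session ICC(2,1) (two-way random,
   absolute agreement) with F-based confidence intervals.
4. **Associations** — linear generalized estimating equations
   (identity link, exchangeable working correlation, robust sandwich
   SEs) clustering fellow eyes within subject; continuous predictors
   standardized per SD, DR severity as dummies versus "no DR";
   univariate screen at p < 0.05 feeding the multivariable model, all
   repeated on the DME-free subset.
5. **Synthetic data** — vortex-textured DCP angiograms with known FAZ
   radius and injected dropout, SCP images with large curving vessels,
   the four artifact classes, and clustered clinical cohorts with
   configurable covariate marginals and effect sizes, so the entire
   pipeline is testable without patient data.

## Worked example

```r
library(deepangio)
library(dplyr)

# a synthetic DCP/SCP pair with known ground truth
pair <- generate_dcp_angiogram(faz_radius_mm = 0.3, seed = 42)
scp  <- generate_scp_angiogram(seed = 43)

apply_qc(pair$image, scp$image) |>
  select(eye_id, projection, blur, motion, signal_loss, excluded)
#>   eye_id projection blur  motion signal_loss excluded
#> 1 eye01  FALSE      FALSE FALSE  FALSE       FALSE

quantify_dcp(pair$image)
#>   eye_id subject_id session_id   faz_area_mm2 vd_pct    fd
#> 1 eye01  subj01     visit1_scan1        0.284    100  1.81
```

The measured FAZ area (0.284 mm²) recovers the generated truth
(π · 0.3² = 0.283 mm²) within 0.5%; a fully perfused annulus gives
VD = 100%, and the skeleton's box-counting dimension (1.81) sits in the
plausible range for a dense capillary mesh.

```r
coh <- generate_cohort(n_subjects = 300, seed = 7)
res <- run_full_analysis(coh)
filter(res, model_stage == "multivariable",
       cohort_variant == "all", outcome == "FD")
#>   predictor     beta     se  ci_low ci_high        p
#> 1 dr_mild     -0.284 0.0940 -0.468  -0.100  2.5e-03
#> 2 dr_moderate -0.366 0.114  -0.589  -0.143  1.3e-03
#> 3 dr_severe   -0.845 0.149  -1.14   -0.553  1.4e-08
#> 4 logmar      -0.119 0.0395 -0.197  -0.0416 2.6e-03
#> 5 age_y       -0.214 0.0475 -0.307  -0.121  6.7e-06
#> 6 bmi          0.178 0.0524  0.0748  0.280  7.1e-04
#> 7 ldl          0.143 0.0512  0.0428  0.244  5.2e-03
```

The severe-DR coefficient (−0.845 ± 0.149) recovers the injected
fractal-dimension deficit of −0.891 for severe NPDR/PDR versus no DR;
signs and magnitudes of the other recovered effects match the
generating model (ldl enters by chance at the 5% screen).

```r
rm_ <- simulate_repeated_measures(29, subject_sd = 0.12,
                                  error_sd = 0.03, seed = 8)
compute_icc(rm_, "fd", "intra") |> select(icc, ci_low, ci_high, n_eyes)
#>     icc ci_low ci_high n_eyes
#> 1 0.931  0.858   0.967     29
```

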