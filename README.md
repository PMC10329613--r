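# cbctvol

Three-dimensional radiographic evaluation of bone-block grafts from serial
cone-beam CT (CBCT). `cbctvol` is for clinical researchers who quantify
alveolar ridge augmentation: it turns three CBCT scans of the same patient —
baseline (T1), early follow-up after grafting (T2), late follow-up (T3) —
into the standard volumetric and morphological outcome set:

- **new hard-tissue volume** at T2 and T3 (cm³), obtained by seeded
  region-growing segmentation of bone vs background, seeded watershed
  segmentation of the teeth, screw-head exclusion, rigid intensity-based
  registration of the follow-ups to baseline, and logical-operator
  subtraction `bone(Tx) AND NOT bone(T1)` on the baseline grid;
- **volume stability**, the T3/T2 ratio `100 · vT3 / vT2` (%);
- **morphological stability**, the Dice similarity coefficient
  `DSC = 2|A∩B| / (|A|+|B|)` between the T2 and T3 new-tissue models;
- **resorption colormaps**: signed surface distances on the T2 model
  (loss negative/red, gain positive/blue);
- **linear ridge dimensions** (horizontal widths at fixed depths below the
  crest, vertical height) at implantation sites;
- **cohort statistics**: descriptives, the Wilcoxon matched-pairs
  signed-rank test of vT2 vs vT3 (exact enumeration for ≤ 15 pairs), and
  Spearman rank correlation between ratio and DSC.

Because clinical CBCT series cannot be shared, the package includes a serial
CBCT **phantom generator** (`phantom_spec()` / `generate_case()` /
`make_cohort()`): an atrophied ridge with cortical shell and teeth, a
volume-calibrated graft block fixed by titanium screws, smooth
buccally/crestally biased resorption, partial-volume blur, noise, and known
rigid inter-scan misalignment — with exact ground truth (labels, transforms,
volumes) for validating every stage. See the vignette
(`vignettes/cbct-graft-volumetry.Rmd`) for the methods in full.

## Worked example

```r
library(cbctvol)

## a synthetic study case: 128^3 voxels at 0.25 mm, 0.75 cm^3 graft,
## 32% resorption, realistic noise, known patient repositioning
case <- generate_case(phantom_spec(seed = 1))

## the full evaluation: segment -> register -> subtract -> measure
report <- run_phantom_case(case, case_id = "demo")

round(c(vT2 = report$new_volume_t2_cm3,
        vT3 = report$new_volume_t3_cm3,
        ratio_pct = report$stability_ratio_pct,
        dsc = report$dsc), 4)
#>       vT2       vT3 ratio_pct       dsc 
#>    0.7319    0.5016   68.5317    0.8080

## against the generator's ground truth
round(unlist(case$truth$volumes), 4)
#>  v_t2_cm3  v_t3_cm3 ratio_pct       dsc 
#>    0.7492    0.5095   67.9992    0.8095
```

Under realistic noise the pipeline recovered the ~0.75 cm³ graft volume to
about 2%, the resorbed volume to about 1.5%, the stability ratio to half a
percentage point, and the spatial-overlap DSC to 0.002. `run_case()` is the same entry point for
real data (volumes from NRRD/NIfTI files, seeds from JSON annotations,
screw-head masks, site specifications); `run_cohort()` aggregates per-case
reports into the descriptive and nonparametric battery. A thin command-line
wrapper lives in `inst/cli/cbctvol.R`.

Cohort demographics parse from a standard CSV (`participant, sex, age,
tooth, hvc`); a 23-participant / 40-site example table ships in
`inst/extdata/cohort_table1.csv`:

```r
summ <- cohort_summary(parse_cohort_table(
  system.file("extdata", "cohort_table1.csv", package = "cbctvol")))
c(summ$age$mean, summ$age$sd, summ$sex_counts)
#> 45.48 12.52    14     9
```

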