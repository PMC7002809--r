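# sisdce

Kinetic and textural DCE-MRI analysis for early prediction of
breast-cancer response to neoadjuvant therapy.

After the first cycle of neoadjuvant therapy, responding tumours change
their contrast-enhancement kinetics and their spatial heterogeneity well
before they change size on conventional imaging. `sisdce` implements a
complete analysis of paired pre/post-treatment dynamic contrast-enhanced
MRI (DCE-MRI) examinations that quantifies both effects and evaluates
every measure as a classifier of pathological complete response (pCR,
Miller-Payne grade 5) versus non-pCR:

* **Semiquantitative kinetics.** Each voxel's time-intensity curve (TIC)
  is fitted with a three-segment piecewise-linear model — a constant
  baseline before contrast arrival, a linear washin, and a linear washout
  — by exhaustive search over breakpoint pairs on the sampling grid,
  minimising the total sum of squared errors. From the fit come the
  maximum signal difference (MSD), time to peak (TTP), washin and washout
  slopes (WIS, WOS) and intercepts, and the trapezoidal areas under the
  baseline-subtracted curve (washin, washout, total). The VOI
  representative of each parameter is the voxelwise median (with SD and
  range).

* **Standardised Index of Shape (SIS).** With Δx = (x₁ − x₂)/x₁ × 100
  the pre-to-post percentage change,

      SIS = 0.7780 · ΔMSD + 0.6157 · ΔWOS

  so a post-treatment collapse of peak enhancement and flattening of the
  washout both push SIS up.

* **Radiomic texture panel.** Fifty features of the arterial-phase volume
  restricted to the tumour VOI: 9 first-order statistics, 9 gray-level
  co-occurrence (GLCM, including entropy), 13 run-length (GLRLM,
  including long-run emphasis), 13 size-zone (GLSZM) and 5 neighbourhood
  gray-tone difference (NGTDM, including busyness) features, plus VOI
  volume. Matrices are 3-D, pooled over the 13 unique grid directions at
  distance 1, on a 32-level equal-width quantisation of the VOI.

* **Diagnostic evaluation.** Per-feature percentage changes are compared
  between groups with the tie-corrected Kruskal-Wallis test (Bonferroni
  correction across the tested family), and classification performance is
  summarised by the Mann-Whitney ROC-AUC and the Youden-optimal cutoff
  with sensitivity, specificity, PPV, NPV and accuracy.

* **Synthetic cohorts.** A generator produces paired pre/post
  examinations (NIfTI volumes + masks + JSON timing sidecars + CSV
  manifest) with known ground-truth kinetics, lognormal patient
  variability, Gaussian-random-field heterogeneity, treatment effects,
  tumour shrinkage and residual enhancing foci, so the entire pipeline is
  testable without patient data.

## Worked example

Simulate a 15-patient cohort (5 pCR, 10 non-pCR), analyse it, and look at
the diagnostic table for the kinetic and texture features of interest:

```r
library(sisdce)

cfg    <- cohort_config(n_pcr = 5, n_nonpcr = 10, seed = 7)
cohort <- generate_cohort(cfg)
res    <- analyze_cohort(cohort)

t2  <- res$tables$diagnostics
sig <- c("glcm_entropy", "glrlm_lre", "ngtdm_busyness",
         "msd", "wis", "wos", "sis")
t2[t2$feature %in% sig,
   c("feature", "kruskal_p", "roc_auc", "cutoff",
     "sensitivity", "specificity", "accuracy")]
```

```
        feature kruskal_p roc_auc cutoff sensitivity specificity accuracy
   glcm_entropy    0.0022    1.00   4.54         1.0           1    1.000
      glrlm_lre    0.1110    0.76   5.12         0.6           1    0.867
 ngtdm_busyness    0.0662    0.80  27.70         0.8           1    0.933
            msd    0.0022    1.00  87.60         1.0           1    1.000
            wis    0.0022    1.00  86.40         1.0           1    1.000
            wos    0.0022    1.00  83.80         1.0           1    1.000
            sis    0.0022    1.00 120.00         1.0           1    1.000
```

Each row reports, for one feature's percentage change, the Kruskal-Wallis
p-value for the pCR versus non-pCR comparison, the ROC-AUC (higher change
⇒ pCR), the Youden-optimal cutoff in percent, and the operating
characteristics at that cutoff. With the generator's default treatment
effects the kinetic changes separate the groups completely (AUC 1.0, SIS
cutoff 120%), while the texture changes separate them only partially —
the same ordering of kinetic over textural information seen in clinical
studies of this design.

The same pipeline runs from the shell on cohorts stored on disk:

```sh
Rscript inst/cli/sisdce.R simulate --out cohort/ --seed 7
Rscript inst/cli/sisdce.R analyze  --manifest cohort/manifest.csv --out results/
Rscript inst/cli/sisdce.R sis      --pre pre_tic.csv --post post_tic.csv
```

`analyze` writes per-examination feature tables, the per-patient
percentage-change table, the group-summary table (`table1.csv`), the
diagnostic table (`table2.csv`) and a full-precision `report.json`.

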