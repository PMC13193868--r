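# octrao

Quantitative OCT biomarkers for acute central retinal artery occlusion
(CRAO): a simulation-backed analysis pipeline for diagnosing the occluded
eye and stratifying ischemia duration at the 4.5-hour reperfusion window.

## Who this is for

Researchers working on OCT-based triage of acute retinal ischemia who need
a reproducible, fully testable implementation of reflectivity- and
thickness-based CRAO biomarkers — and a mechanistic synthetic cohort to run
it on, since clinical CRAO OCT datasets are rarely shareable.

## The science in brief

Occlusion of the central retinal artery injures the inner retinal layers
(IRL): they turn hyperreflective early and swell with cytotoxic edema,
which in turn shadows the outer retinal layers (ORL). Three biomarker
families capture this on macular OCT:

- **Within-eye IRL/ORL reflectivity ratio** `rho = R_IRL / R_ORL` per
  B-scan — near 0.94 in healthy eyes, strongly elevated in CRAO, and rising
  with time-to-OCT (TTO) because ORL attenuation is progressive while IRL
  hyperreflectivity plateaus early.
- **Inter-eye IRL and ORL ratios** (CRAO eye normalized to the fellow eye),
  used to show that the temporal signal lives in the ORL compartment.
- **ETDRS sector thickness**, its inter-eye difference, and the relative
  retinal thickness increase `RRTI = T_CRAO / T_fellow` (1.20 = +20%), with
  inferior sectors — S8 above all — carrying the strongest temporal signal
  and the fovea carrying almost none.

The package implements: an open OCT container (multi-page 8-bit TIFF +
JSON sidecar with sub-pixel boundary polylines), compartment reflectivity
extraction with fractional-pixel masks, en-face thickness maps and ETDRS
sectorization, the full biomarker table per patient, exact/non-parametric
tests (Wilcoxon signed-rank, Mann–Whitney U with small-sample enumeration),
empirical ROC/AUC with Youden cut-points, TTO trend regression,
chained-equation (PMM) imputation, an exploratory logistic model, and a
mechanistic simulator of paired CRAO/fellow eyes calibrated to published
group summaries. See the vignette (`vignettes/oct-crao-biomarkers.Rmd`)
for the model and all defaults.

## Worked example

```r
library(octrao)
cfg <- simulator_config(seed = 42)   # 39 patients, 12 early / 27 late
run <- run_full(cfg)                 # simulate -> render -> extract -> analyze
print(run)
```

```
octrao run: 39 patients (seed 42)
  diagnostic AUC (within-eye ratio): rho_m2 0.99, rho_m1 0.99, rho_c 1.00, rho_p1 1.00, rho_p2 1.00
  temporal AUC (within-eye ratio): rho_m2 0.88, rho_m1 0.91, rho_c 0.91, rho_p1 0.93, rho_p2 0.93
  exploratory model: apparent AUC 1.00, 0 misclassified
```

Diagnosis (CRAO vs fellow eye) is essentially solved by the within-eye
ratio at every scan location (AUC ≈ 0.99–1.00 with Youden cut-offs around
1.2), while early-vs-late classification lands at AUC ≈ 0.88–0.93 —
the separation a plateauing IRL plus progressive ORL attenuation can
deliver. The sector × metric AUC matrix for the temporal task shows the
inferior outer sector dominating the thickness-based families:

```r
round(run$temporal$auc_matrix, 2)
```

```
            S1   S2   S3   S4   S5   S6   S7   S8   S9
thickness 0.70 0.85 0.82 0.87 0.82 0.90 0.83 0.98 0.86
ratio     0.88 0.91 0.91 0.93 0.93   NA   NA   NA   NA
rrti      0.80 0.89 0.90 0.90 0.84 0.84 0.88 0.98 0.84
```

(`ratio` is a per-location metric, so its S6–S9 cells are empty; the S8
RRTI row reads AUC 0.98 with a cut-off near 1.12, i.e. a ~12% thickness
increase flags late presentation in this cohort realization.)

A command-line wrapper covers the same workflow from a shell:

```sh
Rscript inst/cli/octrao.R simulate --n 39 --frac-late 0.6923 --seed 42 --out sim/
Rscript inst/cli/octrao.R extract  --in sim/ --out biomarkers.csv
Rscript inst/cli/octrao.R run      --simulate --n 39 --seed 42 --out out/
```

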