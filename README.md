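# esitools

Emphysema severity scoring from the shape of the maximal expiratory
flow-volume (MEFV) curve, with the CT quantification and statistics needed
to validate it.

## What problem this solves

Spirometry measures airflow obstruction in COPD but cannot tell whether the
obstruction comes from conductive airway disease or from emphysematous
parenchymal destruction; quantitative CT can, but is not always available.
The *shape* of the MEFV descending limb discriminates the two mechanisms:
airway-predominant disease scoops the curve smoothly, emphysema flattens it
at high lung volumes and then lets flow collapse abruptly ("kinking").
`esitools` quantifies that shape as the **Emphysema Severity Index (ESI)**,
a 0–10 score computed from the curve alone — no percent-predicted reference
values — and provides everything needed to benchmark such a score against
imaging:

* **ESI model** — normalize the descending limb to (u, q) ∈ [0,1]², fit the
  two-regime power law `q(u) = u^θ(u)` with
  `θ(u) = θ_d + (θ_p − θ_d)·S((u − u*)/w)` (S = logistic), and score
  `ESI = 10·clamp((θ_d − θ_p)/3.5, 0, 1)`; single-phase (kinkless) limbs
  score 0.
* **CT densitometry** — %LAA below −950 HU (inspiration) / −856 HU
  (expiration), parametric response mapping of co-registered scan pairs into
  Normal / fLDA / pLDA voxel classes, and NE/ME/SE staging at the 6% / 14%
  cut-offs. NIfTI in and out.
* **SILA + affinity propagation** — an ordinal earth-mover dissimilarity
  between regional parenchymal pattern profiles (ordered classes Normal →
  Severe LAA), clustered by exemplar message passing.
* **Synthetic cohort** — a seeded generator in which one latent severity
  drives curve shape, CT fractions and pattern profiles for a three-group
  (57/58/79) study design.
* **Validation statistics** — Welch ANOVA (raw data or published
  summaries), Games-Howell post-hocs, Steiger's Z for dependent
  correlations, stratified 10-fold cross-validated logistic ROC analysis
  with Youden operating points, chi-squared.

Everything is tidyverse-shaped: curves and profiles are tibbles, results
have `tidy()` / `glance()` / `autoplot()` methods, and the pieces compose
with the pipe.

## Worked example

```r
library(esitools)

# a severe-emphysema archetype curve (latent severity 0.85), no noise
params <- severity_to_params(0.85, seed = 1)
curve  <- generate_curve(params, noise_sd = 0, seed = 1)
result <- score_curve(curve)
result$esi
#> [1] 7.529252
```

The true score implied by severity 0.85 is 10·(3.1·0.85)/3.5 = 7.5286, so
the round trip through curve synthesis, limb extraction and refitting is
exact to ~1e-3. A mild archetype (severity 0.05) scores 0.44 — the two sit
on opposite sides of the clinically used boundary of 5. `glance(result)`
returns the fitted exponents, SSE and spirometric indices as a one-row
tibble; `autoplot(result)` draws the fitted limb.

The full synthetic study, end to end:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "out"))
dplyr::count(res$cohort, group)
#>   group  n
#> 1 NE    57
#> 2 ME    58
#> 3 SE    79
res$stats$roc_severe$auc          # ESI vs CT-defined severe emphysema
#> [1] 0.9040176
cor(res$cohort$esi_fit, res$cohort$laa950_insp)
#> [1] 0.8845523
```

which writes `cohort.csv`, per-subject curves and score reports,
`clusters.csv` and a statistics report (JSON + Markdown) under `out/`. A
command-line front end with the same stages is at `exec/esitool`
(subcommands `score`, `simulate`, `ct-prm`, `cluster`, `validate`, `run`).

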