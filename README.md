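# renivim

Quantitative renal diffusion-MRI analysis for early chronic kidney disease
(CKD). The package implements the three signal-decay models used in
multi-b renal imaging and everything needed to run a complete three-group
study around them:

* **Signal models** — monoexponential
  (`S(b)/S0 = exp(-b·ADC)`), biexponential IVIM
  (`S(b)/S0 = f·exp(-b·D_fast) + (1-f)·exp(-b·D_slow)`) and stretched
  exponential (`S(b)/S0 = exp(-(b·DDC)^α)`), over the 13-point renal
  protocol (b = 0–1000 s/mm²).
* **Fitters** — log-linear least squares for ADC; bounded
  Levenberg–Marquardt with segmented initialisation and deterministic
  multistart for `(f, D_slow, D_fast)` and `(DDC, α)`.
* **Clinical arithmetic** — ID-MS MDRD eGFR
  (`186 · SCr⁻¹·¹⁵⁴ · age⁻⁰·²⁰³ · 0.742 if female`, creatinine converted
  from µmol/L), the eGFR-90 grouping rule, and Katafuchi-style pathology
  score handling.
* **Synthetic cohort generator** — a fully seeded stand-in for the
  (unavailable) patient data: 19 controls / 33 preserved-eGFR / 28
  reduced-eGFR subjects with group-anchored parameter marginals, latent
  severity coupling, Rician ROI signals and two simulated readers.
* **Statistics** — Shapiro screening, Kruskal–Wallis + Dunn (Bonferroni),
  Mann–Whitney, Spearman with Bonferroni families, ICC(2,1) with
  McGraw–Wong intervals, and ROC analysis with DeLong intervals and
  Youden thresholds.

It is aimed at imaging researchers who want a tested, reproducible
reference implementation of this analysis chain — to validate their own
fitting code against, to prototype protocol changes on synthetic cohorts,
or to run the statistical pipeline on their own ROI tables.

## Worked example

Fit all three models to a noiseless curve synthesised from the published
preserved-eGFR patient case, then run the full synthetic study:

```r
library(renivim)

sch <- renal_bscheme()
curve <- signal_curve(sch, biexp_signal(sch$b_values,
                                        f = 0.29,
                                        d_slow = 1.75e-3,
                                        d_fast = 26.5e-3))
unlist(fit_biexp(curve)$params)
#>       f  d_slow  d_fast
#> 0.29000 0.00175 0.02650

curve2 <- signal_curve(sch, stretched_signal(sch$b_values,
                                             ddc = 3.12e-3, alpha = 0.64))
unlist(fit_stretched(curve2)$params)
#>     ddc   alpha
#> 0.00312 0.64000
```

The fitters recover the generating parameters exactly: `f = 0.29` (the
perfusion fraction, i.e. 29% of the voxel signal comes from the fast
perfusion compartment), `D_slow = 1.75` and `D_fast = 26.5` (×10⁻³ mm²/s),
and `DDC = 3.12 ×10⁻³ mm²/s` with heterogeneity index `α = 0.64`.

End-to-end synthetic study:

```r
res <- cmd_reproduce(seed = 1, out = "run1")
#> [renivim:generate] seed=1 config_hash=1304356 subjects=80 roi_curves=617
#> [renivim:fit] curves=617 converged_biexp=617/617
#> [renivim:analyze] report written to run1/report
#> [renivim:reproduce] done: run1
```

`run1/report/` then contains the five study-shaped tables. On this seed
the cohort reproduces the expected qualitative pattern: group medians of
the five bi/stretched-exponential parameters decrease from controls
through preserved- to reduced-eGFR patients; the perfusion-sensitive
markers correlate positively with eGFR and negatively with the pathology
scores (e.g. Spearman ρ = 0.70 for D_fast vs eGFR, −0.45 for D_fast vs the
tubulointerstitial score); and the control-vs-CKD AUCs order as
α (0.95) ≈ f (0.95) > D_fast (0.92) > DDC (0.77) ≈ D_slow (0.75) — the
perfusion/heterogeneity markers detect CKD that the slow-diffusion markers
miss. Running the same command twice yields byte-identical output.

A thin shell wrapper for the four pipeline stages
(`generate`/`fit`/`analyze`/`reproduce`) is installed at
`inst/cli/renivim.R`.

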