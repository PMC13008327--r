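# bpvar

Short-timescale blood-pressure (BP) variability metrology for the first 24 h
after endovascular thrombectomy, and its association with radiological
haemorrhagic transformation (HT).

## The problem

After mechanical reperfusion of a large-vessel stroke, bleeding into the
infarcted tissue (HT, seen on 24–36 h follow-up imaging) is a feared
complication. BP *variability* — not just BP level — is a candidate risk
marker, but the standard arm-cuff monitoring schedule (a reading every
15 min for 2 h, every 30 min for 6 h, then hourly) cannot resolve
fluctuations on minute timescales. Continuous non-invasive finger-cuff
monitoring, averaged to 1-min samples, can. `bpvar` implements the full
analysis chain needed to compare the two monitoring modalities head to head
on the same patients:

1. **Data model / IO** — long-format CSV recordings (per patient, source
   `continuous`/`intermittent`, channel SBP/DBP/MBP, minute, mmHg) plus a
   clinical covariate table; MBP = SBP/3 + 2·DBP/3 where not recorded.
2. **QC** — plausibility bounds, a step-change limit, and a rolling Hampel
   rule (flag |x − med| > 5·MAD over a 15-min window of valid samples);
   Gaussian-filter imputation of gaps < 5 min; per-period eligibility:
   outcome and covariates available, ≥30% valid data in *both* sources, and
   a contiguous run of ≥128 valid minutes.
3. **Features** — per 8-h window (P1 = 0–8 h, P2, P3, plus the full day),
   per source and channel: mean, maximum, range, SD, coefficient of
   variation, % of readings above threshold (SBP > 185, DBP > 110,
   MBP > 130 mmHg), computed on observed samples only; and, for the
   continuous source, normalised discrete-wavelet band energies

   E_j = (1/T) Σ_k d_{j,k}²   [mmHg²/min]

   over five dyadic oscillation-period bands, from an orthogonal periodic
   DWT (16-tap least-asymmetric filter by default) of the mean-subtracted
   longest contiguous span.
4. **Inference** — per-feature logistic regression reported as the odds
   ratio of HT per 1-SD shift, univariable and adjusted for NIHSS category,
   admission MBP, time to reperfusion, IV thrombolysis and periprocedural
   antithrombotics; and a stratified 10-fold cross-validated comparison of
   ridge-logistic models on all continuous vs all intermittent features
   (rank AUC-ROC and average precision, paired fold t-tests).
5. **Synthetic cohorts** — a generator whose band-limited oscillations are
   random-phase sinusoid mixtures with closed-form band energies, artefact
   spikes, wear-off missingness, a scheduled noisy cuff, and an HT outcome
   whose log-odds rise with the latent sub-32-min oscillation energy. Every
   stage of the pipeline is validated against this stated world.

## Worked example

```r
library(bpvar)
cfg <- run_config(simulate = list(n_patients = 200), seed = 42,
                  windows = c("P1", "FULL24"), outdir = "readme_run")
report <- run_pipeline(cfg)
cat(summarize_run(report), sep = "\n")
```

prints (verbatim):

```
bpvar run (seed 42), 2 window(s)
== window P1: eligible n=184
   HT: 46 (25%)
   top adjusted features: cont_SBP_range_mmHg (OR 2.01, p=0.000113); cont_DBP_range_mmHg (OR 1.85, p=0.000588); cont_DBP_wav_2_4_mmHg2_per_min (OR 2.08, p=0.000728); cont_MBP_range_mmHg (OR 1.76, p=0.00145); cont_DBP_sd_mmHg (OR 1.76, p=0.00156)
   CV AUC continuous 0.61 (0.51-0.71) vs intermittent 0.58 (0.53-0.64) (paired p=0.556)
   CV AP  continuous 0.50 (0.38-0.63) vs intermittent 0.39 (0.31-0.47) (paired p=0.106)
== window FULL24: eligible n=154
   HT: 42 (27%)
   top adjusted features: cont_MBP_wav_2_4_mmHg2_per_min (OR 1.91, p=0.00228); cont_DBP_wav_2_4_mmHg2_per_min (OR 1.88, p=0.00253); cont_SBP_wav_2_4_mmHg2_per_min (OR 1.78, p=0.00496); cont_SBP_range_mmHg (OR 1.74, p=0.00593); int_SBP_sd_mmHg (OR 1.74, p=0.00703)
```

Reading this: of the 200 simulated patients, 184 meet the first-8-h
eligibility ladder and 46 (25%) have the HT label. The continuous-source
range, SD and short-period wavelet-energy features show the strongest
covariate-adjusted associations (OR per 1-SD ≈ 1.8–2.1) — exactly the
feature classes the generator's outcome mechanism rewards — while the
cross-validated model comparison shows a modest AUC advantage for
continuous features. All tables (eligibility, features, associations,
CV folds, manifest) are written under `readme_run/`; re-running with the
same config reproduces them bit-identically.

A command-line front end covers the same pipeline:

```sh
Rscript inst/cli/bpvar.R run-all --seed 42 --outdir out --windows P1,FULL24
```

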