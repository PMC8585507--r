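# tcrstrong

Quantifying T cell receptor (TCR) signal strength — from fluorescent-Timer
reporter kinetics in mice to a transcriptomic score that stratifies melanoma
patient outcomes under anti-PD1 therapy.

## What this package is for

T cells integrate the strength of TCR engagement into transcriptional
programs, and checkpoint blockade (anti-PD1) effectively increases the TCR
signal strength a T cell experiences. `tcrstrong` implements the
computational side of that analysis for immunologists and computational
biologists:

* **Timer reporter simulation and quantification.** An NFAT-driven
  fluorescent Timer reporter matures irreversibly from blue to red, so a
  cell's position in blue–red space encodes time since transcription. The
  package solves the maturation kinetics

  dB/dt = s(t) − λ_B·B,  dR/dt = λ_B·B − λ_R·R

  with λ = ln 2 / t½ (blue t½ = 4 h, red t½ = 120 h), simulates
  flow-cytometry samples under immunization / re-challenge protocols
  (digital per-cell activation via a Hill dose-response, dose-dependent
  threshold recalibration, checkpoint-blockade multipliers), and quantifies
  events by Timer angle θ = atan2(red, blue) and signal locus
  (*new* / *persistent* / *arrested*).

* **Signature scoring.** The TCR.strong score of a sample is the geometric
  mean of the offset TPM of five genes — *TNFRSF4, ICOS, IRF8, TNIP3,
  STAT4*:

  score_s = exp( (1/5) Σ_g ln TPM_gs ),  TPM_gs = FPKM_gs / Σ_g FPKM_gs × 10⁶ + 0.01

  with a `counts → CPM` path for count data and a 4-gene T-activation
  comparator (*NR4A1, CD69, IL2RA/CD25, TNFRSF9*).

* **Signature derivation.** Thresholded up-regulated DEG sets from four
  contrasts — responders (Res), on-therapy (OT), 4-h strong TCR stimulation
  (4 h), and anti-PD1 re-challenge (PD1) — are intersected and classified
  into groups I–VI; the signature is the union of groups I and II.

* **Survival stratification.** Responder classification (CR/PR/SD vs PD),
  median-split into High/Low score groups, Kaplan–Meier estimation,
  log-rank (Mantel–Cox) and Mann–Whitney U tests, and paired pre/on-therapy
  score changes.

* **Synthetic cohorts.** Seeded generators for paired pre/on expression
  cohorts with responder-specific signature effects, survival endpoints with
  a score-linked hazard (h_i = h₀·exp(β·z_i)), and DEG tables that encode
  prescribed set memberships exactly — so the whole pipeline can be
  exercised and validated end to end without any external data.

## Worked example

```r
library(tcrstrong)

# a synthetic anti-PD1 cohort at the default study conditions
cfg <- synth_cohort_config(seed = 42)   # 31 responders, 24 non-responders
coh <- generate_cohort(cfg)
head(coh$scores, 3)
#>   sample_id signature  score
#> 1 PT001     TCR.strong 3693.
#> 2 PT002     TCR.strong 2984.
#> 3 PT003     TCR.strong 3350.

on <- subset(coh$metadata, timepoint == "on")
on$score <- coh$scores$score[match(on$patient_id, coh$scores$sample_id)]
resp <- classify_response(on$bor)
mannwhitney_u(on$score[resp == "responder"], on$score[resp == "nonresponder"])
#> U = 744, two-sided p = 2.73e-10   (responders score higher on therapy)

strat <- stratified_survival(on, endpoint = "PFS")
strat$median                         # 2895 (TPM-scale score cut)
strat$test                           # log-rank chi-square 13.79, p = 0.000204
km_survival_at(strat$curves$High, 365)  # 0.370
km_survival_at(strat$curves$Low, 365)   # 0.0357
```

The score cut splits the cohort at its median on-therapy TCR.strong score;
under the default protective score–hazard link (β = −0.7) the High group
retains 37% progression-free survival at one year versus 3.6% in the Low
group, and the log-rank test rejects equality.

On the reporter side:

```r
kin <- timer_kinetics()                       # blue t1/2 4 h, red t1/2 120 h
solve_timer(kin, signal_schedule(cbind(0, 2)), c(2, 4, 12, 24))
#>   time_h   blue   red
#> 1      2 169.    30.9    # end of the transcription pulse: blue-high
#> 2      4 120.    79.7    # maturing: blue + red
#> 3     12  29.9  163.     # persistent locus
#> 4     24   3.73 177.     # arrested: red only, blue decayed
```

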