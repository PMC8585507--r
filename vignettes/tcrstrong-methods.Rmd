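---
title: "Models and methods behind tcrstrong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrstrong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrstrong)
```

This vignette is the package's own account of its models: the Timer
reporter kinetics and the measurement model layered on top of them, the
signature score and its unit transforms, the set-intersection derivation,
the survival statistics, and the synthetic data generators used to
validate everything. It also records the numerical and design choices made
where the problem was genuinely open, and what the synthetic validation
does and does not establish about real data.

## 1. Timer reporter kinetics

A fluorescent Timer protein is translated in a blue form that matures
irreversibly into a red form. With NFAT-driven transcription active the
reporter is produced at rate $s(t)$, and the two fluorescent pools obey

$$\frac{dB}{dt} = s(t) - \lambda_B B, \qquad
  \frac{dR}{dt} = \lambda_B B - \lambda_R R,$$

with $\lambda = \ln 2 / t_{1/2}$ and half-lives of 4 h (blue) and 120 h
(red). The model deliberately attributes *all* blue loss to maturation
into red rather than adding a separate immature-protein degradation rate:
a single maturation parameter reproduces the quoted blue half-life and
keeps the model identifiable from blue/red trajectories alone.

`solve_timer()` evaluates the exact piecewise solution. On any interval
where $s$ is constant, starting from $(B_0, R_0)$,

$$B(\tau) = \frac{s}{\lambda_B} + C e^{-\lambda_B \tau}, \qquad
  C = B_0 - \frac{s}{\lambda_B},$$

$$R(\tau) = R_0 e^{-\lambda_R \tau}
  + \frac{s}{\lambda_R}\left(1 - e^{-\lambda_R \tau}\right)
  + \frac{\lambda_B C}{\lambda_R - \lambda_B}
    \left(e^{-\lambda_B \tau} - e^{-\lambda_R \tau}\right),$$

with the $\lambda_R \to 0$ limit handled separately (useful as a
conservation check: with $\lambda_R = 0$ and $s = 0$, $B + R$ is
constant). The solver walks the union of schedule breakpoints and
requested times, so there is no discretization error; the test suite
cross-checks it against a fourth-order Runge–Kutta integration at step
0.01 h whose steps are aligned with the transcription on/off boundaries
(a fixed-grid integrator straddling the discontinuities is only accurate
to about $10^{-3}$ relative, which is a property of the integrator, not
of the solution).

### Activation, recalibration, blockade

Per-cell activation is digital: at each dose $d$ a cell crosses the
activation threshold with Hill probability

$$p = \frac{d^n}{d^n + (\mathrm{EC}_{50} \cdot m)^n},$$

and every activated cell then follows the *same* deterministic kinetics,
with `signal_duration_h` of transcription per activation. Dose therefore
moves the responding fraction, not the trajectory — the simulator analogue
of digital single-cell activation with graded population responses.

The multiplier $m$ encodes two biological effects at re-challenge:

* **Threshold recalibration.** A priming dose within the preceding
  `recalibration_reset_h` (default 72 h) raises the effective threshold by
  $1 + \kappa \cdot d_\mathrm{prime}/\mathrm{EC}_{50}$ ($\kappa$ default 1).
  The functional form is this package's choice: the underlying data show a
  dose-dependent, reversible threshold shift but no equation, so the
  simplest monotone, dose-proportional form was adopted, with a hard reset
  beyond the window.
* **Checkpoint blockade**, applied to re-challenge doses only:
  `blockade_ec50_mult` $\le 1$ lowers the threshold, and
  `blockade_rate_mult` $\ge 1$ raises the transcription rate of
  re-challenge signaling episodes. Property tests verify both directions
  (more responders; brighter blue among responders).

### Measurement model and quantification

Measured fluorescence is `kinetic value × LogNormal(mean 1, CV
noise_cv)` plus additive Gaussian autofluorescence truncated at zero.
Defaults — transcription rate 100 a.u./h, background 10 ± 3 a.u., CV
0.25 — were chosen once to give a clearly separated positive population
over an autofluorescence floor, which is the regime the quantification
assumes. The background SD is a package parameter (the positivity rule
needs one); positivity gates are control mean + 3 SD per channel.

Normalization maps each channel to $[0, 100]$: subtract the control mean,
divide by the 99th percentile of the positive events, scale by 100 and
clip. The Timer angle is $\theta = \mathrm{atan2}(red_n, blue_n)$ in
degrees ($0°$ = new signal, $90°$ = arrested), averaged over positive
events only. The specific constants (mean subtraction, 99th percentile,
3 SD) are stand-ins for a previously published quantification algorithm
whose constants are not restated in the source describing this analysis;
they are documented here precisely because they are package choices.

`signal_duration_h` defaults to 2 h — a transient transcription pulse.
This value was fixed from the kinetics: with a 4 h blue half-life, a
short pulse makes the simulated population peak in Blue$^+$ cells within
the first hours and accumulate $>90\%$ of positives in the arrested locus
by 24 h, matching the observed arrest of reporter transcription within
one day. Longer durations leave too much blue at 16–24 h to reproduce
that arrest.

### Seeding

One master seed; cell $i$ draws from a stream seeded deterministically
from $(\text{seed}, i)$ (a Weyl-sequence hash into 31 bits). Growing
`n_cells` therefore never reshuffles earlier cells, and every simulation
is bit-reproducible.

## 2. Signature scores and unit transforms

The TCR.strong score is the geometric mean of the offset TPM of
*TNFRSF4, ICOS, IRF8, TNIP3, STAT4*; the T-activation comparator uses
*NR4A1, CD69, IL2RA, TNFRSF9* (CD25 is resolved to IL2RA via the
signature's alias map — one canonical symbol).

$$\mathrm{TPM}_{gs} = \frac{\mathrm{FPKM}_{gs}}{\sum_g \mathrm{FPKM}_{gs}}
  \times 10^6 + 0.01, \qquad
  \mathrm{score}_s = \exp\Big(\tfrac1k \sum_g \ln v_{gs}\Big).$$

Two details matter:

* **The offset comes after the ratio step.** Because of that order, the
  composition `signature_score(fpkm_to_tpm(x))` is *exactly* invariant to
  per-sample rescaling of FPKM — adding the offset before normalizing
  would break this. The same transform with the same offset serves count
  data as CPM.
* **Missing genes are a hard error** by default; `allow_missing = TRUE`
  scores on the intersection and warns, mirroring the reality that a gene
  may be undetectable in a given dataset. Nothing is dropped silently.

The per-sample TPM denominator runs over all genes present in the input
matrix; whether the original patient-level sums ran over all annotated or
only detected genes cannot be settled from the available text, and the
all-genes convention is the reproducible one for a self-contained matrix.

## 3. Derivation: thresholds, orthologs, groups I–VI

Up-regulated DEG sets use strict inequalities — `log2fc > 0.5` and
`padj < 0.1` for the human contrasts, `log2fc > 1` and `padj < 0.05` for
the mouse dose contrast, `padj < 0.05` alone for the mouse anti-PD1
contrast — so boundary values are excluded, matching the stated "greater
than / less than" wording.

Mouse symbols map to human through a static override table plus an
uppercase rule, never a live database query, for reproducibility. Riken
clones (`…Rik`), predicted `Gm` models and digit-led identifiers are
reported as unmapped rather than guessed.

Genes upregulated in responders (Res) are partitioned by membership of
the OT, 4-h and PD1 sets into groups I–VI (a 16-pattern truth table,
tested exhaustively); the derived signature is the union of groups I and
II, i.e. anti-PD1 pharmacodynamic correlates that mark strong TCR
signaling plus responder-only strong-TCR/anti-PD1 genes. The classifier
labels every gene rather than only annotated exemplars; genes outside Res
are `unassigned`.

## 4. Survival statistics

* **Response**: CR/PR/SD → responder, PD → non-responder, NE/missing →
  excluded (hard error on unknown codes).
* **Median split**: the midpoint-of-order-statistics median; scores
  strictly above the cut are High, ties at the median go Low. The tie
  rule is a package decision (the convention is not stated in the source
  analysis) and the cut is externally settable, so a subgroup can reuse a
  whole-cohort median — the default for subgroup curves.
* **Kaplan–Meier and log-rank** go through the `survival` package
  (`survfit`, `survdiff` with $\rho = 0$), i.e. the product-limit
  estimator and the Mantel–Cox chi-square on 1 df, two-sided. The test
  suite validates both against hand-coded product-limit and
  hypergeometric O−E arithmetic and a permutation reference, and checks
  type-I error calibration (5% ± 2% over 1,000 null simulations at
  n = 25 per arm).
* **Mann–Whitney U** wraps `wilcox.test`: exact two-sided enumeration
  when $\min(n, m) \le 8$ with no ties, otherwise the tie-corrected
  normal approximation without continuity correction (so identical
  samples give $p = 1$). The switch point sits where the cohort sizes of
  interest (7–31 per group) straddle the approximation regime; the exact
  path is verified against full enumeration of all assignments.
* **Paired change**: per-patient on−pre deltas by response group;
  patients lacking either timepoint are reported and excluded, duplicate
  timepoints are an error.

Stratification uses on-therapy scores only; pre-therapy records
contribute only to the paired change. Because only ranks enter the median
split, stratification is invariant to strictly monotone transforms of the
score (tested).

## 5. Synthetic cohort generator

The generator emulates the statistical structure of paired pre/on
anti-PD1 melanoma cohorts, not their gene-level detail:

* log2 FPKM per gene $\sim \mathcal N(3, 1.5^2)$, per-observation noise
  $\mathcal N(0, 0.25^2)$ — log-normal expression, the standard model for
  FPKM-scale data; no count-level simulation since the scored pipeline
  consumes FPKM/CPM.
* On-therapy responders receive a `signature_effect_log2fc` (default 1)
  on the five TCR.strong genes; the T-activation genes carry a separate,
  default-zero effect, so "TCR.strong separates, T activation does not"
  holds by construction at the defaults.
* Survival: exponential event times with hazard
  $h_i = h_0 e^{\beta z_i}$, $z_i$ the standardized log score,
  $h_0 = \ln 2 / 180\,\mathrm{d}$ for PFS (OS uses twice the baseline),
  administrative censoring at 1,095 d. Exponential times keep the model
  analytically transparent; $\beta$ defaults to −0.7 (protective).
* Cohort sizes default to 31 responders / 24 non-responders with ~40%
  ipilimumab-naive, the on-therapy analysis cohort sizes of the
  motivating study. Effect sizes are calibration choices — the study
  reports p values, not effect magnitudes — fixed once and not tuned.

`generate_deg_tables()` inverts `threshold_deg()`: member genes are
placed strictly inside the inclusion region and non-members strictly
outside, with ≥ 0.05 clearance from each threshold. One numerical caveat:
on the member side of the `padj < 0.05` preset a 0.05 clearance is
impossible (adjusted p values cannot go below zero), so the member-side
padj clearance is capped at half the threshold. Round-trip recovery is
exact and property-tested over random membership patterns.

### What the synthetic validation shows — and does not

Passing tests establish that the implementation computes the intended
quantities: transforms that are exactly scale-invariant, a classifier
identical to its truth table, survival statistics that match independent
arithmetic, a simulator whose half-lives and dose-(in)dependence behave
as specified, and a generator whose effects are recovered downstream. It
does *not* establish that real cohorts carry the modelled signal: real
FPKM matrices have gene–gene correlation, batch structure, varying tumor
purity and non-exponential hazards, none of which the generator attempts
to match. Real-data conclusions require the real accessions, which the
pipeline can consume through the same TSV interfaces.

## 6. Problem sizes and numerical choices

The shipped test-and-acceptance configuration uses the sizes at which the
statistical claims are sharp but cheap: 5,000 activated cells per dose
condition for the Timer-angle dose-invariance comparison (the two
trajectories then agree within 1°, at equal Monte-Carlo precision per
condition), 1,000 null simulations at 25 patients per arm for log-rank
calibration, 100 random membership patterns for DEG round-trips, 500
patients for hazard-coefficient recovery (Cox regression recovers
$\beta = -0.7$ within ±0.2), and the default 55-patient cohort for the
end-to-end stratification. Degenerate inputs are signalled, not patched:
empty controls, zero-variance channels, zero library sizes, all-tied
scores (warning, all Low), zero total events in the log-rank test, and
undefined Timer angles at the origin are all explicit errors or warnings.

## 7. Known limitations

* The Timer measurement constants stand in for a previously published
  quantification algorithm; absolute angles are therefore comparable
  within this package, not across implementations.
* Persistent-locus substructure is not modelled (only the three named
  loci), and there is no FCS parsing, no TCR-affinity or spatial
  modelling, and no fit of kinetics to real flow files.
* No Cox modelling, competing risks or multiple-testing correction across
  endpoints in the stratification module; the derivation module does not
  re-estimate differential expression — DEG tables are inputs.
* The ortholog map is intentionally minimal; a real cross-species
  analysis should supply a curated table through the same interface.
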