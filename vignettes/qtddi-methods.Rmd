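---
title: "Methods: simulating drug-drug interaction effects on the QT interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating drug-drug interaction effects on the QT interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two QT-prolonging drugs are co-administered, two mechanisms compound:
a pharmacokinetic interaction (a metabolic inhibitor raises the victim
drug's exposure) and a pharmacodynamic one (both drugs block cardiac ion
channels at once). Terfenadine with a CYP3A4/2D6 inhibitor is the classic
case. In-silico trial simulation can estimate the combined effect on the
Bazett-corrected QT interval (QTcB), but there is no agreed model for how
two drugs' channel-block fractions combine. This package implements three
candidate interaction models inside a complete simulation pipeline, plus
the evaluation machinery for comparing predicted against observed clinical
QTc triplets, so the consequences of the model choice can be quantified.

## Interaction models

Each drug's fractional block of a current is the Hill equation
$E = C^n / (IC_{50}^n + C^n)$. For two drugs with fractions $E_A$, $E_B$
the combined block is, per channel:

* capped sum: $\min(E_A + E_B,\, 1)$ — additivity up to the physiological
  ceiling of complete block;
* Bliss independence: $E_A + E_B - E_A E_B$ — independent sites and
  mechanisms;
* Loewe additivity: $(E_A + E_B - 2 E_A E_B)/(1 - E_A E_B)$ — dose
  addition for a shared site. At $E_A = E_B = 1$ the expression is $0/0$;
  we define the result as 1 by continuity (both drugs alone already block
  completely), and this is tested.

For interior fractions Loewe $\le$ Bliss $\le$ capped sum, with
$\text{Bliss} - \text{Loewe} = E_A E_B (1-E_A)(1-E_B)/(1-E_A E_B) \ge 0$;
all three are symmetric, monotone, and reduce to $E_A$ when $E_B = 0$.
For Hill exponent 1 and a shared IC50, Loewe combination reproduces
$E(C_A + C_B)$ exactly — the dose-addition identity, tested to 1e-12.
None of the models carries a synergy or antagonism term; only pairwise
combination is supported because the Loewe expression used is inherently
a two-drug formula.

## Cardiac electrophysiology

The myocyte is the ten Tusscher–Panfilov 2006 human ventricular model
(endo/M/epi parameter sets). Drug action is tonic conductance scaling:
$g' = g (1 - E)$ for $g_{Kr}, g_{Ks}, g_{Na}, g_{CaL}$, identical across
channels and without state dependence — the simplest defensible reading of
"maximal conductances modified by total inhibition". Integration uses
Rush–Larsen updates for the twelve gates and forward Euler for voltage and
concentrations (rapid-buffering quadratic updates for calcium), with
dt = 0.02 ms by default; halving dt moves APD90 by well under 1 ms.

The tissue model is a 1D transmural monodomain cable: by default 25 endo /
35 M / 40 epi cells at 0.15 mm spacing with diffusion 0.154 mm²/ms,
stimulated at the endo end, solved by operator splitting (reaction per
cell, explicit diffusion with no-flux boundaries; the stability ratio
$D\,dt/dx^2$ is checked). The pseudo-ECG is the standard unipolar-lead
integral $\Phi_e(t) \propto -\int (\partial V/\partial x)\,
\partial(1/r)/\partial x\,dx$ at an axial electrode 20 mm beyond the epi
end; the long-APD M cells mid-strand give the upright T wave. Electrode
distance only scales amplitude, which is tested.

QT is measured as T-wave end minus QRS onset: onset where $|d\Phi/dt|$
first exceeds 5 % of its maximum, T end by the tangent method (steepest
terminal T-wave slope extrapolated to the isoelectric baseline, the
baseline being the median of the final tenth of the beat). Both landmarks
are invariant to time shifts and amplitude scaling. RR is the pacing cycle
length (1000 ms default, so QTcB = QT at default pacing); QTcB = QT /
$\sqrt{RR/1000}$.

Each strand run first pre-paces every subtype as a single cell (50 beats
full scale) under its drug-scaled conductances and seeds the cable with
those states; the cable is then paced for a small number of beats and the
final beat is analysed. The scaled-down configuration used throughout the
test suite (50 cells, 20 pre-pacing beats, 2 strand beats) preserves
propagation, the transmural gradient and the monotone response to IKr
block, at a few seconds per simulation; `strand_config()` is the
full-scale geometry.

## Synthetic pharmacokinetics

The exposure engine that produced the published heart-tissue profiles is a
proprietary PBPK platform. Its role here is played by a deliberately
simple generator whose contract is exposure fidelity, not mechanism: a
one-compartment first-order absorption model
$C(t) = \frac{F D k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})$ (with the
analytic $k_a = k_e$ limit), heart tissue = plasma × a constant partition
ratio (default 1). `calibrate_pk()` solves deterministically for
$(k_e, V)$ so simulated Cmax and AUC match a target pair within 1 %;
the Cmax/AUC ratio fixes $k_e$ by bracketed root-finding (the
one-compartment bound Cmax/AUC < $k_a/e$ is checked and genuinely
infeasible pairs are rejected). Where the bundled exposure table prints a
Cmax but no AUC, the profile shape is fixed by an illustrative terminal
half-life of 8.5 h; only the two studies with printed AUCs participate in
the AUC round-trip checks.

Inter-individual variability is log-normal on $k_a$, $k_e$ and $V$
(default CV 30 %, arithmetic means preserved), seeded and reproducible;
the sampled CV is recovered within 0.02 at n = 10 000. The interaction's
PK side enters only through an exposure modifier — Cmax and AUC
multipliers taken from the ratio of combination-arm to single-drug
predicted values — applied as amplitude times time-rescaling,
$C'(t) = m_c\,C(t\,m_c/m_a)$, which hits both targets exactly.

The in-vitro IC50/Hill values for terfenadine and the seven inhibitors are
not public; `drug_blocks_synthetic.csv` ships illustrative values (hERG
IC50s in the literature-plausible range, Hill 1) and is labelled synthetic.
Absolute predicted QTc levels therefore carry no meaning here; the
package's quantitative claims live in the distance arithmetic on the
published table and in the qualitative/ordering properties of the engine.

## Virtual trials

A trial design is (study, n subjects, n replicates — 10 in the published
design — arms BL/T/I/T+I, models, pacing, master seed). Per replicate the
population is resampled with seeds derived by a fixed rule (master +
1000 × replicate), so results are reproducible across machines. Each
subject's block-driving concentration is the heart-tissue concentration at
the drug's own Tmax — a static worst-case coupling, chosen because the
temporal coupling between profile and ECG is genuinely open; it is a
modelling choice, not a data fact, and a beat-by-beat coupling is out of
scope. The same subject (same PK draw, same strand) is carried across arms
and models, so per-subject ΔQTcB contrasts are paired — which is what makes
the per-patient threshold-flip analysis meaningful. Identical block
vectors are memoized within a run (the baseline arm costs one simulation,
and degenerate designs collapse almost entirely).

Summaries average over subjects within replicate, then over replicates,
with 95 % t-intervals over replicate means.

## Evaluation

For a study with observed and predicted QTc triplets (BL, T, T+I), both
baselines are subtracted within source and

$$D = \sqrt{(\Delta T_p - \Delta T_o)^2 + (\Delta TI_p - \Delta TI_o)^2 +
((\Delta TI_p - \Delta T_p) - (\Delta TI_o - \Delta T_o))^2}.$$

D is invariant to adding a constant to either triplet and is checked
against an independent brute-force evaluation on random triplets. Five of
the eight bundled studies' capped-sum distances reproduce the printed
values exactly to two decimals (paroxetine 4.69, ketoconazole 48.61,
clarithromycin 21.43, erythromycin [second study] 14.27, itraconazole
24.05), and ketoconazole's Bliss/Loewe and the second erythromycin study's
Bliss distances agree within 0.2 %. The remaining printed distances
(fluoxetine, fluconazole, the first erythromycin study) are not
reproducible from the rounded printed triplets under any baseline
convention we tried — recomputation gives ≈1.41, ≈18.3 and ≈17.8
respectively — which we attribute to the original analysis using unrounded
internal values; the recomputed values are reported as-is and those cells
are excluded from exact-match tests. The first erythromycin study reports
only QT changes; its observed deltas are used directly.

Model ranking sorts by D with ties broken in the fixed order sum, Bliss,
Loewe (declared; ties do not occur in the bundled data). Observed and
predicted mean changes are compared with a two-sided Welch t test
(`stats::t.test`, unequal variances), with no multiple-testing
correction. The per-patient analysis counts a subject as a "case" when the
per-model ΔQTcB predictions straddle the 5-ms threshold of regulatory
concern (minimum below, maximum at or above), reported as a percentage.

## What the synthetic data does and does not show

The generator emulates: exposure magnitudes calibrated to the bundled
predicted Cmax/AUC values, log-normal population variability, an
inhibitor-induced exposure increase, and concentration-dependent
multi-channel block. It does not emulate: mechanistic CYP inhibition,
time-varying block within a beat, channel-specific binding kinetics,
demographic covariates, or measurement noise in clinical QT reading.
Passing tests therefore demonstrate internal correctness and the ordering/
invariance properties of the method — not clinical predictive accuracy,
which in the original study rests on proprietary PK inputs and in-vitro
data that are not public.

## Numerical choices and limitations

* dt = 0.02 ms, explicit diffusion; the stability ratio is validated and
  dt-halving convergence is tested.
* QT detection assumes a dominant-polarity T wave; on very short strands
  (about half the scaled-down size) the T wave can become biphasic and the
  tangent landmark unstable, which is why 50 cells is the smallest
  configuration the package uses.
* Loewe at complete double block is defined by continuity; capped-sum
  saturation means model differences vanish as block approaches 1.
* Problem sizes in the test suite (50-cell strand, 1-2 replicates, 1-2
  subjects, 15-30 pre-pacing beats single-cell) are the package's
  desk-scale defaults; full-scale settings (100 cells, 50+ pre-beats,
  10 replicates) are one argument away.
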