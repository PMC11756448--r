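---
title: "Donor-dependent DILI risk prediction: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor-dependent DILI risk prediction: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilirisk)
```

## The problem

Idiosyncratic drug-induced liver injury (DILI) strikes a minority of
patients, often without dose proportionality, and is a leading cause of
post-approval drug withdrawal. Screens built on a single cell background
cannot, by construction, see inter-individual variability in susceptibility.
Donor-dependent spheroid assays address this by measuring a whole cohort of
donors per drug: each donor contributes a viability dose-response curve, and
the *fraction of susceptible donors* — not a single potency number — drives
the risk call. `dilirisk` implements that analysis chain end to end, plus a
synthetic cohort generator so every stage is testable without access to any
proprietary donor data.

## The dose-response model

All concentrations are expressed as multiples of Cmax, the drug's maximal
therapeutic plasma concentration, so potency and safety margins are directly
interpretable against clinical exposure. Per donor × drug, viability
(percent of vehicle control) is fit by the constrained inhibitory Hill
model — the "log(inhibitor) vs. normalized response, variable slope" form
with plateaus fixed at 100 and 0:

$$V(c) = \frac{100}{1 + 10^{(\log_{10} c - \log_{10}\mathrm{IC}_{50})\,h}}$$

The internal slope $h$ is positive; following the reporting convention for
inhibitory curves the returned `hill_slope` is $-h$. Fixing Top/Bottom keeps
the model estimable from a six-point dose series (0.01×–100× Cmax,
triplicate wells by default) even when a curve barely enters its descent.

Numerical choices:

* **Optimizer.** Levenberg–Marquardt least squares under box bounds
  $\log_{10}\mathrm{IC}_{50} \in [\log_{10}(\min c) - 2,\ \log_{10}(\max c) + 2]$,
  $h \in [0.1, 10]$, multi-started from 5 log-spaced guesses across the dose
  range; the lowest-RSS converged start wins. The widened IC50 bounds let
  curves whose potency lies beyond the tested range still be estimated well
  enough to be declared non-toxic. Optimizer failure on every start yields
  `converged = FALSE`, never an error.
* **Replicates** enter the loss individually rather than averaged, keeping
  the replicate-level information; the fit is unweighted.
* **Viability above 100%** is kept during fitting — clipping would bias the
  top plateau downward.
* **Censoring.** A curve that still predicts more than 80% viability at the
  highest tested dose cannot demonstrate the 20%-death criterion within the
  tested range; it is flagged `censored_low_toxicity` and its inhibitory
  concentrations are `Inf`. The 80% threshold is deliberately the complement
  of the 20% death criterion used for scoring.

## From curve to decision

* **Margin of safety.** `MOS20` is the concentration producing 20% cell
  death on the fitted curve, in Cmax multiples — closed form
  $\mathrm{IC}_{20} = 10^{\log_{10}\mathrm{IC}_{50}} (20/80)^{1/h}$. Because
  doses are already Cmax multiples, `MOS20` is the safety margin relative to
  therapeutic exposure.
* **Donor classification.** A donor is DILI positive when
  `MOS20 <= cut_point` (default 100× Cmax, the ROC-calibrated operating
  point). Boundaries are inclusive throughout, mirroring the "at least"
  phrasing of the decision rules.
* **Toxicity score.** `TS = max(0, log10(cut_point / MOS20))`. This formula
  is this package's own reconstruction of a curve-derived toxicity score
  (the original score's formula is not publicly available): it is zero
  exactly for non-positive donors, grows as toxicity moves below the cut
  point, and therefore orders severity. Severity grades bin TS at
  configurable edges (defaults 1, 2, 3 log units) into low / moderate /
  high / severe; note that a donor sitting exactly at the cut point is
  classified positive (inclusive boundary) with TS = 0, a measure-zero edge
  case we resolve in favor of the classification rule.
* **Cohort rule.** A drug is called at clinical DILI risk when at least 10%
  of the cohort is DILI positive (inclusive). Fractions are reported to one
  decimal percent, rounded half away from zero.
* **ROC calibration.** Each donor × drug pair is one observation labeled by
  the drug's clinical DILI status and scored by −MOS20. The ROC is a
  threshold sweep over all unique finite margins; infinite margins
  (non-toxic curves) participate as the least-positive score — dropping
  them would inflate apparent sensitivity and bias specificity. AUC is the
  trapezoidal area, identical to the Mann–Whitney pairwise concordance (a
  test-suite oracle). The operating point maximizes Youden's J, ties
  resolved toward the smaller margin.
* **Cohort planning.** The probability that a cohort of $n$ donors contains
  at least one donor showing an event of incidence $q$ is $1 - (1-q)^n$;
  24 donors give 92% detection of a 10%-incidence event, which is the
  default cohort size of the simulator.

## Covariate associations

Per drug, the package quantifies how donor sex and age relate to DILI risk
and severity: one-way ANOVA partial eta-squared ($\eta_p^2 =
SS_{between}/(SS_{between}+SS_{within})$, equal to classical $\eta^2$ for a
single factor) for sex vs. risk, sex vs. severity, and age vs. risk, and
OLS $R^2$ for age vs. severity on continuous age. Design choices made where
the analysis was genuinely open:

* Risk enters the ANOVA as a 0/1 indicator — a linear-probability
  simplification, adequate for effect-size reporting though not for
  probability modeling.
* Age is dichotomized at 52 years for the risk ANOVA (a published age
  cut-off for elevated adverse-drug-reaction risk); the cut is
  configurable.
* Severity associations use the toxicity score of *all* donors, zeros
  included, so "no injury" carries information rather than being dropped.
* Raw p-values are reported by default, with an optional Benjamini–Hochberg
  switch; effect sizes carry Cohen guideline labels (large above 0.13).
* Degenerate cohorts (constant outcome → effect 0; zero residual variance →
  effect 1) are resolved explicitly rather than left to ANOVA numerics.

## What the simulator emulates — and what it does not

`generate_donors()` + `simulate_viability()` produce cohorts with the
statistical structure the analysis assumes: lognormal inter-donor IC50
variability built from a *shared* donor sensitivity latent (susceptibility
as a donor trait, the default; a switch makes it independent per drug,
since cross-drug correlation of susceptibility is an assumption, not an
established fact), plus per-drug donor spread, optional additive sex and
per-year age shifts on log10 IC50 (age centered at the cohort mean so the
slope's meaning does not depend on cohort composition), Gaussian plate
noise (default SD 5% viability) truncated to [0, 120%] — plate readouts can
exceed 100% of control — and two toxicity archetypes: intrinsic
(dose-dependent, floor 0) and idiosyncratic (plateauing; e.g. a floor of
65% reproduces a drug that kills ~35% of cells and then stays flat).

The simulator does **not** emulate metabolism-driven kinetics, assay drift,
plate-position effects, non-Gaussian outliers, or correlated replicate
error. Passing tests therefore demonstrate that the *statistical machinery*
recovers truth under the model's own assumptions — not that any real assay
satisfies those assumptions.

The bundled `demo_drug_panel()` is a 12-archetype panel (3 clinically
negative, 9 positive, one idiosyncratic plateau archetype, two with
covariate effects) whose potencies were engineered once so that a 24-donor
cohort reproduces the expected pattern of risk calls. It is openly
synthetic: cohort-level quantities computed from it (AUC, effect sizes)
characterize the synthetic panel, not any published dataset.

## Problem sizes and verification

The test suite verifies closed forms against independent oracles (bisection
root-finding for inhibitory concentrations, pairwise concordance for AUC,
explicit sum-of-squares decompositions for eta-squared, Monte Carlo for
detection power) and runs simulation-recovery studies at deliberate desk
scale: 200-donor curve-recovery studies (median |Δlog10 IC50| under 0.15 at
5% noise), 20-seed safe-vs-toxic cohort discrimination, 500-replicate R²
recovery. These sizes were chosen to make sampling error a small fraction
of the tested tolerances while keeping the full suite under a minute.

## Known limitations

* The toxicity score is a reconstruction (see above); absolute TS values
  are not comparable to any published score, though orderings are.
* The per-donor ROC treats donors within a drug as exchangeable
  observations; donor identity across drugs is ignored in the AUC.
* Confidence intervals are not attached to fitted parameters; the pipeline
  reports point estimates and fit diagnostics (RSS, R², censoring flags).
* With fewer than 3 distinct doses a curve is not fit at all; partially
  missing dose series degrade gracefully but are not imputed.
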