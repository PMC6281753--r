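---
title: "Modelling 2-DE spot intensities against clinical outcomes with OPLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 2-DE spot intensities against clinical outcomes with OPLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotopls)
```

## The problem

Two-dimensional gel electrophoresis (2-DE) of depleted plasma yields, for
each sample, a few hundred matched protein spots quantified as integrated
optical density (IOD). Because distinct proteoforms (post-translationally
modified variants of the same protein) resolve as separate spots, the spot
table is a high-dimensional, strongly collinear block: typically far more
spots than samples (here 325 spots against cohorts of 15–23 subjects).
The scientific question is which spots co-vary with a clinical outcome —
pain intensity on the numeric rating scale (NRS), psychological distress
(HADS-total), body mass index, or age — within a patient (CWP, chronic
widespread pain) or control (CON) group.

Ordinary regression is hopeless at this aspect ratio. The chemometric
answer is projection to latent structures: **spotopls** implements
single-response OPLS (orthogonal projections to latent structures)
regression with the surrounding apparatus this kind of study uses — UV
scaling, PCA outlier screening, VIP-based two-step variable selection,
jack-knifed coefficient confidence intervals, CV-ANOVA model validation,
and cross-model "shared proteoform" confounder compensation — plus a
synthetic cohort generator so that every stage can be validated against
planted ground truth.

## The model

With $X$ the column-centred, unit-variance (UV) scaled spot matrix and $y$
the centred/scaled outcome, OPLS splits the systematic variation of $X$
into a component predictive of $y$ and components orthogonal to it. For a
single response all steps are closed form:

* predictive weights $w = X^\top y / \lVert X^\top y \rVert$;
* for each orthogonal component: score $t = Xw$, loading
  $p = X^\top t/(t^\top t)$, orthogonal weight
  $w_o \propto p - (w^\top p)\,w$ (normalised), orthogonal score
  $t_o = X w_o$, loading $p_o = X^\top t_o/(t_o^\top t_o)$, and deflation
  $X \leftarrow X - t_o p_o^\top$;
* finally $t = Xw$ on the filtered matrix and the response loading
  $c = y^\top t/(t^\top t)$, so $\hat y = tc$.

Every model in the emulated workflow uses one predictive plus one
orthogonal component, the form these plasma datasets consistently select.
Reported statistics are $R^2Y = 1 - \sum(y-\hat y)^2/\sum y^2$ (goodness of
fit), $Q^2 = 1 - \mathrm{PRESS}/\sum y^2$ from 7-fold cross-validation
(goodness of prediction), per-variable $p(corr)$ — the loading expressed as
the Pearson correlation between a variable and the predictive score, so it
lives in $[-1, 1]$ — and VIP. For one predictive component with unit-norm
$w$, $\mathrm{VIP}_j = \sqrt{K}\,|w_j|$ and $\overline{\mathrm{VIP}^2} = 1$
exactly, which is what makes the conventional VIP $> 1.0$ threshold ("more
important than average") meaningful. A combined-variation VIP that folds in
the orthogonal components is available (`vip_scores(..., variant =
"total")`) but the predictive-only form is the default and the one the
selection procedure uses, precisely because it preserves the
mean-square-one identity.

## Selection and validation

The two-step procedure (`opls_two_step()`) mirrors how such studies select
variables: a first model on all spots keeps those with VIP strictly above
1.0; a second model is refitted on that subset, and a spot is called
significant when its stage-2 VIP exceeds 1.0 *and* its jack-knifed 95%
confidence interval excludes zero. The jack-knife standard error comes
from the cross-validation sub-models:
$SE_j = \sqrt{\tfrac{G-1}{G}\sum_g (b_{jg}-\bar b_j)^2}$ over $G$ folds,
with a $t_{G-1}$ quantile. Model-level significance uses CV-ANOVA:
$F = \frac{(SS - \mathrm{PRESS})/\mathrm{DF}_{model}}{\mathrm{PRESS}/\mathrm{DF}_{resid}}$
with $\mathrm{DF}_{model}$ = number of fitted components (predictive +
orthogonal), $\mathrm{DF}_{total} = n-1$, $F$ clipped at zero when PRESS
exceeds $SS$; the component-counting convention is exposed as an argument
because published descriptions vary.

Whether the confidence-interval criterion also applies at stage 1 is
ambiguous in the usual description of the procedure; the package defaults
to VIP-only at stage 1 (`stage1_require_ci = FALSE`) with a switch, since
the phrase "selected with VIP > 1.0" describes stage 1 and the combined
criterion describes the final call.

### Cross-validation conventions

Fold assignment is deterministic: samples are sorted lexicographically by
ID (`join_cohort()` enforces this) and folds are dealt round-robin, with 7
folds by default — the historical default of the chemometrics software
this workflow emulates, which does not publish its assignment rule.
Determinism here is what makes the whole pipeline byte-reproducible.

Two pretreatment conventions are implemented for the CV loop. The default,
`cv_scaling = "fixed"`, computes centring/UV scaling once on the full data
and refits only the latent-variable model per fold — this is how the
emulated software cross-validates, and under it the CV-ANOVA test holds
close to its nominal level (measured type-I error 0.044 at $\alpha=0.05$,
$n=24$, $K=20$, 500 null replicates; see `test-acceptance.R`). The
alternative `"refit"` re-estimates the scaler inside each training fold;
it is strictly leakage-free but inflates PRESS through the per-fold mean
estimate, making $Q^2$ slightly lower and the CV-ANOVA test conservative
(type-I error 0.004–0.016 across the shapes we measured). We default to
the software-faithful convention and keep the conservative one available;
neither changes $R^2Y$, VIP, or $p(corr)$.

### A caveat on stage-2 p-values

The stage-2 CV-ANOVA is computed after variables were selected on the same
data, so it inherits selection bias: on pure-noise inputs the stage-2 model
is called significant more often than the nominal 5% (roughly 15–30%
depending on the sample-to-variable ratio), even though the stage-1 model
holds its level. This is a property of the published two-step procedure
itself, not of this implementation; stage-1 statistics are retained in
every result precisely so both can be inspected.

## Outlier screening

Before every regression the scaled X block is screened with unsupervised
PCA (`pca_outlier_screen()`). The number of components is the smallest
explaining 60% of the variance, capped at 5 (configurable; the emulated
software's auto-fit rule is not published). Each sample gets a Hotelling
$T^2$ from its normalised scores, with limits
$\tfrac{A(n-1)}{n-A} F_{1-\alpha}(A, n-A)$, and a DModX-style residual
distance (RMS reconstruction residual relative to the pooled residual,
with an $F$-based 95% limit). "Strong" means beyond the 99% $T^2$ limit;
"moderate" means beyond the 95% (but not 99%) limit or beyond the residual
limit. The screen is advisory by default — `run_model()` warns and
proceeds, matching studies where no outliers are found and none removed —
with `drop_outliers = TRUE` to exclude strong outliers.

## Pretreatment choices

Variables may be log-transformed "if necessary"; since no published
criterion exists, the rule is explicit here: under `log_rule = "auto"` a
variable is flagged when its sample skewness exceeds 2.0 (configurable).
`log1p` is used rather than `log` so that zero IODs — a spot absent from a
gel — stay finite. Zero-variance variables are excluded with a warning.
UV scaling stores training means/SDs so held-out samples are always scaled
with training statistics.

## Report arithmetic

Report tables print, per significant spot, the raw-scale group mean ± SD,
the OD quotient `mean(CWP)/mean(CON)` rounded **half-up** to two decimals,
and an up/down alteration marker. Quotients always use raw IODs over the
full cohort, both groups, even when the model was fitted on transformed
values in one group — the quotient describes group-level regulation, not
the model. The alteration rule is: up iff the unrounded quotient exceeds
1, down iff below 1; exact equality (never observed in real tables, where
1.01 prints ↑ and 0.99 prints ↓) is reported as up with a logged note.

## The synthetic cohort generator

No raw data accompanies studies of this kind, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
with defaults fixed at the emulated study's conditions: 23 CON + 15 CWP
samples and 325 spots. On the log scale each spot is

$$\log x_{ik} = \mu_k + \textstyle\sum_o \beta_{ko} t_{io} + \pi_k u_i +
\log(\phi_k)\,[i \in \mathrm{CWP}] + \varepsilon^{bio}_{ik} +
\varepsilon^{tech}_{ik}$$

* $\mu_k \sim U(\log 50, \log 30000)$: base abundances spanning ~3 orders
  of magnitude, the dynamic range plasma 2-DE tables actually print;
* $t_{io} \sim N(0,1)$: one latent factor per outcome and sample; 20
  disjoint informative spots per outcome carry slope
  $\beta = \pm 0.7$ (random sign), zero elsewhere. The value 0.7, with the
  noise levels below, puts spot–outcome correlations near 0.9 — the regime
  in which such studies report $R^2$ of 0.84–0.97;
* $\pi_k u_i$: one structured component shared by all samples and
  uncorrelated with every outcome, scaled to 30% of the non-informative
  log variance — the y-orthogonal variation the OPLS filter exists for;
* $\phi_k$: multiplicative CWP/CON fold changes on informative spots
  (log-normal, sdlog 0.35, by default; or user-specified per spot),
  reproducing quotient-style up/down regulation;
* biological noise SD 0.2 and technical noise
  $\sigma = \sqrt{\log(1+\mathrm{CV}^2)}$ with CV = 0.20, so the 25%
  replicate-CV bound of 2-DE quantification is an exact, testable property
  of the noise model (`simulate_replicates()`, `replicate_cv()`).

Outcomes are affine in their latent factor with group-specific intercepts
and spreads taken from the cohort descriptives of the emulated study
(e.g. HADS-total $14.0 + 5.3t$ in CWP vs $3.3 + 2.8t$ in CON), clipped and
rounded to their valid ranges; NRS is identically 0 in controls, who
report no pain — which is why no NRS model exists for CON and
`run_model()` refuses a constant outcome. Outcome construction happens
after the latent scores, so the planted X–y association is exactly the
configured structure, and the informative spot numbers are returned as
ground truth.

What the generator does *not* emulate: gel-to-gel missingness, proteoform
charge trains (correlated neighbouring spots), batch effects, and
non-log-normal heavy tails. Passing recovery tests on this generator shows
the pipeline finds planted latent structure at the study's n/K; it does
not certify behaviour under those unmodelled artefacts.

## The seven-model workflow and confounder compensation

`run_study()` fits NRS (CWP only), HADS-total, BMI and age in both groups
— seven models — then recalculates the patient NRS and HADS models after
excluding spots shared with the control-derived BMI/age models and with
each other, the "shared proteoform" compensation used to probe whether an
association with pain or distress is secondary to BMI or age. Exclusions
are recorded per spot with `shared_with:<model>` reason tags, and the
pre-compensation statistics are kept under `$previous`. The compensation
map is configurable as (target, confounders) pairs. The recalculated
significant set can only shrink: it is drawn from the target's stage-1
set minus the removals.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the full suite
completes in seconds: algebraic identities on random 20–25 × 7–30
problems; null calibrations at 100–500 replicates; recovery at the study's
own 38 × 325 shape over 50 generator seeds (mean sensitivity ≈ 0.82,
false-discovery proportion ≈ 0.15 against planted truth). Tolerances:
exact identities at 1e-8–1e-10; stochastic properties at bounds stated in
each test. Degenerate inputs (constant y, zero-variance columns, rank
deficiency, empty stage-1 selection) produce explicit errors or flagged
empty results rather than silent degradation; when a stage-2 subset cannot
support the requested orthogonal components the fit degrades to fewer
components with a warning.

## Limitations

Printed headline statistics of any specific study ($R^2$, $Q^2$, spot
counts) are not reproducible without its raw data and its software's
unpublished CV configuration; this package reproduces the *procedure* and
validates it on synthetic ground truth plus the printed-arithmetic
(quotient) targets. Stage-2 p-values are post-selection (see above).
Multi-response OPLS, OPLS-DA, O2PLS and kernel variants are out of scope,
as are gel image processing and MS identification.
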