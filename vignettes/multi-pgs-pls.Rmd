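---
title: "Ranking correlated polygenic scores with NIPALS partial least squares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking correlated polygenic scores with NIPALS partial least squares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpgspls)
```

## The problem

Modern PRS pipelines can compute thousands of polygenic risk scores per
subject from public scoring files. When several hundred of them — many of
which are near-duplicates of the same trait trained on different source
GWAS — are candidate predictors of a single binary outcome in a cohort of
modest size, ordinary regression fails twice: the predictor count exceeds
the sample size, and the predictors are strongly multicollinear. `mpgspls`
addresses the setting of a case/control psychiatric cohort (history of
peripartum depression, PPD, among parous women with a mood-disorder
diagnosis) with a panel of ~341 PRSs in four trait categories: psychiatric,
hormone/pregnancy, immune-inflammatory, and sleep/circadian.

Partial least squares (PLS) regression handles both failure modes at once:
it extracts a small number of latent components that maximize the
covariance between the predictor block and the outcome, using *all*
predictors without discarding any, and then ranks each predictor by its
contribution to those components.

## The model

Let $X$ be the $n \times p$ autoscaled score matrix and $y$ the autoscaled
0/1 outcome (1 = PPD history). The NIPALS algorithm extracts components
$a = 1, \dots, A$:

$$w_a = \frac{X_a^\top y_a}{\lVert X_a^\top y_a\rVert},\quad
  t_a = X_a w_a,\quad
  p_a = \frac{X_a^\top t_a}{t_a^\top t_a},\quad
  q_a = \frac{y_a^\top t_a}{t_a^\top t_a},$$

followed by deflation $X_{a+1} = X_a - t_a p_a^\top$ and
$y_{a+1} = y_a - q_a t_a$. For a single response the NIPALS iteration
converges in one pass, so each weight vector is analytically
$X_a^\top y_a$ normalized; the iterative loop is retained for generality
and stops at a $10^{-12}$ weight-change tolerance or at the floating-point
floor, whichever is attainable (late components deflate $X$ and $y$ to
near-zero, where $10^{-12}$ is not). Per-component explained variances are
$R^2X_a = \lVert t_a p_a^\top\rVert_F^2 / \lVert X_1\rVert_F^2$ and
$R^2Y_a = q_a^2\, t_a^\top t_a / \lVert y_1\rVert^2$; regression
coefficients are $b = W (P^\top W)^{-1} q$.

Modelling choices worth making explicit:

* **Linear PLS on a binary outcome.** The outcome is coded 0/1, autoscaled
  and fitted with linear PLS — no logistic link. This keeps the weights,
  $R^2Y$ and VIP on the classical chemometrics footing, and the first
  latent variable serves directly as the classifier score for the ROC.
* **Autoscaling.** PRSs from different scoring files have arbitrary units,
  so both $X$ and $y$ are centered and scaled to unit variance. Unit
  variance is also the convention under which the VIP > 1 rule means
  "more important than an average predictor".
* **Sign convention.** Each component is flipped so its largest-magnitude
  weight is positive. This makes fits bitwise reproducible while
  preserving all relative signs; a predictor's reported direction
  (positive weight = predicts PPD presence) is unaffected by the
  convention because it is applied to the whole component.
* **The diagnosis covariate.** The whole-sample model includes the
  mood-disorder diagnosis (MDD vs. BD) as a covariate. PLS has no native
  covariate slot, so it enters as one more numerically coded, autoscaled
  predictor column — but it is excluded from the VIP ranking, the VIP
  normalization and the category tables. Subgroup models (MDD-only,
  BD-only) drop it and re-autoscale within the subgroup.
* **Constant columns** (possible after a subgroup split) are dropped with
  a warning rather than an error.

## Choosing the number of components

`cross_validate()` runs stratified 7-fold cross-validation. Stratification
by outcome is on by default: with 62 cases against 116 controls, unstratified
folds can leave a training split nearly case-free. Autoscaling is
re-estimated inside every training split, so no centering/scaling
information leaks from held-out subjects. For each candidate $A$,

$$Q^2(A) = 1 - \frac{\mathrm{PRESS}(A)}{\sum_k \sum_{i \in k} (y_i - \bar
y_{\text{train}(k)})^2},$$

with PRESS accumulated on the original 0/1 scale. `select_components()`
then picks the smallest $A$ whose $Q^2$ comes within 0.01 of the maximum —
the classical parsimony rule. If no $A$ achieves a positive $Q^2$ the
selector returns $A = 1$ with a `no_predictive_component` flag: the model
is kept as a ranking device even when it has no out-of-sample predictive
value, and the flag is carried into every report.

## VIP scores and the selection rule

The y-variance-weighted VIP is used:

$$\mathrm{VIP}_j = \sqrt{\,p \cdot \frac{\sum_a \mathrm{SSY}_a\,
\tilde w_{aj}^2}{\sum_a \mathrm{SSY}_a}}, \qquad
\mathrm{SSY}_a = q_a^2\, t_a^\top t_a,$$

where $p$ counts the ranked predictors and $\tilde w_{aj}^2$ are the
squared weights renormalized to sum to one over the ranked set. When a
covariate is fitted, both the count $p$ and the weight normalization run
over the score columns only; otherwise the defining identity
$\overline{\mathrm{VIP}^2} = 1$ — the algebraic fact that makes the
threshold VIP > 1 meaningful — could not hold over the ranked predictors.
With $A = 1$ all common VIP variants coincide
($\mathrm{VIP}_j = \sqrt{p}\,\lvert w_{1j}\rvert / \lVert w_1 \rVert$) and
VIP ranking equals $|w|$ ranking exactly, so single-component models are
insensitive to the variant choice. Selection uses the strict inequality
VIP > 1: a boundary score of exactly 1 is not selected. Ties in the
ranking are broken by $|w|$ descending, then score ID.

Category summaries tally, per trait category, how many scores were
selected and how they split by direction (positive weight = predicts PPD,
negative = predicts its absence), plus the percentage of the category
included.

## Evaluation

The classifier score is the first latent variable $t_1$. `roc_curve()`
sweeps all unique thresholds and integrates the AUC by the trapezoidal
rule, which is algebraically the Mann–Whitney pairwise concordance with
ties counted one half — the package computes both routes and tests assert
their equality to $10^{-12}$. Scores that discriminate in the wrong
direction are flipped so the reported AUC is $\ge 0.5$, with the flip
recorded. Both the in-sample AUC and a cross-validated AUC (first latent
scores of held-out folds) are reported and labelled; they answer different
questions, and the in-sample one is the optimistic one.

## The cohort comparison battery

`cohort_table()` reproduces demographic-table statistics: pooled-variance
Student t tests with Cohen's d for continuous variables and uncorrected
Pearson chi-square with Cramér's V for categorical ones. Both are
computable from printed summaries (mean ± SD and group sizes, or 2×2
cells), and the raw-data path routes through the exact group summaries so
the two paths agree to machine precision. These specific forms were chosen
because they are the ones under which the published statistics of the
178-subject cohort reproduce from their printed summaries: pooled (not
Welch) t, and no Yates continuity correction. The shipped reference table
(`cohort_reference()`) flags rows whose published statistics do *not*
reproduce from their printed cells — an apparent column swap in the
smoking row, an alcohol statistic matching neither corrected nor
uncorrected Pearson, and a manic-episode t that likely uses a
subgroup-specific denominator. Those rows are documented, not guessed at.

## The synthetic generator

No real genotype-derived score matrix is distributed, so `generate_panel()`
emulates its statistical structure:

* **Block multicollinearity.** Scores for the same phenotype are generated
  as $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$ with a shared standard
  normal factor $f$ per block — positive semidefinite by construction.
  Default blocks of 3/2/1 near-duplicate scores at $\rho = 0.9$ mimic the
  several same-trait scores per phenotype seen in multi-PGS panels. The
  published panel reports no empirical inter-score correlations, so
  $\rho = 0.9$ within blocks and 0 across categories are stated
  assumptions, not estimates; a global shared factor is available for
  cross-category correlation but defaults to off.
* **Fixed case/control margins.** The binary outcome is assigned by
  ranking the latent liability $X\beta + \mathcal N(0, \sigma^2)$ and
  labelling the top `n_cases` subjects as cases, matching a fixed 62/116
  retrospective design and making prevalence exact rather than binomially
  random.
* **Sparse planted signal.** By default 20 of 341 scores, spread over
  blocks in all four categories, carry effects of $|\beta| = 0.5$ with
  alternating signs; since any single $\beta$ vector spans one direction
  in predictor space, the planted signal is rank-one and 7-fold CV should
  (and in tests does) select one component.
* **Diagnosis independent of outcome.** MDD/BD labels are drawn
  independently of case status (fraction 72/178 by default), so subgroup
  analyses are well-defined without building diagnosis-specific signal in;
  diagnosis-dependent effects can be emulated by generating subgroup
  panels separately.

What the generator does **not** emulate: LD structure or allele-level
sampling noise (everything is generated at the score level), non-Gaussian
score distributions, ancestry stratification, genetic correlation between
categories, or diagnosis-differential genetic architecture. Passing tests
therefore demonstrate that the machinery is correct and well-calibrated
under the stated generative assumptions — not that real PRS panels satisfy
those assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script use study-shaped panels
(178 × 341) for end-to-end checks, 20 × 8 random problems for the
closed-form oracle comparison, 20 generator seeds for the
parameter-recovery property and 10 for the null calibration — sizes chosen
to make the whole suite run in well under a minute of CPU while keeping
the stochastic properties stable across seeds. Degenerate inputs are
handled explicitly: single-class outcomes and empty subgroups error;
residual-variance exhaustion truncates the component count with a warning;
zero-variance columns inside a CV training split contribute zero weight by
construction.

## Limitations

* Linear PLS on a 0/1 outcome is a pragmatic chemometrics convention, not
  a probability model; predicted values are not calibrated probabilities.
* The VIP > 1 rule is a conventional importance cutoff, not a
  significance test — with no signal, roughly the usual fraction of
  scores still exceeds 1, so the rule must not be read as error control.
  No multiplicity correction across scores is performed, deliberately.
* In-sample $R^2Y$ and AUC on $n \ll p$ data are optimistic by
  construction; the cross-validated $Q^2$ and AUC are the honest
  counterparts and both are always reported side by side.
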