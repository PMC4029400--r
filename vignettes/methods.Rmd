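---
title: "Methods: case-based recruitment support from routine codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-based recruitment support from routine codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrss)
```

# The problem and the model

Trial eligibility criteria are free text; routine care data are structured
billing codes. Translating criteria into code queries by hand is expensive
and brittle. `ctrss` takes the case-based route instead: patients who have
already been screened for a trial form a labeled training set
$\{(x_i, y_i)\}$, where $x_i \in \{0,1\}^p \times \mathbb{R} \times \{0,1\}$
collects binary code indicators plus age and gender, and
$y_i \in \{\text{eligible}, \text{ineligible}\}$ is the screening outcome. A
classifier $\hat{f}$ fitted to this set scores unscreened patients, and
screening proceeds down the ranked list.

The central statistical obstacle is sparsity. A patient carries a handful of
codes out of thousands, so the raw patient × code matrix has well under 1 %
of cells valued, and the signal for any single criterion is spread over many
rare sibling codes. The pipeline therefore manipulates three quantities in
tension: matrix density (via hierarchical code aggregation), dimensionality
(via univariate attribute selection), and model capacity (via the choice of
classifier family).

## Code aggregation

ICD-10-GM and OPS are mono-hierarchies, so every code has exactly one parent
chain and aggregation is well-defined. Two levels are exposed:

* **category** — purely syntactic truncation: the first three characters of
  a diagnosis (`L40.4 → L40`), the first four of a procedure
  (`5-121.1 → 5-12`). Idempotent; category-form input passes through.
* **block** — catalogue chapters group categories into inclusive ranges,
  rendered `start…end` (`L40 → L40…L45`, `5-12 → 5-08…5-16`). Ranges are
  not syntactically derivable, so a block map (validated: `start ≤ end`,
  no overlaps per system) must be supplied. Categories not covered by the
  map fall back to themselves with a warning by default; `strict = TRUE`
  turns the fallback into an error. The fallback default suits routine data,
  where a few exotic codes outside the mapped chapters should not abort a
  whole experiment.

Aggregation is monotone by construction: attribute counts can only fall and
per-attribute prevalences can only rise, which the test suite asserts as an
invariant on random cohorts.

## Attribute selection

For each binary attribute, a 2 × 2 contingency table against the label is
tested with Pearson's χ² **without** continuity correction; whenever any
expected cell count is below 5 (Cochran's rule, evaluated strictly: a cell
exactly at 5 stays χ²), the p-value comes from Fisher's exact test instead,
since the χ² approximation is unreliable in exactly the sparse-attribute
regime this tool lives in. Degenerate tables (constant attribute or constant
label) get $p = 1$ and a flag rather than an error, because screens over
thousands of attributes routinely contain constant columns. Ranking is by
ascending p-value with lexicographic tie-breaking, so results are
reproducible across platforms; the top-$k$ set always additionally includes
age and gender, which are near-universally criterion-relevant and cost two
degrees of freedom. A frequency-based ranking (descending prevalence,
label-blind) is provided as the selection baseline.

Selection runs on the training side of the split by default
(`selection_scope = "train"`); scope `"all"` exists for diagnostics but
leaks label information into the test set and is not used in evaluation.

## Model suite

Five families behind one interface, each fitted via its canonical
implementation with that package's documented defaults unless overridden:

| family | implementation | notes |
|---|---|---|
| `cart_tree` | `rpart::rpart` | class method; leaf class fractions as scores |
| `random_forest` | `randomForest::randomForest` | 500 trees, `mtry = ⌊√p⌋`; set `mtry = p` for pure bagging |
| `logistic` | `stats::glm`, binomial | fitted probabilities |
| `logistic_stepwise` | `stats::step` | backward elimination from the full model by AIC |
| `svm` | `e1071::svm` | RBF kernel, cost 1, `gamma = 1/p`, sigmoid-calibrated probabilities; constant columns exempted from scaling |

Attribute names carry catalogue punctuation that R formulas cannot digest,
so fitting happens on an internal positionally-named copy; the model freezes
its attribute schema, and scoring refuses any matrix whose columns do not
match it exactly — silent column misalignment is the classic deployment bug
in EHR pipelines.

## Evaluation

* **Holdout**: one third of labeled patients, stratified by label by default
  so the rare eligible class is represented on both sides at the cohort's
  prevalence; the split errors out rather than silently evaluating on a
  single-class test set.
* **ROC-AUC**: trapezoidal integration of the empirical ROC over distinct
  score thresholds, which equals the Mann–Whitney statistic with half credit
  for tied scores. The suite cross-checks this hand-rolled implementation
  against explicit pair counting and against an established external ROC
  package.
* **Uncertainty**: percentile bootstrap on the test set — 1,000 resamples,
  2.5/97.5 percentiles. Resamples that come out single-class carry no AUC
  information and are redrawn.
* **Learning curves**: the test set is fixed once; the training set is then
  repeatedly reduced by 30 % (`n ← n − round(0.3 n)`, stopping below a
  minimum size, default 10), and each rung is selected/trained/scored
  independently. This shows how each family degrades as screening data
  shrinks — decision trees collapse to uninformative constants well before
  forests do.

Defaults (33 % test fraction, 30 % reduction, $k \in \{20, 40\}$, 1,000
bootstrap resamples) are the pipeline's fixed evaluation constants, housed
in `experiment_config()`. For learning-curve experiments on low-prevalence
cohorts we raise the minimum training size (e.g. to 50): at 10 % prevalence,
rungs much below that frequently contain fewer than two eligible patients,
and the resulting point is an error row rather than a measurement — a
statistical-stability choice, not a runtime one.

## Reproducibility

Every experiment derives all of its randomness from a single master seed.
Per-cell seeds come from `derive_seed(master, label)`, a deterministic
polynomial string hash (exact in doubles, result `< 2^31`), so grid cells
are independent of execution order and a rerun of `cmd_grid()` is
byte-identical. Timestamps live in a separate provenance file, never in
result tables.

# The synthetic cohort generator

Real screening data cannot be distributed, so the generator emulates the
statistical shape of the problem:

* a latent eligibility class $Z \sim \text{Bernoulli}(\pi)$ (default
  $\pi = 0.10$);
* a planted rule — by default *any code in one diagnosis block* AND *no code
  in a second diagnosis block* AND *age ≥ 18* — enforced constructively:
  eligible patients satisfy every clause (rule-family code counts drawn as
  $1 + \text{Poisson}(0.7)$), ineligible patients violate exactly one
  uniformly chosen clause, so at zero label noise the labels equal the rule
  evaluation exactly;
* background codes drawn independently per code with lognormal prevalences
  (median = target, default 0.4 %, `sdlog` 0.8, capped at 50 %) over a
  500-code two-system universe, reproducing the heavy-tailed sparsity of
  routine data;
* label noise: each label flipped independently with probability 0.02 by
  default, emulating imperfect screening records.

With noise rate $\varepsilon$, the label–class confusion is known, so the
generating process has a closed-form optimum: with
$a = P(Z{=}1 \mid Y{=}1)$ and $b = P(Z{=}1 \mid Y{=}0)$,

$$\text{AUC}_{\text{Bayes}} = a(1-b) + \tfrac{1}{2}\bigl(ab + (1-a)(1-b)\bigr),$$

reported by `bayes_auc()`. Model AUCs thus have an absolute ceiling to be
judged against, not just each other.

What the generator does **not** emulate: code co-occurrence structure
(comorbidity clusters), temporal dynamics, per-patient code-volume
heterogeneity beyond the Poisson counts, and site effects. It is a test
harness for the pipeline's statistical machinery, not a clinical simulator.

# Design decisions

* **Patients without demographics are rejected**, not imputed: age and
  gender are always model inputs, and silently imputing them would bias the
  deployment ranking. Patients with demographics but zero codes are kept —
  an empty code history is informative.
* **Age and gender are always appended** to any selected attribute set
  rather than competing in the univariate screen, since the χ² screen over
  binary attributes has no natural place for a continuous covariate.
* **`selection_scope = "train"` by default** — selecting on all labeled data
  before splitting leaks the test labels into the model and inflates AUC.
* **Unmapped block fallback warns rather than errors** by default (see
  aggregation above); strictness is a flag because catalogue coverage varies
  by site and year.
* **Stepwise logistic regression** uses backward elimination from the full
  model by AIC: after top-$k$ selection the design is small enough for the
  full fit, and backward search is the canonical complement to a univariate
  forward screen.

# Limitations

Univariate selection cannot find purely interactive criteria (codes
predictive only in combination); the forest can exploit interactions but
only among attributes that survived the marginal screen. The χ²/Fisher
screen assumes i.i.d. patients — repeated encounters of one patient must be
collapsed upstream (the EAV reader deduplicates identical records, but
cross-visit correlation is the user's responsibility). Scores are sigmoid-
or vote-calibrated but not recalibrated against screening prevalence, so
they order candidates well yet should not be read as absolute eligibility
probabilities. Finally, a model trained at one site inherits that site's
coding habits; transport to another site is untested territory.
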