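---
title: "Moderated mixed graphical models for categorical cohort data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated mixed graphical models for categorical cohort data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Adolescent cohort studies routinely record suicidality, physical pain,
depressive symptoms, anxiety, peer problems and inhibitory-control
difficulties as binary or ordinal questionnaire variables. Two questions
recur: is pain associated with suicidality once the other variables are
conditioned on, and does that conditional association itself depend on the
level of depression (moderation)? `catmgm` implements the full analysis
chain for such data — variable derivation, contingency statistics,
pairwise and moderated mixed graphical models (MGMs), network
descriptors and bootstrap stability — together with generators for
synthetic cohorts so that every stage can be validated against known
ground truth without access to restricted participant-level data.

# The model

All six analysis variables are categorical, so the pairwise MGM is a
categorical Markov random field: with nodes $s = 1, \dots, p$, level
codes $x_s$, the joint density is

$$
P(x) \propto \exp\Big( \sum_s \tau_s(x_s)
  + \sum_{s<t} \theta_{st}(x_s, x_t)
  + \sum_{s<t,\,m} \theta_{stm}(x_s, x_t, x_m) \Big),
$$

with per-level thresholds $\tau_s$, pairwise interaction matrices
$\theta_{st}$ and — in the moderated model — three-way tensors
$\theta_{stm}$ restricted to triples containing the designated moderator.
The conditional distribution of each node given the rest is multinomial
logistic, which licenses nodewise (neighbourhood) estimation: each node is
regressed on dummy encodings of all others (products with the moderator
dummies are added in the moderated model), with an L1 penalty on every
non-intercept coefficient, and the penalty is selected per node by the
extended Bayesian information criterion

$$
\mathrm{EBIC}_\gamma = -2\,\ell + \mathrm{df}\,\log n +
  2\gamma\,\mathrm{df}\,\log p_{\mathrm{total}},
$$

with $\gamma = 0.5$ by default and $p_{\mathrm{total}}$ the number of
candidate non-intercept parameters of that node's regression. Setting
$\gamma = 0$ recovers BIC exactly (this identity is tested). The
penalised solver behind `fit_nodewise()` is glmnet's coordinate descent;
everything around it — encoding, EBIC selection, aggregation, moderation,
conditioning, descriptors, bootstrap — is implemented in this package.

## Edge aggregation and signs

Each pair of nodes is described by two cross-parameter blocks, one from
each of the two regressions. Under the default AND rule an edge is
retained only when both blocks contain a nonzero parameter; the OR rule
is available for sensitivity analyses. The edge weight is the mean
absolute value of all parameters in both blocks — a single non-negative
scalar per edge comparable across mixed level counts. A sign is defined
only for binary–binary edges whose two regressions agree on the direction
of the log odds; edges involving nodes with more than two levels carry
several parameters and no single sign. Because glmnet's multinomial
parameterisation is symmetric across response classes, the weight of a
binary–binary edge is about half the conditional log odds ratio; the
derived `edge_adjusted_or()` therefore exponentiates the mean of the two
regressions' log-odds estimates and is flagged as
interpretation-dependent.

## Moderation and conditioning

In the moderated model the design of node $s \ne m$ gains products of
every other predictor's dummies with the moderator's dummies, and the
moderator's own regression gains products of all predictor-pair dummies,
so each three-way term appears in exactly the three regressions whose
response it involves. A moderation edge for a pair is declared present
when its interaction parameters survive the combine rule across those
three regressions. `condition_on()` substitutes a fixed moderator level:
the effective cross-block at level $l$ is the pairwise block plus the
interaction-block slice for $l$ (zero at the reference level), and the
conditioned weight is the mean absolute value of the two effective
blocks. Edges incident to the moderator keep their pairwise weight at
every level. When all interaction blocks are zero the conditioned
matrices are identical across levels, which is enforced by tests.

## Descriptors

*Predictability* is the in-sample proportion of rows whose observed level
is the arg-max class under the node's fitted regression, against the
modal-category baseline. It is computed in sample (no cross-validation),
matching the single-number reporting convention of the methodology this
package implements. *Expected influence* is the signed sum of incident
edge weights (EI1) and its two-step extension
$\mathrm{EI2}_i = \mathrm{EI1}_i + \sum_j s_{ij} w_{ij}\,\mathrm{EI1}_j$;
unsigned ("grey") edges contribute positively, consistent with reporting
all weights as non-negative magnitudes. The EI–variance diagnostic
correlates EI1 with node variances (binary: $p(1-p)$; ordinal: population
variance of 0-based level codes — a documented convention).

# Variable derivation

The coding rules are exact translations of the instrument conventions:
suicidality is present on any yes among the three items, absent for both
other responses, and missing only when nothing was answered (the only
coherent reading of an at-least-one-item rule); six-month pain maps
not-true to absent; today-pain maps score 0 to absent; combined pain is
present only when both indicators are present, and an observed absent on
either indicator forces absent while present-plus-missing stays missing
("both present" can neither be confirmed nor excluded — this choice is
documented and symmetric). Depression banding is 0–15 / 16–27 / 28–60.
The anxiety and difficulty-subscale band cutpoints are not published in
the main analysis text; the package ships explicit defaults (anxiety
t-score cutpoints 65/70; four-band tables `(0,3,5,7,11)` for peer
problems and `(0,6,7,8,11)` for inhibitory-control deficits) that are
flagged as assumptions and overridable everywhere banding occurs.

# Synthetic data: what it emulates, and what it does not

Two generators make the pipeline testable end to end.

`make_printed_fixture()` is a constant 8072-row table reproducing the
published pain-by-suicidality cross-tabulation exactly (cells
717/1077/889/5327, 62 missing pain, 18 missing suicidality) and the
published marginal counts of the other variables. The joint of the filled
columns is deliberately artificial: each column assigns its most severe
levels first down a fixed severity-ordered row order, with missing values
last. Only the printed margins and the printed pain–suicidality joint are
guaranteed; any joint consistent with the margins would be admissible,
and determinism was preferred over realism. One consequence worth noting:
the printed margins force all 18 suicidality-missing rows into the
pain-missing group, so the two missingness patterns overlap rather than
being disjoint.

`sample_cohort_items()` draws raw item-level data from a thresholded
Gaussian copula. Its defaults are frozen calibrations of the cohort
conditions: marginal probabilities match the published participant
characteristics; the pain-item latent correlation (0.40) was calibrated
once so the two discretised pain items attain a Spearman correlation of
about 0.29; the suicidality common-factor loading (0.90) yields an
any-item-yes prevalence of about 20%; and the suicidality–pain latent
correlations (0.47, 0.42) give a combined-pain/suicidality crude odds
ratio near 4. Score variables use a monotone band-uniform transform, so
band probabilities are hit exactly in expectation and the copula ordering
is preserved. Missingness is completely at random per instrument at the
published per-variable rates. What this generator does **not** emulate:
school-level clustering, item-level psychometrics of the depression and
anxiety scales, systematic (non-MCAR) missingness, and gender differences
in the latent structure (gender is drawn independently). Tests that pass
on these cohorts therefore validate the estimation machinery, not those
aspects of real data.

`gibbs_sample_mgm()` samples any `mgm_spec()` exactly: every participant
is an independent chain updated in parallel sweeps from the full
conditionals. The burn-in default of 1000 sweeps is deliberately
conservative for six-node categorical chains, which mix in a handful of
sweeps; validation runs in the test-suite use 150–300 sweeps, which the
total-variation checks against exact enumeration show to be ample.
Potentials are over-parameterised (no identification constraints); the
convention that planted blocks put zero in every reference row and column
makes planted values directly comparable to estimated reference-coded
parameters.

# Numerical choices

- Penalty path: 50 log-spaced values from the data-derived
  $\lambda_{\max}$ down to $0.01\,\lambda_{\max}$ (the glmnet default
  rule), overridable. EBIC ties break towards the sparser model
  (`which.min` on a decreasing path).
- Indicator columns are not standardised — all predictors share the 0/1
  scale. Intercepts are unpenalised.
- Degrees of freedom count nonzero non-intercept coefficients across all
  response classes; exact zeros come from the coordinate-descent solver.
- Odds ratios use the sample cross-product estimate with a Woolf
  (normal-on-log-OR) interval; zero cells trigger the Haldane–Anscombe
  +0.5 correction, relabelled in the result. An exact conditional
  estimator is available (`method = "exact"`). On the printed
  cross-tabulation the Woolf upper bound (4.49) differs in the second
  decimal from the published 4.51, suggesting the original used an exact
  method; both are provided and labelled.
- The Wilcoxon rank-sum test enumerates the exact permutation
  distribution (valid under ties) up to a pooled size of 10 and uses the
  tie-corrected normal approximation above that, without continuity
  correction.
- Bootstrap: participants are resampled with replacement (clustering is
  ignored by design, matching the analysis this package reproduces);
  percentile intervals; the penalty is re-selected on every resample by
  default (`refit_lambda = FALSE` fixes the full-data penalties).
  Resamples in which an analysis column collapses to a single observed
  level — or the solver fails on a one-observation response class — are
  skipped and counted; more than 20% skipped is an error.

# Validation design and problem sizes

The test-suite validates each stage against an independent route:
exact enumeration of small joint distributions versus the Gibbs sampler
(total variation below 0.02 at $n = 100{,}000$ on two- and three-node
models up to four levels); parameter recovery on six-node cohorts of
$n = 8000$ generated from a spec whose pairwise blocks are proportional
to a published whole-sample weights matrix (weak edges below 0.10 are
omitted from the truth so false positives are observable; recovery
demands weight correlation at least 0.9 with zero false edges at
threshold 0.05 in at least 80% of 20 replicates); null-moderation
stability on pairwise-only cohorts (a zero pain–suicidality moderation
block in at least 80% of 100 bootstrap resamples); planted-moderation
power (a conditional log-OR shift of 0.8 between extreme moderator
levels detected in at least 80% of 20 replicates at $n = 8000$); the
EBIC/BIC identity at $\gamma = 0$; and exact-enumeration agreement of
the Wilcoxon test for all pooled sizes up to 8. Unit tests run the same
properties at reduced sizes ($n$ between 800 and 20{,}000, 5–10
replicates) chosen so the whole suite stays comfortably inside a few
minutes of a single CPU; these sizes are the package's own validation
design, and enlarging them only tightens the Monte-Carlo error around
the same conclusions.

# Known limitations

- Estimated edge weights are penalised and on glmnet's symmetric
  multinomial scale; they are comparable across edges within a model but
  are not log odds ratios, and their absolute scale depends on the
  aggregation convention.
- In-sample predictability is optimistic relative to cross-validation.
- The fixture's auxiliary-column joint is artificial; association
  statistics between, say, depression and pain on the fixture reflect the
  deterministic fill, not the cohort.
- The copula generator controls rank correlations, not conditional
  (network) structure; recovery tests therefore use the Gibbs generator,
  whose conditional structure is known exactly.
- Multiple simultaneous moderators, continuous moderators and
  school-level multilevel structure are out of scope.
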