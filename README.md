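# catmgm

Network analysis of categorical mental-health cohort data: from raw
questionnaire items to moderated mixed graphical models.

## What it does, and for whom

Epidemiologists and clinical researchers studying adolescent cohorts
often ask whether two symptoms — here the running example is physical
pain and suicidality — remain associated after conditioning on their
shared correlates (depression, anxiety, peer problems, inhibitory-control
deficits), and whether that conditional association depends on a
moderator such as depression severity. `catmgm` provides the complete
analysis chain for binary/ordinal cohort data:

- **Variable derivation** — instrument coding rules that turn raw items
  into the analysis variables: any-yes suicidality, six-month and
  today-pain indicators, a both-indicators combined pain measure,
  depression bands (0–15 / 16–27 / 28–60) and configurable ordinal
  banding for the other scores; complete-case filtering with an audit of
  the participant flow.
- **Association statistics** — cross-product odds ratios with Woolf (or
  exact) 95% CIs, moderator-stratified odds-ratio tables, Pearson
  chi-squared tests for equal proportions, exact/tie-corrected Wilcoxon
  rank-sum tests, Spearman correlations with percentile-bootstrap CIs.
- **Mixed graphical models** — a categorical Markov random field
  estimated by nodewise L1-penalised multinomial regression with EBIC
  selection (`gamma = 0.5` default), AND/OR edge aggregation into a
  symmetric non-negative weights matrix with binary-binary edge signs.
- **Moderated networks** — three-way interaction terms involving a
  designated moderator, moderation-edge detection across the three
  regressions containing each term, and level-conditioned weights
  matrices.
- **Descriptors** — nodewise predictability (classification accuracy
  against the modal baseline), one- and two-step expected influence, and
  the expected-influence-versus-variance diagnostic.
- **Stability** — participant-resampling bootstrap with percentile CIs,
  nonzero proportions per edge and zero proportions per moderation pair.
- **Synthetic data** — a Gibbs sampler for categorical Markov random
  fields with known pairwise and three-way structure (ground truth for
  recovery tests), a Gaussian-copula item-level cohort generator
  calibrated to published marginal prevalences, and a deterministic
  8072-row fixture reproducing a published pain-by-suicidality
  cross-tabulation exactly.

The nodewise model for node $s$ with levels $x_s$ is multinomial
logistic; the joint is

P(x) ∝ exp( Σ_s τ_s(x_s) + Σ_{s<t} θ_st(x_s, x_t) + Σ θ_stm(x_s, x_t, x_m) ),

and each node's penalty is chosen by
EBIC_γ = −2ℓ + df·log n + 2γ·df·log p_total.
See the vignette `vignettes/moderated-categorical-networks.Rmd` for the
full methodology, the aggregation and conditioning conventions, and the
calibration of the synthetic generators.

## Worked example

```r
library(catmgm)

# deterministic fixture: the published cross-tabulation
fx <- make_printed_fixture()
ct <- table(fx$pain, fx$suicidality)
odds_ratio_2x2(ct["present", "present"], ct["present", "absent"],
               ct["absent", "present"], ct["absent", "absent"])
#> odds_ratio_woolf: estimate=3.989, 95% CI [3.545, 4.49], p=1.61e-116, n=8010

# synthetic cohort -> derive -> network -> moderation
raw <- sample_cohort_items(cohort_margin_spec(n = 8072, seed = 1))
cohort <- derive_cohort(raw)
net <- estimate_network(cohort, nodes = c("suicidality", "depression",
                                          "anxiety", "inhibition",
                                          "peers", "pain"))
net
#> mgm_network: 6 nodes, 10 edge(s), n = 7210 (gamma = 0.5, AND rule)
#>   depression--anxiety  w=0.683 (undefined)
#>   suicidality--depression  w=0.599 (undefined)
#>   suicidality--pain  w=0.539 (+)
#>   depression--inhibition  w=0.277 (undefined)
#>   depression--peers  w=0.252 (undefined)

expected_influence(net$weights, net$signs)
predictability(net, cohort)

mod <- fit_moderated(cohort, "depression", nodes = net$nodes)
conditioned_weights(mod)       # one matrix per depression level
bootstrap_network(cohort, B = 200, seed = 2,
                  nodes = net$nodes)  # percentile CIs + edge stability
```

The printed odds ratio (3.99, CI [3.54, 4.49]) is the cross-product
ratio of the fixture's four observed cells; the network output lists the
strongest conditional associations in the synthetic cohort, with a sign
only for the binary-binary pain–suicidality edge; `predictability()`
reports, per node, the modal-category baseline and the in-sample
accuracy of the fitted nodewise model.

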