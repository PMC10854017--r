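---
title: "Predicting 30-day ED revisits with per-patient graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 30-day ED revisits with per-patient graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrevisit)
```

## The problem

Children and youth receiving outpatient mental-health care sometimes
return to the emergency department (ED) within 30 days of a previous ED
visit. A 30-day revisit is a standard utilization signal: accurately
predicting it from routinely collected visit records would allow earlier
intervention and better resource targeting. `edrevisit` implements a
complete prediction pipeline over longitudinal ED visit records — label
construction, feature encoding, a per-patient graph representation with
a one-layer graph neural network (GNN) classifier, a recurrent (GRU)
sequence classifier, classical baselines, and a balanced-undersampling
repeated cross-validation protocol — together with a synthetic cohort
generator, because real pediatric mental-health EHR data cannot be
shared.

## Labels and inputs

Each patient contributes one labelled instance. For a patient with $n$
visits, the last visit is removed from the input; the label attached to
visit $n-1$ is 1 iff visit $n$ occurred within `window_days` (default
30, inclusive: a gap of exactly 30 days counts). The input is visits
$1..n-1$, truncated to the most recent `visit_cap` (default 10) visits.
Single-visit patients are labelled 0 — they cannot have had a revisit
after a *previous* visit — and contribute their one visit as input,
which keeps them in the training set.

This committed reading has a consequence worth stating plainly:
*single-visit patients are deterministically negative.* Any model that
can see input length (all of them: padding patterns, sequence length,
graph size) can exploit this. In a cohort with no other signal, the
achievable AUROC on a balanced sample is not 0.5 but
$0.5 + f/2$, where $f$ is the fraction of sampled negatives with a
single visit — about 0.57 with the default visit-count distribution
(roughly 12% of patients have one visit). This is not an artifact of
the generator: real data labelled by the same rule carries the same
floor. The no-signal sanity checks in the test suite are interpreted
against this ceiling; see "What a green test establishes" below.

Visits are encoded as
$[\tilde a,\ \mathrm{onehot}(\text{triage}),\ \mathrm{onehot}(\text{disposition}),\ \mathrm{onehot}(\text{diagnosis}),\ \mathrm{multihot}(\text{services})]$
where $\tilde a$ is the age normalized with training-fold statistics
(z-score by default, min-max as an option; a zero spread falls back to
scale 1). Vocabularies and normalization constants are always fitted on
training folds only; codes unseen at fit time encode as all-zero blocks
rather than errors, because cross-validation folds can hold out rare
codes.

## The patient graph

Each instance becomes a small heterogeneous graph:

* one **visit node** per input visit, carrying age, triage and
  disposition; consecutive visits are chained (visit $t$ — visit
  $t+1$), so temporal order — not timing — is in the structure;
* one **service node** per distinct service code, linked to every visit
  where the service occurred;
* one **diagnosis node** per distinct diagnosis code, linked to the
  service nodes of the visits carrying that diagnosis.

Service and diagnosis nodes are *shared* within the patient: a service
given at two visits bridges both visits' diagnoses. Edges are
undirected, there are no self-loops and no direct visit–diagnosis
edges. Node features are zero-padded to a common width with a 3-slot
node-type indicator prefix, so one feature matrix covers all types.
Node ordering is visits (temporal), then services and diagnoses in
schema order.

## Models

All models output a revisit probability and are trained or fitted on
identical data splits.

**GNN** (`gnn`): one message-passing layer
$H = \mathrm{ReLU}(\hat A X W_1 + b_1)$ with
$\hat A = D^{-1}(A + I)$ (degree-normalized neighbour averaging with
self-inclusion; a count-preserving `sum` variant uses $A + I$
unnormalized), mean-pool readout over the graph's nodes,
then an affine map and sigmoid. One layer is kept deliberately: it
matches the comparability constraint of the protocol and is already
sufficient to express service–diagnosis co-occurrence detectors (a
hidden unit can fire only when a service node's aggregated
neighbourhood contains a specific diagnosis). Training is Adam on
binary cross-entropy, 300 epochs in minibatches of 500 by reference.

**RNN** (`rnn`): a single GRU layer (a plain tanh cell is available)
consumes the encoded visits in temporal order; the final hidden state
feeds an affine map and sigmoid. Variable lengths are left-padded and
masked. Gradients are analytic (backpropagation through time) and are
checked against finite differences in the test suite, as are the GNN
gradients.

**Baselines**: the visits are concatenated into one fixed-width row —
`visit_cap` slots, right-aligned so the most recent visit always
occupies the last slot — and fitted with L2 logistic regression
(glmnet, ridge, fixed small penalty), a CART decision tree (Gini), and
second-order gradient boosting on logistic loss (XGBoost-style gains
and Newton leaf weights). The tree and boosting implementations live in
the package because this stack ships neither `rpart` nor `xgboost`;
their defaults (tree: depth cap 25, minimum split 2; boosting: 50
rounds, depth 3, shrinkage 0.3, L2 penalty 1) were fixed once and are
exposed in `train_config()`.

**Tuned-on-synthetic choices.** The protocol fixes epochs (300) and
batch size (500) but not the hidden width or learning rate. A one-time
sweep on synthetic cohorts selected learning rate $10^{-2}$ (at
$10^{-3}$ the loss barely moves within 300 epochs at these data sizes)
and hidden width 64 by default, 32 for the small reduced-protocol runs.
The same sweep showed that for *relational* signal the `sum`
aggregation generalizes better than `mean`: degree normalization
averages away the multiplicity of service–diagnosis co-occurrences,
which is exactly the evidence the graph is supposed to contribute. The
default remains `mean` (the conventional GCN operator); the
strong-signal experiments below use `sum`.

A 0.5 probability threshold fixes the label metrics (PPV/NPV depend on
it); it is a config value, not a tuned quantity.

## Evaluation protocol

The revisit class is rare (about 17%), so the protocol balances by
undersampling: `n_subsets` (5) balanced datasets are formed, each
containing *all* positives plus an equal-size uniform sample of
negatives (independent across subsets; negatives may recur between
subsets). Each subset is split into `n_folds` (5) stratified folds;
every fold serves as the test set once; each model is fitted on the
remaining folds with the schema refitted on training data only. The
resulting $5 \times 5 = 25$ fold scores per model are summarized as
mean and SD for F1, precision (= PPV), recall, accuracy, AUROC and NPV.
AUROC is trapezoidal over all thresholds, equal to pair concordance
with ties counted one half. Zero-denominator metrics report 0 with a
flag; single-class test labels make AUROC `NA` with a flag rather than
aborting the fold. Models are compared with *paired* two-sided t-tests
on the fold-aligned scores — pairing is natural because all models see
identical splits. Reported ROC curves are vertical averages of per-fold
curves on a fixed false-positive-rate grid.

## The synthetic cohort

`generate_cohort()` draws a world matching the reported cohort
statistics: visit counts from a discretized normal restricted to
$\ge 1$ whose location is calibrated by bisection so the *realized*
mean is 5 (naive truncation of a mean-5/SD-5 normal would inflate the
mean to about 6.4; under the calibrated restriction the realized SD
shrinks to about 4.3 — the mean is matched exactly, the SD
approximately); ages from a normal with mean 12.4, SD 3.9, clipped to
[4, 18]; an acuity-skewed triage distribution; geometric-decay
(skewed) code multinomials with desk-scale default vocabularies (30
diagnoses, 15 services; the full reference sizes of 1377 and 61 are
available by argument).

Predictive signal is planted through a per-patient logistic hazard
$h = \sigma(\beta_0 + \beta_{seq}\,\mathrm{[high\ acuity\ last\ visit]}
+ \beta_{rel}\,\mathrm{[designated\ pair\ co\mbox{-}occurrence]})$,
with $\beta_0$ calibrated by bisection to the target prevalence. For a
multi-visit patient, a Bernoulli draw at $h$ decides whether the final
inter-visit gap is drawn from 1–30 days (revisit) or 31–365 days;
intermediate gaps come from a fixed mixture (20% within 30 days). This
two-range construction is deliberately simple — it is a stand-in for an
unknown real waiting-time process, sufficient for testing label
structure, and is not a claim about the real data.

The relational signal is *conjunction-pure by construction*. Each
designated pair couples a dedicated service code and a dedicated
diagnosis code that never occur in the background multinomials. A
multi-visit patient is "exposed" with probability `pair_exposure`
(default 0.7): half of exposures place both codes at the same input
visit (a co-occurrence, raising the hazard through $\beta_{rel}$), half
place them at two different visits (no co-occurrence, no hazard
effect). Exposed patients therefore carry the same code *marginals*
whether or not they co-occur: a model that only counts code presence
cannot separate them, while the patient graph represents the
co-occurrence directly as a service–diagnosis edge. This is what makes
the relational signal a test of graph structure rather than of code
frequency.

`planted_signal_report()` computes the Bayes-optimal AUROC implied by
the true hazards, brute-forced over the hazard distribution of
multi-visit patients. Single-visit patients are excluded from this
bound on purpose: their deterministic label is a consequence of the
labelling convention, not of planted signal, and including them as a
hazard-0 group would report spurious "signal" ($0.5 + f/2$) at zero
betas.

## What a green test establishes (and what it does not)

The generator emulates marginal summary statistics and label structure.
It does not emulate ICD-10 semantics, seasonal or COVID-era patterns,
code correlations beyond the planted pairs, or inter-visit timing
beyond the two-range gaps. Green tests therefore establish that the
pipeline's machinery is correct (labels match a brute-force oracle,
graphs obey their structural laws, metrics match hand computations,
the protocol has the right shape, fits are reproducible) and that the
models *behave* as designed on controllable worlds: near-chance AUROC
when nothing is planted — up to the single-visit ceiling discussed
above — and a GNN advantage over a linear baseline when the signal is
relational. They do not establish clinical-scale performance, and the
performance numbers reported for the private source cohort are
deliberately not reproduction targets.

## Numerical and degenerate-input choices

* Dates are calendar days; a 30-day window needs no time component.
  Same-day visits are kept as distinct visits in input order.
* Unknown triage (9) is a category, not missingness.
* All-equal training ages: normalization scale falls back to 1.
* Paired t-tests with (numerically) zero-variance differences are
  flagged degenerate: statistic 0 when the mean difference is 0,
  signed infinite otherwise, rather than failing.
* Tree splits break gain ties toward the lowest column index and
  threshold, making fits order-deterministic.
* All randomness (generation, undersampling, folds, initialization,
  batch order) derives from explicit seeds; identical configuration
  and seed reproduce byte-identical metrics files.

## Known limitations

* The GNN and RNN are intentionally one layer; no attention, no
  multi-layer variants, no GPU path — CPU matrix algebra suffices at
  protocol scale.
* The boosting and tree baselines are faithful but minimal
  implementations; they are not drop-in replacements for xgboost/rpart
  at scale.
* The synthetic world's inter-visit gap process and conjunction-pure
  exposure mechanism are design choices for testability, not inferences
  about the source data.
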