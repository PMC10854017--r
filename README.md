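# edrevisit

Predicting 30-day emergency department (ED) revisits among child and
youth mental-health outpatients from longitudinal visit records, using
per-patient heterogeneous graphs and a one-layer graph neural network
(GNN), compared against a recurrent (GRU) sequence classifier and
classical baselines under a balanced-undersampling, repeated five-fold
cross-validation protocol.

## The problem and the approach

A return to the ED within 30 days of a previous visit often signals
unmet mental-health needs. Given a patient's visit history — age at
visit, CTAS triage level, disposition code, most-responsible ICD-10
diagnosis, and service-type codes — the task is to predict whether the
latest visit will be followed by another within 30 days.

For each patient with visits `1..n`, the label is
`1{date(n) − date(n−1) ≤ 30 days}`; the input is visits `1..n−1`
capped at the 10 most recent; single-visit patients are labelled 0.
Each instance becomes a graph with three node types and three edge
types:

```
visit_t — visit_{t+1}        (temporal chain)
visit_t — service_s          (service s given at visit t)
service_s — diagnosis_d      (visit with diagnosis d involved service s)
```

Service and diagnosis nodes are shared across a patient's visits, so
the graph encodes which services co-occur with which diagnoses. The
GNN applies one degree-normalized message-passing layer (ReLU), a
mean-pool readout and a sigmoid:
`p = σ(w₂ᵀ · meanpool(ReLU(Â X W₁ + b₁)) + b₂)`, trained with Adam on
binary cross-entropy (reference: 300 epochs, batches of 500). The
comparison models are a one-layer GRU over the encoded visit sequence
and, on right-aligned concatenated visit rows, L2 logistic regression,
a CART decision tree and second-order gradient boosting.

Because the class is imbalanced (about 17% revisit), evaluation uses
five balanced subsets (all positives plus an equal-size random sample
of negatives) × five stratified CV folds = 25 fold scores per model,
reported as mean (SD) of F1, precision, recall, AUROC, accuracy, PPV
and NPV, with paired t-tests between models on the fold-aligned
scores.

The clinical data behind this design cannot be shared, so the package
ships a seeded synthetic cohort generator that reproduces the
reported summary statistics (visit counts mean 5, ages mean 12.4
clipped to 4–18, ~17% prevalence) and can plant two kinds of signal: a
sequential one (high-acuity last triage raises the revisit hazard) and
a relational one (designated service–diagnosis co-occurrence raises
the hazard, with code marginals balanced so only graph structure
separates the classes).

## Worked example

Simulate a 2,000-patient cohort with a strong relational signal, run a
reduced protocol (2 subsets × 3 folds) for the GNN and the logistic
baseline, and inspect the report:

```r
library(edrevisit)

cfg <- run_config(
  simulate   = cohort_spec(n_patients = 2000, beta_rel = 4, beta_seq = 1),
  train      = train_config(epochs = 300, hidden_width = 32,
                            gnn_aggregation = "sum"),
  evaluation = eval_config(n_subsets = 2, n_folds = 3),
  models     = c("gnn", "logistic"),
  out_dir    = "edrevisit_run", seed = 1)

report <- run_pipeline(cfg)
print(report)
#> evaluation_report: 2 model(s), 6 fold scores each
#>
#> gnn                F1 0.6033 (0.0117)  AUROC 0.6074  acc 0.5825
#> logistic           F1 0.5742 (0.0417)  AUROC 0.6005  acc 0.5730
```

Each line is the mean over the 6 fold scores (SD in parentheses for
F1). Under a planted relational signal the GNN outperforms the linear
baseline, which can only use code presence, not service–diagnosis
co-occurrence (the generator balances the code marginals so presence
alone is uninformative). The run directory contains `metrics.csv` (per-fold
long format), `aggregate.csv`, `roc_<model>.csv`, `ttests.csv`, the
simulated `cohort.csv`/`truth.csv`, a `run.log`, and `manifest.dcf`
recording every setting and seed needed to regenerate the run
byte-identically.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/edrevisit.R --config run.dcf --seed 1 --out results_dir
```

with `run.dcf` a key-value config block (see `?read_run_config`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — synthetic cohort generation, preprocessing, graph
construction, training all five model kinds, and the balanced CV
protocol — and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/ehr_data.R` — visit-table CSV dialect, cohort container
* `R/preprocessing.R` — 30-day labels, truncation, feature schema
* `R/graph_builder.R` — patient graphs, matrices, batching
* `R/models.R`, `R/model_gnn.R`, `R/model_rnn.R`, `R/cart.R` — the
  five classifiers and the shared training loop
* `R/evaluation.R` — undersampling, k-fold CV, metrics, t-tests
* `R/synthetic_cohort.R` — seeded generator with plantable signal
* `R/pipeline.R`, `inst/cli/edrevisit.R` — orchestration and CLI
* `vignettes/patient-graph-revisit.Rmd` — the methods vignette
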