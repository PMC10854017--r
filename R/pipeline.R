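#' Composite run configuration
#'
#' Bundles the preprocessing, training, evaluation and (optionally)
#' simulation settings with the input/output paths for an end-to-end
#' run. The global seed re-seeds every sub-config deterministically, so
#' one integer reproduces the whole run.
#'
#' @param preprocess A [preprocess_config()].
#' @param train A [train_config()].
#' @param evaluation An [eval_config()].
#' @param simulate `NULL` to read `input_csv`, or a [cohort_spec()] to
#'   generate the cohort in-run.
#' @param models Character vector of [model_kinds()] to evaluate.
#' @param input_csv Path to a visit CSV (ignored when simulating).
#' @param out_dir Output directory for artifacts.
#' @param seed Global integer seed propagated to all stages.
#' @return A `run_config` list.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       train = train_config(),
                       evaluation = eval_config(),
                       simulate = NULL,
                       models = c("gnn", "rnn", "logistic",
                                  "decision_tree", "gradient_boosting"),
                       input_csv = NULL, out_dir = "edrevisit_run",
                       seed = 1L) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(train, "train_config"),
            inherits(evaluation, "eval_config"),
            is.null(simulate) || inherits(simulate, "cohort_spec"))
  seed <- as.integer(seed)
  train$seed <- derive_seed(seed, 1L)
  evaluation$seed <- derive_seed(seed, 2L)
  if (!is.null(simulate)) simulate$seed <- derive_seed(seed, 3L)
  structure(list(preprocess = preprocess, train = train,
                 evaluation = evaluation, simulate = simulate,
                 models = models, input_csv = input_csv,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a key-value (DCF) file
#'
#' The config file is a single Debian-control-format block of
#' `key: value` lines. Recognized keys (all optional):
#' `window_days`, `visit_cap`, `window_inclusive`, `age_norm`,
#' `model.hidden`, `train.epochs`, `train.batch`, `train.lr`,
#' `train.seed`, `predict.threshold`, `eval.subsets`, `eval.folds`,
#' `models` (comma separated), `input_csv`, `out_dir`, `seed`, and the
#' simulation keys `sim.n_patients`, `sim.prevalence`, `sim.beta_seq`,
#' `sim.beta_rel`, `sim.n_diagnosis`, `sim.n_service` (presence of
#' `sim.n_patients` switches simulation on).
#'
#' @param path Path to the DCF file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  kv <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  get <- function(key, default, as = identity) {
    if (is.null(kv[[key]])) default else as(kv[[key]])
  }
  pre <- preprocess_config(
    window_days = get("window_days", 30L, as.integer),
    visit_cap = get("visit_cap", 10L, as.integer),
    window_inclusive = get("window_inclusive", TRUE,
                           function(x) toupper(x) %in% c("TRUE", "1", "YES")),
    age_norm = get("age_norm", "zscore")
  )
  trn <- train_config(
    epochs = get("train.epochs", 300L, as.integer),
    batch_size = get("train.batch", 500L, as.integer),
    learning_rate = get("train.lr", 1e-3, as.numeric),
    hidden_width = get("model.hidden", 64L, as.integer),
    seed = get("train.seed", 1L, as.integer),
    threshold = get("predict.threshold", 0.5, as.numeric)
  )
  ev <- eval_config(
    n_subsets = get("eval.subsets", 5L, as.integer),
    n_folds = get("eval.folds", 5L, as.integer)
  )
  sim <- NULL
  if (!is.null(kv[["sim.n_patients"]])) {
    sim <- cohort_spec(
      n_patients = as.integer(kv[["sim.n_patients"]]),
      target_prevalence = get("sim.prevalence", 0.17, as.numeric),
      beta_seq = get("sim.beta_seq", 0, as.numeric),
      beta_rel = get("sim.beta_rel", 0, as.numeric),
      n_diagnosis = get("sim.n_diagnosis", 30L, as.integer),
      n_service = get("sim.n_service", 15L, as.integer)
    )
  }
  run_config(
    preprocess = pre, train = trn, evaluation = ev, simulate = sim,
    models = get("models", c("gnn", "rnn", "logistic", "decision_tree",
                             "gradient_boosting"),
                 function(x) trimws(strsplit(x, ",")[[1L]])),
    input_csv = get("input_csv", NULL),
    out_dir = get("out_dir", "edrevisit_run"),
    seed = get("seed", 1L, as.integer)
  )
}

log_line <- function(con, ...) {
  writeLines(paste0(...), con)
}

#' Run the end-to-end pipeline and write artifacts
#'
#' Orchestrates simulate (or read) -> preprocess -> train -> evaluate ->
#' report. Artifacts written under `config$out_dir`:
#' \itemize{
#'   \item `metrics.csv`: long format (model, subset, fold, metric,
#'     value);
#'   \item `aggregate.csv`: per-model mean/SD for each metric;
#'   \item `roc_<model>.csv`: vertically averaged ROC points;
#'   \item `ttests.csv`: pairwise paired t-tests (when > 1 model);
#'   \item `cohort.csv` plus `truth.csv` when simulating;
#'   \item `manifest.dcf`: every config value and seed needed to
#'     regenerate the run;
#'   \item `run.log`: stage-level progress log.
#' }
#' The same config and seed produce byte-identical metrics files.
#'
#' @param config A [run_config()].
#' @param verbose Print progress to the console as well as the log.
#' @return The `evaluation_report`, invisibly.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  say <- function(...) {
    log_line(logf, ...)
    if (verbose) message(...)
  }

  say("stage: input")
  if (!is.null(config$simulate)) {
    say("  simulating cohort: n=", config$simulate$n_patients,
        " seed=", config$simulate$seed)
    gen <- generate_cohort(config$simulate)
    cohort <- gen$cohort
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    utils::write.csv(gen$truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE)
  } else {
    if (is.null(config$input_csv) || !file.exists(config$input_csv)) {
      stop("input CSV not found: ",
           if (is.null(config$input_csv)) "(no path given)" else
             config$input_csv, call. = FALSE)
    }
    say("  reading cohort: ", config$input_csv)
    cohort <- read_cohort(config$input_csv)
  }

  say("stage: preprocess (window_days=", config$preprocess$window_days,
      ", visit_cap=", config$preprocess$visit_cap, ")")
  instances <- build_instances(cohort, config$preprocess)
  y <- instance_labels(instances)
  say("  instances: ", length(instances), " (", sum(y), " positive)")

  say("stage: evaluate (", config$evaluation$n_subsets, " subsets x ",
      config$evaluation$n_folds, " folds; models: ",
      paste(config$models, collapse = ","), ")")
  report <- run_protocol(config$models, instances,
                         train_cfg = config$train,
                         eval_cfg = config$evaluation,
                         preprocess = config$preprocess,
                         verbose = verbose)

  say("stage: report")
  long <- stats::reshape(
    report$scores[, c("model", "subset", "fold", metric_names())],
    direction = "long", varying = metric_names(), v.names = "value",
    times = metric_names(), timevar = "metric",
    idvar = c("model", "subset", "fold"))
  long <- long[order(long$model, long$subset, long$fold,
                     match(long$metric, metric_names())), ]
  rownames(long) <- NULL
  utils::write.csv(long[, c("model", "subset", "fold", "metric", "value")],
                   file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aggregate,
                   file.path(config$out_dir, "aggregate.csv"),
                   row.names = FALSE)
  if (!is.null(report$ttests)) {
    utils::write.csv(report$ttests,
                     file.path(config$out_dir, "ttests.csv"),
                     row.names = FALSE)
  }
  for (kind in names(report$roc)) {
    if (!is.null(report$roc[[kind]])) {
      utils::write.csv(report$roc[[kind]],
                       file.path(config$out_dir,
                                 paste0("roc_", kind, ".csv")),
                       row.names = FALSE)
    }
  }

  manifest <- c(
    seed = config$seed,
    window_days = config$preprocess$window_days,
    visit_cap = config$preprocess$visit_cap,
    window_inclusive = config$preprocess$window_inclusive,
    age_norm = config$preprocess$age_norm,
    train.epochs = config$train$epochs,
    train.batch = config$train$batch_size,
    train.lr = config$train$learning_rate,
    train.seed = config$train$seed,
    model.hidden = config$train$hidden_width,
    predict.threshold = config$train$threshold,
    eval.subsets = config$evaluation$n_subsets,
    eval.folds = config$evaluation$n_folds,
    eval.seed = config$evaluation$seed,
    models = paste(config$models, collapse = ","),
    simulated = !is.null(config$simulate)
  )
  if (!is.null(config$simulate)) {
    manifest <- c(manifest,
                  sim.n_patients = config$simulate$n_patients,
                  sim.prevalence = config$simulate$target_prevalence,
                  sim.beta_seq = config$simulate$beta_seq,
                  sim.beta_rel = config$simulate$beta_rel,
                  sim.seed = config$simulate$seed)
  }
  write.dcf(as.data.frame(t(manifest)),
            file.path(config$out_dir, "manifest.dcf"))
  say("done")
  invisible(report)
}
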