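#' Preprocessing configuration
#'
#' Controls label construction and input truncation. The revisit window
#' defaults to 30 days and a gap of exactly `window_days` counts as a
#' revisit when `window_inclusive = TRUE` ("within the next 30 days" read
#' inclusively). The visit cap defaults to 10 input visits per patient,
#' chosen in the source setting because visit counts averaged 5 with a
#' standard deviation of 5.
#'
#' @param window_days Positive integer, revisit window in days.
#' @param visit_cap Positive integer, maximum number of input visits kept
#'   (the most recent ones before the final visit).
#' @param window_inclusive Logical; if `TRUE` a gap equal to
#'   `window_days` is a revisit.
#' @param age_norm Age normalization: `"zscore"` (training mean/SD) or
#'   `"minmax"` (training min/range).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(window_days = 30L, visit_cap = 10L,
                              window_inclusive = TRUE,
                              age_norm = c("zscore", "minmax")) {
  window_days <- as.integer(window_days)
  visit_cap <- as.integer(visit_cap)
  stopifnot(window_days >= 1L, visit_cap >= 1L, is.logical(window_inclusive))
  age_norm <- match.arg(age_norm)
  structure(list(window_days = window_days, visit_cap = visit_cap,
                 window_inclusive = window_inclusive, age_norm = age_norm),
            class = "preprocess_config")
}

#' Per-visit 30-day revisit indicators
#'
#' For each visit in a patient's history, flags whether any later visit
#' falls within the revisit window of it. Because visits are sorted
#' ascending, the nearest later visit is the next one, but the definition
#' quantifies over all later visits. The last visit's flag is 0 by
#' construction (no later visit exists); a single-visit history gets
#' `c(0)`.
#'
#' @param history A data.frame of one patient's visits sorted ascending
#'   by `visit_date` (as produced by [patient_histories()]).
#' @param cfg A [preprocess_config()].
#' @return Integer vector of 0/1 flags, one per visit.
#' @export
revisit_indicators <- function(history, cfg = preprocess_config()) {
  stopifnot(is.data.frame(history), nrow(history) >= 1L)
  n <- nrow(history)
  if (n == 1L) return(0L)
  d <- as.integer(history$visit_date)
  gaps <- d[-1L] - d[-n]
  hit <- if (cfg$window_inclusive) gaps <= cfg$window_days else
    gaps < cfg$window_days
  as.integer(c(hit, FALSE))
}

#' Build a labelled training instance from one patient history
#'
#' Implements the labelling rule: for a patient with `n > 1` visits, the
#' final visit is removed from the input and the label attached to visit
#' `n-1` is 1 iff visit `n` followed within the revisit window; the input
#' is visits `1..n-1` truncated to the most recent `visit_cap`. A
#' single-visit patient contributes that one visit as input with label 0
#' (their indicator is fixed at 0; using the visit itself keeps them
#' trainable).
#'
#' @inheritParams revisit_indicators
#' @return A `labeled_instance`: list with `patient_id`, `input_visits`
#'   (data.frame, `1 <= nrow <= visit_cap`), and `label` (0 or 1).
#' @export
build_instance <- function(history, cfg = preprocess_config()) {
  stopifnot(is.data.frame(history))
  if (nrow(history) == 0L) stop("empty history", call. = FALSE)
  n <- nrow(history)
  if (n == 1L) {
    input <- history
    label <- 0L
  } else {
    gap <- as.integer(history$visit_date[n]) -
      as.integer(history$visit_date[n - 1L])
    label <- if (cfg$window_inclusive) as.integer(gap <= cfg$window_days)
    else as.integer(gap < cfg$window_days)
    keep <- max(1L, n - cfg$visit_cap):(n - 1L)
    input <- history[keep, , drop = FALSE]
  }
  rownames(input) <- NULL
  structure(list(patient_id = history$patient_id[1L],
                 input_visits = input, label = label),
            class = "labeled_instance")
}

#' Build labelled instances for a whole cohort
#'
#' @param cohort An [ed_cohort()].
#' @param cfg A [preprocess_config()].
#' @return List of `labeled_instance`, one per patient.
#' @export
build_instances <- function(cohort, cfg = preprocess_config()) {
  lapply(patient_histories(cohort), build_instance, cfg = cfg)
}

#' Extract instance labels
#' @param instances List of `labeled_instance`.
#' @return Integer vector of labels.
#' @export
instance_labels <- function(instances) {
  vapply(instances, function(x) as.integer(x$label), 1L)
}

#' Fit the feature-encoding schema on training instances
#'
#' Builds the per-vocabulary index maps (lexicographic over codes
#' observed in the training instances' input visits) and the age
#' normalization parameters. Vocabularies may be overridden, e.g. with a
#' cohort's full vocabularies, so that encoders can be dimensioned to
#' codes rarer than the training folds happened to contain.
#'
#' The encoded visit width is
#' `1 + |triage| + |disposition| + |diagnosis| + |service|`
#' (age slot plus the four one-/multi-hot blocks); with the reference
#' vocabulary sizes (6 triage levels including unknown, 20 dispositions,
#' 1377 diagnoses, 61 services) that is 1465.
#'
#' @param instances Non-empty list of `labeled_instance` (training data
#'   only; held-out codes map to all-zero blocks at encode time).
#' @param cfg A [preprocess_config()]; `age_norm` selects z-scoring
#'   (default) or min-max.
#' @param vocabularies Optional list with entries `triage`,
#'   `disposition`, `diagnosis`, `service` overriding the observed
#'   vocabularies.
#' @return A `feature_schema` list with the vocabularies, `age_center`,
#'   `age_scale`, per-block offsets and total `width`.
#' @export
fit_schema <- function(instances, cfg = preprocess_config(),
                       vocabularies = NULL) {
  if (length(instances) == 0L) stop("no instances to fit schema on",
                                    call. = FALSE)
  visits <- do.call(rbind, lapply(instances, function(x)
    x$input_visits[c("age_years", "triage_level", "disposition_code",
                     "diagnosis_code")]))
  services <- unlist(lapply(instances, function(x)
    unlist(x$input_visits$service_codes)))
  vocab <- list(
    triage = sort(unique(visits$triage_level)),
    disposition = sort(unique(visits$disposition_code)),
    diagnosis = sort(unique(visits$diagnosis_code)),
    service = sort(unique(services))
  )
  if (!is.null(vocabularies)) {
    for (nm in names(vocabularies)) vocab[[nm]] <- sort(vocabularies[[nm]])
  }
  ages <- visits$age_years
  if (cfg$age_norm == "zscore") {
    center <- mean(ages)
    scale <- stats::sd(ages)
    if (is.na(scale) || scale == 0) scale <- 1
  } else {
    center <- min(ages)
    scale <- max(ages) - min(ages)
    if (scale == 0) scale <- 1
  }
  sizes <- c(1L, length(vocab$triage), length(vocab$disposition),
             length(vocab$diagnosis), length(vocab$service))
  offsets <- cumsum(c(0L, sizes[-5L]))  # 0-based start of each block
  structure(list(
    triage_levels = vocab$triage,
    disposition_codes = vocab$disposition,
    diagnosis_codes = vocab$diagnosis,
    service_codes = vocab$service,
    age_norm = cfg$age_norm,
    age_center = center,
    age_scale = scale,
    offsets = stats::setNames(offsets, c("age", "triage", "disposition",
                                         "diagnosis", "service")),
    width = sum(sizes)
  ), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("feature_schema: width", x$width, "=",
      "1 (age) +", length(x$triage_levels), "(triage) +",
      length(x$disposition_codes), "(disposition) +",
      length(x$diagnosis_codes), "(diagnosis) +",
      length(x$service_codes), "(service)\n")
  invisible(x)
}

normalize_age <- function(age, schema) {
  (age - schema$age_center) / schema$age_scale
}

#' Encode one visit as a numeric feature vector
#'
#' Layout: `[normalized age]` then one-hot triage, one-hot disposition,
#' one-hot diagnosis, multi-hot services. Codes unseen when the schema
#' was fitted map to an all-zero block (cross-validation folds can hold
#' out rare codes; that is not an error).
#'
#' @param visit A one-row data.frame (a row of `input_visits`).
#' @param schema A [fit_schema()] result.
#' @return Numeric vector of length `schema$width`.
#' @export
encode_visit <- function(visit, schema) {
  stopifnot(inherits(schema, "feature_schema"), nrow(visit) == 1L)
  out <- numeric(schema$width)
  out[1L] <- normalize_age(visit$age_years, schema)
  i <- match(visit$triage_level, schema$triage_levels)
  if (!is.na(i)) out[schema$offsets[["triage"]] + i] <- 1
  i <- match(visit$disposition_code, schema$disposition_codes)
  if (!is.na(i)) out[schema$offsets[["disposition"]] + i] <- 1
  i <- match(visit$diagnosis_code, schema$diagnosis_codes)
  if (!is.na(i)) out[schema$offsets[["diagnosis"]] + i] <- 1
  i <- match(visit$service_codes[[1L]], schema$service_codes)
  out[schema$offsets[["service"]] + i[!is.na(i)]] <- 1
  out
}

# Encode all input visits of an instance as a (n_visits x width) matrix.
# Hot path for the sequence and baseline models; avoids per-visit
# data.frame subsetting.
encode_instance_matrix <- function(instance, schema) {
  v <- instance$input_visits
  n <- nrow(v)
  out <- matrix(0, nrow = n, ncol = schema$width)
  out[, 1L] <- normalize_age(v$age_years, schema)
  idx <- match(v$triage_level, schema$triage_levels)
  ok <- which(!is.na(idx))
  out[cbind(ok, schema$offsets[["triage"]] + idx[ok])] <- 1
  idx <- match(v$disposition_code, schema$disposition_codes)
  ok <- which(!is.na(idx))
  out[cbind(ok, schema$offsets[["disposition"]] + idx[ok])] <- 1
  idx <- match(v$diagnosis_code, schema$diagnosis_codes)
  ok <- which(!is.na(idx))
  out[cbind(ok, schema$offsets[["diagnosis"]] + idx[ok])] <- 1
  svc <- v$service_codes
  for (i in seq_len(n)) {
    j <- match(svc[[i]], schema$service_codes)
    j <- j[!is.na(j)]
    out[i, schema$offsets[["service"]] + j] <- 1
  }
  out
}
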