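# In-code fixtures shared across test files.

# A minimal visits data.frame for one or more patients; dates given as
# day offsets from a fixed origin.
make_visits <- function(patient_id, day_offsets, triage = 3L,
                        disposition = "HOME", diagnosis = "F32",
                        services = list("SVC01"), age0 = 12) {
  n <- length(day_offsets)
  recycle <- function(x) rep_len(x, n)
  df <- data.frame(
    patient_id = recycle(patient_id),
    visit_date = as.Date("2020-01-01") + day_offsets,
    age_years = pmin(18, age0 + day_offsets / 365.25),
    triage_level = recycle(triage),
    disposition_code = recycle(disposition),
    diagnosis_code = recycle(diagnosis),
    stringsAsFactors = FALSE
  )
  df$service_codes <- rep_len(services, n)
  df
}

make_history <- function(day_offsets, ...) {
  ed_cohort(make_visits("P1", day_offsets, ...))$visits
}

# Random histories for property tests: random visit counts and gaps.
random_history <- function(n_visits, max_gap = 90L) {
  offsets <- cumsum(c(0L, sample.int(max_gap, n_visits - 1L,
                                     replace = TRUE)))
  make_history(offsets,
               triage = sample(c(1L, 2L, 3L, 4L, 5L, 9L), n_visits,
                               replace = TRUE),
               diagnosis = sample(sprintf("DX%02d", 1:8), n_visits,
                                  replace = TRUE),
               services = replicate(n_visits, sample(
                 sprintf("SVC%02d", 1:6), sample(1:3, 1L)),
                 simplify = FALSE))
}

# The worked two-visit example: v1 {service A, diagnosis D1},
# v2 {services A and B, diagnosis D2}.
two_visit_instance <- function() {
  visits <- make_visits("P1", c(0L, 40L),
                        diagnosis = c("D1", "D2"),
                        services = list("A", c("A", "B")))
  history <- ed_cohort(visits)$visits
  structure(list(patient_id = "P1", input_visits = history, label = 1L),
            class = "labeled_instance")
}

# Small labelled toy set with a perfectly separating diagnosis code.
separable_instances <- function(n_per_class = 10L) {
  out <- list()
  for (i in seq_len(n_per_class)) {
    pos <- make_history(c(0L, 10L), diagnosis = "DXPOS")
    neg <- make_history(c(0L, 10L), diagnosis = "DXNEG")
    out[[length(out) + 1L]] <- structure(
      list(patient_id = paste0("pos", i), input_visits = pos, label = 1L),
      class = "labeled_instance")
    out[[length(out) + 1L]] <- structure(
      list(patient_id = paste0("neg", i), input_visits = neg, label = 0L),
      class = "labeled_instance")
  }
  out
}

small_cohort_instances <- function(n_patients = 120L, seed = 42L,
                                   beta_rel = 0, beta_seq = 0) {
  gen <- generate_cohort(cohort_spec(
    n_patients = n_patients, beta_rel = beta_rel, beta_seq = beta_seq,
    n_diagnosis = 12L, n_service = 8L, seed = seed))
  build_instances(gen$cohort)
}
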