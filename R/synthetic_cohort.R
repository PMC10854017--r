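#' Specification of a synthetic ED cohort
#'
#' Parameters of the seeded generator that emulates the source cohort's
#' reported summary statistics: visit counts from a discretized normal
#' with mean 5 / SD 5 truncated to >= 1, ages from a normal with mean
#' 12.4 / SD 3.9 clipped to \[4, 18\], roughly 17% prevalence of a
#' 30-day revisit, and skewed categorical vocabularies. Desk-scale
#' defaults use small diagnosis/service vocabularies; the full reference
#' cardinalities (20 dispositions, 1377 diagnoses, 61 services) are
#' available by argument.
#'
#' Predictive signal is planted through a per-patient logistic hazard
#' `h = plogis(base + beta_seq * seq_flag + beta_rel * rel_flag)` where
#' `seq_flag` is 1 when the last input visit is high-acuity (triage 1 or
#' 2) and `rel_flag` is 1 when any designated service-diagnosis pair
#' co-occurs at one input visit. `base` is calibrated by bisection so
#' the expected prevalence matches `target_prevalence`.
#'
#' @param n_patients Positive integer.
#' @param visit_count_mean,visit_count_sd Visit-count distribution
#'   (rounded normal, redrawn until >= 1).
#' @param age_mean,age_sd Age-at-first-visit distribution, clipped to
#'   `age_range`.
#' @param age_range Two-element numeric, inclusive age bounds.
#' @param n_disposition,n_diagnosis,n_service Vocabulary sizes (>= 2).
#' @param services_per_visit Integer range (min, max) of services drawn
#'   per visit.
#' @param target_prevalence Fraction of patients with a 30-day revisit,
#'   in (0, 1).
#' @param beta_seq,beta_rel Log-odds strengths of the sequential and
#'   relational planted signals (0 = no signal).
#' @param n_signal_pairs Number of designated service-diagnosis pairs.
#' @param pair_exposure Probability that a multi-visit patient is
#'   exposed to a designated pair's codes; half of exposures place both
#'   codes at the same visit (a co-occurrence) and half place them at
#'   different visits, so the marginal frequency of each code is nearly
#'   the same with and without the co-occurrence and the relational
#'   signal is carried by the service-diagnosis structure, not by code
#'   presence alone.
#' @param code_skew Geometric decay rate of category frequencies in
#'   (0, 1); larger = more imbalanced code usage.
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, visit_count_mean = 5,
                        visit_count_sd = 5, age_mean = 12.4,
                        age_sd = 3.9, age_range = c(4, 18),
                        n_disposition = 20L, n_diagnosis = 30L,
                        n_service = 15L, services_per_visit = c(1L, 3L),
                        target_prevalence = 0.17,
                        beta_seq = 0, beta_rel = 0,
                        n_signal_pairs = 2L, pair_exposure = 0.7,
                        code_skew = 0.1, seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  stopifnot(target_prevalence > 0, target_prevalence < 1,
            n_disposition >= 2L, n_diagnosis >= 2L, n_service >= 2L,
            code_skew > 0, code_skew < 1,
            length(services_per_visit) == 2L,
            services_per_visit[1L] >= 1L,
            services_per_visit[2L] >= services_per_visit[1L],
            n_signal_pairs >= 1L,
            n_signal_pairs <= min(n_service, n_diagnosis),
            pair_exposure >= 0, pair_exposure <= 1)
  structure(list(
    n_patients = n_patients, visit_count_mean = visit_count_mean,
    visit_count_sd = visit_count_sd, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, n_disposition = as.integer(n_disposition),
    n_diagnosis = as.integer(n_diagnosis),
    n_service = as.integer(n_service),
    services_per_visit = as.integer(services_per_visit),
    target_prevalence = target_prevalence,
    beta_seq = beta_seq, beta_rel = beta_rel,
    n_signal_pairs = as.integer(n_signal_pairs),
    pair_exposure = pair_exposure,
    code_skew = code_skew, seed = as.integer(seed)
  ), class = "cohort_spec")
}

geom_probs <- function(k, skew) {
  p <- (1 - skew)^(seq_len(k) - 1L)
  p / sum(p)
}

#' Designated signal-carrying service-diagnosis pairs of a spec
#'
#' The pair codes are dedicated: they are placed only by the exposure
#' mechanism of [generate_cohort()] and never drawn from the background
#' code multinomials, so the co-occurrence rate (and with it the
#' relational signal) is fully under the generator's control.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns `service`, `diagnosis`.
#' @export
signal_pairs <- function(spec) {
  k <- seq_len(spec$n_signal_pairs)
  data.frame(
    service = sprintf("SVCP%02d", k),
    diagnosis = sprintf("DXP%03d", k),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort with planted predictive signal
#'
#' Draws per-patient visit histories matching the spec's summary
#' statistics and plants signal via the final inter-visit gap: a
#' per-patient Bernoulli draw at the calibrated hazard decides whether
#' the last gap falls in 1..30 days (revisit) or 31..365 days.
#' Intermediate gaps are drawn from a fixed mixture (20% within 30
#' days) regardless of signal, so earlier per-visit indicators vary
#' naturally. Single-visit patients never revisit by construction.
#'
#' The triage distribution is fixed and acuity-skewed
#' (P(triage = 1, 2, 3, 4, 5, 9) = .03, .15, .35, .30, .12, .05);
#' disposition, diagnosis and service codes follow geometric-decay
#' multinomials with rate `code_skew`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (an [ed_cohort()]) and `truth` (data.frame
#'   per patient: `patient_id`, `n_visits`, `seq_flag`, `rel_flag`,
#'   `hazard`, `revisit`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients

  # visit counts: discretized normal restricted to >= 1, location
  # calibrated so the truncated mean matches the spec mean (plain
  # truncation would inflate the mean to ~6.4 for mean 5 / SD 5)
  kmax <- max(2L, as.integer(ceiling(spec$visit_count_mean +
                                       8 * spec$visit_count_sd)))
  count_probs <- function(mu) {
    k <- seq_len(kmax)
    p <- stats::pnorm((k + 0.5 - mu) / spec$visit_count_sd) -
      stats::pnorm((k - 0.5 - mu) / spec$visit_count_sd)
    p / sum(p)
  }
  lo <- spec$visit_count_mean - 6 * spec$visit_count_sd
  hi <- spec$visit_count_mean + 6 * spec$visit_count_sd
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (sum(seq_len(kmax) * count_probs(mid)) < spec$visit_count_mean) {
      lo <- mid
    } else hi <- mid
  }
  counts <- sample.int(kmax, n, replace = TRUE,
                       prob = count_probs((lo + hi) / 2))

  disp_codes <- sprintf("DISP%02d", seq_len(spec$n_disposition))
  diag_codes <- sprintf("DX%04d", seq_len(spec$n_diagnosis))
  svc_codes <- sprintf("SVC%02d", seq_len(spec$n_service))
  triage_levels <- c(1L, 2L, 3L, 4L, 5L, 9L)
  triage_probs <- c(0.03, 0.15, 0.35, 0.30, 0.12, 0.05)
  p_disp <- geom_probs(spec$n_disposition, spec$code_skew)
  p_diag <- geom_probs(spec$n_diagnosis, spec$code_skew)
  p_svc <- geom_probs(spec$n_service, spec$code_skew)
  pairs <- signal_pairs(spec)

  per_patient <- vector("list", n)
  seq_flag <- integer(n)
  rel_flag <- integer(n)
  for (i in seq_len(n)) {
    ni <- counts[i]
    triage <- sample(triage_levels, ni, replace = TRUE,
                     prob = triage_probs)
    disp <- sample(disp_codes, ni, replace = TRUE, prob = p_disp)
    dx <- sample(diag_codes, ni, replace = TRUE, prob = p_diag)
    svc <- lapply(seq_len(ni), function(t) {
      k <- sample(spec$services_per_visit[1L]:spec$services_per_visit[2L],
                  1L)
      sort(sample(svc_codes, k, prob = p_svc))
    })
    gaps <- if (ni > 1L) {
      short <- stats::runif(ni - 1L) < 0.2
      ifelse(short, sample(1:30, ni - 1L, replace = TRUE),
             sample(31:365, ni - 1L, replace = TRUE))
    } else integer(0)
    start <- as.Date("2012-01-01") + sample.int(2500L, 1L)
    dates <- start + c(0L, cumsum(gaps))
    age0 <- min(max(stats::rnorm(1L, spec$age_mean, spec$age_sd),
                    spec$age_range[1L]), spec$age_range[2L])
    ages <- pmin(pmax(age0 + c(0, cumsum(gaps)) / 365.25,
                      spec$age_range[1L]), spec$age_range[2L])
    # pair exposure over the model-visible input window: half of
    # exposed patients get a same-visit co-occurrence, half get the two
    # codes spread out (at two visits, or a single random code when the
    # window has one visit), so code marginals are balanced between
    # co-occurring and non-co-occurring patients and across window
    # lengths -- code presence alone carries no signal
    win <- if (ni > 1L) max(1L, ni - 10L):(ni - 1L) else 1L
    u <- stats::runif(1L)
    k <- sample.int(nrow(pairs), 1L)
    if (u < spec$pair_exposure / 2) {
      t1 <- if (length(win) == 1L) win else sample(win, 1L)
      dx[t1] <- pairs$diagnosis[k]
      svc[[t1]] <- sort(union(svc[[t1]], pairs$service[k]))
    } else if (u < spec$pair_exposure) {
      if (length(win) >= 2L) {
        ts <- sample(win, 2L)
        dx[ts[1L]] <- pairs$diagnosis[k]
        svc[[ts[2L]]] <- sort(union(svc[[ts[2L]]], pairs$service[k]))
      } else if (stats::runif(1L) < 0.5) {
        dx[win] <- pairs$diagnosis[k]
      } else {
        svc[[win]] <- sort(union(svc[[win]], pairs$service[k]))
      }
    }
    if (ni > 1L) {
      seq_flag[i] <- as.integer(triage[ni - 1L] %in% c(1L, 2L))
      rel_flag[i] <- as.integer(any(vapply(win, function(t) {
        hit <- pairs$diagnosis == dx[t]
        any(hit & vapply(pairs$service, function(s)
          s %in% svc[[t]], TRUE))
      }, TRUE)))
    }
    per_patient[[i]] <- list(triage = triage, disp = disp, dx = dx,
                             svc = svc, dates = dates, ages = ages,
                             gaps = gaps)
  }

  multi <- counts > 1L
  if (!any(multi)) {
    stop("calibration failure: no multi-visit patients, prevalence ",
         "target unreachable", call. = FALSE)
  }
  lin <- spec$beta_seq * seq_flag + spec$beta_rel * rel_flag
  expected_prev <- function(base) {
    sum(stats::plogis(base + lin[multi])) / n
  }
  if (expected_prev(30) < spec$target_prevalence - 1e-9) {
    stop("calibration failure: target prevalence ",
         spec$target_prevalence, " exceeds the multi-visit fraction ",
         round(mean(multi), 4), call. = FALSE)
  }
  lo <- -30; hi <- 30
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (expected_prev(mid) < spec$target_prevalence) lo <- mid else
      hi <- mid
  }
  base <- (lo + hi) / 2

  hazard <- ifelse(multi, stats::plogis(base + lin), 0)
  revisit <- as.integer(stats::rbinom(n, 1L, hazard) == 1L)

  # realize the final gap according to the drawn label
  rows <- vector("list", n)
  ids <- sprintf("P%06d", seq_len(n))
  for (i in seq_len(n)) {
    pp <- per_patient[[i]]
    ni <- counts[i]
    if (ni > 1L) {
      final_gap <- if (revisit[i] == 1L) sample(1:30, 1L) else
        sample(31:365, 1L)
      pp$dates[ni] <- pp$dates[ni - 1L] + final_gap
      pp$ages[ni] <- min(max(pp$ages[ni - 1L] + final_gap / 365.25,
                             spec$age_range[1L]), spec$age_range[2L])
    }
    df <- data.frame(
      patient_id = ids[i],
      visit_date = pp$dates,
      age_years = pp$ages,
      triage_level = pp$triage,
      disposition_code = pp$disp,
      diagnosis_code = pp$dx,
      stringsAsFactors = FALSE
    )
    df$service_codes <- pp$svc
    rows[[i]] <- df
  }
  visits <- do.call(rbind, rows)
  truth <- data.frame(patient_id = ids, n_visits = counts,
                      seq_flag = seq_flag, rel_flag = rel_flag,
                      hazard = hazard, revisit = revisit,
                      stringsAsFactors = FALSE)
  list(cohort = ed_cohort(visits), truth = truth)
}

#' Achievable discrimination implied by the planted hazards
#'
#' Computes the Bayes-optimal AUROC of the true hazard as a score,
#' brute-forced over the hazard distribution of multi-visit patients:
#' with label probability equal to the hazard, the optimal ranking's
#' AUROC is `P(h_pos > h_neg) + 0.5 P(h_pos = h_neg)` under the induced
#' positive/negative mixtures. Single-visit patients are excluded: their
#' label is deterministically 0 by the labelling convention, which is an
#' artifact of the construction rather than planted signal. With zero
#' betas every multi-visit hazard is equal and the bound is exactly 0.5.
#'
#' @param truth The `truth` component of [generate_cohort()].
#' @param cohort The matching cohort (used for consistency checks).
#' @return List with `bayes_auroc`, `realized_prevalence`, and `groups`
#'   (distinct hazard levels with patient counts).
#' @export
planted_signal_report <- function(truth, cohort = NULL) {
  stopifnot(is.data.frame(truth), "hazard" %in% names(truth))
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "ed_cohort"),
              setequal(truth$patient_id, unique(cohort$visits$patient_id)))
  }
  multi <- truth$n_visits > 1L
  h <- truth$hazard[multi]
  tab <- table(h)
  hv <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  w_pos <- hv * cnt          # expected positives per hazard level
  w_neg <- (1 - hv) * cnt    # expected negatives per hazard level
  P <- sum(w_pos); N <- sum(w_neg)
  num <- 0
  for (a in seq_along(hv)) {
    num <- num + w_pos[a] * (sum(w_neg[hv < hv[a]]) + 0.5 * w_neg[a])
  }
  list(bayes_auroc = if (P > 0 && N > 0) num / (P * N) else NA_real_,
       realized_prevalence = mean(truth$revisit),
       groups = data.frame(hazard = hv, n = cnt))
}
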