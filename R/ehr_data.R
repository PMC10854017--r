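#' Longitudinal ED visit data
#'
#' An `ed_cohort` holds one row per emergency-department (ED) visit for a
#' set of patients, together with the categorical vocabularies observed in
#' those visits. Visits are stored date-sorted within patient (stable on
#' ties, preserving input order), which is the ordering every downstream
#' stage (labelling, graph construction, sequence models) relies on.
#'
#' Each visit carries the feature set used for revisit prediction:
#' age in years at the visit, CTAS triage level (1 = resuscitation to
#' 5 = non-urgent, 9 = unknown), a disposition code (mode of separation
#' from ambulatory care), a most-responsible diagnosis code, and one or
#' more service-type codes for the responsible health professionals.
#'
#' @param visits A data.frame with columns `patient_id` (character),
#'   `visit_date` (`Date`), `age_years` (numeric in \[4, 18\]),
#'   `triage_level` (integer in \{1,2,3,4,5,9\}), `disposition_code`
#'   (character), `diagnosis_code` (character) and `service_codes`
#'   (a list column of non-empty character vectors).
#' @return An object of class `ed_cohort`: a list with elements `visits`
#'   (the validated, sorted data.frame) and `vocabularies` (a list with
#'   entries `triage`, `disposition`, `diagnosis`, `service` holding the
#'   sorted unique codes observed).
#' @examples
#' visits <- data.frame(
#'   patient_id = "P1",
#'   visit_date = as.Date("2020-01-01") + c(0, 19),
#'   age_years = c(12, 12.1),
#'   triage_level = c(3L, 2L),
#'   disposition_code = "HOME",
#'   diagnosis_code = c("F32", "F43")
#' )
#' visits$service_codes <- list("SVC01", c("SVC01", "SVC02"))
#' coh <- ed_cohort(visits)
#' n_patients(coh)
#' @export
ed_cohort <- function(visits) {
  stopifnot(is.data.frame(visits))
  required <- c("patient_id", "visit_date", "age_years", "triage_level",
                "disposition_code", "diagnosis_code", "service_codes")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(visits) == 0L) {
    stop("empty cohort: no visit rows", call. = FALSE)
  }
  visits$patient_id <- as.character(visits$patient_id)
  if (!inherits(visits$visit_date, "Date")) {
    parsed <- as.Date(as.character(visits$visit_date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) {
      stop("unparseable visit_date at row ", bad[1L], ": '",
           visits$visit_date[bad[1L]], "'", call. = FALSE)
    }
    visits$visit_date <- parsed
  }
  if (anyNA(visits$visit_date)) {
    stop("unparseable visit_date at row ", which(is.na(visits$visit_date))[1L],
         call. = FALSE)
  }
  visits$age_years <- as.numeric(visits$age_years)
  bad_age <- which(is.na(visits$age_years) |
                     visits$age_years < 4 | visits$age_years > 18)
  if (length(bad_age) > 0L) {
    stop("age_years out of range [4, 18] at row ", bad_age[1L], ": ",
         visits$age_years[bad_age[1L]], call. = FALSE)
  }
  visits$triage_level <- as.integer(visits$triage_level)
  bad_tri <- which(!visits$triage_level %in% c(1L, 2L, 3L, 4L, 5L, 9L))
  if (length(bad_tri) > 0L) {
    stop("triage_level outside {1,2,3,4,5,9} at row ", bad_tri[1L],
         call. = FALSE)
  }
  visits$disposition_code <- as.character(visits$disposition_code)
  visits$diagnosis_code <- as.character(visits$diagnosis_code)
  if (!is.list(visits$service_codes)) {
    visits$service_codes <- as.list(as.character(visits$service_codes))
  }
  visits$service_codes <- lapply(visits$service_codes, function(s) {
    sort(unique(as.character(s)))
  })
  empty_svc <- which(vapply(visits$service_codes, length, 1L) == 0L)
  if (length(empty_svc) > 0L) {
    stop("empty service_codes at row ", empty_svc[1L], call. = FALSE)
  }

  # stable sort: patient, then date; ties keep input order
  ord <- order(visits$patient_id, visits$visit_date, method = "radix")
  visits <- visits[ord, , drop = FALSE]
  rownames(visits) <- NULL

  vocab <- list(
    triage = sort(unique(visits$triage_level)),
    disposition = sort(unique(visits$disposition_code)),
    diagnosis = sort(unique(visits$diagnosis_code)),
    service = sort(unique(unlist(visits$service_codes)))
  )
  structure(list(visits = visits, vocabularies = vocab),
            class = "ed_cohort")
}

#' @export
print.ed_cohort <- function(x, ...) {
  v <- x$visits
  cat("ed_cohort:", length(unique(v$patient_id)), "patients,",
      nrow(v), "visits\n")
  cat("  vocabularies: triage", length(x$vocabularies$triage),
      "| disposition", length(x$vocabularies$disposition),
      "| diagnosis", length(x$vocabularies$diagnosis),
      "| service", length(x$vocabularies$service), "\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An [ed_cohort()].
#' @return Integer count of distinct patients.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "ed_cohort"))
  length(unique(cohort$visits$patient_id))
}

#' Split a cohort into per-patient histories
#'
#' @param cohort An [ed_cohort()].
#' @return A named list of data.frames, one per patient, each sorted
#'   ascending by `visit_date` (stable ties). Order of patients follows
#'   sorted `patient_id`.
#' @export
patient_histories <- function(cohort) {
  stopifnot(inherits(cohort, "ed_cohort"))
  v <- cohort$visits
  split(v, factor(v$patient_id, levels = unique(v$patient_id)))
}

#' Read a visit-table CSV into a cohort
#'
#' The on-disk dialect is one row per ED visit with a header and columns
#' `patient_id`, `visit_date` (ISO-8601 `YYYY-MM-DD`), `age_years`,
#' `triage_level`, `disposition_code`, `diagnosis_code`, and
#' `service_codes` where multiple services at one visit are packed into a
#' single pipe-delimited cell (e.g. `"SVC01|SVC07"`). Duplicate codes in
#' one cell are collapsed: service codes form a set.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping the canonical
#'   column names above to the names used in the file, e.g.
#'   `c(patient_id = "mrn")`. Unmapped columns keep canonical names.
#' @return An [ed_cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  canonical <- c("patient_id", "visit_date", "age_years", "triage_level",
                 "disposition_code", "diagnosis_code", "service_codes")
  colmap <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    colmap[names(schema)] <- schema
  }
  missing_cols <- colmap[!colmap %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("empty cohort file (header only): ", path, call. = FALSE)
  }
  visits <- data.frame(
    patient_id = raw[[colmap["patient_id"]]],
    visit_date = raw[[colmap["visit_date"]]],
    age_years = as.numeric(raw[[colmap["age_years"]]]),
    triage_level = as.integer(raw[[colmap["triage_level"]]]),
    disposition_code = raw[[colmap["disposition_code"]]],
    diagnosis_code = raw[[colmap["diagnosis_code"]]],
    stringsAsFactors = FALSE
  )
  visits$service_codes <- strsplit(raw[[colmap["service_codes"]]], "|",
                                   fixed = TRUE)
  ed_cohort(visits)
}

#' Write a cohort to the visit-table CSV dialect
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c))` reproduces
#' `c` (visit order is canonical, so the round trip is exact). Passing
#' `cohort = NULL` writes a header-only file.
#'
#' @param cohort An [ed_cohort()], or `NULL` for an empty (header-only)
#'   file.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  header <- c("patient_id", "visit_date", "age_years", "triage_level",
              "disposition_code", "diagnosis_code", "service_codes")
  if (is.null(cohort)) {
    ok <- tryCatch(suppressWarnings({
      writeLines(paste(header, collapse = ","), path)
      TRUE
    }), error = function(e) FALSE)
    if (!ok) stop("cannot write to path: ", path, call. = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(cohort, "ed_cohort"))
  v <- cohort$visits
  out <- data.frame(
    patient_id = v$patient_id,
    visit_date = format(v$visit_date, "%Y-%m-%d"),
    age_years = v$age_years,
    triage_level = v$triage_level,
    disposition_code = v$disposition_code,
    diagnosis_code = v$diagnosis_code,
    service_codes = vapply(v$service_codes, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch(suppressWarnings({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop("cannot write to path: ", path, call. = FALSE)
  invisible(path)
}
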