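#' First-diagnosis ages per patient and code
#'
#' Reduces a stream of diagnosis events to one record per (patient, code)
#' pair, keeping the minimum age at which the code was ever recorded for that
#' patient. This is the quantity the cohort construction is based on: the
#' patient's age when diagnosed for the first time with each of their codes.
#'
#' @param events a `diagnosis_records` object or a data.frame with columns
#'   `patient_id`, `gender`, `icd_code`, `age_at_event`.
#' @return data.frame with columns `patient_id`, `gender`, `icd_code`,
#'   `age_first`, one row per (patient, code).
#' @export
first_diagnosis_ages <- function(events) {
  ev <- as.data.frame(events)
  need <- c("patient_id", "gender", "icd_code", "age_at_event")
  if (!all(need %in% names(ev)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  if (nrow(ev) == 0L)
    return(data.frame(patient_id = character(0), gender = character(0),
                      icd_code = character(0), age_first = integer(0),
                      stringsAsFactors = FALSE))
  g <- unique(ev[, c("patient_id", "gender")])
  conflict <- g$patient_id[duplicated(g$patient_id)]
  if (length(conflict) > 0L)
    stop("conflicting gender for patient(s): ",
         paste(utils::head(unique(conflict), 10L), collapse = ", "))
  o <- order(ev$patient_id, ev$icd_code, ev$age_at_event)
  ev <- ev[o, , drop = FALSE]
  first <- !duplicated(paste(ev$patient_id, ev$icd_code, sep = "\r"))
  out <- data.frame(patient_id = ev$patient_id[first],
                    gender = ev$gender[first],
                    icd_code = ev$icd_code[first],
                    age_first = as.integer(ev$age_at_event[first]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# decade index: 0-9 -> 0, ..., 70-79 -> 7, 80+ -> 8 (open-ended top bucket)
.decade_index <- function(age) pmin(age %/% 10L, 8L)

#' Label a ten-year age decade
#'
#' @param lo lower bound of the decade (0, 10, ..., 80).
#' @return `"0-9"`, `"10-19"`, ..., `"70-79"`, or the open-ended `"80-XX"`.
#' @export
decade_label <- function(lo) ifelse(lo >= 80, "80-XX", sprintf("%d-%d", lo, lo + 9))

#' Build ten-year age-gender cohorts with cumulative diagnosis histories
#'
#' Each patient contributes to the (gender, decade) cohort of every decade in
#' which they have at least one first diagnosis; within a cohort, the
#' patient's code set is their entire history up to the end of that decade
#' (all codes with first-diagnosis age not exceeding the decade's upper
#' bound). A patient first diagnosed with one code at 56 and another at 63 is
#' therefore a member of the 50-59 cohort with the first code only, and of
#' the 60-69 cohort with both. The top decade is the open-ended 80-XX bucket.
#'
#' With `carry_forward = TRUE` a patient is instead a member of every decade
#' from their first diagnosis onward (up to the latest decade observed in the
#' data), whether or not a new first diagnosis falls in it — a sensitivity
#' variant; the default requires a new first diagnosis in the decade.
#'
#' @param first_dx data.frame from [first_diagnosis_ages()].
#' @param carry_forward membership rule, see Details.
#' @return list of `cohort_dataset` objects, each with fields `gender`,
#'   `decade` (c(lo, hi); `hi = Inf` for 80-XX), `label`, and `histories`
#'   (named list: patient id -> sorted character vector of codes). Cohorts
#'   with zero members are omitted; the list is ordered by gender then decade.
#' @export
build_cohorts <- function(first_dx, carry_forward = FALSE) {
  if (nrow(first_dx) == 0L) return(list())
  first_dx$age_first <- as.integer(first_dx$age_first)
  cohorts <- list()
  for (g in sort(unique(first_dx$gender))) {
    fx <- first_dx[first_dx$gender == g, , drop = FALSE]
    dec <- .decade_index(fx$age_first)
    max_dec <- max(dec)
    for (d in 0:max_dec) {
      if (carry_forward) {
        pat_first_dec <- tapply(dec, fx$patient_id, min)
        members <- names(pat_first_dec)[pat_first_dec <= d]
      } else {
        members <- unique(fx$patient_id[dec == d])
      }
      if (length(members) == 0L) next
      hi_age <- if (d >= 8L) Inf else d * 10L + 9L
      sub <- fx[fx$patient_id %in% members & fx$age_first <= hi_age, , drop = FALSE]
      histories <- lapply(split(sub$icd_code, sub$patient_id), function(x) sort(unique(x)))
      histories <- histories[order(names(histories))]
      cohorts[[length(cohorts) + 1L]] <- structure(
        list(gender = g, decade = c(d * 10L, hi_age),
             label = decade_label(d * 10L), histories = histories),
        class = "cohort_dataset")
    }
  }
  cohorts
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n_codes <- length(unique(unlist(x$histories, use.names = FALSE)))
  cat(sprintf("cohort %s %s: %d patients, %d distinct codes\n",
              x$gender, x$label, length(x$histories), n_codes))
  invisible(x)
}

.cohort_key <- function(cohort) paste(cohort$gender, cohort$label)

#' Export cohorts to CSV files plus a manifest
#'
#' Writes one `cohort_<gender>_<decade>.csv` per cohort (columns
#' `patient_id`, `icd_code`, one row per code in the patient's cumulative
#' history) and a `cohort_manifest.json` listing the cohorts present with
#' their sizes.
#'
#' @param cohorts list of `cohort_dataset` objects from [build_cohorts()].
#' @param outdir output directory, created if missing.
#' @return invisibly, the manifest list.
#' @export
write_cohorts <- function(cohorts, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- list()
  for (coh in cohorts) {
    stem <- sprintf("cohort_%s_%s.csv", tolower(coh$gender),
                    gsub("[^0-9X]", "", coh$label))
    df <- data.frame(
      patient_id = rep(names(coh$histories), lengths(coh$histories)),
      icd_code = unlist(coh$histories, use.names = FALSE),
      stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(outdir, stem), row.names = FALSE, quote = FALSE)
    manifest[[.cohort_key(coh)]] <- list(gender = coh$gender, decade = coh$label,
                                         n_patients = length(coh$histories),
                                         file = stem)
  }
  jsonlite::write_json(manifest, file.path(outdir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
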