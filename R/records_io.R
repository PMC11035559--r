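#' Normalize raw ICD-10 codes to the XX.X level
#'
#' Diagnosis codes are analyzed at the three-character category level plus at
#' most one sub-category digit ("XX.X"). Input strings are upper-cased and
#' whitespace-trimmed; dotless subcategory codes (e.g. `"I671"`) are
#' re-punctuated to `"I67.1"`; any digits beyond the first post-decimal digit
#' are discarded (not rounded), so `"I67.12"` becomes `"I67.1"`. Codes already
#' at the three-character level (`"Z72"`) pass through unchanged.
#'
#' @param raw character vector of raw code strings.
#' @param invalid what to do with strings that cannot be reduced to a valid
#'   code: `"error"` (default) stops and names the offending strings, `"na"`
#'   returns `NA` for them.
#' @return character vector of normalized codes matching
#'   `^[A-Z][0-9]{2}(\.[0-9])?$`.
#' @examples
#' normalize_icd(c("I67.1", "I67.12", "z72", "I671"))
#' @export
normalize_icd <- function(raw, invalid = c("error", "na")) {
  invalid <- match.arg(invalid)
  if (length(raw) == 0L) return(character(0))
  x <- toupper(trimws(as.character(raw)))
  m <- regmatches(x, regexec("^([A-Z])([0-9]{2})\\.?([0-9]*)$", x))
  out <- vapply(m, function(g) {
    if (length(g) == 0L) return(NA_character_)
    if (nzchar(g[4L])) paste0(g[2L], g[3L], ".", substr(g[4L], 1L, 1L))
    else paste0(g[2L], g[3L])
  }, character(1))
  if (invalid == "error" && anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    stop("invalid ICD-10 code(s): ", paste(utils::head(bad, 10L), collapse = ", "))
  }
  out
}

.is_normalized_icd <- function(x) grepl("^[A-Z][0-9]{2}(\\.[0-9])?$", x)

#' ICD-10 chapter category table
#'
#' Blocks of ICD-10 codes used to categorize diagnosis codes. The default
#' table splits the H letter into eye/adnexa (H00-H59) and ear/mastoid
#' (H60-H99) blocks and carries the display colors used for ego-network
#' figures; `merged_h = TRUE` merges them into a single H00-H99 block, the
#' grouping used by the chapter summary tables.
#'
#' Within every letter the numeric ranges cover 00-99 without overlap, so
#' every normalized code maps to exactly one category.
#'
#' @param merged_h merge the two H blocks into H00-H99.
#' @return data.frame with columns `letter`, `lo`, `hi`, `block`, `label`,
#'   `color` (color may be `NA`).
#' @export
icd_chapters <- function(merged_h = FALSE) {
  ch <- function(letter, lo, hi, label, color = NA_character_) {
    data.frame(letter = letter, lo = lo, hi = hi,
               block = sprintf("%s%02d-%s%02d", letter, lo, letter, hi),
               label = label, color = color, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    ch("A", 0, 99, "certain infectious and parasitic diseases"),
    ch("B", 0, 99, "certain infectious and parasitic diseases"),
    ch("C", 0, 99, "neoplasms"),
    ch("D", 0, 48, "neoplasms"),
    ch("D", 49, 99, "diseases of the blood and blood-forming organs"),
    ch("E", 0, 99, "endocrine, nutritional and metabolic diseases", "lightblue"),
    ch("F", 0, 99, "mental and behavioural disorders", "cyan"),
    ch("G", 0, 99, "diseases of the nervous system", "yellow"),
    ch("H", 0, 59, "diseases of the eye and adnexa", "coral"),
    ch("H", 60, 99, "diseases of the ear and mastoid process", "coral"),
    ch("I", 0, 99, "diseases of the circulatory system", "green"),
    ch("J", 0, 99, "diseases of the respiratory system"),
    ch("K", 0, 99, "diseases of the digestive system"),
    ch("L", 0, 99, "diseases of the skin and subcutaneous tissue"),
    ch("M", 0, 99, "diseases of the musculoskeletal system and connective tissue"),
    ch("N", 0, 99, "diseases of the genitourinary system"),
    ch("O", 0, 99, "pregnancy, childbirth and the puerperium"),
    ch("P", 0, 99, "certain conditions originating in the perinatal period"),
    ch("Q", 0, 99, "congenital malformations, deformations and chromosomal abnormalities", "pink"),
    ch("R", 0, 99, "symptoms, signs and abnormal clinical and laboratory findings", "orange"),
    ch("S", 0, 99, "injury, poisoning and certain other consequences of external causes"),
    ch("T", 0, 99, "injury, poisoning and certain other consequences of external causes"),
    ch("U", 0, 99, "codes for special purposes"),
    ch("V", 0, 99, "external causes of morbidity and mortality"),
    ch("W", 0, 99, "external causes of morbidity and mortality"),
    ch("X", 0, 99, "external causes of morbidity and mortality"),
    ch("Y", 0, 99, "external causes of morbidity and mortality"),
    ch("Z", 0, 99, "factors influencing health status and contact with health services", "violet")
  )
  if (merged_h) {
    tab <- tab[!(tab$letter == "H" & tab$lo == 60), ]
    i <- tab$letter == "H"
    tab$hi[i] <- 99
    tab$block[i] <- "H00-H99"
    tab$label[i] <- "diseases of the eye and adnexa / ear and mastoid process"
  }
  tab
}

#' Map normalized ICD-10 codes to chapter categories
#'
#' @param code character vector of normalized codes (see [normalize_icd()]).
#' @param merged_h use the merged H00-H99 block (see [icd_chapters()]).
#' @param value which column of the category table to return: the block key
#'   (default), the human-readable label, or the display color.
#' @return character vector, one category per code.
#' @examples
#' chapter_of("I67.1")              # "I00-I99"
#' chapter_of("H53.0", value = "label")
#' @export
chapter_of <- function(code, merged_h = FALSE, value = c("block", "label", "color")) {
  value <- match.arg(value)
  ok <- .is_normalized_icd(code)
  if (any(!ok)) stop("not normalized ICD-10 code(s): ",
                     paste(utils::head(unique(code[!ok]), 10L), collapse = ", "))
  tab <- icd_chapters(merged_h = merged_h)
  letter <- substr(code, 1L, 1L)
  num <- as.integer(substr(code, 2L, 3L))
  out <- character(length(code))
  for (r in seq_len(nrow(tab))) {
    i <- letter == tab$letter[r] & num >= tab$lo[r] & num <= tab$hi[r]
    out[i] <- tab[[value]][r]
  }
  out
}

# Table-1-style merged blocks: named letter chapters kept, everything else "other"
.summary_block <- function(code) {
  blk <- chapter_of(code, merged_h = TRUE)
  keep <- c("E", "F", "G", "H", "I", "J", "M", "Q", "R", "Z")
  ifelse(substr(blk, 1L, 1L) %in% keep, blk, "other")
}

#' Parse raw diagnosis records from delimited text
#'
#' Reads one diagnosis event per row, normalizes ICD codes, derives the age at
#' the event (directly from an age column, or as completed years
#' `floor(days(diagnosis - birth) / 365.25)` when birth and diagnosis dates are
#' given), validates gender against the strict M/W stratification, and
#' collapses duplicate (patient, code, date) rows. Malformed rows are never
#' silently discarded: every dropped row is tallied by reason in the attached
#' parse report.
#'
#' @param source path to a delimited text file with a header row.
#' @param schema named list mapping the fields `patient_id`, `gender`,
#'   `icd_code`, and either `age_at_event` or both `birth_date` and
#'   `diagnosis_date`, to column names in the file. Defaults to identity
#'   names.
#' @param delim field delimiter, default `","`.
#' @return a `diagnosis_records` object: a data.frame with columns
#'   `patient_id`, `gender`, `icd_code`, `age_at_event` (and `diagnosis_date`
#'   when present), carrying the parse report in `attr(, "report")` — a list
#'   with `rows_read`, `kept`, `dropped` and per-reason drop counts.
#' @export
parse_records <- function(source, schema = list(), delim = ",") {
  if (!file.exists(source)) stop("input file not found: ", source)
  defaults <- list(patient_id = "patient_id", gender = "gender",
                   icd_code = "icd_code", diagnosis_date = "diagnosis_date",
                   birth_date = "birth_date", age_at_event = "age_at_event")
  schema <- utils::modifyList(defaults, as.list(schema))
  raw <- utils::read.table(source, header = TRUE, sep = delim,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "\"", comment.char = "")
  for (f in c("patient_id", "gender", "icd_code")) {
    if (!schema[[f]] %in% names(raw))
      stop("required column '", schema[[f]], "' (", f, ") missing from ", source)
  }
  has_age <- schema$age_at_event %in% names(raw)
  has_dates <- schema$diagnosis_date %in% names(raw) && schema$birth_date %in% names(raw)
  if (!has_age && !has_dates)
    stop("need either an age column ('", schema$age_at_event,
         "') or both birth and diagnosis date columns")

  n <- nrow(raw)
  drop_reason <- rep(NA_character_, n)
  mark <- function(i, reason) ifelse(is.na(drop_reason) & i, reason, drop_reason)

  pid <- trimws(raw[[schema$patient_id]])
  drop_reason <- mark(is.na(pid) | !nzchar(pid), "missing_patient_id")

  gender <- toupper(trimws(raw[[schema$gender]]))
  drop_reason <- mark(!gender %in% c("M", "W"), "unknown_gender")

  code <- normalize_icd(raw[[schema$icd_code]], invalid = "na")
  drop_reason <- mark(is.na(code), "invalid_icd_code")

  if (has_age) {
    age <- suppressWarnings(as.integer(trimws(raw[[schema$age_at_event]])))
    drop_reason <- mark(is.na(age), "unparseable_age")
    ddate <- if (schema$diagnosis_date %in% names(raw))
      raw[[schema$diagnosis_date]] else rep(NA_character_, n)
  } else {
    dd <- as.Date(trimws(raw[[schema$diagnosis_date]]), format = "%Y-%m-%d")
    bd <- as.Date(trimws(raw[[schema$birth_date]]), format = "%Y-%m-%d")
    drop_reason <- mark(is.na(dd) | is.na(bd), "unparseable_date")
    age <- as.integer(floor(as.numeric(dd - bd) / 365.25))
    ddate <- as.character(dd)
  }
  drop_reason <- mark(!is.na(age) & (age < 0L | age > 130L), "age_out_of_range")

  keep <- is.na(drop_reason)
  ev <- data.frame(patient_id = pid[keep], gender = gender[keep],
                   icd_code = code[keep], age_at_event = age[keep],
                   stringsAsFactors = FALSE)
  ev$diagnosis_date <- ddate[keep]
  dedup_key <- paste(ev$patient_id, ev$icd_code,
                     ifelse(is.na(ev$diagnosis_date), ev$age_at_event, ev$diagnosis_date),
                     sep = "\r")
  dup <- duplicated(dedup_key)
  ev <- ev[!dup, , drop = FALSE]
  rownames(ev) <- NULL

  reasons <- table(drop_reason[!is.na(drop_reason)])
  report <- list(rows_read = n, kept = nrow(ev),
                 dropped = sum(!keep), duplicates_collapsed = sum(dup),
                 drop_reasons = as.list(stats::setNames(as.integer(reasons), names(reasons))))
  structure(ev, report = report, class = c("diagnosis_records", "data.frame"))
}

#' @export
print.diagnosis_records <- function(x, ...) {
  r <- attr(x, "report")
  cat(sprintf("diagnosis records: %d events (%d patients, %d codes)\n",
              nrow(x), length(unique(x$patient_id)), length(unique(x$icd_code))))
  if (!is.null(r))
    cat(sprintf("  parsed %d rows: %d kept, %d dropped, %d duplicates collapsed\n",
                r$rows_read, r$kept, r$dropped, r$duplicates_collapsed))
  invisible(x)
}

#' Retrieve the parse report of a records object
#'
#' @param records a `diagnosis_records` object from [parse_records()].
#' @return list with `rows_read`, `kept`, `dropped`, `duplicates_collapsed`
#'   and `drop_reasons`.
#' @export
parse_report <- function(records) attr(records, "report")
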