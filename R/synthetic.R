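#' Configuration for the synthetic diagnosis registry generator
#'
#' Describes a synthetic population with the statistical structure the
#' comorbidity analysis assumes: code prevalences spanning orders of
#' magnitude (log-uniform), heterogeneous per-patient diagnosis counts
#' (sums of independent Bernoulli assignments), gender and age structure,
#' a focal code at population prevalence 3%, and optional planted excess
#' co-occurrence for chosen code pairs.
#'
#' @param n_patients patients per gender (default 2000).
#' @param n_codes number of distinct ICD codes including the focal code
#'   (default 150).
#' @param prevalence_range c(p_min, p_max) of the log-uniform prevalence law
#'   (default c(0.001, 0.3)).
#' @param focal_code label of the focal code (default `"I67.1"`).
#' @param focal_prevalence prevalence of the focal code (default 0.03).
#' @param planted_pairs list of planted comorbidity effects; each element a
#'   list with `code_a`, `code_b`, `rho` (relative risk >= 1), and optional
#'   `gender` (`"M"`/`"W"`) and `decade` (lower bound, e.g. 50) restrictions.
#'   Carriers of `code_a` receive `code_b` with probability
#'   `min(1, rho * p_b)` instead of `p_b`; a pair with `rho * p_b > 1` is
#'   capped at 1 with a warning.
#' @param prevalence_overrides optional named numeric vector or list,
#'   code -> prevalence, pinning chosen codes to exact target prevalences
#'   after the log-uniform draw (useful for planted-pair power designs).
#' @param age_range default first-diagnosis age range c(lo, hi), uniform
#'   integer ages (default c(30, 89)).
#' @param code_age_ranges optional named list code -> c(lo, hi) overriding
#'   `age_range` per code.
#' @param seed RNG seed; identical (config, seed) reproduces the registry
#'   byte for byte.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_patients = 2000L, n_codes = 150L,
                             prevalence_range = c(0.001, 0.3),
                             focal_code = "I67.1", focal_prevalence = 0.03,
                             planted_pairs = NULL,
                             prevalence_overrides = NULL,
                             age_range = c(30L, 89L),
                             code_age_ranges = NULL,
                             seed = 1L) {
  stopifnot(n_patients >= 1L, n_codes >= 2L,
            length(prevalence_range) == 2L,
            prevalence_range[1] > 0, prevalence_range[1] <= prevalence_range[2],
            prevalence_range[2] < 1,
            focal_prevalence > 0, focal_prevalence < 1,
            length(age_range) == 2L, age_range[1] >= 0, age_range[1] <= age_range[2],
            age_range[2] <= 130)
  if (!.is_normalized_icd(focal_code)) stop("focal_code must be a normalized ICD code")
  if (!is.null(planted_pairs)) {
    for (pp in planted_pairs) {
      if (!all(c("code_a", "code_b", "rho") %in% names(pp)))
        stop("each planted pair needs code_a, code_b, rho")
      if (pp$rho < 1) stop("planted relative risk rho must be >= 1")
    }
  }
  if (!is.null(prevalence_overrides)) {
    pv <- unlist(prevalence_overrides)
    if (is.null(names(pv)) || any(!nzchar(names(pv))) || any(pv <= 0) || any(pv > 1))
      stop("prevalence_overrides must be named, with values in (0, 1]")
    prevalence_overrides <- pv
  }
  structure(list(n_patients = as.integer(n_patients), n_codes = as.integer(n_codes),
                 prevalence_range = as.numeric(prevalence_range),
                 focal_code = focal_code, focal_prevalence = focal_prevalence,
                 planted_pairs = planted_pairs,
                 prevalence_overrides = prevalence_overrides,
                 age_range = as.integer(age_range),
                 code_age_ranges = code_age_ranges,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic pool of ICD-like code labels spread over the letter chapters;
# independent of the RNG so the code book depends only on n_codes
.synthetic_codebook <- function(n_codes, focal_code) {
  letters_pool <- c("A", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                    "L", "M", "N", "Q", "R", "Z")
  labs <- character(0)
  k <- 0L
  while (length(labs) < n_codes) {
    L <- letters_pool[(k %% length(letters_pool)) + 1L]
    num <- (k %/% length(letters_pool)) %% 100L
    dig <- (k %/% (length(letters_pool) * 100L)) %% 10L
    labs <- c(labs, sprintf("%s%02d.%d", L, num, dig))
    k <- k + 1L
  }
  labs <- setdiff(labs, focal_code)[seq_len(n_codes - 1L)]
  c(focal_code, labs)
}

#' Generate a synthetic diagnosis registry
#'
#' Draws, independently per patient and code, whether the patient carries the
#' code (Bernoulli with the code's prevalence), then assigns each carried
#' code a first-diagnosis age uniform in the code's age range. Planted pairs
#' modify the conditional: carriers of `code_a` receive `code_b` with
#' probability `min(1, rho * p_b)`, within any gender restriction; when a
#' planted pair carries a decade restriction, the ages of both codes for the
#' boosted carriers are drawn inside that decade so the excess co-occurrence
#' lands in the corresponding cohort. One event is emitted per
#' (patient, carried code).
#'
#' Under `rho = 1` for all pairs the construction is an exact null for the
#' degree-preserving co-occurrence test: codes are independent given their
#' prevalences.
#'
#' @param config a [synthetic_config()].
#' @return a `diagnosis_records` data.frame (columns `patient_id`, `gender`,
#'   `icd_code`, `age_at_event`) with attributes `prevalences` (target
#'   prevalence per code) and `manifest` (seed, realized prevalences per
#'   gender).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  codes <- .synthetic_codebook(config$n_codes, config$focal_code)
  lp <- log(config$prevalence_range)
  prev <- exp(stats::runif(config$n_codes, lp[1], lp[2]))
  prev[1] <- config$focal_prevalence
  names(prev) <- codes
  for (cd in names(config$prevalence_overrides)) {
    if (!cd %in% codes) stop("prevalence override for unknown code: ", cd)
    prev[cd] <- config$prevalence_overrides[[cd]]
  }

  age_lo <- rep(config$age_range[1], config$n_codes)
  age_hi <- rep(config$age_range[2], config$n_codes)
  names(age_lo) <- names(age_hi) <- codes
  for (cd in names(config$code_age_ranges)) {
    age_lo[cd] <- config$code_age_ranges[[cd]][1]
    age_hi[cd] <- config$code_age_ranges[[cd]][2]
  }

  boost_prob <- vapply(config$planted_pairs, function(pp) {
    p_boost <- pp$rho * prev[[pp$code_b]]
    if (p_boost > 1) {
      warning(sprintf("planted pair %s-%s: rho*p_b = %.3f capped at 1",
                      pp$code_a, pp$code_b, p_boost))
      p_boost <- 1
    }
    p_boost
  }, numeric(1))

  out <- vector("list", 2L)
  realized <- list()
  for (gi in 1:2) {
    g <- c("M", "W")[gi]
    n <- config$n_patients
    carry <- matrix(stats::runif(n * config$n_codes), n, config$n_codes) <
      matrix(prev, n, config$n_codes, byrow = TRUE)
    colnames(carry) <- codes
    boosted_age_decade <- matrix(NA_integer_, n, config$n_codes,
                                 dimnames = list(NULL, codes))
    for (k in seq_along(config$planted_pairs)) {
      pp <- config$planted_pairs[[k]]
      if (!is.null(pp$gender) && pp$gender != g) next
      p_boost <- boost_prob[k]
      a_carriers <- which(carry[, pp$code_a])
      carry[a_carriers, pp$code_b] <- stats::runif(length(a_carriers)) < p_boost
      if (!is.null(pp$decade)) {
        boosted_age_decade[a_carriers, pp$code_a] <- pp$decade
        boosted_age_decade[a_carriers, pp$code_b] <- pp$decade
      }
    }
    idx <- which(carry, arr.ind = TRUE)
    code_j <- idx[, 2L]
    lo <- age_lo[code_j]; hi <- age_hi[code_j]
    dec <- boosted_age_decade[idx]
    lo <- ifelse(is.na(dec), lo, dec)
    hi <- ifelse(is.na(dec), hi, pmin(dec + 9L, 130L))
    ages <- lo + floor(stats::runif(nrow(idx)) * (hi - lo + 1))
    ev <- data.frame(
      patient_id = sprintf("%s%06d", g, idx[, 1L]),
      gender = g,
      icd_code = codes[code_j],
      age_at_event = as.integer(ages),
      stringsAsFactors = FALSE)
    ev <- ev[order(ev$patient_id, ev$icd_code), , drop = FALSE]
    out[[gi]] <- ev
    realized[[g]] <- stats::setNames(colSums(carry) / n, codes)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, prevalences = prev,
            manifest = list(seed = config$seed, n_patients_per_gender = config$n_patients,
                            n_codes = config$n_codes, realized_prevalence = realized),
            class = c("diagnosis_records", "data.frame"))
}

#' Write a synthetic registry to CSV
#'
#' Writes the event table in the schema [parse_records()] consumes, plus a
#' JSON manifest (seed, realized prevalences) alongside when requested.
#'
#' @param events a `diagnosis_records` data.frame.
#' @param path output CSV path.
#' @param manifest write `<path>.manifest.json` too (default TRUE when the
#'   events carry a manifest attribute).
#' @return `path`, invisibly.
#' @export
write_population <- function(events, path, manifest = !is.null(attr(events, "manifest"))) {
  utils::write.csv(as.data.frame(events)[, c("patient_id", "gender", "icd_code",
                                             "age_at_event")],
                   path, row.names = FALSE, quote = FALSE)
  if (manifest)
    jsonlite::write_json(attr(events, "manifest"), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read or write a generator configuration as structured text
#'
#' Serializes a [synthetic_config()] to JSON (key-value with nesting) and
#' back, so simulation settings can live beside their outputs.
#'
#' @param config a `synthetic_config` object.
#' @param path file path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns a validated `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- unclass(config)
  # keep names on length-1 override vectors (auto_unbox would drop them)
  if (!is.null(x$prevalence_overrides))
    x$prevalence_overrides <- as.list(x$prevalence_overrides)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(raw$planted_pairs) && length(raw$planted_pairs) == 0L)
    raw$planted_pairs <- NULL
  if (!is.null(raw$prevalence_overrides))
    raw$prevalence_overrides <- unlist(raw$prevalence_overrides)
  do.call(synthetic_config, raw)
}

#' Monte-Carlo rewiring estimate of the co-occurrence null tail
#'
#' Test oracle for [hypergeom_pvalue()]: estimates P(X >= N_ij) under the
#' degree-preserving null by repeatedly drawing two independent uniform
#' random patient subsets of sizes N_i and N_j and counting their overlap.
#' Intended for small cohorts (N up to a few hundred) only.
#'
#' @param incidence a `bipartite_incidence` object.
#' @param pair character vector of the two codes.
#' @param n_draws number of Monte-Carlo draws (>= 1e4 recommended).
#' @param seed RNG seed.
#' @return list with `estimate`, `se` (binomial standard error), `n_draws`,
#'   and the margins used.
#' @export
rewiring_null_oracle <- function(incidence, pair, n_draws = 1e4L, seed = 1L) {
  stopifnot(inherits(incidence, "bipartite_incidence"), length(pair) == 2L)
  N <- incidence$N
  ni <- incidence$code_counts[pair[1L]]
  nj <- incidence$code_counts[pair[2L]]
  if (anyNA(c(ni, nj))) stop("pair codes not present in incidence")
  key <- incidence$pair_counts
  row <- key[(key$code_i == pair[1L] & key$code_j == pair[2L]) |
             (key$code_i == pair[2L] & key$code_j == pair[1L]), , drop = FALSE]
  nij <- if (nrow(row)) row$n[1L] else 0L
  if (nij == 0L)
    return(list(estimate = 1, se = 0, n_draws = as.integer(n_draws),
                N = N, n_i = unname(ni), n_j = unname(nj), n_ij = 0L))
  set.seed(seed)
  hits <- 0L
  for (d in seq_len(n_draws)) {
    a <- sample.int(N, ni)
    b <- sample.int(N, nj)
    if (sum(a %in% b) >= nij) hits <- hits + 1L
  }
  est <- hits / n_draws
  list(estimate = est, se = sqrt(est * (1 - est) / n_draws),
       n_draws = as.integer(n_draws), N = N,
       n_i = unname(ni), n_j = unname(nj), n_ij = as.integer(nij))
}
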