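#' Null calibration study: realized false-discovery proportion
#'
#' Generates replicate synthetic cohorts with no planted comorbidity (codes
#' independent given their prevalences — an exact null for the
#' degree-preserving co-occurrence test), runs the full validation on one
#' single-decade cohort per replicate, and records the number of validated
#' links. With no true effects every validated link is a false discovery, so
#' the realized false-discovery proportion of a replicate is 1 when any link
#' is validated and 0 otherwise; its mean over replicates estimates the
#' procedure's family-level error, which FDR control bounds by alpha.
#'
#' @param n_replicates number of replicate populations (default 200).
#' @param n_patients patients in the analyzed cohort (default 2000).
#' @param n_codes codes per population (default 150).
#' @param prevalence_range log-uniform prevalence bounds
#'   (default c(0.005, 0.30)).
#' @param alpha FDR level (default 0.01).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list with `mean_fdp`, `median_validated`, `n_validated`
#'   (per-replicate counts), and the settings used.
#' @export
null_fdp_study <- function(n_replicates = 200L, n_patients = 2000L,
                           n_codes = 150L, prevalence_range = c(0.005, 0.30),
                           alpha = 0.01, seed = 1L) {
  vc <- validation_config(alpha = alpha)
  n_validated <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- synthetic_config(n_patients = n_patients, n_codes = n_codes,
                            prevalence_range = prevalence_range,
                            age_range = c(50L, 59L), seed = seed + r)
    reg <- generate_population(cfg)
    coh <- build_cohorts(first_diagnosis_ages(reg))
    m <- coh[[which(vapply(coh, function(c) c$gender == "M", logical(1)))[1L]]]
    n_validated[r] <- nrow(build_svn(m, vc)$edges)
  }
  list(mean_fdp = mean(n_validated > 0L),
       median_validated = stats::median(n_validated),
       n_validated = n_validated,
       n_replicates = n_replicates, n_patients = n_patients,
       n_codes = n_codes, alpha = alpha)
}

#' Analytic power of recovering a planted comorbidity link
#'
#' Closed-form power estimate for a planted pair, computed from the
#' hypergeometric tail at the expected margins rather than by simulation:
#' the critical co-occurrence count k* is the smallest k whose tail
#' probability at margins (N, E\[N_a\], E\[N_b\]) falls below the
#' (Bonferroni-conservative) per-test threshold alpha / T, and the power is
#' the probability that the planted pair's co-occurrence count — binomial
#' with success probability `p_a * min(1, rho * p_b)` — reaches k*.
#'
#' @param N cohort size.
#' @param p_a,p_b marginal prevalences of the two codes.
#' @param rho planted relative risk (carriers of a receive b with
#'   probability `min(1, rho * p_b)`).
#' @param n_tests number of simultaneous tests T.
#' @param alpha FDR level.
#' @return list with `power`, `k_star`, the expected margins and the
#'   per-test threshold used.
#' @export
analytic_planted_power <- function(N, p_a, p_b, rho, n_tests, alpha = 0.01) {
  q <- min(1, rho * p_b)
  e_na <- round(N * p_a)
  e_nb <- round(N * (1 - p_a) * p_b + N * p_a * q)
  threshold <- alpha / n_tests
  ks <- seq_len(min(e_na, e_nb))
  pv <- hypergeom_pvalue(N, e_na, e_nb, ks)
  hit <- which(pv <= threshold)
  if (!length(hit))
    return(list(power = 0, k_star = NA_integer_, e_na = e_na, e_nb = e_nb,
                threshold = threshold))
  k_star <- ks[hit[1L]]
  list(power = stats::pbinom(k_star - 1, N, p_a * q, lower.tail = FALSE),
       k_star = k_star, e_na = e_na, e_nb = e_nb, threshold = threshold)
}

#' Monte-Carlo recovery study of a planted focal comorbidity
#'
#' Generates replicate populations with one planted pair between the focal
#' code and a partner code of pinned prevalence, runs the full validation on
#' a single-decade cohort, and measures how often the planted link is
#' validated. Also returns the matching [analytic_planted_power()] estimate
#' (using the mean number of tested pairs for T) for comparison.
#'
#' @param n_replicates replicate populations (default 100).
#' @param n_patients patients in the analyzed cohort (default 5000).
#' @param n_codes codes per population (default 150).
#' @param focal_prevalence prevalence of the focal code (default 0.03).
#' @param partner_prevalence prevalence of the planted partner (default 0.20).
#' @param rho planted relative risk (default 5).
#' @param alpha FDR level (default 0.01).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list with `recovery_rate`, `analytic` (power estimate list),
#'   `recovered` (logical per replicate), `mean_tested`, and settings.
#' @export
planted_recovery_study <- function(n_replicates = 100L, n_patients = 5000L,
                                   n_codes = 150L, focal_prevalence = 0.03,
                                   partner_prevalence = 0.20, rho = 5,
                                   alpha = 0.01, seed = 1L) {
  vc <- validation_config(alpha = alpha)
  partner <- "A00.0"   # first non-focal code of the deterministic code book
  recovered <- logical(n_replicates)
  tested <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- synthetic_config(
      n_patients = n_patients, n_codes = n_codes,
      focal_prevalence = focal_prevalence,
      prevalence_overrides = stats::setNames(partner_prevalence, partner),
      planted_pairs = list(list(code_a = "I67.1", code_b = partner, rho = rho)),
      age_range = c(50L, 59L), seed = seed + r)
    reg <- suppressWarnings(generate_population(cfg))
    coh <- build_cohorts(first_diagnosis_ages(reg))
    m <- coh[[which(vapply(coh, function(c) c$gender == "M", logical(1)))[1L]]]
    fit <- build_svn(m, vc)
    tested[r] <- fit$n_tested
    key <- paste(fit$edges$code_i, fit$edges$code_j)
    recovered[r] <- paste(partner, "I67.1") %in% key ||
      paste("I67.1", partner) %in% key
  }
  analytic <- analytic_planted_power(n_patients, focal_prevalence,
                                     partner_prevalence, rho,
                                     n_tests = max(round(mean(tested)), 1L),
                                     alpha = alpha)
  list(recovery_rate = mean(recovered), analytic = analytic,
       recovered = recovered, mean_tested = mean(tested),
       n_replicates = n_replicates, n_patients = n_patients, rho = rho,
       partner = partner, alpha = alpha)
}
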