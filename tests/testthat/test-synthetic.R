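test_that("identical config and seed reproduce the registry byte for byte", {
  cfg <- synthetic_config(n_patients = 200, n_codes = 30, seed = 99)
  r1 <- generate_population(cfg)
  r2 <- generate_population(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_population(r1, f1, manifest = FALSE)
  write_population(r2, f2, manifest = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  r3 <- generate_population(synthetic_config(n_patients = 200, n_codes = 30, seed = 100))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(prevalence_range = c(0, 0.3)))
  expect_error(synthetic_config(prevalence_range = c(0.5, 0.3)))
  expect_error(synthetic_config(focal_code = "bad"))
  expect_error(synthetic_config(planted_pairs = list(list(code_a = "A00", code_b = "B00",
                                                          rho = 0.5))), "rho")
  expect_error(synthetic_config(planted_pairs = list(list(code_a = "A00"))),
               "code_a, code_b, rho")
})

test_that("empirical prevalences match their targets within binomial error", {
  cfg <- synthetic_config(n_patients = 5000, n_codes = 60,
                          prevalence_range = c(0.002, 0.3), seed = 41)
  reg <- generate_population(cfg)
  target <- attr(reg, "prevalences")
  real <- attr(reg, "manifest")$realized_prevalence
  for (g in c("M", "W")) {
    se <- sqrt(target * (1 - target) / 5000)
    expect_true(all(abs(real[[g]] - target) <= 4 * se))
  }
  # focal code sits at its configured 3% prevalence
  expect_lt(abs(real$M[["I67.1"]] - 0.03), 4 * sqrt(0.03 * 0.97 / 5000))
})

test_that("a prevalence-1 code is carried by every patient", {
  cfg <- synthetic_config(n_patients = 50, n_codes = 10,
                          prevalence_range = c(0.999999, 0.9999999), seed = 3)
  reg <- generate_population(cfg)
  tab <- table(reg$icd_code)
  non_focal <- setdiff(names(tab), "I67.1")
  expect_true(all(tab[non_focal] == 100L))  # both genders, 50 each
})

test_that("planted pairs boost the conditional carriage rate as configured", {
  rho <- 4
  cfg <- synthetic_config(
    n_patients = 8000, n_codes = 20, prevalence_range = c(0.05, 0.2),
    focal_prevalence = 0.10,
    planted_pairs = list(list(code_a = "I67.1", code_b = "A00.0", rho = rho)),
    seed = 57)
  reg <- generate_population(cfg)
  p_b <- attr(reg, "prevalences")[["A00.0"]]
  all_ids <- sprintf("%s%06d", rep(c("M", "W"), each = 8000), 1:8000)
  has_a <- all_ids %in% reg$patient_id[reg$icd_code == "I67.1"]
  has_b <- all_ids %in% reg$patient_id[reg$icd_code == "A00.0"]
  p_b_given_a <- mean(has_b[has_a])
  p_b_given_nota <- mean(has_b[!has_a])
  n_a <- sum(has_a)
  expect_lt(abs(p_b_given_a - rho * p_b), 4 * sqrt(rho * p_b / n_a))
  expect_lt(abs(p_b_given_nota - p_b), 4 * sqrt(p_b / sum(!has_a)))
})

test_that("rho * p_b above one is capped with a warning", {
  cfg <- synthetic_config(
    n_patients = 300, n_codes = 10, prevalence_range = c(0.2, 0.4),
    planted_pairs = list(list(code_a = "I67.1", code_b = "A00.0", rho = 50)),
    seed = 5)
  expect_warning(reg <- generate_population(cfg), "capped")
  a_ids <- reg$patient_id[reg$icd_code == "I67.1"]
  b_ids <- reg$patient_id[reg$icd_code == "A00.0"]
  expect_true(all(a_ids %in% b_ids))
})

test_that("gender and decade restrictions confine the planted effect", {
  cfg <- synthetic_config(
    n_patients = 3000, n_codes = 15, prevalence_range = c(0.05, 0.15),
    focal_prevalence = 0.2, age_range = c(20, 79),
    planted_pairs = list(list(code_a = "I67.1", code_b = "A00.0", rho = 6,
                              gender = "W", decade = 50)),
    seed = 61)
  suppressWarnings(reg <- generate_population(cfg))
  p_b <- attr(reg, "prevalences")[["A00.0"]]
  for (g in c("M", "W")) {
    ids <- sprintf("%s%06d", g, 1:3000)
    has_a <- ids %in% reg$patient_id[reg$icd_code == "I67.1"]
    has_b <- ids %in% reg$patient_id[reg$icd_code == "A00.0"]
    ratio <- mean(has_b[has_a]) / mean(has_b[!has_a])
    if (g == "W") expect_gt(ratio, 3) else expect_lt(ratio, 2)
  }
  # boosted carriers' ages for both planted codes fall in the 50-59 decade
  w <- reg[reg$gender == "W", ]
  wc <- split(w, w$patient_id)
  for (p in wc) {
    if ("I67.1" %in% p$icd_code && "A00.0" %in% p$icd_code) {
      ages <- p$age_at_event[p$icd_code %in% c("I67.1", "A00.0")]
      expect_true(all(ages >= 50 & ages <= 59))
    }
  }
})

test_that("the rewiring oracle reproduces the exact tail probability", {
  # incidence with margins N = 10, N_i = 4, N_j = 5, N_ij = 4
  hist <- c(rep(list(c("A00", "B00")), 4), list("B00"), rep(list("C00"), 5))
  inc <- build_incidence(make_cohort(hist))
  expect_identical(inc$N, 10L)
  ora <- rewiring_null_oracle(inc, c("A00", "B00"), n_draws = 1e5, seed = 8)
  exact <- enum_tail_prob(10, 4, 5, 4)
  expect_lt(abs(ora$estimate - exact), 3 * ora$se + 1e-12)
  expect_equal(hypergeom_pvalue(10, 4, 5, 4), exact, tolerance = 1e-12)

  # a pair that never co-occurs has estimate exactly 1
  inc2 <- build_incidence(make_cohort(list("A00", "B00", c("A00", "C00"))))
  ora2 <- rewiring_null_oracle(inc2, c("A00", "B00"), n_draws = 10)
  expect_identical(ora2$estimate, 1)
  expect_error(rewiring_null_oracle(inc, c("A00", "ZZZ")), "not present")
})

test_that("per-patient diagnosis counts are heterogeneous", {
  reg <- generate_population(synthetic_config(n_patients = 1000, n_codes = 100,
                                              seed = 77))
  counts <- table(reg$patient_id)
  expect_gt(stats::var(as.numeric(counts)), 0)
  expect_gt(max(counts), 2 * stats::median(as.numeric(counts)))
})

test_that("generator configs round-trip through their text serialization", {
  cfg <- synthetic_config(
    n_patients = 120, n_codes = 25, prevalence_range = c(0.01, 0.2),
    focal_prevalence = 0.05, prevalence_overrides = c("A00.0" = 0.15),
    planted_pairs = list(list(code_a = "I67.1", code_b = "A00.0", rho = 3,
                              gender = "W", decade = 40)),
    age_range = c(20, 69), code_age_ranges = list("A00.0" = c(40, 49)),
    seed = 12)
  path <- tempfile(fileext = ".json")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  # the reloaded config drives an identical registry
  expect_identical(as.data.frame(generate_population(back)),
                   as.data.frame(generate_population(cfg)))
})
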