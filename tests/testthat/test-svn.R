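test_that("build_incidence counts margins and pairs correctly", {
  inc <- build_incidence(make_cohort(list(c("A00", "B00"), "A00")))
  expect_identical(inc$N, 2L)
  expect_identical(inc$code_counts[["A00"]], 2L)
  expect_identical(inc$code_counts[["B00"]], 1L)
  expect_identical(inc$pair_counts$n, 1L)

  inc <- build_incidence(make_cohort(rep(list(c("A00", "B00", "C00")), 3)))
  expect_identical(nrow(inc$pair_counts), 3L)
  expect_true(all(inc$pair_counts$n == 3L))

  expect_error(build_incidence(make_cohort(list())), "empty cohort")
})

test_that("build_incidence matches a brute-force double loop on simulated patients", {
  set.seed(5)
  codes <- sprintf("C%02d", 0:14)
  hist <- lapply(1:100, function(i) sort(sample(codes, sample(1:6, 1))))
  inc <- build_incidence(make_cohort(hist))
  # brute force: count carriers and co-carriers by scanning every patient pair
  for (k in sample(nrow(inc$pair_counts), 25)) {
    ci <- inc$pair_counts$code_i[k]; cj <- inc$pair_counts$code_j[k]
    n_bf <- sum(vapply(hist, function(h) ci %in% h && cj %in% h, logical(1)))
    expect_identical(inc$pair_counts$n[k], n_bf)
  }
  for (cd in names(inc$code_counts))
    expect_identical(inc$code_counts[[cd]],
                     sum(vapply(hist, function(h) cd %in% h, logical(1))))
  # margin bounds invariant
  ni <- inc$code_counts[inc$pair_counts$code_i]
  nj <- inc$code_counts[inc$pair_counts$code_j]
  expect_true(all(inc$pair_counts$n <= pmin(ni, nj)))
  expect_true(all(inc$pair_counts$n >= pmax(0, ni + nj - inc$N)))
})

test_that("min_prevalence excludes rare codes before pairing", {
  coh <- make_cohort(list(c("A00", "B00"), c("A00", "B00"), c("A00", "C00")))
  inc <- build_incidence(coh, validation_config(min_prevalence = 2))
  expect_false("C00" %in% names(inc$code_counts))
  expect_identical(nrow(inc$pair_counts), 1L)
})

test_that("hypergeom_pvalue handles degenerate and reference cases", {
  expect_identical(hypergeom_pvalue(100, 10, 20, 0), 1)      # empty sum
  expect_identical(hypergeom_pvalue(50, 50, 7, 7), 1)        # code carried by all
  expect_equal(hypergeom_pvalue(10, 4, 5, 4), 6 / 252, tolerance = 1e-14)
  expect_error(hypergeom_pvalue(10, 11, 5, 2), "margin bound")
  expect_error(hypergeom_pvalue(10, 4, 5, 5), "outside")
})

test_that("hypergeom_pvalue equals exhaustive enumeration on a sampled grid", {
  set.seed(9)
  for (rep in 1:60) {
    N <- sample(2:12, 1)
    ni <- sample(N, 1); nj <- sample(N, 1)
    lo <- max(0, ni + nj - N); hi <- min(ni, nj)
    nij <- sample(lo:hi, 1)
    expect_equal(hypergeom_pvalue(N, ni, nj, nij), enum_tail_prob(N, ni, nj, nij),
                 tolerance = 1e-12)
  }
})

test_that("hypergeom_pvalue agrees with the survival function of the
           hypergeometric distribution at large N", {
  set.seed(11)
  for (rep in 1:200) {
    N <- sample(100:200000, 1)
    ni <- sample(N, 1); nj <- sample(N, 1)
    lo <- max(0, ni + nj - N); hi <- min(ni, nj)
    nij <- sample(lo:hi, 1)
    p <- hypergeom_pvalue(N, ni, nj, nij)
    ref <- stats::phyper(nij - 1, ni, N - ni, nj, lower.tail = FALSE)
    if (ref > 1e-280) expect_equal(p, ref, tolerance = 1e-9)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("the null pmf is normalized and the tail is strictly monotone", {
  set.seed(13)
  for (rep in 1:100) {
    N <- sample(10:1e6, 1)
    ni <- sample(N, 1); nj <- sample(N, 1)
    lo <- max(0, ni + nj - N); hi <- min(ni, nj)
    lp <- comorbnet:::.lhg(lo:hi, N, ni, nj)
    m <- max(lp)
    expect_equal(exp(m) * sum(exp(lp - m)), 1, tolerance = 1e-9)
  }
  for (rep in 1:100) {
    N <- sample(10:2000, 1)
    ni <- sample(N, 1); nj <- sample(N, 1)
    lo <- max(0, ni + nj - N); hi <- min(ni, nj)
    if (hi - lo < 1) next
    xs <- if (hi - lo <= 40) lo:(hi - 1) else sort(sample(lo:(hi - 1), 20))
    p1 <- hypergeom_pvalue(N, ni, nj, xs)
    p2 <- hypergeom_pvalue(N, ni, nj, xs + 1)
    # non-increasing everywhere; strictly decreasing wherever both values
    # are distinguishable from 1 and 0 in double precision
    expect_true(all(p2 <= p1))
    strict <- p1 > 1e-300 & p1 < 1 - 1e-12
    expect_true(all(p2[strict] < p1[strict]))
  }
})

test_that("hypergeom_pvalue is symmetric in the two margins", {
  set.seed(17)
  for (rep in 1:50) {
    N <- sample(20:5000, 1)
    ni <- sample(N, 1); nj <- sample(N, 1)
    nij <- sample(max(0, ni + nj - N):min(ni, nj), 1)
    expect_equal(hypergeom_pvalue(N, ni, nj, nij),
                 hypergeom_pvalue(N, nj, ni, nij), tolerance = 1e-12)
  }
})

test_that("fdr_select applies the step-up rule with per-rank thresholds", {
  res <- data.frame(code_i = c("A00", "B00", "C00"),
                    code_j = c("B00", "C00", "D00"),
                    p_value = c(1, 1, 1))
  out <- fdr_select(res)
  expect_false(any(out$validated))

  res$p_value <- c(0.001, 0.5, 0.002)
  out <- fdr_select(res)  # thresholds 1,2,3 * 0.01/3
  expect_equal(out$threshold, c(1, 2, 3) * 0.01 / 3)
  expect_identical(out$validated, c(TRUE, TRUE, FALSE))
  expect_identical(out$p_value, c(0.001, 0.002, 0.5))
  expect_identical(sort(out$rank), 1:3)

  out <- fdr_select(data.frame(code_i = "A00", code_j = "B00", p_value = 0.009))
  expect_true(out$validated)

  expect_error(fdr_select(data.frame(code_i = c("A00", "B00"),
                                     code_j = c("B00", "A00"),
                                     p_value = c(0.1, 0.2))), "duplicate")
})

test_that("fdr_select matches p.adjust(BH) and is order invariant", {
  set.seed(19)
  for (rep in 1:20) {
    T_n <- sample(5:200, 1)
    p <- stats::runif(T_n)^sample(1:3, 1)
    res <- data.frame(code_i = sprintf("A%02d.%d", seq_len(T_n) %/% 10, seq_len(T_n) %% 10),
                      code_j = sprintf("B%02d.%d", seq_len(T_n) %/% 10, seq_len(T_n) %% 10),
                      p_value = p)
    out <- fdr_select(res, validation_config(alpha = 0.05))
    bh <- stats::p.adjust(p, method = "BH") <= 0.05
    key <- function(d) paste(d$code_i, d$code_j)
    expect_identical(out$validated[match(key(res), key(out))], unname(bh))
    # permuting the input changes nothing
    perm <- sample(T_n)
    out2 <- fdr_select(res[perm, ], validation_config(alpha = 0.05))
    expect_identical(out, out2)
  }
})

test_that("bonferroni mode validates iff p <= alpha / T", {
  res <- data.frame(code_i = c("A00", "B00", "C00"),
                    code_j = c("B00", "C00", "D00"),
                    p_value = c(0.003, 0.004, 0.01))
  out <- fdr_select(res, validation_config(alpha = 0.01, correction = "bonferroni"))
  expect_identical(out$validated, c(TRUE, FALSE, FALSE))
  expect_true(all(out$threshold == 0.01 / 3))
})

test_that("build_svn validates a fully co-occurring pair and nothing else", {
  # 1000 patients: codes A and B always together in 50 patients, plus
  # independent background codes
  set.seed(23)
  hist <- lapply(1:1000, function(i) {
    h <- sprintf("C%02d", which(stats::runif(20) < 0.1))
    if (i <= 50) h <- c(h, "A00", "B00")
    if (length(h) == 0) h <- "Z00"
    sort(h)
  })
  fit <- build_svn(make_cohort(hist))
  key <- paste(fit$edges$code_i, fit$edges$code_j)
  expect_true("A00 B00" %in% key)
  # the planted pair is overwhelming: p far below its threshold
  ab <- fit$edges[key == "A00 B00", ]
  expect_lt(ab$p_value, 1e-50)
  # degrees consistent with edges
  for (nd in fit$nodes)
    expect_identical(fit$degrees[[nd]],
                     sum(fit$edges$code_i == nd) + sum(fit$edges$code_j == nd))
  # permuting patient order leaves the validated edge set unchanged
  fit2 <- build_svn(make_cohort(hist[sample(1000)]))
  expect_identical(fit$edges[order(fit$edges$code_i, fit$edges$code_j),
                             c("code_i", "code_j", "p_value")],
                   fit2$edges[order(fit2$edges$code_i, fit2$edges$code_j),
                              c("code_i", "code_j", "p_value")])
})

test_that("build_svn yields no tests when no pair co-occurs", {
  fit <- build_svn(make_cohort(list("A00", "B00", "C00")))
  expect_identical(fit$n_tested, 0L)
  expect_identical(nrow(fit$edges), 0L)
  expect_length(fit$nodes, 0L)
})

test_that("degree_distribution normalizes over nodes", {
  tri <- make_svn(edge_df(c("A00", "B00", "A00"), c("B00", "C00", "C00")))
  expect_identical(degree_distribution(tri), c("2" = 1))
  star <- make_svn(edge_df(rep("A00", 4), c("B00", "C00", "D00", "E00")))
  expect_identical(degree_distribution(star), c("1" = 0.8, "4" = 0.2))
  expect_equal(sum(degree_distribution(star)), 1)
  empty <- make_svn(edge_df(character(0), character(0))[0, ])
  expect_error(degree_distribution(empty), "no nodes")
})

test_that("svn objects print, summarize and convert to igraph", {
  fit <- build_svn(make_cohort(c(rep(list(c("A00", "B00")), 60),
                                 lapply(1:140, function(i) sprintf("D%02d", i %% 7)))))
  expect_output(print(fit), "validated")
  s <- summary(fit)
  expect_output(print(s), "degree distribution")
  g <- as_igraph(fit)
  expect_s3_class(g, "igraph")
  expect_equal(igraph::gorder(g), length(fit$nodes))
  expect_equal(igraph::gsize(g), nrow(fit$edges))
  expect_identical(igraph::vertex_attr(g, "chapter"), chapter_of(fit$nodes))
})
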