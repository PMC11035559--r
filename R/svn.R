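#' Validation settings for comorbidity link testing
#'
#' @param alpha false-discovery-rate level (or familywise level under
#'   Bonferroni), in (0, 1); default 0.01.
#' @param correction multiple-testing procedure: `"fdr"` (Benjamini-Hochberg
#'   step-up, default) or `"bonferroni"`.
#' @param min_cooccurrence minimum observed co-occurrence count for a pair to
#'   be tested (default 1).
#' @param min_prevalence minimum number of carriers for a code to enter the
#'   analysis (default 1).
#' @param test_all_pairs if `TRUE`, the number of tests T counts all pairs of
#'   retained codes, including pairs that never co-occur (those have p = 1 and
#'   can never be rejected, but they inflate T and so tighten every
#'   threshold); default `FALSE` counts only pairs actually tested.
#' @return a `validation_config` object.
#' @export
validation_config <- function(alpha = 0.01, correction = c("fdr", "bonferroni"),
                              min_cooccurrence = 1L, min_prevalence = 1L,
                              test_all_pairs = FALSE) {
  correction <- match.arg(correction)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            min_cooccurrence >= 1L, min_prevalence >= 1L)
  structure(list(alpha = alpha, correction = correction,
                 min_cooccurrence = as.integer(min_cooccurrence),
                 min_prevalence = as.integer(min_prevalence),
                 test_all_pairs = isTRUE(test_all_pairs)),
            class = "validation_config")
}

#' Bipartite disease-patient incidence counts for one cohort
#'
#' Counts, within a cohort, the total number of patients N, the number of
#' carriers N_i of each code, and the number of co-carriers N_ij of every
#' unordered code pair that co-occurs in at least one patient. These margins
#' are all the hypergeometric null needs.
#'
#' @param cohort a `cohort_dataset` (see [build_cohorts()]).
#' @param config a [validation_config()]; codes with fewer than
#'   `min_prevalence` carriers are excluded before pairs are counted.
#' @return a `bipartite_incidence` object: list with `N` (patients),
#'   `code_counts` (named integer vector N_i), and `pair_counts` (data.frame
#'   `code_i`, `code_j`, `n` with `code_i < code_j` lexicographically).
#' @export
build_incidence <- function(cohort, config = validation_config()) {
  h <- cohort$histories
  if (length(h) == 0L) stop("empty cohort: no patients")
  codes <- sort(unique(unlist(h, use.names = FALSE)))
  lens <- lengths(h)
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(h), lens),
    j = match(unlist(h, use.names = FALSE), codes),
    x = 1, dims = c(length(h), length(codes)))
  counts <- stats::setNames(as.integer(Matrix::colSums(M)), codes)
  keep <- counts >= config$min_prevalence
  M <- M[, keep, drop = FALSE]
  counts <- counts[keep]
  codes <- codes[keep]
  P <- Matrix::crossprod(M)                     # code x code co-carrier counts
  P <- methods::as(Matrix::triu(P, k = 1), "TsparseMatrix")
  nz <- P@x >= 1
  pair_counts <- data.frame(code_i = codes[P@i[nz] + 1L],
                            code_j = codes[P@j[nz] + 1L],
                            n = as.integer(P@x[nz]),
                            stringsAsFactors = FALSE)
  pair_counts <- pair_counts[order(pair_counts$code_i, pair_counts$code_j), ,
                             drop = FALSE]
  rownames(pair_counts) <- NULL
  structure(list(N = length(h), code_counts = counts, pair_counts = pair_counts),
            class = "bipartite_incidence")
}

#' @export
print.bipartite_incidence <- function(x, ...) {
  cat(sprintf("bipartite incidence: N = %d patients, %d codes, %d co-occurring pairs\n",
              x$N, length(x$code_counts), nrow(x$pair_counts)))
  invisible(x)
}

# log hypergeometric pmf terms at overlap values x (vectorized in x)
.lhg <- function(x, N, ni, nj) {
  lchoose(ni, x) + lchoose(N - ni, nj - x) - lchoose(N, nj)
}

.hg_tail_one <- function(N, ni, nj, nij) {
  lo <- max(0, ni + nj - N)
  hi <- min(ni, nj)
  if (nij < 0 || nij > hi)
    stop(sprintf("N_ij = %g outside [0, min(N_i, N_j) = %g] for N = %g, N_i = %g, N_j = %g",
                 nij, hi, N, ni, nj))
  if (nij <= lo) return(1)
  mode <- floor((ni + 1) * (nj + 1) / (N + 2))
  if (nij > mode) {
    # above the mode the right tail is the small one: sum it directly, in
    # log space with the smallest terms first, so tiny p-values keep full
    # relative precision
    lp <- .lhg(nij:hi, N, ni, nj)
    m <- max(lp)
    # clamp at the smallest positive double: p is in (0, 1] by construction
    min(max(exp(m + log(sum(exp(sort(lp - m))))), .Machine$double.xmin), 1)
  } else {
    # at or below the mode p >= ~0.5, so the complement of the left tail
    # loses no precision that matters
    lp <- .lhg(lo:(nij - 1), N, ni, nj)
    m <- max(lp)
    s <- exp(m + log(sum(exp(sort(lp - m)))))
    max(1 - s, .Machine$double.xmin)
  }
}

#' Exact right-tail p-value of the degree-preserving co-occurrence null
#'
#' Under random rewiring of the bipartite disease-patient network that keeps
#' every code's prevalence and every patient's diagnosis count fixed, the
#' number of co-carriers X of two codes with N_i and N_j carriers among N
#' patients follows the hypergeometric law
#' \deqn{H(X \mid N, N_i, N_j) = \binom{N_i}{X}\binom{N-N_i}{N_j-X} / \binom{N}{N_j}.}
#' The p-value of an observed co-occurrence count is the probability of that
#' count or more, \eqn{p = P(X \ge N_{ij}) = 1 - \sum_{X < N_{ij}} H(X)}.
#'
#' The sum is evaluated over whichever tail is shorter, in log space with the
#' smallest terms accumulated first, so results are exact for integer margins
#' and accurate down to p of order 1e-300 at registry-scale N.
#'
#' @param N total number of patients (scalar or vector, recycled).
#' @param n_i,n_j carrier counts of the two codes.
#' @param n_ij observed co-occurrence count.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' hypergeom_pvalue(10, 4, 5, 4)  # 6/252
#' @export
hypergeom_pvalue <- function(N, n_i, n_j, n_ij) {
  n <- max(length(N), length(n_i), length(n_j), length(n_ij))
  N <- rep_len(as.numeric(N), n); n_i <- rep_len(as.numeric(n_i), n)
  n_j <- rep_len(as.numeric(n_j), n); n_ij <- rep_len(as.numeric(n_ij), n)
  bad <- n_i < 0 | n_j < 0 | n_i > N | n_j > N
  if (any(bad))
    stop("margin bound violated: need 0 <= N_i, N_j <= N (first offending index ",
         which(bad)[1L], ")")
  vapply(seq_len(n), function(k) .hg_tail_one(N[k], n_i[k], n_j[k], n_ij[k]),
         numeric(1))
}

#' Select validated links by rank-dependent p-value thresholds
#'
#' Orders the tested pairs by increasing p-value and applies the
#' Benjamini-Hochberg step-up rule: with T tests and level alpha, the
#' validated set is all pairs of rank at most
#' \eqn{k^* = \max\{k : p_{(k)} \le k\alpha/T\}} (empty when no rank
#' qualifies). Tied p-values share eligibility. Under
#' `correction = "bonferroni"` a pair is validated iff \eqn{p \le \alpha/T}.
#'
#' @param results data.frame with columns `code_i`, `code_j`, `p_value`, and
#'   optionally `n` (co-occurrence count, copied through as
#'   `n_cooccurrence`). Every pair must appear once.
#' @param config a [validation_config()].
#' @param n_tests the number of tests T; defaults to `nrow(results)`. Pass a
#'   larger value to account for pairs not present in `results` (see
#'   `test_all_pairs`).
#' @return data.frame `code_i`, `code_j`, `n_cooccurrence`, `p_value`,
#'   `rank`, `threshold`, `validated`, sorted by (p-value, pair); ranks are a
#'   permutation of 1..nrow.
#' @export
fdr_select <- function(results, config = validation_config(), n_tests = NULL) {
  res <- as.data.frame(results)
  if (!all(c("code_i", "code_j", "p_value") %in% names(res)))
    stop("results must have columns code_i, code_j, p_value")
  key <- paste(pmin(res$code_i, res$code_j), pmax(res$code_i, res$code_j), sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate pair(s) in results: ",
         gsub("\r", "-", key[duplicated(key)][1L]))
  T_eff <- if (is.null(n_tests)) nrow(res) else as.integer(n_tests)
  if (T_eff < nrow(res)) stop("n_tests smaller than number of supplied results")
  o <- order(res$p_value, res$code_i, res$code_j)
  res <- res[o, , drop = FALSE]
  T_here <- nrow(res)
  out <- data.frame(code_i = res$code_i, code_j = res$code_j,
                    n_cooccurrence = if ("n" %in% names(res)) res$n else NA_integer_,
                    p_value = res$p_value, rank = seq_len(T_here),
                    stringsAsFactors = FALSE)
  if (config$correction == "fdr") {
    out$threshold <- out$rank * config$alpha / T_eff
    pass <- which(out$p_value <= out$threshold)
    k_star <- if (length(pass)) max(pass) else 0L
    out$validated <- out$rank <= k_star
  } else {
    out$threshold <- rep(config$alpha / T_eff, T_here)
    out$validated <- out$p_value <= out$threshold
  }
  rownames(out) <- NULL
  out
}

#' Fit a statistically validated comorbidity network to a cohort
#'
#' The estimator at the core of the package. From a cohort's patient
#' histories it (i) builds the bipartite incidence margins
#' ([build_incidence()]), (ii) computes, for every code pair co-occurring at
#' least `min_cooccurrence` times, the exact right-tail p-value of the
#' degree-preserving hypergeometric null ([hypergeom_pvalue()]), and (iii)
#' retains the pairs surviving multiple-testing control ([fdr_select()]).
#' The result is the cohort's statistically validated network (SVN): an
#' undirected graph on ICD codes whose every edge rejects random
#' co-occurrence.
#'
#' @param cohort a `cohort_dataset` (see [build_cohorts()]).
#' @param config a [validation_config()].
#' @param keep_isolated keep tested codes with no validated edge as isolated
#'   nodes (default `FALSE`: nodes are codes incident to a validated edge).
#' @return an object of class `"svn"` with components `cohort_key`, `gender`,
#'   `decade`, `N` (patients), `n_codes`, `n_tested`, `results` (the full
#'   [fdr_select()] table), `edges` (validated rows only), `nodes`,
#'   `degrees`, `prevalence` (carrier counts of the node codes), and
#'   `config`. Methods: `print`, `summary`, `plot`, [degree_distribution()],
#'   [as_igraph()], [ego_network()].
#' @examples
#' reg <- generate_population(synthetic_config(n_patients = 300, n_codes = 40,
#'                                             seed = 7))
#' coh <- build_cohorts(first_diagnosis_ages(reg))
#' fit <- build_svn(coh[[3]])
#' fit
#' @export
build_svn <- function(cohort, config = validation_config(), keep_isolated = FALSE) {
  inc <- build_incidence(cohort, config)
  pairs <- inc$pair_counts[inc$pair_counts$n >= config$min_cooccurrence, , drop = FALSE]
  n_codes <- length(inc$code_counts)
  T_eff <- if (config$test_all_pairs) n_codes * (n_codes - 1) / 2 else nrow(pairs)
  if (nrow(pairs) > 0L) {
    pairs$p_value <- hypergeom_pvalue(inc$N,
                                      inc$code_counts[pairs$code_i],
                                      inc$code_counts[pairs$code_j],
                                      pairs$n)
    results <- fdr_select(pairs, config, n_tests = max(T_eff, 1))
  } else {
    results <- data.frame(code_i = character(0), code_j = character(0),
                          n_cooccurrence = integer(0), p_value = numeric(0),
                          rank = integer(0), threshold = numeric(0),
                          validated = logical(0), stringsAsFactors = FALSE)
  }
  edges <- results[results$validated, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$code_i, edges$code_j)))
  if (keep_isolated) nodes <- sort(unique(c(nodes, names(inc$code_counts))))
  degrees <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0L) {
    tab <- table(c(edges$code_i, edges$code_j))
    degrees[names(tab)] <- as.integer(tab)
  }
  structure(list(cohort_key = .cohort_key(cohort), gender = cohort$gender,
                 decade = cohort$decade, N = inc$N, n_codes = n_codes,
                 n_tested = nrow(pairs), results = results, edges = edges,
                 nodes = nodes, degrees = degrees,
                 prevalence = inc$code_counts[nodes], config = config),
            class = "svn")
}

#' @export
print.svn <- function(x, ...) {
  cat(sprintf("statistically validated comorbidity network  [%s]\n", x$cohort_key))
  cat(sprintf("  %d patients, %d codes; %d pairs tested, %d links validated (%s, alpha = %g)\n",
              x$N, x$n_codes, x$n_tested, nrow(x$edges),
              x$config$correction, x$config$alpha))
  invisible(x)
}

#' @export
summary.svn <- function(object, ...) {
  ans <- list(cohort_key = object$cohort_key, N = object$N,
              n_codes = object$n_codes, n_tested = object$n_tested,
              n_validated = nrow(object$edges), n_nodes = length(object$nodes),
              alpha = object$config$alpha, correction = object$config$correction,
              degree_distribution = if (length(object$nodes))
                degree_distribution(object) else NULL,
              top_edges = utils::head(object$edges, 10L))
  class(ans) <- "summary.svn"
  ans
}

#' @export
print.summary.svn <- function(x, ...) {
  cat(sprintf("SVN summary [%s]: N = %d, codes = %d, tested = %d, validated = %d, nodes = %d\n",
              x$cohort_key, x$N, x$n_codes, x$n_tested, x$n_validated, x$n_nodes))
  if (!is.null(x$degree_distribution)) {
    cat("degree distribution P(k):\n")
    print(round(x$degree_distribution, 4))
  }
  if (nrow(x$top_edges) > 0L) {
    cat("strongest validated links:\n")
    print(x$top_edges, digits = 3)
  }
  invisible(x)
}

#' Degree distribution of a validated network
#'
#' @param network an `"svn"` (or any object with a `degrees` vector).
#' @return named numeric vector: `P(k)`, the fraction of nodes with degree
#'   k, for each observed k; sums to 1.
#' @export
degree_distribution <- function(network) {
  deg <- network$degrees
  if (length(deg) == 0L) stop("network has no nodes")
  tab <- table(deg)
  stats::setNames(as.numeric(tab) / length(deg), names(tab))
}

#' Convert a validated network to an igraph graph
#'
#' Nodes carry `chapter` (block key), `degree` and `prevalence` attributes;
#' edges carry `n_cooccurrence`, `p_value`, `rank` and `threshold`.
#'
#' @param x an `"svn"` or `"ego_network"` object.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(x) {
  edges <- x$edges
  nodes <- if (!is.null(x$nodes)) x$nodes else x$members
  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  vdf$chapter <- if (length(nodes)) chapter_of(nodes) else character(0)
  if (!is.null(x$degrees)) vdf$degree <- as.integer(x$degrees[nodes])
  if (!is.null(x$prevalence)) vdf$prevalence <- as.integer(x$prevalence[nodes])
  edf <- edges[, intersect(c("code_i", "code_j", "n_cooccurrence", "p_value",
                             "rank", "threshold"), names(edges)), drop = FALSE]
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' @export
#' @param x an `"svn"` object.
#' @param ... passed to `igraph::plot.igraph`.
#' @rdname build_svn
plot.svn <- function(x, ...) {
  g <- as_igraph(x)
  col <- chapter_of(igraph::V(g)$name, value = "color")
  col[is.na(col)] <- "grey80"
  igraph::plot.igraph(g, vertex.color = col, vertex.label.cex = 0.7, ...)
}
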