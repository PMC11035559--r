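# Independent oracles and fixture builders used across the suite.

# Exhaustive-enumeration tail probability: fix the carriers of code i as
# patients 1..ni; enumerate every possible carrier set of code j (all
# subsets of size nj of 1..N, equally likely under the degree-preserving
# null) and count those overlapping 1..ni in at least nij patients.
# Independent of the package's log-space tail-sum implementation.
enum_tail_prob <- function(N, ni, nj, nij) {
  if (nij <= max(0, ni + nj - N)) return(1)
  subsets <- utils::combn(N, nj)
  overlap <- colSums(subsets <= ni)
  mean(overlap >= nij)
}

# All right-tail probabilities for one (N, nj) at once, for speed in the
# full-grid oracle test: returns function(ni, nij) -> enumerated p.
enum_tail_table <- function(N, nj) {
  subsets <- utils::combn(N, nj)
  function(ni, nij) {
    overlap <- colSums(subsets <= ni)
    mean(overlap >= nij)
  }
}

# Minimal cohort fixture: histories is a (possibly named) list of character
# vectors of codes, one per patient.
make_cohort <- function(histories, gender = "M", lo = 50L) {
  if (is.null(names(histories)))
    names(histories) <- sprintf("P%03d", seq_along(histories))
  structure(list(gender = gender,
                 decade = c(lo, if (lo >= 80) Inf else lo + 9L),
                 label = decade_label(lo),
                 histories = histories),
            class = "cohort_dataset")
}

# Minimal svn fixture from an explicit validated edge list.
make_svn <- function(edges, gender = "M", lo = 50L) {
  nodes <- sort(unique(c(edges$code_i, edges$code_j)))
  degrees <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(c(edges$code_i, edges$code_j))
  degrees[names(tab)] <- as.integer(tab)
  structure(list(cohort_key = paste(gender, decade_label(lo)), gender = gender,
                 decade = c(lo, lo + 9L), N = 100L, n_codes = length(nodes),
                 n_tested = nrow(edges), results = edges, edges = edges,
                 nodes = nodes, degrees = degrees,
                 prevalence = stats::setNames(rep(10L, length(nodes)), nodes),
                 config = validation_config()),
            class = "svn")
}

edge_df <- function(code_i, code_j, p = 1e-6, n = 10L) {
  k <- length(code_i)
  data.frame(code_i = code_i, code_j = code_j,
             n_cooccurrence = rep_len(n, k), p_value = rep_len(p, k),
             rank = seq_len(k), threshold = rep_len(0.01, k),
             validated = rep_len(TRUE, k), stringsAsFactors = FALSE)
}

# Registry CSV writer for parse tests.
write_registry_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# An ego_network fixture with prescribed member codes.
make_ego <- function(members, focal = "I67.1", gender = "M", lo = 50L) {
  structure(list(cohort_key = paste(gender, decade_label(lo)), gender = gender,
                 decade = c(lo, lo + 9L), focal = focal, mode = "induced",
                 members = c(focal, setdiff(members, focal)),
                 edges = edge_df(rep(focal, length(setdiff(members, focal))),
                                 setdiff(members, focal)),
                 degrees = NULL, prevalence = NULL),
            class = "ego_network")
}
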