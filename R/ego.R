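#' Extract the ego network of a focal code
#'
#' The ego network of a code is the subgraph of the validated comorbidity
#' network consisting of the focal node and all nodes directly connected to
#' it. In `"induced"` mode (default) all validated edges among the members
#' are kept, including edges between two neighbors of the focal code; in
#' `"star"` mode only edges incident to the focal code are kept. A focal code
#' absent from the network yields the singleton ego network (the focal code
#' alone, no edges).
#'
#' @param network an `"svn"` object from [build_svn()].
#' @param focal normalized focal ICD code; default `"I67.1"` (unruptured
#'   intracranial aneurysm).
#' @param mode `"induced"` or `"star"`.
#' @return an `"ego_network"` object: list with `cohort_key`, `gender`,
#'   `decade`, `focal`, `mode`, `members` (focal first, then neighbors
#'   sorted), `edges` (validated edge rows), `degrees`, `prevalence`.
#' @export
ego_network <- function(network, focal = "I67.1", mode = c("induced", "star")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "svn"))
  if (!.is_normalized_icd(focal)) stop("focal is not a normalized ICD code: ", focal)
  e <- network$edges
  nb <- sort(unique(c(e$code_j[e$code_i == focal], e$code_i[e$code_j == focal])))
  members <- c(focal, nb)
  if (mode == "induced") {
    keep <- e$code_i %in% members & e$code_j %in% members
  } else {
    keep <- e$code_i == focal | e$code_j == focal
  }
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  degrees <- stats::setNames(integer(length(members)), members)
  if (nrow(edges) > 0L) {
    tab <- table(c(edges$code_i, edges$code_j))
    degrees[names(tab)] <- as.integer(tab)
  }
  prev <- network$prevalence[intersect(members, names(network$prevalence))]
  structure(list(cohort_key = network$cohort_key, gender = network$gender,
                 decade = network$decade, focal = focal, mode = mode,
                 members = members, edges = edges, degrees = degrees,
                 prevalence = prev),
            class = "ego_network")
}

#' @export
print.ego_network <- function(x, ...) {
  cat(sprintf("ego network of %s  [%s, %s mode]: %d neighbors, %d edges\n",
              x$focal, x$cohort_key, x$mode, length(x$members) - 1L, nrow(x$edges)))
  if (length(x$members) > 1L)
    cat("  neighbors:", paste(x$members[-1L], collapse = " "), "\n")
  invisible(x)
}

# half-up rounding to `digits` decimals (round() rounds half to even)
.round_half_up <- function(x, digits = 1L) floor(x * 10^digits + 0.5) / 10^digits

#' Percentage rule of the chapter summary table
#'
#' Converts a vector of per-chapter counts into row percentages: 100 times
#' the count over the row total, rounded half-up to one decimal — the
#' convention of the printed summary tables (e.g. 14 of 19 renders as 73.7).
#'
#' @param counts non-negative numeric vector (a table row for one gender).
#' @return numeric vector of percentages; all zero when the row total is 0.
#' @export
chapter_percentages <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(rep(0, length(counts)))
  .round_half_up(100 * counts / tot, 1L)
}

.summary_blocks_order <- c("E00-E99", "F00-F99", "G00-G99", "H00-H99",
                           "I00-I99", "J00-J99", "M00-M99", "Q00-Q99",
                           "R00-R99", "Z00-Z99", "other")

#' Chapter-stratified summary of ego networks across cohorts
#'
#' For a collection of ego networks sharing one focal code, counts the
#' non-focal members per ICD chapter block (E00-E99, F00-F99, G00-G99, merged
#' H00-H99, I00-I99, J00-J99, M00-M99, Q00-Q99, R00-R99, Z00-Z99, plus an
#' `other` block for remaining letters) in each (decade, gender) cell, with
#' percentages taken within each gender's row total.
#'
#' @param egos list of `"ego_network"` objects (typically one per cohort).
#' @return a `"chapter_summary"` object: data.frame with columns `decade`,
#'   `gender`, `block`, `count`, `pct`, `row_total`, one row per
#'   (decade, gender, block) with a nonzero row total; all-zero when `egos`
#'   is empty.
#' @export
summarize_by_chapter <- function(egos) {
  if (length(egos) == 0L) {
    out <- data.frame(decade = character(0), gender = character(0),
                      block = character(0), count = integer(0),
                      pct = numeric(0), row_total = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("chapter_summary", "data.frame")
    return(out)
  }
  focals <- unique(vapply(egos, `[[`, character(1), "focal"))
  if (length(focals) > 1L)
    stop("mixed focal codes in ego collection: ", paste(focals, collapse = ", "))
  rows <- list()
  for (eg in egos) {
    alters <- setdiff(eg$members, eg$focal)
    blk <- if (length(alters)) .summary_block(alters) else character(0)
    cnt <- table(factor(blk, levels = .summary_blocks_order))
    rows[[length(rows) + 1L]] <- data.frame(
      decade = decade_label(eg$decade[1L]), gender = eg$gender,
      block = .summary_blocks_order, count = as.integer(cnt),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  # cohorts are unique per (gender, decade); aggregate defensively anyway
  df <- stats::aggregate(count ~ decade + gender + block, df, sum)
  df <- df[order(match(df$decade, c(decade_label(seq(0, 80, 10)))),
                 df$gender, match(df$block, .summary_blocks_order)), ]
  totals <- stats::aggregate(count ~ decade + gender, df, sum)
  df$row_total <- totals$count[match(paste(df$decade, df$gender),
                                     paste(totals$decade, totals$gender))]
  df$pct <- 0
  for (k in unique(paste(df$decade, df$gender))) {
    i <- paste(df$decade, df$gender) == k
    df$pct[i] <- chapter_percentages(df$count[i])
  }
  df <- df[, c("decade", "gender", "block", "count", "pct", "row_total")]
  rownames(df) <- NULL
  class(df) <- c("chapter_summary", "data.frame")
  df
}

#' @export
print.chapter_summary <- function(x, ...) {
  if (nrow(x) == 0L) { cat("chapter summary: empty\n"); return(invisible(x)) }
  cat("ego-network members per ICD chapter block (count, row % per gender):\n")
  for (d in unique(x$decade)) {
    for (g in unique(x$gender[x$decade == d])) {
      i <- x$decade == d & x$gender == g & x$count > 0
      if (!any(i)) next
      cells <- sprintf("%s %d (%.1f)", sub("00-.*", "", x$block[i]),
                       x$count[i], x$pct[i])
      cat(sprintf("  %-6s %s  total %-3d %s\n", d, g,
                  x$row_total[i][1L], paste(cells, collapse = "  ")))
    }
  }
  invisible(x)
}

#' Presence of ego-network codes across cohorts
#'
#' Tabulates which non-focal codes appear in which cohort's ego network, and
#' reports the distinct-code counts per gender, the pooled distinct count,
#' and the total with multiplicity (code-cohort incidences) — the two ways of
#' counting "how many comorbidity codes" a stratified analysis selects.
#'
#' @param egos list of `"ego_network"` objects sharing one focal code.
#' @return an `"ego_presence"` object: list with `presence` (logical matrix,
#'   codes x cohorts), `distinct_by_gender` (named integer), `n_distinct`
#'   (pooled), `n_with_multiplicity`, `focal`.
#' @export
cross_cohort_presence <- function(egos) {
  focals <- unique(vapply(egos, `[[`, character(1), "focal"))
  if (length(focals) > 1L)
    stop("mixed focal codes in ego collection: ", paste(focals, collapse = ", "))
  keys <- vapply(egos, `[[`, character(1), "cohort_key")
  alters <- lapply(egos, function(e) setdiff(e$members, e$focal))
  codes <- sort(unique(unlist(alters, use.names = FALSE)))
  pres <- matrix(FALSE, nrow = length(codes), ncol = length(egos),
                 dimnames = list(codes, keys))
  for (k in seq_along(egos)) pres[alters[[k]], k] <- TRUE
  genders <- vapply(egos, `[[`, character(1), "gender")
  distinct_by_gender <- vapply(split(seq_along(egos), genders), function(i)
    length(unique(unlist(alters[i], use.names = FALSE))), integer(1))
  structure(list(presence = pres,
                 distinct_by_gender = distinct_by_gender,
                 n_distinct = length(codes),
                 n_with_multiplicity = sum(pres),
                 focal = if (length(focals)) focals else NA_character_),
            class = "ego_presence")
}

#' @export
print.ego_presence <- function(x, ...) {
  cat(sprintf("codes with validated links to %s: %d distinct (%s), %d code-cohort incidences\n",
              x$focal, x$n_distinct,
              paste(sprintf("%s: %d", names(x$distinct_by_gender),
                            x$distinct_by_gender), collapse = ", "),
              x$n_with_multiplicity))
  invisible(x)
}
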