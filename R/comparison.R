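#' Head-tail consistency rate between two rankings
#'
#' With `k = floor(0.2 n)`, counts the hospitals jointly placed in both
#' top-k sets (`x`) and both bottom-k sets (`y`) and returns
#' `(x + y) / (0.4 n)`. Membership is set-based: order within the head or
#' tail does not matter. Because `k` is the floor of `0.2 n` while the
#' denominator keeps the fractional `0.4 n`, the attainable maximum is
#' `2 k / (0.4 n)` (0.9375 at n = 16), reached exactly when the two
#' methodologies agree on both sets.
#'
#' @param ranking_a,ranking_b `ranking_table` objects over the same
#'   hospitals.
#' @return the consistency rate (a single number).
#' @export
head_tail_consistency <- function(ranking_a, ranking_b) {
  ha <- ranking_a$hospital_id; hb <- ranking_b$hospital_id
  if (!setequal(ha, hb) || length(ha) != length(hb))
    stop("rankings must cover the same hospital set")
  n <- length(ha)
  if (n < 5L) stop("head-tail consistency needs at least 5 hospitals")
  k <- floor(0.2 * n)
  # rows are sorted by rank (ties broken deterministically), so head/tail
  # sets are the first/last k rows
  x <- length(intersect(ha[seq_len(k)], hb[seq_len(k)]))
  y <- length(intersect(ha[seq.int(n - k + 1L, n)], hb[seq.int(n - k + 1L, n)]))
  (x + y) / (0.4 * n)
}

#' Standardise scores for the discrimination degree
#'
#' Maps a descending score list onto `[0, n]` by
#' `V_i = n * (1 - |V'_i - V'_1| / (V'_1 - V'_n))`, so the best score maps
#' to `n` and the worst to 0.
#'
#' @param scores numeric vector sorted in descending order, with
#'   `max > min`.
#' @return numeric vector of standardised values.
#' @export
standardize_scores <- function(scores) {
  n <- length(scores)
  if (n < 2L) stop("at least two scores are required")
  if (is.unsorted(rev(scores))) stop("scores must be sorted in descending order")
  if (scores[1] <= scores[n])
    stop("degenerate scores: all values equal, standardisation undefined")
  n * (1 - abs(scores - scores[1]) / (scores[1] - scores[n]))
}

#' Discrimination degree of a score list
#'
#' Measures how strongly a methodology's scores separate the ranked
#' hospitals, from the squared gaps between consecutive standardised
#' scores: with `g = sum_i (V_{i+1} - V_i)^2`, the statistic is
#' `(g + 1) / (2 n^2 - 2 n - 1)` (reading `"ratio"`, the default) or its
#' square root (reading `"sqrt"`). The two readings are monotonically
#' related, so they order methodologies identically; both are invariant
#' under positive affine transformation of the raw scores because the
#' standardisation removes location and scale. Scores are sorted descending
#' internally.
#'
#' @param scores numeric vector of raw per-hospital scores (any order).
#' @param reading `"ratio"` or `"sqrt"`; which algebraic grouping of the
#'   defining formula to use.
#' @return nonnegative scalar.
#' @export
discrimination_degree <- function(scores, reading = c("ratio", "sqrt")) {
  reading <- match.arg(reading)
  n <- length(scores)
  if (n < 2L) stop("at least two scores are required")
  v <- standardize_scores(sort(scores, decreasing = TRUE))
  d <- (sum(diff(v)^2) + 1) / (2 * n^2 - 2 * n - 1)
  if (reading == "sqrt") sqrt(d) else d
}

#' Pairwise comparison of evaluation methodologies
#'
#' For every pair of methodologies, computes the head-tail consistency rate
#' of their rankings and the absolute difference of their discrimination
#' degrees. The discrimination degree is a per-methodology scalar, so the
#' reported pairwise deltas are additively consistent (for methodologies
#' with ordered degrees, delta(a,c) = delta(a,b) + delta(b,c)).
#'
#' @param rankings named list of `ranking_table` objects (names are
#'   methodology labels; unnamed lists fall back to each table's own
#'   methodology attribute).
#' @param reading passed to [discrimination_degree()].
#' @return data frame of class `comparison_metrics` with columns
#'   `method_a`, `method_b`, `head_tail_rate`, `discrimination_delta`.
#' @export
compare_methodologies <- function(rankings, reading = c("ratio", "sqrt")) {
  reading <- match.arg(reading)
  if (length(rankings) < 2L) stop("at least two methodologies are required")
  if (is.null(names(rankings)) || any(!nzchar(names(rankings))))
    names(rankings) <- vapply(rankings, methodology, character(1))
  degrees <- vapply(rankings, function(r)
    discrimination_degree(r$score, reading), numeric(1))
  pairs <- utils::combn(names(rankings), 2L)
  out <- data.frame(
    method_a = pairs[1L, ], method_b = pairs[2L, ],
    head_tail_rate = apply(pairs, 2L, function(p)
      head_tail_consistency(rankings[[p[1L]]], rankings[[p[2L]]])),
    discrimination_delta = apply(pairs, 2L, function(p)
      abs(degrees[[p[1L]]] - degrees[[p[2L]]])),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "discrimination_degrees") <- degrees
  class(out) <- c("comparison_metrics", class(out))
  out
}

#' @export
print.comparison_metrics <- function(x, digits = 4, ...) {
  cat("<comparison_metrics>\n")
  y <- as.data.frame(x)
  y$head_tail_rate <- round(y$head_tail_rate, digits)
  y$discrimination_delta <- round(y$discrimination_delta, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
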