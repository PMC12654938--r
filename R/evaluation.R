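#' Scale a performance matrix by indicator weights
#'
#' Multiplies each column of the matrix by the corresponding indicator
#' weight, giving the weighted score matrix of one methodology.
#'
#' @param matrix a [performance_matrix()] (or plain numeric matrix with
#'   indicator column names).
#' @param weights a [weight_vector()] over the matrix's indicators.
#' @return numeric matrix of weighted cell scores.
#' @export
apply_weights <- function(matrix, weights) {
  x <- unclass(as.matrix(matrix))
  if (!identical(colnames(x), names(weights)))
    stop("weight vector indicator order must match matrix columns")
  sweep(x, 2L, unclass(weights), `*`)
}

#' Total weighted score per hospital
#'
#' Row sums of a weighted score matrix.
#'
#' @param weighted numeric matrix from [apply_weights()].
#' @return named numeric vector of per-hospital totals.
#' @export
total_scores <- function(weighted) rowSums(as.matrix(weighted))

#' Rank hospitals by total score
#'
#' Descending competition ranking: the best score gets rank 1, tied scores
#' share the smallest applicable rank, and output rows are sorted by rank
#' with ties broken lexicographically by hospital id so the table is
#' deterministic.
#'
#' @param scores named numeric vector of per-hospital total scores.
#' @param methodology label for the ranking (`"original"`, `"subjective"`,
#'   `"objective"`, `"combined"` or any custom label).
#' @return data frame of class `ranking_table` with columns `hospital_id`,
#'   `score`, `rank` and attribute `methodology`.
#' @export
rank_scores <- function(scores, methodology = "custom") {
  if (is.null(names(scores))) stop("scores must be named by hospital id")
  if (any(!is.finite(scores))) stop("scores must be finite")
  rk <- rank(-scores, ties.method = "min")
  ord <- order(rk, names(scores))
  out <- data.frame(hospital_id = names(scores)[ord],
                    score = as.numeric(scores)[ord],
                    rank = as.integer(rk)[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "methodology") <- methodology
  class(out) <- c("ranking_table", class(out))
  out
}

#' @export
print.ranking_table <- function(x, digits = 4, ...) {
  cat(sprintf("<ranking_table> methodology: %s\n", attr(x, "methodology")))
  y <- as.data.frame(x)
  y$score <- round(y$score, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Methodology label of a ranking table
#' @param ranking a `ranking_table`.
#' @return character scalar.
#' @export
methodology <- function(ranking) attr(ranking, "methodology")

#' Score and rank a performance matrix under one weighting methodology
#'
#' Convenience wrapper: weight the matrix, total the rows, rank the
#' hospitals.
#'
#' @inheritParams apply_weights
#' @param label methodology label for the resulting table.
#' @return a `ranking_table`.
#' @export
evaluate_methodology <- function(matrix, weights, label = provenance(weights)) {
  rank_scores(total_scores(apply_weights(matrix, weights)), label)
}

#' Unit weights reproducing the plain-sum "original" methodology
#'
#' The original review methodology simply sums awarded points; that is a
#' weighted evaluation with weight 1 on every indicator. The vector has
#' provenance `"custom"` and deliberately does not sum to 1.
#'
#' @param indicator_ids character vector of indicator ids.
#' @return a [weight_vector()] of ones.
#' @export
original_weights <- function(indicator_ids) {
  weight_vector(rep(1, length(indicator_ids)), indicator_ids, "custom")
}
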