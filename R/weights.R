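#' Construct a weight vector
#'
#' A set of `m` nonnegative indicator weights tagged with its provenance.
#' Weights of provenance `subjective`, `objective`, `combined` or `equal`
#' must sum to 1 (tolerance 1e-9); `custom` vectors (e.g. the unit weights
#' of the plain-sum "original" methodology) are exempt from the sum
#' constraint.
#'
#' @param weights numeric vector of nonnegative weights.
#' @param indicator_ids labels, defaulting to `names(weights)`.
#' @param provenance one of `"subjective"`, `"objective"`, `"combined"`,
#'   `"equal"`, `"custom"`.
#' @return a named numeric vector of class `weight_vector`.
#' @export
weight_vector <- function(weights, indicator_ids = names(weights),
                          provenance = c("subjective", "objective",
                                         "combined", "equal", "custom")) {
  provenance <- match.arg(provenance)
  if (is.null(indicator_ids)) stop("indicator ids are required")
  stopifnot(is.numeric(weights), length(weights) == length(indicator_ids))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (provenance != "custom" && abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights), digits = 12), ")")
  structure(as.numeric(weights), names = indicator_ids,
            provenance = provenance, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat(sprintf("<weight_vector> provenance: %s\n", attr(x, "provenance")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Provenance tag of a weight vector
#' @param w a [weight_vector()].
#' @return character scalar.
#' @export
provenance <- function(w) attr(w, "provenance")

#' Subjective weights from expert-assigned indicator scores
#'
#' Each indicator's weight is its expert-assigned score divided by the sum
#' of all assigned scores.
#'
#' @param scheme list of [indicator()] objects.
#' @return a [weight_vector()] with provenance `"subjective"`.
#' @examples
#' subjective_weights(default_scheme())["X1"]  # 35/112 = 0.3125
#' @export
subjective_weights <- function(scheme) {
  if (!length(scheme)) stop("empty scheme")
  s <- assigned_scores(scheme)
  if (any(s <= 0)) stop("assigned scores must be positive")
  weight_vector(s / sum(s), names(s), "subjective")
}

#' Attribute-aware min-max normalisation of a performance matrix
#'
#' Standardises each indicator column to `[0, 1]` according to its
#' attribute: positive columns by `(x - min) / (max - min)`, negative
#' columns by `(max - x) / (max - min)`, and moderate columns by
#' `1 - |x - mean| / max |x - mean|` (closest to the column mean is best).
#' A constant column, where every rule divides by zero, is set to the
#' midpoint 0.5 with a warning; its entropy weight downstream is zero
#' regardless of the value chosen.
#'
#' @param matrix a [performance_matrix()] (or plain numeric matrix).
#' @param attributes character vector of per-column attributes
#'   (`"positive"`/`"negative"`/`"moderate"`), or a scheme list from which
#'   they are taken.
#' @return a numeric matrix of class `normalized_matrix` with attribute
#'   `shifted = FALSE`.
#' @export
normalize_matrix <- function(matrix, attributes) {
  x <- unclass(as.matrix(matrix))
  if (nrow(x) < 2L) stop("normalisation needs at least two hospitals")
  if (is.list(attributes)) attributes <- scheme_attributes(attributes)
  if (length(attributes) != ncol(x))
    stop("one attribute per indicator column is required")
  bad <- setdiff(attributes, c("positive", "negative", "moderate"))
  if (length(bad)) stop("unknown attribute(s): ", paste(bad, collapse = ", "))
  y <- x
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    rng <- max(xj) - min(xj)
    yj <- switch(attributes[j],
      positive = if (rng > 0) (xj - min(xj)) / rng else NULL,
      negative = if (rng > 0) (max(xj) - xj) / rng else NULL,
      moderate = {
        dev <- abs(xj - mean(xj))
        if (max(dev) > 0) 1 - dev / max(dev) else NULL
      })
    if (is.null(yj)) {
      warning("constant column ", colnames(x)[j] %||% j,
              ": normalised to midpoint 0.5", call. = FALSE)
      yj <- rep(0.5, length(xj))
    }
    y[, j] <- yj
  }
  structure(y, shifted = FALSE, class = c("normalized_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a normalised matrix away from zero
#'
#' Adds 0.001 to every cell so that zero normalised values do not zero out
#' the entropy proportions.
#'
#' @param matrix a `normalized_matrix` with values in `[0, 1]`.
#' @return the shifted matrix (`shifted = TRUE`), values in `[0.001, 1.001]`.
#' @export
shift_matrix <- function(matrix) {
  x <- as.matrix(matrix)
  if (isTRUE(attr(matrix, "shifted")))
    stop("matrix is already shifted")
  if (any(x < 0) || any(x > 1)) stop("expected normalised values in [0, 1]")
  structure(unclass(x) + 0.001, shifted = TRUE,
            class = c("normalized_matrix", "matrix", "array"))
}

#' Objective weights by the entropy weight method
#'
#' From a shifted normalised matrix, computes per-column proportions
#' `P_ij = y_ij / sum_i y_ij`, information entropy
#' `E_j = -(1/ln n) * sum_i P_ij ln P_ij`, and objective weights
#' `(1 - E_j) / sum_k (1 - E_k)`. Indicators whose values vary more across
#' hospitals carry lower entropy and receive larger weights; a column that
#' was constant before the shift has `E_j = 1` and weight 0.
#'
#' @param matrix a shifted `normalized_matrix` (see [shift_matrix()]), or
#'   any positive matrix.
#' @return an object of class `entropy_result`: a list with elements
#'   `proportions` (n x m), `entropies` (length m) and `weights`
#'   (a [weight_vector()], provenance `"objective"`).
#' @export
entropy_weights <- function(matrix) {
  y <- unclass(as.matrix(matrix))
  n <- nrow(y)
  if (n < 2L) stop("entropy weighting needs at least two hospitals")
  if (any(y <= 0))
    stop("all cells must be positive; apply shift_matrix() first")
  p <- sweep(y, 2L, colSums(y), `/`)
  # 0 * log(0) := 0 guard kept for custom unshifted inputs
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(n)
  d <- 1 - e
  if (sum(d) <= 0)
    stop("all indicator columns are constant (sum of 1 - E_j is zero); ",
         "entropy weights are undefined -- consider equal weights")
  w <- weight_vector(d / sum(d), colnames(y), "objective")
  structure(list(proportions = p, entropies = stats::setNames(e, colnames(y)),
                 weights = w),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, digits = 4, ...) {
  cat("<entropy_result>\n  entropies:\n")
  print(round(x$entropies, digits))
  cat("  objective weights:\n")
  print(round(unclass(x$weights), digits))
  invisible(x)
}

#' Combine weight vectors by multiplicative synthesis with normalisation
#'
#' The combined weight of each indicator is the product of its weights
#' under the supplied methodologies, renormalised to sum 1. Multiplicative
#' synthesis widens the spread between indicators that the component
#' methods agree are important and those they agree are not, while
#' normalisation keeps the result interpretable as a weight vector.
#'
#' @param ... [weight_vector()] objects (or a single list of them), all over
#'   the same indicators in the same order.
#' @return a [weight_vector()] with provenance `"combined"`.
#' @export
combine_msn <- function(...) {
  vs <- list(...)
  if (length(vs) == 1L && is.list(vs[[1]]) && !inherits(vs[[1]], "weight_vector"))
    vs <- vs[[1]]
  if (!length(vs)) stop("at least one weight vector is required")
  ids <- names(vs[[1]])
  for (v in vs) {
    if (!identical(names(v), ids))
      stop("all weight vectors must share the same indicator order")
  }
  prod <- Reduce(`*`, lapply(vs, unclass))
  if (sum(prod) <= 0)
    stop("all per-indicator weight products are zero; combination is degenerate")
  weight_vector(prod / sum(prod), ids, "combined")
}

#' Per-indicator percentage change between two weight vectors
#'
#' Signed percentage change of each indicator's weight from `baseline` to
#' `comparison`: `(comparison - baseline) / baseline * 100`. Indicators with
#' zero baseline weight get `NA` and are flagged.
#'
#' @param baseline,comparison [weight_vector()] objects over the same
#'   indicators in the same order.
#' @return data frame with columns `indicator_id`, `baseline`, `comparison`,
#'   `change_pct`, `undefined`.
#' @examples
#' sub <- weight_vector(c(X1 = 0.3125, X2 = 0.6875), provenance = "custom")
#' obj <- weight_vector(c(X1 = 0.0236, X2 = 0.9764), provenance = "custom")
#' weight_change(sub, obj)$change_pct[1]  # -92.45
#' @export
weight_change <- function(baseline, comparison) {
  if (!identical(names(baseline), names(comparison)))
    stop("weight vectors must share the same indicator order")
  b <- unclass(baseline); cmp <- unclass(comparison)
  undef <- b == 0
  if (any(undef))
    warning("zero baseline weight for: ",
            paste(names(baseline)[undef], collapse = ", "), call. = FALSE)
  chg <- ifelse(undef, NA_real_, (cmp - b) / b * 100)
  data.frame(indicator_id = names(baseline), baseline = as.numeric(b),
             comparison = as.numeric(cmp), change_pct = as.numeric(chg),
             undefined = undef, row.names = NULL, stringsAsFactors = FALSE)
}
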