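#' Construct a hospitals-by-indicators performance matrix
#'
#' The central data container: `n` hospitals by `m` indicators of awarded
#' points, with row labels (hospital codes) and column labels (indicator
#' ids). When a scheme is supplied the columns are reordered to scheme order
#' and every cell is validated against `[0, max_points]` for its indicator;
#' a warning is raised for cells that are not on an indicator's band-point
#' lattice (legal for raw-rate workflows, suspicious for awarded points).
#'
#' @param points numeric matrix or data frame of awarded points.
#' @param hospital_ids,indicator_ids optional labels; default to the
#'   dimnames of `points`.
#' @param scheme optional list of [indicator()] objects to validate against.
#' @return a numeric matrix of class `performance_matrix`.
#' @export
performance_matrix <- function(points, hospital_ids = rownames(points),
                               indicator_ids = colnames(points),
                               scheme = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (is.null(hospital_ids) || is.null(indicator_ids))
    stop("hospital and indicator labels are required")
  if (anyDuplicated(hospital_ids)) stop("duplicated hospital ids")
  if (anyDuplicated(indicator_ids)) stop("duplicated indicator ids")
  dimnames(points) <- list(hospital_ids, indicator_ids)
  if (anyNA(points))
    stop("performance matrix has missing cells: every hospital must supply ",
         "every indicator")
  if (nrow(points) < 2L)
    stop("at least two hospitals are required (n >= 2)")
  if (ncol(points) < 1L) stop("at least one indicator is required")
  if (!is.null(scheme)) {
    ids <- scheme_ids(scheme)
    missing_cols <- setdiff(ids, colnames(points))
    if (length(missing_cols))
      stop("matrix lacks indicator column(s): ", paste(missing_cols, collapse = ", "))
    extra <- setdiff(colnames(points), ids)
    if (length(extra))
      stop("unknown indicator column(s): ", paste(extra, collapse = ", "))
    points <- points[, ids, drop = FALSE]
    caps <- max_points(scheme)
    for (j in seq_along(ids)) {
      xj <- points[, j]
      if (any(xj < 0) || any(xj > caps[j]))
        stop("points for ", ids[j], " outside [0, ", caps[j], "]")
      lattice <- band_points(scheme[[j]])
      off <- !vapply(xj, function(v) any(abs(v - lattice) < 1e-9), logical(1))
      if (any(off))
        warning("indicator ", ids[j], " holds value(s) off its band-point ",
                "lattice (", paste(unique(xj[off]), collapse = ", "), ")",
                call. = FALSE)
    }
  }
  structure(points, class = c("performance_matrix", "matrix", "array"))
}

#' @export
print.performance_matrix <- function(x, ...) {
  cat(sprintf("<performance_matrix> %d hospitals x %d indicators\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Assemble a performance matrix from per-hospital records
#'
#' Accepts either a wide data frame whose first column holds hospital ids
#' and remaining columns one indicator each, or a named list of named
#' per-hospital point vectors. Completeness is enforced: a missing
#' hospital/indicator cell is an error, as is a value above the indicator's
#' maximum points.
#'
#' @param records wide data frame (first column = hospital id) or named
#'   list of named numeric vectors.
#' @param scheme list of [indicator()] objects defining column order and
#'   point caps.
#' @return a [performance_matrix()].
#' @export
build_matrix <- function(records, scheme) {
  ids <- scheme_ids(scheme)
  if (is.data.frame(records)) {
    hosp <- as.character(records[[1L]])
    mat <- as.matrix(records[, -1L, drop = FALSE])
    rownames(mat) <- hosp
  } else if (is.list(records)) {
    hosp <- names(records)
    if (is.null(hosp)) stop("record list must be named by hospital id")
    mat <- do.call(rbind, lapply(records, function(r) {
      miss <- setdiff(ids, names(r))
      if (length(miss))
        stop("missing indicator value(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      unlist(r)[ids]
    }))
    rownames(mat) <- hosp
    colnames(mat) <- ids
  } else stop("'records' must be a data frame or a named list")
  if (!is.numeric(mat)) stop("non-numeric point values in records")
  performance_matrix(mat, scheme = scheme)
}
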