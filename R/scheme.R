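#' Define one scoring band of an evaluation indicator
#'
#' A band maps an interval of performance rates to an awarded point value.
#' Bounds are either absolute fractions (e.g. 0.95 for 95%) or, for bands
#' whose thresholds are expressed relative to an external reference standard,
#' multipliers of that standard (mode `"relative"`; a lower bound of 0.9
#' means 90% of the standard). Intervals are left-closed and right-open
#' unless the closure flags say otherwise; `-Inf`/`Inf` bounds give
#' open-ended or catch-all bands.
#'
#' @param lower,upper numeric bounds of the band (fractions, or multipliers
#'   of the reference standard when `mode = "relative"`).
#' @param points nonnegative integer awarded when a rate falls in the band.
#' @param mode `"absolute"` or `"relative"` (relative to the indicator's
#'   reference standard).
#' @param lower_closed,upper_closed logical; is the bound included?
#' @return a one-row data frame of class `scoring_band`.
#' @examples
#' scoring_band(0.95, 1, 30)
#' scoring_band(0.9, 1, 9, mode = "relative")
#' @export
scoring_band <- function(lower, upper, points,
                         mode = c("absolute", "relative"),
                         lower_closed = TRUE, upper_closed = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, length(points) == 1L)
  if (points < 0) stop("band 'points' must be nonnegative")
  if (is.finite(lower) && is.finite(upper) && lower > upper)
    stop("band lower bound exceeds upper bound")
  band <- data.frame(lower = as.numeric(lower), upper = as.numeric(upper),
                     points = as.numeric(points), mode = mode,
                     lower_closed = lower_closed, upper_closed = upper_closed,
                     stringsAsFactors = FALSE)
  class(band) <- c("scoring_band", class(band))
  band
}

#' Define an evaluation indicator
#'
#' An indicator couples an attribute direction (positive: higher is better;
#' moderate: closest to the panel mean is best; negative: lower is better),
#' the expert-assigned score that drives subjective weighting, and an ordered
#' list of scoring bands that convert a raw performance rate into awarded
#' points. Bands are matched in listed order; the first matching band wins,
#' which is also the tie rule where printed criteria overlap at a boundary.
#'
#' @param id short label, e.g. `"X1"`.
#' @param name human-readable indicator name.
#' @param attribute `"positive"`, `"moderate"` or `"negative"`.
#' @param assigned_score positive expert-assigned score (the basis of
#'   subjective weights).
#' @param bands list of [scoring_band()] rows, in matching order.
#' @param max_points maximum awardable points; defaults to the largest band
#'   points and must equal it.
#' @param reference_standard optional external standard (a fraction) that
#'   relative bands are resolved against; left `NULL` when not configured.
#' @return an object of class `indicator`.
#' @export
indicator <- function(id, name, attribute = c("positive", "moderate", "negative"),
                      assigned_score, bands, max_points = NULL,
                      reference_standard = NULL) {
  attribute <- match.arg(attribute)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(assigned_score) || length(assigned_score) != 1L ||
      assigned_score <= 0)
    stop("'assigned_score' must be a single positive number")
  if (!length(bands)) stop("an indicator needs at least one scoring band")
  bands <- do.call(rbind, lapply(bands, function(b) {
    if (!inherits(b, "scoring_band")) stop("'bands' must be scoring_band objects")
    as.data.frame(b)
  }))
  top <- max(bands$points)
  if (is.null(max_points)) max_points <- top
  if (max_points != top)
    stop("'max_points' must equal the maximum band points (", top, ")")
  if (!is.null(reference_standard)) {
    stopifnot(is.numeric(reference_standard), length(reference_standard) == 1L,
              reference_standard > 0)
  }
  structure(
    list(id = id, name = name, attribute = attribute,
         assigned_score = as.numeric(assigned_score),
         max_points = as.numeric(max_points), bands = bands,
         reference_standard = reference_standard),
    class = "indicator")
}

#' @export
print.indicator <- function(x, ...) {
  cat(sprintf("<indicator> %s: %s [%s, score %g, max %g points, %d bands]\n",
              x$id, x$name, x$attribute, x$assigned_score, x$max_points,
              nrow(x$bands)))
  invisible(x)
}

#' Attach reference standards to a scheme
#'
#' Reference standards (national or provincial target values) are external
#' configuration, not part of the published scoring table, so the default
#' scheme ships without them. This helper fills them in before rate scoring.
#'
#' @param scheme a list of [indicator()] objects.
#' @param standards named numeric vector, names matching indicator ids.
#' @return the scheme with `reference_standard` set where supplied.
#' @export
set_reference_standards <- function(scheme, standards) {
  stopifnot(is.numeric(standards), !is.null(names(standards)))
  ids <- scheme_ids(scheme)
  unknown <- setdiff(names(standards), ids)
  if (length(unknown))
    stop("unknown indicator id(s) in standards: ", paste(unknown, collapse = ", "))
  for (nm in names(standards)) {
    i <- match(nm, ids)
    scheme[[i]]$reference_standard <- unname(standards[[nm]])
  }
  scheme
}

#' Indicator ids of a scheme
#' @param scheme a list of [indicator()] objects.
#' @return character vector of ids, in scheme order.
#' @export
scheme_ids <- function(scheme) vapply(scheme, `[[`, character(1), "id")

#' Indicator attributes of a scheme
#' @inheritParams scheme_ids
#' @return named character vector of attributes.
#' @export
scheme_attributes <- function(scheme) {
  out <- vapply(scheme, `[[`, character(1), "attribute")
  names(out) <- scheme_ids(scheme)
  out
}

#' Expert-assigned scores of a scheme
#' @inheritParams scheme_ids
#' @return named numeric vector of assigned scores.
#' @export
assigned_scores <- function(scheme) {
  out <- vapply(scheme, `[[`, numeric(1), "assigned_score")
  names(out) <- scheme_ids(scheme)
  out
}

#' Maximum awardable points of each indicator
#' @inheritParams scheme_ids
#' @return named numeric vector of band maxima.
#' @export
max_points <- function(scheme) {
  out <- vapply(scheme, `[[`, numeric(1), "max_points")
  names(out) <- scheme_ids(scheme)
  out
}

# Resolve a band table against a reference standard; errors if a relative
# band has no standard to resolve against.
resolve_bands <- function(ind) {
  bands <- ind$bands
  rel <- bands$mode == "relative"
  if (any(rel)) {
    if (is.null(ind$reference_standard))
      stop("indicator ", ind$id, " has relative scoring bands but no ",
           "reference_standard configured", call. = FALSE)
    bands$lower[rel] <- bands$lower[rel] * ind$reference_standard
    bands$upper[rel] <- bands$upper[rel] * ind$reference_standard
  }
  bands
}

#' Convert a raw performance rate into awarded points
#'
#' Matches `rate` against the indicator's scoring bands in listed order and
#' returns the points of the first band whose interval contains it. Bands in
#' relative mode have their thresholds resolved as multiples of the
#' indicator's `reference_standard` first.
#'
#' @param rate nonnegative performance rate expressed as a fraction
#'   (1.00 = 100%). Vectorised.
#' @param indicator an [indicator()] object.
#' @return numeric vector of awarded points.
#' @examples
#' sch <- default_scheme()
#' score_indicator(c(1, 0.97, 0), sch[[1]])  # 35, 30, 0
#' @export
score_indicator <- function(rate, indicator) {
  stopifnot(inherits(indicator, "indicator"), is.numeric(rate))
  if (any(rate < 0 & indicator$attribute != "moderate"))
    stop("rates must be nonnegative")
  bands <- resolve_bands(indicator)
  vapply(rate, function(p) {
    ok_lo <- ifelse(bands$lower_closed, p >= bands$lower, p > bands$lower)
    ok_hi <- ifelse(bands$upper_closed, p <= bands$upper, p < bands$upper)
    hit <- which(ok_lo & ok_hi)
    if (!length(hit))
      stop("rate ", p, " matches no scoring band of indicator ",
           indicator$id, call. = FALSE)
    bands$points[hit[1L]]
  }, numeric(1))
}

# Band builders for the two recurring layouts of the published table:
# absolute percentage thresholds, and thresholds at decreasing multiples of
# an external standard with a catch-all zero band.
relative_ladder <- function(multipliers, points) {
  stopifnot(length(multipliers) == length(points))
  bands <- vector("list", length(multipliers) + 1L)
  upper <- Inf
  for (k in seq_along(multipliers)) {
    bands[[k]] <- scoring_band(multipliers[k], upper, points[k], mode = "relative")
    upper <- multipliers[k]
  }
  bands[[length(bands)]] <- scoring_band(-Inf, Inf, 0)  # "Others"
  bands
}

#' The default eleven-indicator evaluation scheme
#'
#' The published annual quality-control scheme for stroke-screening base
#' hospitals: eleven indicators (X1--X11) with expert-assigned scores
#' totalling 112, each scored by threshold bands on a performance rate.
#' Six indicators are positive-attribute and five moderate-attribute.
#' Indicators whose bands reference national or provincial standards ship
#' with `reference_standard` unset; supply the configured values through
#' [set_reference_standards()] before scoring raw rates.
#'
#' @return list of eleven [indicator()] objects, in X1..X11 order.
#' @examples
#' sch <- default_scheme()
#' sum(assigned_scores(sch))  # 112
#' @export
default_scheme <- function() {
  list(
    indicator("X1", "Task Completion Rate", "positive", 35, list(
      scoring_band(1.00, Inf, 35),
      scoring_band(0.95, 1.00, 30),
      scoring_band(0.90, 0.95, 25),
      scoring_band(0.85, 0.90, 20),
      # 0 itself scores 0 (dedicated final band), so the 15-point band is
      # open at its lower end
      scoring_band(0, 0.85, 15, lower_closed = FALSE),
      scoring_band(0, 0, 0, upper_closed = TRUE))),
    indicator("X2", "Risk Factor Control Rate", "positive", 12,
              relative_ladder(c(1.0, 0.9, 0.8, 0.7), c(12, 9, 6, 3))),
    indicator("X3", "Stroke High-Risk Detection Rate", "moderate", 6, list(
      scoring_band(0.26, Inf, 3, lower_closed = FALSE),
      scoring_band(0.20, 0.26, 6, upper_closed = TRUE),
      scoring_band(0.15, 0.20, 4),
      scoring_band(0.10, 0.15, 3),
      scoring_band(-Inf, 0.10, 0))),
    indicator("X4", "Hypertension Awareness Rate", "positive", 6,
              relative_ladder(c(1.0, 0.9, 0.8, 0.7, 0.6), c(6, 4, 3, 2, 1))),
    indicator("X5", "Hypertension Detection Rate", "moderate", 3,
              relative_ladder(c(1.0, 0.9, 0.8), c(3, 2, 1))),
    indicator("X6", "Diabetes Detection Rate", "moderate", 3,
              relative_ladder(c(1.0, 0.9, 0.8), c(3, 2, 1))),
    indicator("X7", "Dyslipidemia Detection Rate", "moderate", 3,
              relative_ladder(c(1.0, 0.9, 0.8), c(3, 2, 1))),
    indicator("X8", "Stroke High-Risk Intervention Rate", "positive", 8,
              relative_ladder(c(1.0, 0.9, 0.8, 0.7), c(8, 6, 3, 1))),
    indicator("X9", "Intervention Rate", "positive", 12, list(
      scoring_band(0.85, Inf, 12),
      scoring_band(0.70, 0.85, 10),
      scoring_band(0.50, 0.70, 7),
      scoring_band(0.30, 0.50, 5),
      scoring_band(-Inf, 0.30, 0))),
    indicator("X10", "Follow-up Completion Rate", "positive", 12, list(
      scoring_band(1.00, Inf, 12),
      scoring_band(0.85, 1.00, 10),
      scoring_band(0.70, 0.85, 7),
      scoring_band(0.50, 0.70, 5),
      scoring_band(-Inf, 0.50, 0))),
    indicator("X11", "Age Deviation Degree", "moderate", 12,
              relative_ladder(c(1.0, 0.9, 0.8, 0.7), c(12, 9, 6, 3)))
  )
}

# Admissible awarded point values of an indicator (the band-point lattice).
band_points <- function(ind) sort(unique(ind$bands$points))
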