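#' Configuration for the synthetic hospital-panel generator
#'
#' Describes a synthetic panel of banded point scores shaped like an annual
#' base-hospital review: `n_hospitals` sites scored on every indicator of a
#' scheme. Dispersion is controlled per indicator: `"none"` pins a column
#' at its maximum (a fully saturated indicator), `"low"` is near-constant
#' -- the top band with an occasional drop to the band below (the
#' compliance ceiling typical of process-oriented indicators such as task
#' completion), `"high"` spreads scores uniformly across all bands. `ceiling_fraction` additionally pins
#' that share of hospitals at maximum points on every indicator.
#'
#' @param n_hospitals number of sites (default 16, the panel size of a
#'   provincial review year).
#' @param scheme list of [indicator()] objects (default [default_scheme()]).
#' @param spread single dispersion level or named per-indicator vector with
#'   values in `"none"`, `"low"`, `"high"`.
#' @param ceiling_fraction fraction of hospitals pinned at maximum points
#'   per indicator (default 0).
#' @param seed integer seed; the same configuration and seed always yield
#'   the identical matrix.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_hospitals = 16, scheme = default_scheme(),
                             spread = "high", ceiling_fraction = 0,
                             seed = 1L) {
  stopifnot(n_hospitals >= 2, ceiling_fraction >= 0, ceiling_fraction <= 1)
  ids <- scheme_ids(scheme)
  if (length(spread) == 1L && is.null(names(spread)))
    spread <- stats::setNames(rep(spread, length(ids)), ids)
  if (!all(names(spread) %in% ids) || !all(ids %in% names(spread)))
    stop("'spread' must name every indicator of the scheme")
  bad <- setdiff(spread, c("none", "low", "high"))
  if (length(bad)) stop("unknown spread level(s): ", paste(bad, collapse = ", "))
  structure(list(n_hospitals = as.integer(n_hospitals), scheme = scheme,
                 spread = spread[ids], ceiling_fraction = ceiling_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic performance matrix
#'
#' Samples every cell from the indicator's admissible band-point lattice
#' under the dispersion levels of the configuration. Each indicator column
#' uses its own seed stream derived from the configuration seed, so
#' changing one column's dispersion leaves the draws of the other columns
#' untouched. The caller's RNG state is preserved.
#'
#' @param config a [generator_config()].
#' @return a [performance_matrix()] carrying the configuration as
#'   attribute `"generator"`.
#' @examples
#' m <- generate_matrix(generator_config(seed = 42))
#' dim(m)  # 16 x 11
#' @export
generate_matrix <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  n <- config$n_hospitals
  scheme <- config$scheme
  ids <- scheme_ids(scheme)
  hosp <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("H%03d", seq_len(n))
  mat <- matrix(NA_real_, n, length(ids), dimnames = list(hosp, ids))
  for (j in seq_along(ids)) {
    lattice <- band_points(scheme[[j]])
    top <- max(lattice)
    set.seed((config$seed + 7919L * j) %% .Machine$integer.max)
    col <- switch(config$spread[[ids[j]]],
      none = rep(top, n),
      low = {
        # near-constant: mostly the top band with an occasional drop to the
        # band below; a two-point column with substantial mass at both
        # values would be rescaled to {0, 1} by min-max normalisation and
        # no longer read as low-dispersion downstream
        vals <- utils::tail(lattice, 2L)
        if (length(vals) == 1L) rep(vals, n)
        else sample(vals, n, replace = TRUE, prob = c(0.1, 0.9))
      },
      high = sample(lattice, n, replace = TRUE))
    n_ceiling <- round(config$ceiling_fraction * n)
    if (n_ceiling > 0) col[sample.int(n, n_ceiling)] <- top
    mat[, j] <- col
  }
  out <- performance_matrix(mat, scheme = scheme)
  attr(out, "generator") <- config
  out
}

#' Published reference tables of the sixteen-hospital Sichuan panel
#'
#' The printed results of the 2024 provincial stroke-screening review of
#' sixteen base hospitals, transcribed as fixture objects: the expert
#' assigned scores, the published subjective, objective and combined
#' weight vectors (4 decimals as printed), and the four score/rank columns
#' of the published results table. These are inputs for regression checks
#' and for reproducing the published inter-methodology comparisons; the
#' underlying raw data matrix is not part of the publication and is not
#' included.
#'
#' @return list with elements `assigned_scores` (named numeric),
#'   `subjective_weights`, `objective_weights`, `combined_weights`
#'   ([weight_vector()] objects) and `rankings` (named list of four
#'   `ranking_table` objects: original, subjective, objective, combined).
#' @export
reference_tables <- function() {
  subj <- c(X1 = 0.3125, X2 = 0.1071, X3 = 0.0536, X4 = 0.0536,
            X5 = 0.0268, X6 = 0.0268, X7 = 0.0268, X8 = 0.0714,
            X9 = 0.1071, X10 = 0.1071, X11 = 0.1071)
  obj <- c(X1 = 0.0236, X2 = 0.1527, X3 = 0.1176, X4 = 0.0518,
           X5 = 0.0878, X6 = 0.1108, X7 = 0.0936, X8 = 0.1485,
           X9 = 0.1594, X10 = 0.0286, X11 = 0.0256)
  comb <- c(X1 = 0.0995, X2 = 0.2207, X3 = 0.0850, X4 = 0.0375,
            X5 = 0.0318, X6 = 0.0401, X7 = 0.0339, X8 = 0.1430,
            X9 = 0.2303, X10 = 0.0413, X11 = 0.0370)
  scores <- list(
    original = c(A = 99.0000, B = 96.2500, C = 91.0000, D = 90.0000,
                 E = 87.0000, F = 86.5000, G = 85.7500, H = 84.0000,
                 I = 79.7500, J = 76.0000, K = 67.4000, L = 66.8000,
                 M = 63.2000, N = 62.8000, O = 56.8000, P = 56.0000),
    subjective = c(A = 16.3824, B = 15.9006, G = 15.4345, F = 15.3810,
                   C = 15.2580, E = 15.2578, I = 15.1131, H = 15.0704,
                   D = 14.6593, L = 13.2996, K = 13.2569, M = 13.2085,
                   N = 12.9249, O = 12.6569, P = 12.4106, J = 12.3149),
    objective = c(D = 7.6998, B = 7.6021, A = 7.3770, C = 6.7346,
                  H = 6.5609, F = 6.4842, E = 6.3922, G = 6.3314,
                  I = 6.2837, J = 6.2666, K = 2.7206, L = 2.5531,
                  N = 2.4553, P = 2.1406, M = 2.1389, O = 2.0551),
    combined = c(A = 11.4458, B = 11.2582, D = 11.0085, I = 10.3172,
                 E = 9.9964, G = 9.9930, H = 9.9650, F = 9.8955,
                 C = 9.8600, J = 9.1810, K = 4.9734, L = 4.8145,
                 N = 4.7988, M = 4.6854, O = 4.5789, P = 4.5001))
  list(
    assigned_scores = assigned_scores(default_scheme()),
    subjective_weights = weight_vector(subj / sum(subj), names(subj), "subjective"),
    objective_weights = weight_vector(obj / sum(obj), names(obj), "objective"),
    combined_weights = weight_vector(comb / sum(comb), names(comb), "combined"),
    weights_printed = list(subjective = subj, objective = obj, combined = comb),
    rankings = mapply(rank_scores, scores, names(scores), SIMPLIFY = FALSE))
}
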