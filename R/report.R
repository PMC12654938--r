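#' Run the full combined-weight evaluation pipeline
#'
#' Executes the whole methodology on one performance matrix: subjective
#' weights from the scheme's assigned scores, objective weights by the
#' entropy weight method on the matrix (attribute-aware normalisation,
#' 0.001 shift, entropy), combined weights by multiplicative synthesis
#' with normalisation, total weighted scores and rankings under the
#' original (plain-sum), subjective, objective and combined methodologies,
#' the subjective-to-objective weight-change table, and all pairwise
#' methodology comparisons. The run is deterministic given its inputs.
#'
#' Degenerate inputs degrade gracefully rather than aborting: if every
#' indicator column is constant the entropy weights are undefined and the
#' objective slot falls back to equal weights with a warning, and if a
#' methodology's scores are all tied its discrimination degree is
#' undefined, so the pairwise comparison table is omitted with a warning.
#'
#' @param matrix a [performance_matrix()] over the scheme's indicators.
#' @param scheme list of [indicator()] objects (default [default_scheme()]).
#' @param reading discrimination-degree reading, see
#'   [discrimination_degree()].
#' @return an object of class `evaluation_report`: a list with elements
#'   `scheme`, `weights` (named list of four weight vectors),
#'   `weight_changes`, `rankings` (named list of four ranking tables),
#'   `comparisons`, `provenance`.
#' @export
run_evaluation <- function(matrix, scheme = default_scheme(),
                           reading = c("ratio", "sqrt")) {
  reading <- match.arg(reading)
  matrix <- performance_matrix(as.matrix(matrix), scheme = scheme)
  w_sub <- subjective_weights(scheme)
  norm <- normalize_matrix(matrix, scheme_attributes(scheme))
  ent <- tryCatch(entropy_weights(shift_matrix(norm)), error = function(e) {
    warning("objective weighting degraded to equal weights: ",
            conditionMessage(e), call. = FALSE)
    m <- ncol(matrix)
    list(proportions = NULL, entropies = NULL,
         weights = weight_vector(rep(1 / m, m), colnames(matrix), "equal"))
  })
  w_obj <- ent$weights
  w_comb <- combine_msn(w_sub, w_obj)
  w_orig <- original_weights(scheme_ids(scheme))
  weights <- list(original = w_orig, subjective = w_sub,
                  objective = w_obj, combined = w_comb)
  rankings <- lapply(stats::setNames(nm = names(weights)), function(meth)
    evaluate_methodology(matrix, weights[[meth]], meth))
  comparisons <- tryCatch(compare_methodologies(rankings, reading),
                          error = function(e) {
    warning("methodology comparison unavailable: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  structure(
    list(scheme = scheme,
         matrix = matrix,
         weights = weights,
         entropy = ent,
         weight_changes = weight_change(w_sub, w_obj),
         rankings = rankings,
         comparisons = comparisons,
         provenance = list(
           n_hospitals = nrow(matrix), n_indicators = ncol(matrix),
           reading = reading,
           tool_version = as.character(utils::packageVersion("screeneval")),
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  p <- x$provenance
  cat(sprintf("<evaluation_report> %d hospitals x %d indicators\n",
              p$n_hospitals, p$n_indicators))
  wt <- round(do.call(cbind, lapply(x$weights, unclass)), digits)
  cat("\nWeights by methodology:\n")
  print(wt)
  cat("\nTop 3 hospitals by methodology:\n")
  for (meth in names(x$rankings)) {
    top <- utils::head(x$rankings[[meth]], 3L)
    cat(sprintf("  %-10s %s\n", meth,
                paste(sprintf("%s (%.4f)", top$hospital_id, top$score),
                      collapse = ", ")))
  }
  if (!is.null(x$comparisons)) {
    cat("\nPairwise comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

# Wide, one-row-per-rank table juxtaposing the four methodologies, the
# layout used in annual review reports.
wide_rankings <- function(rankings) {
  cols <- lapply(names(rankings), function(meth) {
    r <- rankings[[meth]]
    stats::setNames(
      data.frame(r$hospital_id, r$score, r$rank, stringsAsFactors = FALSE),
      paste0(meth, c("_hospital", "_score", "_rank")))
  })
  do.call(cbind, cols)
}

#' Write an evaluation report to a directory
#'
#' Emits `weights.csv` (long: indicator, weight, provenance),
#' `rankings.csv` (wide, four methodologies side by side),
#' `weight_changes.csv`, `comparisons.csv` and `report.json`, a
#' machine-readable twin of the whole report.
#'
#' @param report an [run_evaluation()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  weights_long <- do.call(rbind, lapply(names(report$weights), function(meth) {
    w <- report$weights[[meth]]
    data.frame(indicator_id = names(w), weight = as.numeric(w),
               provenance = meth, stringsAsFactors = FALSE)
  }))
  utils::write.csv(weights_long, file.path(dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(wide_rankings(report$rankings),
                   file.path(dir, "rankings.csv"), row.names = FALSE)
  utils::write.csv(report$weight_changes,
                   file.path(dir, "weight_changes.csv"), row.names = FALSE)
  if (!is.null(report$comparisons))
    utils::write.csv(as.data.frame(report$comparisons),
                     file.path(dir, "comparisons.csv"), row.names = FALSE)
  json <- list(
    provenance = report$provenance,
    weights = lapply(report$weights, function(w) as.list(unclass(w))),
    weight_changes = report$weight_changes,
    rankings = lapply(report$rankings, as.data.frame),
    comparisons = if (!is.null(report$comparisons))
      as.data.frame(report$comparisons),
    discrimination_degrees = if (!is.null(report$comparisons))
      as.list(attr(report$comparisons, "discrimination_degrees")))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
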