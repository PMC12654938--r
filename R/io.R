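#' Read a performance matrix from CSV, TSV or XLSX
#'
#' Expects a header row, hospital ids in the first column and one indicator
#' per remaining column. When a scheme is supplied, columns are reconciled
#' against it by indicator id (any column order is accepted; downstream
#' results are order-invariant) and validated. XLSX files are read through
#' the readxl package; legacy XLS is not supported directly -- convert to
#' XLSX or CSV first.
#'
#' @param path file path ending in `.csv`, `.tsv` or `.xlsx`.
#' @param scheme optional list of [indicator()] objects.
#' @return a [performance_matrix()].
#' @export
read_matrix <- function(path, scheme = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading .xlsx requires the 'readxl' package")
      as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
    },
    xls = stop("legacy .xls is not supported; convert to .xlsx or .csv"),
    stop("unsupported matrix format: .", ext))
  if (ncol(df) < 2L) stop("matrix file needs a hospital column plus indicators")
  vals <- df[, -1L, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric cells in column(s): ",
         paste(names(vals)[nonnum], collapse = ", "))
  mat <- as.matrix(vals)
  rownames(mat) <- as.character(df[[1L]])
  performance_matrix(mat, scheme = scheme)
}

#' Write a performance matrix to CSV
#'
#' First column `hospital_id`, one column per indicator; full double
#' precision so that a write/read round trip is lossless.
#'
#' @param matrix a [performance_matrix()] or numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(hospital_id = rownames(matrix),
                   as.data.frame(unclass(as.matrix(matrix))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a scheme from a JSON or YAML configuration file
#'
#' One entry per indicator with fields `id`, `name`, `attribute`,
#' `assigned_score`, `bands` (list of `lower`, `upper`, `points`,
#' optionally `mode`, `lower_closed`, `upper_closed`) and optionally
#' `reference_standard`. Missing bounds default to `-Inf`/`Inf`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return list of [indicator()] objects.
#' @export
read_scheme <- function(path) {
  ext <- tolower(tools::file_ext(path))
  entries <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = , yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML requires the 'yaml' package")
      yaml::read_yaml(path)
    },
    stop("unsupported scheme format: .", ext))
  lapply(entries, function(e) {
    bands <- lapply(e$bands, function(b)
      scoring_band(b$lower %||% -Inf, b$upper %||% Inf, b$points,
                   mode = b$mode %||% "absolute",
                   lower_closed = b$lower_closed %||% TRUE,
                   upper_closed = b$upper_closed %||% FALSE))
    indicator(e$id, e$name %||% e$id, e$attribute, e$assigned_score, bands,
              reference_standard = e$reference_standard)
  })
}

#' Score a table of raw rates into awarded points
#'
#' Converts per-hospital raw performance rates (fractions) into awarded
#' points using each indicator's scoring bands, then assembles the result
#' into a validated [performance_matrix()].
#'
#' @param rates wide data frame or matrix of raw rates: hospital ids in
#'   the first column (data frame) or rownames (matrix), indicator ids in
#'   the header.
#' @param scheme list of [indicator()] objects, with reference standards
#'   configured for any relative-band indicators.
#' @return a [performance_matrix()] of awarded points.
#' @export
score_rates <- function(rates, scheme) {
  if (is.data.frame(rates)) {
    m <- as.matrix(rates[, -1L, drop = FALSE])
    rownames(m) <- as.character(rates[[1L]])
  } else m <- as.matrix(rates)
  ids <- scheme_ids(scheme)
  miss <- setdiff(ids, colnames(m))
  if (length(miss))
    stop("rate table lacks indicator(s): ", paste(miss, collapse = ", "))
  pts <- vapply(seq_along(ids), function(j)
    score_indicator(m[, ids[j]], scheme[[j]]), numeric(nrow(m)))
  dimnames(pts) <- list(rownames(m), ids)
  performance_matrix(pts, scheme = scheme)
}
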