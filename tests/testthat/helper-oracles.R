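# Independent oracles, written as literal loop-by-loop transcriptions of the
# defining formulas. They deliberately share no code with the package
# implementation so that agreement is evidence, not tautology.

# Entropy weight method on an already-shifted positive matrix.
oracle_ewm <- function(y) {
  n <- nrow(y); m <- ncol(y)
  p <- matrix(0, n, m)
  for (j in seq_len(m)) {
    colsum <- 0
    for (i in seq_len(n)) colsum <- colsum + y[i, j]
    for (i in seq_len(n)) p[i, j] <- y[i, j] / colsum
  }
  e <- numeric(m)
  for (j in seq_len(m)) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + p[i, j] * log(p[i, j])
    e[j] <- -acc / log(n)
  }
  w <- numeric(m)
  for (j in seq_len(m)) w[j] <- (1 - e[j])
  w / sum(w)
}

# Full EWM pipeline from raw points: attribute normalisation, +0.001 shift,
# entropy weights.
oracle_ewm_raw <- function(x, attributes) {
  n <- nrow(x); m <- ncol(x)
  y <- matrix(0, n, m)
  for (j in seq_len(m)) {
    xj <- x[, j]
    if (attributes[j] == "positive") {
      y[, j] <- (xj - min(xj)) / (max(xj) - min(xj))
    } else if (attributes[j] == "negative") {
      y[, j] <- (max(xj) - xj) / (max(xj) - min(xj))
    } else {
      dev <- abs(xj - mean(xj))
      y[, j] <- 1 - dev / max(dev)
    }
  }
  oracle_ewm(y + 0.001)
}

# Discrimination degree: standardise a descending score list onto [0, n],
# then combine squared consecutive gaps. Both algebraic readings.
oracle_discrimination <- function(scores, reading = "ratio") {
  v_raw <- sort(scores, decreasing = TRUE)
  n <- length(v_raw)
  v <- numeric(n)
  for (i in seq_len(n))
    v[i] <- n * (1 - abs(v_raw[i] - v_raw[1]) / (v_raw[1] - v_raw[n]))
  g <- 0
  for (i in seq_len(n - 1)) g <- g + (v[i + 1] - v[i])^2
  d <- (g + 1) / (2 * n^2 - 2 * n - 1)
  if (reading == "sqrt") sqrt(d) else d
}

# Strip a weight_vector to a bare named numeric for value comparisons.
bare <- function(w) stats::setNames(as.numeric(w), names(w))

# A small complete valid wide data frame of records for build_matrix tests.
make_records <- function(n = 16, seed = 1) {
  sch <- default_scheme()
  m <- generate_matrix(generator_config(n_hospitals = n, scheme = sch,
                                        seed = seed))
  data.frame(hospital_id = rownames(m), as.data.frame(unclass(m)),
             check.names = FALSE, stringsAsFactors = FALSE)
}
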