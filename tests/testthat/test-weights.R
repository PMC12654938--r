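test_that("subjective weights divide assigned scores by their total", {
  w <- subjective_weights(default_scheme())
  expect_s3_class(w, "weight_vector")
  expect_identical(provenance(w), "subjective")
  expect_equal(unname(w["X1"]), 35 / 112)  # 0.3125 exactly
  expect_equal(unname(w["X8"]), 8 / 112, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  eq <- subjective_weights(lapply(1:4, function(i)
    indicator(paste0("Z", i), "z", "positive", 7,
              list(scoring_band(-Inf, Inf, 1)))))
  expect_equal(unname(bare(eq)), rep(0.25, 4))
  expect_error(subjective_weights(list()), "empty")
})

test_that("normalisation follows the attribute rules", {
  x <- cbind(pos = c(10, 20, 30), mod = c(1, 2, 3), neg = c(10, 20, 30))
  y <- normalize_matrix(x, c("positive", "moderate", "negative"))
  expect_equal(unname(y[, "pos"]), c(0, 0.5, 1))
  expect_equal(unname(y[, "mod"]), c(0, 1, 0))  # mean 2 is best
  expect_equal(unname(y[, "neg"]), c(1, 0.5, 0))
  expect_false(attr(y, "shifted"))
  expect_error(normalize_matrix(x[1, , drop = FALSE], rep("positive", 3)),
               "two hospitals")
  expect_error(normalize_matrix(x, c("positive", "up", "negative")),
               "unknown attribute")
})

test_that("constant columns normalise to the midpoint with a warning", {
  x <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
  expect_warning(y <- normalize_matrix(x, c("positive", "positive")),
                 "constant column a")
  expect_equal(unname(y[, "a"]), rep(0.5, 3))
})

test_that("the zero shift adds exactly 0.001 everywhere", {
  y <- normalize_matrix(cbind(a = c(0, 5, 10)), "positive")
  s <- shift_matrix(y)
  expect_equal(unname(s[, 1]), c(0.001, 0.501, 1.001))
  expect_identical(dim(s), dim(y))
  expect_true(attr(s, "shifted"))
  expect_error(shift_matrix(s), "already shifted")
})

test_that("entropy weights match the independent oracle to 1e-12", {
  # symmetric 2x2: both columns must weigh 0.5
  y <- shift_matrix(structure(cbind(a = c(1, 0), b = c(0, 1)),
                              shifted = FALSE))
  expect_equal(unname(bare(entropy_weights(y)$weights)), c(0.5, 0.5))

  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:12, 1)
    m <- sample(2:8, 1)
    y <- matrix(runif(n * m), n, m,
                dimnames = list(NULL, paste0("I", seq_len(m)))) + 0.001
    res <- entropy_weights(y)
    expect_equal(unname(bare(res$weights)), oracle_ewm(y),
                 tolerance = 1e-12)
    expect_equal(unname(colSums(res$proportions)), rep(1, m),
                 tolerance = 1e-9)
    expect_true(all(res$entropies >= 0))
  }
})

test_that("entropy weights are invariant to hospital-row permutation", {
  set.seed(11)
  y <- matrix(runif(60), 10, 6, dimnames = list(NULL, paste0("I", 1:6))) + 0.001
  w1 <- entropy_weights(y)$weights
  w2 <- entropy_weights(y[sample(10), ])$weights
  expect_equal(unclass(w1), unclass(w2), tolerance = 1e-12)
})

test_that("lower post-normalisation dispersion never earns more weight", {
  # two-column grids: one column is a strict contraction of the other
  # toward its own mean, holding nothing else in the matrix
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:16, 1)
    u <- runif(n)
    v <- mean(u) + runif(1, 0.1, 0.9) * (u - mean(u))
    y <- cbind(spread = u, concentrated = v) + 0.001
    w <- entropy_weights(y)$weights
    expect_lte(w[["concentrated"]], w[["spread"]] + 1e-12)
    expect_equal(unname(bare(w)), oracle_ewm(y), tolerance = 1e-12)
  }
})

test_that("a pre-shift constant column gets zero objective weight", {
  y <- cbind(const = rep(0.5, 8), vary = seq(0, 1, length.out = 8)) + 0.001
  res <- entropy_weights(y)
  expect_equal(res$entropies[["const"]], 1, tolerance = 1e-12)
  expect_equal(res$weights[["const"]], 0, tolerance = 1e-12)
  # all-constant matrix is degenerate
  expect_error(entropy_weights(cbind(a = rep(1, 5), b = rep(2, 5))),
               "equal weights")
})

test_that("multiplicative synthesis combines and renormalises", {
  a <- weight_vector(c(X1 = 0.6, X2 = 0.4), provenance = "subjective")
  b <- weight_vector(c(X1 = 0.2, X2 = 0.8), provenance = "objective")
  cmb <- combine_msn(a, b)
  expect_identical(provenance(cmb), "combined")
  expect_equal(unname(bare(cmb)), c(0.12, 0.32) / 0.44, tolerance = 1e-12)
  # order of input methods must not matter
  expect_equal(unclass(combine_msn(b, a)), unclass(cmb), tolerance = 1e-12)
  # a single method renormalises to itself
  expect_equal(unname(bare(combine_msn(a))), c(0.6, 0.4), tolerance = 1e-12)
  # uniform inputs stay uniform
  u <- weight_vector(c(X1 = 0.5, X2 = 0.5), provenance = "equal")
  expect_equal(unname(bare(combine_msn(u, u))), c(0.5, 0.5))
  # mismatched indicator sets are rejected
  d <- weight_vector(c(X9 = 0.5, X2 = 0.5), provenance = "equal")
  expect_error(combine_msn(a, d), "same indicator order")
  # disjoint supports make every product zero
  z1 <- weight_vector(c(X1 = 1, X2 = 0), provenance = "custom")
  z2 <- weight_vector(c(X1 = 0, X2 = 1), provenance = "custom")
  expect_error(combine_msn(z1, z2), "degenerate")
})

test_that("every produced weight vector is a unit simplex point", {
  sch <- default_scheme()
  m <- generate_matrix(generator_config(seed = 5))
  ws <- subjective_weights(sch)
  wo <- entropy_weights(shift_matrix(
    normalize_matrix(m, scheme_attributes(sch))))$weights
  wc <- combine_msn(ws, wo)
  for (w in list(ws, wo, wc)) {
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
  expect_error(weight_vector(c(X1 = 0.7, X2 = 0.2), provenance = "objective"),
               "sum to 1")
  expect_error(weight_vector(c(X1 = -0.1, X2 = 1.1), provenance = "objective"),
               "nonnegative")
})

test_that("weight changes are signed percentages of the baseline", {
  base <- weight_vector(c(X1 = 0.3125, X6 = 0.0268, X9 = 0.1071),
                        provenance = "custom")
  comp <- weight_vector(c(X1 = 0.0236, X6 = 0.1108, X9 = 0.1594),
                        provenance = "custom")
  chg <- weight_change(base, comp)
  expect_equal(chg$change_pct[chg$indicator_id == "X1"], -92.448)
  expect_equal(chg$change_pct[chg$indicator_id == "X6"], 313.4328,
               tolerance = 1e-4)
  expect_equal(weight_change(base, base)$change_pct, rep(0, 3))
  zero <- weight_vector(c(X1 = 0, X6 = 0.5, X9 = 0.5), provenance = "custom")
  expect_warning(chg0 <- weight_change(zero, comp), "zero baseline")
  expect_true(chg0$undefined[1] && is.na(chg0$change_pct[1]))
})
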