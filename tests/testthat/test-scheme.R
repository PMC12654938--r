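test_that("default scheme has the published structure", {
  sch <- default_scheme()
  expect_length(sch, 11L)
  expect_identical(scheme_ids(sch), paste0("X", 1:11))
  expect_equal(sum(assigned_scores(sch)), 112)
  expect_equal(unname(assigned_scores(sch)),
               c(35, 12, 6, 6, 3, 3, 3, 8, 12, 12, 12))
  attrs <- scheme_attributes(sch)
  expect_identical(unname(attrs[c("X1", "X2", "X4", "X8", "X9", "X10")]),
                   rep("positive", 6))
  expect_identical(unname(attrs[c("X3", "X5", "X6", "X7", "X11")]),
                   rep("moderate", 5))
  # the maximum awardable points of each indicator equal its assigned score
  expect_equal(max_points(sch), assigned_scores(sch))
})

test_that("threshold bands award the published points", {
  sch <- default_scheme()
  x1 <- sch[[1]]
  expect_equal(score_indicator(c(1.00, 0.97, 0.92, 0.87, 0.5, 0), x1),
               c(35, 30, 25, 20, 15, 0))
  expect_equal(score_indicator(1.10, x1), 35)  # over-completion still 35
  # intervention rate: flat 12-point band at and above 85%
  expect_equal(score_indicator(c(0.85, 0.99, 0.7, 0.5, 0.3, 0.1), sch[[9]]),
               c(12, 12, 10, 7, 5, 0))
  # follow-up completion
  expect_equal(score_indicator(c(1, 0.9, 0.75, 0.6, 0.2), sch[[10]]),
               c(12, 10, 7, 5, 0))
})

test_that("overlapping detection-rate bands resolve by listed order", {
  x3 <- default_scheme()[[3]]
  expect_equal(score_indicator(0.27, x3), 3)
  # 26% exactly falls in the closed 20-26% band, not the open >26% band
  expect_equal(score_indicator(0.26, x3), 6)
  expect_equal(score_indicator(c(0.20, 0.17, 0.12, 0.05), x3), c(6, 4, 3, 0))
})

test_that("relative bands resolve against the reference standard", {
  sch <- default_scheme()
  # scoring a relative-band indicator without a standard is a config error
  expect_error(score_indicator(0.5, sch[[2]]), "reference_standard")
  sch <- set_reference_standards(sch, c(X2 = 0.5))
  x2 <- sch[[2]]
  expect_equal(score_indicator(c(0.50, 0.60), x2), c(12, 12))
  expect_equal(score_indicator(0.46, x2), 9)   # within 10% below standard
  expect_equal(score_indicator(0.42, x2), 6)   # within 20%
  expect_equal(score_indicator(0.36, x2), 3)   # within 30%
  expect_equal(score_indicator(0.30, x2), 0)   # beyond 30%: catch-all
  expect_error(set_reference_standards(sch, c(Z9 = 0.5)), "unknown")
})

test_that("every rate maps to exactly one band across the unit interval", {
  sch <- set_reference_standards(
    default_scheme(),
    c(X2 = 0.6, X4 = 0.55, X5 = 0.3, X6 = 0.12, X7 = 0.35, X8 = 0.8,
      X11 = 0.5))
  grid <- seq(0, 1, by = 0.001)
  for (ind in sch) {
    pts <- score_indicator(grid, ind)  # errors if any rate is uncovered
    expect_true(all(pts >= 0 & pts <= ind$max_points))
    expect_true(all(pts %in% ind$bands$points))
  }
})

test_that("positive indicators score monotonically in the rate", {
  sch <- set_reference_standards(
    default_scheme(),
    c(X2 = 0.6, X4 = 0.55, X5 = 0.3, X6 = 0.12, X7 = 0.35, X8 = 0.8,
      X11 = 0.5))
  grid <- seq(0, 1, by = 0.001)
  for (ind in sch[scheme_attributes(sch) == "positive"]) {
    expect_false(is.unsorted(score_indicator(grid, ind)),
                 label = paste("monotone scoring for", ind$id))
  }
})

test_that("indicator constructor enforces its invariants", {
  expect_error(scoring_band(0.9, 0.5, 3), "lower bound exceeds")
  expect_error(scoring_band(0, 1, -1), "nonnegative")
  b <- list(scoring_band(0.5, Inf, 10), scoring_band(-Inf, 0.5, 0))
  expect_error(indicator("Z1", "z", "positive", 5, b, max_points = 12),
               "maximum band points")
  expect_error(indicator("Z1", "z", "positive", 0, b), "positive")
})

test_that("build_matrix validates completeness and point ranges", {
  sch <- default_scheme()
  rec <- make_records(n = 16, seed = 3)
  m <- build_matrix(rec, sch)
  expect_s3_class(m, "performance_matrix")
  expect_equal(dim(m), c(16L, 11L))

  rec_na <- rec; rec_na$X5[4] <- NA
  expect_error(build_matrix(rec_na, sch), "missing")

  rec_hi <- rec; rec_hi$X1[2] <- 40  # above the 35-point cap
  expect_error(build_matrix(rec_hi, sch), "outside")

  rec_miss <- rec[, setdiff(names(rec), "X7")]
  expect_error(build_matrix(rec_miss, sch), "X7")

  # named-list records with a missing indicator entry
  lst <- setNames(lapply(seq_len(3), function(i)
    setNames(as.numeric(rec[i, -1]), names(rec)[-1])), rec$hospital_id[1:3])
  expect_identical(dim(build_matrix(lst, sch)), c(3L, 11L))
  lst[[2]] <- lst[[2]][-4]
  expect_error(build_matrix(lst, sch), "missing indicator")
})

test_that("off-lattice points are flagged but not fatal", {
  sch <- default_scheme()
  rec <- make_records(n = 4, seed = 9)
  rec$X9[1] <- 6.5  # legal range, not an awardable band value
  expect_warning(build_matrix(rec, sch), "lattice")
})
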