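test_that("NODF matches closed-form cases", {
  expect_equal(nodf(staircase(4)), 100)
  m <- matrix(1, 4, 4)
  m[4, 4] <- 0            # identical rows 1-3: decreasing-fill rule bites
  expect_lt(nodf(m), 100)
  same <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0))
  expect_equal(nodf(same), 0)
})

test_that("NODF equals the brute-force oracle and vegan on random matrices", {
  set.seed(10)
  for (k in 1:25) {
    m <- random_binary(5, 5)
    if (all(m == 0)) next
    expect_equal(nodf(m), oracle_nodf(m))
    expect_equal(nodf(m),
                 unname(vegan::nestednodf(m, order = FALSE)$statistic["NODF"]))
    expect_equal(nodf(m, "sorted"),
                 unname(vegan::nestednodf(m, order = TRUE)$statistic["NODF"]))
  }
})

test_that("weighted NODF follows the strict-inequality rule", {
  expect_equal(weighted_nodf(weighted_staircase(4)), 100)
  eq <- staircase(4) * 5   # equal weights in all overlapping cells
  expect_equal(weighted_nodf(eq), 0)
  set.seed(11)
  for (k in 1:20) {
    w <- matrix(rpois(20, 2), 4, 5)
    if (sum(w > 0) < 2 || all(w == 0)) next
    expect_equal(weighted_nodf(w),
                 unname(vegan::nestednodf(w, order = FALSE,
                                          weighted = TRUE)$statistic["NODF"]))
  }
})

test_that("WNODA matches hand-worked and structural cases", {
  expect_equal(wnoda(weighted_staircase(4)), 100)
  expect_equal(wnoda(staircase(3) * 2), 0)     # equal weights, equal or tied
  expect_lt(wnoda(checkerboard(4)), 20)
  # frozen hand computation (see inst/metrics-reference.md)
  w <- rbind(c(4, 2, 1), c(2, 3, 0), c(1, 0, 0))
  expect_equal(wnoda(w), 500 / 6, tolerance = 1e-9)
})

test_that("WINE matches its hand-worked 2x2 oracle", {
  w <- rbind(c(4, 2), c(1, 0))
  st <- wine(w)
  expect_equal(st$statistic, 3 / 7)
  expect_equal(st$d_packed, 3 / 7)
  expect_equal(st$d_random, (2 + sqrt(2)) / 4)
  expect_equal(st$eta, 1)
  flat <- matrix(1, 2, 2)
  expect_true(is.na(wine(flat)$eta))   # calibration points coincide
})

test_that("WINE is invariant to row/column shuffles and rewards packing", {
  set.seed(12)
  w <- matrix(rpois(30, 3), 5, 6)
  w[1, 1] <- 9
  base <- wine(w)
  for (k in 1:5) {
    ws <- w[sample(5), sample(6)]
    st <- wine(ws)
    expect_equal(st$statistic, base$statistic, tolerance = 1e-12)
    expect_equal(st$eta, base$eta, tolerance = 1e-12)
  }
  # adding weight at the packed corner cannot reduce nestedness
  w2 <- w
  w2[which.max(rowSums(w)), which.max(colSums(w))] <-
    max(w) + 5
  expect_gte(wine(w2)$eta, base$eta - 1e-9)
})

test_that("temperature recovers packing of shuffled nested matrices", {
  set.seed(13)
  m <- staircase(6)
  t_sorted <- matrix_temperature(m, budget = 20000, seed = 1)
  expect_lte(as.numeric(t_sorted), 1)
  for (k in 1:3) {
    ms <- m[sample(6), sample(6)]
    ts <- matrix_temperature(ms, budget = 20000, seed = k)
    expect_lte(as.numeric(ts), 1)
  }
})

test_that("temperature separates nested from checkerboard structure", {
  tc <- matrix_temperature(checkerboard(4), budget = 20000, seed = 2)
  expect_gt(as.numeric(tc), 50)
  # determinism under a fixed seed
  t1 <- matrix_temperature(checkerboard(4), budget = 5000, seed = 7)
  t2 <- matrix_temperature(checkerboard(4), budget = 5000, seed = 7)
  expect_identical(t1, t2)
})

test_that("temperature is stable under input permutation and beats the
           fill-sort packing vegan uses", {
  set.seed(14)
  m <- random_binary(6, 8, 0.4)
  m[1, ] <- 1; m[, 1] <- 1   # keep it non-degenerate
  t_a <- as.numeric(matrix_temperature(m, budget = 30000, seed = 3))
  t_b <- as.numeric(matrix_temperature(m[sample(6), sample(8)],
                                       budget = 30000, seed = 4))
  expect_lt(abs(t_a - t_b), 2)
  t_vegan <- unname(vegan::nestedtemp(m)$statistic)
  expect_lte(t_a, t_vegan + 2)
})

test_that("discrepancy counts displaced presences", {
  expect_equal(discrepancy(staircase(5)), 0)
  m <- staircase(4)
  m[2, 3] <- 0; m[2, 4] <- 1   # one presence pushed out of the packed block
  expect_equal(discrepancy(m, "fixed_order"), 1)
  # totals-sorted packing absorbs the swap (columns 3 and 4 exchange rank)
  expect_equal(discrepancy(m, "fill_sorted"), 0)
  set.seed(15)
  for (k in 1:20) {
    m <- random_binary(4, 5)
    expect_equal(discrepancy(m, "fill_sorted"),
                 oracle_discrepancy(m, sort_cols = TRUE))
    expect_equal(discrepancy(m, "fixed_order"),
                 oracle_discrepancy(m, sort_cols = FALSE))
    expect_lte(discrepancy(m), sum(m))
  }
})

test_that("discrepancy agrees with vegan when column sums are untied", {
  set.seed(16)
  found <- 0
  while (found < 5) {
    m <- random_binary(5, 5, 0.5)
    if (anyDuplicated(colSums(m)) || all(m == 0) ||
        any(rowSums(m) == 0)) next
    found <- found + 1
    expect_equal(discrepancy(m, "fill_sorted"),
                 unname(vegan::nesteddisc(m)$statistic))
  }
})

test_that("nestedness decreases along a staircase-to-checkerboard path", {
  # interpolate by flipping staircase cells toward the checkerboard
  s <- staircase(6); cb <- checkerboard(6)
  diff_cells <- which(s != cb)
  set.seed(17)
  ord <- sample(diff_cells)
  steps <- seq(0, 1, by = 0.25)
  vals_nodf <- vals_temp <- numeric(length(steps))
  for (i in seq_along(steps)) {
    m <- s
    flip <- ord[seq_len(floor(steps[i] * length(ord)))]
    m[flip] <- cb[flip]
    vals_nodf[i] <- nodf(m, "sorted")
    vals_temp[i] <- as.numeric(matrix_temperature(m, budget = 10000,
                                                  seed = 5))
  }
  expect_lt(vals_nodf[length(steps)], vals_nodf[1])
  expect_gt(vals_temp[length(steps)], vals_temp[1])
  # broadly monotone: each step away from the staircase never increases
  # sorted NODF by more than a small wobble
  expect_true(all(diff(vals_nodf) <= 10))
})

test_that("degenerate matrices are rejected across metrics", {
  one_row <- matrix(c(1, 0, 1), 1, 3)
  expect_error(nodf(one_row), "degenerate")
  expect_error(wnoda(one_row), "degenerate")
  expect_error(matrix_temperature(matrix(0, 3, 3)), "degenerate")
  expect_error(wine(matrix(0, 2, 2)), "degenerate")
})
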