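test_that("identical matrices score zero with deterministic tie-breaking", {
  set.seed(41)
  P <- rand_upper(30)
  d <- interval_scan_distance(P, P, min_len = 10)
  expect_identical(d$score, 0)
  # ties: shortest interval, then smallest start
  expect_equal(c(d$start, d$end), c(1L, 10L))
  expect_identical(two_step_scan(P, P, fixed_len = 20, min_len = 10)$score, 0)
})

test_that("a single differing cell is localized with the tie-break rule", {
  P <- matrix(0, 12, 12)
  Q <- P; Q[4, 9] <- 0.5
  d <- interval_scan_distance(P, Q, min_len = 6)
  expect_equal(d$score, 0.5)
  expect_equal(c(d$start, d$end), c(4L, 9L))   # smallest qualifying interval
  b <- brute_force_scan(P, Q, min_len = 6, measure = "distance")
  expect_equal(c(b$start, b$end, b$score), c(4, 9, 0.5))
})

test_that("DP scans agree with the brute-force oracle on random matrices", {
  set.seed(43)
  for (k in 1:5) {
    A <- rand_upper(60); B <- rand_upper(60)
    d <- interval_scan_distance(A, B, min_len = 30)
    bd <- brute_force_scan(A, B, min_len = 30, measure = "distance")
    expect_lt(abs(d$score - bd$score), 1e-9)
    expect_equal(c(d$start, d$end), c(bd$start, bd$end))

    A2 <- rand_upper(40); B2 <- rand_upper(40)
    r <- interval_scan_correlation(A2, B2, min_len = 15, prob_floor = 0.3)
    br <- brute_force_scan(A2, B2, min_len = 15, measure = "correlation",
                           prob_floor = 0.3)
    expect_lt(abs(r$score - br$score), 1e-9)
    expect_equal(c(r$start, r$end), c(br$start, br$end))
  }
})

test_that("the distance is symmetric and monotone under interval inclusion", {
  set.seed(47)
  A <- rand_upper(40); B <- rand_upper(40)
  d1 <- interval_scan_distance(A, B, min_len = 10, landscape = TRUE)
  d2 <- interval_scan_distance(B, A, min_len = 10, landscape = TRUE)
  expect_equal(d1$score, d2$score)
  expect_equal(c(d1$start, d1$end), c(d2$start, d2$end))
  S <- attr(d1, "landscape")
  for (i in 2:20) for (j in 25:39) {
    expect_lte(S[i, j], S[i - 1, j] + 1e-12)   # widen left
    expect_lte(S[i, j], S[i, j + 1] + 1e-12)   # widen right
  }
})

test_that("correlation handles perfect, anti- and un-scorable cases", {
  set.seed(53)
  P <- rand_upper(30)
  r <- interval_scan_correlation(P, P, min_len = 10, prob_floor = 0.2)
  expect_equal(r$score, 1, tolerance = 1e-12)

  # construct anti-correlated mutant cells on the qualifying cells
  Q <- ifelse(P >= 0.2, 1 - 0.8 * P, P)
  Q[lower.tri(Q, diag = TRUE)] <- 0
  r2 <- interval_scan_correlation(P, Q, min_len = 30, prob_floor = 0.2)
  expect_lt(r2$score, 0)
  # direct verification on the reported interval
  cells <- which(upper.tri(P) & row(P) >= r2$start & col(P) <= r2$end &
                 pmax(P, Q) >= 0.2)
  expect_equal(r2$score, cor(P[cells], Q[cells]), tolerance = 1e-9)

  # nothing reaches the probability floor -> explicit no-result
  Z <- matrix(0, 20, 20)
  r3 <- interval_scan_correlation(Z, Z, min_len = 5, prob_floor = 0.5)
  expect_true(is.na(r3$score))
})

test_that("two-step refinement finds a confined difference patch", {
  set.seed(59)
  A <- rand_upper(80)
  B <- A
  patch <- 31:50
  B[patch, patch] <- A[patch, patch] +
    rand_upper(80)[patch, patch] * 0.5
  B[lower.tri(B, diag = TRUE)] <- 0
  ts <- two_step_scan(A, B, fixed_len = 40, min_len = 10)
  expect_true(ts$start <= 31 && ts$end >= 50 ||
              (ts$start >= 31 && ts$end <= 50) ||
              (ts$start <= 50 && ts$end >= 31))  # overlaps the patch
  # the patch fits in one fixed window: the two-step score equals the full scan
  full <- interval_scan_distance(A, B, min_len = 10)
  expect_equal(ts$score, full$score, tolerance = 1e-9)
  expect_equal(c(ts$start, ts$end), c(full$start, full$end))

  # step-2 score dominates every sub-interval of the step-1 winner
  w <- attr(ts, "step1")
  S <- attr(interval_scan_distance(A, B, min_len = 10, landscape = TRUE),
            "landscape")
  sub <- S[w[1]:w[2], w[1]:w[2], drop = FALSE]
  lens <- outer(seq_len(nrow(sub)), seq_len(ncol(sub)),
                function(i, j) j - i + 1)
  expect_gte(ts$score + 1e-12, max(sub[lens >= 10]))
})

test_that("the landscape dump lists every qualifying interval", {
  set.seed(67)
  A <- rand_upper(20); B <- rand_upper(20)
  d <- interval_scan_distance(A, B, min_len = 8, landscape = TRUE)
  f <- tempfile()
  df <- write_landscape_tsv(attr(d, "landscape"), min_len = 8, f)
  expect_equal(nrow(df), sum(outer(1:20, 1:20, function(i, j)
    j - i + 1 >= 8 & j >= i)))
  expect_equal(max(df$score), d$score)
  expect_true(file.exists(f))
})

test_that("degenerate and error cases are handled", {
  A <- rand_upper(10)
  expect_error(interval_scan_distance(A, rand_upper(9), min_len = 5), "size")
  expect_error(interval_scan_distance(A, A, min_len = 11), "min_len")
  expect_error(brute_force_scan(rand_upper(81), rand_upper(81), 10), "80")
  # n < fixed_len degrades to the single interval [1, n]
  ts <- two_step_scan(A, A, fixed_len = 120, min_len = 5)
  expect_equal(attr(ts, "step1"), c(1L, 10L))
})
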