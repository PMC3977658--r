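# Locating the sequence interval of maximal structural divergence between
# wild-type and mutant base-pair probability matrices.  Only pairs with BOTH
# endpoints inside an interval contribute to its score ("self-contained"
# local structures), which makes the Euclidean distance monotone under
# interval inclusion.  All-interval scores are obtained in O(n^2) by
# two-dimensional cumulative sums rather than per-interval recomputation.

#' @keywords internal
new_interval_score <- function(start, end, measure, score) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 measure = measure, score = as.numeric(score)),
            class = "interval_score")
}

#' @export
print.interval_score <- function(x, ...) {
  if (is.na(x$score))
    cat("<interval_score> no scorable interval\n")
  else
    cat(sprintf("<interval_score> [%d, %d] %s = %.6g\n",
                x$start, x$end, x$measure, x$score))
  invisible(x)
}

# Interval-accumulated sums: given an upper-triangular cell matrix M,
# returns C with C[i, j] = sum of M[k, l] over i <= k < l <= j.
.interval_sums <- function(M) {
  M[lower.tri(M, diag = TRUE)] <- 0
  B <- apply(M, 2, function(v) rev(cumsum(rev(v))))   # B[i,l] = sum_{k>=i} M[k,l]
  t(apply(B, 1, cumsum))                              # C[i,j] = sum_{l<=j} B[i,l]
}

# Pick the best interval from a score landscape.  `better` is "max" or
# "min"; ties resolved by shortest interval, then smallest start.
.pick_interval <- function(S, min_len, better) {
  n <- nrow(S)
  len <- outer(seq_len(n), seq_len(n), function(i, j) j - i + 1L)
  S[len < min_len] <- NA
  S[lower.tri(S, diag = FALSE)] <- NA
  if (all(is.na(S))) return(NULL)
  best <- if (better == "max") max(S, na.rm = TRUE) else min(S, na.rm = TRUE)
  cand <- which(S == best, arr.ind = TRUE)
  ord <- order(cand[, 2] - cand[, 1], cand[, 1])
  i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
  list(start = as.integer(i), end = as.integer(j), score = best)
}

.check_pair_mats <- function(P_wt, P_mut, min_len) {
  if (!all(dim(P_wt) == dim(P_mut)))
    stop("wild-type and mutant matrices differ in size")
  n <- nrow(P_wt)
  if (min_len > n) stop("min_len exceeds the matrix size")
  n
}

#' Scan all intervals for maximal Euclidean base-pair distance
#'
#' For every interval \[i, j\] of at least `min_len` positions, the distance
#' d(i, j) is the Euclidean norm of the difference between the two
#' probability matrices restricted to pairs lying entirely inside the
#' interval.  The maximizing interval is returned (ties: shortest interval,
#' then smallest start).
#'
#' @param P_wt,P_mut Pair-probability matrices of the two alleles.
#' @param min_len Minimum interval length (default 50 nt).
#' @param landscape If `TRUE`, attach the full score matrix as attribute
#'   `"landscape"` (`S[i, j]` = d over interval \[i, j\]).
#' @return An `interval_score` with `measure = "distance"`.
#' @export
interval_scan_distance <- function(P_wt, P_mut, min_len = 50L,
                                   landscape = FALSE) {
  n <- .check_pair_mats(P_wt, P_mut, min_len)
  S <- sqrt(pmax(.interval_sums((P_wt - P_mut)^2), 0))
  best <- .pick_interval(S, min_len, "max")
  out <- new_interval_score(best$start, best$end, "distance", best$score)
  if (landscape) attr(out, "landscape") <- S
  out
}

#' Scan all intervals for minimal Pearson correlation
#'
#' For each interval, the Pearson correlation r between the wild-type and
#' mutant probabilities is computed over the cells inside the interval where
#' either allele reaches `prob_floor` (correlations on a sea of near-zero
#' cells are meaningless).  Intervals with fewer than 3 qualifying cells or
#' without variance are skipped; the minimizing interval is returned.
#'
#' @inheritParams interval_scan_distance
#' @param prob_floor Only cells with `max(p_wt, p_mut) >= prob_floor`
#'   enter the correlation (default 0.01).
#' @return An `interval_score` with `measure = "correlation"`, or one with
#'   `score = NA` if no interval is scorable.
#' @export
interval_scan_correlation <- function(P_wt, P_mut, min_len = 50L,
                                      prob_floor = 0.01) {
  n <- .check_pair_mats(P_wt, P_mut, min_len)
  stopifnot(prob_floor >= 0, prob_floor < 1)
  Q <- (pmax(P_wt, P_mut) >= prob_floor) * 1
  N   <- .interval_sums(Q)
  Sx  <- .interval_sums(P_wt * Q)
  Sy  <- .interval_sums(P_mut * Q)
  Sxx <- .interval_sums(P_wt^2 * Q)
  Syy <- .interval_sums(P_mut^2 * Q)
  Sxy <- .interval_sums(P_wt * P_mut * Q)
  vx <- Sxx - Sx^2 / N
  vy <- Syy - Sy^2 / N
  R <- (Sxy - Sx * Sy / N) / sqrt(vx * vy)
  R[N < 3 | !is.finite(R) | vx <= 1e-12 | vy <= 1e-12] <- NA
  best <- .pick_interval(R, min_len, "min")
  if (is.null(best))
    return(new_interval_score(NA_integer_, NA_integer_, "correlation",
                              NA_real_))
  new_interval_score(best$start, best$end, "correlation", best$score)
}

#' Two-step interval refinement for local-fold matrices
#'
#' Step 1 scans all intervals of length exactly `fixed_len` (stride 1) with
#' the Euclidean distance and keeps the maximum.  Step 2 rescans every
#' sub-interval of that winner with length at least `min_len` and reports
#' the sub-interval of maximal distance, in whole-matrix coordinates.  If
#' the matrix is shorter than `fixed_len`, step 1 degrades to the single
#' interval \[1, n\].
#'
#' @inheritParams interval_scan_distance
#' @param fixed_len Fixed window length for the first pass (default 120 nt).
#' @return An `interval_score` (distance measure) with the step-1 window
#'   attached as attribute `"step1"`.
#' @export
two_step_scan <- function(P_wt, P_mut, fixed_len = 120L, min_len = 50L) {
  n <- .check_pair_mats(P_wt, P_mut, min(min_len, nrow(P_wt)))
  S <- sqrt(pmax(.interval_sums((P_wt - P_mut)^2), 0))
  if (n <= fixed_len) {
    w <- c(1L, n)
  } else {
    idx <- cbind(seq_len(n - fixed_len + 1L),
                 seq_len(n - fixed_len + 1L) + fixed_len - 1L)
    sc <- S[idx]
    k <- which(sc == max(sc))[1]          # ties: smallest start
    w <- c(idx[k, 1], idx[k, 2])
  }
  sub_wt <- P_wt[w[1]:w[2], w[1]:w[2], drop = FALSE]
  sub_mut <- P_mut[w[1]:w[2], w[1]:w[2], drop = FALSE]
  ml <- min(min_len, w[2] - w[1] + 1L)
  inner <- interval_scan_distance(sub_wt, sub_mut, min_len = ml)
  out <- new_interval_score(inner$start + w[1] - 1L, inner$end + w[1] - 1L,
                            "distance", inner$score)
  attr(out, "step1") <- w
  out
}

#' Dump a score landscape as TSV
#'
#' Diagnostic output of every qualifying interval's score, one row of
#' `(i, j, score)` per interval, from the `"landscape"` attribute of
#' [interval_scan_distance()].
#'
#' @param landscape Score matrix (`S[i, j]` = score of interval \[i, j\]).
#' @param min_len Minimum interval length to include.
#' @param path Output TSV path or connection.
#' @export
write_landscape_tsv <- function(landscape, min_len, path) {
  n <- nrow(landscape)
  idx <- which(upper.tri(landscape, diag = TRUE) &
               col(landscape) - row(landscape) + 1L >= min_len,
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(i = idx[, 1], j = idx[, 2], score = landscape[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Brute-force interval scan (test oracle)
#'
#' Recomputes the score of every qualifying interval directly from the
#' matrix cells, with tie-breaking identical to the dynamic-programming
#' scans.  Guarded to matrices of at most 80 positions.
#'
#' @inheritParams interval_scan_correlation
#' @param measure `"distance"` or `"correlation"`.
#' @return An `interval_score`.
#' @export
brute_force_scan <- function(P_wt, P_mut, min_len = 50L,
                             measure = c("distance", "correlation"),
                             prob_floor = 0.01) {
  measure <- match.arg(measure)
  n <- .check_pair_mats(P_wt, P_mut, min_len)
  if (n > 80L) stop("brute-force scan is guarded to n <= 80")
  best <- NULL
  for (i in seq_len(n)) {
    if (i + min_len - 1L > n) break
    for (j in seq(i + min_len - 1L, n, by = 1L)) {
      cells <- which(upper.tri(P_wt) &
                     row(P_wt) >= i & col(P_wt) <= j)
      x <- P_wt[cells]; y <- P_mut[cells]
      if (measure == "distance") {
        s <- sqrt(sum((x - y)^2))
      } else {
        keep <- pmax(x, y) >= prob_floor
        x <- x[keep]; y <- y[keep]
        m <- length(x)
        if (m < 3) next
        vx <- sum(x^2) - sum(x)^2 / m
        vy <- sum(y^2) - sum(y)^2 / m
        if (vx <= 1e-12 || vy <= 1e-12) next
        s <- (sum(x * y) - sum(x) * sum(y) / m) / sqrt(vx * vy)
        if (!is.finite(s)) next
      }
      if (is.null(best)) { best <- list(i = i, j = j, s = s); next }
      gain <- if (measure == "distance") s > best$s else s < best$s
      tie <- s == best$s &&
        ((j - i) < (best$j - best$i) ||
         ((j - i) == (best$j - best$i) && i < best$i))
      if (gain || tie) best <- list(i = i, j = j, s = s)
    }
  }
  if (is.null(best))
    return(new_interval_score(NA_integer_, NA_integer_, measure, NA_real_))
  new_interval_score(best$i, best$j, measure, best$s)
}
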