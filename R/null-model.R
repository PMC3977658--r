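# Empirical null distributions of substitution effects.  Random sequences of
# a given length and GC content receive one random substitution each; the
# same folding-and-scan pipeline as the foreground run turns each into a
# score, and the stratified score distributions convert observed scores into
# empirical P-values.

TABLE_MAGIC <- "SNPFOLDSCAN-TABLE v1"

#' Random RNA sequence of given length and GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(U) =
#' (1 - gc)/2.  Uses the R random number generator; seed control is the
#' caller's responsibility.
#'
#' @param length Sequence length (>= 1).
#' @param gc Target GC fraction in \[0, 1\].
#' @param id Identifier for the generated sequence.
#' @return An [rna_seq()].
#' @export
random_sequence <- function(length, gc = 0.5, id = "random") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  b <- sample(BASES, length, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  rna_seq(id, paste(b, collapse = ""))
}

#' Sample null substitution-effect scores
#'
#' Repeats `n` times: draw a random sequence of the given length and GC,
#' place one substitution at a uniformly random position (alternative base
#' uniform over the three non-reference bases), and score the structural
#' difference between the two alleles with the pipeline described by
#' `params` (same measure, folding method and scan settings as the
#' foreground run).
#'
#' @param length,gc Stratum the scores are drawn for.
#' @param n Number of scores.
#' @param params A [run_params()] object.
#' @return Numeric vector of `n` scores.
#' @export
sample_null_scores <- function(length, gc, n, params = run_params()) {
  stopifnot(n >= 1)
  scores <- numeric(n)
  for (k in seq_len(n)) {
    repeat {
      wt <- random_sequence(length, gc)
      pos <- sample.int(length, 1L)
      ref <- substr(wt$bases, pos, pos)
      alt <- sample(setdiff(BASES, ref), 1L)
      ms <- .parse_one_spec(sprintf("%s%d%s", ref, pos, alt))
      mut <- apply_mutations(wt, ms)
      s <- score_structure_change(wt, mut, params)$score
      if (!is.na(s)) break
      # correlation can be unscorable on a degenerate draw; redraw
    }
    scores[k] <- s
  }
  scores
}

#' Build a background table of null score distributions
#'
#' One sorted stratum of `n` null scores per (length bin, GC bin) grid cell.
#' The defaults mirror the folding-window range the method exposes (length
#' bins every 50 nt from 100 to 800, GC bins every 0.05 from 0.30 to 0.70);
#' note that the full default grid is expensive — screens at a single known
#' length/GC should pass a one-cell grid.
#'
#' @param length_bins Numeric vector of stratum lengths.
#' @param gc_bins Numeric vector of stratum GC fractions.
#' @param n Null samples per stratum.
#' @param params A [run_params()].
#' @param seed Integer seed; together with the metadata it fully determines
#'   the table.
#' @return An object of class `background_table`.
#' @export
build_background_table <- function(length_bins = seq(100, 800, by = 50),
                                   gc_bins = seq(0.30, 0.70, by = 0.05),
                                   n = 500L, params = run_params(),
                                   seed = 1L) {
  stopifnot(length(length_bins) >= 1, length(gc_bins) >= 1, n >= 1)
  set.seed(seed)
  strata <- list()
  for (L in length_bins) for (g in gc_bins) {
    strata[[.stratum_key(L, g)]] <- sort(sample_null_scores(L, g, n, params))
  }
  structure(list(
    meta = list(measure = params$measure, mode = params$mode,
                flank = params$flank, min_len = params$min_len,
                window = params$window, max_span = params$max_span,
                fixed_len = params$fixed_len,
                prob_floor = params$prob_floor,
                n_per_stratum = as.integer(n), seed = as.integer(seed),
                model_id = params$model$id,
                length_bins = length_bins, gc_bins = gc_bins),
    strata = strata), class = "background_table")
}

.stratum_key <- function(L, g) sprintf("%g|%g", L, g)

#' @export
print.background_table <- function(x, ...) {
  cat(sprintf(paste0("<background_table> %d strata x %d scores ",
                     "(measure %s, mode %d, seed %d)\n"),
              length(x$strata), x$meta$n_per_stratum, x$meta$measure,
              x$meta$mode, x$meta$seed))
  invisible(x)
}

#' Empirical P-value of an observed score
#'
#' Looks up the stratum with the nearest length bin and nearest GC bin
#' (clamping outside the grid) and applies the add-one estimator: for the
#' distance measure p = (1 + #\{null >= score\}) / (n + 1); for correlation
#' (where smaller means more disrupted) the inequality is reversed.  The
#' result lies in \[1/(n+1), 1\].
#'
#' @param score Observed interval score.
#' @param length,gc Length and GC content of the folding region the score
#'   was computed on.
#' @param table A [build_background_table()] result.
#' @return Empirical P-value.
#' @export
empirical_pvalue <- function(score, length, gc, table) {
  stopifnot(inherits(table, "background_table"))
  if (!length(table$strata)) stop("background table has no strata")
  lb <- table$meta$length_bins
  gb <- table$meta$gc_bins
  L <- lb[which.min(abs(lb - length))]
  g <- gb[which.min(abs(gb - gc))]
  null <- table$strata[[.stratum_key(L, g)]]
  n <- length(null)
  extreme <- if (identical(table$meta$measure, "correlation"))
    sum(null <= score) else sum(null >= score)
  (1 + extreme) / (n + 1)
}

#' Save a background table as versioned plain TSV
#'
#' Format: a magic line, `#key<TAB>value` metadata lines, a column header,
#' then one row per (length_bin, gc_bin, rank, score).  Human-inspectable
#' and diff-able; loading is lossless.
#'
#' @param table A `background_table`.
#' @param path Output path.
#' @export
save_table <- function(table, path) {
  stopifnot(inherits(table, "background_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", TABLE_MAGIC), con)
  m <- table$meta
  for (key in names(m)) {
    val <- if (length(m[[key]]) > 1) paste(m[[key]], collapse = ",")
           else as.character(m[[key]])
    writeLines(sprintf("#%s\t%s", key, val), con)
  }
  writeLines("length_bin\tgc_bin\trank\tscore", con)
  for (key in names(table$strata)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sc <- table$strata[[key]]
    writeLines(sprintf("%s\t%s\t%d\t%.17g", parts[1], parts[2],
                       seq_along(sc), sc), con)
  }
  invisible(NULL)
}

#' Load a background table written by [save_table()]
#'
#' @param path Path to a table file.
#' @return A `background_table`.
#' @export
load_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != paste0("# ", TABLE_MAGIC))
    stop(sprintf("not a background table (expected magic '%s')", TABLE_MAGIC))
  meta_lines <- grep("^#[^ ]", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  for (key in c("flank", "min_len", "window", "max_span", "fixed_len",
                "n_per_stratum", "seed", "mode"))
    if (!is.null(meta[[key]])) meta[[key]] <- as.integer(meta[[key]])
  meta$prob_floor <- as.numeric(meta$prob_floor)
  meta$length_bins <- as.numeric(strsplit(meta$length_bins, ",")[[1]])
  meta$gc_bins <- as.numeric(strsplit(meta$gc_bins, ",")[[1]])
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1L) stop("truncated table file: no data rows")
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!all(c("length_bin", "gc_bin", "rank", "score") %in% names(df)))
    stop("truncated or malformed table file")
  strata <- list()
  for (key in unique(.stratum_key(df$length_bin, df$gc_bin))) {
    sel <- .stratum_key(df$length_bin, df$gc_bin) == key
    strata[[key]] <- df$score[sel][order(df$rank[sel])]
  }
  structure(list(meta = meta, strata = strata), class = "background_table")
}
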