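# The three operation modes: global-fold analysis of user-supplied variants
# (Mode 1), windowed local folding with two-step refinement for long
# sequences (Mode 2), and the brute-force screen of every possible
# substitution (Mode 3).

#' Analysis parameter set
#'
#' Bundles every knob of the folding-and-scan pipeline.  Defaults follow the
#' method's published parameter surface: a folding flank of 200 nt on each
#' side of the variant, Euclidean distance as the primary measure, minimum
#' local-region length 50 nt, local folding with window 200 / maximum pair
#' span 120, first-pass fixed window 120 nt, screen cutoff 0.2 and report
#' cutoff 0.05.
#'
#' @param mode Operation mode, 1, 2 or 3.
#' @param measure `"distance"` or `"correlation"` (Mode 1 only; Modes 2/3
#'   use the distance).
#' @param flank Folding flank in nt around the variant (Mode 1: 100-800;
#'   Modes 2/3: 200-800 in multiples of 50).
#' @param min_len Minimum local-region length in nt.
#' @param window,max_span Local-folding window W and maximum pair span L.
#' @param fixed_len First-pass window of the two-step scan.
#' @param prob_floor Cell floor for the correlation measure.
#' @param screen_cutoff Mode 3: P-value below which a substitution proceeds
#'   from the Mode 2 screen to Mode 1 confirmation.
#' @param report_cutoff Mode 3: Mode 1 P-value below which a substitution is
#'   reported.
#' @param model The [energy_model()] used for folding.
#' @return A list of class `run_params`.
#' @export
run_params <- function(mode = 1L, measure = c("distance", "correlation"),
                       flank = 200L, min_len = 50L, window = 200L,
                       max_span = 120L, fixed_len = 120L, prob_floor = 0.01,
                       screen_cutoff = 0.2, report_cutoff = 0.05,
                       model = energy_model()) {
  measure <- match.arg(measure)
  stopifnot(mode %in% 1:3, flank >= 1, min_len >= 2,
            screen_cutoff > 0, screen_cutoff <= 1,
            report_cutoff > 0, report_cutoff <= 1)
  structure(list(mode = as.integer(mode), measure = measure,
                 flank = as.integer(flank), min_len = as.integer(min_len),
                 window = as.integer(window),
                 max_span = as.integer(max_span),
                 fixed_len = as.integer(fixed_len), prob_floor = prob_floor,
                 screen_cutoff = screen_cutoff,
                 report_cutoff = report_cutoff, model = model),
            class = "run_params")
}

#' Extract the folding region around a variant
#'
#' The region extends `flank` nt upstream and downstream of the variant
#' (for compound mutants, of the span of all mutated positions), truncated
#' at the sequence ends.  A variant at position 22 with the default flank of
#' 200 on a sufficiently long sequence yields region 1-222.
#'
#' @param seq An [rna_seq()].
#' @param ms A `mutation_set`.
#' @param flank Flank size in nt.
#' @return List with `region` (start, end; 1-based inclusive original
#'   coordinates), `subseq` (the extracted [rna_seq()]) and `offset`
#'   (original coordinate of subsequence position 1, minus 1).
#' @export
extract_folding_region <- function(seq, ms, flank = 200L) {
  stopifnot(inherits(seq, "rna_seq"), inherits(ms, "mutation_set"))
  if (!length(ms$mutations)) stop("empty mutation set")
  n <- nchar(seq$bases)
  pos <- vapply(ms$mutations, `[[`, integer(1), "pos")
  if (any(pos > n)) stop("mutation position beyond sequence end")
  start <- max(1L, min(pos) - as.integer(flank))
  end <- min(n, max(pos) + as.integer(flank))
  sub <- rna_seq(seq$id, substr(seq$bases, start, end))
  list(region = c(start, end), subseq = sub, offset = start - 1L)
}

#' Score the structural change between two alleles
#'
#' Folds both alleles (globally for Mode 1, locally for Modes 2/3) and
#' locates the interval of maximal structural difference.  This is the
#' scoring core shared by the mode runners and the null-distribution
#' sampler.
#'
#' @param wt,mut [rna_seq()] objects of identical length.
#' @param params A [run_params()].
#' @return An `interval_score` (coordinates local to the given sequences).
#' @export
score_structure_change <- function(wt, mut, params = run_params()) {
  n <- nchar(wt$bases)
  stopifnot(nchar(mut$bases) == n)
  ml <- min(params$min_len, n)
  if (params$mode == 1L) {
    P1 <- .fold_cached(wt, params, global = TRUE)
    P2 <- global_pair_probabilities(mut, params$model)
    if (params$measure == "distance")
      interval_scan_distance(P1, P2, min_len = ml)
    else
      interval_scan_correlation(P1, P2, min_len = ml,
                                prob_floor = params$prob_floor)
  } else {
    P1 <- .fold_cached(wt, params, global = FALSE)
    P2 <- local_pair_probabilities(mut, params$model,
                                   window = params$window,
                                   max_span = params$max_span)
    two_step_scan(P1, P2, fixed_len = params$fixed_len, min_len = ml)
  }
}

# Wild-type matrices recur unchanged across the 3n substitutions of a
# Mode 3 screen; keep the most recent folds around.
.fold_cache <- new.env(parent = emptyenv())

.fold_cached <- function(seq, params, global) {
  key <- paste(seq$bases, global, params$window, params$max_span,
               params$model$id, sep = "#")
  hit <- .fold_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- if (global) global_pair_probabilities(seq, params$model)
       else local_pair_probabilities(seq, params$model,
                                     window = params$window,
                                     max_span = params$max_span)
  keys <- ls(.fold_cache)
  if (length(keys) >= 8L) rm(list = keys[1], envir = .fold_cache)
  .fold_cache[[key]] <- P
  P
}

#' @keywords internal
new_snp_effect_result <- function(seq_id, mutation, mode, fold_region,
                                  local_region, measure, score, p_value,
                                  mut_positions) {
  structure(list(seq_id = seq_id, mutation = mutation, mode = mode,
                 fold_region = fold_region, local_region = local_region,
                 measure = measure, score = score, p_value = p_value,
                 mut_positions = mut_positions),
            class = "snp_effect_result")
}

#' @export
print.snp_effect_result <- function(x, ...) {
  cat(sprintf(
    "<snp_effect_result> %s %s (mode %d): region %d-%d, local %d-%d, %s = %.4g, P = %.4f\n",
    x$seq_id, x$mutation, x$mode, x$fold_region[1], x$fold_region[2],
    x$local_region[1], x$local_region[2], x$measure, x$score, x$p_value))
  invisible(x)
}

#' GC fraction of a sequence string
#' @keywords internal
.gc_content <- function(bases) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  mean(ch %in% c("G", "C"))
}

.run_mode_core <- function(seq, ms, params, table, mode) {
  params$mode <- mode
  fr <- extract_folding_region(seq, ms, params$flank)
  wt <- fr$subseq
  local_ms <- .shift_mutation_set(ms, -fr$offset)
  mut <- apply_mutations(wt, local_ms)
  sc <- score_structure_change(wt, mut, params)
  region_len <- fr$region[2] - fr$region[1] + 1L
  gc <- .gc_content(wt$bases)
  p <- if (is.na(sc$score)) 1 else
    empirical_pvalue(sc$score, region_len, gc, table)
  local_region <- if (is.na(sc$score)) fr$region else
    c(sc$start, sc$end) + fr$offset
  new_snp_effect_result(
    seq_id = seq$id, mutation = ms$label, mode = mode,
    fold_region = fr$region, local_region = local_region,
    measure = if (mode == 1L) params$measure else "distance",
    score = sc$score, p_value = p,
    mut_positions = vapply(ms$mutations, `[[`, integer(1), "pos"))
}

.shift_mutation_set <- function(ms, shift) {
  muts <- lapply(ms$mutations, function(m) {
    m$pos <- m$pos + as.integer(shift); m
  })
  structure(list(mutations = muts, label = ms$label),
            class = "mutation_set")
}

#' Mode 1: global-fold analysis of a variant
#'
#' Extracts the folding region around the variant, folds both alleles with
#' the global partition function, scans all intervals for the maximal
#' structural difference and converts the score to an empirical P-value
#' using the stratum matching the folding-region length and GC content.
#'
#' @param seq An [rna_seq()].
#' @param ms A `mutation_set` (positions in original sequence coordinates).
#' @param params A [run_params()].
#' @param table A `background_table` for the P-value lookup.
#' @return A `snp_effect_result` in original sequence coordinates.
#' @export
run_mode1 <- function(seq, ms, params = run_params(), table) {
  .run_mode_core(seq, ms, params, table, 1L)
}

#' Mode 2: local-fold analysis for long sequences
#'
#' As [run_mode1()], but both alleles are folded with the sliding-window
#' local method and the disrupted interval is located by the two-step scan
#' (fixed-length first pass, refinement inside the winner).
#'
#' @inheritParams run_mode1
#' @export
run_mode2 <- function(seq, ms, params = run_params(), table) {
  .run_mode_core(seq, ms, params, table, 2L)
}

#' Mode 3: brute-force screen of all possible substitutions
#'
#' Evaluates all 3n substitutions of the input with the Mode 2 pipeline,
#' re-scores those below `screen_cutoff` with Mode 1, and reports the
#' substitutions whose Mode 1 P-value falls below `report_cutoff`, sorted
#' by P-value then position.  Inputs longer than 1000 nt trigger a warning
#' (the method's published screening cap), not an error.
#'
#' @param seq An [rna_seq()].
#' @param params A [run_params()].
#' @param tables Either a single `background_table` used for both stages or
#'   a list with elements `mode1` and `mode2`.
#' @param keep_all If `TRUE`, attach the full screen (every substitution's
#'   Mode 2 result, plus Mode 1 confirmations) as attribute `"screen"`.
#' @return List of `snp_effect_result` objects (the reported SNPs).
#' @export
run_mode3 <- function(seq, params = run_params(), tables,
                      keep_all = FALSE) {
  stopifnot(inherits(seq, "rna_seq"))
  n <- nchar(seq$bases)
  if (n > 1000L)
    warning("input exceeds 1000 nt; the published screen caps Mode 3 there")
  t2 <- if (inherits(tables, "background_table")) tables else tables$mode2
  t1 <- if (inherits(tables, "background_table")) tables else tables$mode1
  chars <- strsplit(seq$bases, "", fixed = TRUE)[[1]]
  screened <- list()
  reported <- list()
  for (pos in seq_len(n)) {
    for (alt in setdiff(BASES, chars[pos])) {
      ms <- .parse_one_spec(sprintf("%s%d%s", chars[pos], pos, alt))
      r2 <- run_mode2(seq, ms, params, t2)
      if (keep_all) screened[[length(screened) + 1L]] <- r2
      if (r2$p_value <= params$screen_cutoff) {
        r1 <- run_mode1(seq, ms, params, t1)
        if (keep_all) screened[[length(screened) + 1L]] <- r1
        if (r1$p_value < params$report_cutoff)
          reported[[length(reported) + 1L]] <- r1
      }
    }
  }
  if (length(reported)) {
    ord <- order(vapply(reported, `[[`, numeric(1), "p_value"),
                 vapply(reported, function(r) r$mut_positions[1], integer(1)))
    reported <- reported[ord]
  }
  if (keep_all) attr(reported, "screen") <- screened
  reported
}
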