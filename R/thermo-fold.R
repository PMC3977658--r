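# Ensemble folding: global McCaskill partition-function pair probabilities,
# sliding-window local folding, MFE structure, and an exhaustive-enumeration
# oracle used to validate the dynamic programs on small sequences.

.fold_par <- function(seq_codes, model) {
  tabs <- .model_tables(model, length(seq_codes))
  list(pair_table = model$pair_table,
       stack = model$stack,
       hairpin = tabs$hairpin,
       interior = tabs$interior,
       max_interior = model$max_interior,
       min_hairpin = model$min_hairpin,
       ml_close = model$ml_close,
       ml_branch = model$ml_branch,
       ml_unpaired = model$ml_unpaired,
       kT = model$kT)
}

#' Global ensemble base-pair probabilities
#'
#' Computes, for every position pair (i, j), the Boltzmann-ensemble
#' probability that i pairs with j over all pseudoknot-free secondary
#' structures of the sequence, via inside/outside partition-function
#' recursions (McCaskill's algorithm) under the package energy model.
#'
#' @param seq An [rna_seq()] object or a plain A/C/G/U string.
#' @param model An [energy_model()]; defaults to the package model at 37 C.
#' @return An n x n numeric matrix with probabilities in the upper triangle
#'   (`P[i, j]` for i < j) and zeros elsewhere.
#' @examples
#' P <- global_pair_probabilities("GGGAAAACCC")
#' P[1, 10]
#' @export
global_pair_probabilities <- function(seq, model = energy_model()) {
  codes <- .seq_codes(seq)
  c_pair_probs(codes, .fold_par(codes, model))
}

#' Local (sliding-window) ensemble base-pair probabilities
#'
#' Pair probabilities for long sequences computed the way windowed local
#' folding tools do: every window of `window` nt (stride 1, truncated at the
#' 3' end) is folded globally, and p(i, j) is the average of the
#' window-local probabilities over all windows containing both i and j.
#' Pairs spanning `max_span` or more nucleotides are reported as zero.
#' With `window >= n` and `max_span >= n - 1` the result equals
#' [global_pair_probabilities()].
#'
#' @param seq An [rna_seq()] or A/C/G/U string.
#' @param model An [energy_model()].
#' @param window Window width W in nt (values beyond the sequence length are
#'   truncated).
#' @param max_span Maximum base-pair span L; pairs with `j - i >= L` get
#'   probability zero.
#' @return n x n upper-triangular probability matrix.
#' @export
local_pair_probabilities <- function(seq, model = energy_model(),
                                     window = 200L, max_span = 120L) {
  codes <- .seq_codes(seq)
  n <- length(codes)
  if (max_span > window) stop("max_span (L) must not exceed window (W)")
  if (max_span < 1L) stop("max_span must be >= 1")
  W <- min(as.integer(window), n)
  L <- min(as.integer(max_span), n)
  c_local_pair_probs(codes, .fold_par(codes, model), W, L)
}

#' Minimum free energy structure
#'
#' @param seq An [rna_seq()] or A/C/G/U string.
#' @param model An [energy_model()].
#' @return List with `structure` (dot-bracket string), `energy` (kcal/mol)
#'   and `partner` (1-based pairing vector, 0 = unpaired).
#' @export
mfe_structure <- function(seq, model = energy_model()) {
  codes <- .seq_codes(seq)
  res <- c_mfe(codes, .fold_par(codes, model))
  partner <- res$partner
  db <- rep(".", length(codes))
  db[partner > seq_along(partner)] <- "("
  db[partner != 0 & partner < seq_along(partner)] <- ")"
  list(structure = paste(db, collapse = ""), energy = res$energy,
       partner = partner)
}

# ------------------------------------------------------------------------
# Exhaustive enumeration oracle.  Completely independent of the C++ dynamic
# programs: structures are generated recursively and each is scored by
# explicit loop decomposition.

#' Enumerate all secondary structures of a short sequence
#'
#' Generates every pseudoknot-free structure (admissible pairs, minimum
#' hairpin size respected) of a sequence of at most 14 nt, scores each by
#' loop decomposition under the model, and attaches Boltzmann weights.
#' Serves as the brute-force oracle for the partition-function and MFE
#' dynamic programs.
#'
#' @param seq An [rna_seq()] or A/C/G/U string, length <= 14.
#' @param model An [energy_model()].
#' @return A list of structures, each a list with `pairs` (2-column matrix),
#'   `structure` (dot-bracket), `energy` and `weight` (exp(-E/kT)).
#'   Structures of infinite energy (oversized interior loops) are dropped.
#'   The summed weight (the partition function) is attached as attribute
#'   `"Q"`.
#' @export
enumerate_structures <- function(seq, model = energy_model()) {
  codes <- .seq_codes(seq)
  n <- length(codes)
  if (n > 14L) stop("enumeration is limited to sequences of <= 14 nt")
  h <- model$min_hairpin
  pt <- model$pair_table
  memo <- new.env(parent = emptyenv())

  gen <- function(i, j) {
    if (j - i < h + 1L) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- gen(i + 1L, j)                       # i unpaired
    for (l in (i + h + 1L):j) {
      if (pt[codes[i], codes[l]] == 0L) next
      left <- gen(i + 1L, l - 1L)
      right <- if (l < j) gen(l + 1L, j) else list(matrix(integer(0), 0, 2))
      for (sl in left) for (sr in right) {
        out[[length(out) + 1L]] <- rbind(c(i, l), sl, sr)
      }
    }
    memo[[key]] <- out
    out
  }

  all_pairs <- if (n >= h + 2L) gen(1L, n) else list(matrix(integer(0), 0, 2))
  res <- list()
  for (pr in all_pairs) {
    e <- structure_energy(codes, pr, model)
    if (!is.finite(e)) next
    db <- rep(".", n)
    if (nrow(pr)) { db[pr[, 1]] <- "("; db[pr[, 2]] <- ")" }
    res[[length(res) + 1L]] <- list(pairs = pr,
                                    structure = paste(db, collapse = ""),
                                    energy = e,
                                    weight = exp(-e / model$kT))
  }
  attr(res, "Q") <- sum(vapply(res, `[[`, numeric(1), "weight"))
  res
}

#' Free energy of a given structure by loop decomposition
#'
#' Scores a fixed secondary structure under the model by summing its loop
#' terms (hairpins, stacks, interior/bulge loops, multibranch loops; the
#' exterior loop contributes zero).  Independent of the folding recursions.
#'
#' @param seq Integer base codes or an A/C/G/U string / [rna_seq()].
#' @param pairs 2-column matrix of 1-based pair positions (i < j).
#' @param model An [energy_model()].
#' @return Energy in kcal/mol (`Inf` if an interior loop exceeds the model's
#'   size cap).
#' @export
structure_energy <- function(seq, pairs, model = energy_model()) {
  codes <- if (is.numeric(seq)) as.integer(seq) else .seq_codes(seq)
  n <- length(codes)
  if (!nrow(pairs)) return(0)
  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  pc <- function(i, j) model$pair_table[codes[i], codes[j]]
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (pc(i, j) == 0L) return(Inf)
    # children: maximal pairs directly enclosed by (i, j)
    children <- list()
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else if (partner[k] != 0L) {
        return(Inf)  # crossing / malformed
      } else k <- k + 1L
    }
    nc <- length(children)
    if (nc == 0L) {
      if (j - i - 1L < model$min_hairpin) return(Inf)
      e <- e + hairpin_energy(model, j - i - 1L)
    } else if (nc == 1L) {
      kk <- children[[1]][1]; ll <- children[[1]][2]
      if (kk == i + 1L && ll == j - 1L) {
        e <- e + stack_energy(model, pc(i, j), pc(kk, ll))
      } else {
        e <- e + interior_energy(model, kk - i - 1L, j - ll - 1L)
      }
    } else {
      unpaired <- (j - i - 1L) -
        sum(vapply(children, function(ch) ch[2] - ch[1] + 1L, integer(1)))
      e <- e + model$ml_close + model$ml_branch * nc +
        model$ml_unpaired * unpaired
    }
    if (!is.finite(e)) return(Inf)
  }
  e
}

#' Pair probabilities by exhaustive enumeration
#'
#' Boltzmann-weighted pair frequencies over all enumerated structures; the
#' reference against which [global_pair_probabilities()] is validated.
#'
#' @inheritParams enumerate_structures
#' @return n x n upper-triangular probability matrix.
#' @export
enum_pair_probs <- function(seq, model = energy_model()) {
  codes <- .seq_codes(seq)
  n <- length(codes)
  structs <- enumerate_structures(seq, model)
  Q <- attr(structs, "Q")
  P <- matrix(0, n, n)
  for (s in structs) {
    if (!nrow(s$pairs)) next
    P[s$pairs] <- P[s$pairs] + s$weight
  }
  P / Q
}

#' Check the invariants of a pair-probability matrix
#'
#' Probabilities within [0, 1], per-position pairing mass at most one, and
#' zero probability for pairs tighter than the minimum hairpin size.
#'
#' @param P n x n upper-triangular probability matrix.
#' @param model An [energy_model()] (for the minimum hairpin size).
#' @param tol Numerical tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_pair_probs <- function(P, model = energy_model(), tol = 1e-9) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(P < -tol) || any(P > 1 + tol))
    stop("pair probabilities outside [0, 1]")
  mass <- rowSums(P) + colSums(P)
  if (any(mass > 1 + tol))
    stop("per-position pairing mass exceeds 1")
  n <- nrow(P)
  for (i in seq_len(n)) {
    jmax <- min(n, i + model$min_hairpin)
    if (i < jmax && any(P[i, (i + 1):jmax] > tol))
      stop("nonzero probability inside the minimum hairpin span")
  }
  invisible(TRUE)
}

.seq_codes <- function(seq) {
  if (inherits(seq, "rna_seq")) encode_bases(seq$bases)
  else if (is.character(seq) && length(seq) == 1L) encode_bases(seq)
  else stop("expected an rna_seq object or a single A/C/G/U string")
}
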