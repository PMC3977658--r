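# Nearest-neighbor thermodynamic model for pseudoknot-free RNA secondary
# structure.  The free energy of a structure is the sum of its loop terms:
# stacked pairs use a sequence-dependent table, hairpin/bulge/internal loops
# use size-dependent initiation penalties with logarithmic extrapolation, and
# multibranch loops use the usual affine (closing + per-branch + per-unpaired)
# model.  Watson-Crick stack values follow the standard unified nearest-
# neighbor set; wobble-containing stacks are approximate.  Full Turner-2004
# feature completeness (dangling ends, coaxial stacking, tetraloop bonuses,
# 1x1/2x2 tables) is deliberately not attempted: the model is self-contained
# and exactly reproducible by exhaustive enumeration, which is what the test
# oracle requires.

BASES <- c("A", "C", "G", "U")

# pair type codes; 0 = not an admissible pair
PAIR_CODES <- c(CG = 1L, GC = 2L, GU = 3L, UG = 4L, AU = 5L, UA = 6L)

# gas constant in kcal/(mol K)
.RGAS <- 0.0019872

#' Construct the RNA folding energy model
#'
#' Assembles the nearest-neighbor parameter set used by all folding routines:
#' stacking free energies for the 21 distinct stacked combinations of the six
#' admissible pairs (AU, UA, GC, CG, GU, UG), size-dependent hairpin, bulge
#' and internal-loop initiation penalties, and affine multibranch-loop
#' constants.  All energies are in kcal/mol at the given temperature.
#'
#' @param temperature Folding temperature in Kelvin (default 310.15, i.e.
#'   37 degrees C, giving kT = 0.6163 kcal/mol).
#' @param min_hairpin Minimum number of unpaired bases enclosed by a hairpin
#'   pair (default 3).
#' @param max_interior Largest interior/bulge loop considered (sum of the two
#'   unpaired strand lengths); larger loops are assigned infinite energy.
#'   Default 30, the convention used by standard folding engines.
#' @return An object of class `energy_model`.
#' @examples
#' m <- energy_model()
#' m$kT
#' @export
energy_model <- function(temperature = 310.15, min_hairpin = 3L,
                         max_interior = 30L) {
  stopifnot(temperature > 0, min_hairpin >= 3, max_interior >= 2)

  # admissible-pair lookup: 4x4, bases A=1 C=2 G=3 U=4
  pt <- matrix(0L, 4, 4, dimnames = list(BASES, BASES))
  for (p in names(PAIR_CODES)) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    pt[a, b] <- PAIR_CODES[[p]]
  }

  model <- structure(list(
    kT            = .RGAS * temperature,
    temperature   = temperature,
    min_hairpin   = as.integer(min_hairpin),
    max_interior  = as.integer(max_interior),
    pair_table    = pt,
    stack         = .stack_table(),
    hairpin_init  = c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4),  # sizes 3..9
    bulge_init    = c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4),       # sizes 1..6
    internal_init = c(1.5, 1.8, 2.0, 2.2, 2.5),            # sizes 2..6
    loop_extrap   = 1.75 * .RGAS * temperature,             # Jacobson-Stockmayer
    asym_per_nt   = 0.5,   # internal-loop asymmetry penalty per unpaired nt
    asym_max      = 3.0,   # cap on the asymmetry penalty
    ml_close      = 3.4,   # multiloop closing penalty
    ml_branch     = 0.4,   # per inner branch
    ml_unpaired   = 0.0,   # per unpaired nt inside a multiloop
    id            = "snpfoldscan-nn-v1"
  ), class = "energy_model")
  model
}

# The 21 unique stacked-pair motifs.  A motif is an outer pair (i,j) with the
# inner pair (i+1, j-1) directly stacked on it; rotating the helix maps
# (outer, inner) -> (rev(inner), rev(outer)), so E[outer, inner] must equal
# E[rev(inner), rev(outer)].  Watson-Crick x Watson-Crick values are the
# unified nearest-neighbor set; wobble-containing values are approximate.
.STACK_MOTIFS <- list(
  # outer, inner, dG37 (kcal/mol)
  list("AU", "AU", -0.93),
  list("AU", "UA", -1.10),
  list("UA", "AU", -1.33),
  list("CG", "UA", -2.08),
  list("CG", "AU", -2.11),
  list("GC", "UA", -2.24),
  list("GC", "AU", -2.35),
  list("CG", "GC", -2.36),
  list("GC", "GC", -3.26),
  list("GC", "CG", -3.42),
  # wobble-containing stacks
  list("CG", "GU", -2.1),
  list("CG", "UG", -1.4),
  list("GC", "GU", -2.5),
  list("GC", "UG", -1.5),
  list("AU", "GU", -0.6),
  list("AU", "UG", -1.4),
  list("UA", "GU", -1.0),
  list("UA", "UG", -1.3),
  list("GU", "GU",  0.5),
  list("GU", "UG",  1.3),
  list("UG", "GU", -0.5)
)

.rev_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))

.stack_table <- function() {
  st <- matrix(NA_real_, 6, 6,
               dimnames = list(names(PAIR_CODES), names(PAIR_CODES)))
  for (m in .STACK_MOTIFS) {
    outer <- m[[1]]; inner <- m[[2]]; e <- m[[3]]
    st[outer, inner] <- e
    st[.rev_pair(inner), .rev_pair(outer)] <- e
  }
  stopifnot(!anyNA(st))
  st
}

#' Hairpin loop initiation energy
#'
#' @param model An [energy_model()].
#' @param size Number of unpaired bases enclosed by the hairpin pair.
#' @return Energy in kcal/mol; `Inf` for loops smaller than the minimum
#'   hairpin size.
#' @export
hairpin_energy <- function(model, size) {
  n <- length(model$hairpin_init)
  ifelse(size < model$min_hairpin, Inf,
         ifelse(size <= n + 2,
                model$hairpin_init[pmax(1L, size - 2L)],
                model$hairpin_init[n] + model$loop_extrap * log(size / (n + 2))))
}

#' Interior/bulge loop energy
#'
#' Size-dependent penalty for the loop between an outer pair and its single
#' inner pair, given the two unpaired strand lengths.  `l1 == l2 == 0` is a
#' stack and is not handled here.
#'
#' @param model An [energy_model()].
#' @param l1,l2 Unpaired lengths on the 5' and 3' sides (either order).
#' @return Energy in kcal/mol; `Inf` beyond `max_interior`.
#' @export
interior_energy <- function(model, l1, l2) {
  stopifnot(l1 >= 0, l2 >= 0, l1 + l2 >= 1)
  tot <- l1 + l2
  if (tot > model$max_interior) return(Inf)
  if (min(l1, l2) == 0L) {                       # bulge
    nb <- length(model$bulge_init)
    if (tot <= nb) model$bulge_init[tot]
    else model$bulge_init[nb] + model$loop_extrap * log(tot / nb)
  } else {                                       # internal loop
    ni <- length(model$internal_init)
    base <- if (tot <= ni + 1) model$internal_init[tot - 1L]
            else model$internal_init[ni] + model$loop_extrap * log(tot / (ni + 1))
    base + min(model$asym_max, model$asym_per_nt * abs(l1 - l2))
  }
}

#' Stacking energy of two adjacent base pairs
#'
#' @param model An [energy_model()].
#' @param outer,inner Pair type codes (1..6) of the outer pair (i,j) and the
#'   directly stacked inner pair (i+1, j-1).
#' @return Energy in kcal/mol.
#' @export
stack_energy <- function(model, outer, inner) {
  model$stack[outer, inner]
}

#' Encode an RNA string as integer base codes
#'
#' @param bases Character scalar over A/C/G/U.
#' @return Integer vector, A=1 C=2 G=3 U=4.
#' @keywords internal
encode_bases <- function(bases) {
  codes <- match(strsplit(bases, "", fixed = TRUE)[[1]], BASES)
  stopifnot(!anyNA(codes))
  codes
}

#' Pair type code of two base codes
#' @keywords internal
pair_code <- function(model, a, b) model$pair_table[a, b]

# Precompute the size-dependent tables the C++ engine consumes.
# Returns vectors indexed by loop size (hairpin: 1..n, interior: matrix
# (l1+1) x (l2+1) over 0..max_interior).
.model_tables <- function(model, n) {
  hp <- vapply(seq_len(max(n, model$min_hairpin)), function(l)
    hairpin_energy(model, l), numeric(1))
  ml <- model$max_interior
  il <- matrix(Inf, ml + 1L, ml + 1L)
  for (a in 0:ml) for (b in 0:ml) {
    if (a + b >= 1L && a + b <= ml) il[a + 1L, b + 1L] <- interior_energy(model, a, b)
  }
  list(hairpin = hp, interior = il)
}
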