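# Shared fixtures, all generated in code.

# random upper-triangular "probability" matrix (not normalized; the scans
# only assume nonnegative cell values)
rand_upper <- function(n, rng = NULL) {
  M <- matrix(stats::runif(n * n), n, n)
  M[lower.tri(M, diag = TRUE)] <- 0
  M
}

# a sequence with one strong planted hairpin; everything else is drawn from
# {A, C} so it cannot pair.  Returns the sequence plus the stem coordinates.
planted_hairpin_seq <- function(n = 150L, at = 60L) {
  bg <- sample(c("A", "C"), n, replace = TRUE)
  stem5 <- strsplit("GGCGGCGGCGGCG", "")[[1]]   # 13 nt
  loop  <- strsplit("AAAA", "")[[1]]
  stem3 <- strsplit("CGCCGCCGCCGCC", "")[[1]]   # reverse complement
  ins <- c(stem5, loop, stem3)
  bg[at:(at + length(ins) - 1L)] <- ins
  list(seq = rna_seq("planted", paste(bg, collapse = "")),
       stem = c(at, at + length(ins) - 1L),
       mid = at + 6L)   # a stem position whose change breaks pairing
}

# an energy model whose stack table is constant: fully symmetric, used for
# the sequence-reversal symmetry property
flat_stack_model <- function(value = -2) {
  m <- energy_model()
  m$stack[, ] <- value
  m$id <- "flat-stack"
  m
}

# quick one-cell background table for pipeline tests
tiny_table <- function(length_bin, gc = 0.5, n = 30L, params = run_params(),
                       seed = 99L) {
  build_background_table(length_bins = length_bin, gc_bins = gc, n = n,
                         params = params, seed = seed)
}
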