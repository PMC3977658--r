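# Mode runners on small sequences; background tables are deliberately tiny
# (the P-values only need to exist, except where calibration is the point).

test_that("the folding region follows the flank convention", {
  set.seed(91)
  s <- random_sequence(1000, 0.5)
  ms <- parse_mutation_spec(sprintf("%s300%s", substr(s$bases, 300, 300),
                                    setdiff(c("A", "C", "G", "U"),
                                            substr(s$bases, 300, 300))[1]))[[1]]
  fr <- extract_folding_region(s, ms, flank = 200)
  expect_equal(fr$region, c(100L, 500L))
  expect_equal(nchar(fr$subseq$bases), 401L)
  expect_equal(fr$offset, 99L)

  # flank >= n covers the whole sequence
  fr2 <- extract_folding_region(s, ms, flank = 2000)
  expect_equal(fr2$region, c(1L, 1000L))

  # compound mutants span all mutated positions
  lab <- sprintf("%s100%s-%s900%s",
                 substr(s$bases, 100, 100),
                 setdiff(c("A", "C", "G", "U"), substr(s$bases, 100, 100))[1],
                 substr(s$bases, 900, 900),
                 setdiff(c("A", "C", "G", "U"), substr(s$bases, 900, 900))[1])
  fr3 <- extract_folding_region(s, parse_mutation_spec(lab)[[1]], flank = 50)
  expect_equal(fr3$region, c(50L, 950L))

  expect_error(extract_folding_region(
    s, structure(list(mutations = list(), label = ""),
                 class = "mutation_set"), 200), "empty")
})

test_that("a mutation with no pairing potential scores zero with p = 1", {
  # an {A, C}-only sequence folds to the open chain in both alleles
  set.seed(97)
  bases <- paste(sample(c("A", "C"), 60, replace = TRUE), collapse = "")
  s <- rna_seq("flat", bases)
  ref <- substr(bases, 30, 30)
  alt <- if (ref == "A") "C" else "A"
  ms <- parse_mutation_spec(sprintf("%s30%s", ref, alt))[[1]]
  params <- run_params(mode = 1, min_len = 20, flank = 100)
  tab <- tiny_table(60, 0.5, n = 20, params = params)
  r <- run_mode1(s, ms, params, tab)
  expect_equal(r$score, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$fold_region, c(1L, 60L))
})

test_that("mode results respect the coordinate round-trip invariants", {
  set.seed(103)
  params <- run_params(mode = 1, min_len = 20, flank = 30)
  tab <- tiny_table(61, 0.5, n = 15, params = params)
  s <- random_sequence(120, 0.55)
  for (pos in c(10L, 60L, 115L)) {
    ref <- substr(s$bases, pos, pos)
    alt <- setdiff(c("A", "C", "G", "U"), ref)[1]
    ms <- parse_mutation_spec(sprintf("%s%d%s", ref, pos, alt))[[1]]
    r <- run_mode1(s, ms, params, tab)
    expect_true(r$fold_region[1] <= r$local_region[1])
    expect_true(r$local_region[1] <= r$local_region[2])
    expect_true(r$local_region[2] <= r$fold_region[2])
    expect_true(pos >= r$fold_region[1] && pos <= r$fold_region[2])
    expect_true(r$p_value > 0 && r$p_value <= 1)
  }
})

test_that("mode 2 localizes a planted disruptive substitution", {
  set.seed(107)
  px <- planted_hairpin_seq(n = 150, at = 60)
  ref <- substr(px$seq$bases, px$mid, px$mid)
  expect_equal(ref, "G")   # inside the stem by construction
  ms <- parse_mutation_spec(sprintf("G%dC", px$mid))[[1]]
  params <- run_params(mode = 2, min_len = 30, flank = 200,
                       window = 80, max_span = 60, fixed_len = 60)
  # the stratum only needs to exist (nearest-bin clamping); sample it with
  # the cheap global pipeline at a short length
  tab <- tiny_table(40, 0.4, n = 8, params = run_params(mode = 1,
                                                        min_len = 30),
                    seed = 3)
  r2 <- run_mode2(px$seq, ms, params, tab)
  expect_gt(r2$score, 0.5)   # a broken stem moves a lot of pairing mass
  expect_true(r2$local_region[1] <= px$mid && px$mid <= r2$local_region[2])

  # mode 1 on the same fixture flags the same neighborhood
  params1 <- run_params(mode = 1, min_len = 30, flank = 200)
  r1 <- run_mode1(px$seq, ms, params1, tab)
  expect_true(r1$local_region[1] <= px$mid && px$mid <= r1$local_region[2])
  ov <- min(r1$local_region[2], r2$local_region[2]) -
        max(r1$local_region[1], r2$local_region[1])
  expect_gt(ov, 0)
})

test_that("mode 3 with screen_cutoff = 1 equals mode 1 on every substitution", {
  set.seed(109)
  s <- random_sequence(30, 0.6)
  params <- run_params(mode = 1, min_len = 15, flank = 200,
                       screen_cutoff = 1, report_cutoff = 1)
  tab <- tiny_table(30, 0.6, n = 15, params = params, seed = 7)
  res <- run_mode3(s, params, tab)
  # every substitution with p < 1 is reported; cross-check a sample by
  # running mode 1 directly
  expect_true(length(res) <= 90)
  for (r in res[seq(1, length(res), length.out = min(5, length(res)))]) {
    ms <- parse_mutation_spec(r$mutation)[[1]]
    direct <- run_mode1(s, ms, params, tab)
    expect_equal(r$score, direct$score)
    expect_equal(r$p_value, direct$p_value)
    expect_equal(r$local_region, direct$local_region)
  }
  # sorted by p, then position
  ps <- vapply(res, `[[`, numeric(1), "p_value")
  expect_true(all(diff(ps) >= 0))
})

test_that("mode 3 output is deterministic and within contract bounds", {
  set.seed(113)
  s <- random_sequence(10, 0.6)
  params <- run_params(mode = 1, min_len = 5, screen_cutoff = 1,
                       report_cutoff = 1)
  tab <- tiny_table(10, 0.5, n = 10, params = params, seed = 13)
  r1 <- run_mode3(s, params, tab)
  r2 <- run_mode3(s, params, tab)
  expect_identical(results_to_df(r1), results_to_df(r2))
  expect_true(length(r1) <= 30)
  ps <- vapply(r1, `[[`, numeric(1), "p_value")
  expect_true(all(ps >= 1 / 11 & ps <= 1))
})
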