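test_that("FASTA records are normalized and ids taken from headers", {
  recs <- read_fasta(c(">x some description", "acgt"))
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$bases, "ACGU")

  recs <- read_fasta(c(">a", "AC", ">b", "GU"))
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("a", "b"))
  expect_equal(vapply(recs, `[[`, character(1), "bases"), c("AC", "GU"))
})

test_that("invalid characters are rejected with their position", {
  expect_error(read_fasta(c(">x", "ACGN")), "position 4")
  expect_error(rna_seq("y", "AC-GU"), "position 3")
  expect_error(read_fasta(c(">z", "")), "length >= 1")
})

test_that("mutation notation parses, formats and round-trips", {
  ms <- parse_mutation_spec("U22G")[[1]]
  expect_equal(ms$label, "U22G")
  expect_equal(ms$mutations[[1]], list(pos = 22L, ref = "U", alt = "G"))

  ms2 <- parse_mutation_spec("U22G-G14C")[[1]]
  expect_length(ms2$mutations, 2)
  expect_equal(vapply(ms2$mutations, `[[`, integer(1), "pos"), c(22L, 14L))
  expect_equal(ms2$label, "U22G-G14C")

  # several specs, comments, blank lines
  specs <- parse_mutation_spec("# two variants\nU22G\n\nU22G-G14C\n")
  expect_length(specs, 2)

  # round-trip parse(format(ms)) == ms for assorted labels
  for (lab in c("A1C", "G100U", "U22G-G14C", "C5A-A9G-G12U", "t3a")) {
    ms <- parse_mutation_spec(lab)[[1]]
    expect_identical(parse_mutation_spec(format_mutation_set(ms))[[1]], ms)
  }
})

test_that("malformed mutation specs are rejected", {
  expect_error(parse_mutation_spec("A5A"), "identical")
  expect_error(parse_mutation_spec("X5G"), "malformed")
  expect_error(parse_mutation_spec("U22"), "malformed")
  expect_error(parse_mutation_spec("U22G-U22C"), "duplicate")
})

test_that("mutations apply, check the reference, and invert", {
  s <- rna_seq("s", "AAUAA")
  out <- apply_mutations(s, parse_mutation_spec("U3G")[[1]])
  expect_equal(out$bases, "AAGAA")

  expect_error(apply_mutations(s, parse_mutation_spec("G3C")[[1]]),
               "position 3.*expected G.*found U")

  # involution: applying the swapped set restores the original
  set.seed(11)
  orig <- random_sequence(40, 0.5)
  ms <- parse_mutation_spec("A1G-C2U")[[1]]
  chars <- strsplit(orig$bases, "")[[1]]
  chars[1] <- "A"; chars[2] <- "C"
  orig <- rna_seq("s", paste(chars, collapse = ""))
  mut <- apply_mutations(orig, ms)
  inv <- .parse_one_spec("G1A-U2C")
  expect_equal(apply_mutations(mut, inv)$bases, orig$bases)
})

test_that("results TSV has the documented columns and formats", {
  f <- tempfile(fileext = ".tsv")
  write_results_tsv(list(), f)
  df <- read.delim(f)
  expect_equal(nrow(df), 0)
  expect_equal(names(df), c("seq_id", "mutation", "fold_start", "fold_end",
                            "region_start", "region_end", "measure", "score",
                            "p_value"))

  r <- snpfoldscan:::new_snp_effect_result(
    "FTL-like", "U22G", 1L, c(1L, 222L), c(15L, 64L), "distance",
    0.123456789, 0.0518, 22L)
  write_results_tsv(list(r), f)
  txt <- readLines(f)
  expect_match(txt[2], "\t1\t222\t15\t64\tdistance\t")
  expect_match(txt[2], "0\\.0518$")          # four-decimal P-value
  expect_match(txt[2], "0\\.123457")          # >= 4 significant digits
})

test_that("BED output follows the coordinate and score conventions", {
  r <- snpfoldscan:::new_snp_effect_result(
    "s", "A1C", 1L, c(1L, 100L), c(15L, 64L), "distance", 1.0, 1.0, 1L)
  org <- genomic_origin("hg19", "chr1", 101L, "+")
  f <- tempfile(fileext = ".bed")
  write_bed(list(r), org, f, n = 100L)
  bed <- read.table(f, sep = "\t")
  # SNP at sequence position 1, origin start 101 -> 0-based interval 100..101
  expect_equal(unlist(bed[1, 2:3]), c(100, 101), ignore_attr = TRUE)
  # local region 15-64, origin start S -> S+13 .. S+63
  expect_equal(unlist(bed[2, 2:3]), c(101 + 13, 101 + 63),
               ignore_attr = TRUE)
  # p = 1 -> score 0
  expect_equal(bed[, 5], c(0, 0))

  r$p_value <- 1e-9
  write_bed(list(r), org, f, n = 100L)
  expect_equal(read.table(f, sep = "\t")[, 5], c(1000, 1000))
})

test_that("BED intervals map back to sequence coordinates on both strands", {
  n <- 200L
  for (strand in c("+", "-")) {
    org <- genomic_origin("hg19", "chr2", 5000L, strand)
    r <- snpfoldscan:::new_snp_effect_result(
      "s", "A37C", 1L, c(1L, n), c(37L, 120L), "distance", 0.5, 0.2, 37L)
    f <- tempfile(fileext = ".bed")
    write_bed(list(r), org, f, n = n)
    gr <- rtracklayer::import(f)
    reg <- gr[2]
    # invert the genomic mapping
    if (strand == "+") {
      i <- GenomicRanges::start(reg) - org$start + 1L
      j <- GenomicRanges::end(reg) - org$start + 1L
    } else {
      i <- org$start + n - GenomicRanges::end(reg)
      j <- org$start + n - GenomicRanges::start(reg)
    }
    expect_equal(c(i, j), c(37L, 120L))
    expect_equal(as.character(GenomicRanges::strand(reg)), strand)
  }
})

test_that("dot-plot records mirror the matrices", {
  set.seed(21)
  P <- rand_upper(12)
  P[P < 0.5] <- 0          # make some structural sparsity
  f <- tempfile(fileext = ".tsv")

  df <- write_dotplot_records(P, P, path = f)
  expect_true(all(df$p_wt == df$p_mut))

  Z <- matrix(0, 12, 12)
  expect_equal(nrow(write_dotplot_records(Z, Z, path = f)), 0)

  # record count equals a direct recount of nonzero cells in the region
  Q <- rand_upper(12); Q[Q < 0.6] <- 0
  region <- c(3L, 9L)
  df <- write_dotplot_records(P, Q, region, f)
  cnt <- 0
  for (i in 3:9) for (j in 3:9) if (j > i && max(P[i, j], Q[i, j]) > 1e-8)
    cnt <- cnt + 1
  expect_equal(nrow(df), cnt)

  expect_error(write_dotplot_records(P, matrix(0, 5, 5), path = f), "size")
})
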