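# Sequence input, mutation notation, and all standard-format writers
# (results TSV, BED6 genome-browser tracks, dot-plot records).

#' RNA sequence object
#'
#' A normalized RNA sequence: uppercase A/C/G/U (DNA T is converted to U on
#' input), with an optional genomic origin used for BED export.
#'
#' @param id Sequence identifier.
#' @param bases Sequence string; T/t accepted and converted to U.
#' @param origin Optional genomic locus: a list with `assembly`, `chrom`,
#'   `start` (1-based genomic position of sequence position 1 on the plus
#'   strand, or of the 3'-most genomic base for minus-strand loci) and
#'   `strand` ("+" or "-").  See [genomic_origin()].
#' @return An object of class `rna_seq`.
#' @examples
#' s <- rna_seq("x", "acgt")
#' s$bases
#' @export
rna_seq <- function(id, bases, origin = NULL) {
  norm <- normalize_bases(bases)
  if (nchar(norm) < 1L) stop("sequence must have length >= 1")
  structure(list(id = as.character(id), bases = norm, origin = origin),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  n <- nchar(x$bases)
  cat(sprintf("<rna_seq> %s (%d nt)\n", x$id, n))
  show <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(" ", show, "\n")
  if (!is.null(x$origin))
    cat(sprintf("  origin: %s %s:%d (%s)\n", x$origin$assembly,
                x$origin$chrom, x$origin$start, x$origin$strand))
  invisible(x)
}

#' @export
length.rna_seq <- function(x) nchar(x$bases)

#' Genomic origin of a sequence
#'
#' @param assembly Assembly identifier (e.g. "hg19").
#' @param chrom Chromosome name.
#' @param start 1-based genomic coordinate of the first sequence position
#'   (plus strand) or such that sequence position p maps to
#'   `start + n - p` on the minus strand.
#' @param strand "+" or "-".
#' @return A list of class `genomic_origin`.
#' @export
genomic_origin <- function(assembly, chrom, start, strand = "+") {
  stopifnot(strand %in% c("+", "-"), start >= 1)
  structure(list(assembly = assembly, chrom = chrom,
                 start = as.integer(start), strand = strand),
            class = "genomic_origin")
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U.  Any character outside A/C/G/U/T (either
#' case) is an error reporting the position of the first offender.
#'
#' @param bases Character scalar.
#' @return Normalized string over A/C/G/U.
#' @export
normalize_bases <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  up <- chartr("acgut", "ACGUT", bases)
  bad <- regexpr("[^ACGUT]", up)
  if (bad > 0)
    stop(sprintf("invalid character '%s' at position %d (allowed: A/C/G/U/T)",
                 substr(up, bad, bad), bad))
  chartr("T", "U", up)
}

#' Read RNA (or DNA) sequences from a FASTA file
#'
#' Records are normalized (uppercased, T converted to U); the record id is
#' the first whitespace-delimited token of the header line.
#'
#' @param input Path to a FASTA file, or a character vector of FASTA lines.
#' @return List of [rna_seq()] objects.
#' @export
read_fasta <- function(input) {
  path <- input
  if (length(input) > 1L || grepl("\n", input[1]) || grepl("^>", input[1])) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(input, "\n", fixed = TRUE)), path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found")
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    out[[k]] <- tryCatch(rna_seq(ids[k], as.character(set[[k]])),
                         error = function(e)
                           stop(sprintf("record '%s': %s", ids[k],
                                        conditionMessage(e)), call. = FALSE))
  }
  out
}

# ------------------------------------------------------------ mutations --

#' Parse compact mutation notation
#'
#' One specification per line; each line is one mutant.  A single
#' substitution is written `RefPosAlt` (e.g. `"U22G"`); a compound mutant
#' joins several substitutions with hyphens (e.g. `"U22G-G14C"`, a double
#' mutant applied jointly).  Lines starting with `#` and blank lines are
#' ignored.
#'
#' @param text Character vector of lines (or one string with embedded
#'   newlines).
#' @return List of `mutation_set` objects, each with fields `mutations`
#'   (list of `list(pos, ref, alt)`) and `label`.
#' @examples
#' ms <- parse_mutation_spec("U22G-G14C")[[1]]
#' ms$label
#' @export
parse_mutation_spec <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no mutation specifications found")
  lapply(lines, .parse_one_spec)
}

.parse_one_spec <- function(spec) {
  tokens <- strsplit(spec, "-", fixed = TRUE)[[1]]
  muts <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([ACGUTacgut])([0-9]+)([ACGUTacgut])$", tok))[[1]]
    if (length(m) != 4L)
      stop(sprintf("malformed mutation token '%s' (expected e.g. U22G)", tok))
    ref <- chartr("acgutT", "ACGUUU", m[2])
    alt <- chartr("acgutT", "ACGUUU", m[4])
    pos <- as.integer(m[3])
    if (pos < 1L) stop(sprintf("non-positive position in '%s'", tok))
    if (ref == alt)
      stop(sprintf("'%s': reference and alternative base are identical", tok))
    list(pos = pos, ref = ref, alt = alt)
  })
  pos <- vapply(muts, `[[`, integer(1), "pos")
  if (anyDuplicated(pos))
    stop(sprintf("'%s': duplicate positions in compound mutant", spec))
  structure(list(mutations = muts, label = format_mutation_set(muts)),
            class = "mutation_set")
}

#' Canonical label of a mutation set
#' @param mutations List of `list(pos, ref, alt)`.
#' @return Compact hyphen-joined label, e.g. `"U22G-G14C"`.
#' @export
format_mutation_set <- function(mutations) {
  if (inherits(mutations, "mutation_set")) mutations <- mutations$mutations
  paste(vapply(mutations, function(m) sprintf("%s%d%s", m$ref, m$pos, m$alt),
               character(1)), collapse = "-")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("<mutation_set> %s (%d substitution%s)\n", x$label,
              length(x$mutations), if (length(x$mutations) > 1) "s" else ""))
  invisible(x)
}

#' Apply a mutation set to a sequence
#'
#' @param seq An [rna_seq()] object.
#' @param ms A `mutation_set` from [parse_mutation_spec()].
#' @return A new `rna_seq` differing from `seq` exactly at the mutated
#'   positions; every reference base is checked against the sequence first.
#' @export
apply_mutations <- function(seq, ms) {
  stopifnot(inherits(seq, "rna_seq"), inherits(ms, "mutation_set"))
  chars <- strsplit(seq$bases, "", fixed = TRUE)[[1]]
  for (m in ms$mutations) {
    if (m$pos > length(chars))
      stop(sprintf("position %d beyond sequence length %d", m$pos,
                   length(chars)))
    if (chars[m$pos] != m$ref)
      stop(sprintf("reference mismatch at position %d: expected %s, found %s",
                   m$pos, m$ref, chars[m$pos]))
    chars[m$pos] <- m$alt
  }
  rna_seq(seq$id, paste(chars, collapse = ""), origin = seq$origin)
}

# -------------------------------------------------------------- writers --

#' Write a results table as TSV
#'
#' One row per mutant: sequence id, mutation label, folding region, predicted
#' local region (all 1-based inclusive, original sequence coordinates), the
#' comparison measure, its score (>= 4 significant digits) and the empirical
#' P-value (4 decimals).
#'
#' @param results List of `snp_effect_result` objects (or a single one).
#' @param path Output file path or connection.
#' @export
write_results_tsv <- function(results, path) {
  df <- results_to_df(results)
  df$score <- vapply(df$score, function(s) format(signif(s, 6)), character(1))
  df$p_value <- sprintf("%.4f", df$p_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Convert results to a data frame
#' @param results List of `snp_effect_result` objects.
#' @return data.frame with one row per result.
#' @export
results_to_df <- function(results) {
  if (inherits(results, "snp_effect_result")) results <- list(results)
  cols <- data.frame(seq_id = character(0), mutation = character(0),
                     fold_start = integer(0), fold_end = integer(0),
                     region_start = integer(0), region_end = integer(0),
                     measure = character(0), score = numeric(0),
                     p_value = numeric(0), stringsAsFactors = FALSE)
  if (!length(results)) return(cols)
  do.call(rbind, lapply(results, function(r)
    data.frame(seq_id = r$seq_id, mutation = r$mutation,
               fold_start = r$fold_region[1], fold_end = r$fold_region[2],
               region_start = r$local_region[1],
               region_end = r$local_region[2],
               measure = r$measure, score = r$score, p_value = r$p_value,
               stringsAsFactors = FALSE)))
}

#' Map sequence positions to 1-based genomic coordinates
#' @keywords internal
.to_genomic <- function(origin, n, i, j) {
  if (origin$strand == "+") c(origin$start + i - 1L, origin$start + j - 1L)
  else c(origin$start + n - j, origin$start + n - i)
}

#' Write results as a BED6 genome-browser track
#'
#' Two features per result: the mutated position(s) (1 bp each) and the
#' predicted local region.  The BED score is `round(1000 * (1 - p))` clamped
#' to 0..1000, so strong structure-disruption lights up dark.  Minus-strand
#' loci are mirrored onto genome coordinates.
#'
#' @param results List of `snp_effect_result` objects.
#' @param origin A [genomic_origin()]; required.
#' @param path Output BED path.
#' @param n Length of the original sequence (needed for minus-strand
#'   mapping).
#' @export
write_bed <- function(results, origin, path, n) {
  if (is.null(origin)) stop("a genomic origin is required for BED output")
  if (inherits(results, "snp_effect_result")) results <- list(results)
  feats <- list()
  for (r in results) {
    sc <- max(0L, min(1000L, as.integer(round(1000 * (1 - r$p_value)))))
    for (m in r$mut_positions) {
      g <- .to_genomic(origin, n, m, m)
      feats[[length(feats) + 1L]] <-
        list(start = g[1], end = g[2], name = paste0(r$mutation, "_snp"),
             score = sc)
    }
    g <- .to_genomic(origin, n, r$local_region[1], r$local_region[2])
    feats[[length(feats) + 1L]] <-
      list(start = g[1], end = g[2], name = paste0(r$mutation, "_region"),
           score = sc)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = origin$chrom,
    ranges = IRanges::IRanges(
      start = vapply(feats, `[[`, numeric(1), "start"),
      end = vapply(feats, `[[`, numeric(1), "end")),
    strand = origin$strand,
    name = vapply(feats, `[[`, character(1), "name"),
    score = vapply(feats, `[[`, numeric(1), "score"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(NULL)
}

#' Write dot-plot records comparing wild-type and mutant ensembles
#'
#' TSV of `(i, j, p_wt, p_mut)` for every pair inside the region where
#' either allele has probability above the output floor (1e-8); suitable for
#' rendering the conventional upper-triangle (wild-type) / lower-triangle
#' (mutant) dot plot.
#'
#' @param P_wt,P_mut Pair-probability matrices of identical size.
#' @param region Integer vector `c(start, end)` restricting the records
#'   (defaults to the whole matrix).
#' @param path Output TSV path or connection.
#' @return Invisibly, the data frame written.
#' @export
write_dotplot_records <- function(P_wt, P_mut, region = NULL, path) {
  if (!all(dim(P_wt) == dim(P_mut)))
    stop("wild-type and mutant matrices differ in size")
  n <- nrow(P_wt)
  if (is.null(region)) region <- c(1L, n)
  stopifnot(region[1] >= 1, region[2] <= n, region[1] <= region[2])
  idx <- which(upper.tri(P_wt) & (pmax(P_wt, P_mut) > 1e-8), arr.ind = TRUE)
  keep <- idx[, 1] >= region[1] & idx[, 2] <= region[2]
  idx <- idx[keep, , drop = FALSE]
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   p_wt = P_wt[idx], p_mut = P_mut[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
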