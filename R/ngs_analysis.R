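# Sequencing analysis: paired-read exact-consensus filtering, global
# (end-to-end) edit alignment against the panel references, error
# classification, purity statistics, relative-concentration normalization
# against a reference library, and Gini/Lorenz inequality summaries.

#' Exact-consensus filter for overlapped paired reads
#'
#' Keeps a pair only when the forward read equals the reverse complement of
#' the reverse read over the full overlapped region; intrinsic sequencing
#' errors almost never strike both mates identically, so surviving
#' consensus sequences reflect the molecule. Length-discordant pairs are
#' discarded and counted separately.
#'
#' @param mate1,mate2 character vectors of equal length (trimmed reads).
#' @return list: `consensus` (kept sequences), `kept`, `discarded`,
#'   `length_discordant`.
#' @export
consensus_filter <- function(mate1, mate2) {
  if (length(mate1) != length(mate2)) {
    stop("mate vectors must have the same number of reads")
  }
  if (!length(mate1)) {
    return(list(consensus = character(0), kept = 0L, discarded = 0L,
                length_discordant = 0L))
  }
  len_ok <- nchar(mate1) == nchar(mate2)
  rc2 <- rep(NA_character_, length(mate2))
  rc2[len_ok] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(mate2[len_ok])))
  agree <- len_ok & mate1 == rc2
  list(consensus = mate1[agree],
       kept = sum(agree),
       discarded = sum(len_ok & !agree),
       length_discordant = sum(!len_ok))
}

#' Read a paired FASTQ run
#'
#' @param r1_path,r2_path FASTQ paths (gzip accepted).
#' @return list of two character vectors `r1`, `r2` and the read ids.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  list(r1 = as.character(r1), r2 = as.character(r2), ids = names(r1))
}

#' Globally align reads against the panel references
#'
#' End-to-end unit-cost edit alignment (matches free; substitutions and
#' single-base gaps cost 1) of every read against every reference. The
#' best reference is the one with minimum cost; ties go to the lowest
#' reference index with the `ambiguous` flag set. Reads whose best cost
#' exceeds `max_cost` are reported unaligned (`reference_id` NA), a result
#' rather than an error. Identical read sequences are aligned once.
#'
#' @param reads character vector of consensus reads.
#' @param references named character vector of product reference sequences.
#' @param max_cost maximum edit cost for a read to count as aligned.
#'   Default 25.
#' @return data.frame: `read`, `reference_id`, `cost`, `ambiguous`.
#' @export
align_reads <- function(reads, references, max_cost = 25) {
  if (!length(reads) || !length(references)) {
    stop("reads and references must be non-empty")
  }
  uniq <- unique(reads)
  res <- align_batch_cpp(uniq, unname(references), as.integer(max_cost))
  ref_id <- ifelse(res$ref == 0, NA_character_, names(references)[res$ref])
  map <- match(reads, uniq)
  data.frame(read = reads, reference_id = ref_id[map],
             cost = res$cost[map], ambiguous = res$ambiguous[map],
             stringsAsFactors = FALSE)
}

#' Align one read and recover its edit operations
#'
#' Same scoring as [align_reads()], returning the full operation list for
#' the best reference: runs of `match`, `sub`, `del` (reference bases
#' absent from the read), `ins` (read bases absent from the reference),
#' with 1-based reference start positions.
#'
#' @param read a single read sequence.
#' @param references named character vector of references.
#' @param max_cost unaligned threshold.
#' @return list: `reference_id` (NA if unaligned), `cost`, `ambiguous`,
#'   `edit_ops` data.frame (`op`, `ref_pos`, `length`), `n_errors`.
#' @export
align_read <- function(read, references, max_cost = 25) {
  hit <- align_reads(read, references, max_cost)
  if (is.na(hit$reference_id)) {
    return(list(reference_id = NA_character_, cost = hit$cost,
                ambiguous = FALSE, edit_ops = NULL, n_errors = NA_integer_))
  }
  aln <- nw_align_cpp(read, references[[hit$reference_id]])
  ops <- data.frame(op = c("match", "sub", "del", "ins")[aln$op + 1L],
                    ref_pos = aln$ref_pos, length = aln$length,
                    stringsAsFactors = FALSE)
  list(reference_id = hit$reference_id, cost = aln$cost,
       ambiguous = hit$ambiguous, edit_ops = ops,
       n_errors = sum(ops$length[ops$op != "match"]))
}

#' Classify an aligned read's errors
#'
#' `perfect` when there are no non-match operations. `trunc5` when the only
#' non-matches are a single deletion run starting at reference position 1
#' (a lost 5' prefix). Single-run internal `deletion`, `insertion`, or
#' `substitution` otherwise keep their own category; anything else is
#' `mixed`. `size` is the total number of affected nucleotides and the
#' `gross` flag marks `size >= gross_threshold` (default 6, the "6+" bin).
#'
#' @param edit_ops data.frame from [align_read()].
#' @param gross_threshold nucleotides affected at which an error is gross.
#' @return list: `category`, `size`, `gross`.
#' @export
classify_errors <- function(edit_ops, gross_threshold = 6) {
  err <- edit_ops[edit_ops$op != "match", , drop = FALSE]
  size <- sum(err$length)
  if (size == 0) {
    return(list(category = "perfect", size = 0L, gross = FALSE))
  }
  category <- if (nrow(err) == 1L) {
    if (err$op == "del" && err$ref_pos == 1L) "trunc5"
    else switch(err$op, del = "deletion", ins = "insertion",
                sub = "substitution")
  } else "mixed"
  list(category = category, size = as.integer(size),
       gross = size >= gross_threshold)
}

#' Per-oligo purity report
#'
#' Purity is the number of reads perfectly matching the designed sequence
#' divided by the number of reads aligning to it. The gross-excluded
#' variant removes reads with `gross_threshold` or more affected
#' nucleotides from the denominator (such reads are dominated by library
#' artifacts rather than synthesis quality). Also reports the error-class
#' histogram binned by category and size 1..5 and 6+.
#'
#' @param alignments data.frame from [align_reads()] (column
#'   `reference_id`; unaligned rows NA).
#' @param references named character vector of panel references.
#' @param gross_threshold size at which an error is gross. Default 6.
#' @param max_cost passed through to per-read op recovery.
#' @return list of class `snop_purity`: `per_oligo` data.frame
#'   (`oligo_id`, `aligned_reads`, `perfect_reads`, `gross_reads`,
#'   `purity`, `purity_excluding_gross`), `class_histogram` (counts by
#'   oligo, category, size bin), `median_purity`,
#'   `median_purity_excluding_gross`.
#' @export
purity_stats <- function(alignments, references, gross_threshold = 6,
                         max_cost = 25) {
  aligned <- alignments[!is.na(alignments$reference_id), , drop = FALSE]
  # classify unique (read, reference) pairs once
  key <- paste(aligned$read, aligned$reference_id, sep = "\r")
  uk <- !duplicated(key)
  cls <- vector("list", sum(uk))
  urows <- which(uk)
  for (i in seq_along(urows)) {
    r <- urows[i]
    if (aligned$read[r] == references[[aligned$reference_id[r]]]) {
      cls[[i]] <- list(category = "perfect", size = 0L, gross = FALSE)
    } else {
      aln <- nw_align_cpp(aligned$read[r],
                          references[[aligned$reference_id[r]]])
      ops <- data.frame(op = c("match", "sub", "del", "ins")[aln$op + 1L],
                        ref_pos = aln$ref_pos, length = aln$length,
                        stringsAsFactors = FALSE)
      cls[[i]] <- classify_errors(ops, gross_threshold)
    }
  }
  lut <- match(key, key[uk])
  category <- vapply(cls, `[[`, character(1), "category")[lut]
  size <- vapply(cls, `[[`, integer(1), "size")[lut]
  gross <- vapply(cls, `[[`, logical(1), "gross")[lut]

  ids <- names(references)
  per <- lapply(ids, function(id) {
    sel <- aligned$reference_id == id
    n_al <- sum(sel)
    n_perf <- sum(sel & category == "perfect")
    n_gross <- sum(sel & gross)
    data.frame(oligo_id = id, aligned_reads = n_al, perfect_reads = n_perf,
               gross_reads = n_gross,
               purity = if (n_al > 0) n_perf / n_al else NA_real_,
               purity_excluding_gross = if (n_al - n_gross > 0) {
                 n_perf / (n_al - n_gross)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  size_bin <- ifelse(size >= gross_threshold,
                     paste0(gross_threshold, "+"), as.character(size))
  hist <- as.data.frame(table(oligo_id = aligned$reference_id,
                              category = category, size = size_bin),
                        stringsAsFactors = FALSE)
  hist <- hist[hist$Freq > 0, , drop = FALSE]
  names(hist)[4] <- "count"
  structure(list(per_oligo = per, class_histogram = hist,
                 median_purity = stats::median(per$purity, na.rm = TRUE),
                 median_purity_excluding_gross =
                   stats::median(per$purity_excluding_gross, na.rm = TRUE)),
            class = "snop_purity")
}

#' Relative concentrations against a reference library
#'
#' Per-oligo aligned read counts are divided by the counts of the same
#' oligos in a reference library sequenced from a nominally equimolar pool
#' (cancelling ligation and flow-cell biases), giving nominal
#' concentrations up to a common scaling constant that is fixed at 1; the
#' nominal values are then divided by their median so the panel median
#' relative concentration is 1 (exactly, for an odd number of oligos).
#'
#' @param counts named vector of aligned read counts in the library of
#'   interest.
#' @param reference_counts named vector of aligned read counts in the
#'   reference library; oligos with zero reference counts are excluded
#'   with a warning.
#' @return list of class `snop_concentration`: `per_oligo` data.frame
#'   (`oligo_id`, `reads`, `reference_reads`, `nominal`, `rel_conc`),
#'   `frac_within_2fold` (relative concentration in \[0.5, 2\]), `gini`,
#'   `lorenz` (cumulative-share points), `excluded` oligo ids.
#' @export
relative_concentrations <- function(counts, reference_counts) {
  ids <- intersect(names(counts), names(reference_counts))
  if (!length(ids)) stop("no shared oligo ids between count vectors")
  ref <- as.numeric(reference_counts[ids])
  excluded <- ids[ref <= 0]
  if (length(excluded)) {
    warning("excluding oligos with zero reference counts: ",
            paste(excluded, collapse = ", "))
  }
  keep <- ids[ref > 0]
  nominal <- as.numeric(counts[keep]) / as.numeric(reference_counts[keep])
  rel <- nominal / stats::median(nominal)
  gl <- gini_lorenz(rel)
  structure(list(
    per_oligo = data.frame(oligo_id = keep,
                           reads = as.numeric(counts[keep]),
                           reference_reads = as.numeric(
                             reference_counts[keep]),
                           nominal = nominal, rel_conc = rel,
                           stringsAsFactors = FALSE),
    frac_within_2fold = mean(rel >= 0.5 & rel <= 2),
    gini = gl$gini, lorenz = gl$lorenz, excluded = excluded),
    class = "snop_concentration")
}

#' Gini coefficient and Lorenz curve
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`: 0 for a perfectly uniform
#' vector, `(n - 1) / n` when a single species holds everything. The
#' Lorenz curve gives the cumulative share of the total held by the
#' poorest `k/n` fraction, from (0, 0) to (1, 1).
#'
#' @param values non-negative vector, not all zero.
#' @return list: `gini`, `lorenz` data.frame (`frac_species`,
#'   `cum_share`).
#' @export
gini_lorenz <- function(values) {
  x <- as.numeric(values)
  if (!length(x) || any(!is.finite(x)) || any(x < 0) || sum(x) == 0) {
    stop("values must be non-negative, finite, and not all zero")
  }
  n <- length(x)
  xs <- sort(x)
  # equivalent O(n log n) form of the pairwise-difference definition
  gini <- sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
  lorenz <- data.frame(frac_species = c(0, seq_len(n)) / n,
                       cum_share = c(0, cumsum(xs)) / sum(xs))
  list(gini = gini, lorenz = lorenz)
}

#' Full read-level analysis of a sequencing run
#'
#' Consensus-filters the mate pairs, aligns the surviving consensus reads
#' end-to-end against the panel, computes the purity report and, when a
#' reference-library count table is supplied, the relative-concentration
#' report.
#'
#' @param r1,r2 character vectors of mate sequences (or use
#'   [read_fastq_pair()] first).
#' @param references named character vector of product references.
#' @param reference_counts optional named vector of aligned counts from
#'   the reference (equimolar) library.
#' @param max_cost unaligned threshold (edit operations). Default 25.
#' @param gross_threshold gross error size. Default 6.
#' @return list of class `snop_analysis`: `filter` (consensus counts),
#'   `alignments`, `purity` ([purity_stats()] result), `counts` (aligned
#'   reads per oligo), `concentration` (NULL without `reference_counts`).
#' @export
analyze_reads <- function(r1, r2, references, reference_counts = NULL,
                          max_cost = 25, gross_threshold = 6) {
  flt <- consensus_filter(r1, r2)
  if (!flt$kept) stop("no read pairs survived the consensus filter")
  al <- align_reads(flt$consensus, references, max_cost)
  pur <- purity_stats(al, references, gross_threshold, max_cost)
  counts <- table(factor(al$reference_id, levels = names(references)))
  counts <- stats::setNames(as.numeric(counts), names(references))
  conc <- if (!is.null(reference_counts)) {
    relative_concentrations(counts, reference_counts)
  }
  structure(list(filter = flt[c("kept", "discarded", "length_discordant")],
                 alignments = al, purity = pur, counts = counts,
                 concentration = conc),
            class = "snop_analysis")
}
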