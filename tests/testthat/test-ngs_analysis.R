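test_that("consensus filter keeps only perfectly agreeing overlapped pairs", {
  s <- rand_dna(30)
  good2 <- revcomp(s)
  bad2 <- good2
  substr(bad2, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                  substr(bad2, 12, 12))[1]
  flt <- consensus_filter(c(s, s, s), c(good2, bad2, revcomp(rand_dna(28))))
  expect_equal(flt$kept, 1L)
  expect_equal(flt$discarded, 1L)
  expect_equal(flt$length_discordant, 1L)
  expect_identical(flt$consensus, s)
  empty <- consensus_filter(character(0), character(0))
  expect_equal(empty$kept, 0L)
  expect_length(empty$consensus, 0)
  expect_error(consensus_filter("A", c("T", "T")), "same number")
})

test_that("consensus retention matches the independent-error expectation", {
  set.seed(8)
  s <- rand_dna(70)
  prods <- data.frame(oligo_id = "x", sequence = s)
  e <- 0.002; n <- 20000
  rd <- emit_reads(prods, n, seq_error_rate = e, seed = 3)
  flt <- consensus_filter(rd$r1, rd$r2)
  expected <- (1 - e)^(2 * 70)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(flt$kept / n - expected), 3 * se + 5e-4)
})

test_that("alignment recovers identity, single deletions, and flags ties", {
  refs <- c(a = "ACGTGCATTGCA", b = "GGATCCGTATGC")
  hit <- align_read(refs[["a"]], refs)
  expect_equal(hit$reference_id, "a")
  expect_equal(hit$cost, 0)
  expect_equal(hit$n_errors, 0L)
  # remove one internal base with unambiguous placement
  read <- paste0(substr(refs[["a"]], 1, 3), substr(refs[["a"]], 5, 12))
  hit <- align_read(read, refs)
  expect_equal(hit$reference_id, "a")
  ops <- hit$edit_ops[hit$edit_ops$op != "match", ]
  expect_equal(ops$op, "del")
  expect_equal(ops$ref_pos, 4L)
  expect_equal(ops$length, 1L)
  # equidistant read: lowest reference index wins, ambiguity flagged
  refs2 <- c(x = "ACGTACGT", y = "ACGTACGA")
  h <- align_reads("ACGTACGC", refs2)
  expect_equal(h$reference_id, "x")
  expect_true(h$ambiguous)
  # cost above max_cost reports unaligned
  h2 <- align_reads(strrep("T", 60), c(r = strrep("A", 60)), max_cost = 25)
  expect_true(is.na(h2$reference_id))
  expect_error(align_reads(character(0), refs), "non-empty")
})

test_that("alignment cost equals the brute-force edit-distance oracle", {
  set.seed(55)
  for (i in 1:200) {
    ref <- rand_dna(sample(40:80, 1))
    read <- mutate_seq(ref, sample(0:6, 1))
    aln <- align_read(read, c(r = ref), max_cost = 100)
    oracle <- as.integer(utils::adist(read, ref))
    expect_identical(as.integer(aln$cost), oracle)
    # ops reconstruct the read from the reference
    expect_identical(aln$n_errors,
                     sum(aln$edit_ops$length[aln$edit_ops$op != "match"]))
  }
})

test_that("error classes follow the truncation/deletion/gross rules", {
  ref <- "ATATGCGTTACGGTCAAT"
  refs <- c(r = ref)
  cls <- function(read) {
    classify_errors(align_read(read, refs)$edit_ops)
  }
  expect_equal(cls(ref)$category, "perfect")
  expect_equal(cls(ref)$size, 0L)
  # 2 nt 5' truncation
  c2 <- cls(substr(ref, 3, nchar(ref)))
  expect_equal(c2$category, "trunc5")
  expect_equal(c2$size, 2L)
  expect_false(c2$gross)
  # single internal deletion
  cd <- cls(paste0(substr(ref, 1, 4), substr(ref, 6, nchar(ref))))
  expect_equal(cd$category, "deletion")
  expect_equal(cd$size, 1L)
  # single substitution
  sub <- ref; substr(sub, 8, 8) <- "A"
  expect_equal(cls(sub)$category, "substitution")
  # insertion
  ins <- paste0(substr(ref, 1, 9), "C", substr(ref, 10, nchar(ref)))
  expect_equal(cls(ins)$category, "insertion")
  # 7 scattered substitutions: mixed and gross
  many <- strsplit(ref, "")[[1]]
  pos <- c(1, 4, 6, 9, 12, 15, 18)
  for (p in pos) many[p] <- setdiff(c("A", "C", "G", "T"), many[p])[1]
  cm <- cls(paste(many, collapse = ""))
  expect_equal(cm$category, "mixed")
  expect_true(cm$gross)
  expect_gte(cm$size, 6L)
})

test_that("purity statistics implement perfect-over-aligned with gross exclusion", {
  refs <- c(o1 = "ACGTGCATTGCAGGTCAATC")
  perfect <- refs[["o1"]]
  del1 <- paste0(substr(perfect, 1, 9), substr(perfect, 11, 20))
  gross <- paste0(substr(perfect, 8, 20))  # 7 nt truncation
  al <- align_reads(c(rep(perfect, 3), gross, del1), refs)
  ps <- purity_stats(al, refs)
  row <- ps$per_oligo[ps$per_oligo$oligo_id == "o1", ]
  expect_equal(row$aligned_reads, 5)
  expect_equal(row$purity, 0.6)
  expect_equal(row$purity_excluding_gross, 0.75)
  expect_gte(row$purity_excluding_gross, row$purity)
  # histogram counts sum to aligned reads
  expect_equal(sum(ps$class_histogram$count), 5)
  # 3 perfect + 1 single-deletion = 0.75; all-perfect = 1
  ps2 <- purity_stats(align_reads(c(rep(perfect, 3), del1), refs), refs)
  expect_equal(ps2$per_oligo$purity, 0.75)
  ps3 <- purity_stats(align_reads(rep(perfect, 4), refs), refs)
  expect_equal(ps3$per_oligo$purity, 1)
  # an oligo with no aligned reads is reported missing, excluded from median
  refs2 <- c(refs, o2 = rand_dna(20))
  ps4 <- purity_stats(align_reads(rep(perfect, 2), refs2), refs2)
  expect_true(is.na(ps4$per_oligo$purity[ps4$per_oligo$oligo_id == "o2"]))
  expect_equal(ps4$median_purity, 1)
})

test_that("relative concentrations follow the reference-normalized median rule", {
  rc <- relative_concentrations(c(a = 10, b = 20, c = 40),
                                c(a = 10, b = 10, c = 10))
  expect_equal(rc$per_oligo$nominal, c(1, 2, 4))
  expect_equal(rc$per_oligo$rel_conc, c(0.5, 1, 2))
  expect_equal(rc$frac_within_2fold, 1)
  # identical counts: everything at relative concentration 1
  rc2 <- relative_concentrations(c(a = 7, b = 7), c(a = 7, b = 7))
  expect_true(all(rc2$per_oligo$rel_conc == 1))
  # median of relative concentrations is exactly 1 for odd panel sizes
  set.seed(2)
  counts <- setNames(rpois(9, 100) + 1, letters[1:9])
  refs <- setNames(rpois(9, 100) + 1, letters[1:9])
  rc3 <- relative_concentrations(counts, refs)
  expect_equal(median(rc3$per_oligo$rel_conc), 1)
  # zero reference counts are excluded with a warning
  expect_warning(
    rc4 <- relative_concentrations(c(a = 5, b = 5), c(a = 5, b = 0)),
    "zero reference")
  expect_identical(rc4$excluded, "b")
})

test_that("Gini and Lorenz behave like inequality measures", {
  expect_equal(gini_lorenz(rep(3, 10))$gini, 0)
  expect_equal(gini_lorenz(c(1, 0, 0, 0))$gini, 0.75)
  set.seed(14)
  x <- rgamma(20, 2)
  g <- gini_lorenz(x)
  expect_equal(gini_lorenz(7.3 * x)$gini, g$gini, tolerance = 1e-12)
  # matches the O(n^2) pairwise-difference definition
  pairwise <- sum(abs(outer(x, x, "-"))) / (2 * length(x)^2 * mean(x))
  expect_equal(g$gini, pairwise, tolerance = 1e-12)
  # Lorenz: starts (0,0), ends (1,1), convex nondecreasing
  expect_equal(g$lorenz$cum_share[1], 0)
  expect_equal(tail(g$lorenz$cum_share, 1), 1)
  expect_true(all(diff(g$lorenz$cum_share) >= 0))
  expect_true(all(diff(diff(g$lorenz$cum_share)) >= -1e-12))
  # transfer principle: moving mass from poorest to richest raises G
  y <- sort(x)
  y[1] <- y[1] - 0.1; y[length(y)] <- y[length(y)] + 0.1
  expect_gt(gini_lorenz(y)$gini, g$gini)
  expect_error(gini_lorenz(rep(0, 3)), "not all zero")
  expect_error(gini_lorenz(c(1, -1)), "non-negative")
})

test_that("relative concentrations round-trip known sampling weights", {
  set.seed(33)
  panel <- random_panel(4, 50, seed = 33)
  weights <- c(1, 2, 4, 8)
  pool <- data.frame(
    oligo_id = rep(names(panel), weights),
    sequence = rep(unname(panel), weights), stringsAsFactors = FALSE)
  ref_pool <- data.frame(oligo_id = names(panel),
                         sequence = unname(panel),
                         stringsAsFactors = FALSE)
  n <- 40000
  rd <- emit_reads(pool, n, 0, seed = 9)
  ref_rd <- emit_reads(ref_pool, n, 0, seed = 10)
  counts <- table(factor(rd$oligo_id, levels = names(panel)))
  refc <- table(factor(ref_rd$oligo_id, levels = names(panel)))
  rc <- relative_concentrations(setNames(as.numeric(counts), names(panel)),
                                setNames(as.numeric(refc), names(panel)))
  expected <- weights / median(weights)
  for (i in seq_along(weights)) {
    tol <- 5 * expected[i] * sqrt(1 / counts[i] + 1 / refc[i])
    expect_lt(abs(rc$per_oligo$rel_conc[i] - expected[i]), tol)
  }
})

test_that("analyze_reads stitches filtering, alignment, purity, and concentrations", {
  panel <- random_panel(3, 40, seed = 44)
  pool <- data.frame(oligo_id = names(panel), sequence = unname(panel),
                     stringsAsFactors = FALSE)
  rd <- emit_reads(pool, 3000, 0.001, seed = 2)
  ana <- analyze_reads(rd$r1, rd$r2, panel,
                       reference_counts = setNames(rep(1000, 3),
                                                   names(panel)))
  expect_s3_class(ana, "snop_analysis")
  expect_equal(sum(ana$counts), ana$filter$kept)
  expect_true(all(ana$purity$per_oligo$purity > 0.9))
  expect_equal(median(ana$concentration$per_oligo$rel_conc), 1)
})
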