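params_37_1M <- thermo_params(temperature_C = 37, salt_M = 1)

test_that("duplex free energy equals independent hand summation over the shipped table", {
  tab <- read.delim(system.file("extdata", "nn_dna_unified.tsv",
                                package = "snop"))
  dh <- setNames(tab$dH_kcal_mol, tab$stack)
  ds <- setNames(tab$dS_cal_mol_K, tab$stack)
  hand_sum <- function(seq, T_K, salt) {
    b <- strsplit(seq, "")[[1]]
    stacks <- paste0(head(b, -1), b[-1])
    H <- sum(dh[stacks]); S <- sum(ds[stacks])
    for (t in c(b[1], b[length(b)])) {
      key <- if (t %in% c("G", "C")) "init_GC" else "init_AT"
      H <- H + dh[[key]]; S <- S + ds[[key]]
    }
    S <- S + 0.368 * (length(b) - 1) * log(salt)
    H - T_K * S / 1000
  }
  expect_equal(duplex_dG("ACGTACGT", params_37_1M),
               hand_sum("ACGTACGT", 310.15, 1), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:25) {
    s <- rand_dna(sample(2:40, 1))
    p <- thermo_params(temperature_C = runif(1, 20, 80),
                       salt_M = runif(1, 0.05, 1))
    expect_equal(duplex_dG(s, p), hand_sum(s, p$temperature_K, p$salt_M),
                 tolerance = 1e-10)
  }
})

test_that("a duplex has the same free energy read from either strand", {
  set.seed(7)
  for (i in 1:1000) {
    s <- rand_dna(sample(2:40, 1))
    expect_equal(duplex_dG(s), duplex_dG(revcomp(s)), tolerance = 1e-10)
  }
})

test_that("free energy is affine in temperature with slope -dS_total", {
  s <- "GATTACACCGGTT"
  t1 <- duplex_dG(s, thermo_params(20, 0.5))
  t2 <- duplex_dG(s, thermo_params(60, 0.5))
  t3 <- duplex_dG(s, thermo_params(80, 0.5))
  slope <- (t2 - t1) / 40
  expect_equal(t3, t2 + 20 * slope, tolerance = 1e-10)
  # slope is -dS_total in kcal/(mol K), i.e. dG decreases as T rises for
  # a negative-entropy association? no: duplex dS < 0, so dG rises with T
  expect_gt(slope, 0)
})

test_that("invalid duplex inputs are rejected", {
  expect_error(duplex_dG("A"), "at least 2")
  expect_error(duplex_dG("ACGX"), "unresolvable")
  expect_error(duplex_dG(c("AC", "GT")), "single string")
  expect_error(thermo_params(salt_M = 0), "salt_M")
})

test_that("deoxyuracil is scored as thymine", {
  expect_equal(duplex_dG("ACGUACGU"), duplex_dG("ACGTACGT"),
               tolerance = 1e-12)
})

test_that("accessibility penalty matches the exhaustive complementary-segment oracle", {
  p <- thermo_params()
  # no >= s_min complementarity between product and tag: zero penalty
  u <- default_universal()
  quiet <- paste0(u, "CTCTCT", "U", strrep("C", 40))
  expect_identical(brute_stem(quiet, c(1, 23)) < p$s_min, TRUE)
  expect_equal(tag_accessibility_penalty(quiet, 1, 23, p), 0)
  # product carrying the exact reverse complement of the full barcode
  bc <- "GTGTGT"
  occl <- paste0(u, bc, "U", "AAAAA", revcomp(paste0(u, bc)), "AAAAA")
  L <- brute_stem(occl, c(1, 23))
  expect_gte(L, 6)
  expect_equal(tag_accessibility_penalty(occl, 1, 23, p),
               p$stem_penalty_per_bp * (L - p$s_min + 1))
  # random precursors agree with the oracle everywhere
  set.seed(42)
  for (i in 1:50) {
    seq <- paste0(u, "CACACA", "U", rand_dna(40))
    L <- brute_stem(seq, c(1, 23))
    expected <- if (L >= p$s_min) p$stem_penalty_per_bp * (L - p$s_min + 1)
                else 0
    expect_equal(tag_accessibility_penalty(seq, 1, 23, p), expected)
  }
})

test_that("accessibility penalty is non-decreasing in occluding stem length", {
  p <- thermo_params()
  u <- default_universal()
  bc <- "GTGTGT"
  tag <- paste0(u, bc)
  pen <- vapply(4:8, function(L) {
    seq <- paste0(tag, "U", strrep("A", 10),
                  revcomp(substr(tag, nchar(tag) - L + 1, nchar(tag))),
                  strrep("A", 10))
    tag_accessibility_penalty(seq, 1, nchar(tag), p)
  }, numeric(1))
  expect_true(all(diff(pen) >= 0))
  expect_gt(pen[length(pen)], 0)
})

test_that("malformed tag spans are rejected", {
  expect_error(tag_accessibility_penalty("ACGTACGT", 0, 4), "span")
  expect_error(tag_accessibility_penalty("ACGTACGT", 5, 2), "span")
  expect_error(tag_accessibility_penalty("ACGTACGT", 1, 99), "span")
})

test_that("reaction free energy decomposes into duplex, mismatch, and structure terms", {
  p <- thermo_params()
  u <- default_universal()
  pre <- build_precursor("o1", strrep("C", 40), "CTCTCT", u)
  # verified unstructured by the exhaustive oracle: pairing equals the
  # plain tag duplex energy
  expect_lt(brute_stem(pre$full_sequence, pre$tag_span), p$s_min)
  expect_equal(rxn_dG(pre, params = p), duplex_dG(paste0(u, "CTCTCT"), p),
               tolerance = 1e-12)
  # one barcode mismatch costs at least the per-mismatch penalty
  expect_gte(rxn_dG(pre, "GTCTCT", p),
             rxn_dG(pre, params = p) + p$mismatch_penalty - 1e-12)
  # same tag inside a structured precursor binds strictly more weakly
  occl <- build_precursor("o2", paste0("AAAAA", revcomp(paste0(u, "CTCTCT")),
                                       "AAAAA"), "CTCTCT", u)
  expect_gt(rxn_dG(occl, params = p), rxn_dG(pre, params = p))
  expect_error(rxn_dG(pre, "CACA", p), "length mismatch")
})

test_that("reaction free energy is non-decreasing in barcode mismatches", {
  p <- thermo_params()
  pre <- build_precursor("o1", strrep("ACGT", 10), "CACACA",
                         default_universal())
  probes <- c("CACACA", "GACACA", "GTCACA", "GTGACA", "GTGTCA", "GTGTGA",
              "GTGTGT")
  dgs <- vapply(probes, function(b) rxn_dG(pre, b, p), numeric(1))
  expect_true(all(diff(dgs) >= -1e-12))
})

test_that("alternating S/W barcodes cluster duplex energies more tightly than random 6-mers", {
  p <- thermo_params()
  u <- default_universal()
  cognate <- vapply(enumerate_barcodes(6),
                    function(b) duplex_dG(paste0(u, b), p), numeric(1))
  set.seed(11)
  rand6 <- vapply(1:64, function(i) duplex_dG(paste0(u, rand_dna(6)), p),
                  numeric(1))
  expect_lt(diff(range(cognate)), diff(range(rand6)))
})

test_that("crosstalk matrix holds pairwise reaction energies with cognate diagonal", {
  p <- thermo_params()
  panel <- random_panel(4, len = 40, seed = 3)
  asg <- optimize_assignment(panel, barcode_length = 3, iterations = 100,
                             seed = 1, params = p)
  ct <- crosstalk_matrix(asg, p)
  expect_equal(dim(ct$values), c(4, 4))
  expect_equal(unname(diag(ct$values)), unname(asg$dG_cognate),
               tolerance = 1e-12)
  # entries recompute from rxn_dG directly
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(ct$values[i, j],
                   rxn_dG(asg$precursors[[i]], asg$barcode_seq[j], p),
                   tolerance = 1e-12)
    }
  }
  # single-pair panel gives a 1x1 matrix equal to its rxn_dG
  asg1 <- optimize_assignment(panel[1], barcode_length = 3, iterations = 10,
                              seed = 1, params = p)
  ct1 <- crosstalk_matrix(asg1, p)
  expect_equal(unname(ct1$values[1, 1]),
               rxn_dG(asg1$precursors[[1]], params = p))
  # fully mismatched barcodes bind strictly more weakly than cognate
  pre <- build_precursor("x", strrep("A", 30), "CACACA", default_universal())
  expect_gt(rxn_dG(pre, "GTGTGT", p), rxn_dG(pre, params = p))
})
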