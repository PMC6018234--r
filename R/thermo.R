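#' Hybridization thermodynamics parameters
#'
#' Bundles everything the free-energy engine needs: the nearest-neighbor
#' (NN) stack table, duplex initiation terms, the monovalent-salt entropy
#' correction, the per-internal-mismatch penalty used for non-cognate
#' barcode pairings, and the secondary-structure (tag accessibility)
#' penalty settings.
#'
#' The shipped NN table is the unified DNA/DNA parameter set (enthalpy in
#' kcal/mol, entropy in cal/(mol K) per stack, plus terminal initiation
#' terms split by G/C vs A/T closing pair). Salt is handled as a
#' logarithmic entropy correction of `0.368 * (L - 1) * log(salt_M)`
#' cal/(mol K) for a duplex of length `L`.
#'
#' @param temperature_C hybridization temperature in degrees Celsius.
#'   Default 60, the capture condition the method is run at.
#' @param salt_M monovalent cation concentration in mol/L. Default 0.5.
#' @param mismatch_penalty free-energy penalty in kcal/mol added per
#'   internal barcode mismatch when a precursor tag pairs with a
#'   non-cognate probe instance. A single scalar: the design goal is
#'   rank-correct discrimination of mismatched tags, not base-resolved
#'   mismatch energetics.
#' @param s_min minimum intramolecular stem length (base pairs) that counts
#'   as tag-occluding secondary structure.
#' @param stem_penalty_per_bp penalty in kcal/mol per stem base pair at or
#'   beyond `s_min`; the accessibility penalty is
#'   `stem_penalty_per_bp * (L - s_min + 1)` for the longest occluding stem
#'   of length `L >= s_min`, else 0.
#' @param min_loop minimum hairpin loop size in nucleotides.
#' @param nn_table optional replacement NN table: a data.frame with columns
#'   `stack`, `dH_kcal_mol`, `dS_cal_mol_K` covering all 16 Watson-Crick
#'   stacks plus `init_GC` and `init_AT` rows.
#' @return an object of class `snop_thermo`.
#' @export
thermo_params <- function(temperature_C = 60, salt_M = 0.5,
                          mismatch_penalty = 3, s_min = 4,
                          stem_penalty_per_bp = 1, min_loop = 3,
                          nn_table = NULL) {
  if (!is.numeric(salt_M) || salt_M <= 0) stop("salt_M must be > 0")
  temperature_K <- temperature_C + 273.15
  if (temperature_K <= 0) stop("temperature must be above absolute zero")
  if (mismatch_penalty < 0) stop("mismatch_penalty must be >= 0")
  if (is.null(nn_table)) nn_table <- load_nn_table()
  stacks <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  missing <- setdiff(c(stacks, "init_GC", "init_AT"), nn_table$stack)
  if (length(missing)) {
    stop("nn_table is missing entries: ", paste(missing, collapse = ", "))
  }
  dH <- stats::setNames(nn_table$dH_kcal_mol, nn_table$stack)
  dS <- stats::setNames(nn_table$dS_cal_mol_K, nn_table$stack)
  if (any(!is.finite(dH)) || any(!is.finite(dS))) {
    stop("nn_table contains non-finite parameters")
  }
  structure(list(temperature_K = temperature_K, salt_M = salt_M,
                 mismatch_penalty = mismatch_penalty, s_min = s_min,
                 stem_penalty_per_bp = stem_penalty_per_bp,
                 min_loop = min_loop, dH = dH, dS = dS),
            class = "snop_thermo")
}

#' @export
print.snop_thermo <- function(x, ...) {
  cat(sprintf(paste0("snop thermodynamic conditions: %.2f K, %.3g M Na+, ",
                     "mismatch penalty %.2f kcal/mol, stem >= %d bp ",
                     "(%.2f kcal/mol per bp)\n"),
              x$temperature_K, x$salt_M, x$mismatch_penalty, x$s_min,
              x$stem_penalty_per_bp))
  invisible(x)
}

load_nn_table <- function() {
  path <- system.file("extdata", "nn_dna_unified.tsv", package = "snop")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

check_dna <- function(seq, what = "sequence", allow_u = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single string")
  }
  seq <- toupper(seq)
  ok <- if (allow_u) "^[ACGTU]*$" else "^[ACGT]*$"
  if (!grepl(ok, seq)) stop(what, " contains unresolvable characters")
  seq
}

#' Duplex free energy of a sequence with its perfect complement
#'
#' Computes the standard free energy (kcal/mol) of the duplex formed by
#' `seq` and its exact reverse complement at the temperature and salt in
#' `params`, as `dG = dH_total - T * dS_total`, where totals are the sum of
#' nearest-neighbor stack contributions plus the two terminal initiation
#' terms, and the entropy carries the monovalent-salt correction.
#' Deoxyuracil (`U`) is scored as `T` (it base-pairs identically).
#'
#' @param seq DNA string, 5' to 3', length >= 2, alphabet ACGT (plus U).
#' @param params a [thermo_params()] object.
#' @return duplex free energy in kcal/mol (negative = favorable).
#' @export
duplex_dG <- function(seq, params = thermo_params()) {
  seq <- check_dna(seq, "seq")
  seq <- gsub("U", "T", seq, fixed = TRUE)
  n <- nchar(seq)
  if (n < 2) stop("seq must have at least 2 nucleotides")
  b <- strsplit(seq, "")[[1]]
  stacks <- paste0(b[-n], b[-1])
  dH <- sum(params$dH[stacks])
  dS <- sum(params$dS[stacks])
  for (term in c(b[1], b[n])) {
    key <- if (term %in% c("G", "C")) "init_GC" else "init_AT"
    dH <- dH + params$dH[[key]]
    dS <- dS + params$dS[[key]]
  }
  dS <- dS + 0.368 * (n - 1) * log(params$salt_M)
  unname(dH - params$temperature_K * dS / 1000)
}

#' Penalty for tag-occluding intramolecular secondary structure
#'
#' Scans a precursor for contiguous antiparallel self-complementary
#' segments (stems) of length at least `params$s_min` whose arms are
#' separated by a loop of at least `params$min_loop` nt and where at least
#' one arm overlaps the tag span. Returns 0 when no such stem exists,
#' otherwise `stem_penalty_per_bp * (L - s_min + 1)` for the longest
#' occluding stem length `L` -- non-decreasing in `L` by construction. A
#' precursor whose tag is sequestered in structure binds its probe more
#' weakly, which this positive penalty models at the free-energy level.
#'
#' @param seq precursor sequence (U allowed; scored as T).
#' @param tag_start,tag_end 1-based inclusive bounds of the tag region.
#' @param params a [thermo_params()] object.
#' @return penalty in kcal/mol, >= 0.
#' @export
tag_accessibility_penalty <- function(seq, tag_start, tag_end,
                                      params = thermo_params()) {
  seq <- check_dna(seq, "seq")
  n <- nchar(seq)
  if (!is.numeric(tag_start) || !is.numeric(tag_end) ||
      tag_start < 1 || tag_end > n || tag_start > tag_end) {
    stop("malformed tag span")
  }
  seq <- gsub("U", "T", seq, fixed = TRUE)
  L <- longest_stem_cpp(seq, as.integer(tag_start), as.integer(tag_end),
                        as.integer(params$min_loop))
  if (L < params$s_min) return(0)
  params$stem_penalty_per_bp * (L - params$s_min + 1)
}

#' Reaction free energy of a precursor hybridizing to a probe instance
#'
#' The reaction free energy is the duplex free energy of the precursor's
#' tag (universal + barcode; the cleavable deoxyuracil is not probed) with
#' a perfectly complementary probe, plus one `mismatch_penalty` for every
#' barcode position at which the probe instance differs from the
#' precursor's own barcode, plus the precursor's tag accessibility penalty.
#' More positive values mean weaker binding.
#'
#' @param precursor a precursor object from [build_precursor()].
#' @param probe_barcode barcode carried by the probe instance (same length
#'   as the precursor's barcode). Defaults to the cognate barcode.
#' @param params a [thermo_params()] object.
#' @return reaction free energy in kcal/mol.
#' @export
rxn_dG <- function(precursor, probe_barcode = NULL,
                   params = thermo_params()) {
  stopifnot(inherits(precursor, "snop_precursor"))
  if (is.null(probe_barcode)) probe_barcode <- precursor$barcode
  probe_barcode <- check_dna(probe_barcode, "probe_barcode", allow_u = FALSE)
  if (nchar(probe_barcode) != nchar(precursor$barcode)) {
    stop("probe/tag barcode length mismatch")
  }
  tag <- paste0(precursor$universal, precursor$barcode)
  mm <- sum(strsplit(precursor$barcode, "")[[1]] !=
              strsplit(probe_barcode, "")[[1]])
  duplex_dG(tag, params) + mm * params$mismatch_penalty +
    tag_accessibility_penalty(precursor$full_sequence,
                              precursor$tag_span[1], precursor$tag_span[2],
                              params)
}

#' Precursor-by-probe crosstalk matrix of reaction free energies
#'
#' Entry (i, j) is the reaction free energy of precursor i binding probe
#' instance j. The diagonal holds the cognate values the assignment score
#' is computed from; weak off-diagonal binding (more positive entries)
#' means little crosstalk between precursors and unmatched probe instances.
#'
#' @param assignment a tag assignment from [optimize_assignment()] (or any
#'   object with `precursors` and `barcode_seq` fields).
#' @param params a [thermo_params()] object.
#' @return a list of class `snop_dg_matrix` with `values` (numeric matrix,
#'   kcal/mol, rows = precursors, columns = probe instances), `row_ids`,
#'   `col_ids`, and the `conditions` snapshot.
#' @export
crosstalk_matrix <- function(assignment, params = thermo_params()) {
  prec <- assignment$precursors
  n <- length(prec)
  if (n < 1) stop("assignment has no precursors")
  probes <- assignment$barcode_seq
  ids <- vapply(prec, function(p) p$oligo_id, character(1))
  # decompose: per-precursor baseline (tag duplex + structure) and
  # per-pair mismatch counts
  base <- vapply(prec, function(p) {
    duplex_dG(paste0(p$universal, p$barcode), params) +
      tag_accessibility_penalty(p$full_sequence, p$tag_span[1],
                                p$tag_span[2], params)
  }, numeric(1))
  bc_mat <- do.call(rbind, strsplit(vapply(prec, function(p) p$barcode,
                                           character(1)), ""))
  probe_mat <- do.call(rbind, strsplit(probes, ""))
  values <- matrix(0, n, length(probes), dimnames = list(ids, probes))
  for (j in seq_along(probes)) {
    mm <- rowSums(bc_mat != matrix(probe_mat[j, ], n, ncol(bc_mat),
                                   byrow = TRUE))
    values[, j] <- base + mm * params$mismatch_penalty
  }
  structure(list(values = values, row_ids = ids, col_ids = probes,
                 conditions = params),
            class = "snop_dg_matrix")
}
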