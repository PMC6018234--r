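# Panel design: barcode enumeration, Monte Carlo tag-oligo assignment,
# degenerate barcode blocks, precursor assembly, and advisory panel checks.

# run expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

barcode_letter <- function(position, bit) {
  # odd positions are strong (C/G), even positions weak (A/T)
  if (position %% 2 == 1) c("C", "G")[bit + 1] else c("A", "T")[bit + 1]
}

#' Enumerate all strong/weak alternating barcodes of length B
#'
#' Barcodes alternate strong (G or C) and weak (A or T) nucleotides,
#' starting strong: position 1 is C or G, position 2 is A or T, and so on.
#' The identical base composition of all barcodes keeps their duplex free
#' energies tightly clustered. Index encoding: bit `B - p` of the index
#' selects the base at position `p` (most-significant bit = position 1;
#' 0 selects C or A, 1 selects G or T), so index 0 is "CACA..." and index
#' `2^B - 1` is "GTGT...".
#'
#' @param B barcode length in nucleotides, between 1 and 20.
#' @return character vector of `2^B` barcode sequences; element `i`
#'   corresponds to index `i - 1`.
#' @export
enumerate_barcodes <- function(B) {
  if (!is.numeric(B) || length(B) != 1 || B != round(B) || B < 1 || B > 20) {
    stop("B must be an integer in [1, 20]")
  }
  B <- as.integer(B)
  cols <- lapply(seq_len(B), function(p) {
    bit <- bitwAnd(bitwShiftR(seq_len(2^B) - 1L, B - p), 1L)
    if (p %% 2 == 1) c("C", "G")[bit + 1L] else c("A", "T")[bit + 1L]
  })
  do.call(paste0, cols)
}

#' Assignment fitness score
#'
#' The fitness of a tag-oligo assignment is the sum of the population
#' standard deviation and the range (max minus min) of the cognate
#' reaction free energies: lower is better, 0 means perfectly uniform
#' capture thermodynamics across the panel.
#'
#' @param dG_vector numeric vector of cognate reaction free energies
#'   (kcal/mol), one per product.
#' @return the score S in kcal/mol (>= 0).
#' @export
score_S <- function(dG_vector) {
  if (!is.numeric(dG_vector) || length(dG_vector) < 1 ||
      any(!is.finite(dG_vector))) {
    stop("dG_vector must be a non-empty finite numeric vector")
  }
  n <- length(dG_vector)
  pop_sd <- sqrt(sum((dG_vector - mean(dG_vector))^2) / n)
  pop_sd + (max(dG_vector) - min(dG_vector))
}

#' Assemble a precursor from its parts
#'
#' A precursor is, 5' to 3': the universal sequence shared by the whole
#' panel, the precursor-specific barcode, a single deoxyuracil (written
#' `U`) at which the product is enzymatically released, the product
#' sequence, and an optional common 3' tail (e.g. a sequencing primer
#' site). The probed tag is the universal + barcode region; the tag span
#' is recorded 1-based inclusive.
#'
#' @param oligo_id identifier of the oligo product.
#' @param product product sequence (non-empty DNA).
#' @param barcode barcode sequence; may contain degenerate S/W letters for
#'   degenerate-block precursors.
#' @param universal universal 5' sequence (non-empty DNA).
#' @param common3 optional common 3' sequence ("" for none).
#' @return an object of class `snop_precursor` with fields `oligo_id`,
#'   `universal`, `barcode`, `product`, `common3`, `full_sequence`,
#'   `tag_span` (universal + barcode, 1-based inclusive), `du_pos`, and
#'   `product_span`.
#' @export
build_precursor <- function(oligo_id, product, barcode, universal,
                            common3 = "") {
  if (!nzchar(product)) stop("product must be non-empty")
  if (!nzchar(universal)) stop("universal must be non-empty")
  product <- check_dna(product, "product", allow_u = FALSE)
  universal <- check_dna(universal, "universal", allow_u = FALSE)
  if (!grepl("^[ACGTSW]+$", toupper(barcode))) {
    stop("barcode contains characters outside ACGT/SW")
  }
  barcode <- toupper(barcode)
  if (nzchar(common3)) common3 <- check_dna(common3, "common3", allow_u = FALSE)
  ul <- nchar(universal); bl <- nchar(barcode)
  full <- paste0(universal, barcode, "U", product, common3)
  structure(list(oligo_id = as.character(oligo_id), universal = universal,
                 barcode = barcode, product = product, common3 = common3,
                 full_sequence = full,
                 tag_span = c(1L, ul + bl),
                 du_pos = ul + bl + 1L,
                 product_span = c(ul + bl + 2L,
                                  ul + bl + 1L + nchar(product))),
            class = "snop_precursor")
}

#' Default universal sequence
#'
#' A fixed 17 nt GC-balanced sequence used as the shared 5' region of every
#' precursor, screened so that neither it nor any universal + barcode tag
#' (B = 6 or 8) contains a self-complementary stem of 4 or more base pairs,
#' and so it cannot dimerize with itself over more than 4 nt. Any panel
#' should still be screened against it with [validate_panel()].
#'
#' @return a 17-character DNA string.
#' @export
default_universal <- function() "GCGCCGCAATGTTAATA"

#' Monte Carlo optimization of the tag-oligo assignment
#'
#' Starts from a random injective assignment of barcodes to products, then
#' repeatedly proposes either swapping the barcodes of two uniformly chosen
#' products or (when spare barcodes exist, with probability 0.5) moving one
#' product onto an unused barcode. A proposal is accepted only if the
#' fitness score [score_S()] of the cognate reaction free energies strictly
#' decreases. The best assignment seen is returned, so the best-score
#' trajectory is non-increasing.
#'
#' @param products named character vector of product sequences (names are
#'   oligo ids).
#' @param barcode_length barcode length B; the candidate set is
#'   `enumerate_barcodes(B)`. Ignored if `barcodes` is given.
#' @param barcodes explicit candidate barcode vector (index order).
#' @param universal universal 5' sequence.
#' @param common3 optional common 3' sequence on every precursor.
#' @param iterations number of proposal iterations (default 500).
#' @param seed RNG seed; fixed default so runs are reproducible.
#' @param params a [thermo_params()] object.
#' @param dg_fun optional stub replacing the thermodynamic engine: a
#'   function `(product_index, barcode_index) -> kcal/mol`, vectorized over
#'   its arguments. Used for testing and for plugging in external engines.
#' @return an object of class `snop_assignment`: `mapping` data.frame
#'   (oligo_id, barcode_index 0-based, barcode_seq, dG_rxn_kcal_mol),
#'   `score`, `trajectory` (best score after each iteration),
#'   `iterations_run`, `rng_seed`, `precursors` (list of
#'   [build_precursor()] objects), `barcode_seq` (assigned probe-instance
#'   barcodes, product order), `universal`, `dG_cognate`.
#' @export
optimize_assignment <- function(products, barcode_length = NULL,
                                barcodes = NULL,
                                universal = default_universal(),
                                common3 = "", iterations = 500, seed = 1,
                                params = thermo_params(), dg_fun = NULL) {
  if (is.null(names(products)) || any(!nzchar(names(products)))) {
    stop("products must be a named character vector")
  }
  if (is.null(barcodes)) {
    if (is.null(barcode_length)) stop("supply barcode_length or barcodes")
    barcodes <- enumerate_barcodes(barcode_length)
  }
  n <- length(products); k <- length(barcodes)
  if (n > k) stop("more products than barcodes: capacity exceeded")
  if (iterations < 0) stop("iterations must be >= 0")

  # Precompute the cognate dG of every (product, barcode) pairing once;
  # the Monte Carlo loop is then pure bookkeeping.
  if (is.null(dg_fun)) {
    tag_dG <- vapply(barcodes,
                     function(b) duplex_dG(paste0(universal, b), params),
                     numeric(1))
    dg_mat <- matrix(0, n, k)
    for (i in seq_len(n)) {
      for (b in seq_len(k)) {
        p <- build_precursor(names(products)[i], products[[i]], barcodes[b],
                             universal, common3)
        dg_mat[i, b] <- tag_dG[b] +
          tag_accessibility_penalty(p$full_sequence, p$tag_span[1],
                                    p$tag_span[2], params)
      }
    }
  } else {
    dg_mat <- outer(seq_len(n), seq_len(k), dg_fun)
  }

  # Strictly-improving proposals trap a single chain in local optima of the
  # swap neighborhood; restarting the chain from a fresh random assignment
  # after a stall (while keeping the best assignment seen) preserves the
  # accept-only-improvement rule and makes long runs find the optimum.
  stall_limit <- max(50L, 10L * n)
  res <- with_seed(seed, {
    assign <- sample.int(k, n)   # random injection (bijection when n == k)
    s <- score_S(dg_mat[cbind(seq_len(n), assign)])
    best <- assign; best_s <- s
    traj <- numeric(iterations)
    stall <- 0L
    for (it in seq_len(iterations)) {
      cand <- assign
      if (n < k && stats::runif(1) < 0.5) {
        i <- sample.int(n, 1)
        unused <- setdiff(seq_len(k), assign)
        cand[i] <- unused[sample.int(length(unused), 1)]
      } else if (n >= 2) {
        ij <- sample.int(n, 2)
        cand[ij] <- cand[rev(ij)]
      }
      s_cand <- score_S(dg_mat[cbind(seq_len(n), cand)])
      if (s_cand < s) { assign <- cand; s <- s_cand; stall <- 0L }
      else stall <- stall + 1L
      if (s < best_s) { best <- assign; best_s <- s }
      if (stall >= stall_limit) {
        assign <- sample.int(k, n)
        s <- score_S(dg_mat[cbind(seq_len(n), assign)])
        stall <- 0L
      }
      traj[it] <- best_s
    }
    list(assign = best, score = best_s, traj = traj)
  })

  dG_cognate <- dg_mat[cbind(seq_len(n), res$assign)]
  # with a stubbed engine the "barcodes" may be abstract labels
  precs <- if (all(grepl("^[ACGTSW]+$", toupper(barcodes[res$assign])))) {
    lapply(seq_len(n), function(i) {
      build_precursor(names(products)[i], products[[i]],
                      barcodes[res$assign[i]], universal, common3)
    })
  }
  structure(list(
    mapping = data.frame(oligo_id = names(products),
                         barcode_index = res$assign - 1L,
                         barcode_seq = barcodes[res$assign],
                         dG_rxn_kcal_mol = dG_cognate,
                         stringsAsFactors = FALSE),
    score = res$score, trajectory = res$traj,
    iterations_run = iterations, rng_seed = seed,
    precursors = precs, barcode_seq = barcodes[res$assign],
    universal = universal, dG_cognate = dG_cognate),
    class = "snop_assignment")
}

#' @export
print.snop_assignment <- function(x, ...) {
  cat(sprintf(paste0("snop tag assignment: %d products, score S = %.4f ",
                     "kcal/mol after %d iterations (seed %s)\n"),
              nrow(x$mapping), x$score, x$iterations_run,
              format(x$rng_seed)))
  invisible(x)
}

#' Allocate degenerate barcode blocks
#'
#' Assigns each product a block of `copies` barcode instances expressed as
#' a single barcode with `log2(copies)` degenerate positions (IUPAC S at
#' odd positions, W at even positions). Because blocks must share all
#' specified positions, `copies` must be a power of 2 and blocks occupy
#' consecutive barcode indices; the degenerate positions are the trailing
#' (lowest-significance) positions of the barcode. A product's relative
#' concentration in the purified pool scales with its number of barcode
#' instances.
#'
#' @param requests named integer vector: product id -> number of barcode
#'   instances (each a power of 2; the sum must not exceed `2^B`).
#' @param B barcode length.
#' @return data.frame with columns `oligo_id`, `copies`, `start_index`
#'   (0-based), `barcode_seq` (with S/W at degenerate positions), and
#'   `degenerate_positions`.
#' @export
allocate_degenerate <- function(requests, B) {
  if (is.null(names(requests)) || any(!nzchar(names(requests)))) {
    stop("requests must be named by product id")
  }
  copies <- as.numeric(requests)
  if (any(copies < 1) || any(copies != round(copies)) ||
      any(bitwAnd(as.integer(copies), as.integer(copies) - 1L) != 0L)) {
    stop("every request must be a power of 2")
  }
  if (sum(copies) > 2^B) stop("requests exceed barcode capacity 2^B")
  ord <- order(-copies)  # largest blocks first keeps starts aligned
  bcs <- enumerate_barcodes(B)
  start <- 0L
  out <- vector("list", length(requests))
  for (r in ord) {
    cp <- as.integer(copies[r]); d <- as.integer(log2(cp))
    seq_chars <- strsplit(bcs[start + 1L], "")[[1]]
    if (d > 0) {
      degpos <- (B - d + 1):B
      seq_chars[degpos] <- ifelse(degpos %% 2 == 1, "S", "W")
    } else degpos <- integer(0)
    out[[r]] <- data.frame(oligo_id = names(requests)[r], copies = cp,
                           start_index = start,
                           barcode_seq = paste0(seq_chars, collapse = ""),
                           degenerate_positions = paste(degpos,
                                                        collapse = ","),
                           stringsAsFactors = FALSE)
    start <- start + cp
  }
  do.call(rbind, out)
}

#' Expand a degenerate barcode block into its concrete instances
#'
#' @param barcode_seq barcode possibly containing S/W letters.
#' @return character vector of all concrete barcode sequences the block
#'   represents (a single sequence when fully specified).
#' @export
expand_block <- function(barcode_seq) {
  chars <- strsplit(toupper(barcode_seq), "")[[1]]
  opts <- lapply(chars, function(ch) switch(ch, S = c("C", "G"),
                                            W = c("A", "T"), ch))
  grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(opts)), drop = FALSE], 1, paste0,
        collapse = "")
}

#' Advisory screening of a product panel
#'
#' Flags (1) product pairs sharing a contiguous reverse-complementary
#' stretch of at least `pair_threshold` nt, which risks daisy-chain capture
#' of unintended molecules, and (2) products with a contiguous
#' complementary stretch of at least `universal_threshold` nt to the
#' universal region, which risks capture via the product rather than the
#' tag. Warnings are advisory: the design outputs are unchanged.
#'
#' @param products named character vector of product sequences.
#' @param universal universal sequence to screen against.
#' @param pair_threshold minimum inter-product complementary stretch (nt)
#'   to flag. Default 15.
#' @param universal_threshold minimum product-universal complementary
#'   stretch (nt) to flag. Default 10.
#' @return data.frame of warnings with columns `type`
#'   (`"pair_complementarity"` or `"universal_binding"`), `id1`, `id2`,
#'   `stretch_nt`; zero rows when the panel is clean.
#' @export
validate_panel <- function(products, universal = default_universal(),
                           pair_threshold = 15, universal_threshold = 10) {
  ids <- names(products)
  warnings <- list()
  n <- length(products)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        L <- longest_duplex_cpp(toupper(products[[i]]),
                                toupper(products[[j]]))
        if (L >= pair_threshold) {
          warnings[[length(warnings) + 1]] <-
            data.frame(type = "pair_complementarity", id1 = ids[i],
                       id2 = ids[j], stretch_nt = L,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (i in seq_len(n)) {
    L <- longest_duplex_cpp(toupper(products[[i]]), toupper(universal))
    if (L >= universal_threshold) {
      warnings[[length(warnings) + 1]] <-
        data.frame(type = "universal_binding", id1 = ids[i],
                   id2 = "universal", stretch_nt = L,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(warnings)) do.call(rbind, warnings)
  else data.frame(type = character(), id1 = character(), id2 = character(),
                  stretch_nt = integer(), stringsAsFactors = FALSE)
}

#' Read a product panel from TSV or FASTA
#'
#' @param path TSV with columns `oligo_id` and `sequence` (header optional
#'   if exactly two columns), or a FASTA file (extension .fa/.fasta/.fna).
#' @return named character vector of product sequences.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fa", "fasta", "fna")) {
    ss <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("oligo_id", "sequence") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("panel TSV needs columns oligo_id, sequence")
    names(df)[1:2] <- c("oligo_id", "sequence")
  }
  stats::setNames(toupper(df$sequence), df$oligo_id)
}

#' Write design outputs
#'
#' Writes the precursor FASTA (deoxyuracil written as `U`), the capture
#' probe sequence (reverse complement of the tag template with degenerate
#' S/W positions), the assignment TSV, the crosstalk matrix TSV, and a
#' JSON design summary (score trajectory, seed, conditions).
#'
#' @param assignment a [optimize_assignment()] result.
#' @param dir output directory (created if needed).
#' @param params the [thermo_params()] used for design.
#' @return invisibly, the paths written.
#' @export
write_design <- function(assignment, dir, params = thermo_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(precursors = file.path(dir, "precursors.fasta"),
             probe = file.path(dir, "capture_probe.txt"),
             assignment = file.path(dir, "assignment.tsv"),
             crosstalk = file.path(dir, "crosstalk.tsv"),
             summary = file.path(dir, "design_summary.json"))
  seqs <- vapply(assignment$precursors, function(p) p$full_sequence,
                 character(1))
  ids <- vapply(assignment$precursors, function(p) p$oligo_id, character(1))
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), paths["precursors"])
  B <- nchar(assignment$barcode_seq[1])
  template <- paste0(assignment$universal,
                     paste0(ifelse(seq_len(B) %% 2 == 1, "S", "W"),
                            collapse = ""))
  # S and W are self-complementary IUPAC classes; reverse for the probe
  comp <- c(A = "T", C = "G", G = "C", T = "A", S = "S", W = "W")
  probe <- paste(rev(comp[strsplit(template, "")[[1]]]), collapse = "")
  writeLines(probe, paths["probe"])
  utils::write.table(assignment$mapping, paths["assignment"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ct <- crosstalk_matrix(assignment, params)
  utils::write.table(ct$values, paths["crosstalk"], sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(score = assignment$score, trajectory = assignment$trajectory,
         iterations = assignment$iterations_run, seed = assignment$rng_seed,
         temperature_K = params$temperature_K, salt_M = params$salt_M),
    paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
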