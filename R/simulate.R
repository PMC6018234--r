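# Synthetic-data generator: correlated oligo synthesis errors, the
# capture/cleavage purification itself, and overlapped paired-end reads.
# The correlation mechanism is a per-molecule "zone" multiplier on all
# synthesis error rates, modeling uneven surface chemistry: a molecule
# synthesized in a bad zone accumulates errors everywhere, which is why a
# perfect tag predicts a perfect product.

#' Synthesis and sequencing error model
#'
#' Per-coupling probabilities are baselines multiplied, per molecule, by a
#' zone-quality factor drawn from a two-component mixture (good zones
#' `f = 1`, bad zones `f = zone_bad_factor` with weight `zone_bad_weight`).
#' Setting `zone_bad_weight = 0` (or `zone_bad_factor = 1`) removes the
#' correlation between tag and product errors; any positive zone variance
#' induces it.
#'
#' @param per_base_deletion_prob baseline probability a coupling skips a
#'   base (internal deletion).
#' @param per_base_truncation_prob baseline probability synthesis
#'   terminates at a coupling (loss of the remaining 5' prefix; synthesis
#'   runs 3' to 5').
#' @param substitution_prob baseline per-base substitution probability.
#' @param insertion_prob baseline probability of an extra base after a
#'   coupling.
#' @param zone_bad_weight mixture weight of bad zones, in \[0, 1\].
#' @param zone_bad_factor error-rate multiplier in bad zones (>= 1).
#' @param seq_error_rate independent per-base sequencing error rate used
#'   by [emit_reads()].
#' @return an object of class `snop_error_model`.
#' @export
error_model <- function(per_base_deletion_prob = 0.003,
                        per_base_truncation_prob = 0.002,
                        substitution_prob = 5e-4,
                        insertion_prob = 2e-4,
                        zone_bad_weight = 0.15,
                        zone_bad_factor = 8,
                        seq_error_rate = 0.001) {
  probs <- c(per_base_deletion_prob, per_base_truncation_prob,
             substitution_prob, insertion_prob, zone_bad_weight,
             seq_error_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (!is.finite(zone_bad_factor) || zone_bad_factor < 1) {
    stop("zone_bad_factor must be finite and >= 1")
  }
  structure(list(per_base_deletion_prob = per_base_deletion_prob,
                 per_base_truncation_prob = per_base_truncation_prob,
                 substitution_prob = substitution_prob,
                 insertion_prob = insertion_prob,
                 zone_bad_weight = zone_bad_weight,
                 zone_bad_factor = zone_bad_factor,
                 seq_error_rate = seq_error_rate),
            class = "snop_error_model")
}

random_other_base <- function(current) {
  bases <- c("A", "C", "G", "T")
  alt <- lapply(current, function(b) setdiff(bases, b))
  vapply(alt, function(a) a[sample.int(3, 1)], character(1))
}

#' Simulate synthesis of a precursor
#'
#' Simulates `n` molecules of a precursor base by base in synthesis order
#' (3' to 5'). Each molecule first draws a zone factor `f`; at every
#' coupling the base is deleted with probability `f * p_del`, substituted
#' or followed by an inserted random base with the analogous
#' probabilities, and synthesis terminates (truncating the remaining 5'
#' prefix) with probability `f * p_trunc` per coupling, so truncations are
#' always a 5' prefix loss.
#'
#' @param precursor a [build_precursor()] object (fully specified barcode).
#' @param n number of molecules.
#' @param model an [error_model()].
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param sequences if `FALSE`, skip building realized sequences (the
#'   error annotations alone are enough for error-statistics studies and
#'   are much faster at large `n`).
#' @return data.frame of class `snop_molecules`, one row per molecule:
#'   `source_id`, `zone_factor`, `trunc_len` (5' bases lost),
#'   `n_tag_errors` (errors touching the universal + barcode region,
#'   truncated tag bases included), `n_product_errors`, `tag_perfect`,
#'   `product_perfect`, `du_intact`, `annotations`
#'   (`type@position` list, `;`-separated), `sequence` and `product_seq`
#'   (realized product region 3' of the deoxyuracil; NA when `sequences =
#'   FALSE` or the dU was destroyed).
#' @export
synthesize_molecules <- function(precursor, n, model = error_model(),
                                 seed = 1, sequences = TRUE) {
  stopifnot(inherits(precursor, "snop_precursor"),
            inherits(model, "snop_error_model"))
  if (n < 0) stop("n must be >= 0")
  full <- precursor$full_sequence
  L <- nchar(full)
  chars <- strsplit(full, "")[[1]]
  tag_end <- precursor$tag_span[2]
  du <- precursor$du_pos
  prod_start <- precursor$product_span[1]

  empty <- data.frame(source_id = character(), zone_factor = numeric(),
                      trunc_len = integer(), n_tag_errors = integer(),
                      n_product_errors = integer(), tag_perfect = logical(),
                      product_perfect = logical(), du_intact = logical(),
                      annotations = character(), sequence = character(),
                      product_seq = character(), stringsAsFactors = FALSE)
  if (n == 0) return(structure(empty, class = c("snop_molecules",
                                                "data.frame")))

  res <- with_seed(seed, {
    f <- ifelse(stats::runif(n) < model$zone_bad_weight,
                model$zone_bad_factor, 1)
    q_trunc <- pmin(1, f * model$per_base_truncation_prob)
    coupled <- if (model$per_base_truncation_prob > 0) {
      pmin(L, stats::rgeom(n, q_trunc))
    } else rep(L, n)
    trunc_len <- L - coupled
    p_del <- pmin(1, f * model$per_base_deletion_prob)
    p_sub <- pmin(1, f * model$substitution_prob)
    p_ins <- pmin(1, f * model$insertion_prob)
    # single uniform per synthesized position, cut by cumulative thresholds
    ev_mol <- integer(0); ev_pos <- integer(0); ev_type <- integer(0)
    for (p in seq_len(L)) {
      made <- p > trunc_len
      if (!any(made)) next
      u <- stats::runif(n)
      del <- made & u < p_del
      sub <- made & !del & u < p_del + p_sub
      ins <- made & !del & !sub & u < p_del + p_sub + p_ins
      idx <- which(del | sub | ins)
      if (length(idx)) {
        ev_mol <- c(ev_mol, idx)
        ev_pos <- c(ev_pos, rep.int(p, length(idx)))
        ev_type <- c(ev_type, ifelse(del[idx], 1L, ifelse(sub[idx], 2L, 3L)))
      }
    }
    ev_base <- rep(NA_character_, length(ev_mol))
    if (any(ev_type == 2L)) {
      ev_base[ev_type == 2L] <- random_other_base(chars[ev_pos[ev_type == 2L]])
    }
    if (any(ev_type == 3L)) {
      ev_base[ev_type == 3L] <- c("A", "C", "G", "T")[
        sample.int(4, sum(ev_type == 3L), replace = TRUE)]
    }
    list(f = f, trunc_len = trunc_len, ev_mol = ev_mol, ev_pos = ev_pos,
         ev_type = ev_type, ev_base = ev_base)
  })

  ord <- order(res$ev_mol, res$ev_pos)
  ev <- data.frame(mol = res$ev_mol[ord], pos = res$ev_pos[ord],
                   type = res$ev_type[ord], base = res$ev_base[ord],
                   stringsAsFactors = FALSE)

  trunc_len <- res$trunc_len
  n_tag <- pmin(trunc_len, tag_end)
  n_prod <- integer(n)
  du_gone <- trunc_len >= du
  if (nrow(ev)) {
    in_tag <- ev$pos <= tag_end
    in_prod <- ev$pos >= prod_start
    tag_tab <- tabulate(ev$mol[in_tag], nbins = n)
    prod_tab <- tabulate(ev$mol[in_prod], nbins = n)
    n_tag <- n_tag + tag_tab
    n_prod <- prod_tab
    du_gone <- du_gone | seq_len(n) %in% ev$mol[ev$pos == du &
                                                  ev$type %in% c(1L, 2L)]
  }

  ann <- character(n)
  ann[trunc_len > 0] <- paste0("trunc5@1-", trunc_len[trunc_len > 0])
  if (nrow(ev)) {
    lab <- paste0(c("del", "sub", "ins")[ev$type], "@", ev$pos)
    ev_ann <- vapply(split(lab, factor(ev$mol, levels = seq_len(n))),
                     paste, character(1), collapse = ";")
    ann <- ifelse(nzchar(ann) & nzchar(ev_ann), paste(ann, ev_ann, sep = ";"),
                  paste0(ann, ev_ann))
  }

  seq_out <- rep(NA_character_, n); prod_out <- rep(NA_character_, n)
  if (sequences) {
    touched <- unique(c(which(trunc_len > 0), ev$mol))
    seq_out[] <- full
    prod_out[] <- precursor$product
    prod_out[du_gone] <- NA_character_
    for (m in touched) {
      keep <- rep(TRUE, L)
      if (trunc_len[m] > 0) keep[seq_len(trunc_len[m])] <- FALSE
      cc <- chars
      ins_after <- vector("list", L)
      if (nrow(ev)) {
        e <- ev[ev$mol == m, , drop = FALSE]
        keep[e$pos[e$type == 1L]] <- FALSE
        cc[e$pos[e$type == 2L]] <- e$base[e$type == 2L]
        for (r in which(e$type == 3L)) {
          ins_after[[e$pos[r]]] <- c(ins_after[[e$pos[r]]], e$base[r])
        }
      }
      pieces <- character(0)
      for (p in seq_len(L)) {
        if (keep[p]) pieces <- c(pieces, cc[p])
        if (!is.null(ins_after[[p]])) pieces <- c(pieces, ins_after[[p]])
      }
      seq_out[m] <- paste0(pieces, collapse = "")
      if (!du_gone[m]) {
        # released product: everything strictly 3' of the intact dU
        cut <- sum(keep[seq_len(du)]) +
          sum(lengths(ins_after[seq_len(du - 1)]))
        prod_out[m] <- substr(seq_out[m], cut + 1, nchar(seq_out[m]))
      } else prod_out[m] <- NA_character_
    }
  }

  out <- data.frame(source_id = rep(precursor$oligo_id, n),
                    zone_factor = res$f, trunc_len = trunc_len,
                    n_tag_errors = as.integer(n_tag),
                    n_product_errors = as.integer(n_prod),
                    tag_perfect = n_tag == 0L,
                    product_perfect = n_prod == 0L & trunc_len < prod_start,
                    du_intact = !du_gone,
                    annotations = ann, sequence = seq_out,
                    product_seq = prod_out, stringsAsFactors = FALSE)
  structure(out, class = c("snop_molecules", "data.frame"))
}

#' Capture on the probe and release by deoxyuracil cleavage
#'
#' Models the purification on a pool of synthesized molecules. Each
#' molecule's capture weight relative to a perfect-tag molecule is
#' `delta^k` where `k` is its number of tag errors and `delta < 1` is the
#' per-tag-error discrimination factor (single tag errors already cut
#' binding sharply). Each probe instance captures up to `probe_count`
#' molecules of its cognate precursor, sampled without replacement with
#' probability proportional to weight; captured molecules are then cleaved
#' at the deoxyuracil, releasing the product region with whatever
#' synthesis errors it carries. Molecules whose dU was lost are captured
#' but not releasable.
#'
#' @param molecules a `snop_molecules` data.frame (possibly pooled over
#'   precursors) with realized sequences.
#' @param probe_counts probe capacity per product: a single number or a
#'   named vector keyed by oligo id (molecule counts, not concentrations).
#' @param delta per-tag-error discrimination factor in (0, 1\].
#' @param seed RNG seed.
#' @return data.frame of released products: `oligo_id`, `sequence`,
#'   `product_perfect`.
#' @export
snop_capture_and_cleave <- function(molecules, probe_counts, delta = 0.05,
                                    seed = 1) {
  stopifnot(is.data.frame(molecules))
  if (delta <= 0 || delta > 1) stop("delta must be in (0, 1]")
  if (any(probe_counts < 0)) stop("probe counts must be >= 0")
  ids <- unique(molecules$source_id)
  if (is.null(names(probe_counts))) {
    probe_counts <- stats::setNames(rep(probe_counts[1], length(ids)), ids)
  }
  with_seed(seed, {
    out <- lapply(ids, function(id) {
      mm <- molecules[molecules$source_id == id, , drop = FALSE]
      w <- delta^pmin(mm$n_tag_errors, 500)
      cand <- which(w > 0)
      take <- min(length(cand), floor(probe_counts[[id]]))
      if (take == 0) return(NULL)
      sel <- if (take == length(cand)) cand else {
        cand[sample.int(length(cand), take, prob = w[cand])]
      }
      rel <- sel[mm$du_intact[sel]]
      if (!length(rel)) return(NULL)
      data.frame(oligo_id = id, sequence = mm$product_seq[rel],
                 product_perfect = mm$product_perfect[rel],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Emit overlapped paired-end reads as FASTQ
#'
#' Samples released products with replacement, writes the forward mate as
#' the product sequence and the reverse mate as its reverse complement,
#' each with independent per-base substitution errors at `seq_error_rate`.
#' This emulates a fully overlapped paired-end run after adaptor trimming:
#' both mates cover the whole molecule.
#'
#' @param products data.frame from [snop_capture_and_cleave()] (or any
#'   frame with `oligo_id`, `sequence`).
#' @param n_pairs number of read pairs to emit.
#' @param seq_error_rate per-base sequencing error rate per mate.
#' @param seed RNG seed (fixed seed gives byte-identical files).
#' @param r1_path,r2_path output FASTQ paths (gzip if they end in `.gz`).
#' @return invisibly, a data.frame of the emitted truth: `read_id`,
#'   `oligo_id`, `r1`, `r2`.
#' @export
emit_reads <- function(products, n_pairs, seq_error_rate = 0.001, seed = 1,
                       r1_path = NULL, r2_path = NULL) {
  stopifnot(is.data.frame(products), nrow(products) > 0)
  if (seq_error_rate < 0 || seq_error_rate > 1) {
    stop("seq_error_rate must be in [0, 1]")
  }
  truth <- with_seed(seed, {
    idx <- sample.int(nrow(products), n_pairs, replace = TRUE)
    fwd <- products$sequence[idx]
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)))
    list(oligo_id = products$oligo_id[idx],
         r1 = inject_seq_errors(fwd, seq_error_rate),
         r2 = inject_seq_errors(rev, seq_error_rate))
  })
  read_id <- sprintf("read%07d", seq_len(n_pairs))
  out <- data.frame(read_id = read_id, oligo_id = truth$oligo_id,
                    r1 = truth$r1, r2 = truth$r2, stringsAsFactors = FALSE)
  if (!is.null(r1_path)) write_fastq(out$r1, read_id, r1_path)
  if (!is.null(r2_path)) write_fastq(out$r2, read_id, r2_path)
  invisible(out)
}

# independent per-base substitutions at rate e (vectorized over reads)
inject_seq_errors <- function(seqs, e) {
  if (e == 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  chars <- strsplit(seqs, "")
  flat <- unlist(chars, use.names = FALSE)
  hit <- stats::runif(length(flat)) < e
  if (any(hit)) flat[hit] <- random_other_base(flat[hit])
  grp <- rep.int(seq_along(seqs), lens)
  mutated <- unique(grp[hit])
  if (length(mutated)) {
    rebuilt <- vapply(split(flat[grp %in% mutated], grp[grp %in% mutated]),
                      paste, character(1), collapse = "")
    seqs[mutated] <- rebuilt
  }
  seqs
}

write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(L) {
    paste(rep("I", L), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
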