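# Independent oracles and fixture builders used across the suite. These
# deliberately use brute-force or closed-form routes that share no code
# with the implementation paths they check.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# apply k random single-base edits (sub/del/ins) to a sequence
mutate_seq <- function(seq, k) {
  for (i in seq_len(k)) {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample.int(length(chars), 1)
    op <- sample(c("sub", "del", "ins"), 1)
    if (op == "sub") {
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
    } else if (op == "del" && length(chars) > 2) {
      chars <- chars[-pos]
    } else {
      chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = pos)
    }
    seq <- paste(chars, collapse = "")
  }
  seq
}

# exhaustive stem scan: longest antiparallel complementary run with a loop
# of >= min_loop whose arms overlap [span[1], span[2]]
brute_stem <- function(seq, span, min_loop = 3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # deoxyuracil pairs like thymine
  b <- strsplit(gsub("U", "T", toupper(seq)), "")[[1]]
  n <- length(b)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      L <- 0L
      while (i + L <= n && j - L >= 1 && i + L < j - L &&
             comp[[b[i + L]]] == b[j - L]) {
        L2 <- L + 1L
        loop <- (j - L2 + 1) - (i + L2 - 1) - 1
        if (loop >= min_loop) {
          arms_overlap <- (i <= span[2] && (i + L2 - 1) >= span[1]) ||
            ((j - L2 + 1) <= span[2] && j >= span[1])
          if (arms_overlap && L2 > best) best <- L2
        }
        L <- L2
      }
    }
  }
  best
}

# stable smaller root of K x^2 - (K (P + Q) + 1) x + K P Q = 0: the bound
# duplex concentration of a single-species hybridization
quad_bound_1x1 <- function(K, P, Q) {
  b <- K * (P + Q) + 1
  disc <- K^2 * (P - Q)^2 + 2 * K * (P + Q) + 1
  2 * K * P * Q / (b + sqrt(disc))
}

# 2x2 competitive equilibrium by nested bisection on the free probe
# concentrations (each probe-balance is monotone in its free concentration)
solve_2x2_oracle <- function(K, P, Q, tol = 1e-14) {
  fp <- function(fq) P / (1 + as.vector(K %*% fq))
  bal1 <- function(fq1, fq2) {
    f <- fp(c(fq1, fq2))
    fq1 * (1 + sum(K[, 1] * f)) - Q[1]
  }
  bal2 <- function(fq2) {
    fq1 <- stats::uniroot(bal1, c(0, Q[1]), fq2 = fq2, tol = tol)$root
    f <- fp(c(fq1, fq2))
    fq2 * (1 + sum(K[, 2] * f)) - Q[2]
  }
  fq2 <- stats::uniroot(bal2, c(0, Q[2]), tol = tol)$root
  fq1 <- stats::uniroot(bal1, c(0, Q[1]), fq2 = fq2, tol = tol)$root
  f <- fp(c(fq1, fq2))
  K * outer(f, c(fq1, fq2))
}

# all injective assignments of n products to k slots, as a list of index
# vectors (brute-force optimum oracle for the Monte Carlo optimizer)
all_injections <- function(n, k) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  out <- list()
  for (cmb in utils::combn(k, n, simplify = FALSE)) {
    for (p in perms(cmb)) out[[length(out) + 1]] <- p
  }
  out
}

brute_best_score <- function(M) {
  min(vapply(all_injections(nrow(M), ncol(M)),
             function(a) score_S(M[cbind(seq_len(nrow(M)), a)]), numeric(1)))
}

# small random product panel fixture (leaves the caller's RNG untouched)
random_panel <- function(n, len = 70, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(vapply(seq_len(n), function(i) rand_dna(len), ""),
                  sprintf("oligo%02d", seq_len(n)))
}
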