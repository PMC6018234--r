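# Mass-action competitive hybridization: how much of each precursor each
# capture probe instance binds at the thermodynamic limit. Two-state
# duplexes only; the wet reaction may not fully equilibrate, so these are
# upper-bound predictions of the normalization mechanism.

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal/(mol K)

#' Association constant from a reaction free energy
#'
#' `K = exp(-dG / (R * T))` with R = 1.987e-3 kcal/(mol K); strictly
#' decreasing in `dG` (more negative free energy binds tighter).
#'
#' @param dG reaction free energy, kcal/mol (vectorized).
#' @param T_K absolute temperature in K.
#' @return association constant(s), 1/M.
#' @export
equilibrium_constant <- function(dG, T_K = 333.15) {
  if (any(!is.finite(dG))) stop("dG must be finite")
  if (T_K <= 0) stop("temperature must be positive")
  exp(-dG / (GAS_CONSTANT_KCAL * T_K))
}

#' Solve a competitive hybridization equilibrium
#'
#' Given an N x M matrix of association constants between N precursor
#' species and M probe instances and the total concentration of each,
#' finds the free concentrations satisfying mass action
#' (`bound_ij = K_ij * free_p_i * free_q_j`) and mass balance. Uses a
#' geometrically damped fixed-point iteration on the free concentrations,
#' which is robust across the enormous K spreads that cognate versus
#' mismatched tags produce.
#'
#' @param K N x M matrix of association constants (1/M), all finite and
#'   non-negative.
#' @param precursor_totals length-N vector of total precursor
#'   concentrations (mol/L).
#' @param probe_totals length-M vector of total probe-instance
#'   concentrations (mol/L).
#' @param tol convergence tolerance on the maximum relative mass-balance
#'   violation. Default 1e-9.
#' @param max_iter cap on damped fixed-point iterations before the solver
#'   switches to exact coordinate sweeps; if those stall too, a convergence
#'   error reports the residual.
#' @return list of class `snop_equilibrium`: `bound` (N x M, mol/L),
#'   `free_precursor`, `free_probe`, `residual`, `iterations`.
#' @export
solve_competitive_equilibrium <- function(K, precursor_totals, probe_totals,
                                          tol = 1e-9, max_iter = 10000) {
  K <- as.matrix(K)
  P <- as.numeric(precursor_totals); Q <- as.numeric(probe_totals)
  if (nrow(K) != length(P) || ncol(K) != length(Q)) {
    stop("K dimensions must match the totals vectors")
  }
  if (any(!is.finite(K)) || any(K < 0)) stop("K must be finite and >= 0")
  if (any(P < 0) || any(Q < 0)) stop("totals must be >= 0")

  residual_of <- function(fp, fq) {
    bound_p <- fp * as.vector(K %*% fq)
    bound_q <- fq * as.vector(crossprod(K, fp))
    rp <- abs(P - fp - bound_p) / pmax(P, .Machine$double.xmin)
    rq <- abs(Q - fq - bound_q) / pmax(Q, .Machine$double.xmin)
    max(c(rp[P > 0], rq[Q > 0], 0))
  }

  fp <- P; fq <- Q
  resid <- residual_of(fp, fq)
  it <- 0L
  while (it < max_iter && resid >= tol) {
    it <- it + 1L
    fp_new <- P / (1 + as.vector(K %*% fq))
    fq_new <- Q / (1 + as.vector(crossprod(K, fp)))
    fp <- sqrt(fp * fp_new)               # geometric (log-space) damping
    fq <- sqrt(fq * fq_new)
    resid <- residual_of(fp, fq)
  }

  # Stagnation fallback: sweep the probe balances, solving each exactly by
  # bisection with the free precursors eliminated (each balance is monotone
  # in its own free-probe concentration).
  if (resid >= tol) {
    s <- as.vector(K %*% fq)
    for (sweep in seq_len(500L)) {
      for (j in seq_along(Q)) {
        if (Q[j] == 0) { fq[j] <- 0; next }
        kj <- K[, j]
        base <- s - kj * fq[j]
        bal <- function(t) t * (1 + sum(kj * P / (1 + base + kj * t))) - Q[j]
        lo <- 0; hi <- Q[j]
        for (b in seq_len(80L)) {
          mid <- (lo + hi) / 2
          if (bal(mid) > 0) hi <- mid else lo <- mid
        }
        fq[j] <- (lo + hi) / 2
        s <- base + kj * fq[j]
      }
      fp <- P / (1 + s)
      it <- it + 1L
      resid <- residual_of(fp, fq)
      if (resid < tol) break
    }
  }
  if (resid >= tol) {
    stop(sprintf("equilibrium solver did not converge (residual %.3g)",
                 resid))
  }
  bound <- K * outer(fp, fq)
  structure(list(bound = bound, free_precursor = fp, free_probe = fq,
                 residual = resid, iterations = it),
            class = "snop_equilibrium")
}

#' Predicted product stoichiometry of a designed panel
#'
#' Builds the precursor-by-probe association-constant matrix from the
#' design's crosstalk free energies, solves the competitive equilibrium,
#' and reports the captured (hence released) amount of each product along
#' with the Gini coefficient and the fraction of products within 2-fold of
#' the median captured amount. When the probe is the limiting reagent and
#' binding is strong, captured amounts track the (roughly equal) probe
#' instance concentrations rather than the input precursor concentrations:
#' that is the normalization mechanism.
#'
#' @param assignment a [optimize_assignment()] result.
#' @param precursor_concs named vector of precursor total concentrations
#'   (mol/L), names matching the assignment's oligo ids.
#' @param probe_conc_per_instance total concentration of each probe
#'   instance (mol/L). Default is precursor median / 4, the 4x
#'   precursor-excess operating point.
#' @param params a [thermo_params()] object.
#' @return list with `captured` (named vector, mol/L), `yield` (captured /
#'   input per product), `gini`, `frac_within_2fold` (of the median
#'   captured amount), and the underlying `equilibrium` state.
#' @export
predicted_stoichiometry <- function(assignment, precursor_concs,
                                    probe_conc_per_instance = NULL,
                                    params = thermo_params()) {
  ids <- assignment$mapping$oligo_id
  if (!all(ids %in% names(precursor_concs))) {
    stop("precursor_concs must cover every oligo in the assignment")
  }
  P <- as.numeric(precursor_concs[ids])
  if (is.null(probe_conc_per_instance)) {
    probe_conc_per_instance <- stats::median(P) / 4
  }
  ct <- crosstalk_matrix(assignment, params)
  K <- equilibrium_constant(ct$values, params$temperature_K)
  Q <- rep(probe_conc_per_instance, ncol(K))
  st <- solve_competitive_equilibrium(K, P, Q)
  captured <- stats::setNames(rowSums(st$bound), ids)
  med <- stats::median(captured)
  gl <- gini_lorenz(captured)
  list(captured = captured,
       yield = ifelse(P > 0, captured / P, 0),
       gini = gl$gini,
       frac_within_2fold = mean(captured >= med / 2 & captured <= med * 2),
       equilibrium = st)
}
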