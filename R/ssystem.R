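#' Derive the S-system equivalent of a parameterized GMA instance
#'
#' After normalizing every pool to its (unknown) wild-type steady-state level,
#' `Y_i = X_i / X_iS`, each term's rate constant is replaced by its sampled
#' steady-state flux `V_kS`, so the wild-type operating point is `Y = 1` with
#' all derivatives zero. Aggregating each pool's production terms into one
#' power law and its consumption terms into another yields the S-system:
#' the aggregate rate `alpha_i` (`beta_i`) is the total steady-state
#' production (consumption) flux, and each aggregate kinetic order `g_ij`
#' (`h_ij`) is the flux-weighted mean of the contributing terms' kinetic
#' orders. At the operating point the S-system and the GMA model coincide
#' through first order.
#'
#' @param model a [build_gma()] model.
#' @param flux named flux vector (one `V_kS` per model term), e.g. a row of
#'   [sample_fluxes()]; all fluxes must be strictly positive.
#' @param korders named kinetic-order vector keyed `"term:variable"`, e.g. a
#'   row of [sample_kinetic_orders()].
#' @return An object of class `ssystem_instance`: list with aggregate
#'   exponent matrices `G`, `H` (pools x pools) and `GE`, `HE` (pools x
#'   enzymes), aggregate rates `alpha`, `beta`, the per-term exponent matrix
#'   `F`, enzyme matrix `E`, `stoich`, `flux`, and bookkeeping fields.
#' @export
derive_ssystem <- function(model, flux, korders) {
  stopifnot(inherits(model, "gma_model"))
  flux <- drop(as.matrix(flux))
  if (is.matrix(flux)) flux <- flux[1, ]
  v <- flux[model$terms$id]
  if (anyNA(v)) stop("flux values missing for some model terms")
  if (any(v <= 0)) stop("all steady-state fluxes must be strictly positive")

  F <- exponent_matrix(model, korders)
  E <- enzyme_matrix(model)
  S <- model$stoich
  nv <- nrow(S)

  P <- (S > 0) * 1   # production membership, pools x terms
  C <- (S < 0) * 1
  alpha <- as.numeric(P %*% v)
  beta <- as.numeric(C %*% v)
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("zero total production or consumption flux through a pool")
  }
  Wp <- P * rep(v, each = nv) / alpha
  Wc <- C * rep(v, each = nv) / beta

  structure(
    list(
      G = Wp %*% F, H = Wc %*% F,
      GE = Wp %*% E, HE = Wc %*% E,
      alpha = stats::setNames(alpha, rownames(S)),
      beta = stats::setNames(beta, rownames(S)),
      F = F, E = E, stoich = S, flux = v,
      metabolites = model$metabolites,
      reactions = model$terms$id,
      enzymes = model$enzymes,
      model = model
    ),
    class = "ssystem_instance"
  )
}

#' Effective enzyme multipliers of a perturbation scenario
#'
#' Starts from 1 for all six enzymes, applies the scenario's direct
#' multipliers (down-regulation `0 < v < 1`, knockout as small residual
#' activity), and, if `hierarchical` is `TRUE`, the hierarchical-regulation
#' multipliers as well (e.g. CCR1/CCoAOMT up-regulation in the *ccr2*
#' knockout).
#'
#' @param scenario a perturbation scenario (see [default_scenarios()]).
#' @param hierarchical apply the scenario's hierarchical multipliers?
#' @param enzymes enzyme symbols.
#' @return Named positive multiplier vector over the six enzymes.
#' @export
effective_multipliers <- function(scenario, hierarchical = FALSE,
                                  enzymes = base_scaffold()$enzymes) {
  m <- stats::setNames(rep(1, length(enzymes)), enzymes)
  for (e in names(scenario$multipliers)) m[[e]] <- scenario$multipliers[[e]]
  if (isTRUE(hierarchical)) {
    for (e in names(scenario$hierarchical_multipliers)) {
      m[[e]] <- m[[e]] * scenario$hierarchical_multipliers[[e]]
    }
  }
  if (any(m <= 0)) stop("enzyme multipliers must be positive")
  m
}

solution_shell <- function(ssys, rho_wt, multipliers) {
  list(y = stats::setNames(rep(NA_real_, length(ssys$metabolites)),
                           ssys$metabolites),
       flux_factors = stats::setNames(rep(NA_real_, length(ssys$reactions)),
                                      ssys$reactions),
       sg_ratio = NA_real_, ill_behaved = FALSE, degenerate = FALSE,
       ok = FALSE, rho_wt = rho_wt, multipliers = multipliers)
}

finish_solution <- function(sol, ssys, y, logm, fold_limit = 1000) {
  ff <- as.numeric(exp(ssys$F %*% y + ssys$E %*% logm))
  names(ff) <- ssys$reactions
  sol$y <- stats::setNames(as.numeric(y), ssys$metabolites)
  sol$flux_factors <- ff
  if (all(c("efflux_S", "efflux_G") %in% names(ff))) {
    sol$sg_ratio <- sol$rho_wt * ff[["efflux_S"]] / ff[["efflux_G"]]
  }
  sol$ill_behaved <- max(abs(y)) > log(fold_limit)  # strictly more than
  sol$ok <- !sol$ill_behaved
  sol
}

#' Solve a perturbed steady state in log-linear S-system form
#'
#' In log deviations `y_i = ln Y_i` the S-system steady-state condition is
#' the linear system `(G - H) y = (HE - GE) ln m`, where `m` holds the enzyme
#' multipliers. The solution yields per-reaction flux factors
#' `V/V_S = exp(F y) * prod(m^e)` and the predicted S/G ratio
#' `rho_wt * (S-efflux factor) / (G-efflux factor)`. An instantiation whose
#' system matrix is near-singular (reciprocal condition below `1e-12`) is
#' flagged `degenerate`; one predicting a more than 1000-fold change in any
#' pool is flagged `ill_behaved`. Neither raises an error.
#'
#' @param ssys a [derive_ssystem()] instance.
#' @param scenario a perturbation scenario, or a named multiplier vector.
#' @param rho_wt wild-type S/G ratio used to scale the prediction.
#' @param hierarchical apply hierarchical multipliers (ignored when
#'   `scenario` is already a multiplier vector).
#' @param fold_limit ill-behavedness threshold (default 1000-fold).
#' @return An object of class `steady_state_solution`: list with `y`
#'   (log deviations), `flux_factors`, `sg_ratio`, and flags `ill_behaved`,
#'   `degenerate`, `ok`.
#' @export
solve_steady_state <- function(ssys, scenario, rho_wt,
                               hierarchical = FALSE, fold_limit = 1000) {
  stopifnot(inherits(ssys, "ssystem_instance"))
  m <- if (is.numeric(scenario)) {
    full <- stats::setNames(rep(1, length(ssys$enzymes)), ssys$enzymes)
    full[names(scenario)] <- scenario
    full
  } else {
    effective_multipliers(scenario, hierarchical, ssys$enzymes)
  }
  sol <- solution_shell(ssys, rho_wt, m)
  A <- ssys$G - ssys$H
  logm <- log(m)
  b <- (ssys$HE - ssys$GE) %*% logm
  rc <- tryCatch(rcond(A), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    sol$degenerate <- TRUE
    class(sol) <- "steady_state_solution"
    return(sol)
  }
  y <- solve(A, b)
  sol <- finish_solution(sol, ssys, y, logm, fold_limit)
  class(sol) <- "steady_state_solution"
  sol
}

#' @export
print.steady_state_solution <- function(x, ...) {
  status <- if (x$degenerate) "degenerate"
            else if (x$ill_behaved) "ill-behaved"
            else "ok"
  cat("Steady state (", status, "): predicted S/G =",
      format(x$sg_ratio, digits = 4), "\n")
  invisible(x)
}

#' Numerical GMA steady state (oracle for the log-linear solver)
#'
#' Finds the fixed point of the normalized GMA system directly by damped
#' Newton iteration in log space, initialized at the wild-type operating
#' point `y = 0`. At the operating point the GMA and S-system models are
#' equivalent, so this routine provides an independent numerical check of
#' [solve_steady_state()]; it is intended for testing and diagnostics.
#'
#' @inheritParams solve_steady_state
#' @param tol residual tolerance (relative to the unit total influx).
#' @param max_iter Newton iteration cap; non-convergence is flagged via
#'   `converged = FALSE`, never an error.
#' @return A `steady_state_solution` with an extra `converged` flag.
#' @export
gma_numerical_steady_state <- function(ssys, scenario, rho_wt,
                                       hierarchical = FALSE,
                                       fold_limit = 1000,
                                       tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(ssys, "ssystem_instance"))
  m <- if (is.numeric(scenario)) {
    full <- stats::setNames(rep(1, length(ssys$enzymes)), ssys$enzymes)
    full[names(scenario)] <- scenario
    full
  } else {
    effective_multipliers(scenario, hierarchical, ssys$enzymes)
  }
  logm <- log(m)
  S <- ssys$stoich
  vS <- ssys$flux
  emod <- as.numeric(exp(ssys$E %*% logm))
  resid <- function(y) {
    as.numeric(S %*% (vS * emod * as.numeric(exp(ssys$F %*% y))))
  }
  y <- rep(0, nrow(S))
  r <- resid(y)
  converged <- max(abs(r)) < tol
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    v <- vS * emod * as.numeric(exp(ssys$F %*% y))
    J <- S %*% (v * ssys$F)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    t <- 1
    repeat {
      y_new <- y + t * step
      r_new <- resid(y_new)
      finite <- all(is.finite(r_new))
      if (finite && (max(abs(r_new)) < max(abs(r)) || t < 1e-6)) break
      if (t < 1e-8) break   # cannot make finite progress
      t <- t / 2
    }
    if (!all(is.finite(r_new))) break
    y <- y_new
    r <- r_new
    converged <- max(abs(r)) < tol
  }
  sol <- solution_shell(ssys, rho_wt, m)
  sol$converged <- converged
  if (converged) {
    sol <- finish_solution(sol, ssys, y, logm, fold_limit)
    sol$converged <- TRUE
  }
  class(sol) <- "steady_state_solution"
  sol
}

#' Predicted S/G ratio of a steady-state solution
#'
#' @param solution a `steady_state_solution`.
#' @param rho_wt wild-type S/G ratio.
#' @return `rho_wt` times the ratio of the S-efflux to G-efflux flux factors.
#' @export
compute_sg_ratio <- function(solution, rho_wt) {
  if (isTRUE(solution$degenerate)) {
    stop("cannot compute an S/G ratio from a degenerate solution")
  }
  rho_wt * solution$flux_factors[["efflux_S"]] /
    solution$flux_factors[["efflux_G"]]
}
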