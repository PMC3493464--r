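#' Steady-state flux constraints for a topology
#'
#' At steady state every dependent pool's balance turns into a linear equation
#' of fluxes. Together with the wild-type S/G flux-ratio row
#' `V_S - rho * V_G = 0`, the scale-fixing normalization `V_influx = 1`, and a
#' strict positivity bound `V_i >= epsilon` on every present reaction, these
#' define a bounded polytope P of admissible wild-type flux distributions.
#'
#' @param model a [build_gma()] model (its terms define the flux coordinates).
#' @param rho_wt wild-type S/G flux ratio (> 0).
#' @param epsilon lower bound per flux, as a fraction of the unit influx;
#'   default `1e-3`. A present edge carrying zero flux would be
#'   indistinguishable from an absent edge and would break the flux-weighted
#'   kinetic-order aggregation.
#' @return An object of class `flux_constraints`: list with equality matrix
#'   `A` (rows: one balance per dependent pool, the ratio row, the
#'   normalization row), right-hand side `b`, per-flux `lower` bounds, and
#'   `reactions` (column names).
#' @examples
#' cfg <- enumerate_configurations()
#' m <- build_gma(new_design(config_by_label("S", cfg)))
#' fc <- build_flux_constraints(m, rho_wt = 1)
#' fc$A[1, ]  # caffeoyl CoA balance: influx - CCR2 - methylation = 0
#' @export
build_flux_constraints <- function(model, rho_wt, epsilon = 1e-3) {
  stopifnot(inherits(model, "gma_model"), rho_wt > 0, epsilon > 0)
  reactions <- model$terms$id
  m <- length(reactions)
  A <- rbind(model$stoich, ratio = 0, normalization = 0)
  A["ratio", "efflux_S"] <- 1
  A["ratio", "efflux_G"] <- -rho_wt
  A["normalization", "influx"] <- 1
  b <- c(rep(0, nrow(model$stoich)), 0, 1)
  names(b) <- rownames(A)
  structure(
    list(A = A, b = b, lower = stats::setNames(rep(epsilon, m), reactions),
         reactions = reactions, rho_wt = rho_wt, epsilon = epsilon),
    class = "flux_constraints"
  )
}

# basic-feasible-solution enumeration for {x : A x = b, x >= lower}
basic_vertices <- function(A, b, lower, tol = 1e-9) {
  m <- ncol(A)
  rk <- qr(A)$rank
  d <- m - rk
  verts <- list()
  if (d == 0L) {
    x <- qr.solve(qr(A), b)
    if (max(abs(A %*% x - b)) < 1e-7 && all(x >= lower - tol)) {
      verts[[1L]] <- as.numeric(x)
    }
  } else {
    combos <- utils::combn(m, d)
    eye <- diag(m)
    for (j in seq_len(ncol(combos))) {
      act <- combos[, j]
      M <- rbind(A, eye[act, , drop = FALSE])
      qrM <- qr(M)
      if (qrM$rank < m) next
      rhs <- c(b, lower[act])
      x <- tryCatch(qr.coef(qrM, rhs), error = function(e) NULL)
      if (is.null(x) || anyNA(x)) next
      if (max(abs(M %*% x - rhs)) > 1e-7) next
      if (any(x < lower - tol)) next
      verts[[length(verts) + 1L]] <- as.numeric(x)
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, m))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V / tol) * tol), , drop = FALSE]
}

# bounded iff the recession cone {z : A z = 0, z >= 0} is trivial, i.e. the
# normalized cone section {A z = 0, sum z = 1, z >= 0} is empty
polytope_is_bounded <- function(A) {
  m <- ncol(A)
  A2 <- rbind(A, rep(1, m))
  b2 <- c(rep(0, nrow(A)), 1)
  nrow(basic_vertices(A2, b2, rep(0, m))) == 0L
}

#' Enumerate the extreme points of the flux polytope
#'
#' Exact vertex enumeration by scanning basic feasible solutions: every subset
#' of lower bounds whose active set, together with the equality rows, has full
#' column rank defines one candidate basic point, which is kept if feasible.
#' Vertices are deduplicated within tolerance. These extreme points play the
#' role of extreme pathways: every admissible wild-type flux vector is a
#' convex combination of them.
#'
#' @param constraints a [build_flux_constraints()] object.
#' @param tol deduplication/feasibility tolerance (default `1e-9`).
#' @return An object of class `flux_polytope`: list with `vertices` (matrix,
#'   one row per extreme point, columns named by reaction), `dim` (affine
#'   dimension), and the originating `constraints`.
#' @export
enumerate_vertices <- function(constraints, tol = 1e-9) {
  stopifnot(inherits(constraints, "flux_constraints"))
  A <- constraints$A
  if (!polytope_is_bounded(A)) {
    stop("flux constraint set is unbounded; a normalization row is missing")
  }
  V <- basic_vertices(A, constraints$b, constraints$lower, tol)
  if (nrow(V) == 0L) {
    stop("flux constraint set is infeasible for this topology")
  }
  colnames(V) <- constraints$reactions
  ctr <- sweep(V, 2, colMeans(V))
  adim <- if (nrow(V) == 1L) 0L else {
    sv <- svd(ctr)$d
    sum(sv > max(sv[1], 1) * 1e-9)
  }
  structure(
    list(vertices = V, dim = adim, constraints = constraints),
    class = "flux_polytope"
  )
}

#' @export
print.flux_polytope <- function(x, ...) {
  cat("Flux polytope:", nrow(x$vertices), "vertices in",
      ncol(x$vertices), "flux dimensions (affine dimension", x$dim, ")\n")
  invisible(x)
}

#' Sample wild-type flux vectors from the polytope
#'
#' Default measure: flat Dirichlet weights over the vertices, matching the
#' convex-combination parameterization `V = sum_i lambda_i u_i` literally.
#' `method = "hitandrun"` instead runs a hit-and-run walk in the polytope's
#' affine hull for an approximately uniform measure over P.
#'
#' @param polytope a [enumerate_vertices()] object.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @param method `"dirichlet"` (default) or `"hitandrun"`.
#' @param burn,thin hit-and-run walk controls.
#' @return An `n x m` matrix of fluxes (columns named by reaction); for the
#'   Dirichlet method the convex weights are attached as attribute
#'   `"lambda"`.
#' @export
sample_fluxes <- function(polytope, n = 1L, seed = NULL,
                          method = c("dirichlet", "hitandrun"),
                          burn = 100L, thin = 5L) {
  stopifnot(inherits(polytope, "flux_polytope"), n >= 1)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  U <- polytope$vertices
  v <- nrow(U)
  if (method == "dirichlet" || polytope$dim == 0L) {
    lam <- matrix(stats::rgamma(n * v, shape = 1), n, v)
    lam <- lam / rowSums(lam)
    X <- lam %*% U
    colnames(X) <- colnames(U)
    attr(X, "lambda") <- lam
    return(X)
  }
  # hit-and-run in the null space of the equality rows
  cns <- polytope$constraints
  N <- qr.Q(qr(t(cns$A)), complete = TRUE)[, -seq_len(qr(cns$A)$rank),
                                           drop = FALSE]
  x <- colMeans(U)
  lower <- cns$lower
  X <- matrix(NA_real_, n, ncol(U), dimnames = list(NULL, colnames(U)))
  steps <- burn + n * thin
  kept <- 0L
  for (s in seq_len(steps)) {
    dirn <- N %*% stats::rnorm(ncol(N))
    dirn <- as.numeric(dirn / sqrt(sum(dirn^2)))
    # chord limits from x + t * dirn >= lower
    tlo <- -Inf; thi <- Inf
    for (i in seq_along(x)) {
      if (abs(dirn[i]) < 1e-14) next
      t_bound <- (lower[i] - x[i]) / dirn[i]
      if (dirn[i] > 0) tlo <- max(tlo, t_bound) else thi <- min(thi, t_bound)
    }
    if (is.finite(tlo) && is.finite(thi) && thi > tlo) {
      x <- x + stats::runif(1, tlo, thi) * dirn
    }
    if (s > burn && (s - burn) %% thin == 0L) {
      kept <- kept + 1L
      X[kept, ] <- x
    }
  }
  X
}

#' Check a flux vector against its constraint set
#'
#' @param sample a flux vector or matrix of row vectors.
#' @param constraints a [build_flux_constraints()] object.
#' @param tol tolerance on equalities and bounds.
#' @return `TRUE` iff every row satisfies all equalities and bounds within
#'   `tol`.
#' @export
validate_flux_sample <- function(sample, constraints, tol = 1e-9) {
  X <- if (is.matrix(sample)) sample else matrix(sample, nrow = 1)
  res <- X %*% t(constraints$A)
  eq_ok <- max(abs(sweep(res, 2, constraints$b))) <= tol
  lb_ok <- all(sweep(X, 2, constraints$lower) >= -tol)
  eq_ok && lb_ok
}

#' Dump polytope vertices (and constraint matrix) as TSV
#'
#' @param polytope a [enumerate_vertices()] object.
#' @param path output TSV path for the vertices.
#' @param constraints_path optional TSV path for the equality matrix.
#' @return `path`, invisibly.
#' @export
write_polytope_tsv <- function(polytope, path, constraints_path = NULL) {
  utils::write.table(as.data.frame(polytope$vertices), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(constraints_path)) {
    A <- as.data.frame(polytope$constraints$A)
    A <- cbind(row = rownames(polytope$constraints$A), A,
               b = polytope$constraints$b)
    utils::write.table(A, constraints_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
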