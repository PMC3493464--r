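#' Validity criteria for the design screen
#'
#' * Quantitative correctness: the mean squared difference between predicted
#'   and observed S/G ratios over the quantitative (alfalfa) lines must be
#'   below `mse_threshold`.
#' * Qualitative correctness: each qualitative (knockout) line's predicted
#'   S/G must move beyond `qual_margin` of the wild-type ratio in the
#'   observed direction (predictions within the margin strip count as
#'   unchanged).
#' * Relaxed screen: an instantiation also counts if every quantitative line
#'   is within `relaxed_pct` relative error (relaxation never removes a
#'   strictly valid instantiation, so Q <= Q').
#' * Instantiations predicting more than a `fold_limit` change in any pool in
#'   any scenario are ill-behaved and excluded.
#'
#' @param mse_threshold squared S/G units; default 0.01.
#' @param qual_margin fraction of wild type; default 0.05.
#' @param relaxed_pct relative error allowed by the relaxed screen; 0.25.
#' @param fold_limit exclusion fold-change; 1000.
#' @return A `validity_criteria` list.
#' @export
validity_criteria <- function(mse_threshold = 0.01, qual_margin = 0.05,
                              relaxed_pct = 0.25, fold_limit = 1000) {
  stopifnot(mse_threshold > 0, qual_margin > 0, relaxed_pct > 0,
            fold_limit > 0)
  structure(list(mse_threshold = mse_threshold, qual_margin = qual_margin,
                 relaxed_pct = relaxed_pct, fold_limit = fold_limit),
            class = "validity_criteria")
}

#' Classify one model instantiation against the observations
#'
#' @param predictions named list over the four scenarios; each element either
#'   a [solve_steady_state()] solution or a list with `sg_ratio`,
#'   `ill_behaved`, `degenerate`.
#' @param observed a `scenario_set` (provides `rho_wt`, observed values and
#'   directions).
#' @param criteria a [validity_criteria()] list.
#' @return One of `"valid"`, `"valid_relaxed_only"`, `"invalid"`,
#'   `"ill_behaved"`.
#' @export
evaluate_instantiation <- function(predictions, observed,
                                   criteria = validity_criteria()) {
  missing <- setdiff(names(observed$scenarios), names(predictions))
  if (length(missing)) {
    stop("missing prediction for scenario '",
         paste(missing, collapse = "', '"), "'")
  }
  flags <- vapply(predictions, function(p) {
    isTRUE(p$ill_behaved) || isTRUE(p$degenerate)
  }, logical(1))
  if (any(flags)) return("ill_behaved")

  rho <- observed$rho_wt
  sq_err <- c()
  rel_ok <- TRUE
  qual_ok <- TRUE
  for (nm in names(observed$scenarios)) {
    sc <- observed$scenarios[[nm]]
    pred <- predictions[[nm]]$sg_ratio
    if (!is.null(sc$observed_sg)) {
      sq_err <- c(sq_err, (pred - sc$observed_sg)^2)
      rel_ok <- rel_ok &&
        abs(pred - sc$observed_sg) / sc$observed_sg <= criteria$relaxed_pct
    } else {
      qual_ok <- qual_ok && switch(sc$direction,
        down = pred < (1 - criteria$qual_margin) * rho,
        up = pred > (1 + criteria$qual_margin) * rho
      )
    }
  }
  quant_ok <- length(sq_err) == 0L || mean(sq_err) < criteria$mse_threshold
  if (quant_ok && qual_ok) return("valid")
  if ((rel_ok || quant_ok) && qual_ok) return("valid_relaxed_only")
  "invalid"
}

derive_seed <- function(seed, index) {
  ((as.double(seed) %% 2147483647) * 48271 + index * 16807) %% 2147483647 + 1
}

# Precompute everything reusable across the Monte-Carlo ensemble of a design.
compile_design <- function(design, scenario_set,
                           criteria = validity_criteria(),
                           overrides = NULL, epsilon = 1e-3,
                           scaffold = base_scaffold()) {
  model <- build_gma(design, scaffold)
  bounds <- default_bounds(model, overrides)
  constraints <- build_flux_constraints(model, scenario_set$rho_wt, epsilon)
  polytope <- enumerate_vertices(constraints)

  nt <- nrow(model$terms)
  nv <- length(model$metabolites)
  F0 <- matrix(0, nt, nv, dimnames = list(model$terms$id, model$metabolites))
  slot_idx <- cbind(match(bounds$term, model$terms$id),
                    match(bounds$variable, model$metabolites))
  slot_lin <- (slot_idx[, 2] - 1L) * nt + slot_idx[, 1]
  E <- enzyme_matrix(model)
  S <- model$stoich
  Pmask <- (S > 0) * 1
  Cmask <- (S < 0) * 1

  scen_names <- names(scenario_set$scenarios)
  logM <- vapply(scenario_set$scenarios, function(sc) {
    log(effective_multipliers(sc, design$hierarchical, model$enzymes))
  }, numeric(length(model$enzymes)))
  EL <- E %*% logM  # per-term enzyme log contribution, terms x scenarios

  quant <- vapply(scenario_set$scenarios,
                  function(sc) !is.null(sc$observed_sg), logical(1))
  observed_sg <- vapply(scenario_set$scenarios,
                        function(sc) sc$observed_sg %||% NA_real_,
                        numeric(1))
  directions <- vapply(scenario_set$scenarios,
                       function(sc) sc$direction %||% NA_character_,
                       character(1))

  list(design = design, model = model, bounds = bounds,
       constraints = constraints, polytope = polytope,
       criteria = criteria, rho_wt = scenario_set$rho_wt,
       F0 = F0, slot_lin = slot_lin, E = E, EL = EL,
       Pmask = Pmask, Cmask = Cmask,
       iS = match("efflux_S", model$terms$id),
       iG = match("efflux_G", model$terms$id),
       scen_names = scen_names, quant = quant,
       observed_sg = observed_sg, directions = directions,
       scenario_set = scenario_set)
}

# Draw and solve n instantiations of a compiled design. Returns per-
# instantiation predictions, flags, and (optionally) log-deviations of the
# valid ones. Draw order is fixed, so a given seed fully determines the
# ensemble.
screen_kernel <- function(cd, n, seed, keep_records = TRUE) {
  set.seed(seed)
  U <- cd$polytope$vertices
  v <- nrow(U)
  nt <- nrow(cd$F0)
  nv <- ncol(cd$F0)
  ns <- length(cd$scen_names)
  nk <- length(cd$slot_lin)

  lam <- matrix(stats::rgamma(n * v, shape = 1), n, v)
  lam <- lam / rowSums(lam)
  V <- lam %*% U
  K <- matrix(stats::runif(n * nk), n, nk)
  K <- sweep(sweep(K, 2, cd$bounds$hi - cd$bounds$lo, "*"), 2,
             cd$bounds$lo, "+")

  ln_lim <- log(cd$criteria$fold_limit)
  dSG_E <- cd$EL[cd$iS, ] - cd$EL[cd$iG, ]

  preds <- matrix(NA_real_, n, ns, dimnames = list(NULL, cd$scen_names))
  ill <- logical(n)
  degen <- logical(n)
  ymax <- numeric(n)
  Ys <- if (keep_records) vector("list", n) else NULL

  for (i in seq_len(n)) {
    vi <- V[i, ]
    F <- cd$F0
    F[cd$slot_lin] <- K[i, ]
    alpha <- as.numeric(cd$Pmask %*% vi)
    beta <- as.numeric(cd$Cmask %*% vi)
    W <- cd$Pmask * rep(vi, each = nv) / alpha -
      cd$Cmask * rep(vi, each = nv) / beta
    A <- W %*% F
    rc <- tryCatch(rcond(A), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12) {
      degen[i] <- TRUE
      next
    }
    Y <- solve(A, -(W %*% cd$EL))
    ymax[i] <- max(abs(Y))
    ill[i] <- ymax[i] > ln_lim
    preds[i, ] <- cd$rho_wt *
      exp(as.numeric((F[cd$iS, ] - F[cd$iG, ]) %*% Y) + dSG_E)
    if (keep_records) Ys[[i]] <- Y
  }

  list(preds = preds, ill = ill, degen = degen, V = V, K = K, Ys = Ys)
}

classify_ensemble <- function(cd, kr) {
  crit <- cd$criteria
  rho <- cd$rho_wt
  n <- nrow(kr$preds)
  usable <- !kr$ill & !kr$degen

  qual_ok <- rep(TRUE, n)
  for (j in which(!is.na(cd$directions))) {
    qual_ok <- qual_ok & switch(cd$directions[j],
      down = kr$preds[, j] < (1 - crit$qual_margin) * rho,
      up = kr$preds[, j] > (1 + crit$qual_margin) * rho
    )
  }
  qj <- which(cd$quant)
  if (length(qj)) {
    err <- sweep(kr$preds[, qj, drop = FALSE], 2, cd$observed_sg[qj])
    mse <- rowMeans(err^2)
    quant_ok <- mse < crit$mse_threshold
    rel <- sweep(abs(err), 2, cd$observed_sg[qj], "/")
    relaxed_ok <- quant_ok |
      apply(rel <= crit$relaxed_pct, 1, all)
  } else {
    quant_ok <- relaxed_ok <- rep(TRUE, n)
  }

  j1 <- match("ccr1_ko", cd$scen_names)
  j2 <- match("ccr2_ko", cd$scen_names)
  ccr2_up <- usable & kr$preds[, j2] > (1 + crit$qual_margin) * rho
  nw <- ccr2_up & kr$preds[, j1] < (1 - crit$qual_margin) * rho

  list(valid = usable & quant_ok & qual_ok,
       valid_relaxed = usable & relaxed_ok & qual_ok,
       ccr2_up = ccr2_up, nw = nw, usable = usable)
}

#' Screen one design with a Monte-Carlo model ensemble
#'
#' Draws `n` independently parameterized instantiations of the design
#' (wild-type fluxes from the constrained polytope, kinetic orders from their
#' sign-constrained ranges), derives each instantiation's S-system, solves
#' all four perturbation scenarios in log-linear form, and classifies every
#' instantiation against the observations. `Q` counts strictly valid
#' instantiations, `Q_prime` those valid under the relaxed quantitative
#' screen; ill-behaved (more than 1000-fold pool change) and degenerate
#' (singular system) instantiations are tallied and excluded.
#'
#' @param design a `lignin_design`.
#' @param scenario_set a `scenario_set` (see [default_scenarios()],
#'   [load_scenarios()]).
#' @param n ensemble size (>= 1).
#' @param seed integer seed; the ensemble is a deterministic function of it.
#' @param criteria a [validity_criteria()] list.
#' @param keep_records keep per-instantiation records (predicted S/G for all
#'   scenarios, pool log-deviations) for the valid instantiations?
#' @param overrides kinetic-order bound overrides (see [default_bounds()]).
#' @param epsilon flux positivity bound (see [build_flux_constraints()]).
#' @param scaffold pathway scaffold.
#' @return An object of class `design_screen_result`: list with `design`
#'   label, counts `n`, `n_ill_behaved`, `n_degenerate`, `Q`, `Q_prime`,
#'   `n_ccr2_up`, `n_nw`, the `predictions` matrix, and `valid_records` (a
#'   data frame, one row per strictly valid instantiation).
#' @export
screen_design <- function(design, scenario_set, n, seed,
                          criteria = validity_criteria(),
                          keep_records = TRUE, overrides = NULL,
                          epsilon = 1e-3, scaffold = base_scaffold()) {
  stopifnot(n >= 1)
  cd <- compile_design(design, scenario_set, criteria, overrides, epsilon,
                       scaffold)
  kr <- screen_kernel(cd, n, seed, keep_records)
  cl <- classify_ensemble(cd, kr)

  records <- NULL
  if (keep_records) {
    idx <- which(cl$valid)
    if (length(idx)) {
      rows <- lapply(idx, function(i) {
        y <- kr$Ys[[i]]
        yv <- as.numeric(y)
        names(yv) <- paste0("y.", rep(cd$scen_names,
                                      each = nrow(y)), ".",
                            rep(cd$model$metabolites, ncol(y)))
        c(stats::setNames(kr$preds[i, ], paste0("sg.", cd$scen_names)), yv)
      })
      records <- data.frame(instantiation = idx,
                            do.call(rbind, rows),
                            check.names = FALSE)
    }
  }

  structure(
    list(design = design$label,
         topology = design$topology$label,
         pattern = pattern_label(design$crosstalk),
         hierarchical = design$hierarchical,
         n = n, seed = seed,
         n_ill_behaved = sum(kr$ill),
         n_degenerate = sum(kr$degen),
         Q = sum(cl$valid),
         Q_prime = sum(cl$valid_relaxed),
         n_ccr2_up = sum(cl$ccr2_up),
         n_nw = sum(cl$nw),
         predictions = kr$preds,
         ill_behaved = kr$ill,
         degenerate = kr$degen,
         valid = cl$valid,
         nw = cl$nw,
         valid_records = records,
         criteria = criteria,
         rho_wt = cd$rho_wt),
    class = "design_screen_result"
  )
}

#' @export
print.design_screen_result <- function(x, ...) {
  cat("Screen of design", x$design, ": n =", x$n,
      "| Q =", x$Q, "| Q' =", x$Q_prime,
      "| ill-behaved =", x$n_ill_behaved,
      "| degenerate =", x$n_degenerate,
      "| NW quadrant =", x$n_nw, "\n")
  invisible(x)
}

#' Screen a full design family
#'
#' Runs [screen_design()] for every design and assembles Q (and related
#' counts) into crosstalk-pattern x topology matrices, plus the
#' "filled-circle" boolean matrix `Q > 0` used to summarize which designs
#' admit at least one valid instantiation.
#'
#' Per-design seeds are derived deterministically from `seed` and the design
#' index, so results do not depend on evaluation order.
#'
#' @param designs list of designs from [enumerate_designs()].
#' @param scenario_set,n,seed,criteria,keep_records,overrides,epsilon,scaffold
#'   passed to [screen_design()].
#' @param progress print one line per design?
#' @return An object of class `design_screen_matrix`: list with `results`
#'   (per-design screen results), matrices `Q`, `Q_prime`, `nw`, `ccr2_up`,
#'   `filled` (patterns x topologies), and `row_flagged` (patterns with any
#'   filled cell).
#' @export
screen_all <- function(designs, scenario_set, n, seed,
                       criteria = validity_criteria(),
                       keep_records = FALSE, overrides = NULL,
                       epsilon = 1e-3, scaffold = base_scaffold(),
                       progress = FALSE) {
  topo <- unique(vapply(designs, function(d) d$topology$label, character(1)))
  pats <- unique(vapply(designs, function(d) pattern_label(d$crosstalk),
                        character(1)))
  mk <- function() matrix(0L, length(pats), length(topo),
                          dimnames = list(pats, topo))
  Q <- Qp <- NW <- UP <- mk()
  results <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    r <- suppressWarnings(
      screen_design(d, scenario_set, n, derive_seed(seed, i), criteria,
                    keep_records = keep_records, overrides = overrides,
                    epsilon = epsilon, scaffold = scaffold)
    )
    results[[i]] <- r
    p <- pattern_label(d$crosstalk)
    t <- d$topology$label
    Q[p, t] <- r$Q
    Qp[p, t] <- r$Q_prime
    NW[p, t] <- r$n_nw
    UP[p, t] <- r$n_ccr2_up
    if (progress) {
      cat(sprintf("[%3d/%d] %-18s Q=%d Q'=%d nw=%d\n", i, length(designs),
                  r$design, r$Q, r$Q_prime, r$n_nw))
    }
  }
  structure(
    list(results = results, Q = Q, Q_prime = Qp, nw = NW, ccr2_up = UP,
         filled = Q > 0, row_flagged = rowSums(Q > 0) > 0,
         n = n, seed = seed, criteria = criteria),
    class = "design_screen_matrix"
  )
}

#' @export
print.design_screen_matrix <- function(x, ...) {
  cat("Design screen:", length(x$results), "designs, n =", x$n,
      "per design\n")
  cat("Designs with Q > 0:", sum(x$filled), "| crosstalk rows flagged:",
      sum(x$row_flagged), "\n")
  invisible(x)
}

#' Median and IQR of a metabolite's relative level across valid models
#'
#' Summarizes `exp(y_metabolite)` (pool level relative to wild type) over the
#' valid instantiations of a screen, for one perturbation scenario.
#'
#' @param result a [screen_design()] result with records, or its
#'   `valid_records` data frame.
#' @param metabolite pool id (e.g. `"X2"` for caffeyl aldehyde).
#' @param scenario scenario name (e.g. `"ccr2_ko"`).
#' @return List with `median`, `iqr`, and `n` (number of valid records).
#' @export
summarize_metabolite <- function(result, metabolite, scenario) {
  records <- if (inherits(result, "design_screen_result")) {
    result$valid_records
  } else {
    result
  }
  if (is.null(records) || nrow(records) == 0L) {
    stop("no valid model instantiations to summarize")
  }
  col <- paste0("y.", scenario, ".", metabolite)
  if (!col %in% names(records)) {
    stop("no record column for scenario '", scenario, "' and metabolite '",
         metabolite, "'")
  }
  lev <- exp(records[[col]])
  list(median = stats::median(lev), iqr = stats::IQR(lev), n = length(lev))
}
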