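#' Generate a synthetic observation scenario from a known ground-truth design
#'
#' Samples one instantiation of `true_design` (wild-type fluxes plus kinetic
#' orders, exactly as the screening kernel would draw them), solves the four
#' perturbation scenarios, and emits the predictions as a new scenario set:
#' quantitative observed S/G values for the two down-regulation lines
#' (optionally perturbed by multiplicative lognormal noise of scale
#' `noise_sd`) and qualitative directions for the two knockout lines. All
#' values are tagged `provenance: synthetic`. Screening the true design
#' against its own synthetic scenario must recover it (`Q > 0`).
#'
#' A draw is rejected and retried (with the next seed) if any scenario is
#' ill-behaved or degenerate. A knockout line whose prediction falls inside
#' the qualitative margin strip (where a direction would be undefined — e.g.
#' *ccr1* has exactly no phenotype in the channels-only topology) is emitted
#' as a quantitative observation instead of a direction.
#'
#' @param true_design a `lignin_design`.
#' @param seed integer seed for the instantiation draw (and noise).
#' @param noise_sd standard deviation of lognormal observation noise on the
#'   quantitative lines; 0 (default) emits the exact predictions.
#' @param scenario_set template providing `rho_wt` and the perturbation
#'   multipliers; defaults to [default_scenarios()].
#' @param criteria margins used to check direction definedness.
#' @param max_tries bounded retry count.
#' @param scaffold pathway scaffold.
#' @return A `scenario_set` with attributes `instantiation_seed` (the seed of
#'   the accepted draw) and `predictions` (the four exact predicted ratios).
#' @export
generate_synthetic_scenario <- function(true_design, seed, noise_sd = 0,
                                        scenario_set = default_scenarios(),
                                        criteria = validity_criteria(),
                                        max_tries = 100L,
                                        scaffold = base_scaffold()) {
  cd <- suppressWarnings(
    compile_design(true_design, scenario_set, criteria, scaffold = scaffold)
  )
  margin <- criteria$qual_margin
  rho <- cd$rho_wt
  for (t in seq_len(max_tries)) {
    try_seed <- if (t == 1L) seed else derive_seed(seed, t - 1L)
    kr <- screen_kernel(cd, n = 1L, seed = try_seed, keep_records = FALSE)
    if (kr$ill[1] || kr$degen[1]) next
    preds <- kr$preds[1, ]

    out <- scenario_set
    for (nm in names(out$scenarios)) {
      j <- match(nm, cd$scen_names)
      sc <- out$scenarios[[nm]]
      in_strip <- abs(preds[j] - rho) <= margin * rho
      if (!is.null(sc$observed_sg) || in_strip) {
        obs <- preds[j]
        if (noise_sd > 0) obs <- obs * exp(stats::rnorm(1, 0, noise_sd))
        sc$observed_sg <- as.numeric(obs)
        sc$direction <- NULL
      } else {
        sc$direction <- if (preds[j] > rho) "up" else "down"
        sc$observed_sg <- NULL
      }
      sc$provenance <- "synthetic"
      out$scenarios[[nm]] <- sc
    }
    out$rho_provenance <- "synthetic"
    attr(out, "instantiation_seed") <- try_seed
    attr(out, "predictions") <- preds
    attr(out, "true_design") <- true_design$label
    return(out)
  }
  stop("failed to draw a well-behaved ground-truth instantiation of design ",
       true_design$label, " after ", max_tries, " tries")
}
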