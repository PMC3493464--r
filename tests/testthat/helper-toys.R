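# Shared fixtures: independent oracles and minimal hand-built model objects.

# Independent brute-force enumeration of admissible optional-edge subsets,
# written directly from the admissibility rules (bitmask loop, no shared code
# with the package's enumerator).
oracle_enumerate_masks <- function(both_directions = TRUE) {
  keep <- list()
  for (mask in 0:63) {
    fCOMT <- bitwAnd(mask, 1L) > 0
    Sch <- bitwAnd(mask, 2L) > 0
    fCCR1 <- bitwAnd(mask, 4L) > 0
    Gch <- bitwAnd(mask, 8L) > 0
    fCAD <- bitwAnd(mask, 16L) > 0
    fF5H <- bitwAnd(mask, 32L) > 0
    if (!(fCOMT || Sch)) next          # caffeyl aldehyde must be drained
    if (!(fCCR1 || Gch)) next          # feruloyl CoA must be drained
    if (!(Gch || fCAD)) next           # coniferyl alcohol must be fed
    if (!(Sch || fF5H)) next           # 5-OH-coniferyl aldehyde must be fed
    produced <- fCOMT || fCCR1
    consumed <- fCAD || fF5H
    if (produced && !consumed) next
    if (both_directions && consumed && !produced) next
    keep[[length(keep) + 1L]] <- c(free_COMT = fCOMT, S_channel = Sch,
                                   free_CCR1 = fCCR1, G_channel = Gch,
                                   free_CAD = fCAD, free_F5H = fF5H)
  }
  do.call(rbind, keep)
}

# single-pool toy: constant influx, one efflux with substrate kinetic order h
# carried by one enzyme; closed-form perturbed level Y* = m^(-1/h)
make_single_pool <- function(h, flux = 1) {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("P1", c("in", "out")))
  F <- matrix(c(0, h), 2, 1, dimnames = list(c("in", "out"), "P1"))
  E <- matrix(c(0, 1), 2, 1, dimnames = list(c("in", "out"), "E1"))
  structure(
    list(G = matrix(0, 1, 1, dimnames = list("P1", "P1")),
         H = matrix(h, 1, 1, dimnames = list("P1", "P1")),
         GE = matrix(0, 1, 1, dimnames = list("P1", "E1")),
         HE = matrix(1, 1, 1, dimnames = list("P1", "E1")),
         alpha = c(P1 = flux), beta = c(P1 = flux),
         F = F, E = E, stoich = S,
         flux = c("in" = flux, out = flux),
         metabolites = "P1", reactions = c("in", "out"), enzymes = "E1",
         model = NULL),
    class = "ssystem_instance"
  )
}

# hand-made flux constraint set (bypasses the pathway scaffold)
make_constraints <- function(A, b, lower, reactions = colnames(A)) {
  if (is.null(reactions)) reactions <- paste0("v", seq_len(ncol(A)))
  colnames(A) <- reactions
  structure(list(A = A, b = b,
                 lower = stats::setNames(lower, reactions),
                 reactions = reactions, rho_wt = NA_real_, epsilon = NA_real_),
            class = "flux_constraints")
}

# one random, fully parameterized instantiation of a design
random_instance <- function(design, rho_wt = 0.5, seed = 1) {
  model <- suppressWarnings(build_gma(design))
  pt <- enumerate_vertices(build_flux_constraints(model, rho_wt))
  flux <- sample_fluxes(pt, n = 1, seed = seed)[1, ]
  bounds <- default_bounds(model)
  k <- sample_kinetic_orders(bounds, n = 1, seed = seed + 1)[1, ]
  list(model = model, flux = flux, korders = k,
       ssys = derive_ssystem(model, flux, k))
}

default_configs <- enumerate_configurations()
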