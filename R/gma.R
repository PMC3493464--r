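#' Build the symbolic Generalized Mass Action model for a design
#'
#' Every flux present in the design's topology becomes one power-law term
#' `gamma_i * prod_j X_j^f_ij`: a constant influx into caffeoyl CoA, one term
#' per enzymatic step, and one efflux per lignin sink (G, 5HG, S). Substrates
#' enter their term with a positive kinetic order, enzymes with kinetic order
#' fixed at 1, and each crosstalk mechanism of the design adds a signed
#' effector exponent to its target term (or, for M5, turns the substrate
#' exponent of the free-COMT term into an apparent inhibition). Rate constants
#' remain symbolic: they are eliminated later by normalization to a sampled
#' wild-type steady state.
#'
#' A mechanism whose target reaction is absent from the topology (M4/M5 when
#' the free-COMT edge is off) is recorded as vacuous with a warning; it alters
#' nothing.
#'
#' @param design a [new_design()] / [enumerate_designs()] object.
#' @param scaffold a [base_scaffold()]; must be the scaffold the design's
#'   topology was enumerated on.
#' @return An object of class `gma_model`: list with `design`, `metabolites`
#'   (present dependent pool ids), `enzymes`, `terms` (data frame of present
#'   reactions), `stoich` (signed membership matrix, pools x terms), `slots`
#'   (data frame of kinetic-order slots: `term`, `variable`, `role`,
#'   `mechanism`), and `vacuous` (character vector of vacuous mechanism ids).
#' @examples
#' cfg <- enumerate_configurations()
#' m <- build_gma(new_design(config_by_label("A", cfg)))
#' length(m$metabolites)  # 7
#' @export
build_gma <- function(design, scaffold = base_scaffold()) {
  stopifnot(inherits(design, "lignin_design"))
  bits <- unlist(design$topology[, scaffold$optional_edges])
  terms <- present_reactions(scaffold, bits)
  mets <- present_metabolites(scaffold, bits)

  nv <- length(mets)
  nt <- nrow(terms)
  stoich <- matrix(0L, nv, nt, dimnames = list(mets, terms$id))
  for (k in seq_len(nt)) {
    s <- terms$substrate[k]
    p <- terms$product[k]
    if (!is.na(s) && s %in% mets) stoich[s, k] <- -1L
    if (p %in% mets) stoich[p, k] <- stoich[p, k] + 1L
  }

  # substrate slots
  has_sub <- !is.na(terms$substrate)
  slots <- data.frame(
    term = terms$id[has_sub],
    variable = terms$substrate[has_sub],
    role = "substrate",
    mechanism = NA_character_,
    stringsAsFactors = FALSE
  )

  mechs <- crosstalk_mechanisms()
  vacuous <- character(0)
  for (m in design$crosstalk) {
    row <- mechs[mechs$id == m, ]
    if (!row$target %in% terms$id) {
      vacuous <- c(vacuous, m)
      warning("mechanism ", m, " is vacuous in topology ",
              design$topology$label, " (target reaction ", row$target,
              " absent)", call. = FALSE)
      next
    }
    if (row$substrate_inhibition) {
      # M5: the substrate's apparent kinetic order becomes negative
      i <- which(slots$term == row$target & slots$variable == row$effector &
                   slots$role == "substrate")
      slots$role[i] <- "inhibitor"
      slots$mechanism[i] <- m
    } else {
      slots <- rbind(slots, data.frame(
        term = row$target, variable = row$effector,
        role = if (row$sign > 0) "activator" else "inhibitor",
        mechanism = m, stringsAsFactors = FALSE
      ))
    }
  }
  rownames(slots) <- NULL

  structure(
    list(
      design = design,
      metabolites = mets,
      enzymes = scaffold$enzymes,
      terms = terms,
      stoich = stoich,
      slots = slots,
      vacuous = vacuous
    ),
    class = "gma_model"
  )
}

#' @export
print.gma_model <- function(x, ...) {
  cat("GMA model for design", x$design$label, "-",
      length(x$metabolites), "dependent variables,",
      length(x$enzymes), "independent (enzyme) variables,",
      nrow(x$terms), "power-law terms,",
      nrow(x$slots), "sampled kinetic orders\n")
  if (length(x$vacuous)) cat("vacuous mechanisms:",
                             paste(x$vacuous, collapse = ", "), "\n")
  invisible(x)
}

slot_key <- function(slots) paste(slots$term, slots$variable, sep = ":")

default_range_for_role <- function(role) {
  switch(role,
    substrate = c(0.1, 1.0),
    inhibitor = c(-1.0, -0.1),
    activator = c(0.1, 1.0),
    stop("unknown kinetic-order role: ", role)
  )
}

check_range_sign <- function(role, lo, hi) {
  if (!(is.finite(lo) && is.finite(hi) && lo <= hi)) {
    stop("empty or invalid kinetic-order interval [", lo, ", ", hi, "]")
  }
  ok <- switch(role,
    substrate = ,
    activator = lo > 0 && hi <= 1,
    inhibitor = hi < 0 && lo >= -1
  )
  if (!ok) {
    stop("kinetic-order interval [", lo, ", ", hi, "] violates the sign ",
         "rule for role '", role, "' (substrates/activators in (0, 1], ",
         "inhibitors in [-1, 0))")
  }
  invisible(TRUE)
}

#' Default kinetic-order bounds for a model
#'
#' One closed interval per sampled kinetic order: substrates `[0.1, 1]`,
#' inhibitors `[-1, -0.1]`, activators `[0.1, 1]`. Enzyme kinetic orders are
#' fixed at 1 by convention and are not sampled, hence carry no bounds. The
#' M5 substrate-inhibition slot uses `m5_range`.
#'
#' @param model a [build_gma()] model.
#' @param overrides optional named list, names `"term:variable"`, values
#'   `c(lo, hi)`. An override violating the slot's sign rule is an error.
#' @param m5_range interval for the free-COMT substrate exponent under M5.
#' @return A data frame of class `kinetic_order_bounds`: `term`, `variable`,
#'   `role`, `mechanism`, `lo`, `hi`.
#' @export
default_bounds <- function(model, overrides = NULL,
                           m5_range = c(-1.0, -0.1)) {
  stopifnot(inherits(model, "gma_model"))
  b <- model$slots
  rng <- t(vapply(seq_len(nrow(b)), function(i) {
    if (identical(b$mechanism[i], "M5")) m5_range
    else default_range_for_role(b$role[i])
  }, numeric(2)))
  b$lo <- rng[, 1]
  b$hi <- rng[, 2]
  keys <- slot_key(b)
  for (nm in names(overrides)) {
    i <- match(nm, keys)
    if (is.na(i)) stop("override for unknown kinetic-order slot: ", nm)
    v <- overrides[[nm]]
    check_range_sign(b$role[i], v[1], v[2])
    b$lo[i] <- v[1]
    b$hi[i] <- v[2]
  }
  for (i in seq_len(nrow(b))) check_range_sign(b$role[i], b$lo[i], b$hi[i])
  class(b) <- c("kinetic_order_bounds", "data.frame")
  b
}

#' Sample kinetic orders from their bounds
#'
#' Independent uniform draws on each slot's interval (the maximum-entropy
#' choice on a bounded range). Reproducible given a seed.
#'
#' @param bounds a [default_bounds()] data frame.
#' @param n number of parameter sets to draw.
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return An `n x nrow(bounds)` matrix; column names are `"term:variable"`
#'   slot keys.
#' @export
sample_kinetic_orders <- function(bounds, n = 1L, seed = NULL) {
  stopifnot(nrow(bounds) >= 0, n >= 1)
  if (any(bounds$hi < bounds$lo)) stop("empty kinetic-order interval")
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(bounds)
  u <- matrix(stats::runif(n * ns), n, ns)
  k <- sweep(sweep(u, 2, bounds$hi - bounds$lo, "*"), 2, bounds$lo, "+")
  colnames(k) <- slot_key(bounds)
  k
}

# numeric exponent matrix (terms x dependent variables) for one kinetic-order
# set; `korders` is a named vector or one-row matrix keyed by "term:variable"
exponent_matrix <- function(model, korders) {
  korders <- drop(as.matrix(korders))
  if (is.matrix(korders)) korders <- korders[1, ]
  f <- matrix(0, nrow(model$terms), length(model$metabolites),
              dimnames = list(model$terms$id, model$metabolites))
  keys <- slot_key(model$slots)
  vals <- korders[keys]
  if (anyNA(vals)) stop("kinetic orders missing for slots: ",
                        paste(keys[is.na(vals)], collapse = ", "))
  f[cbind(match(model$slots$term, model$terms$id),
          match(model$slots$variable, model$metabolites))] <- vals
  f
}

# 0/1 enzyme kinetic-order matrix (terms x 6 enzymes); by convention every
# independent variable enters its reactions with kinetic order 1
enzyme_matrix <- function(model) {
  e <- matrix(0, nrow(model$terms), length(model$enzymes),
              dimnames = list(model$terms$id, model$enzymes))
  for (k in seq_len(nrow(model$terms))) {
    enz <- strsplit(model$terms$enzymes[k], ",", fixed = TRUE)[[1]]
    enz <- enz[nzchar(enz)]
    e[k, enz] <- 1
  }
  e
}

#' Serialize a GMA model (with optional bounds) to JSON
#'
#' Round-trips losslessly through [read_gma_json()].
#'
#' @param model a [build_gma()] model.
#' @param path output path.
#' @param bounds optional [default_bounds()] table to embed.
#' @return `path`, invisibly.
#' @export
write_gma_json <- function(model, path, bounds = NULL) {
  obj <- list(
    design = list(
      topology = as.list(model$design$topology),
      crosstalk = model$design$crosstalk,
      hierarchical = model$design$hierarchical
    ),
    metabolites = model$metabolites,
    enzymes = model$enzymes,
    terms = model$terms,
    stoich = model$stoich,
    slots = model$slots,
    vacuous = model$vacuous,
    bounds = if (!is.null(bounds)) as.data.frame(bounds) else NULL
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a GMA model dump written by [write_gma_json()]
#'
#' @param path JSON path.
#' @return A list with the model fields (and `bounds` if embedded).
#' @export
read_gma_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$stoich <- matrix(as.numeric(obj$stoich),
                       nrow = length(obj$metabolites),
                       dimnames = list(obj$metabolites, obj$terms$id))
  obj
}
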