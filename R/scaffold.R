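#' Pathway scaffold for the G/S branch of monolignol biosynthesis
#'
#' Builds the fixed reaction scaffold on which all topological configurations
#' are defined: the metabolites between caffeoyl CoA and the three lignin
#' efflux sinks (G, 5HG, S), the six enzymes (CCR1, CCR2, CCoAOMT, COMT, F5H,
#' CAD), the two putative enzyme channels (CCR1·CAD for G lignin, COMT·F5H for
#' S lignin), and the six toggleable "optional" edges whose presence or absence
#' distinguishes the topological configurations.
#'
#' Dependent metabolites are pools with mass balances; `G`, `FHG` (5HG) and `S`
#' are efflux sinks representing incorporation into the lignin polymer.
#' 5-hydroxyconiferyl alcohol and sinapyl alcohol are lumped into the 5HG and S
#' efflux steps respectively, so the seventh dependent pool is sinapaldehyde.
#'
#' @param split_methylation logical; if `TRUE`, each of the two
#'   3-O-methylation steps (of caffeoyl CoA, normally CCoAOMT-dominant, and of
#'   caffeyl aldehyde, normally COMT-dominant) is split into two parallel
#'   reactions carried by the two methyltransferases, instead of a single
#'   lumped flux. Default `FALSE` (lumped, minimal model).
#' @return An object of class `lignin_scaffold`: a list with elements
#'   `metabolites` (data frame: `id`, `name`), `reactions` (data frame: `id`,
#'   `substrate`, `product`, `enzymes` (comma-separated), `optional`,
#'   `channel`), `enzymes` (character vector of the six enzyme symbols),
#'   `optional_edges` (the six optional reaction ids in canonical order) and
#'   `sinks`.
#' @examples
#' sc <- base_scaffold()
#' sc$enzymes
#' subset(sc$reactions, optional)
#' @export
base_scaffold <- function(split_methylation = FALSE) {
  metabolites <- data.frame(
    id = paste0("X", 1:7),
    name = c(
      "caffeoyl CoA", "caffeyl aldehyde", "feruloyl CoA",
      "coniferyl aldehyde", "coniferyl alcohol",
      "5-hydroxyconiferyl aldehyde", "sinapaldehyde"
    ),
    stringsAsFactors = FALSE
  )

  rx <- function(id, sub, prod, enz, optional = FALSE, channel = FALSE) {
    data.frame(
      id = id, substrate = sub, product = prod, enzymes = enz,
      optional = optional, channel = channel, stringsAsFactors = FALSE
    )
  }

  reactions <- rbind(
    rx("influx", NA_character_, "X1", ""),
    rx("CCR2", "X1", "X2", "CCR2"),
    rx("OMT_CCoA", "X1", "X3", "CCoAOMT"),
    rx("free_COMT", "X2", "X4", "COMT", optional = TRUE),
    rx("S_channel", "X2", "X6", "COMT,F5H", optional = TRUE, channel = TRUE),
    rx("free_CCR1", "X3", "X4", "CCR1", optional = TRUE),
    rx("G_channel", "X3", "X5", "CCR1,CAD", optional = TRUE, channel = TRUE),
    rx("free_CAD", "X4", "X5", "CAD", optional = TRUE),
    rx("free_F5H", "X4", "X6", "F5H", optional = TRUE),
    rx("OMT_5OH", "X6", "X7", "COMT"),
    rx("efflux_G", "X5", "G", ""),
    rx("efflux_5HG", "X6", "FHG", "CAD"),
    rx("efflux_S", "X7", "S", "CAD")
  )

  if (split_methylation) {
    # parallel methyltransferase terms; the *_b flux is the minor contributor
    reactions <- rbind(
      reactions,
      rx("OMT_CCoA_b", "X1", "X3", "COMT"),
      rx("free_COMT_b", "X2", "X4", "CCoAOMT", optional = TRUE)
    )
  }

  structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      enzymes = c("CCR1", "CCR2", "CCoAOMT", "COMT", "F5H", "CAD"),
      optional_edges = c("free_COMT", "S_channel", "free_CCR1",
                         "G_channel", "free_CAD", "free_F5H"),
      sinks = c("G", "FHG", "S"),
      split_methylation = split_methylation
    ),
    class = "lignin_scaffold"
  )
}

#' @export
print.lignin_scaffold <- function(x, ...) {
  cat("Monolignol pathway scaffold:",
      nrow(x$metabolites), "dependent metabolites,",
      nrow(x$reactions), "reactions,",
      length(x$enzymes), "enzymes,",
      length(x$optional_edges), "optional edges\n")
  invisible(x)
}

# reaction ids present in a configuration given the 6 optional-edge bits
present_reactions <- function(scaffold, bits) {
  opt <- scaffold$optional_edges
  drop <- opt[!bits]
  rxn <- scaffold$reactions
  # a split secondary methylation term follows its primary edge's bit
  if (isTRUE(scaffold$split_methylation) && !bits[["free_COMT"]]) {
    drop <- c(drop, "free_COMT_b")
  }
  rxn[!(rxn$id %in% drop), , drop = FALSE]
}

# dependent metabolite ids actually wired in a configuration
present_metabolites <- function(scaffold, bits) {
  rxn <- present_reactions(scaffold, bits)
  used <- union(rxn$substrate, rxn$product)
  scaffold$metabolites$id[scaffold$metabolites$id %in% used]
}

config_constraints_ok <- function(bits, coniferyl_rule = "bidirectional") {
  b <- as.logical(bits)
  names(b) <- names(bits)
  # mass must leave caffeyl aldehyde and feruloyl CoA
  if (!(b[["free_COMT"]] || b[["S_channel"]])) return(FALSE)
  if (!(b[["free_CCR1"]] || b[["G_channel"]])) return(FALSE)
  # mass must reach coniferyl alcohol and 5-hydroxyconiferyl aldehyde
  if (!(b[["G_channel"]] || b[["free_CAD"]])) return(FALSE)
  if (!(b[["S_channel"]] || b[["free_F5H"]])) return(FALSE)
  produced <- b[["free_COMT"]] || b[["free_CCR1"]]
  consumed <- b[["free_CAD"]] || b[["free_F5H"]]
  if (coniferyl_rule %in% c("bidirectional", "produced_only")) {
    if (produced && !consumed) return(FALSE)
  }
  if (coniferyl_rule == "bidirectional") {
    if (consumed && !produced) return(FALSE)
  }
  TRUE
}

#' Enumerate admissible topological configurations
#'
#' Scans all `2^6 = 64` subsets of the six optional edges and keeps those that
#' satisfy the admissibility constraints: (i) at least one edge leaves caffeyl
#' aldehyde and feruloyl CoA, (ii) at least one edge enters coniferyl alcohol
#' and 5-hydroxyconiferyl aldehyde (otherwise mass would accumulate or a pool
#' would be starved), and (iii) the coniferyl-aldehyde consistency rule: the
#' pool has free-route producers if and only if it has free-route consumers.
#' Under the default (bidirectional) rule exactly 19 configurations survive.
#'
#' Configurations are ordered by descending optional-edge count, ties broken by
#' the canonical edge-tuple order, and labelled `A` (all six edges) through `S`
#' (channels only, the unique configuration with 6 rather than 7 dependent
#' metabolites).
#'
#' @param scaffold a [base_scaffold()] object.
#' @param coniferyl_rule one of `"bidirectional"` (default: free producers iff
#'   free consumers), `"produced_only"` (only produced-implies-consumed, which
#'   admits 22 configurations) or `"none"`.
#' @return A data frame of class `topology_configurations` with one row per
#'   configuration: `label`, one logical column per optional edge
#'   (`free_COMT`, `S_channel`, `free_CCR1`, `G_channel`, `free_CAD`,
#'   `free_F5H`), `n_edges`, and `n_dependent`.
#' @examples
#' cfg <- enumerate_configurations()
#' nrow(cfg)            # 19
#' cfg[cfg$label == "S", ]
#' @export
enumerate_configurations <- function(scaffold = base_scaffold(),
                                     coniferyl_rule = c("bidirectional",
                                                        "produced_only",
                                                        "none")) {
  coniferyl_rule <- match.arg(coniferyl_rule)
  opt <- scaffold$optional_edges
  stopifnot(length(opt) == 6L)

  masks <- expand.grid(rep(list(c(TRUE, FALSE)), 6L), KEEP.OUT.ATTRS = FALSE)
  names(masks) <- opt
  keep <- apply(masks, 1L, function(row) {
    config_constraints_ok(row, coniferyl_rule)
  })
  cfg <- masks[keep, , drop = FALSE]
  cfg$n_edges <- rowSums(cfg[, opt])

  # canonical order: descending edge count, then lexicographic on the edge
  # tuple with present-before-absent in canonical edge order
  ord <- do.call(order, c(
    list(-cfg$n_edges),
    lapply(cfg[, opt], function(col) !col)
  ))
  cfg <- cfg[ord, , drop = FALSE]
  rownames(cfg) <- NULL
  cfg$label <- LETTERS[seq_len(nrow(cfg))]
  cfg$n_dependent <- vapply(seq_len(nrow(cfg)), function(i) {
    length(present_metabolites(scaffold, unlist(cfg[i, opt])))
  }, integer(1))
  cfg <- cfg[, c("label", opt, "n_edges", "n_dependent")]
  class(cfg) <- c("topology_configurations", "data.frame")
  cfg
}

#' Look up a configuration by its letter label
#'
#' @param label a single letter label, e.g. `"A"`.
#' @param configs a configuration table from [enumerate_configurations()].
#' @return The single matching row (a one-row data frame).
#' @export
config_by_label <- function(label, configs = enumerate_configurations()) {
  i <- match(label, configs$label)
  if (is.na(i)) stop("unknown configuration label: ", label)
  configs[i, , drop = FALSE]
}

#' The five candidate crosstalk mechanisms
#'
#' Metabolite-level regulatory interactions linking the CCR2/COMT and
#' CCoAOMT/CCR1 branches:
#' * `M1` — feruloyl CoA competitively inhibits the CCR2 reduction of
#'   caffeoyl CoA (documented substrate competition).
#' * `M2` — caffeyl aldehyde weakly inhibits the 3-O-methylation of
#'   caffeoyl CoA.
#' * `M3` — caffeyl aldehyde *activates* the 3-O-methylation of caffeoyl CoA
#'   (the hypothesized activation; mutually exclusive with `M2`).
#' * `M4` — caffeoyl CoA competitively inhibits the 3-O-methylation of
#'   caffeyl aldehyde (the free-COMT route).
#' * `M5` — caffeyl aldehyde inhibits its own 3-O-methylation (substrate
#'   inhibition of free COMT).
#'
#' `M4` and `M5` are vacuous in configurations lacking the free-COMT edge.
#'
#' @return A data frame with columns `id`, `target` (reaction id), `effector`
#'   (metabolite id), `sign` (+1 activation, -1 inhibition), and
#'   `substrate_inhibition` (logical; `M5` modifies the substrate exponent
#'   rather than adding an effector).
#' @export
crosstalk_mechanisms <- function() {
  data.frame(
    id = paste0("M", 1:5),
    target = c("CCR2", "OMT_CCoA", "OMT_CCoA", "free_COMT", "free_COMT"),
    effector = c("X3", "X2", "X2", "X1", "X2"),
    sign = c(-1L, -1L, 1L, -1L, -1L),
    substrate_inhibition = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Enumerate crosstalk patterns of a mechanism family
#'
#' @param family `"inhibition"` — all `2^4 = 16` subsets of the four
#'   independent inhibition mechanisms M1, M2, M4, M5 (including the empty
#'   pattern); `"activation"` — the two activation-based patterns `{M3}` and
#'   `{M1, M3}`; `"none"` — the single empty pattern.
#' @return A list of character vectors of mechanism ids, in a fixed canonical
#'   order (by pattern size, then lexicographically).
#' @examples
#' length(enumerate_crosstalk_patterns("inhibition"))  # 16
#' enumerate_crosstalk_patterns("activation")
#' @export
enumerate_crosstalk_patterns <- function(family = c("inhibition", "activation",
                                                    "none")) {
  family <- match.arg(family)
  switch(family,
    inhibition = {
      mechs <- c("M1", "M2", "M4", "M5")
      pats <- lapply(0:15, function(mask) {
        mechs[bitwAnd(mask, 2^(0:3)) > 0]
      })
      sizes <- lengths(pats)
      keys <- vapply(pats, paste, character(1), collapse = "+")
      pats[order(sizes, keys)]
    },
    activation = list("M3", c("M1", "M3")),
    none = list(character(0))
  )
}

pattern_label <- function(pattern) {
  if (length(pattern) == 0L) "none" else paste(pattern, collapse = "+")
}

#' Enumerate designs (topology x crosstalk pattern)
#'
#' A design pairs one topological configuration with one crosstalk pattern and
#' a flag stating whether hierarchical regulation acts in the *ccr2* knockout
#' (increased CCR1 and CCoAOMT activity beyond the directly targeted gene).
#'
#' @param configs configuration table from [enumerate_configurations()].
#' @param patterns list of crosstalk patterns from
#'   [enumerate_crosstalk_patterns()].
#' @param hierarchical logical flag applied to every design.
#' @return A list of `lignin_design` objects (length
#'   `nrow(configs) * length(patterns)`), each with elements `topology` (a
#'   one-row configuration), `crosstalk` (character vector), `hierarchical`,
#'   and `label`.
#' @examples
#' d <- enumerate_designs(enumerate_configurations(),
#'                        enumerate_crosstalk_patterns("inhibition"))
#' length(d)  # 304
#' @export
enumerate_designs <- function(configs, patterns, hierarchical = FALSE) {
  for (p in patterns) {
    if (all(c("M2", "M3") %in% p)) {
      stop("crosstalk pattern cannot contain both M2 and M3 ",
           "(opposite signs on the same interaction)")
    }
  }
  designs <- vector("list", nrow(configs) * length(patterns))
  k <- 0L
  for (j in seq_along(patterns)) {
    for (i in seq_len(nrow(configs))) {
      k <- k + 1L
      designs[[k]] <- new_design(configs[i, , drop = FALSE], patterns[[j]],
                                 hierarchical)
    }
  }
  designs
}

#' Construct a single design
#'
#' @param topology one-row configuration data frame.
#' @param crosstalk character vector of mechanism ids (at most one of M2/M3).
#' @param hierarchical logical.
#' @return A `lignin_design` object.
#' @export
new_design <- function(topology, crosstalk = character(0),
                       hierarchical = FALSE) {
  stopifnot(is.data.frame(topology), nrow(topology) == 1L)
  if (all(c("M2", "M3") %in% crosstalk)) {
    stop("crosstalk pattern cannot contain both M2 and M3")
  }
  structure(
    list(
      topology = topology,
      crosstalk = sort(unname(unlist(crosstalk))),
      hierarchical = isTRUE(hierarchical),
      label = paste0(topology$label, ":", pattern_label(crosstalk),
                     if (isTRUE(hierarchical)) ":hier" else "")
    ),
    class = "lignin_design"
  )
}

#' @export
print.lignin_design <- function(x, ...) {
  cat("Design", x$label, "- topology", x$topology$label,
      sprintf("(%d edges, %d dependent pools),", x$topology$n_edges,
              x$topology$n_dependent),
      "crosstalk", pattern_label(x$crosstalk),
      if (x$hierarchical) "with hierarchical ccr2 regulation" else "", "\n")
  invisible(x)
}

#' Write the configuration table to TSV
#'
#' One row per configuration: label, the six presence bits, `n_dependent` and
#' `n_edges`.
#'
#' @param configs configuration table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_designs_tsv <- function(configs, path) {
  out <- configs[, c("label", attr(configs, "names")[2:7], "n_dependent",
                     "n_edges")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
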