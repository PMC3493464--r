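#' Perturbation scenario sets
#'
#' A scenario set bundles the wild-type S/G ratio `rho_wt` with the four
#' perturbation lines the screen tests every instantiation against:
#'
#' * `CCoAOMT_down` — CCoAOMT down-regulated alfalfa line (quantitative:
#'   carries an observed S/G ratio). Default multiplier 0.24 (activity
#'   reduced about 4.2-fold).
#' * `COMT_down` — COMT down-regulated alfalfa line (quantitative).
#' * `ccr1_ko` — *ccr1* knockout (qualitative: S/G decreases by more than the
#'   5% margin). Knockouts are simulated as small residual activity because a
#'   zero multiplier is outside the power-law domain.
#' * `ccr2_ko` — *ccr2* knockout (qualitative: S/G increases). Its
#'   `hierarchical_multipliers` raise CCR1 and CCoAOMT when hierarchical
#'   regulation is switched on.
#'
#' Each value carries a provenance tag: `"literature"`, `"placeholder"`
#' (shipped default that must be replaced by the user's observed data for
#' literal reproduction), or `"synthetic"` (generated by
#' [generate_synthetic_scenario()]).
#'
#' @param rho_wt wild-type S/G ratio.
#' @param ko_residual residual enzyme activity used for knockouts.
#' @return An object of class `scenario_set`.
#' @export
default_scenarios <- function(rho_wt = 0.5, ko_residual = 0.05) {
  structure(
    list(
      rho_wt = rho_wt,
      rho_provenance = "placeholder",
      scenarios = list(
        CCoAOMT_down = list(
          name = "CCoAOMT_down",
          multipliers = list(CCoAOMT = 0.24),
          observed_sg = 0.75,
          provenance = "placeholder"
        ),
        COMT_down = list(
          name = "COMT_down",
          multipliers = list(COMT = 0.1),
          observed_sg = 0.05,
          provenance = "placeholder"
        ),
        ccr1_ko = list(
          name = "ccr1_ko",
          multipliers = list(CCR1 = ko_residual),
          direction = "down",
          provenance = "literature"
        ),
        ccr2_ko = list(
          name = "ccr2_ko",
          multipliers = list(CCR2 = ko_residual),
          hierarchical_multipliers = list(CCR1 = 1.5, CCoAOMT = 1.5),
          direction = "up",
          provenance = "literature"
        )
      )
    ),
    class = "scenario_set"
  )
}

required_scenarios <- c("CCoAOMT_down", "COMT_down", "ccr1_ko", "ccr2_ko")

validate_scenario_set <- function(ss, warn_placeholder = TRUE) {
  if (is.null(ss$rho_wt) || !is.numeric(ss$rho_wt) || ss$rho_wt <= 0) {
    stop("scenario file error: 'rho_wt' must be a positive number")
  }
  missing <- setdiff(required_scenarios, names(ss$scenarios))
  if (length(missing)) {
    stop("scenario file error: missing scenario entry '",
         paste(missing, collapse = "', '"), "'")
  }
  placeholders <- if (identical(ss$rho_provenance, "placeholder")) "rho_wt"
                  else character(0)
  for (nm in names(ss$scenarios)) {
    sc <- ss$scenarios[[nm]]
    mult <- unlist(sc$multipliers)
    if (is.null(mult) || any(!is.finite(mult)) || any(mult <= 0)) {
      stop("scenario file error: '", nm,
           "' needs positive enzyme multipliers")
    }
    hm <- unlist(sc$hierarchical_multipliers)
    if (!is.null(hm) && any(hm <= 0)) {
      stop("scenario file error: '", nm,
           "' has a non-positive hierarchical multiplier")
    }
    unknown <- setdiff(c(names(mult), names(hm)), base_scaffold()$enzymes)
    if (length(unknown)) {
      stop("scenario file error: '", nm, "' names unknown enzyme '",
           paste(unknown, collapse = "', '"), "'")
    }
    has_obs <- !is.null(sc$observed_sg)
    has_dir <- !is.null(sc$direction)
    if (has_obs == has_dir) {
      stop("scenario file error: '", nm, "' must carry exactly one of ",
           "'observed_sg' (quantitative) or 'direction' (qualitative)")
    }
    if (has_obs && (!is.numeric(sc$observed_sg) || sc$observed_sg <= 0)) {
      stop("scenario file error: '", nm, "' observed_sg must be positive")
    }
    if (has_dir && !sc$direction %in% c("down", "up")) {
      stop("scenario file error: '", nm, "' direction must be 'down' or 'up'")
    }
    if (!is.null(sc$provenance) &&
        !sc$provenance %in% c("literature", "placeholder", "synthetic")) {
      stop("scenario file error: '", nm, "' has unknown provenance tag '",
           sc$provenance, "'")
    }
    if (identical(sc$provenance, "placeholder")) {
      placeholders <- c(placeholders, nm)
    }
  }
  if (warn_placeholder && length(placeholders)) {
    warning("scenario values for ", paste(placeholders, collapse = ", "),
            " are placeholders; replace them with observed data for literal ",
            "reproduction", call. = FALSE)
  }
  invisible(ss)
}

#' Load a scenario file (YAML)
#'
#' Schema: top-level `rho_wt` (positive), optional `rho_provenance`, and a
#' `scenarios` mapping with entries `CCoAOMT_down`, `COMT_down`, `ccr1_ko`,
#' `ccr2_ko`. Every entry has `multipliers` (enzyme -> positive factor),
#' optionally `hierarchical_multipliers`, exactly one of `observed_sg`
#' (quantitative line) or `direction: down|up` (qualitative line), and a
#' `provenance` tag. Placeholder-tagged values trigger a warning.
#'
#' @param path YAML file path.
#' @return A validated `scenario_set`.
#' @export
load_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$scenarios <- lapply(stats::setNames(names(raw$scenarios),
                                          names(raw$scenarios)),
                          function(nm) {
                            sc <- raw$scenarios[[nm]]
                            sc$name <- nm
                            sc
                          })
  ss <- structure(raw, class = "scenario_set")
  validate_scenario_set(ss)
}

#' Write a scenario set to YAML
#'
#' Writing then reading reproduces the same scenario set (numeric values to
#' 15 significant digits).
#'
#' @param scenario_set a `scenario_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenario_set, path) {
  obj <- unclass(scenario_set)
  obj$scenarios <- lapply(obj$scenarios, function(sc) {
    sc$name <- NULL
    sc
  })
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("Scenario set: rho_wt =", x$rho_wt, "\n")
  for (sc in x$scenarios) {
    obs <- if (!is.null(sc$observed_sg)) {
      paste("observed S/G", format(sc$observed_sg, digits = 4))
    } else paste("direction", sc$direction)
    cat(sprintf("  %-13s %s  [%s]\n", sc$name, obs,
                sc$provenance %||% "unspecified"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path of the shipped default scenario file
#'
#' @return Path to the package's placeholder-flagged default scenario YAML.
#' @export
default_scenario_path <- function() {
  system.file("extdata", "default_scenarios.yaml", package = "lignindesign",
              mustWork = TRUE)
}
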