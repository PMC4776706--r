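# Scenario flags, model parameters and their priors.

# Fixed scenario constants (generations before present unless noted).
NEOLITHIC_TIME_GEN <- 320   # sudden K -> KNeo increase, 8,000 years BP
LDD_MAX_DEMES <- 6L         # hard cap on LDD distance (900 km at 150-km demes)
LDD_MIN_DEMES <- 2L         # LDD is by definition non-adjacent
GENERATION_YEARS <- 25
ROOT_REPEAT <- 30L          # repeat count at the root of every genealogy

#' Scenario specification
#'
#' A scenario combines an LDD regime (`none`, `any`, `empty_only`,
#' `occupied_only`), a glacial range contraction flag, a Neolithic
#' size-increase flag and the deme side length.
#'
#' @param ldd_regime one of `"none"`, `"any"`, `"empty_only"`,
#'   `"occupied_only"`.
#' @param range_contraction logical.
#' @param neolithic logical.
#' @param deme_side_km 150 (default) or 250.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(ldd_regime = c("none", "any", "empty_only",
                                         "occupied_only"),
                          range_contraction = FALSE, neolithic = FALSE,
                          deme_side_km = 150) {
  ldd_regime <- match.arg(ldd_regime)
  structure(list(ldd_regime = ldd_regime,
                 range_contraction = isTRUE(range_contraction),
                 neolithic = isTRUE(neolithic),
                 deme_side_km = deme_side_km),
            class = "scenario_spec")
}

# canonical model names <-> flags
MODEL_TABLE <- list(
  noLDDnoRC  = list(ldd_regime = "none",          range_contraction = FALSE),
  noLDDRC    = list(ldd_regime = "none",          range_contraction = TRUE),
  LDDnoRC    = list(ldd_regime = "any",           range_contraction = FALSE),
  LDDRC      = list(ldd_regime = "any",           range_contraction = TRUE),
  LDDnoRCep  = list(ldd_regime = "empty_only",    range_contraction = FALSE),
  LDDnoRCop  = list(ldd_regime = "occupied_only", range_contraction = FALSE),
  LDDRCep    = list(ldd_regime = "empty_only",    range_contraction = TRUE),
  LDDRCop    = list(ldd_regime = "occupied_only", range_contraction = TRUE),
  noLDDRCNeo = list(ldd_regime = "none",          range_contraction = TRUE,
                    neolithic = TRUE)
)

#' Scenario from a canonical model name
#'
#' Maps the named models (`noLDDnoRC`, `noLDDRC`, `LDDnoRC`, `LDDRC`,
#' `LDDnoRCep`, `LDDnoRCop`, `LDDRCep`, `LDDRCop`, `noLDDRCNeo`) onto
#' scenario flags.
#'
#' @param name model name.
#' @param deme_side_km deme side in km.
#' @return a `scenario_spec`.
#' @export
scenario_from_name <- function(name, deme_side_km = 150) {
  if (!name %in% names(MODEL_TABLE))
    stop("unknown model name '", name, "'; known: ",
         paste(names(MODEL_TABLE), collapse = ", "))
  fl <- MODEL_TABLE[[name]]
  sc <- scenario_spec(ldd_regime = fl$ldd_regime,
                      range_contraction = fl$range_contraction,
                      neolithic = isTRUE(fl$neolithic),
                      deme_side_km = deme_side_km)
  sc$name <- name
  sc
}

PARAM_NAMES <- c("T_STARTEXP", "T_OOA", "Ne_ANC", "K", "r", "m",
                 "LDD_PROP", "mu_bar", "alpha", "STR_MUTRATE", "KNeo")

#' Default parameter priors
#'
#' Uniform prior bounds for the model parameters, read from the packaged
#' priors file (`inst/extdata/priors.yaml`).  Mutation rate, Neolithic
#' carrying capacity and the expansion start time bounds are fixed by the
#' study design; the remaining bounds are reconstructed as the smallest
#' round intervals containing the published 95% posterior intervals, and are
#' labelled as such in the file.
#'
#' @return data.frame with columns `param`, `lower`, `upper`.
#' @export
default_priors <- function() {
  p <- yaml::read_yaml(system.file("extdata", "priors.yaml",
                                   package = "lddexpand"))
  do.call(rbind, lapply(names(p$priors), function(nm)
    data.frame(param = nm, lower = p$priors[[nm]][[1]],
               upper = p$priors[[nm]][[2]], stringsAsFactors = FALSE)))
}

#' Draw a parameter vector from the priors
#'
#' Independent uniform draws within the prior bounds.  Parameters irrelevant
#' to the scenario (LDD kernel parameters under `none`, `KNeo` without the
#' Neolithic flag) are set to zero.
#'
#' @param priors data.frame as from [default_priors()].
#' @param scenario a `scenario_spec`.
#' @param seed optional integer seed.
#' @return named numeric parameter vector.
#' @export
sample_prior <- function(priors = default_priors(), scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- setNames(runif(nrow(priors), priors$lower, priors$upper), priors$param)
  p <- p[PARAM_NAMES[PARAM_NAMES %in% names(p)]]
  if (scenario$ldd_regime == "none") p[c("LDD_PROP", "mu_bar", "alpha")] <- 0
  if (!scenario$neolithic) p["KNeo"] <- 0
  validate_params(p, scenario)
  p
}

validate_params <- function(params, scenario) {
  need <- c("T_STARTEXP", "T_OOA", "Ne_ANC", "K", "r", "m", "STR_MUTRATE")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (params[["T_STARTEXP"]] <= params[["T_OOA"]])
    stop("T_STARTEXP must exceed T_OOA")
  if (scenario$ldd_regime != "none") {
    if (params[["mu_bar"]] > LDD_MAX_DEMES)
      stop("mu_bar must not exceed the ", LDD_MAX_DEMES, "-deme LDD cap")
    if (params[["LDD_PROP"]] < 0 || params[["LDD_PROP"]] > 1)
      stop("LDD_PROP must lie in [0, 1]")
  }
  invisible(params)
}
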