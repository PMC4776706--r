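# Synthetic inputs: packaged fixture landscapes, pseudo-observed genotype
# panels emulating the 22-population / 87-locus study panel, and the
# reference-table sampler.

#' Packaged fixture landscapes
#'
#' \describe{
#'   \item{strip-16}{a 1 x 16 all-land strip with 4 samples; distances and
#'     front-speed checks are exact multiples of the deme side.}
#'   \item{island-pair}{two adjacent land demes; coalescent and R_ST
#'     oracles.}
#'   \item{schematic-old-world-small}{a 30 x 60 schematic Africa-Eurasia
#'     world: Levant corridor, Sahara and Himalaya barriers, Arabian desert,
#'     four refuge blocks, optional Horn-of-Africa and Gibraltar crossing
#'     edges, 22 sampled demes in 4 regional groups.}
#'   \item{schematic-old-world-mini}{a 12 x 24 reduction of the same
#'     topology with 12 sampled demes (3 per group); the desk-scale world
#'     for simulation studies.}
#' }
#'
#' @param name fixture name; `NULL` lists the available names.
#' @return a `landscape`, or a character vector of names.
#' @export
fixture_landscape <- function(name = NULL) {
  files <- c("strip-16" = "strip16.yaml",
             "island-pair" = "island_pair.yaml",
             "schematic-old-world-small" = "schematic_old_world_small.yaml",
             "schematic-old-world-mini" = "schematic_old_world_mini.yaml")
  if (is.null(name)) return(names(files))
  if (!name %in% names(files))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(files), collapse = ", "))
  build_landscape(system.file("extdata", files[[name]],
                              package = "lddexpand"))
}

#' Load the full fixture suite
#' @return named list of `landscape` objects.
#' @export
fixture_suite <- function() {
  nms <- fixture_landscape()
  setNames(lapply(nms, fixture_landscape), nms)
}

#' Generate a pseudo-observed genotype panel
#'
#' Runs the forward and backward passes under one scenario and parameter
#' vector, producing a panel shaped like the empirical study data: the
#' landscape's sampling design (22 populations in 4 regional groups on the
#' schematic old-world fixtures), 87 loci, and optional missingness injected
#' completely at random.
#'
#' @param scenario a `scenario_spec`.
#' @param params named parameter vector.
#' @param landscape a `landscape` with a sampling design.
#' @param n_loci loci in the panel (87 by convention).
#' @param missing_rate per-allele missingness (at most 0.05).
#' @param seed optional integer seed.
#' @return a `genotype_dataset`, or `NULL` for a failed (extinct or
#'   unsampleable) replicate.
#' @export
make_pseudo_observed <- function(scenario, params, landscape, n_loci = 87,
                                 missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- sampling_design(landscape, n_loci = n_loci)
  rec <- run_forward(landscape, scenario, params)
  if (isTRUE(rec$extinct)) return(NULL)
  occ <- rec$densities[1, (design$col - 1L) * rec$n_rows + design$row]
  if (any(occ < 2 * design$n)) return(NULL)
  ds <- simulate_dataset(rec, design, params[["STR_MUTRATE"]])
  if (missing_rate > 0) ds <- inject_missing(ds, missing_rate)
  ds
}

#' Build an ABC reference table
#'
#' For each scenario, repeatedly draws parameters from the priors, runs the
#' forward demography and backward coalescent, and records the parameter
#' vector and 39-statistic summary.  Failed replicates (metapopulation
#' extinction, or sampled demes too small at present) are logged and
#' replaced by fresh prior draws.
#'
#' @param scenarios character vector of model names (see
#'   [scenario_from_name()]).
#' @param n_sims simulations per scenario.
#' @param landscape a `landscape` with a sampling design.
#' @param n_loci loci per simulated dataset (50 by convention).
#' @param priors prior bounds, as from [default_priors()].
#' @param seed integer seed; fully determines the table.
#' @param progress print a line every `progress` simulations (0 = quiet).
#' @return data.frame: `sim_id`, `model`, `seed`, the parameter columns and
#'   the 39 summary columns; attribute `n_failed` counts replaced
#'   replicates.
#' @export
abc_sample <- function(scenarios, n_sims, landscape, n_loci = 50,
                       priors = default_priors(), seed = 1, progress = 0) {
  set.seed(seed)
  design <- sampling_design(landscape, n_loci = n_loci)
  rows <- vector("list", length(scenarios) * n_sims)
  n_failed <- 0L
  k <- 0L
  for (sc_name in scenarios) {
    sc <- scenario_from_name(sc_name)
    for (i in seq_len(n_sims)) {
      repeat {
        sim_seed <- sample.int(.Machine$integer.max, 1)
        set.seed(sim_seed)
        params <- sample_prior(priors, sc)
        rec <- run_forward(landscape, sc, params)
        occ <- rec$densities[1, (design$col - 1L) * rec$n_rows + design$row]
        if (!isTRUE(rec$extinct) && all(occ >= 2 * design$n)) break
        n_failed <- n_failed + 1L
        if (n_failed > 50L * length(rows))
          stop("too many failed replicates; check the configuration")
      }
      ds <- simulate_dataset(rec, design, params[["STR_MUTRATE"]])
      ss <- summarize_dataset(ds, landscape, design)
      k <- k + 1L
      rows[[k]] <- c(list(sim_id = k, model = sc_name, seed = sim_seed),
                     as.list(params), as.list(ss))
      if (progress > 0 && k %% progress == 0)
        message("  [", format(Sys.time(), "%H:%M:%S"), "] ", k, "/",
                length(rows), " simulations")
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  attr(out, "n_failed") <- n_failed
  out
}

#' Write / read a reference table as TSV
#' @param table a reference table from [abc_sample()].
#' @param path file path.
#' @export
write_reference_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) read.delim(path, check.names = FALSE)
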