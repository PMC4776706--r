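# Forward demography: generation-by-generation deme densities,
# nearest-neighbour migration and long-distance dispersal, recording
# everything the backward coalescent needs.
#
# Densities and migrant counts are in GENE copies (2x diploids): a deme at
# carrying capacity K holds 2K genes, and the migrant pool each generation
# is round(2*N_t*m) gene copies for N_t resident diploids.

#' Logistic density update
#'
#' One generation of logistic regulation: `N + r*N*(1 - N/K)`, and 0 where
#' the carrying capacity is 0 (a contraction kills the deme).  A deme above
#' capacity declines towards `K` but never below it (the discrete-time
#' logistic would otherwise crash a strongly overfull deme, e.g. the
#' ancestral deme holding `2*Ne_ANC` genes, to a negative density).
#'
#' @param N haploid (gene-copy) count, vectorised.
#' @param r intrinsic growth rate.
#' @param K haploid carrying capacity, recycled against `N`.
#' @return updated haploid counts.
#' @export
logistic_update <- function(N, r, K) {
  stopifnot(all(N >= 0), all(K >= 0))
  ifelse(K > 0, pmax(pmin(N, K), N + r * N * (1 - N / K)), 0)
}

#' Split a deme's migrant pool into LDD and adjacent migrants
#'
#' The pool is `M = round(N*m)` gene copies; the LDD count is
#' `Binomial(M, ldd_prop)` and the remainder is split across the four
#' neighbour directions by an equal-probability multinomial (genes aimed at
#' sea or barrier demes are lost by the caller).
#'
#' @param N haploid (gene-copy) count of the deme.
#' @param m migration rate per gene.
#' @param ldd_prop proportion of migrants that disperse long-distance.
#' @return list with `ldd_count` and `adjacent` (named counts N/S/W/E).
#' @export
emigrate <- function(N, m, ldd_prop = 0) {
  stopifnot(m >= 0, m <= 1, ldd_prop >= 0, ldd_prop <= 1)
  M <- round(N * m)
  ldd <- if (M > 0 && ldd_prop > 0) rbinom(1, M, ldd_prop) else 0L
  adjacent <- if (M - ldd > 0) {
    as.vector(rmultinom(1, M - ldd, rep(0.25, 4)))
  } else rep(0L, 4)
  list(ldd_count = as.integer(ldd),
       adjacent = setNames(as.integer(adjacent), c("N", "S", "W", "E")))
}

#' Sample LDD travel distances (in demes)
#'
#' Distances are `Gamma(shape alpha, rate alpha/mu_bar)` draws rounded to
#' the nearest integer and resampled until they lie in
#' `[2, 6]` demes (LDD is non-adjacent by definition; the upper cap avoids
#' unrealistically long jumps).
#'
#' @param n number of draws.
#' @param alpha gamma shape.
#' @param mu_bar mean of the untruncated kernel, in demes.
#' @param truncate if `FALSE`, return raw (continuous, untruncated) draws.
#' @return integer (or numeric, untruncated) vector of distances.
#' @export
sample_ldd_distance <- function(n, alpha, mu_bar, truncate = TRUE) {
  if (!truncate) return(rgamma(n, shape = alpha, rate = alpha / mu_bar))
  sample_ldd_distance_cpp(n, alpha, mu_bar, LDD_MIN_DEMES, LDD_MAX_DEMES)
}

#' Probability mass of the truncated-rounded LDD kernel
#'
#' Numeric reference distribution over distances 2..6: gamma mass falling in
#' `[k-1/2, k+1/2]`, renormalised over the admissible range.
#'
#' @inheritParams sample_ldd_distance
#' @return named numeric vector of probabilities for distances 2..6.
#' @export
ldd_kernel_pmf <- function(alpha, mu_bar) {
  k <- LDD_MIN_DEMES:LDD_MAX_DEMES
  p <- pgamma(k + 0.5, shape = alpha, rate = alpha / mu_bar) -
       pgamma(k - 0.5, shape = alpha, rate = alpha / mu_bar)
  setNames(p / sum(p), k)
}

#' Sample the target deme of one LDD migrant
#'
#' A distance is drawn from the truncated-rounded gamma kernel and a
#' direction uniformly on the circle; the displaced coordinate is rounded to
#' a lattice deme.  The migrant is discarded (a normal outcome) if the
#' target is off-grid, uninhabitable, occupied under the `empty_only`
#' regime, or empty under the `occupied_only` regime.
#'
#' @param source `[row, col]` of the sending deme.
#' @param alpha,mu_bar LDD kernel parameters.
#' @param landscape a `landscape`.
#' @param occupancy logical matrix: which demes hold at least one gene.
#' @param regime `"any"`, `"empty_only"` or `"occupied_only"`.
#' @return `[row, col]` of the target, or `NULL` if the migrant is discarded.
#' @export
sample_ldd_target <- function(source, alpha, mu_bar, landscape, occupancy,
                              regime = c("any", "empty_only",
                                         "occupied_only")) {
  regime <- match.arg(regime)
  dist <- sample_ldd_distance(1, alpha, mu_bar)
  theta <- runif(1, 0, 2 * pi)
  r2 <- source[1] + round(dist * sin(theta))
  c2 <- source[2] + round(dist * cos(theta))
  if (r2 < 1 || r2 > landscape$n_rows || c2 < 1 || c2 > landscape$n_cols)
    return(NULL)
  if (!landscape$land[r2, c2] || landscape$barrier[r2, c2]) return(NULL)
  occ <- occupancy[r2, c2]
  if (regime == "empty_only" && occ) return(NULL)
  if (regime == "occupied_only" && !occ) return(NULL)
  c(r2, c2)
}

#' Run the forward demographic simulation
#'
#' Starting `T_STARTEXP` generations before present with `2*Ne_ANC` genes in
#' the origin deme, each generation applies (in order) the capacity update,
#' logistic growth, emigration (adjacent + LDD) and immigrant deposition.
#' Corridor demes open at `T_OOA`; under range contraction the habitable
#' area follows the 30-event schedule.  The returned record holds, for every
#' generation to the present, the deme densities and the immigrant ledger
#' (adjacent counts by source direction, LDD arrivals by source deme).
#'
#' @param landscape a `landscape`.
#' @param scenario a `scenario_spec`.
#' @param params named parameter vector (see [sample_prior()]).
#' @param seed optional integer seed.
#' @return a `demography_record`; its `extinct` flag marks failed
#'   replicates (whole-metapopulation extinction).
#' @export
run_forward <- function(landscape, scenario, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_params(params, scenario)
  t_start <- as.integer(round(params[["T_STARTEXP"]]))
  schedule <- if (scenario$range_contraction)
    contraction_schedule(landscape) else NULL
  epochs <- capacity_epochs(landscape, schedule, scenario, params, t_start)
  regime <- match(scenario$ldd_regime,
                  c("none", "any", "empty_only", "occupied_only")) - 1L
  origin0 <- (landscape$origin[2] - 1L) * landscape$n_rows +
    landscape$origin[1] - 1L
  res <- run_forward_cpp(landscape$n_rows, landscape$n_cols, epochs, origin0,
                         2 * params[["Ne_ANC"]], params[["r"]], params[["m"]],
                         params[["LDD_PROP"]], params[["alpha"]],
                         params[["mu_bar"]], regime, t_start,
                         LDD_MIN_DEMES, LDD_MAX_DEMES)
  structure(list(
    n_rows = landscape$n_rows, n_cols = landscape$n_cols,
    t_start = t_start,
    densities = res$densities,       # row g+1 = generation g BP
    adj = res$adj,                   # column 4*(d-1)+dir, dir in N/S/W/E
    # LDD arrival ledger: 0-based demes, CSR offsets per generation,
    # target-sorted within each generation's slice
    ldd = list(gen = res$ldd_gen, target = res$ldd_target,
               source = res$ldd_source,
               count = rep(1L, length(res$ldd_gen)),
               off = res$ldd_off),
    origin = landscape$origin,
    ne_anc_genes = 2 * params[["Ne_ANC"]],
    diagnostics = res$diagnostics,
    extinct = res$extinct,
    params = params,
    scenario = scenario$name %||% scenario$ldd_regime
  ), class = "demography_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a demography record by hand
#'
#' Constructor for small, hand-built records (single demes, two-deme
#' worlds) used to check the backward coalescent against closed forms.
#'
#' @param densities numeric matrix, row `g+1` = haploid densities at
#'   generation `g` BP (row 1 = present).
#' @param n_rows,n_cols lattice dimensions.
#' @param origin `[row, col]` of the ancestral deme.
#' @param ne_anc_genes haploid size of the ancestral Wright-Fisher deme.
#' @param adj integer matrix of adjacent-immigrant counts (same rows as
#'   `densities`, `4 * n_demes` columns, direction order N/S/W/E); defaults
#'   to no migration.
#' @param ldd data.frame with columns `gen`, `target` (1-based deme index),
#'   `source`, `count` of LDD arrivals; defaults to none.
#' @return a `demography_record`.
#' @export
demography_record <- function(densities, n_rows, n_cols, origin,
                              ne_anc_genes, adj = NULL, ldd = NULL) {
  nd <- n_rows * n_cols
  stopifnot(ncol(densities) == nd)
  if (is.null(adj))
    adj <- matrix(0L, nrow(densities), 4 * nd)
  storage.mode(adj) <- "integer"
  ng <- nrow(densities)
  if (is.null(ldd))
    ldd <- data.frame(gen = integer(), target = integer(),
                      source = integer(), count = integer())
  ord <- order(ldd$gen, ldd$target)
  cnt <- tabulate(ldd$gen + 1L, ng)
  ldd <- list(gen = as.integer(ldd$gen[ord]),
              target = as.integer(ldd$target[ord] - 1L),
              source = as.integer(ldd$source[ord] - 1L),
              count = as.integer(ldd$count[ord]),
              off = c(0L, cumsum(cnt)))
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 t_start = nrow(densities) - 1L,
                 densities = densities, adj = adj, ldd = ldd,
                 origin = origin, ne_anc_genes = ne_anc_genes,
                 diagnostics = NULL, extinct = FALSE, params = NULL,
                 scenario = "hand-built"),
            class = "demography_record")
}

#' @export
print.demography_record <- function(x, ...) {
  cat("<demography_record> ", x$n_rows, "x", x$n_cols, " demes, ",
      x$t_start, " generations (", x$scenario, ")\n", sep = "")
  occ <- sum(x$densities[1, ] >= 1)
  cat("  occupied at present: ", occ, " demes; LDD arrival events: ",
      length(x$ldd$gen), if (isTRUE(x$extinct)) "; EXTINCT", "\n", sep = "")
  invisible(x)
}

#' Serialise / restore a demography record
#'
#' Records round-trip bit-exactly through R serialisation (a compressed
#' binary file).
#' @param record a `demography_record`.
#' @param path file path.
#' @export
write_record <- function(record, path) {
  saveRDS(record, path)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) readRDS(path)

# deme (row, col) -> column-major index
deme_index <- function(record, deme) {
  (deme[2] - 1L) * record$n_rows + deme[1]
}
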