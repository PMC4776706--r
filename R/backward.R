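# Backward structured coalescent over a recorded demography, and stepwise
# mutation of microsatellite repeat counts along the genealogy.

#' Sampling design
#'
#' One row per sampled population: label, deme coordinate, diploid sample
#' size and regional group.  Defaults to the landscape's packaged design.
#'
#' @param landscape a `landscape` with a `samples` table.
#' @param n_loci number of unlinked loci to simulate.
#' @return a `sampling_design`: the samples data.frame with an `n_loci`
#'   attribute.
#' @export
sampling_design <- function(landscape, n_loci = 50) {
  if (is.null(landscape$samples)) stop("landscape has no sampling design")
  d <- landscape$samples
  stopifnot(all(d$n >= 1))
  attr(d, "n_loci") <- as.integer(n_loci)
  class(d) <- c("sampling_design", "data.frame")
  d
}

#' Backward migration distribution for one deme and generation
#'
#' Probability that a lineage observed in `deme` at generation `t` was, one
#' generation earlier (backward), in each source deme:
#' `immigrants(s -> d, t) / N_t(d)`, residual mass staying put.
#'
#' @param record a `demography_record`.
#' @param deme `[row, col]`.
#' @param t generation BP (`0` = present).
#' @return data.frame `source_row`, `source_col`, `prob` (the `deme` row is
#'   the stay-put mass); probabilities sum to 1.
#' @export
backward_move <- function(record, deme, t) {
  d <- deme_index(record, deme)
  N <- record$densities[t + 1L, d]
  if (N < 1) stop("record corruption: deme (", deme[1], ",", deme[2],
                  ") has zero density at generation ", t)
  offs <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))  # N/S/W/E
  src <- NULL
  for (dir in 1:4) {
    cnt <- record$adj[t + 1L, 4L * (d - 1L) + dir]
    if (cnt > 0)
      src <- rbind(src, c(deme[1] + offs[dir, 1], deme[2] + offs[dir, 2],
                          cnt / N))
  }
  slice <- which(record$ldd$gen == t & record$ldd$target == (d - 1L))
  if (length(slice)) {
    sr <- record$ldd$source[slice] %% record$n_rows + 1L
    sc <- record$ldd$source[slice] %/% record$n_rows + 1L
    src <- rbind(src, cbind(sr, sc, record$ldd$count[slice] / N))
  }
  out <- data.frame(source_row = integer(), source_col = integer(),
                    prob = numeric())
  if (!is.null(src))
    out <- data.frame(source_row = src[, 1], source_col = src[, 2],
                      prob = src[, 3])
  stay <- 1 - sum(out$prob)
  if (stay < -1e-9) stop("record corruption: immigrants exceed density")
  out <- rbind(out, data.frame(source_row = deme[1], source_col = deme[2],
                               prob = max(stay, 0)))
  # merge duplicate sources (a deme can send both adjacent and LDD genes)
  out <- aggregate(prob ~ source_row + source_col, out, sum)
  out
}

#' Simulate one genealogy through the recorded demography
#'
#' Lineages start in the sampled demes at present, migrate backward each
#' generation with probabilities given by the immigrant ledger, and
#' coalesce pairwise within demes (probability `1/N_t`, at most one merger
#' per deme per generation).  Lineages remaining at the start of the
#' expansion coalesce in a single Wright-Fisher deme of `2*Ne_ANC` genes.
#'
#' @param record a `demography_record`.
#' @param design a `sampling_design` (or its data.frame).
#' @return a `genealogy`: `parent` (NA for the root), `node_time`
#'   (generations; tips at 0), `n_tips`, and the tip population labels.
#' @export
simulate_genealogy <- function(record, design) {
  genes_per_pop <- 2L * design$n
  deme0 <- rep((design$col - 1L) * record$n_rows + design$row - 1L,
               genes_per_pop)
  res <- simulate_genealogy_cpp(
    record$densities, record$adj,
    record$ldd$target, record$ldd$source, record$ldd$count, record$ldd$off,
    record$n_rows, record$n_cols,
    (record$origin[2] - 1L) * record$n_rows + record$origin[1] - 1L,
    record$ne_anc_genes, record$t_start, deme0)
  structure(list(parent = res$parent + 1L, node_time = res$node_time,
                 n_tips = res$n_tips,
                 tip_pop = rep(design$pop, genes_per_pop)),
            class = "genealogy")
}

#' Time to the most recent common ancestor of a genealogy
#' @param tree a `genealogy`.
#' @return TMRCA in generations.
#' @export
tmrca <- function(tree) max(tree$node_time)

#' Convert a genealogy to an `ape` phylo object
#' @param tree a `genealogy`.
#' @return an object of class `phylo`.
#' @export
as_phylo <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for as_phylo()")
  n <- tree$n_tips
  child <- which(!is.na(tree$parent))
  # phylo numbering: tips 1..n, root n+1, then other internals
  root <- which(is.na(tree$parent))
  internals <- setdiff((n + 1L):(2L * n - 1L), root)
  remap <- integer(2L * n - 1L)
  remap[1:n] <- 1:n
  remap[root] <- n + 1L
  remap[internals] <- seq_along(internals) + n + 1L
  edge <- cbind(remap[tree$parent[child]], remap[child])
  structure(list(edge = edge,
                 edge.length = tree$node_time[tree$parent[child]] -
                   tree$node_time[child],
                 tip.label = paste0("t", 1:n),
                 Nnode = n - 1L),
            class = "phylo", order = "cladewise")
}

#' Drop stepwise mutations on a genealogy
#'
#' Each branch receives `Poisson(rate * length)` mutations, each changing
#' the repeat count by +/-1 with equal probability; repeat counts are
#' floored at 1.
#'
#' @param tree a `genealogy`.
#' @param mutation_rate per-locus per-generation mutation rate.
#' @param root_repeat repeat count at the root.
#' @return integer vector of tip repeat counts.
#' @export
mutate_smm <- function(tree, mutation_rate, root_repeat = ROOT_REPEAT) {
  stopifnot(mutation_rate >= 0)
  n_nodes <- length(tree$parent)
  value <- integer(n_nodes)
  root <- which(is.na(tree$parent))
  value[root] <- root_repeat
  child <- which(!is.na(tree$parent))
  len <- tree$node_time[tree$parent[child]] - tree$node_time[child]
  nmut <- rpois(length(child), mutation_rate * len)
  net <- 2L * rbinom(length(child), nmut, 0.5) - nmut
  # parents are strictly older than children: process by decreasing age
  ord <- child[order(tree$node_time[child], decreasing = TRUE)]
  net_by_node <- integer(n_nodes)
  net_by_node[child] <- net
  for (v in ord)
    value[v] <- max(1L, value[tree$parent[v]] + net_by_node[v])
  value[seq_len(tree$n_tips)]
}

#' Simulate a multilocus microsatellite dataset
#'
#' Runs `n_loci` independent genealogies through the record and drops
#' stepwise mutations on each, assembling genotypes per individual.
#'
#' @param record a `demography_record`.
#' @param design a `sampling_design` (its `n_loci` attribute sets the locus
#'   count unless `n_loci` is given).
#' @param mutation_rate per-locus per-generation rate.
#' @param seed optional integer seed.
#' @param n_loci override for the number of loci.
#' @return a `genotype_dataset`.
#' @export
simulate_dataset <- function(record, design, mutation_rate, seed = NULL,
                             n_loci = attr(design, "n_loci")) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_loci)) n_loci <- 50L
  n_genes <- 2L * sum(design$n)
  geno <- matrix(NA_integer_, n_genes, n_loci)
  for (l in seq_len(n_loci)) {
    tree <- simulate_genealogy(record, design)
    geno[, l] <- mutate_smm(tree, mutation_rate)
  }
  genotype_dataset(geno,
                   pop = rep(design$pop, 2L * design$n),
                   groups = setNames(design$group, design$pop))
}
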