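# The 39-statistic summary layer: within-population diversity (K, H, NGW),
# R_ST differentiation averaged within and between regional groups, and two
# heterozygosity-vs-distance slopes.

GROUPS <- c("AFR", "ENA", "CAS", "EAS")

#' Names of the 39 summary statistics
#'
#' Per group: group means of the per-population locus-means and locus-SDs of
#' K (allele count), H (unbiased expected heterozygosity) and NGW (modified
#' Garza-Williamson) [24]; SD over loci of each statistic on the pooled
#' sample [3]; mean pairwise R_ST within each group [4] and between each
#' group pair [6]; the heterozygosity-distance slope under the
#' `levant_horn_gibraltar` routing (`slope`) and under `levant_only`
#' (`slope_levant`) [2].
#'
#' @return character vector of length 39 (the join keys of the ABC layer).
#' @export
summary_names <- function() {
  per_group <- as.vector(t(outer(GROUPS, c("K", "Ksd", "H", "Hsd",
                                           "NGW", "NGWsd"),
                                 function(g, s) paste0(s, "_", g))))
  pairs <- combn(GROUPS, 2, paste, collapse = "-")
  c(per_group,
    c("Ksd_pooled", "Hsd_pooled", "NGWsd_pooled"),
    paste0("FST_", GROUPS),
    paste0("FST_", pairs),
    c("slope", "slope_levant"))
}

#' Per-locus diversity statistics of one population
#'
#' For every locus with at least two typed genes in the population:
#' K = number of distinct alleles; H = unbiased expected heterozygosity
#' `n/(n-1) * (1 - sum p_i^2)`; NGW = `K / (range + 1)` with the range in
#' repeat units.
#'
#' @param dataset a `genotype_dataset`.
#' @param population population label.
#' @return data.frame `locus`, `K`, `H`, `NGW` (under-typed loci excluded).
#' @export
locus_stats <- function(dataset, population) {
  m <- dataset$geno[dataset$pop == population, , drop = FALSE]
  if (!nrow(m)) stop("unknown population '", population, "'")
  out <- do.call(rbind, lapply(seq_len(ncol(m)), function(l) {
    x <- m[, l]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) return(NULL)
    p <- tabulate(factor(x)) / n
    data.frame(locus = colnames(m)[l],
               K = length(p),
               H = n / (n - 1) * (1 - sum(p^2)),
               NGW = length(p) / (max(x) - min(x) + 1),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stop("population '", population,
                         "' has no locus with >= 2 typed genes")
  out
}

# per-population, per-locus first and second moments of allele size and
# typed-gene counts, for the AMOVA machinery (columns = loci)
pop_moments <- function(dataset) {
  pops <- unique(dataset$pop)
  L <- ncol(dataset$geno)
  n <- s1 <- s2 <- matrix(0, length(pops), L,
                          dimnames = list(pops, colnames(dataset$geno)))
  for (p in pops) {
    m <- dataset$geno[dataset$pop == p, , drop = FALSE]
    ok <- !is.na(m)
    n[p, ] <- colSums(ok)
    m0 <- ifelse(ok, m, 0)
    s1[p, ] <- colSums(m0)
    s2[p, ] <- colSums(m0^2)
  }
  list(n = n, s1 = s1, s2 = s2)
}

# multilocus AMOVA variance decomposition of squared repeat differences for
# one population pair, from per-pop moments (vectors over loci)
rst_from_moments <- function(na, s1a, s2a, nb, s1b, s2b) {
  ok <- na >= 1 & nb >= 1 & (na + nb) >= 3
  if (!any(ok)) stop("no shared typed locus between the two populations")
  na <- na[ok]; s1a <- s1a[ok]; s2a <- s2a[ok]
  nb <- nb[ok]; s1b <- s1b[ok]; s2b <- s2b[ok]
  N <- na + nb
  ssw <- (s2a - s1a^2 / na) + (s2b - s1b^2 / nb)
  gbar <- (s1a + s1b) / N
  ssa <- na * (s1a / na - gbar)^2 + nb * (s1b / nb - gbar)^2
  msw <- ssw / (N - 2)
  msa <- ssa / 1
  nc <- (N - (na^2 + nb^2) / N) / 1
  sig_w <- msw
  sig_a <- (msa - msw) / nc
  den <- sum(sig_a + sig_w)
  if (den == 0) return(0)
  sum(sig_a) / den
}

#' Multilocus R_ST between two populations
#'
#' AMOVA variance decomposition of squared repeat-count differences;
#' numerator and denominator variance components are summed over loci
#' before dividing.
#'
#' @param dataset a `genotype_dataset`.
#' @param pop_a,pop_b population labels.
#' @return R_ST (can be slightly negative for undifferentiated pairs).
#' @export
pairwise_rst <- function(dataset, pop_a, pop_b) {
  mo <- pop_moments(dataset)
  rst_from_moments(mo$n[pop_a, ], mo$s1[pop_a, ], mo$s2[pop_a, ],
                   mo$n[pop_b, ], mo$s1[pop_b, ], mo$s2[pop_b, ])
}

#' Slope of population heterozygosity against distance from the origin
#'
#' Ordinary least-squares slope of per-population mean expected
#' heterozygosity on least-cost distance (km).
#'
#' @param dataset a `genotype_dataset`.
#' @param distances named numeric vector of per-population distances (km).
#' @return slope (per km).
#' @export
het_distance_slope <- function(dataset, distances) {
  pops <- unique(dataset$pop)
  if (length(pops) < 3) stop("need at least 3 populations for a slope")
  if (!all(pops %in% names(distances)))
    stop("missing distances for: ",
         paste(setdiff(pops, names(distances)), collapse = ", "))
  h <- vapply(pops, function(p) mean(locus_stats(dataset, p)$H), 0)
  d <- distances[pops]
  if (var(d) == 0) stop("zero variance in distances; slope undefined")
  unname(coef(lm(h ~ d))[2])
}

#' Compute the 39-statistic summary vector
#'
#' @param dataset a `genotype_dataset` whose populations are assigned to the
#'   four regional groups.
#' @param landscape the `landscape` the data were sampled on (provides the
#'   least-cost distances for the two slope statistics).
#' @param design a `sampling_design` naming the sampled demes.
#' @return named numeric vector of length 39 (see [summary_names()]).
#' @export
summarize_dataset <- function(dataset, landscape, design) {
  pops <- unique(dataset$pop)
  grp <- dataset$groups[pops]
  if (anyNA(grp)) stop("every population needs a regional group")
  for (g in GROUPS) if (sum(grp == g) < 2)
    stop("group ", g, " has fewer than 2 populations; ",
         "within-group R_ST is undefined")

  ls <- lapply(pops, function(p) locus_stats(dataset, p))
  names(ls) <- pops
  pop_mean <- t(vapply(ls, function(s) colMeans(s[c("K", "H", "NGW")]),
                       numeric(3)))
  pop_sd <- t(vapply(ls, function(s) apply(s[c("K", "H", "NGW")], 2, sd),
                     numeric(3)))

  out <- numeric(0)
  for (g in GROUPS) {
    sel <- grp == g
    v <- c(K = mean(pop_mean[sel, "K"]), Ksd = mean(pop_sd[sel, "K"]),
           H = mean(pop_mean[sel, "H"]), Hsd = mean(pop_sd[sel, "H"]),
           NGW = mean(pop_mean[sel, "NGW"]),
           NGWsd = mean(pop_sd[sel, "NGW"]))
    names(v) <- paste0(names(v), "_", g)
    out <- c(out, v)
  }

  # SD over loci of the statistics computed on the pooled sample
  pooled <- dataset
  pooled$pop <- rep("ALL", length(dataset$pop))
  pooled$groups <- c(ALL = "ALL")
  ps <- locus_stats(pooled, "ALL")
  out <- c(out, Ksd_pooled = sd(ps$K), Hsd_pooled = sd(ps$H),
           NGWsd_pooled = sd(ps$NGW))

  # pairwise R_ST averaged within and between groups
  mo <- pop_moments(dataset)
  prs <- combn(pops, 2)
  rst <- apply(prs, 2, function(pr)
    rst_from_moments(mo$n[pr[1], ], mo$s1[pr[1], ], mo$s2[pr[1], ],
                     mo$n[pr[2], ], mo$s1[pr[2], ], mo$s2[pr[2], ]))
  g1 <- grp[prs[1, ]]; g2 <- grp[prs[2, ]]
  for (g in GROUPS)
    out[paste0("FST_", g)] <- mean(rst[g1 == g & g2 == g])
  for (pr in combn(GROUPS, 2, simplify = FALSE)) {
    sel <- (g1 == pr[1] & g2 == pr[2]) | (g1 == pr[2] & g2 == pr[1])
    out[paste0("FST_", pr[1], "-", pr[2])] <- mean(rst[sel])
  }

  # heterozygosity-distance slopes under the two routings
  h <- setNames(pop_mean[, "H"], pops)
  for (routing in c("levant_horn_gibraltar", "levant_only")) {
    dd <- least_cost_distance(landscape, routing = routing)
    d <- setNames(dd$distance_km, dd$population_label)[pops]
    nm <- if (routing == "levant_only") "slope_levant" else "slope"
    out[nm] <- unname(coef(lm(h ~ d))[2])
  }
  stopifnot(identical(names(out), summary_names()))
  out
}

#' Write / read summary vectors as TSV
#'
#' Batch format: one row per simulation with leading `sim_id` and `model`
#' columns followed by the 39 named statistics (the ABC exchange format).
#'
#' @param vectors a named numeric vector (single row) or a data.frame with
#'   `sim_id`, `model` and the 39 statistic columns.
#' @param path file path.
#' @export
write_summaries <- function(vectors, path) {
  if (is.numeric(vectors))
    vectors <- cbind(data.frame(sim_id = 1L, model = NA_character_),
                     as.data.frame(as.list(vectors), check.names = FALSE))
  write.table(vectors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) read.delim(path, check.names = FALSE)
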