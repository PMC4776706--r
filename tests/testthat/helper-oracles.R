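# Shared helpers: independent oracles and small builders used across tests.

# Brute-force multilocus R_ST oracle via the pairwise-difference identity:
# SS within a group of n genes equals the sum of squared differences over
# all pairs divided by n.  Independent of the moment-based implementation.
brute_rst <- function(dataset, pop_a, pop_b) {
  num <- den <- 0
  for (l in seq_len(ncol(dataset$geno))) {
    xa <- dataset$geno[dataset$pop == pop_a, l]
    xb <- dataset$geno[dataset$pop == pop_b, l]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    na <- length(xa); nb <- length(xb); N <- na + nb
    if (na < 1 || nb < 1 || N < 3) next
    ssd_pairs <- function(x) {
      s <- 0
      n <- length(x)
      if (n < 2) return(0)
      for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + (x[i] - x[j])^2
      s / n
    }
    ss_w <- ssd_pairs(xa) + ssd_pairs(xb)
    ss_t <- ssd_pairs(c(xa, xb))
    ss_a <- ss_t - ss_w
    ms_w <- ss_w / (N - 2)
    ms_a <- ss_a / 1
    n_c <- (N - (na^2 + nb^2) / N) / 1
    num <- num + (ms_a - ms_w) / n_c
    den <- den + (ms_a - ms_w) / n_c + ms_w
  }
  if (den == 0) return(0)
  num / den
}

# two-population dataset from explicit gene-level repeat vectors (per locus)
two_pop_dataset <- function(a_loci, b_loci) {
  geno <- rbind(do.call(cbind, a_loci), do.call(cbind, b_loci))
  genotype_dataset(geno,
                   pop = rep(c("A", "B"), c(length(a_loci[[1]]),
                                            length(b_loci[[1]]))),
                   groups = c(A = "AFR", B = "ENA"))
}

# constant single-deme record (haploid size N, n_gen recorded generations)
single_deme_record <- function(N, n_gen = 20) {
  demography_record(matrix(N, n_gen + 1, 1), 1, 1, c(1, 1),
                    ne_anc_genes = N)
}

one_pop_design <- function(n, n_loci = 1) {
  d <- data.frame(pop = "A", row = 1, col = 1, n = n, group = "AFR")
  attr(d, "n_loci") <- as.integer(n_loci)
  d
}

# matched demographic parameters (posterior-mean-like values) used by the
# mechanistic-signature tests
matched_params <- function(ldd = FALSE) {
  p <- c(T_STARTEXP = 4000, T_OOA = 2000, Ne_ANC = 12000, K = 1000,
         r = 0.56, m = 0.155, LDD_PROP = 0, mu_bar = 0, alpha = 0,
         STR_MUTRATE = 1.7e-4, KNeo = 0)
  if (ldd) p[c("LDD_PROP", "mu_bar", "alpha")] <- c(0.038, 4.78, 1.25)
  p
}

# session-level cache for expensive shared objects (reference tables)
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the shared scaled-down reference table over the four main models on the
# mini world (sizes documented in the methods vignette)
main_reference_table <- function() {
  cached("main_table", {
    land <- fixture_landscape("schematic-old-world-mini")
    abc_sample(c("noLDDnoRC", "noLDDRC", "LDDnoRC", "LDDRC"),
               n_sims = 100, landscape = land, n_loci = 12, seed = 20260922)
  })
}

# a larger single-model table for the parameter-recovery study
recovery_reference_table <- function() {
  cached("recovery_table", {
    land <- fixture_landscape("schematic-old-world-mini")
    abc_sample("noLDDnoRC", n_sims = 400, landscape = land, n_loci = 12,
               seed = 4181)
  })
}

# Gaussian toy reference table with two models whose summaries either
# coincide or separate; used by the MLR calibration tests
toy_table <- function(n = 400, shift = 0, seed = 1) {
  set.seed(seed)
  nm <- summary_names()
  X <- matrix(rnorm(2 * n * 39), 2 * n, 39, dimnames = list(NULL, nm))
  X[(n + 1):(2 * n), ] <- X[(n + 1):(2 * n), ] + shift
  cbind(data.frame(sim_id = 1:(2 * n),
                   model = rep(c("M1", "M2"), each = n)),
        as.data.frame(X))
}
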