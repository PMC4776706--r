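# The 39-statistic summary layer: hand-computed values, AMOVA oracle,
# slopes and invariances.

test_that("per-locus K, H, NGW match hand computations", {
  # monomorphic locus
  ds <- two_pop_dataset(list(rep(10L, 6)), list(rep(10L, 6)))
  s <- locus_stats(ds, "A")
  expect_equal(unlist(s[c("K", "H", "NGW")]),
               c(K = 1, H = 0, NGW = 1))
  # alleles {10, 14} at 1/2 each, 4 genes: H = (4/3)(1 - 0.5), NGW = 2/5
  ds <- two_pop_dataset(list(c(10L, 10L, 14L, 14L)), list(rep(10L, 4)))
  s <- locus_stats(ds, "A")
  expect_equal(s$K, 2)
  expect_equal(s$H, 4 / 3 * 0.5, tolerance = 1e-12)
  expect_equal(s$NGW, 0.4)
  # equifrequent {10, 11, 12}, 6 genes: NGW = 3/3 = 1
  ds <- two_pop_dataset(list(rep(c(10L, 11L, 12L), 2)), list(rep(10L, 6)))
  expect_equal(locus_stats(ds, "A")$NGW, 1)
  # under-typed loci are excluded
  g <- cbind(c(10L, 11L, NA, NA), c(10L, 12L, 11L, 13L))
  ds <- genotype_dataset(rbind(g, g), pop = rep(c("A", "B"), each = 4),
                         groups = c(A = "AFR", B = "ENA"))
  ds$geno[1:4, 1] <- c(10L, rep(NA_integer_, 3))
  expect_equal(nrow(locus_stats(ds, "A")), 1)
})

test_that("R_ST equals the brute-force AMOVA oracle on random instances", {
  set.seed(21)
  for (i in 1:25) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1); L <- sample(1:2, 1)
    a <- lapply(seq_len(L), function(l) sample(8:14, 2 * na, replace = TRUE))
    b <- lapply(seq_len(L), function(l) sample(8:16, 2 * nb, replace = TRUE))
    ds <- two_pop_dataset(a, b)
    expect_equal(pairwise_rst(ds, "A", "B"), brute_rst(ds, "A", "B"),
                 tolerance = 1e-10)
  }
})

test_that("R_ST separates fixed populations and vanishes under admixture", {
  # fixed for 10 vs 20 repeats, 10 diploids each
  ds <- two_pop_dataset(list(rep(10L, 20)), list(rep(20L, 20)))
  r <- pairwise_rst(ds, "A", "B")
  expect_equal(r, brute_rst(ds, "A", "B"), tolerance = 1e-12)
  expect_equal(r, 1)                     # no within-population variance
  # 50:50 admixture of the two gene pools into both populations
  mix <- rep(c(10L, 20L), 10)
  ds <- two_pop_dataset(list(mix), list(mix))
  r <- pairwise_rst(ds, "A", "B")
  expect_equal(r, brute_rst(ds, "A", "B"), tolerance = 1e-12)
  expect_lt(abs(r), 0.06)
  # identical populations: zero up to the finite-sample correction
  set.seed(22)
  x <- sample(10:15, 24, replace = TRUE)
  ds <- two_pop_dataset(list(x), list(x))
  expect_lt(abs(pairwise_rst(ds, "A", "B")), 0.06)
})

test_that("heterozygosity-distance slopes recover exact linear data", {
  g <- cbind(c(rep(10L, 10), rep(11L, 10),
               rep(10L, 16), rep(11L, 4),
               rep(10L, 19), rep(11L, 1)))
  ds <- genotype_dataset(g, pop = rep(c("P1", "P2", "P3"), each = 20),
                         groups = c(P1 = "AFR", P2 = "ENA", P3 = "CAS"))
  h <- vapply(c("P1", "P2", "P3"),
              function(p) mean(locus_stats(ds, p)$H), 0)
  d <- setNames(c(0, 1000, 2000), c("P1", "P2", "P3"))
  sl <- het_distance_slope(ds, d)
  expect_equal(sl, unname(coef(lm(h ~ d))[2]), tolerance = 1e-12)
  # identical H everywhere -> slope 0
  ds2 <- genotype_dataset(rbind(g[1:20, , drop = FALSE],
                                g[1:20, , drop = FALSE],
                                g[1:20, , drop = FALSE]),
                          pop = rep(c("P1", "P2", "P3"), each = 20),
                          groups = c(P1 = "AFR", P2 = "ENA", P3 = "CAS"))
  expect_equal(het_distance_slope(ds2, d), 0, tolerance = 1e-12)
  # degenerate distances are an error
  expect_error(het_distance_slope(ds, setNames(rep(1, 3), names(d))),
               "zero variance")
})

test_that("the summary vector has the 39 documented names and symmetries", {
  land <- fixture_landscape("schematic-old-world-mini")
  sc <- scenario_from_name("noLDDnoRC")
  p <- matched_params()
  p[["T_STARTEXP"]] <- 1500; p[["T_OOA"]] <- 1200
  rec <- run_forward(land, sc, p, seed = 31)
  design <- sampling_design(land, n_loci = 8)
  ds <- simulate_dataset(rec, design, 2e-4, seed = 32)
  ss <- summarize_dataset(ds, land, design)
  expect_length(ss, 39)
  expect_identical(names(ss), summary_names())
  expect_true(all(ss[grep("^H_", names(ss))] >= 0 &
                    ss[grep("^H_", names(ss))] <= 1))
  expect_true(all(ss[grep("^NGW_", names(ss))] <= 1))
  expect_true(all(ss[grep("^FST", names(ss))] <= 1))

  # permuting population order within groups leaves the vector unchanged
  pops <- unique(ds$pop)
  grp <- ds$groups[pops]
  new_order <- unlist(lapply(split(pops, grp)[unique(grp)], rev))
  perm <- unlist(lapply(new_order, function(p) which(ds$pop == p)))
  ds2 <- ds
  ds2$geno <- ds$geno[perm, , drop = FALSE]
  ds2$pop <- ds$pop[perm]
  ss2 <- summarize_dataset(ds2, land, design)
  expect_equal(ss2, ss, tolerance = 1e-12)

  # translating every repeat count at a locus leaves the vector unchanged
  ds3 <- ds
  ds3$geno[, 3] <- ds3$geno[, 3] + 7L
  expect_equal(summarize_dataset(ds3, land, design), ss, tolerance = 1e-12)

  # exchangeability: permuting individuals within a population
  set.seed(33)
  ds4 <- ds
  i_a <- which(ds$pop == design$pop[1])
  pairs <- matrix(i_a, nrow = 2)
  pairs <- pairs[, sample(ncol(pairs))]
  ds4$geno[i_a, ] <- ds$geno[as.vector(pairs), ]
  expect_equal(summarize_dataset(ds4, land, design), ss, tolerance = 1e-12)
})

test_that("identical populations give zero FST and SD statistics", {
  land <- fixture_landscape("schematic-old-world-mini")
  design <- sampling_design(land, n_loci = 3)
  block <- cbind(c(rep(10L, 8), rep(12L, 8)),
                 rep(c(10L, 13L), 8),
                 rep(11L, 16))
  geno <- do.call(rbind, rep(list(block), 12))
  ds <- genotype_dataset(geno, pop = rep(design$pop, each = 16),
                         groups = setNames(design$group, design$pop))
  ss <- summarize_dataset(ds, land, design)
  # identical samples leave only the finite-sample AMOVA correction,
  # bounded by ~1/(n_genes/2 - 1)
  expect_true(all(abs(ss[grep("^FST", names(ss))]) < 0.1))
  expect_equal(unname(ss["Ksd_AFR"]), unname(ss["Ksd_EAS"]))
  expect_equal(unname(ss["slope"]), 0, tolerance = 1e-12)
})

test_that("group structure prerequisites are enforced", {
  g <- cbind(rep(10:11, 8))
  ds <- genotype_dataset(g, pop = rep(c("A", "B"), each = 8),
                         groups = c(A = "AFR", B = "ENA"))
  land <- fixture_landscape("schematic-old-world-mini")
  design <- sampling_design(land, 1)
  expect_error(summarize_dataset(ds, land, design), "fewer than 2")
})

test_that("summary vectors round-trip as TSV", {
  v <- setNames(rnorm(39), summary_names())
  f <- tempfile(fileext = ".tsv")
  write_summaries(v, f)
  back <- read_summaries(f)
  expect_equal(unlist(back[summary_names()]),
               setNames(v, summary_names()))
})
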