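# Forward demography: logistic growth, emigration, the LDD kernel, and the
# recorded ledger.

test_that("logistic update honours its fixed points and hand values", {
  expect_equal(logistic_update(1000, 0.5, 1000), 1000)  # N = K equilibrium
  expect_equal(logistic_update(0, 0.9, 500), 0)          # absorbing state
  expect_equal(logistic_update(100, 0.5, 1000), 145)     # hand evaluation
  expect_equal(logistic_update(100, 0.5, 0), 0)          # killed deme
  # an overfull deme relaxes to K, never below
  expect_equal(logistic_update(50000, 0.6, 1000), 1000)
})

test_that("emigration splits the migrant pool as binomial/multinomial", {
  set.seed(1)
  z <- emigrate(1000, 0, 0.5)
  expect_equal(z$ldd_count, 0L)
  expect_equal(sum(z$adjacent), 0L)
  z <- emigrate(1000, 0.2, 0)
  expect_equal(z$ldd_count, 0L)
  expect_equal(sum(z$adjacent), 200L)
  # mean LDD count ~ M * p  (M = N*m gene copies)
  draws <- replicate(10000, emigrate(1000, 0.1, 0.04)$ldd_count)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 4), 3 * se)
})

test_that("the raw LDD kernel has mean mu_bar and the truncated-rounded
           kernel matches numerical integration", {
  set.seed(2)
  raw <- sample_ldd_distance(1e5, alpha = 1.25, mu_bar = 4.9,
                             truncate = FALSE)
  expect_lt(abs(mean(raw) - 4.9), 3 * sd(raw) / sqrt(length(raw)))
  # truncated-rounded draws vs the numeric pmf
  x <- sample_ldd_distance(1e5, alpha = 1.25, mu_bar = 4.9)
  expect_true(all(x >= 2 & x <= 6))
  pmf <- ldd_kernel_pmf(1.25, 4.9)
  obs <- tabulate(x, 6)[2:6]
  chi <- suppressWarnings(chisq.test(obs, p = pmf))
  expect_gt(chi$p.value, 0.01)
})

test_that("LDD targets respect masks and occupancy regimes", {
  land <- fixture_landscape("schematic-old-world-mini")
  full <- matrix(TRUE, land$n_rows, land$n_cols)     # fully occupied world
  set.seed(3)
  hits <- vapply(1:200, function(i)
    !is.null(sample_ldd_target(c(10, 6), 1.25, 4.9, land, full,
                               regime = "empty_only")), TRUE)
  expect_false(any(hits))                            # nothing empty to found
  # occupied_only on an empty world likewise discards everything
  empty <- matrix(FALSE, land$n_rows, land$n_cols)
  hits <- vapply(1:200, function(i)
    !is.null(sample_ldd_target(c(10, 6), 1.25, 4.9, land, empty,
                               regime = "occupied_only")), TRUE)
  expect_false(any(hits))
  # under "any", accepted targets are land demes within the 6-deme cap
  tg <- Filter(Negate(is.null), lapply(1:500, function(i)
    sample_ldd_target(c(10, 6), 1.25, 4.9, land, full, regime = "any")))
  expect_true(length(tg) > 0)
  for (t in tg) {
    expect_true(land$land[t[1], t[2]] && !land$barrier[t[1], t[2]])
    expect_lte(sqrt(sum((t - c(10, 6))^2)), 6 * sqrt(2))
  }
})

test_that("a single-deme world reproduces the scalar logistic recurrence", {
  land <- build_landscape("grid: |\n  L\norigin: [1, 1]\n")
  sc <- scenario_from_name("noLDDnoRC")
  p <- matched_params()
  p[c("T_STARTEXP", "T_OOA", "Ne_ANC", "K", "r", "m")] <-
    c(60, 30, 50, 400, 0.5, 0)
  rec <- run_forward(land, sc, p, seed = 1)
  N <- 2 * 50
  for (g in 59:0) {
    N <- logistic_update(N, 0.5, 2 * 400)
    expect_equal(rec$densities[g + 1, 1], N)
  }
})

test_that("gene counts are conserved through migration and the record is
           consistent", {
  land <- fixture_landscape("schematic-old-world-mini")
  sc <- scenario_from_name("LDDRC")
  p <- matched_params(ldd = TRUE)
  p[["T_STARTEXP"]] <- 1500; p[["T_OOA"]] <- 1200
  rec <- run_forward(land, sc, p, seed = 9)
  dg <- rec$diagnostics
  expect_equal(dg$emigrants,
               dg$immigrants + dg$lost_at_sea + dg$ldd_discarded)
  # densities vanish outside the habitable area
  expect_true(all(rec$densities[, !as.vector(land$land)] == 0))
  # densities bounded by the logistic overshoot bound K*(1+r/4)
  expect_lte(max(rec$densities[1:1000, ]),
             2 * p[["K"]] * (1 + p[["r"]] / 4) + 1e-6)
})

test_that("without LDD the front advances at most one deme per generation", {
  strip <- fixture_landscape("strip-16")
  sc <- scenario_from_name("noLDDnoRC")
  p <- matched_params()
  p[["T_STARTEXP"]] <- 300; p[["T_OOA"]] <- 200
  rec <- run_forward(strip, sc, p, seed = 4)
  first_gen <- apply(rec$densities >= 1, 2, function(col) max(which(col))) - 1
  lattice_d <- abs(seq_len(16) - 1)
  expect_true(all(300 - first_gen >= lattice_d))
  # occupied set stays 4-connected (contiguous on a strip)
  for (g in c(290, 250, 150, 0)) {
    occ <- which(rec$densities[g + 1, ] >= 1)
    if (length(occ)) expect_equal(occ, seq(min(occ), max(occ)))
  }
})

test_that("occupied_only runs never land LDD migrants in empty demes", {
  land <- fixture_landscape("schematic-old-world-mini")
  sc <- scenario_from_name("LDDnoRCop")
  p <- matched_params(ldd = TRUE)
  p[["T_STARTEXP"]] <- 2000; p[["T_OOA"]] <- 1500
  rec <- run_forward(land, sc, p, seed = 5)
  expect_gt(length(rec$ldd$gen), 0)
  dens_before <- rec$densities[cbind(rec$ldd$gen + 2L, rec$ldd$target + 1L)]
  expect_true(all(dens_before > 0))
})

test_that("under contraction the refuge phase confines the population", {
  land <- fixture_landscape("schematic-old-world-mini")
  sc <- scenario_from_name("noLDDRC")
  p <- matched_params()
  p[["T_STARTEXP"]] <- 2000; p[["T_OOA"]] <- 1500
  rec <- run_forward(land, sc, p, seed = 6)
  for (t in c(870, 800, 725)) {
    occ <- matrix(rec$densities[t + 1, ] >= 1, land$n_rows, land$n_cols)
    expect_true(all(!occ | land$refugia))
  }
  # recolonisation resumes after release
  occ0 <- matrix(rec$densities[1, ] >= 1, land$n_rows, land$n_cols)
  expect_gt(sum(occ0), sum(land$refugia))
})

test_that("records round-trip bit-exactly through serialisation", {
  land <- fixture_landscape("island-pair")
  sc <- scenario_from_name("noLDDnoRC")
  p <- matched_params()
  p[["T_STARTEXP"]] <- 100; p[["T_OOA"]] <- 50
  rec <- run_forward(land, sc, p, seed = 2)
  f <- tempfile(fileext = ".rds")
  write_record(rec, f)
  expect_identical(read_record(f), rec)
})
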