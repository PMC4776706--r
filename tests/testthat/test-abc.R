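# ABC machinery on controlled toy tables: rejection contract, logistic
# model choice, Box-Cox/PLS estimation, HPDIs and goodness-of-fit.

test_that("rejection retains exactly ceiling(tolerance * n) rows", {
  tab <- toy_table(n = 500, shift = 0.5, seed = 51)
  obs <- setNames(rnorm(39), summary_names())
  for (tol in c(0.02, 0.1, 0.33, 1)) {
    rej <- rejection(tab, obs, tol)
    expect_equal(nrow(rej$table), ceiling(tol * nrow(tab)))
  }
  # tolerance 1: the whole table, distances sorted
  rej <- rejection(tab, obs, 1)
  expect_equal(nrow(rej$table), nrow(tab))
  expect_true(!is.unsorted(rej$dist))
  # a row equal to the observation is retained first at distance zero
  obs2 <- unlist(tab[17, summary_names()])
  rej2 <- rejection(tab, obs2, 0.05)
  expect_equal(rej2$index[1], 17L)
  expect_equal(rej2$dist[1], 0)
  # zero-variance columns are dropped with a warning
  tab2 <- tab
  tab2$K_AFR <- 1
  expect_warning(rejection(tab2, obs, 0.1), "zero-variance")
})

test_that("model probabilities are symmetric for indistinguishable models", {
  # the logistic fit at the observed point carries sampling noise of order
  # sqrt(4 * n_stats / n_retained); 2,000 retained rows keep it below 0.15
  tab <- toy_table(n = 1500, shift = 0, seed = 52)
  set.seed(53)
  obs <- setNames(rnorm(39), summary_names())
  p <- mlr_model_posterior(rejection(tab, obs, 2 / 3))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_lt(abs(p[["M1"]] - 0.5), 0.15)
})

test_that("MLR is near-uniform when summaries carry no model signal", {
  # calibration property over repeated draws, 4,000 retained rows each
  set.seed(54)
  res <- replicate(8, {
    tab <- toy_table(n = 2500, shift = 0, seed = sample.int(1e6, 1))
    obs <- setNames(rnorm(39), summary_names())
    mlr_model_posterior(rejection(tab, obs, 0.8))[["M1"]]
  })
  expect_lt(mean(abs(res - 0.5)), 0.08)    # close to uniform per replicate
  expect_lt(abs(mean(res) - 0.5), 0.05)    # and unbiased across replicates
})

test_that("a separable toy yields near-certain model choice", {
  tab <- toy_table(n = 400, shift = 6, seed = 55)
  obs <- setNames(rnorm(39), summary_names())     # inside M1's cloud
  p <- suppressWarnings(mlr_model_posterior(rejection(tab, obs, 0.5)))
  expect_gt(p[["M1"]], 0.99)
})

test_that("a single retained model gives probability one with a warning", {
  tab <- toy_table(n = 100, shift = 0, seed = 56)
  tab <- tab[tab$model == "M1", ]
  obs <- setNames(rnorm(39), summary_names())
  expect_warning(p <- mlr_model_posterior(rejection(tab, obs, 0.5)),
                 "single model")
  expect_equal(unname(p), 1)
})

test_that("model choice aggregates bootstrap replicates as order
           statistics", {
  tab <- toy_table(n = 400, shift = 5, seed = 57)
  set.seed(58)
  reps <- matrix(rnorm(20 * 39), 20, 39,
                 dimnames = list(NULL, summary_names()))  # M1's cloud
  mc <- suppressWarnings(model_choice(tab, reps, tolerance = 0.5))
  expect_equal(dim(mc$posteriors), c(20L, 2L))
  expect_equal(unname(rowSums(mc$posteriors)), rep(1, 20), tolerance = 1e-9)
  agg <- mc$aggregate
  expect_gt(agg$median[agg$model == "M1"], 0.95)
  expect_lt(agg$median[agg$model == "M2"], 0.05)
  # interval bounds are order statistics of the replicate probabilities
  expect_equal(agg$lo95[1], unname(quantile(mc$posteriors[, 1], 0.025,
                                            type = 1)))
  expect_true(all(agg$lo95 <= agg$median & agg$median <= agg$hi95))
})

test_that("locus bootstrap replicates behave at the edge cases", {
  land <- fixture_landscape("schematic-old-world-mini")
  sc <- scenario_from_name("noLDDnoRC")
  p <- matched_params()
  p[["T_STARTEXP"]] <- 1500; p[["T_OOA"]] <- 1200
  rec <- run_forward(land, sc, p, seed = 57)
  design <- sampling_design(land, n_loci = 10)
  ds <- simulate_dataset(rec, design, 2e-4, seed = 58)
  # loci_per_replicate = all loci: every replicate equals the full panel
  full <- summarize_dataset(ds, land, design)
  B <- bootstrap_observed(ds, land, design, loci_per_replicate = 10,
                          n_replicates = 3, seed = 59)
  expect_equal(B[1, ], full, tolerance = 1e-12)
  expect_equal(B[3, ], full, tolerance = 1e-12)
  # proper subsets vary from replicate to replicate
  B2 <- bootstrap_observed(ds, land, design, loci_per_replicate = 5,
                           n_replicates = 20, seed = 60)
  expect_true(all(apply(B2[, c("H_AFR", "Ksd_pooled")], 2, sd) > 0))
  expect_error(bootstrap_observed(ds, land, design, loci_per_replicate = 50,
                                  n_replicates = 2), "fewer than")
  # determinism
  B3 <- bootstrap_observed(ds, land, design, loci_per_replicate = 5,
                           n_replicates = 20, seed = 60)
  expect_identical(B2, B3)
})

test_that("the HPDI is the shortest interval with the stated mass", {
  set.seed(61)
  x <- c(rnorm(5000), rnorm(1000, 10))
  h <- hpdi(x, 0.95)
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.95, tolerance = 0.01)
  # exact on a small sorted sample: shortest window of k+1 points
  y <- c(0, 1, 2, 3, 100)
  expect_equal(hpdi(y, 0.8), c(0, 3))
})

test_that("parameter estimation recovers a linear toy and respects priors", {
  set.seed(62)
  n <- 600
  theta <- runif(n, 0, 1)
  nm <- summary_names()
  X <- matrix(rnorm(n * 39, sd = 0.15), n, 39, dimnames = list(NULL, nm))
  X[, 1:10] <- X[, 1:10] + theta           # ten informative summaries
  tab <- cbind(data.frame(sim_id = 1:n, model = "M1", K = theta * 1950 + 50),
               as.data.frame(X))
  priors <- data.frame(param = "K", lower = 50, upper = 2000)
  truth <- 0.62
  obs <- setNames(c(rep(truth, 10), rep(0, 29)), nm)
  est <- estimate_parameters(tab, obs, tolerance = 0.2, n_pls = 5,
                             priors = priors)
  s <- est$summary
  expect_equal(s$param, "K")
  k_true <- truth * 1950 + 50
  expect_lt(abs(s$mean - k_true), 150)
  expect_true(s$hpdi_lo <= k_true && k_true <= s$hpdi_hi)
  expect_gte(s$hpdi_lo, 50)
  expect_lte(s$hpdi_hi, 2000)
  expect_true(all(est$sample >= 50 & est$sample <= 2000))
  # the RMSE curve is reported for every component
  expect_length(est$rmse_curve, 5)
  expect_true(all(is.finite(est$rmse_curve)))
  # an informative model beats the intercept-only spread
  expect_lt(s$hpdi_hi - s$hpdi_lo, 0.95 * (2000 - 50))
})

test_that("estimation demands a large enough table", {
  tab <- toy_table(n = 30, shift = 0, seed = 63)
  tab$K <- runif(60, 50, 2000)
  obs <- setNames(rnorm(39), summary_names())
  expect_error(estimate_parameters(tab, obs, tolerance = 0.2), "too small")
})

test_that("2D highest-density p-values grade from centroid to tail", {
  set.seed(64)
  B <- matrix(rnorm(2000), 1000, 2,
              dimnames = list(NULL, c("H_AFR", "H_ENA")))
  centre <- gof_2d_pvalue(B, c(0, 0), c("H_AFR", "H_ENA"))
  far <- gof_2d_pvalue(B, c(8, 8), c("H_AFR", "H_ENA"))
  expect_gt(centre, 0.9)
  expect_lt(far, 0.02)
  # bivariate normal: the 90% HDR contour has p ~ 0.10
  r90 <- sqrt(qchisq(0.90, df = 2))
  p90 <- gof_2d_pvalue(B, c(r90, 0), c("H_AFR", "H_ENA"))
  expect_lt(abs(p90 - 0.10), 0.05)
  expect_error(gof_2d_pvalue(cbind(H_AFR = rep(1, 200), H_ENA = rnorm(200)),
                             c(1, 0), c("H_AFR", "H_ENA")),
               "degenerate")
})

test_that("posterior predictive PCA is calibrated and nested", {
  set.seed(65)
  nm <- summary_names()
  P <- matrix(rnorm(300 * 39), 300, 39, dimnames = list(NULL, nm))
  obs <- setNames(P[7, ], nm)              # drawn from the same cloud
  ppc <- posterior_predictive_pca(P, obs)
  expect_length(ppc$pairs, 6)              # four PCs -> six pair panels
  for (pr in ppc$pairs) {
    expect_true(pr$pvalue >= 0 && pr$pvalue <= 1)
    # envelopes nested: the 95% density level is the lowest
    expect_true(all(diff(pr$levels) <= 0))
  }
  # observed points from the cloud give non-extreme p-values on average
  ps <- vapply(1:15, function(i) {
    o <- setNames(P[i, ], nm)
    mean(vapply(posterior_predictive_pca(P, o)$pairs,
                function(z) z$pvalue, 0))
  }, 0)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.85)
  expect_error(posterior_predictive_pca(P[1:20, ], obs), "fewer")
})

test_that("reference tables round-trip as TSV", {
  tab <- toy_table(n = 20, shift = 1, seed = 66)
  f <- tempfile(fileext = ".tsv")
  write_reference_table(tab, f)
  back <- read_reference_table(f)
  expect_equal(back$model, tab$model)
  expect_equal(back$K_AFR, tab$K_AFR, tolerance = 1e-9)
})
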