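# Approximate Bayesian computation: rejection sampling, multinomial
# logistic-regression model choice, locus-bootstrap uncertainty, Box-Cox/PLS
# parameter estimation with regression adjustment, pseudo-observed power
# studies and goodness-of-fit diagnostics.

#' Rejection step
#'
#' Statistics are standardised with per-column means/SDs estimated from the
#' full reference table, Euclidean distances to the observed vector are
#' computed, and exactly `ceiling(tolerance * n)` nearest rows are retained
#' (ties broken by row order).
#'
#' @param table reference table: data.frame with a `model` column, parameter
#'   columns and the 39 summary columns.
#' @param observed named numeric summary vector.
#' @param tolerance fraction of rows to retain, in (0, 1].
#' @return an `abc_rejection`: retained rows (`$table`), their distances
#'   (`$dist`), the standardisation (`$center`, `$scale`) and the statistic
#'   columns used.
#' @export
rejection <- function(table, observed, tolerance) {
  stopifnot(tolerance > 0, tolerance <= 1)
  stat_cols <- intersect(summary_names(), names(table))
  stat_cols <- intersect(stat_cols, names(observed))
  X <- as.matrix(table[stat_cols])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  drop <- scl == 0 | !is.finite(scl)
  if (any(drop)) {
    warning("dropping zero-variance statistic(s): ",
            paste(stat_cols[drop], collapse = ", "))
    stat_cols <- stat_cols[!drop]
    X <- X[, !drop, drop = FALSE]
    ctr <- ctr[!drop]; scl <- scl[!drop]
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  zobs <- (observed[stat_cols] - ctr) / scl
  d <- sqrt(rowSums(sweep(Z, 2, zobs)^2))
  keep <- order(d)[seq_len(ceiling(tolerance * nrow(table)))]
  structure(list(table = table[keep, , drop = FALSE],
                 dist = d[keep], index = keep,
                 center = ctr, scale = scl, stat_cols = stat_cols,
                 observed = observed[stat_cols]),
            class = "abc_rejection")
}

# Epanechnikov kernel weights on rejection distances
epanechnikov_weights <- function(d) {
  dmax <- max(d) * (1 + 1e-9)
  if (dmax == 0) return(rep(1, length(d)))
  1 - (d / dmax)^2
}

#' Model posterior probabilities by multinomial logistic regression
#'
#' Weighted multinomial logistic regression of the model label on the
#' standardised summaries within the retained set (Epanechnikov kernel
#' weights on the rejection distances), evaluated at the observed vector.
#'
#' @param rej an `abc_rejection` whose retained rows carry a `model` column.
#' @return named probability simplex over the models; attribute
#'   `regularized` flags a fallback ridge-penalised fit.
#' @export
mlr_model_posterior <- function(rej) {
  tab <- rej$table
  models <- sort(unique(tab$model))
  if (length(models) < 2) {
    warning("single model among retained simulations; probability 1")
    return(setNames(1, models))
  }
  Z <- sweep(sweep(as.matrix(tab[rej$stat_cols]), 2, rej$center),
             2, rej$scale, "/")
  zobs <- (rej$observed - rej$center) / rej$scale
  df <- data.frame(Z, check.names = TRUE)
  df$.model <- factor(tab$model, levels = models)
  w <- epanechnikov_weights(rej$dist)
  w <- w / mean(w)
  newd <- data.frame(as.list(setNames(zobs, colnames(Z))),
                     check.names = TRUE)
  fit <- nnet::multinom(.model ~ ., data = df, weights = w, trace = FALSE,
                        maxit = 200, MaxNWts = 10000)
  regularized <- FALSE
  if (max(abs(coef(fit))) > 30) {   # quasi-separation: ridge fallback
    fit <- nnet::multinom(.model ~ ., data = df, weights = w, trace = FALSE,
                          maxit = 200, MaxNWts = 10000, decay = 0.5)
    regularized <- TRUE
  }
  p <- predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(p))) {
    if (length(p) == 1) p <- c(1 - p, p)   # two models: P(second level)
    names(p) <- models
  }
  p <- pmax(as.vector(p), 0)
  p <- p / sum(p)
  structure(setNames(p, models), regularized = regularized)
}

#' Model choice over a set of observed replicate vectors
#'
#' Runs rejection plus multinomial-logistic model choice for each observed
#' replicate (typically the locus-bootstrap panels) and aggregates the
#' per-model posterior probabilities as order statistics: median and
#' central 95% interval over the replicates.
#'
#' @param table reference table with a `model` column.
#' @param observed_replicates matrix of summary vectors, one row per
#'   replicate (named columns), or a single named vector.
#' @param tolerance rejection tolerance.
#' @return a `model_choice_result`: `$posteriors` (replicates x models) and
#'   `$aggregate` (per model: median, lo95, hi95).
#' @export
model_choice <- function(table, observed_replicates, tolerance) {
  if (is.null(dim(observed_replicates)))
    observed_replicates <- matrix(observed_replicates, 1,
                                  dimnames = list(NULL,
                                                  names(observed_replicates)))
  models <- sort(unique(table$model))
  probs <- t(apply(observed_replicates, 1, function(obs) {
    p <- suppressWarnings(
      mlr_model_posterior(rejection(table, obs, tolerance)))
    out <- setNames(numeric(length(models)), models)
    out[names(p)] <- p
    out
  }))
  agg <- data.frame(model = models,
                    median = apply(probs, 2, median),
                    lo95 = apply(probs, 2, quantile, 0.025, type = 1),
                    hi95 = apply(probs, 2, quantile, 0.975, type = 1),
                    row.names = NULL)
  structure(list(posteriors = probs, aggregate = agg,
                 tolerance = tolerance),
            class = "model_choice_result")
}

#' Locus-bootstrap replicates of the observed summary vector
#'
#' Each replicate resamples `loci_per_replicate` distinct loci without
#' replacement and recomputes the full summary vector.
#'
#' @param dataset a `genotype_dataset` (the observed panel).
#' @param landscape,design as for [summarize_dataset()].
#' @param loci_per_replicate loci per replicate (50 by convention).
#' @param n_replicates number of bootstrap replicates (1,000 by convention).
#' @param seed optional integer seed.
#' @return numeric matrix, one row per replicate, 39 named columns.
#' @export
bootstrap_observed <- function(dataset, landscape, design,
                               loci_per_replicate = 50,
                               n_replicates = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(dataset)
  if (L < loci_per_replicate)
    stop("dataset has fewer than ", loci_per_replicate, " loci")
  t(vapply(seq_len(n_replicates), function(i) {
    keep <- sample.int(L, loci_per_replicate)
    summarize_dataset(subset_loci(dataset, keep), landscape, design)
  }, numeric(39)))
}

# ---- Box-Cox ----------------------------------------------------------------

# per-column Box-Cox: shift to positivity, lambda by profile ML on [-2, 2]
boxcox_fit <- function(x) {
  eps <- 1e-6
  shift <- if (min(x) <= 0) -min(x) + eps + 0.01 * diff(range(x)) else 0
  y <- x + shift
  loglik <- function(l) {
    z <- if (abs(l) < 1e-8) log(y) else (y^l - 1) / l
    -length(y) / 2 * log(var(z) + 1e-300) + (l - 1) * sum(log(y))
  }
  lambda <- optimize(loglik, c(-2, 2), maximum = TRUE)$maximum
  list(shift = shift, lambda = lambda)
}

boxcox_apply <- function(x, bc) {
  y <- pmax(x + bc$shift, 1e-12)
  if (abs(bc$lambda) < 1e-8) log(y) else (y^bc$lambda - 1) / bc$lambda
}

# ---- posterior summaries ----------------------------------------------------

#' Highest posterior density interval of a sample
#'
#' Shortest interval containing `mass` of the sorted sample.
#'
#' @param x numeric sample.
#' @param mass interval mass (0.95 by default).
#' @return numeric `c(lo, hi)`.
#' @export
hpdi <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(2L, ceiling(mass * n))   # points inside the interval
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

density_mode <- function(x, weights = NULL) {
  if (length(unique(x)) == 1) return(x[1])
  # bandwidth selection ignores the weights; silence R's note about it
  d <- if (is.null(weights)) density(x, n = 512) else
    suppressWarnings(density(x, weights = weights / sum(weights), n = 512))
  d$x[which.max(d$y)]
}

#' ABC parameter estimation with Box-Cox/PLS and regression adjustment
#'
#' Summaries are Box-Cox transformed (per-column maximum-likelihood lambda
#' estimated on the reference table) and reduced to `n_pls` partial
#' least-squares components fitted against the parameters.  Rejection runs
#' in component space; the retained parameter values are adjusted by a
#' weighted linear regression on the components (local-linear posterior
#' adjustment) and truncated to the prior support.
#'
#' @param table reference table restricted to one model.
#' @param observed named numeric summary vector.
#' @param tolerance rejection tolerance (fraction retained).
#' @param n_pls number of PLS components (12 by default).
#' @param priors data.frame of prior bounds for truncation.
#' @return a `posterior_result`: per-parameter summaries (`$summary`:
#'   mode, mean, median, 95% HPDI), the adjusted posterior sample
#'   (`$sample`), the PLS/Box-Cox transform, the RMSE-vs-components curve
#'   and the truncated fraction.
#' @export
estimate_parameters <- function(table, observed, tolerance, n_pls = 12,
                                priors = default_priors()) {
  stat_cols <- intersect(summary_names(), names(table))
  par_cols <- intersect(PARAM_NAMES, names(table))
  par_cols <- par_cols[vapply(par_cols,
                              function(p) var(table[[p]]) > 0, TRUE)]
  n <- nrow(table)
  if (ceiling(tolerance * n) < 50)
    stop("table too small: fewer than 50 simulations would be retained")

  X <- as.matrix(table[stat_cols])
  keepc <- apply(X, 2, function(z) sd(z) > 0)
  X <- X[, keepc, drop = FALSE]
  stat_cols <- stat_cols[keepc]
  bc <- lapply(seq_len(ncol(X)), function(j) boxcox_fit(X[, j]))
  Xt <- vapply(seq_len(ncol(X)), function(j) boxcox_apply(X[, j], bc[[j]]),
               numeric(n))
  colnames(Xt) <- stat_cols
  xobs <- vapply(seq_along(stat_cols), function(j)
    boxcox_apply(observed[[stat_cols[j]]], bc[[j]]), 0)
  Y <- as.matrix(table[par_cols])

  ncomp <- min(n_pls, ncol(Xt) - 1, n - 2)
  fit <- mixOmics::pls(Xt, Y, ncomp = ncomp, mode = "regression")
  comps <- fit$variates$X
  obs_comp <- predict(fit, matrix(xobs, 1,
                                  dimnames = list(NULL, stat_cols)))$variates

  # RMSE-vs-components on a deterministic 4:1 split of the table
  hold <- seq_len(n) %% 5 == 0
  rmse <- rep(NA_real_, ncomp)
  if (sum(hold) >= 10 && sum(!hold) > ncomp + 2) {
    f2 <- mixOmics::pls(Xt[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                        ncomp = ncomp, mode = "regression")
    pr <- predict(f2, Xt[hold, , drop = FALSE])$predict
    ysd <- apply(Y, 2, sd)
    for (k in seq_len(ncomp))
      rmse[k] <- sqrt(mean(sweep(Y[hold, , drop = FALSE] - pr[, , k],
                                 2, ysd, "/")^2))
  }

  # rejection in (standardised) component space
  csd <- apply(comps, 2, sd)
  Z <- sweep(comps, 2, csd, "/")
  zobs <- as.vector(obs_comp) / csd
  d <- sqrt(rowSums(sweep(Z, 2, zobs)^2))
  keep <- order(d)[seq_len(ceiling(tolerance * n))]
  w <- epanechnikov_weights(d[keep])

  # local-linear adjustment of each parameter on the components
  adj <- matrix(NA_real_, length(keep), length(par_cols),
                dimnames = list(NULL, par_cols))
  truncated <- 0L
  for (p in par_cols) {
    lf <- lm.wfit(cbind(1, comps[keep, , drop = FALSE]), table[[p]][keep], w)
    b <- lf$coefficients[-1]
    b[is.na(b)] <- 0
    shift <- (comps[keep, , drop = FALSE] -
                matrix(as.vector(obs_comp), length(keep), ncomp,
                       byrow = TRUE)) %*% b
    vals <- table[[p]][keep] - as.vector(shift)
    pr <- priors[priors$param == p, ]
    if (nrow(pr) == 1) {
      out_of <- vals < pr$lower | vals > pr$upper
      truncated <- truncated + sum(out_of)
      vals <- pmin(pmax(vals, pr$lower), pr$upper)
    }
    adj[, p] <- vals
  }

  summ <- do.call(rbind, lapply(par_cols, function(p)
    data.frame(param = p,
               mode = density_mode(adj[, p], w),
               mean = sum(w * adj[, p]) / sum(w),
               median = median(adj[, p]),
               hpdi_lo = hpdi(adj[, p])[1],
               hpdi_hi = hpdi(adj[, p])[2],
               stringsAsFactors = FALSE)))
  structure(list(summary = summ, sample = adj, weights = w,
                 pls = list(boxcox = bc, ncomp = ncomp,
                            loadings = fit$loadings$X),
                 rmse_curve = rmse,
                 truncated_fraction = truncated /
                   (length(keep) * length(par_cols))),
            class = "posterior_result")
}

#' Power of the model-choice procedure on pseudo-observed datasets
#'
#' PODS are reference simulations scored against the table with themselves
#' left out; a PODS is assigned to a model when its posterior probability
#' exceeds the threshold, and left unassigned otherwise.
#'
#' @param table combined reference table over the candidate models.
#' @param n_pods PODS per true model.
#' @param threshold assignment threshold (0.50 or 0.85).
#' @param tolerance rejection tolerance.
#' @param seed optional integer seed.
#' @return a `power_study`: `$confusion` (rows = true model; columns =
#'   assigned models plus `unassigned`, as fractions) and the per-PODS
#'   posterior matrix `$posteriors`.
#' @export
power_study <- function(table, n_pods, threshold = 0.5, tolerance = 0.1,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  models <- sort(unique(table$model))
  conf <- matrix(0, length(models), length(models) + 1,
                 dimnames = list(true = models,
                                 assigned = c(models, "unassigned")))
  posts <- NULL
  for (mtrue in models) {
    rows <- which(table$model == mtrue)
    pods <- sample(rows, min(n_pods, length(rows)))
    for (i in pods) {
      obs <- unlist(table[i, intersect(summary_names(), names(table))])
      rej <- rejection(table[-i, , drop = FALSE], obs, tolerance)
      p <- suppressWarnings(mlr_model_posterior(rej))
      p <- p[models]
      p[is.na(p)] <- 0
      names(p) <- models
      posts <- rbind(posts, data.frame(true = mtrue, t(p),
                                       check.names = FALSE))
      j <- which.max(p)
      if (p[j] > threshold)
        conf[mtrue, names(p)[j]] <- conf[mtrue, names(p)[j]] + 1
      else conf[mtrue, "unassigned"] <- conf[mtrue, "unassigned"] + 1
    }
    conf[mtrue, ] <- conf[mtrue, ] / length(pods)
  }
  structure(list(confusion = conf, posteriors = posts,
                 threshold = threshold, tolerance = tolerance),
            class = "power_study")
}

# ---- goodness of fit --------------------------------------------------------

# Gaussian product-kernel 2D density of cloud `pts` evaluated at `at`
kde2d_at <- function(pts, at) {
  h <- c(MASS::bandwidth.nrd(pts[, 1]), MASS::bandwidth.nrd(pts[, 2])) / 4
  h[h == 0] <- 1e-9
  vapply(seq_len(nrow(at)), function(i) {
    mean(exp(-0.5 * (((pts[, 1] - at[i, 1]) / h[1])^2 +
                       ((pts[, 2] - at[i, 2]) / h[2])^2)) /
           (2 * pi * h[1] * h[2]))
  }, 0)
}

#' Two-dimensional highest-density-region p-value
#'
#' Kernel density estimate over the bootstrap cloud of a pair of summary
#' statistics; the p-value of a queried 2D point (typically the posterior
#' mode of a model) is the fraction of bootstrap points whose density falls
#' below the density at the query.
#'
#' @param bootstrap_vectors matrix of bootstrap summary vectors (rows).
#' @param point named or ordered numeric length-2 query point.
#' @param pair character vector of the two statistic names.
#' @return p-value in `[0, 1]` (1 = query at the centroid).
#' @export
gof_2d_pvalue <- function(bootstrap_vectors, point, pair) {
  pts <- bootstrap_vectors[, pair, drop = FALSE]
  if (any(apply(pts, 2, sd) == 0))
    stop("degenerate (zero-variance) statistic pair: ",
         paste(pair, collapse = ", "))
  if (!is.null(names(point))) point <- point[pair]
  dens_boot <- kde2d_at(pts, pts)
  dens_q <- kde2d_at(pts, matrix(as.numeric(point), 1))
  mean(dens_boot < dens_q)
}

#' Posterior predictive check in principal-component space
#'
#' PCA is fitted on posterior-replicate summary vectors; the observed vector
#' is projected, and for each pair of the first `n_pc` components the
#' highest-density-region p-value of the observed point and the 50/75/95%
#' envelope density levels are returned.
#'
#' @param posterior_vectors matrix of summary vectors simulated from the
#'   posterior (rows).
#' @param observed named numeric summary vector.
#' @param n_pc number of leading components (4 by default, 6 pairs).
#' @return a `ppc_pca`: `$scores`, `$obs_scores`, and per-pair `$pairs`
#'   entries with `pvalue` and the envelope density `levels`.
#' @export
posterior_predictive_pca <- function(posterior_vectors, observed, n_pc = 4) {
  if (nrow(posterior_vectors) < ncol(posterior_vectors))
    stop("fewer posterior replicates than summary dimensions")
  keep <- apply(posterior_vectors, 2, sd) > 0
  pc <- prcomp(posterior_vectors[, keep, drop = FALSE],
               center = TRUE, scale. = TRUE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  obs <- predict(pc, matrix(observed[colnames(posterior_vectors)[keep]], 1,
                            dimnames = list(NULL,
                                            colnames(posterior_vectors)[keep])))
  obs <- obs[, seq_len(n_pc), drop = FALSE]
  prs <- combn(n_pc, 2, simplify = FALSE)
  pairs <- lapply(prs, function(pr) {
    pts <- scores[, pr]
    dens <- kde2d_at(pts, pts)
    dq <- kde2d_at(pts, matrix(obs[, pr], 1))
    list(pc = pr,
         pvalue = mean(dens < dq),
         levels = stats::quantile(dens, probs = 1 - c(0.50, 0.75, 0.95),
                                  names = FALSE))
  })
  names(pairs) <- vapply(prs, paste, "", collapse = "-")
  structure(list(scores = scores, obs_scores = obs, pairs = pairs),
            class = "ppc_pca")
}
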