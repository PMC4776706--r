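# Lattice world: masks, time-varying carrying capacities, least-cost distances.
#
# A landscape is a rectangular grid of square demes.  Cell classes come from
# an ASCII grid: '.' sea, 'L' land, 'B' barrier (carrying capacity forced to
# zero, e.g. deserts and high mountain ranges), 'C' corridor (habitable only
# once the out-of-Africa corridor opens), 'R' glacial refuge (land that stays
# habitable through the range contraction).

GRID_CHARS <- c(sea = ".", land = "L", barrier = "B", corridor = "C",
                refuge = "R")

#' Build a lattice landscape from a configuration document
#'
#' The configuration is a YAML document (file path, single string, or an
#' already-parsed list) with fields:
#' \describe{
#'   \item{grid}{an ASCII block, one row per line, characters `.` (sea),
#'     `L` (land), `B` (barrier), `C` (corridor), `R` (refuge).}
#'   \item{deme_side_km}{side of a square deme in km (default 150).}
#'   \item{origin}{`[row, col]` of the expansion origin deme.}
#'   \item{samples}{list of `{pop, row, col, n, group}` entries giving the
#'     sampled demes, diploid sample sizes and regional group (one of
#'     AFR, ENA, CAS, EAS).}
#'   \item{crossings}{optional list of `[[r1,c1],[r2,c2]]` short sea-crossing
#'     edges (e.g. Horn of Africa, Gibraltar) used by the
#'     `levant_horn_gibraltar` routing.}
#' }
#'
#' @param config path to a YAML file, a YAML string, or a list.
#' @return an object of class `landscape` with logical masks `land`,
#'   `barrier`, `corridor`, `refugia` (matrices `n_rows` x `n_cols`),
#'   the origin, the sampling design and the crossing edges.
#' @export
build_landscape <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1) {
    if (file.exists(config)) yaml::read_yaml(config) else yaml::yaml.load(config)
  } else if (is.list(config)) config else {
    stop("config must be a file path, a YAML string or a list")
  }
  if (is.null(cfg$grid)) stop("configuration error: missing 'grid' block")
  rows <- strsplit(cfg$grid, "\n")[[1]]
  rows <- rows[nzchar(rows)]
  widths <- nchar(rows)
  if (length(unique(widths)) != 1)
    stop("configuration error: grid rows have unequal widths (",
         paste(unique(widths), collapse = ", "), ")")
  n_rows <- length(rows)
  n_cols <- widths[1]
  cells <- matrix(unlist(strsplit(rows, "")), nrow = n_rows, ncol = n_cols,
                  byrow = TRUE)
  bad <- setdiff(unique(as.vector(cells)), GRID_CHARS)
  if (length(bad))
    stop("configuration error: unknown grid character(s): ",
         paste(bad, collapse = " "))

  land <- cells %in% c("L", "C", "R")
  dim(land) <- dim(cells)
  barrier  <- cells == "B"
  corridor <- cells == "C"
  refugia  <- cells == "R"

  origin <- as.integer(unlist(cfg$origin))
  if (length(origin) != 2 || any(is.na(origin)))
    stop("configuration error: origin must be [row, col]")
  if (origin[1] < 1 || origin[1] > n_rows || origin[2] < 1 || origin[2] > n_cols ||
      !land[origin[1], origin[2]])
    stop("configuration error: origin deme (", origin[1], ",", origin[2],
         ") is not on land")

  samples <- NULL
  if (!is.null(cfg$samples)) {
    samples <- do.call(rbind, lapply(cfg$samples, function(s)
      data.frame(pop = as.character(s$pop), row = as.integer(s$row),
                 col = as.integer(s$col), n = as.integer(s$n),
                 group = as.character(s$group), stringsAsFactors = FALSE)))
    for (i in seq_len(nrow(samples))) {
      r <- samples$row[i]; c <- samples$col[i]
      if (r < 1 || r > n_rows || c < 1 || c > n_cols || !land[r, c])
        stop("configuration error: sample '", samples$pop[i],
             "' at deme (", r, ",", c, ") is not on land")
    }
    if (anyDuplicated(samples$pop))
      stop("configuration error: duplicated population labels")
  }

  crossings <- lapply(cfg$crossings, function(x) {
    m <- matrix(as.integer(unlist(x)), nrow = 2, byrow = TRUE)
    for (k in 1:2) if (!land[m[k, 1], m[k, 2]])
      stop("configuration error: crossing endpoint (", m[k, 1], ",", m[k, 2],
           ") is not on land")
    m
  })

  structure(list(
    name = if (is.null(cfg$name)) "landscape" else cfg$name,
    n_rows = n_rows, n_cols = n_cols,
    land = land, barrier = barrier, corridor = corridor, refugia = refugia,
    deme_side_km = if (is.null(cfg$deme_side_km)) 150 else cfg$deme_side_km,
    origin = origin, samples = samples, crossings = crossings
  ), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", x$name, ": ", x$n_rows, "x", x$n_cols, " demes, ",
      x$deme_side_km, " km side\n", sep = "")
  cat("  land: ", sum(x$land), "  barrier: ", sum(x$barrier),
      "  corridor: ", sum(x$corridor), "  refuge: ", sum(x$refugia), "\n",
      sep = "")
  cat("  origin: (", x$origin[1], ",", x$origin[2], ")",
      if (!is.null(x$samples)) paste0("  samples: ", nrow(x$samples)), "\n",
      sep = "")
  invisible(x)
}

#' Glacial range-contraction schedule
#'
#' Thirty contraction events strip latitudinal layers of demes (north to
#' south) down to the refugia; populations then stay confined to refugia for
#' `refuge_duration_gen` generations before being released.  Event gaps are
#' four generations so that the contraction spans 120 generations.
#'
#' @param landscape a `landscape`.
#' @param t_start_gen onset of the contraction, generations before present.
#' @param n_events number of contraction events.
#' @param refuge_duration_gen length of the refugia-only phase, generations.
#' @return an object of class `contraction_schedule`: event times, the rows
#'   stripped at each event, and the refuge phase bounds.
#' @export
contraction_schedule <- function(landscape, t_start_gen = 1000, n_events = 30,
                                 refuge_duration_gen = 160) {
  gaps <- rep(4L, n_events)                      # 30 x 4 = 120 generations
  # rows holding land demes outside the refugia, ordered north -> south
  strip <- which(apply(landscape$land & !landscape$refugia, 1, any))
  if (length(strip) > 2L * n_events)
    stop("landscape has more contractible rows than 2 layers x ", n_events,
         " events")
  # spread rows over the events so the last event completes the contraction
  ev <- if (length(strip)) {
    ceiling(seq_along(strip) / (length(strip) / n_events))
  } else integer(0)
  rows_by_event <- split(strip, factor(ev, levels = seq_len(n_events)))
  event_times <- t_start_gen - cumsum(gaps) + gaps[1]  # first event at onset
  t_end <- t_start_gen - sum(gaps)
  structure(list(
    t_start_gen = t_start_gen, n_events = n_events,
    inter_event_gaps = gaps,
    event_times = event_times,
    rows_by_event = rows_by_event,
    layers_per_event = lengths(rows_by_event),
    t_end_contraction = t_end,
    refuge_duration_gen = refuge_duration_gen,
    t_release = t_end - refuge_duration_gen
  ), class = "contraction_schedule")
}

#' Carrying-capacity grid at a generation
#'
#' Per-deme diploid carrying capacity at `t` generations before present:
#' `K` on habitable land, 0 on sea and barriers; corridor demes open at
#' `T_OOA`; under range contraction the habitable area shrinks to the
#' refugia, where populations stay for the refuge phase; under the Neolithic
#' scenario `K` is replaced by `KNeo` from 320 generations BP onward.
#'
#' @param landscape a `landscape`.
#' @param schedule a `contraction_schedule` or `NULL` for no contraction.
#' @param scenario a `scenario_spec`.
#' @param params a parameter vector (needs `K`, `T_OOA`, optionally `KNeo`).
#' @param t generations before present.
#' @return numeric matrix of diploid carrying capacities.
#' @export
capacity_at <- function(landscape, schedule, scenario, params, t) {
  Kval <- params[["K"]]
  if (scenario$neolithic && t < NEOLITHIC_TIME_GEN) Kval <- params[["KNeo"]]
  K <- matrix(0, landscape$n_rows, landscape$n_cols)
  habitable <- landscape$land
  if (t > params[["T_OOA"]]) habitable <- habitable & !landscape$corridor
  if (!is.null(schedule) && scenario$range_contraction) {
    if (t <= schedule$t_end_contraction && t > schedule$t_release) {
      habitable <- habitable & landscape$refugia
    } else if (t > schedule$t_end_contraction && t <= schedule$t_start_gen) {
      gone <- unlist(schedule$rows_by_event[schedule$event_times >= t])
      if (length(gone)) {
        mask <- matrix(FALSE, landscape$n_rows, landscape$n_cols)
        mask[gone, ] <- TRUE
        habitable <- habitable & (landscape$refugia | !mask)
      }
    }
  }
  K[habitable] <- Kval
  K
}

# Piecewise-constant capacity epochs over [0, t_max], for the forward core.
# Returns list of epochs, each with t_hi (inclusive), t_lo (exclusive; the
# epoch covers t in (t_lo, t_hi]) and the K grid in GENE copies.
capacity_epochs <- function(landscape, schedule, scenario, params, t_max) {
  breaks <- c(params[["T_OOA"]])
  if (!is.null(schedule) && scenario$range_contraction)
    breaks <- c(breaks, schedule$event_times, schedule$t_end_contraction,
                schedule$t_release)
  if (scenario$neolithic) breaks <- c(breaks, NEOLITHIC_TIME_GEN)
  breaks <- sort(unique(c(breaks[breaks > 0 & breaks < t_max], 0, t_max)),
                 decreasing = TRUE)
  epochs <- vector("list", length(breaks) - 1)
  for (i in seq_along(epochs)) {
    t_hi <- breaks[i]; t_lo <- breaks[i + 1]
    Kg <- 2 * capacity_at(landscape, schedule, scenario, params, t_hi)
    epochs[[i]] <- list(t_hi = t_hi, t_lo = t_lo, K = as.vector(Kg))
  }
  epochs
}

#' Least-cost distances from an origin deme to the sampled demes
#'
#' Shortest-path distance over land (sea and barrier demes are impassable),
#' with 4-neighbour edges of length `deme_side_km`.  The
#' `levant_horn_gibraltar` routing additionally opens the landscape's
#' configured short sea-crossing edges.
#'
#' @param landscape a `landscape` with a sampling design.
#' @param origin `[row, col]`; defaults to the landscape origin.
#' @param routing `"levant_only"` or `"levant_horn_gibraltar"`.
#' @return data.frame with columns `deme_row`, `deme_col`,
#'   `population_label`, `distance_km`, `routing`.
#' @export
least_cost_distance <- function(landscape,
                                origin = landscape$origin,
                                routing = c("levant_only",
                                            "levant_horn_gibraltar")) {
  routing <- match.arg(routing)
  nr <- landscape$n_rows; nc <- landscape$n_cols
  idx <- function(r, c) (c - 1L) * nr + r
  pass <- landscape$land & !landscape$barrier
  ij <- which(pass, arr.ind = TRUE)
  edges <- NULL; weights <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L))) {      # south and east neighbours
    r2 <- ij[, 1] + d[1]; c2 <- ij[, 2] + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- pass[cbind(r2[ok], c2[ok])]
    edges <- rbind(edges, cbind(idx(ij[ok, 1], ij[ok, 2]), idx(r2[ok], c2[ok])))
    weights <- c(weights, rep(landscape$deme_side_km, sum(ok)))
  }
  if (routing == "levant_horn_gibraltar" && length(landscape$crossings)) {
    for (cr in landscape$crossings) {
      edges <- rbind(edges, c(idx(cr[1, 1], cr[1, 2]), idx(cr[2, 1], cr[2, 2])))
      weights <- c(weights,
                   sqrt(sum((cr[1, ] - cr[2, ])^2)) * landscape$deme_side_km)
    }
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::E(g)$weight <- weights
  if (is.null(landscape$samples)) stop("landscape has no sampling design")
  targets <- idx(landscape$samples$row, landscape$samples$col)
  dmat <- igraph::distances(g, v = idx(origin[1], origin[2]), to = targets)
  dkm <- as.vector(dmat)
  if (any(!is.finite(dkm))) {
    bad <- landscape$samples[!is.finite(dkm), , drop = FALSE]
    stop("unreachable sampled deme(s): ",
         paste0(bad$pop, " (", bad$row, ",", bad$col, ")", collapse = ", "))
  }
  data.frame(deme_row = landscape$samples$row,
             deme_col = landscape$samples$col,
             population_label = landscape$samples$pop,
             distance_km = dkm,
             routing = routing,
             stringsAsFactors = FALSE)
}

#' Write least-cost distances as TSV
#' @param distances output of [least_cost_distance()].
#' @param path file path.
#' @export
write_distances <- function(distances, path) {
  write.table(distances, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
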