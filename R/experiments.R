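#' Wilson score interval
#'
#' Binomial confidence interval used for every success-rate estimate.
#'
#' @param k Number of successes.
#' @param n Number of trials, at least 1.
#' @param confidence Confidence level.
#' @return Named vector `c(low, high)`.
#' @examples
#' wilson_interval(5, 10)
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  ph <- k / n
  denom <- 1 + z^2 / n
  centre <- (ph + z^2 / (2 * n)) / denom
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Sweep configuration
#'
#' Describes a batch of seeded (network, epidemic, algorithm) runs: the
#' base parameters, one swept parameter with its grid, the number of
#' realizations per grid point, and the algorithms to compare.
#'
#' @param N Population size (finite-network runs).
#' @param d_h,d_c Household network parameters.
#' @param params Base [epidemic_params()].
#' @param vary Name of the swept parameter
#'   (`"p_a"`, `"p_h"`, `"p_i"`, `"d_h"`, `"d_c"`), or `NULL` for a single
#'   point.
#' @param grid Values of the swept parameter.
#' @param realizations Independent runs per grid point.
#' @param algorithms Character vector among `"LS"`, `"LS+"`, `"LSv2"`,
#'   `"LS+v2"`, `"SG"`.
#' @param network `"hnm"` for the household network epidemic, or
#'   `"rb_tree"` for the no-recovery epidemic on the red-blue tree (used
#'   for theory validation).
#' @param base_seed Integer; every source of randomness is derived from it.
#' @param horizon,max_redraws Simulation horizon and the cap on redraws of
#'   runs with no hospitalization (which are discarded and counted).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(N = 400, d_h = 2, d_c = 3,
                         params = dde_default_params(),
                         vary = NULL, grid = NA, realizations = 4800,
                         algorithms = c("LS", "LS+"),
                         network = c("hnm", "rb_tree"),
                         base_seed = 1, horizon = 200, max_redraws = 200) {
  network <- match.arg(network)
  stopifnot(realizations >= 1, length(grid) >= 1)
  if (!is.null(vary))
    stopifnot(vary %in% c("p_a", "p_h", "p_i", "d_h", "d_c"))
  structure(list(N = N, d_h = d_h, d_c = d_c, params = params, vary = vary,
                 grid = grid, realizations = realizations,
                 algorithms = algorithms, network = network,
                 base_seed = base_seed, horizon = horizon,
                 max_redraws = max_redraws),
            class = "sweep_config")
}

# one conditioned realization: returns scored results for each algorithm
# plus the ground-truth path length, or NULL when every redraw failed
run_one <- function(config, point_params, d_h, d_c, seeds) {
  for (s in seeds) {
    if (config$network == "hnm") {
      net <- generate_hnm(config$N, d_h, d_c, seed = s,
                          allow_remainder = config$N %% (d_h + 1) != 0)
      source <- sample.int(config$N, 1L)
      trace <- simulate_dde(net, source, point_params,
                            horizon = config$horizon)
      if (is.null(trace$first_hospitalized)) next
      algs <- config$algorithms
      need_ls <- "SG" %in% algs
      run_algs <- union(algs, if (need_ls) c("LS", "LS+"))
      res <- list()
      deadline <- trace$first_hospitalized$day
      for (a in setdiff(run_algs, "SG")) {
        orc <- sictf_oracle(trace, net)
        r <- score_result(run_local_search(orc, a), trace)
        deadline <- max(deadline, orc$detection_day + r$days_elapsed)
        if (a %in% algs) res[[a]] <- r
      }
      if ("SG" %in% algs) {
        orc <- sictf_oracle(trace, net)
        r <- run_size_gain(orc, net, deadline_day = deadline, seed = s + 1)
        res[["SG"]] <- score_result(r, trace)
      }
      h <- trace$first_hospitalized$node
      return(list(results = res, trace_source = trace$source,
                  path_length = length(transmission_path(trace, h)) - 1L,
                  discards = match(s, seeds) - 1L))
    } else {
      # tree runs are re-simulated per algorithm with the same seed (the
      # oracle mutates the live tree), giving each algorithm an identical
      # epidemic
      sim <- simulate_dde_nr(list(d_c = d_c, d_h = d_h), point_params,
                             seed = s)
      if (is.null(sim$first_hospitalized)) next
      res <- list()
      for (a in setdiff(config$algorithms, "SG")) {
        sim_a <- simulate_dde_nr(list(d_c = d_c, d_h = d_h), point_params,
                                 seed = s)
        orc <- sictf_oracle(sim_a)
        res[[a]] <- score_result(run_local_search(orc, a), sim_a)
      }
      h <- sim$first_hospitalized$node
      return(list(results = res, trace_source = sim$source,
                  path_length = sim$level[h],
                  discards = match(s, seeds) - 1L))
    }
  }
  NULL
}

#' Run a parameter-sweep experiment
#'
#' For every grid point and realization: draw a fresh network, a uniform
#' random source, simulate until a first hospitalization occurs (runs with
#' none are discarded, redrawn and counted), run each algorithm through a
#' sealed oracle, and aggregate success rates (true source and first
#' symptomatic patient) with Wilson score intervals and mean query costs
#' with Student-t intervals. Fully deterministic given `base_seed`.
#'
#' @param config A [sweep_config()].
#' @param progress Print a line per grid point.
#' @return A data frame, one row per (grid point, algorithm).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  set.seed(config$base_seed)
  n_pts <- length(config$grid)
  seed_pool <- matrix(
    sample.int(2147483646L, n_pts * config$realizations * (config$max_redraws + 1L),
               replace = TRUE),
    nrow = n_pts)
  rows <- list()
  for (gi in seq_len(n_pts)) {
    val <- config$grid[gi]
    pp <- config$params
    d_h <- config$d_h; d_c <- config$d_c
    if (!is.null(config$vary)) {
      if (config$vary %in% c("p_a", "p_h", "p_i")) pp[[config$vary]] <- val
      else if (config$vary == "d_h") d_h <- val
      else d_c <- val
    }
    per_alg <- list()
    discards <- 0L
    path_lengths <- integer(0)
    for (j in seq_len(config$realizations)) {
      off <- (j - 1L) * (config$max_redraws + 1L)
      seeds <- seed_pool[gi, off + seq_len(config$max_redraws + 1L)]
      one <- run_one(config, pp, d_h, d_c, seeds)
      if (is.null(one)) next
      discards <- discards + one$discards
      path_lengths <- c(path_lengths, one$path_length)
      for (a in names(one$results)) {
        r <- one$results[[a]]
        per_alg[[a]] <- c(per_alg[[a]], list(r))
      }
    }
    for (a in names(per_alg)) {
      rs <- per_alg[[a]]
      n <- length(rs)
      src <- sum(vapply(rs, function(r) isTRUE(r$found_source), logical(1)))
      fs <- sum(vapply(rs, function(r) isTRUE(r$found_first_symptomatic),
                       logical(1)))
      tests <- vapply(rs, function(r) as.numeric(r$tests_used), numeric(1))
      edges <- vapply(rs, function(r) as.numeric(r$edges_revealed), numeric(1))
      t_int <- function(x) {
        if (length(x) < 2L || stats::sd(x) == 0)
          return(c(mean(x), mean(x)))
        m <- mean(x); h <- stats::qt(0.975, length(x) - 1) *
          stats::sd(x) / sqrt(length(x))
        c(m - h, m + h)
      }
      wi_s <- wilson_interval(src, n)
      wi_f <- wilson_interval(fs, n)
      ti_t <- t_int(tests); ti_e <- t_int(edges)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = if (is.null(config$vary)) "none" else config$vary,
        value = val, algorithm = a, runs = n, discarded = discards,
        success_source = src / n, source_low = wi_s[1], source_high = wi_s[2],
        success_first_symptomatic = fs / n,
        fs_low = wi_f[1], fs_high = wi_f[2],
        mean_tests = mean(tests), tests_low = ti_t[1], tests_high = ti_t[2],
        mean_edges = mean(edges), edges_low = ti_e[1], edges_high = ti_e[2],
        mean_path_length = mean(path_lengths))
    }
    if (progress)
      message(sprintf("point %d/%d (%s = %s) done", gi, n_pts,
                      if (is.null(config$vary)) "base" else config$vary,
                      format(val)))
  }
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- experiment_manifest(config)
  out
}

#' Run manifest of a sweep
#'
#' Everything needed to replay a sweep: the base seed, the grid, the
#' realization count, and the R and package versions.
#'
#' @param config A [sweep_config()].
#' @return A list; serialize with `jsonlite::write_json(...,
#'   auto_unbox = TRUE)` alongside the results table.
#' @export
experiment_manifest <- function(config) {
  list(base_seed = config$base_seed,
       network = config$network,
       N = config$N, d_h = config$d_h, d_c = config$d_c,
       vary = config$vary, grid = config$grid,
       realizations = config$realizations,
       algorithms = config$algorithms,
       params = unclass(config$params),
       r_version = as.character(getRversion()),
       package_version =
         as.character(utils::packageVersion("sictf")))
}

#' Overlay analytic predictions on sweep results
#'
#' Joins a sweep table with [predict_success()] values at matching
#' parameter points and flags disagreements: an LS prediction outside the
#' simulated Wilson band, or an LS+ lower bound exceeding the upper end of
#' the simulated band.
#'
#' @param rows Output of [run_experiment()].
#' @param predictions Data frame with columns `value`, `algorithm`,
#'   `prediction` at the same grid points.
#' @return The joined data frame with a logical `flagged` column.
#' @export
overlay_theory <- function(rows, predictions) {
  out <- merge(rows, predictions, by = c("value", "algorithm"))
  if (nrow(out) == 0L)
    stop("no overlapping (value, algorithm) points between simulation ",
         "and predictions")
  out$flagged <- ifelse(
    out$algorithm == "LS",
    out$prediction < out$source_low | out$prediction > out$source_high,
    out$prediction > out$source_high)
  out
}
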