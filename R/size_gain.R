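# Adaptive Size-Gain baseline, adapted to the contact-tracing framework.
# Unlike LS/LS+, Size-Gain assumes full knowledge of the contact network
# and narrows a source candidate set with a deterministic delay constraint.

# signed feasibility core: for observations (t1, d1), (t2, d2) against a
# candidate, the constraint is
#   |(t2 - t1) - (d2 - d1)| < sigma * (d1 + d2)        (both onsets)
# a negative observation only lower-bounds the true onset, so its side of
# the absolute value is dropped; an asymptomatic observation only
# upper-bounds it, so the sign is reversed.
sg_pair_ok <- function(kind1, t1, d1, kind2, t2, d2, sigma, delta = 1) {
  ok <- rep(TRUE, length(d1))
  reach <- is.finite(d1) & is.finite(d2)
  ok[!reach] <- FALSE
  e <- (t2 - t1) - delta * (d2 - d1)
  bound <- sigma * (d1 + d2)
  timed1 <- kind1 == "onset"; timed2 <- kind2 == "onset"
  if (timed1 && timed2) {
    ok[reach] <- abs(e[reach]) < bound[reach]
  } else if (kind2 == "negative" && kind1 != "negative") {
    ok[reach] <- e[reach] < bound[reach]
  } else if (kind1 == "negative" && kind2 != "negative") {
    ok[reach] <- -e[reach] < bound[reach]
  } else if (kind2 == "asymptomatic" && timed1) {
    ok[reach] <- -e[reach] < bound[reach]
  } else if (kind1 == "asymptomatic" && timed2) {
    ok[reach] <- e[reach] < bound[reach]
  }
  # negative-negative and asymptomatic-asymptomatic pairs constrain nothing
  ok
}

#' Size-Gain feasibility of a candidate
#'
#' Checks the deterministic delay constraint for one candidate source
#' against a pair of observations. Observations are lists with elements
#' `node`, `kind` (`"onset"`, `"negative"` or `"asymptomatic"`) and
#' `time`. With two symptom-onset observations the constraint is
#' `|(t2 - t1) - (d2 - d1)| < sigma * (d1 + d2)` where `d_i` is the
#' candidate's graph distance to observation `i`; a negative observation
#' drops the absolute value (its time is only a lower bound on the true
#' onset) and an asymptomatic one drops it with the sign reversed (upper
#' bound). Unreachable candidates are infeasible.
#'
#' @param candidate Candidate source node id.
#' @param obs1,obs2 Observations (see above).
#' @param net A `household_network`.
#' @param sigma Per-hop delay standard deviation, in days.
#' @param delta Mean per-hop transmission delay in days; 1 recovers the
#'   unit-delay constraint of deterministic-spread settings, while
#'   epidemics with latency use their own mean delay (the runner passes
#'   `T_E + 1/p_i - 1` for the discrete-day epidemic).
#' @return `TRUE` if the candidate survives this pair.
#' @export
sg_feasible <- function(candidate, obs1, obs2, net, sigma, delta = 1) {
  check_node(net, candidate)
  d1 <- graph_distance(net, obs1$node, candidate)
  d2 <- graph_distance(net, obs2$node, candidate)
  sg_pair_ok(obs1$kind, obs1$time, d1, obs2$kind, obs2$time, d2, sigma, delta)
}

# filter a candidate vector against the pairs (new_obs, each old obs),
# using a precomputed distance matrix D[node, candidate]
sg_filter <- function(cand, new_obs, old_obs, D, sigma, delta) {
  if (length(cand) == 0L || length(old_obs) == 0L) return(cand)
  d2 <- D[new_obs$node, cand]
  for (o in old_obs) {
    if (length(cand) == 0L) break
    keep <- sg_pair_ok(o$kind, o$time, D[o$node, cand],
                       new_obs$kind, new_obs$time, d2, sigma, delta)
    cand <- cand[keep]
    d2 <- d2[keep]
  }
  cand
}

#' Select the next Size-Gain sensor
#'
#' Scores untested nodes by the expected size of the candidate set after
#' observing them, where the expectation runs over hypotheses
#' (source, infection day) drawn uniformly from the candidate set and a
#' coarsened day grid, and the hypothetical observation is the
#' deterministic distance-based onset under the epidemic's mean per-hop
#' delay `T_E + 1/p_i`. Returns the minimizer (smallest node id on ties).
#'
#' @param state Size-Gain state: a list with `candidate_set`,
#'   `observations`, `sigma`, the distance matrix `D`, `params`, and the
#'   scan knobs `n_hyp`, `day_step`, `scan_cap`, `day_lo`, `day_hi`.
#' @param net A `household_network`.
#' @param untested Integer vector of nodes available as sensors.
#' @return A node id.
#' @export
sg_select_sensor <- function(state, net, untested) {
  scores <- sg_score_sensors(state, untested)
  untested[which.min(scores)]
}

# scores for a set of prospective sensors (lower = better); exact when
# n_hyp/scan_cap cover everything, subsampled (seeded by the caller) when
# the scan would be intractable
sg_score_sensors <- function(state, untested) {
  cand <- state$candidate_set
  D <- state$D
  delay <- state$delta
  onset_lag <- state$params$T_E + state$params$T_P
  days <- seq(state$day_lo, state$day_hi, by = state$day_step)
  hyp <- expand.grid(src = cand, day = days)
  if (nrow(hyp) > state$n_hyp)
    hyp <- hyp[sample.int(nrow(hyp), state$n_hyp), , drop = FALSE]
  timed <- Filter(function(o) o$kind != "negative", state$observations)
  vapply(untested, function(u) {
    du <- D[u, cand]
    tot <- 0
    for (i in seq_len(nrow(hyp))) {
      s <- hyp$src[i]
      tau <- hyp$day[i] + D[u, s] * delay + onset_lag
      keep <- rep(TRUE, length(cand))
      for (o in timed) {
        keep <- keep & sg_pair_ok(o$kind, o$time, D[o$node, cand],
                                  "onset", tau, du, state$sigma, state$delta)
        if (!any(keep)) break
      }
      tot <- tot + sum(keep)
    }
    tot / nrow(hyp)
  }, numeric(1))
}

#' Run the Size-Gain source identification baseline
#'
#' Initializes the candidate set to all nodes, places sensors adaptively
#' under the same daily test budget as the local-search algorithms, filters
#' candidates with the deterministic constraint after every result, and
#' terminates when the candidate set is a singleton. Past `deadline_day`
#' (by convention the day the local-search algorithms finished on the same
#' trace) the estimate is a uniformly random choice from the current
#' candidate set. An inconsistent set of constraints can empty the
#' candidate set, which is recorded as a failure.
#'
#' @param orc A [sictf_oracle()] over a static network.
#' @param net The `household_network` (Size-Gain has full network access).
#' @param deadline_day Absolute day of the fallback deadline.
#' @param seed Integer seed (hypothesis subsampling and the fallback pick).
#' @param sigma Per-hop delay standard deviation; `"auto"` uses
#'   `sqrt(1 - p_i) / p_i`, the standard deviation of the geometric
#'   per-edge infection delay.
#' @param delta Mean per-hop delay in days; defaults to the epidemic's
#'   `T_E + 1/p_i - 1`.
#' @param n_hyp,day_step,scan_cap Scan knobs: number of
#'   (source, infection day) hypotheses kept, day-grid coarsening, and the
#'   maximum number of prospective sensors scored per day (`Inf` for an
#'   exhaustive scan).
#' @return An `identification_result` (algorithm `"SG"`) with the extra
#'   fields `sg_failed` (candidate set emptied) and `candidate_set_size`.
#' @export
run_size_gain <- function(orc, net, deadline_day, seed = NULL,
                          sigma = "auto", delta = NULL, n_hyp = 48,
                          day_step = 2, scan_cap = 80) {
  stopifnot(orc$type == "static")
  if (!is.null(seed)) set.seed(seed)
  params <- orc$trace$params
  if (identical(sigma, "auto")) sigma <- sqrt(1 - params$p_i) / params$p_i
  if (is.null(delta)) delta <- params$T_E + 1 / params$p_i - 1
  N <- net$N
  D <- igraph::distances(net$graph)
  max_back <- (igraph::diameter(net$graph) + 1) * (delta + 1)

  state <- list(candidate_set = seq_len(N), observations = list(), sigma = sigma,
                delta = delta, D = D, params = params, n_hyp = n_hyp,
                day_step = day_step, scan_cap = scan_cap,
                day_lo = orc$detection_day - max_back,
                day_hi = orc$detection_day)

  add_obs <- function(state, obs) {
    state$candidate_set <- sg_filter(state$candidate_set, obs,
                                     state$observations, D, sigma, delta)
    state$observations <- c(state$observations, list(obs))
    state
  }
  state <- add_obs(state, list(node = orc$detection_node, kind = "onset",
                               time = orc$detection_onset))
  failed <- FALSE

  while (length(state$candidate_set) > 1 && orc$day <= deadline_day) {
    untested <- setdiff(seq_len(N), orc$tested)
    if (length(untested)) {
      if (length(untested) > scan_cap)
        untested <- sort(sample(untested, scan_cap))
      k <- min(if (is.finite(orc$budget)) orc$budget else length(untested),
               length(untested))
      scores <- sg_score_sensors(state, untested)
      pick <- untested[order(scores, untested)][seq_len(k)]
      for (u in pick) submit_test(orc, u)
    }
    advance_day(orc)
    res <- collect_results(orc)
    for (i in seq_len(nrow(res))) {
      kind <- switch(res$kind[i], onset_revealed = "onset",
                     negative = "negative", positive_no_time = "asymptomatic")
      tm <- if (kind == "onset") res$onset[i] else res$result_day[i] - 1
      state <- add_obs(state, list(node = res$node[i], kind = kind, time = tm))
    }
    if (length(state$candidate_set) == 0L) { failed <- TRUE; break }
  }

  cs <- state$candidate_set
  estimate <- if (failed) NA_integer_
  else if (length(cs) == 1L) cs
  else cs[sample.int(length(cs), 1L)]   # deadline fallback, uniform

  led <- oracle_ledger(orc)
  structure(list(
    algorithm = "SG",
    estimate = estimate,
    candidate_history = estimate,
    found_source = NA,
    found_first_symptomatic = NA,
    completed = !failed,
    sg_failed = failed,
    candidate_set_size = length(cs),
    tests_used = led$tests_submitted,
    edges_revealed = led$edges_revealed,
    household_queries = led$household_queries,
    days_elapsed = led$days_elapsed
  ), class = "identification_result")
}
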