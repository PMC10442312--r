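#' Simulate the discrete-day epidemic on a household network
#'
#' Day-synchronous dynamics: a node infected on day `t` is exposed on days
#' `t, ..., t + T_E - 1` and infectious from day `t + T_E`. With probability
#' `p_a` the course is asymptomatic (infectious for `T_I` days, then
#' recovered); otherwise the node is presymptomatic-infectious for `T_P`
#' days, then symptomatic, and is either hospitalized at `onset + T_H`
#' (probability `p_h`, after which it stops infecting) or recovers at
#' `onset + T_I - T_P`. Each infectious node attempts to infect each
#' currently susceptible neighbor independently with probability `p_i` per
#' day; all infections drawn on a day take effect simultaneously on that
#' day, and the infector is a uniform choice among that day's infectious
#' attackers.
#'
#' The full trajectory is recorded up to `horizon` days (or epidemic
#' extinction, whichever comes first): because queries never feed back into
#' the epidemic, replaying this record day by day is equivalent to lazy
#' real-time advancement. `stop = "first_hospitalization"` marks the run as
#' detection-oriented; when no hospitalization ever occurs,
#' `first_hospitalized` is `NULL` and the caller decides whether to discard
#' the run.
#'
#' @param net A `household_network`.
#' @param source Source node id (infected on day 0).
#' @param params An [epidemic_params()] object.
#' @param seed Optional integer seed.
#' @param horizon Last day on which new infections are drawn.
#' @param stop Either `"first_hospitalization"` or `"horizon"`; affects only
#'   how the absence of a hospitalization is interpreted, not the recorded
#'   trajectory.
#' @return An object of class `epidemic_trace` with per-node infection
#'   times, infectors, course flags, onset/hospitalization/recovery days,
#'   the `first_hospitalized` pair `(node, day)` (or `NULL`), and the
#'   parameters.
#' @examples
#' net <- generate_hnm(60, 2, 3, seed = 1)
#' tr <- simulate_dde(net, source = 1, dde_default_params(), seed = 2)
#' @export
simulate_dde <- function(net, source, params, seed = NULL, horizon = 200,
                         stop = c("first_hospitalization", "horizon")) {
  stop <- match.arg(stop)
  check_node(net, source)
  stopifnot(inherits(params, "epidemic_params"), horizon >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- net$N
  p_i <- params$p_i
  T_E <- params$T_E; T_P <- params$T_P; T_I <- params$T_I; T_H <- params$T_H

  inf_time <- rep(NA_real_, N)
  infector <- rep(NA_integer_, N)
  asym <- rep(NA, N)
  hospc <- rep(NA, N)

  draw_course <- function(ids) {
    k <- length(ids)
    a <- stats::runif(k) < params$p_a
    h <- !a & stats::runif(k) < params$p_h
    asym[ids] <<- a
    hospc[ids] <<- h
  }

  inf_time[source] <- 0
  draw_course(source)

  # end of the infectious window (exclusive); hospitalized stop at
  # hospitalization, others at recovery
  inf_end <- function(ids) {
    ifelse(asym[ids], inf_time[ids] + T_E + T_I,
           ifelse(hospc[ids], inf_time[ids] + T_E + T_P + T_H,
                  inf_time[ids] + T_E + T_I))
  }

  t <- 0
  repeat {
    t <- t + 1
    if (t > horizon) break
    infected <- which(!is.na(inf_time))
    ends <- inf_end(infected)
    infectious <- infected[inf_time[infected] + T_E <= t & t < ends]
    if (length(infectious) == 0L) {
      # no one infectious today; stop when no exposed node remains either
      if (!any(inf_time[infected] + T_E > t)) break
      next
    }
    nb <- unlist(net$adj[infectious], use.names = FALSE)
    cnt <- tabulate(nb, nbins = N)
    sus <- which(is.na(inf_time) & cnt > 0L)
    if (length(sus)) {
      pr <- 1 - (1 - p_i)^cnt[sus]
      hit <- sus[stats::runif(length(sus)) < pr]
      if (length(hit)) {
        is_infectious <- logical(N)
        is_infectious[infectious] <- TRUE
        for (u in hit) {
          att <- net$adj[[u]]
          att <- att[is_infectious[att]]
          infector[u] <- if (length(att) == 1L) att else
            att[sample.int(length(att), 1L)]
        }
        inf_time[hit] <- t
        draw_course(hit)
      }
    }
  }

  onset <- ifelse(!is.na(inf_time) & !asym, inf_time + T_E + T_P, NA_real_)
  hosp_time <- ifelse(!is.na(onset) & hospc, onset + T_H, NA_real_)
  recovery <- ifelse(is.na(inf_time), NA_real_,
                     ifelse(asym, inf_time + T_E + T_I,
                            ifelse(hospc, NA_real_, inf_time + T_E + T_I)))
  recovery[is.infinite(recovery)] <- NA_real_

  first_hosp <- NULL
  if (any(!is.na(hosp_time))) {
    d <- min(hosp_time, na.rm = TRUE)
    cand <- which(!is.na(hosp_time) & hosp_time == d)
    first_hosp <- list(node = min(cand), day = d)
  }

  structure(list(
    model = "dde", N = N, source = source, params = params,
    infection_time = inf_time, infector = infector,
    is_asymptomatic = asym, is_hospitalized_course = hospc,
    onset_time = onset, hospitalization_time = hosp_time,
    recovery_time = recovery, first_hospitalized = first_hosp,
    horizon = horizon, stop = stop
  ), class = "epidemic_trace")
}

#' @export
print.epidemic_trace <- function(x, ...) {
  n_inf <- sum(!is.na(x$infection_time))
  cat(sprintf("Epidemic trace (%s): source %d, %d/%d nodes ever infected\n",
              x$model, x$source, n_inf, x$N))
  if (!is.null(x$first_hospitalized))
    cat(sprintf("  first hospitalization: node %d on day %g\n",
                x$first_hospitalized$node, x$first_hospitalized$day))
  else cat("  no hospitalization\n")
  invisible(x)
}

# integer state codes, shared by the oracle
STATE_LEVELS <- c("susceptible", "exposed", "presymptomatic",
                  "asymptomatic_infectious", "symptomatic_infectious",
                  "hospitalized", "recovered")

state_code_at <- function(trace, v, t) {
  p <- trace$params
  it <- trace$infection_time[v]
  asym <- trace$is_asymptomatic[v]
  hospc <- trace$is_hospitalized_course[v]
  ht <- trace$hospitalization_time[v]
  out <- rep(1L, length(v))
  inf <- which(!is.na(it) & t >= it)
  if (length(inf) == 0L) return(out)
  exposed <- inf[t < it[inf] + p$T_E]
  out[exposed] <- 2L
  act <- setdiff(inf, exposed)
  ia <- act[asym[act]]
  out[ia] <- ifelse(t < it[ia] + p$T_E + p$T_I, 4L, 7L)
  sy <- act[!asym[act]]
  pre <- sy[t < it[sy] + p$T_E + p$T_P]
  out[pre] <- 3L
  sy <- setdiff(sy, pre)
  sh <- sy[hospc[sy]]
  out[sh] <- ifelse(t < ht[sh], 5L, 6L)
  sn <- sy[!hospc[sy]]
  out[sn] <- ifelse(t < it[sn] + p$T_E + p$T_I, 5L, 7L)
  out
}

#' Per-day disease state
#'
#' @param trace An `epidemic_trace`.
#' @param v Vector of node ids.
#' @param t Day.
#' @return Character vector of states among susceptible, exposed,
#'   presymptomatic, asymptomatic_infectious, symptomatic_infectious,
#'   hospitalized, recovered.
#' @export
state_at <- function(trace, v, t) {
  STATE_LEVELS[state_code_at(trace, v, t)]
}

#' Transmission path from the source to a node
#'
#' Follows infector links back to the source and returns the path in
#' source-to-node order; its length in hops is `length(path) - 1`.
#'
#' @param trace An `epidemic_trace`.
#' @param v An infected node.
#' @return Integer vector of node ids, starting at the source, ending at `v`.
#' @export
transmission_path <- function(trace, v) {
  if (is.na(trace$infection_time[v]))
    stop("node ", v, " was never infected; it has no transmission path")
  path <- v
  while (!is.na(trace$infector[v])) {
    v <- trace$infector[v]
    path <- c(v, path)
  }
  path
}

#' First symptomatic node of a trace
#'
#' The symptomatic node with the smallest infection time (ties broken by
#' smallest node id), or `NA` if every infected node is asymptomatic.
#'
#' @param trace An `epidemic_trace`.
#' @return A node id, or `NA_integer_`.
#' @export
first_symptomatic <- function(trace) {
  sym <- which(!is.na(trace$infection_time) & !trace$is_asymptomatic)
  if (length(sym) == 0L) return(NA_integer_)
  sym[order(trace$infection_time[sym], sym)][1L]
}

#' Write a trace as a comma-separated file
#'
#' One row per infected node: node id, infection time, infector, course
#' (`symptomatic`/`asymptomatic`), onset, hospitalization and recovery days
#' (empty when not applicable). Node ids are 0-based in the file.
#'
#' @param trace An `epidemic_trace`.
#' @param file Output path.
#' @export
write_trace <- function(trace, file) {
  inf <- which(!is.na(trace$infection_time))
  df <- data.frame(
    node = inf - 1L,
    infection_time = trace$infection_time[inf],
    infector = trace$infector[inf] - 1L,
    course = ifelse(trace$is_asymptomatic[inf], "asymptomatic",
                    ifelse(trace$is_hospitalized_course[inf],
                           "symptomatic_hospitalized", "symptomatic")),
    onset_time = trace$onset_time[inf],
    hospitalization_time = trace$hospitalization_time[inf],
    recovery_time = trace$recovery_time[inf]
  )
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(trace)
}
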