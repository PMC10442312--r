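#' Detect the outbreak of a trace
#'
#' The identification task starts when the first hospitalization occurs:
#' this returns the first hospitalized node and its hospitalization day
#' (ties broken by smallest node id). The first hospitalized patient is
#' diagnosed in hospital, so its symptom onset time is known to the agency
#' from the start without spending a test.
#'
#' @param trace An `epidemic_trace` (static network or tree simulation).
#' @return A list with elements `node` and `day`.
#' @export
detect_outbreak <- function(trace) {
  fh <- trace$first_hospitalized
  if (is.null(fh))
    stop("no hospitalization in this trace; the outbreak is never detected ",
         "and the run should be discarded")
  fh
}

#' Create a query oracle over an epidemic
#'
#' The oracle is the only lawful access path from identification algorithms
#' to the ground truth. It starts at the first hospitalization, answers
#' household and contact queries instantly, administers at most `budget`
#' tests per day (submissions beyond the budget spill to the next day) and
#' returns each test result the day after it is administered, while the
#' epidemic keeps advancing in real time. All queries and counters are
#' recorded in a ledger and a replayable query log.
#'
#' @param trace For a static network: an `epidemic_trace` from
#'   [simulate_dde()] together with its `net`. For the tree model: a live
#'   `dde_nr_sim` from [simulate_dde_nr()] (`net` is ignored).
#' @param net The `household_network` the trace was simulated on.
#' @param budget Daily test budget. Defaults to [test_budget()] of the
#'   population size on finite networks and to unlimited on the infinite
#'   tree, where the 1%-of-population cap is vacuous.
#' @return An object of class `sictf_oracle` (an environment).
#' @export
sictf_oracle <- function(trace, net = NULL, budget = NULL) {
  orc <- new.env(parent = emptyenv())
  if (inherits(trace, "dde_nr_sim")) {
    orc$type <- "tree"
    orc$sim <- trace
    if (is.null(budget)) budget <- Inf
  } else {
    stopifnot(inherits(trace, "epidemic_trace"),
              inherits(net, "household_network"))
    orc$type <- "static"
    orc$trace <- trace
    orc$net <- net
    if (is.null(budget)) budget <- test_budget(net$N)
  }
  fh <- detect_outbreak(trace)
  orc$budget <- budget
  orc$day <- fh$day
  orc$detection_day <- fh$day
  orc$detection_node <- fh$node
  orc$detection_onset <- if (orc$type == "tree")
    trace$onset_time[fh$node] else trace$onset_time[fh$node]
  orc$queue <- integer(0)        # submitted, not yet administered
  orc$res_node <- integer(0)     # administered, delivery pending/done
  orc$res_kind <- character(0)
  orc$res_onset <- numeric(0)
  orc$res_day <- numeric(0)
  orc$collected <- logical(0)
  orc$tested <- fh$node          # the detected case is never re-tested
  orc$edge_keys <- new.env(parent = emptyenv())
  orc$tests_submitted <- 0L
  orc$edges_revealed <- 0L
  orc$household_queries <- 0L
  orc$log_day <- numeric(0)
  orc$log_type <- character(0)
  orc$log_arg <- numeric(0)
  orc$log_resp <- character(0)
  class(orc) <- "sictf_oracle"
  orc
}

#' @export
print.sictf_oracle <- function(x, ...) {
  cat(sprintf("SICTF oracle (%s): day %g (detected day %g, node %d)\n",
              x$type, x$day, x$detection_day, x$detection_node))
  cat(sprintf("  ledger: %d tests, %d edges revealed, %d household queries\n",
              x$tests_submitted, x$edges_revealed, x$household_queries))
  invisible(x)
}

log_query <- function(orc, type, arg, resp) {
  orc$log_day <- c(orc$log_day, orc$day)
  orc$log_type <- c(orc$log_type, type)
  orc$log_arg <- c(orc$log_arg, arg)
  orc$log_resp <- c(orc$log_resp, resp)
}

#' Household query
#'
#' Reveals the agents living in the same household as `v` (including `v`).
#' Unlimited and free, but counted in the ledger; answered instantly.
#'
#' @param orc A `sictf_oracle`.
#' @param v Node id.
#' @return Integer vector of household members.
#' @export
household_query <- function(orc, v) {
  res <- if (orc$type == "tree") tree_household_of(orc$sim, v)
  else household_of(orc$net, v)
  orc$household_queries <- orc$household_queries + 1L
  log_query(orc, "household", v, paste0("members=", length(res)))
  res
}

#' Contact query
#'
#' Reveals all direct contacts (graph neighbors) of `v`. The optional time
#' window is part of the interface for time-varying networks and is ignored
#' on static ones. The ledger's `edges_revealed` increases by the number of
#' incident edges not previously revealed; an edge is only ever counted
#' once however often its endpoints are queried.
#'
#' @param orc A `sictf_oracle`.
#' @param v Node id.
#' @param window Optional day interval `c(from, to)`; ignored on static
#'   networks but recorded in the query log.
#' @return Integer vector of neighbors of `v`.
#' @export
contact_query <- function(orc, v, window = NULL) {
  if (orc$type == "tree") {
    nbrs <- tree_neighbors_of(orc$sim, v)
    # a tree edge is uniquely keyed by its child endpoint
    keys <- ifelse(nbrs == orc$sim$parent[v] & !is.na(orc$sim$parent[v]),
                   v, nbrs)
  } else {
    nbrs <- orc$net$adj[[v]]
    keys <- (pmin(v, nbrs) - 1) * orc$net$N + pmax(v, nbrs)
  }
  new <- 0L
  for (k in as.character(keys)) {
    if (!exists(k, envir = orc$edge_keys, inherits = FALSE)) {
      assign(k, TRUE, envir = orc$edge_keys)
      new <- new + 1L
    }
  }
  orc$edges_revealed <- orc$edges_revealed + new
  log_query(orc, "contact", v,
            paste0("neighbors=", length(nbrs), ";new_edges=", new,
                   if (!is.null(window))
                     paste0(";window=", window[1], ":", window[2])))
  nbrs
}

#' Submit a test
#'
#' The test joins the processing queue: at most `budget` queued tests are
#' administered per day (in submission order), each evaluated against the
#' node's disease state on the day it is administered, with the result
#' delivered the following day. Re-testing a node is rejected.
#'
#' @param orc A `sictf_oracle`.
#' @param v Node id.
#' @return Invisibly, `TRUE` if accepted, `FALSE` for a duplicate.
#' @export
submit_test <- function(orc, v) {
  if (v %in% orc$tested || v %in% orc$queue) {
    log_query(orc, "test_submit", v, "rejected_duplicate")
    return(invisible(FALSE))
  }
  orc$queue <- c(orc$queue, v)
  orc$tests_submitted <- orc$tests_submitted + 1L
  log_query(orc, "test_submit", v, "queued")
  invisible(TRUE)
}

# test outcome of node v evaluated at day t
evaluate_test <- function(orc, v, t) {
  src <- if (orc$type == "tree") orc$sim else orc$trace
  code <- state_code_at(src, v, t)
  if (code <= 2L) {
    list(kind = "negative", onset = NA_real_)
  } else if (code == 3L || code == 4L ||
             (code == 7L && isTRUE(src$is_asymptomatic[v]))) {
    # presymptomatic, asymptomatic (current or recovered): positive, no time
    list(kind = "positive_no_time", onset = NA_real_)
  } else {
    list(kind = "onset_revealed", onset = src$onset_time[v])
  }
}

#' Advance the oracle (and the epidemic) by one day
#'
#' Administers up to `budget` queued tests against today's states, advances
#' the epidemic one day, increments the clock, and matures yesterday's
#' results. The epidemic advances whether or not any query was made.
#'
#' @param orc A `sictf_oracle`.
#' @return The new day, invisibly.
#' @export
advance_day <- function(orc) {
  t <- orc$day
  k <- min(length(orc$queue), orc$budget)
  if (k > 0) {
    todo <- orc$queue[seq_len(k)]
    orc$queue <- orc$queue[-seq_len(k)]
    for (v in todo) {
      res <- evaluate_test(orc, v, t)
      orc$res_node <- c(orc$res_node, v)
      orc$res_kind <- c(orc$res_kind, res$kind)
      orc$res_onset <- c(orc$res_onset, res$onset)
      orc$res_day <- c(orc$res_day, t + 1)
      orc$collected <- c(orc$collected, FALSE)
      orc$tested <- c(orc$tested, v)
      log_query(orc, "test_administer", v, res$kind)
    }
  }
  if (orc$type == "tree") step_tree(orc$sim)
  orc$day <- t + 1
  invisible(orc$day)
}

#' Collect matured test results
#'
#' Returns the results delivered up to the current day that have not been
#' collected yet, in administration order. Collecting advances nothing.
#'
#' @param orc A `sictf_oracle`.
#' @return A data frame with columns `node`, `kind`
#'   (`negative` / `positive_no_time` / `onset_revealed`), `onset` (`NA`
#'   unless revealed) and `result_day`.
#' @export
collect_results <- function(orc) {
  idx <- which(!orc$collected & orc$res_day <= orc$day)
  orc$collected[idx] <- TRUE
  data.frame(node = orc$res_node[idx], kind = orc$res_kind[idx],
             onset = orc$res_onset[idx], result_day = orc$res_day[idx])
}

#' Nodes whose hospitalization has been announced so far
#'
#' The agency learns the identity of nodes when they become hospitalized.
#'
#' @param orc A `sictf_oracle`.
#' @return Integer vector of hospitalized node ids (by the current day).
#' @export
announced_hospitalizations <- function(orc) {
  src <- if (orc$type == "tree") orc$sim else orc$trace
  n <- if (orc$type == "tree") src$n else src$N
  ht <- src$hospitalization_time[seq_len(n)]
  which(!is.na(ht) & ht <= orc$day)
}

#' Oracle ledger
#'
#' @param orc A `sictf_oracle`.
#' @return A list with `tests_submitted`, `edges_revealed`,
#'   `household_queries` and `days_elapsed` (since detection).
#' @export
oracle_ledger <- function(orc) {
  list(tests_submitted = orc$tests_submitted,
       edges_revealed = orc$edges_revealed,
       household_queries = orc$household_queries,
       days_elapsed = orc$day - orc$detection_day)
}

#' Query log
#'
#' One row per query (day, type, argument, response kind), for audit and
#' replay; [write_query_log()] saves it as a comma-separated file with
#' 0-based node ids.
#'
#' @param orc A `sictf_oracle`.
#' @param file Output path.
#' @return `query_log` returns the log as a data frame.
#' @export
query_log <- function(orc) {
  data.frame(day = orc$log_day, type = orc$log_type,
             argument = orc$log_arg, response = orc$log_resp)
}

#' @rdname query_log
#' @export
write_query_log <- function(orc, file) {
  log <- query_log(orc)
  log$argument <- log$argument - 1
  utils::write.csv(log, file, row.names = FALSE)
  invisible(log)
}
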