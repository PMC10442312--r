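#' Backward-contact time window
#'
#' The interval in which the infector of a candidate must have been in
#' contact with it. For a symptomatic candidate with onset `t`, the
#' infection happened `T_E + T_P` days before onset, so the window is
#' centred on `t - (T_E + T_P)` with slack `sigma_E + sigma_P` on each
#' side. For an asymptomatic household member of the candidate, the member
#' must have been infectious when the candidate was infected, so it was
#' itself infected between `T_P + 2 T_E + T_I` and `T_P + 2 T_E` days
#' before `t`. On static networks every neighbor counts as a backward
#' contact and the window is informational only.
#'
#' @param t_candidate Symptom onset day of the current candidate.
#' @param params An [epidemic_params()] object.
#' @param target `"symptomatic_candidate"` or `"asymptomatic_member"`.
#' @return Numeric vector `c(from, to)`.
#' @examples
#' backward_window(12, dde_default_params())                # c(7, 7)
#' backward_window(12, dde_default_params(), "asymptomatic_member")
#' @export
backward_window <- function(t_candidate, params,
                            target = c("symptomatic_candidate",
                                       "asymptomatic_member")) {
  target <- match.arg(target)
  if (target == "symptomatic_candidate") {
    mid <- t_candidate - (params$T_E + params$T_P)
    slack <- params$sigma_E + params$sigma_P
    c(mid - slack, mid + slack)
  } else {
    c(t_candidate - (params$T_P + 2 * params$T_E + params$T_I),
      t_candidate - (params$T_P + 2 * params$T_E))
  }
}

#' Run the LocalSearch identification algorithms
#'
#' Greedy backward tracing from the first hospitalized patient. The
#' candidate is always the node with the earliest revealed symptom onset.
#' Per iteration, the household members and backward contacts of the
#' current candidate are queued and tested (respecting the daily budget;
#' the iteration only ends when the test queue empties); any revealed
#' onset earlier than the running best updates the next candidate, and the
#' algorithm terminates when an iteration produces no update.
#'
#' `LS+` additionally reacts to positive tests without an onset time
#' (asymptomatic or presymptomatic nodes): their household members are
#' queued, and when such a node is in the current candidate's household its
#' backward contacts are queued as well, using the wider asymptomatic
#' window. The `v2` variants cut an iteration the moment the candidate is
#' first updated, discarding the remaining queue.
#'
#' @param orc A [sictf_oracle()] whose outbreak has been detected.
#' @param variant One of `"LS"`, `"LS+"`, `"LSv2"`, `"LS+v2"`.
#' @param max_days Guard on identification days after detection; exceeding
#'   it returns a partial result flagged `completed = FALSE`.
#' @return An object of class `identification_result`: the `estimate`, the
#'   `candidate_history`, success flags `found_source` and
#'   `found_first_symptomatic` (filled by the caller via
#'   [score_result()] when ground truth is at hand), and the ledger
#'   counters `tests_used`, `edges_revealed`, `household_queries`,
#'   `days_elapsed`.
#' @export
run_local_search <- function(orc, variant = c("LS", "LS+", "LSv2", "LS+v2"),
                             max_days = 365) {
  variant <- match.arg(variant)
  plus <- variant %in% c("LS+", "LS+v2")
  v2 <- variant %in% c("LSv2", "LS+v2")
  params <- if (orc$type == "tree") orc$sim$params else orc$trace$params

  cand <- orc$detection_node
  cand_onset <- orc$detection_onset
  history <- cand
  seen <- cand                    # never enqueued or tested twice
  asym_known <- integer(0)        # positives with no onset time seen so far
  completed <- TRUE

  repeat {
    sc_prime <- cand
    sc_onset <- cand_onset
    hh <- household_query(orc, cand)
    win <- backward_window(cand_onset, params)
    bc <- contact_query(orc, cand, window = win)
    # household members first, then backward contacts; FIFO, id tie-break
    queue <- c(sort(setdiff(hh, seen)), sort(setdiff(bc, c(seen, hh))))
    if (plus) {
      # backward contacts of the candidate's already-known asymptomatic
      # household members (tested in an earlier iteration)
      awin <- backward_window(cand_onset, params, "asymptomatic_member")
      for (u in intersect(hh, asym_known)) {
        add <- sort(setdiff(contact_query(orc, u, window = awin),
                            c(seen, queue)))
        queue <- c(queue, add)
      }
    }
    seen <- c(seen, queue)
    cut <- FALSE

    for (v in queue) submit_test(orc, v)
    n_pending <- length(queue)
    while (n_pending > 0L) {
      advance_day(orc)
      if (orc$day - orc$detection_day > max_days) {
        completed <- FALSE
        break
      }
      res <- collect_results(orc)
      n_pending <- n_pending - nrow(res)
      for (i in seq_len(nrow(res))) {
        node <- res$node[i]; kind <- res$kind[i]
        if (kind == "onset_revealed" && res$onset[i] < sc_onset) {
          sc_prime <- node
          sc_onset <- res$onset[i]
          if (v2) { cut <- TRUE; break }
        } else if (kind == "positive_no_time" && plus) {
          asym_known <- c(asym_known, node)
          add <- sort(setdiff(household_query(orc, node), seen))
          if (node %in% household_query(orc, cand)) {
            awin <- backward_window(cand_onset, params,
                                    "asymptomatic_member")
            add <- c(add, sort(setdiff(
              setdiff(contact_query(orc, node, window = awin), seen), add)))
          }
          if (length(add)) {
            seen <- c(seen, add)
            for (u in add) submit_test(orc, u)
            n_pending <- n_pending + length(add)
          }
        }
      }
      if (cut || !completed) break
    }
    if (cut) {
      # discard what is still queued or pending from this iteration
      orc$queue <- integer(0)
      orc$collected[] <- TRUE
    }
    if (!completed) break
    if (sc_prime == cand) break
    cand <- sc_prime
    cand_onset <- sc_onset
    history <- c(history, cand)
  }

  led <- oracle_ledger(orc)
  structure(list(
    algorithm = variant,
    estimate = cand,
    candidate_history = history,
    found_source = NA,
    found_first_symptomatic = NA,
    completed = completed,
    tests_used = led$tests_submitted,
    edges_revealed = led$edges_revealed,
    household_queries = led$household_queries,
    days_elapsed = led$days_elapsed
  ), class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("%s estimate: node %d (candidate chain: %s)\n", x$algorithm,
              x$estimate, paste(x$candidate_history, collapse = " -> ")))
  if (!is.na(x$found_source))
    cat(sprintf("  found source: %s; found first symptomatic: %s\n",
                x$found_source, x$found_first_symptomatic))
  cat(sprintf("  %d tests, %d edges revealed, %d household queries, %g days\n",
              x$tests_used, x$edges_revealed, x$household_queries,
              x$days_elapsed))
  invisible(x)
}

#' Score an identification result against ground truth
#'
#' Fills the `found_source` and `found_first_symptomatic` flags by
#' comparing the estimate with the trace's source and its first symptomatic
#' node. Only evaluation code calls this; the algorithms themselves never
#' see the trace.
#'
#' @param result An `identification_result`.
#' @param trace The ground-truth `epidemic_trace`.
#' @return The result with flags filled.
#' @export
score_result <- function(result, trace) {
  result$found_source <- result$estimate == trace$source
  fs <- first_symptomatic(trace)
  result$found_first_symptomatic <- !is.na(fs) && result$estimate == fs
  result
}
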