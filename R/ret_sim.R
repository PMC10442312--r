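# Monte-Carlo simulators for the (d_r, d)-ary random exponential tree.
# Only the level profile matters for the theory, so the simulators track
# per-level node and open-slot counts instead of explicit trees; slot
# exchangeability makes this exact, and it vectorizes across replicates.

#' Simulate random exponential tree profiles
#'
#' Grows `n_rep` independent `(d_r, d)`-ary random exponential trees for
#' `t_max` days: each open child slot fills independently with probability
#' `p_i` per day. Arity counts children: the root has `d_r` child slots
#' and every other node `d` (matching the binary case's two children per
#' node). Returns the
#' per-day mean level profile with standard errors, for comparison with
#' [ret_expected_profile()].
#'
#' @param n_rep Number of replicate trees.
#' @param t_max Number of growth days.
#' @param d_r Root capacity.
#' @param d Arity parameter (child slots per non-root node). Fractional
#'   values are realized by giving each new node `floor(d)` child slots
#'   plus one more with probability `d - floor(d)`; by linearity the
#'   expected profile equals the analytic one at the fractional `d`
#'   exactly.
#' @param p_i Per-day slot-fill probability.
#' @param seed Optional integer seed.
#' @return A list with matrices `mean` and `se` (rows day `t = 1..t_max`,
#'   columns level `l = 0..t_max`), and the realized slot parameters.
#' @export
simulate_ret <- function(n_rep, t_max, d_r, d, p_i, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- as.integer(floor(d))       # child slots per non-root node
  frac <- d - floor(d)
  d_r <- as.integer(round(d_r))
  L <- t_max + 2L
  n <- matrix(0, n_rep, L); n[, 1L] <- 1
  o <- matrix(0, n_rep, L); o[, 1L] <- d_r
  mean_mat <- matrix(0, t_max, t_max + 1L)
  se_mat <- matrix(0, t_max, t_max + 1L)
  for (t in seq_len(t_max)) {
    o_snap <- o
    for (l in seq_len(min(t, t_max))) {
      k <- stats::rbinom(n_rep, o_snap[, l], p_i)
      n[, l + 1L] <- n[, l + 1L] + k
      o[, l + 1L] <- o[, l + 1L] + k * base + stats::rbinom(n_rep, k, frac)
      o[, l] <- o[, l] - k
    }
    cols <- seq_len(t_max + 1L)
    mean_mat[t, ] <- colMeans(n[, cols, drop = FALSE])
    se_mat[t, ] <- apply(n[, cols, drop = FALSE], 2, stats::sd) / sqrt(n_rep)
  }
  list(mean = mean_mat, se = se_mat, d = d, d_r = d_r, n_rep = n_rep)
}

#' Simulate stopped random exponential trees
#'
#' Grows `(d_r, d)`-ary random exponential trees day by day; nodes added
#' within a day are ordered by a uniform random permutation and each is
#' hospitalized with probability `(1 - p_a) p_h` (the root draws at day 0).
#' Growth stops at the first hospitalization; the returned quantity is the
#' level of the hospitalized node, i.e. the transmission-path length.
#'
#' `simulate_ret_stopped_many` is the vectorized batch version used by the
#' Monte-Carlo comparisons; by exchangeability of the within-day
#' permutation, the stopping level is drawn proportionally to that day's
#' per-level additions, which is how the batch simulator realizes it.
#'
#' @param n_rep Number of replicates.
#' @param d_r,d,p_i Tree growth parameters (fractional `d` realized by
#'   randomized slot counts with mean `d`, as in [simulate_ret()]).
#' @param p_a,p_h Course probabilities; the per-node hospitalization
#'   probability is `(1 - p_a) p_h`.
#' @param seed Optional integer seed.
#' @param t_max Day guard; replicates not stopped by then are discarded.
#' @return `simulate_ret_stopped_many`: integer vector of path lengths with
#'   `NA` for discarded replicates. `simulate_ret_stopped`: a list with
#'   `path_length` and the realized per-day level `profile` of one tree.
#' @export
simulate_ret_stopped_many <- function(n_rep, d_r, d, p_i, p_a, p_h,
                                      seed = NULL, t_max = 100) {
  if (!is.null(seed)) set.seed(seed)
  q <- 1 - (1 - p_a) * p_h
  base <- as.integer(floor(d))
  frac <- d - floor(d)
  d_r <- as.integer(round(d_r))
  out <- rep(NA_integer_, n_rep)
  # day-0 root draw
  out[stats::runif(n_rep) >= q] <- 0L
  active <- which(is.na(out))
  L <- t_max + 2L
  n_act <- length(active)
  o <- matrix(0, n_act, L); o[, 1L] <- d_r
  lvl_new <- matrix(0, n_act, L)
  t <- 0L
  while (length(active) && t < t_max) {
    t <- t + 1L
    rows <- seq_along(active)
    lvl_new[rows, ] <- 0
    o_snap <- o[rows, , drop = FALSE]
    for (l in seq_len(min(t, t_max))) {
      k <- stats::rbinom(length(rows), o_snap[, l], p_i)
      lvl_new[rows, l + 1L] <- k
      o[rows, l + 1L] <- o[rows, l + 1L] + k * base +
        stats::rbinom(length(rows), k, frac)
      o[rows, l] <- o[rows, l] - k
    }
    K <- rowSums(lvl_new[rows, , drop = FALSE])
    p_stop <- 1 - exp(K * log(q))
    hit <- which(stats::runif(length(rows)) < p_stop)
    for (i in hit) {
      w <- lvl_new[i, ]
      out[active[i]] <- sample.int(L, 1L, prob = w) - 1L
    }
    if (length(hit)) {
      keep <- setdiff(seq_along(active), hit)
      active <- active[keep]
      o <- o[keep, , drop = FALSE]
      lvl_new <- lvl_new[keep, , drop = FALSE]
    }
  }
  structure(out, n_discarded = sum(is.na(out)))
}

#' @rdname simulate_ret_stopped_many
#' @export
simulate_ret_stopped <- function(d_r, d, p_i, p_a, p_h, seed = NULL,
                                 t_max = 100) {
  if (!is.null(seed)) set.seed(seed)
  q <- 1 - (1 - p_a) * p_h
  base <- as.integer(floor(d))
  frac <- d - floor(d)
  d_r <- as.integer(round(d_r))
  L <- t_max + 2L
  n <- numeric(L); n[1L] <- 1
  o <- numeric(L); o[1L] <- d_r
  profile <- matrix(n[seq_len(t_max + 1L)], nrow = 1L)
  if (stats::runif(1) >= q)
    return(list(path_length = 0L, profile = profile))
  for (t in seq_len(t_max)) {
    o_snap <- o
    new_l <- numeric(L)
    for (l in seq_len(t)) {
      k <- stats::rbinom(1L, o_snap[l], p_i)
      new_l[l + 1L] <- k
      o[l + 1L] <- o[l + 1L] + k * base + stats::rbinom(1L, k, frac)
      o[l] <- o[l] - k
    }
    n <- n + new_l
    profile <- rbind(profile, n[seq_len(t_max + 1L)])
    K <- sum(new_l)
    if (stats::runif(1) < 1 - exp(K * log(q))) {
      lvl <- sample.int(L, 1L, prob = new_l) - 1L
      return(list(path_length = lvl, profile = profile))
    }
  }
  list(path_length = NA_integer_, profile = profile)
}
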