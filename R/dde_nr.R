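# The no-presymptomatic / no-recovery epidemic on the (infinite) RB tree.
#
# The tree is never materialized in full: infected nodes are created when
# the infection reaches them, and susceptible nodes only when a query
# reveals them. Each node keeps counters of its not-yet-realized red/blue
# child slots, so a day of growth is a pair of binomial draws per
# infectious node plus Bernoulli draws for explicitly realized susceptible
# children. The structure is a mutable environment because identification
# algorithms advance it day by day through the oracle.

new_dde_nr_sim <- function(d_c, d_h, params, seed = NULL) {
  stopifnot(inherits(params, "epidemic_params"), d_c >= 1, d_h >= 0)
  if (!is.null(seed)) set.seed(seed)
  # presymptomatic and recovered states removed: onset at infection + T_E
  p_nr <- params
  p_nr$T_P <- 0
  p_nr$T_I <- Inf
  sim <- new.env(parent = emptyenv())
  sim$d_c <- as.integer(d_c); sim$d_h <- as.integer(d_h)
  sim$params <- p_nr
  sim$model <- "dde_nr"
  cap <- 512L
  sim$cap <- cap
  sim$n <- 1L
  sim$day <- 0
  sim$parent <- rep(NA_integer_, cap)
  sim$infector <- rep(NA_integer_, cap)
  sim$color <- rep(NA_integer_, cap)        # 1 red, 2 blue
  sim$level <- rep(NA_integer_, cap)
  sim$house_head <- rep(NA_integer_, cap)
  sim$infection_time <- rep(NA_real_, cap)
  sim$is_asymptomatic <- rep(NA, cap)
  sim$is_hospitalized_course <- rep(NA, cap)
  sim$onset_time <- rep(NA_real_, cap)
  sim$hospitalization_time <- rep(NA_real_, cap)
  sim$urs <- integer(cap)                   # unrealized red child slots
  sim$ubs <- integer(cap)                   # unrealized blue child slots
  sim$children <- vector("list", cap)
  sim$sus <- integer(0)                     # realized susceptible nodes
  sim$first_hospitalized <- NULL
  # root: red, level 0, infected on day 0; root exception: d_c red slots
  sim$color[1L] <- 1L; sim$level[1L] <- 0L; sim$house_head[1L] <- 1L
  sim$urs[1L] <- sim$d_c; sim$ubs[1L] <- sim$d_h
  sim$source <- 1L
  set_infected(sim, 1L, t = 0)
  if (isTRUE(sim$is_hospitalized_course[1L]) &&
      sim$hospitalization_time[1L] == 0)
    sim$first_hospitalized <- list(node = 1L, day = 0)
  class(sim) <- c("dde_nr_sim", "epidemic_trace")
  sim
}

grow_cap <- function(sim, need) {
  while (sim$cap < need) {
    add <- sim$cap
    sim$parent <- c(sim$parent, rep(NA_integer_, add))
    sim$infector <- c(sim$infector, rep(NA_integer_, add))
    sim$color <- c(sim$color, rep(NA_integer_, add))
    sim$level <- c(sim$level, rep(NA_integer_, add))
    sim$house_head <- c(sim$house_head, rep(NA_integer_, add))
    sim$infection_time <- c(sim$infection_time, rep(NA_real_, add))
    sim$is_asymptomatic <- c(sim$is_asymptomatic, rep(NA, add))
    sim$is_hospitalized_course <- c(sim$is_hospitalized_course, rep(NA, add))
    sim$onset_time <- c(sim$onset_time, rep(NA_real_, add))
    sim$hospitalization_time <- c(sim$hospitalization_time, rep(NA_real_, add))
    sim$urs <- c(sim$urs, integer(add))
    sim$ubs <- c(sim$ubs, integer(add))
    sim$children <- c(sim$children, vector("list", add))
    sim$cap <- sim$cap + add
  }
}

# draw the disease course of nodes infected on day t and fix their slots
set_infected <- function(sim, ids, t) {
  p <- sim$params
  k <- length(ids)
  a <- stats::runif(k) < p$p_a
  h <- !a & stats::runif(k) < p$p_h
  sim$infection_time[ids] <- t
  sim$is_asymptomatic[ids] <- a
  sim$is_hospitalized_course[ids] <- h
  sim$onset_time[ids] <- ifelse(a, NA_real_, t + p$T_E)
  sim$hospitalization_time[ids] <- ifelse(h, t + p$T_E + p$T_H, NA_real_)
  invisible(sim)
}

# create child nodes (infected at day t, or susceptible when t is NA)
add_children <- function(sim, par, col, t = NA) {
  k <- length(par)
  if (k == 0L) return(integer(0))
  grow_cap(sim, sim$n + k)
  ids <- sim$n + seq_len(k)
  sim$n <- sim$n + k
  sim$parent[ids] <- par
  sim$color[ids] <- col
  sim$level[ids] <- sim$level[par] + 1L
  sim$house_head[ids] <- ifelse(col == 1L, ids, par)
  sim$urs[ids] <- ifelse(col == 1L, sim$d_c - 1L, sim$d_c)
  sim$ubs[ids] <- ifelse(col == 1L, sim$d_h, 0L)
  for (i in seq_len(k)) {
    v <- par[i]
    sim$children[[v]] <- c(sim$children[[v]], ids[i])
  }
  if (!is.na(t)) {
    sim$infector[ids] <- par
    set_infected(sim, ids, t)
  }
  ids
}

# realize all not-yet-created children of v as susceptible nodes
realize_children <- function(sim, v) {
  nr <- sim$urs[v]; nb <- sim$ubs[v]
  if (nr + nb > 0L) {
    new <- add_children(sim, rep(v, nr + nb), rep(c(1L, 2L), c(nr, nb)))
    sim$urs[v] <- 0L; sim$ubs[v] <- 0L
    sim$sus <- c(sim$sus, new)
  }
  sim$children[[v]]
}

# advance the tree epidemic by one day
step_tree <- function(sim) {
  t <- sim$day + 1
  sim$day <- t
  n <- sim$n
  p <- sim$params
  it <- sim$infection_time[seq_len(n)]
  ht <- sim$hospitalization_time[seq_len(n)]
  infectious <- !is.na(it) & it + p$T_E <= t & (is.na(ht) | ht > t)
  idx <- which(infectious & (sim$urs[seq_len(n)] > 0L |
                               sim$ubs[seq_len(n)] > 0L))
  if (length(idx)) {
    nr <- stats::rbinom(length(idx), sim$urs[idx], p$p_i)
    nb <- stats::rbinom(length(idx), sim$ubs[idx], p$p_i)
    sim$urs[idx] <- sim$urs[idx] - nr
    sim$ubs[idx] <- sim$ubs[idx] - nb
    par <- c(rep(idx, nr), rep(idx, nb))
    col <- rep(c(1L, 2L), c(sum(nr), sum(nb)))
    add_children(sim, par, col, t = t)
  }
  if (length(sim$sus)) {
    cand <- sim$sus[infectious[sim$parent[sim$sus]]]
    if (length(cand)) {
      hit <- cand[stats::runif(length(cand)) < p$p_i]
      if (length(hit)) {
        sim$infector[hit] <- sim$parent[hit]
        set_infected(sim, hit, t)
        sim$sus <- setdiff(sim$sus, hit)
      }
    }
  }
  if (is.null(sim$first_hospitalized)) {
    nh <- which(!is.na(sim$hospitalization_time[seq_len(sim$n)]) &
                  sim$hospitalization_time[seq_len(sim$n)] == t)
    if (length(nh))
      sim$first_hospitalized <- list(node = min(nh), day = t)
  }
  invisible(sim)
}

#' Simulate the no-recovery epidemic on the RB tree
#'
#' Runs the discrete-day epidemic without presymptomatic and recovered
#' states (symptom onset coincides with becoming infectious; `T_I` is
#' infinite) on the red-blue tree rooted at the source, growing the tree
#' lazily, until the first hospitalization occurs. The returned object is a
#' live simulation: the oracle can keep advancing it day by day while an
#' identification algorithm runs.
#'
#' @param tree An [build_rb_tree()] object, or any list with elements `d_c`
#'   and `d_h`; only the branching parameters are used, since the infected
#'   portion of the (infinite) tree is realized on demand.
#' @param params An [epidemic_params()] object (`T_P` and `T_I` are
#'   overridden to 0 and `Inf`).
#' @param seed Optional integer seed.
#' @param t_max Day guard: the run is abandoned if no hospitalization has
#'   occurred by this day.
#' @param max_nodes Node guard against runaway growth.
#' @return An object of classes `dde_nr_sim` and `epidemic_trace` (an
#'   environment). `first_hospitalized` is `NULL` when the guards tripped
#'   first; the caller decides whether to discard the run.
#' @examples
#' sim <- simulate_dde_nr(list(d_c = 3, d_h = 2), dde_default_params(),
#'                        seed = 1)
#' @export
simulate_dde_nr <- function(tree, params, seed = NULL, t_max = 300,
                            max_nodes = 2e5) {
  sim <- new_dde_nr_sim(tree$d_c, tree$d_h, params, seed = seed)
  while (is.null(sim$first_hospitalized) && sim$day < t_max &&
         sim$n < max_nodes) {
    step_tree(sim)
  }
  sim
}

#' @export
print.dde_nr_sim <- function(x, ...) {
  n_inf <- sum(!is.na(x$infection_time[seq_len(x$n)]))
  cat(sprintf("Tree epidemic (no recovery): day %g, %d infected, %d realized nodes\n",
              x$day, n_inf, x$n))
  if (!is.null(x$first_hospitalized))
    cat(sprintf("  first hospitalization: node %d on day %g\n",
                x$first_hospitalized$node, x$first_hospitalized$day))
  invisible(x)
}

# household of a node in the lazy tree (realizes the household if needed)
tree_household_of <- function(sim, v) {
  head <- sim$house_head[v]
  if (sim$ubs[head] > 0L) {
    # realize only the blue (household) slots of the head
    nb <- sim$ubs[head]
    new <- add_children(sim, rep(head, nb), rep(2L, nb))
    sim$ubs[head] <- 0L
    sim$sus <- c(sim$sus, new)
  }
  kids <- sim$children[[head]]
  c(head, kids[sim$color[kids] == 2L])
}

# all neighbors of a node in the lazy tree (realizes children)
tree_neighbors_of <- function(sim, v) {
  kids <- realize_children(sim, v)
  p <- sim$parent[v]
  if (is.na(p)) kids else c(p, kids)
}
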