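# Closed-form source-identification theory on the red-blue tree and its
# exponential-tree approximations.

#' Conditional asymptomatic probability
#'
#' Probability that a node is asymptomatic given that it is not
#' hospitalized: `p_a / (p_a + (1 - p_a)(1 - p_h))`. Nodes on the
#' transmission path other than the first hospitalized one are implicitly
#' conditioned on not being the detected hospitalization, which is why this
#' conditional (not the raw `p_a`) drives the success formulas.
#'
#' @param p_a Asymptomatic probability.
#' @param p_h Hospitalization probability (symptomatic courses).
#' @return A probability.
#' @examples
#' p_asym_given_not_hosp(0.4, 0.083)
#' @export
p_asym_given_not_hosp <- function(p_a, p_h) {
  stopifnot(p_a >= 0, p_a <= 1, p_h >= 0, p_h <= 1)
  denom <- p_a + (1 - p_a) * (1 - p_h)
  if (denom == 0)
    stop("p_a = 0 with p_h = 1 leaves no non-hospitalized nodes to ",
         "condition on")
  p_a / denom
}

#' Path-length distribution container
#'
#' Probability mass over the transmission-path length `n = 0, ..., n_max`,
#' with the truncation deficit `1 - sum(mass)` reported explicitly.
#'
#' @param mass Nonnegative vector, `mass[i]` the probability of length
#'   `i - 1`; must sum to at most 1 (small numerical overshoot tolerated).
#' @return An object of class `path_length_distribution`.
#' @export
path_length_distribution <- function(mass) {
  stopifnot(is.numeric(mass), all(mass >= -1e-12), sum(mass) <= 1 + 1e-9)
  mass <- pmax(mass, 0)
  structure(list(mass = mass, n_max = length(mass) - 1L,
                 truncation_deficit = max(0, 1 - sum(mass))),
            class = "path_length_distribution")
}

#' @export
print.path_length_distribution <- function(x, ...) {
  cat(sprintf("Path-length distribution over 0..%d (deficit %.2e)\n",
              x$n_max, x$truncation_deficit))
  print(round(stats::setNames(x$mass, 0:x$n_max), 4))
  invisible(x)
}

#' Source-identification probability of LS
#'
#' Given the distribution of the transmission-path length `n`, LS finds the
#' source exactly when every path node is symptomatic, which happens with
#' probability `(1 - p)^n`; the success probability is the mixture
#' `sum_n (1 - p)^n P(d(s, h) = n)`, truncated at the distribution's
#' support.
#'
#' @param dist A [path_length_distribution()].
#' @param p Conditional asymptomatic probability, from
#'   [p_asym_given_not_hosp()].
#' @return A probability.
#' @export
ls_success_probability <- function(dist, p) {
  stopifnot(inherits(dist, "path_length_distribution"), p >= 0, p <= 1)
  n <- seq_along(dist$mass) - 1
  sum((1 - p)^n * dist$mass)
}

#' Admissible path-type counts for the LS+ bound
#'
#' For a transmission path of length `n`, `k` counts the path nodes that do
#' not share a household with another path node, and the indicators `alpha`
#' and `beta` record whether the source and the terminal node share their
#' household with another path node. Admissible `k` have parity different
#' from `n` and satisfy `2 - (alpha + beta) <= k <= n + 1 - 2 (alpha + beta)`.
#'
#' @param n Path length, at least 2.
#' @param alpha,beta Indicators in `{0, 1}`.
#' @return Integer vector (possibly empty).
#' @examples
#' valid_k_set(2, 0, 0)  # 3
#' valid_k_set(2, 1, 1)  # empty
#' @export
valid_k_set <- function(n, alpha, beta) {
  stopifnot(n >= 2, alpha %in% c(0, 1), beta %in% c(0, 1))
  lo <- 2 - (alpha + beta)
  hi <- n + 1 - 2 * (alpha + beta)
  if (hi < lo) return(integer(0))
  k <- lo:hi
  k[(k %% 2) != (n %% 2)]
}

# spectral description of the RB level counts: level n (>= 1) has
# lambda1 * rho1^n + lambda2 * rho2^n nodes
rb_spectral <- function(d_c, d_h) {
  if (d_h == 0) {
    # blue type vacuous: levels are d_c (d_c - 1)^(n-1)
    return(list(D = d_c - 1, rho1 = d_c - 1, rho2 = 0,
                lambda1 = d_c / (d_c - 1), lambda2 = 0))
  }
  D <- sqrt((d_c - 1)^2 + 4 * d_c * d_h)
  rho1 <- (d_c - 1 + D) / 2
  rho2 <- (d_c - 1 - D) / 2
  lambda1 <- (d_c + 1 + D) * (2 * d_h + d_c - 1 + D) / (2 * D * (d_c - 1 + D))
  lambda2 <- (D - d_c - 1) * (2 * d_h + d_c - 1 - D) / (2 * D * (d_c - 1 - D))
  list(D = D, rho1 = rho1, rho2 = rho2, lambda1 = lambda1, lambda2 = lambda2)
}

#' Spectral RB-tree level count
#'
#' Closed-form number of RB-tree nodes at level `n >= 1`,
#' `lambda1 rho1^n + lambda2 rho2^n` with
#' `rho_{1,2} = (d_c - 1 +/- D) / 2`, `D = sqrt((d_c - 1)^2 + 4 d_c d_h)`;
#' agrees with the exact recurrence of [rb_level_count()].
#'
#' @param d_c,d_h RB branching parameters.
#' @param n Level, at least 1.
#' @return A (real) node count.
#' @export
rb_level_count_spectral <- function(d_c, d_h, n) {
  stopifnot(n >= 1)
  s <- rb_spectral(d_c, d_h)
  s$lambda1 * s$rho1^n + s$lambda2 * s$rho2^n
}

#' Lower bound on the source-identification probability of LS+
#'
#' LS+ survives asymptomatic path nodes as long as each traversed household
#' contains a symptomatic path node and the source itself is symptomatic.
#' Counting the paths of length `n` by their household embedding (see
#' [valid_k_set()]) yields the bound
#' `P(0) + (1 - p) P(1) + sum_{n >= 2} sum_{alpha, beta, k}
#' C((n + k - 3)/2, k - 2 + alpha + beta) (1 - p)^{(n + k - 1)/2}
#' d_h^{(n - k + 1)/2}
#' (d_c (1 + p))^{(n - k + 1)/2 - alpha - beta} d_c (d_c - 1)^{k + alpha +
#' beta - 2} / level_count(n) * P(n)`:
#' a path with `k` singleton-household nodes traverses `(n + 1 - k)/2`
#' two-node households (each contributing a `d_h` choice and, when
#' interior, an at-least-one-symptomatic factor `(1 - p)(1 + p)`), while
#' the source and the other singleton path nodes apart from the
#' hospitalized endpoint must each be symptomatic, giving the
#' `(1 - p)^{(n + k - 1)/2}` factor. Summed over path types the count
#' factors reproduce the RB level count exactly.
#'
#' @param dist A [path_length_distribution()].
#' @param p Conditional asymptomatic probability.
#' @param d_c,d_h RB branching parameters (`d_c >= 2`; `d_c = 1` falls back
#'   to the LS value, the household chain being degenerate).
#' @return A probability lower bound.
#' @export
ls_plus_success_lower_bound <- function(dist, p, d_c, d_h) {
  stopifnot(inherits(dist, "path_length_distribution"), p >= 0, p <= 1,
            d_c >= 1, d_h >= 0)
  if (d_c < 2) return(ls_success_probability(dist, p))
  mass <- dist$mass
  n_max <- dist$n_max
  total <- mass[1]
  if (n_max >= 1) total <- total + (1 - p) * mass[2]
  if (n_max >= 2) {
    for (n in 2:n_max) {
      if (mass[n + 1] == 0) next
      denom <- rb_level_count_spectral(d_c, d_h, n)
      acc <- 0
      for (alpha in 0:1) for (beta in 0:1) {
        for (k in valid_k_set(n, alpha, beta)) {
          ch <- choose((n + k - 3) / 2, k - 2 + alpha + beta)
          if (ch == 0) next
          acc <- acc + ch *
            (1 - p)^((n + k - 1) / 2) *
            d_h^((n - k + 1) / 2) *
            (d_c * (1 + p))^((n - k + 1) / 2 - alpha - beta) *
            d_c * (d_c - 1)^(k + alpha + beta - 2)
        }
      }
      total <- total + acc / denom * mass[n + 1]
    }
  }
  min(total, 1)
}

#' Expected level profile of the random exponential tree
#'
#' In the `(d_r, d)`-ary random exponential tree each open child slot fills
#' independently with probability `p_i` per day (root capacity `d_r`, other
#' nodes `d - 1` child slots). The expected number of nodes at level `l` on
#' day `t` is `a(t, 0) = 1`,
#' `a(t, l) = d_r p_i (d p_i)^{l-1} sum_{m=l-1}^{t-1} C(m, l-1)
#' (1 - p_i)^{m-l+1}` for `t >= l >= 1`, and 0 for `l > t`.
#'
#' @param t Day, nonnegative.
#' @param l Level, nonnegative.
#' @param d_r Root capacity.
#' @param d Uniform degree parameter (may be fractional in the analytic
#'   formulas).
#' @param p_i Per-day slot-fill probability.
#' @return The expectation `a(t, l)`.
#' @export
ret_expected_profile <- function(t, l, d_r, d, p_i) {
  stopifnot(t >= 0, l >= 0)
  if (l == 0) return(1)
  if (l > t) return(0)
  m <- (l - 1):(t - 1)
  d_r * p_i * (d * p_i)^(l - 1) *
    sum(choose(m, l - 1) * (1 - p_i)^(m - l + 1))
}

#' Expected size of the random exponential tree
#'
#' `a(t) = 1 + d_r ((1 - p_i + d p_i)^t - 1) / (d - 1)`; consistent with
#' summing [ret_expected_profile()] over levels.
#'
#' @inheritParams ret_expected_profile
#' @return The expected node count on day `t`.
#' @export
ret_expected_size <- function(t, d_r, d, p_i) {
  stopifnot(t >= 0)
  if (d <= 1)
    stop("d must exceed 1; the degenerate d = 1 chain is not covered")
  1 + d_r * ((1 - p_i + d * p_i)^t - 1) / (d - 1)
}

# expected-profile matrix: rows t = 0..t_max, cols l = 0..l_max
ret_profile_matrix <- function(t_max, l_max, d_r, d, p_i) {
  out <- matrix(0, nrow = t_max + 1, ncol = l_max + 1)
  for (t in 0:t_max) for (l in 0:min(t, l_max))
    out[t + 1, l + 1] <- ret_expected_profile(t, l, d_r, d, p_i)
  out
}

#' Transmission-path length on a stopped deterministic exponential tree
#'
#' A deterministic exponential tree has exactly `c(t, l)` nodes at level
#' `l` on day `t` (fractional profiles are accepted as approximations of
#' expected profiles). Nodes added on a day are ordered uniformly at
#' random, each is hospitalized with probability `(1 - p_a) p_h`, and
#' growth stops at the first hospitalization. The level of the first
#' hospitalized node then has mass
#' `P(l) = sum_t ((c(t,l) - c(t-1,l)) / (c_t - c_{t-1})) q^{c_{t-1}}
#' (1 - q^{c_t - c_{t-1}})` with `q = 1 - (1 - p_a) p_h` (and the
#' convention `0^0 = 1` when `q = 0`).
#'
#' @param c_profile Matrix of level counts, rows `t = 0, ..., t_max`,
#'   columns `l = 0, ..., l_max`; must have `c[0, 0] = 1` as its only
#'   day-0 entry, be nondecreasing in `t` within each level, and grow by at
#'   least one node per day.
#' @param p_a,p_h Course probabilities.
#' @return A [path_length_distribution()].
#' @export
det_stopped_path_dist <- function(c_profile, p_a, p_h) {
  c_profile <- as.matrix(c_profile)
  if (abs(c_profile[1, 1] - 1) > 1e-9 || any(c_profile[1, -1] != 0))
    stop("the profile must start from a single root: c(0, 0) = 1")
  if (any(diff(c_profile) < -1e-9))
    stop("level counts may not shrink over time")
  ct <- rowSums(c_profile)
  if (any(diff(ct) <= 0))
    stop("the tree must grow by at least one node each day")
  q <- 1 - (1 - p_a) * p_h
  t_max <- nrow(c_profile) - 1
  l_max <- ncol(c_profile) - 1
  pow0 <- function(b, e) ifelse(b == 0 & e == 0, 1, b^e)  # 0^0 = 1
  mass <- numeric(l_max + 1)
  ct_prev <- c(0, ct[-length(ct)])
  inc_t <- ct - ct_prev
  stop_here <- pow0(q, ct_prev) * (1 - pow0(q, inc_t))
  for (l in 0:l_max) {
    cl <- c_profile[, l + 1]
    inc_l <- cl - c(0, cl[-length(cl)])
    mass[l + 1] <- sum(inc_l / inc_t * stop_here)
  }
  path_length_distribution(mass)
}

#' Transmission-path length on the stopped random exponential tree
#'
#' Substitutes the expected `(d_r, d)`-RET profile of
#' [ret_expected_profile()] into the stopped deterministic-tree law of
#' [det_stopped_path_dist()], giving the analytic approximation of the
#' distribution of the first hospitalized node's depth:
#' `P(l) = sum_{t >= l} (d p_i)^{l-1} C(t-1, l-1) (1-p_i)^{t-l} /
#' (1 - p_i + d p_i)^{t-1} q^{a_{t-1}} (1 - q^{d_r p_i (1-p_i+d p_i)^{t-1}})`
#' for `l >= 1`, and `P(0) = 1 - q`.
#'
#' @param params A list or [theory_params()] with `d_r`, `d`, `p_i`
#'   (effective), `p_a`, `p_h`, `n_max`, `t_max`.
#' @return A [path_length_distribution()] over `0, ..., n_max`.
#' @export
ret_stopped_path_dist <- function(params) {
  d_r <- params$d_r; d <- params$d; p_i <- params$p_i_eff %||% params$p_i
  p_a <- params$p_a; p_h <- params$p_h
  n_max <- params$n_max %||% 20L
  t_max <- params$t_max %||% 200L
  q <- 1 - (1 - p_a) * p_h
  g <- 1 - p_i + d * p_i
  mass <- numeric(n_max + 1)
  mass[1] <- 1 - q                       # the root's own draw, day 0
  a_prev <- function(t) 1 + d_r * (g^(t - 1) - 1) / (d - 1)  # a_{t-1}
  for (l in 1:n_max) {
    t <- l:t_max
    terms <- (d * p_i)^(l - 1) * choose(t - 1, l - 1) * (1 - p_i)^(t - l) /
      g^(t - 1) * q^a_prev(t) * (1 - q^(d_r * p_i * g^(t - 1)))
    mass[l + 1] <- sum(terms)
  }
  path_length_distribution(mass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective parameters of the exponential-tree approximation
#'
#' Rescales time so that one unit equals the exposed period: the effective
#' per-contact infection probability is `1 - (1 - p_i)^{T_E}` (infection in
#' at least one of `T_E` days). The root keeps the RB root degree
#' `d_r = d_c + d_h`, and the uniform degree `d` is the average RB-tree
#' degree: with the stationary red fraction `f_r = rho1 / (rho1 + d_h)`
#' from the leading eigenvector of the red/blue branching matrix,
#' `d = f_r (d_c + d_h) + (1 - f_r)(d_c + 1)`.
#'
#' @param p_i Per-day infection probability.
#' @param T_E Exposed duration in days.
#' @param d_c,d_h RB branching parameters.
#' @return A list with `p_i_eff`, `d_r`, `d` and the red fraction `f_r`.
#' @examples
#' effective_params(0.1, 3, 3, 2)  # p_i_eff = 0.271, d_r = 5, d = 4.646
#' @export
effective_params <- function(p_i, T_E, d_c, d_h) {
  s <- rb_spectral(d_c, d_h)
  f_r <- s$rho1 / (s$rho1 + d_h)
  list(p_i_eff = 1 - (1 - p_i)^T_E,
       d_r = d_c + d_h,
       d = f_r * (d_c + d_h) + (1 - f_r) * (d_c + 1),
       f_r = f_r)
}

#' Theory parameter bundle
#'
#' Convenience constructor collecting everything the analytic pipeline
#' needs: the epidemic and branching parameters, their effective
#' (rescaled) versions, and the series truncations.
#'
#' @param p_i,p_a,p_h Epidemic probabilities (per day, unscaled).
#' @param T_E Exposed duration in days.
#' @param d_c,d_h RB branching parameters.
#' @param n_max Path-length truncation.
#' @param t_max Day-sum truncation.
#' @return A list of class `theory_params`.
#' @export
theory_params <- function(p_i = 0.1, p_a = 0.4, p_h = 0.083, T_E = 3,
                          d_c = 3, d_h = 2, n_max = 20L, t_max = 200L) {
  eff <- effective_params(p_i, T_E, d_c, d_h)
  structure(list(p_i = p_i, p_a = p_a, p_h = p_h, T_E = T_E,
                 d_c = d_c, d_h = d_h,
                 p = p_asym_given_not_hosp(p_a, p_h),
                 p_i_eff = eff$p_i_eff, d_r = eff$d_r, d = eff$d,
                 n_max = n_max, t_max = t_max),
            class = "theory_params")
}

#' Analytic source-identification probability
#'
#' Composes the pipeline: effective exponential-tree parameters, the
#' stopped-tree path-length distribution, and the LS mixture (exact on its
#' model) or the LS+ household-counting lower bound.
#'
#' @param kind `"LS"` or `"LS+"`.
#' @param params An [epidemic_params()] (or anything with `p_i`, `p_a`,
#'   `p_h`, `T_E`).
#' @param d_c,d_h RB branching parameters.
#' @param n_max Path-length truncation.
#' @param t_max Day-sum truncation.
#' @return A probability (for `"LS+"`, a lower bound).
#' @export
predict_success <- function(kind = c("LS", "LS+"), params = dde_default_params(),
                            d_c = 3, d_h = 2, n_max = 20L, t_max = 200L) {
  kind <- match.arg(kind)
  tp <- theory_params(p_i = params$p_i, p_a = params$p_a, p_h = params$p_h,
                      T_E = params$T_E, d_c = d_c, d_h = d_h,
                      n_max = n_max, t_max = t_max)
  dist <- ret_stopped_path_dist(tp)
  if (kind == "LS") ls_success_probability(dist, tp$p)
  else ls_plus_success_lower_bound(dist, tp$p, d_c, d_h)
}
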