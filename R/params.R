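#' Epidemic parameters for the discrete-day epidemic model
#'
#' Bundles the parameters of the deterministically developing epidemic (DDE):
#' a per-day, per-edge infection probability and deterministic state
#' durations, with disease-course randomness entering only through the
#' asymptomatic and hospitalization probabilities.
#'
#' @param p_i Per-day probability that an infectious node infects a given
#'   susceptible neighbor.
#' @param p_a Probability that an infected node follows the asymptomatic
#'   course.
#' @param p_h Probability that a symptomatic node is eventually hospitalized.
#' @param T_E Exposed (latent) duration in days; a node infected on day t
#'   becomes infectious on day `t + T_E`.
#' @param T_P Presymptomatic duration in days (symptomatic courses only).
#' @param T_I Infectious duration in days for non-hospitalized courses;
#'   `Inf` disables recovery.
#' @param T_H Days from symptom onset to hospitalization, for hospitalized
#'   courses.
#' @param sigma_E,sigma_P Slack (in days) on the exposed and presymptomatic
#'   durations used when computing backward-contact windows; 0 for the DDE,
#'   where transitions are deterministic.
#'
#' @return An object of class `epidemic_params` (a validated list).
#' @examples
#' dde_default_params()
#' epidemic_params(p_i = 0.2, p_a = 0)
#' @export
epidemic_params <- function(p_i = 0.1, p_a = 0.4, p_h = 0.083,
                            T_E = 3, T_P = 2, T_I = 14, T_H = 7,
                            sigma_E = 0, sigma_P = 0) {
  for (p in list(p_i = p_i, p_a = p_a, p_h = p_h)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("probabilities p_i, p_a, p_h must be single values in [0, 1]")
  }
  for (d in list(T_E = T_E, T_P = T_P, T_H = T_H, sigma_E = sigma_E,
                 sigma_P = sigma_P)) {
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 ||
        (is.finite(d) && d != round(d)))
      stop("durations must be single nonnegative integer day counts")
  }
  if (!is.numeric(T_I) || length(T_I) != 1L || is.na(T_I) || T_I < 0 ||
      (is.finite(T_I) && T_I != round(T_I)))
    stop("T_I must be a nonnegative integer day count or Inf")
  if (is.finite(T_H) && T_P >= T_E + T_H)
    stop("parameters must satisfy T_P < T_E + T_H")
  structure(list(p_i = p_i, p_a = p_a, p_h = p_h,
                 T_E = as.numeric(T_E), T_P = as.numeric(T_P),
                 T_I = as.numeric(T_I), T_H = as.numeric(T_H),
                 sigma_E = as.numeric(sigma_E), sigma_P = as.numeric(sigma_P)),
            class = "epidemic_params")
}

#' Default DDE+HNM parameters
#'
#' The default parameter set of the discrete-day epidemic on the household
#' network: `p_i = 0.1`, `p_a = 0.4`, `p_h = 0.083`, durations
#' `T_E = 3`, `T_P = 2`, `T_I = 14`, `T_H = 7` (all in days).
#'
#' @param ... Overrides passed on to [epidemic_params()].
#' @return An `epidemic_params` object.
#' @export
dde_default_params <- function(...) {
  epidemic_params(...)
}

#' @export
print.epidemic_params <- function(x, ...) {
  cat("Epidemic parameters (discrete-day model)\n")
  cat(sprintf("  p_i = %g, p_a = %g, p_h = %g\n", x$p_i, x$p_a, x$p_h))
  cat(sprintf("  T_E = %g, T_P = %g, T_I = %g, T_H = %g days\n",
              x$T_E, x$T_P, x$T_I, x$T_H))
  if (x$sigma_E != 0 || x$sigma_P != 0)
    cat(sprintf("  window slack: sigma_E = %g, sigma_P = %g\n",
                x$sigma_E, x$sigma_P))
  invisible(x)
}

#' Daily test budget
#'
#' The framework caps the number of tests administered per day at 1% of the
#' total population, with a minimum of one test.
#'
#' @param N Population size.
#' @return `max(1, floor(0.01 * N))`.
#' @examples
#' test_budget(400)   # 4
#' test_budget(9054)  # 90
#' @export
test_budget <- function(N) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  max(1L, as.integer(floor(0.01 * N)))
}
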