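test_that("conditional asymptomatic probability matches a course-drawing oracle", {
  expect_equal(p_asym_given_not_hosp(0, 0.5), 0)
  expect_equal(p_asym_given_not_hosp(0.3, 0), 0.3)
  expect_error(p_asym_given_not_hosp(0, 1), "condition")
  # Monte-Carlo oracle: draw courses, estimate the conditional frequency
  set.seed(1)
  n <- 2e5
  asym <- runif(n) < 0.4
  hosp <- !asym & runif(n) < 0.083
  mc <- mean(asym[!hosp])
  se <- sqrt(mc * (1 - mc) / sum(!hosp))
  expect_lt(abs(p_asym_given_not_hosp(0.4, 0.083) - mc), 3 * se)
  expect_equal(p_asym_given_not_hosp(0.4, 0.083), 0.4210, tolerance = 1e-4)
})

test_that("the LS mixture collapses correctly on point masses", {
  m <- rep(0, 6); m[3] <- 1            # point mass at n = 2
  d <- path_length_distribution(m)
  expect_equal(ls_success_probability(d, 0.5), 0.25)
  d2 <- path_length_distribution(c(0.3, 0.3, 0.3))
  expect_equal(ls_success_probability(d2, 0), 0.9)
  expect_equal(d2$truncation_deficit, 0.1)
})

test_that("admissible k sets enumerate the stated inequalities", {
  expect_equal(valid_k_set(2, 0, 0), 3L)
  expect_equal(valid_k_set(2, 1, 0), 1L)
  expect_equal(valid_k_set(2, 0, 1), 1L)
  expect_length(valid_k_set(2, 1, 1), 0L)
  expect_equal(valid_k_set(5, 0, 0), c(2L, 4L, 6L))
  # independent enumeration oracle over a grid
  for (n in 2:8) for (a in 0:1) for (b in 0:1) {
    brute <- Filter(function(k) (k %% 2) != (n %% 2) &&
                      k >= 2 - (a + b) && k <= n + 1 - 2 * (a + b), 0:(n + 2))
    expect_equal(valid_k_set(n, a, b), as.integer(brute))
  }
})

test_that("the LS+ path-type counts resum to the RB level counts", {
  # at p = 0 the bound's coefficient is the path count over the level
  # count, which must be exactly 1 for every n and branching choice
  for (pars in list(c(3, 2), c(2, 1), c(4, 3))) {
    for (n in 2:8) {
      m <- rep(0, n + 1); m[n + 1] <- 1
      d <- path_length_distribution(m)
      expect_equal(ls_plus_success_lower_bound(d, 0, pars[1], pars[2]), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("LS+ bound point masses reproduce hand-derived values", {
  p <- p_asym_given_not_hosp(0.4, 0.083)
  m0 <- path_length_distribution(c(1))
  expect_equal(ls_plus_success_lower_bound(m0, p, 3, 2), 1)
  m1 <- path_length_distribution(c(0, 1))
  expect_equal(ls_plus_success_lower_bound(m1, p, 3, 2), 1 - p)
  # n = 2 on (d_c, d_h) = (3, 2): 6 red-red paths needing two symptomatic
  # interior nodes and 12 paths through a two-node household needing one,
  # over 18 level-2 nodes
  m2 <- path_length_distribution(c(0, 0, 1))
  expect_equal(ls_plus_success_lower_bound(m2, p, 3, 2),
               (6 * (1 - p)^2 + 12 * (1 - p)) / 18)
  # LS+ bound dominates the LS value for identical inputs
  tp <- theory_params()
  dist <- ret_stopped_path_dist(tp)
  for (pa in c(0.1, 0.4, 0.7)) {
    pc <- p_asym_given_not_hosp(pa, 0.083)
    expect_gte(ls_plus_success_lower_bound(dist, pc, 3, 2),
               ls_success_probability(dist, pc))
  }
  # d_c = 1 falls back to the LS value
  expect_equal(ls_plus_success_lower_bound(dist, p, 1, 2),
               ls_success_probability(dist, p))
})

test_that("expected RET profiles satisfy their boundary and size identities", {
  expect_equal(ret_expected_profile(3, 5, 5, 4.646, 0.271), 0)
  expect_equal(ret_expected_profile(1, 1, 5, 4.646, 0.271), 5 * 0.271)
  expect_equal(ret_expected_profile(7, 0, 5, 4.646, 0.271), 1)
  expect_equal(ret_expected_size(0, 5, 4.646, 0.271), 1)
  expect_equal(ret_expected_size(1, 5, 4.646, 0.271), 1 + 5 * 0.271)
  expect_error(ret_expected_size(3, 5, 1, 0.3), "exceed")
  # sum over levels equals the closed-form size across a parameter grid
  for (par in list(c(5, 4.646, 0.271), c(4, 3.2, 0.15), c(6, 5.5, 0.4))) {
    for (t in c(1, 2, 7, 13, 20)) {
      s <- sum(sapply(0:t, function(l)
        ret_expected_profile(t, l, par[1], par[2], par[3])))
      expect_equal(s, ret_expected_size(t, par[1], par[2], par[3]),
                   tolerance = 1e-9)
    }
  }
  expect_equal(ret_expected_size(2, 5, 4.646, 0.271), 5.0489,
               tolerance = 1e-4)
})

test_that("the stopped deterministic tree law behaves on hand-checkable profiles", {
  # certain hospitalization: all mass on the root
  prof <- sictf:::ret_profile_matrix(10, 5, 5, 4.646, 0.271)
  d1 <- det_stopped_path_dist(prof, 0, 1)
  expect_equal(d1$mass[1], 1)
  expect_equal(sum(d1$mass), 1)
  # one node per day at level 1: geometric split 1/2 - 1/2 at q = 1/2
  c2 <- cbind(rep(1, 41), c(0, seq_len(40)))
  d2 <- det_stopped_path_dist(c2, p_a = 0, p_h = 0.5)
  expect_equal(d2$mass[1], 0.5)
  expect_equal(d2$mass[2], 0.5, tolerance = 1e-9)
  # masses approach total 1 when hospitalization is possible
  d3 <- det_stopped_path_dist(sictf:::ret_profile_matrix(200, 20, 5, 4.646,
                                                         0.271),
                              0.4, 0.083)
  expect_lt(d3$truncation_deficit, 1e-6)
  # malformed profiles are rejected
  bad <- sictf:::ret_profile_matrix(10, 5, 5, 4.646, 0.271)
  bad[4, 2] <- bad[3, 2] - 0.5
  expect_error(det_stopped_path_dist(bad, 0.4, 0.083), "shrink")
})

test_that("the stopped-RET law equals the substitution into the stopped-DET law", {
  # the profile matrix must be square (levels up to t_max) so that the
  # per-day totals are the full tree sizes, not level-truncated ones
  for (tp in list(theory_params(t_max = 60L),
                  theory_params(p_i = 0.2, p_a = 0.2, d_c = 4, d_h = 1,
                                t_max = 50L))) {
    a <- ret_stopped_path_dist(tp)
    prof <- sictf:::ret_profile_matrix(tp$t_max, tp$t_max, tp$d_r, tp$d,
                                       tp$p_i_eff)
    b <- det_stopped_path_dist(prof, tp$p_a, tp$p_h)
    expect_equal(a$mass, b$mass[seq_len(tp$n_max + 1)], tolerance = 1e-9)
  }
})

test_that("effective parameters rescale time and average the RB degrees", {
  e <- effective_params(0.1, 3, 3, 2)
  expect_equal(e$p_i_eff, 1 - 0.9^3)
  expect_equal(e$d_r, 5)
  expect_equal(e$f_r, 0.6457, tolerance = 1e-4)
  expect_equal(e$d, 4.646, tolerance = 1e-3)
  # oracle: level-population-weighted mean degree of an explicit RB tree
  tr <- build_rb_tree(3, 2, 9)
  inner <- tr$level >= 1 & tr$level <= 8
  deg <- ifelse(tr$color == "red", 5, 4)
  expect_equal(e$d, mean(deg[inner]), tolerance = 0.02)
})

test_that("stopped-RET simulator honours its degenerate limits", {
  x <- simulate_ret_stopped_many(200, 5, 4.646, 0.271, 0, 1, seed = 1)
  expect_true(all(x == 0L))
  # p_i = 0: the tree never grows; the root either stops at day 0 or the
  # replicate is discarded
  y <- simulate_ret_stopped_many(500, 5, 4.646, 0, 0.4, 0.083, seed = 2,
                                 t_max = 20)
  expect_true(all(is.na(y) | y == 0L))
  one <- simulate_ret_stopped(5, 4.646, 0.271, 0.4, 0.083, seed = 3)
  expect_true(is.na(one$path_length) || one$path_length >= 0)
  # unstopped growth matches the expected size within Monte-Carlo error
  r <- simulate_ret(4000, 6, 5, 4.646, 0.271, seed = 4)
  tot <- rowSums(r$mean)
  for (t in 1:6) {
    a <- ret_expected_size(t, 5, 4.646, 0.271)
    expect_lt(abs(tot[t] - a) / a, 0.05)
  }
})

test_that("predictions are probabilities, monotone in the asymptomatic rate", {
  prev_ls <- prev_lsp <- 1.01
  for (pa in c(0, 0.2, 0.4, 0.6, 0.8)) {
    p <- dde_default_params(p_a = pa)
    ls <- predict_success("LS", p)
    lsp <- predict_success("LS+", p)
    expect_gte(ls, 0); expect_lte(ls, 1)
    expect_gte(lsp, ls - 1e-12)
    expect_lt(ls, prev_ls); expect_lte(lsp, prev_lsp)
    prev_ls <- ls; prev_lsp <- lsp
  }
  expect_gt(predict_success("LS", dde_default_params(p_a = 0)), 0.999)
})
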