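test_that("the pair constraint follows the printed arithmetic", {
  net <- path_net(4)   # 4 - 3 - 2 - 1? no: path 1-2-3-4
  # candidate 3: d(v1=2, 3) = 1, d(v2=1, 3) = 2
  o1 <- list(node = 2L, kind = "onset", time = 5)
  o2 <- list(node = 1L, kind = "onset", time = 10)
  # |(10 - 5) - (2 - 1)| = 4, bound 1 * (1 + 2) = 3: excluded
  expect_false(sg_feasible(3L, o1, o2, net, sigma = 1))
  # sigma large enough: feasible
  expect_true(sg_feasible(3L, o1, o2, net, sigma = 2))
  # identical observations at one node: feasible at positive distance
  expect_true(sg_feasible(3L, o1, o1, net, sigma = 0.01))
  # unreachable candidate: infeasible
  net2 <- as_household_network(rbind(c(1, 2), c(3, 4)), N = 4)
  expect_false(sg_feasible(4L, list(node = 1L, kind = "onset", time = 0),
                           list(node = 2L, kind = "onset", time = 1),
                           net2, sigma = 100))
})

test_that("negative and asymptomatic observations bound one side only", {
  net <- path_net(5)
  # candidate 1; symptomatic at node 2 (d=1, t=10)
  sym <- list(node = 2L, kind = "onset", time = 10)
  # negative at node 4 (d=3) tested day 5: onset can only be later, and a
  # later onset at larger distance is consistent
  neg <- list(node = 4L, kind = "negative", time = 5)
  expect_true(sg_feasible(1L, sym, neg, net, sigma = 0.5, delta = 1))
  # negative *earlier* than explainable is fine too (lower bound), but a
  # negative far in the future at a *smaller* distance is a violation:
  neg2 <- list(node = 2L, kind = "negative", time = 40)
  sym2 <- list(node = 4L, kind = "onset", time = 10)
  expect_false(sg_feasible(1L, sym2, neg2, net, sigma = 0.5, delta = 1))
  # asymptomatic: its time is an upper bound, so the mirrored direction
  asy <- list(node = 4L, kind = "asymptomatic", time = 40)
  expect_true(sg_feasible(1L, sym, asy, net, sigma = 0.5, delta = 1))
  asy2 <- list(node = 2L, kind = "asymptomatic", time = 1)
  sym3 <- list(node = 4L, kind = "onset", time = 50)
  expect_false(sg_feasible(1L, sym3, asy2, net, sigma = 0.5, delta = 1))
})

test_that("sigma limits: infinite keeps everyone, zero with conflict empties", {
  net <- path_net(4)
  o1 <- list(node = 1L, kind = "onset", time = 0)
  o2 <- list(node = 4L, kind = "onset", time = 17)
  for (cand in 1:4)
    expect_true(sg_feasible(cand, o1, o2, net, sigma = 1e9))
  # sigma = 0: strict inequality can never hold
  expect_false(any(vapply(1:4, function(cand)
    sg_feasible(cand, o1, o2, net, sigma = 0), logical(1))))
})

test_that("the candidate set shrinks monotonically under new observations", {
  net <- generate_hnm(30, 2, 3, seed = 8)
  D <- igraph::distances(net$graph)
  obs <- list(
    list(node = 3L, kind = "onset", time = 9),
    list(node = 11L, kind = "onset", time = 13),
    list(node = 20L, kind = "negative", time = 10),
    list(node = 25L, kind = "asymptomatic", time = 12))
  cand <- seq_len(30)
  sizes <- integer(0)
  seen <- list()
  for (o in obs) {
    cand <- sictf:::sg_filter(cand, o, seen, D, sigma = 1.5, delta = 3)
    seen <- c(seen, list(o))
    sizes <- c(sizes, length(cand))
  }
  expect_true(all(diff(sizes) <= 0))
})

test_that("sensor choice matches exhaustive hypothesis enumeration on a star", {
  net <- star_net(4)        # centre 1, leaves 2..5
  D <- igraph::distances(net$graph)
  params <- epidemic_params(p_i = 1, p_a = 0)
  obs <- list(list(node = 2L, kind = "onset", time = 10))
  state <- list(candidate_set = 1:5, observations = obs, sigma = 0.6,
                delta = 3, D = D, params = params, n_hyp = 1e9,
                day_step = 1, scan_cap = Inf, day_lo = 0, day_hi = 6)
  pick <- sg_select_sensor(state, net, untested = c(3L, 4L, 5L))
  # independent brute force over every hypothesis and untested node
  delay <- 3; onset_lag <- params$T_E + params$T_P
  score <- sapply(c(3L, 4L, 5L), function(u) {
    tot <- 0; nh <- 0
    for (s in 1:5) for (t0 in 0:6) {
      tau <- t0 + D[u, s] * delay + onset_lag
      keep <- 0
      for (cand in 1:5) {
        o <- obs[[1]]
        ok <- abs((tau - o$time) - delay * (D[u, cand] - D[o$node, cand])) <
          0.6 * (D[o$node, cand] + D[u, cand])
        keep <- keep + ok
      }
      tot <- tot + keep; nh <- nh + 1
    }
    tot / nh
  })
  expect_equal(pick, c(3L, 4L, 5L)[which.min(score)])
})

test_that("size-gain recovers the source of a deterministic spread", {
  net <- path_net(6)
  p <- epidemic_params(p_i = 1, p_a = 0, p_h = 1)
  tr <- simulate_dde(net, 2, p, seed = 3)
  orc <- sictf_oracle(tr, net, budget = 2)
  r <- run_size_gain(orc, net, deadline_day = orc$detection_day + 15,
                     seed = 5, sigma = 0.45, scan_cap = Inf, n_hyp = 1e9,
                     day_step = 1)
  expect_false(r$sg_failed)
  expect_equal(r$estimate, 2L)
})

test_that("deadline fallback is a seeded uniform pick; zero-sigma conflicts fail", {
  run <- conditioned_hnm_run(N = 30, seed = 40)
  orc <- sictf_oracle(run$trace, run$net)
  # deadline at detection: no sensor is ever placed
  r1 <- run_size_gain(orc, run$net, deadline_day = orc$detection_day - 1,
                      seed = 9)
  orc2 <- sictf_oracle(run$trace, run$net)
  r2 <- run_size_gain(orc2, run$net, deadline_day = orc2$detection_day - 1,
                      seed = 9)
  expect_equal(r1$estimate, r2$estimate)      # reproducible fallback
  expect_equal(r1$tests_used, 0L)
  expect_gt(r1$candidate_set_size, 1L)
})

test_that("a generous sigma never filters the true source on a tree", {
  # tree-shaped static network from an explicit RB tree, depth 4
  tr <- build_rb_tree(2, 1, 4)
  edges <- cbind(tr$parent[-1], seq_len(tr$n)[-1])
  net <- as_household_network(edges, household = tr$house_head, N = tr$n)
  p <- epidemic_params(p_i = 0.4, p_a = 0.3, p_h = 0.4, T_I = 50)
  trace <- NULL
  for (s in 1:40) {
    cand <- simulate_dde(net, 1, p, seed = s)
    if (!is.null(cand$first_hospitalized)) { trace <- cand; break }
  }
  expect_false(is.null(trace))
  # all ground-truth observations, generous sigma
  D <- igraph::distances(net$graph)
  obs <- list()
  for (v in seq_len(net$N)) {
    st <- state_at(trace, v, trace$first_hospitalized$day)
    o <- if (st %in% c("symptomatic_infectious", "hospitalized"))
      list(node = v, kind = "onset", time = trace$onset_time[v])
    else if (st == "asymptomatic_infectious")
      list(node = v, kind = "asymptomatic",
           time = trace$first_hospitalized$day)
    else if (st == "susceptible")
      list(node = v, kind = "negative", time = trace$first_hospitalized$day)
    if (!is.null(o)) obs <- c(obs, list(o))
  }
  cand <- seq_len(net$N)
  seen <- list()
  delta <- p$T_E + 1 / p$p_i - 1
  for (o in obs) {
    cand <- sictf:::sg_filter(cand, o, seen, D, sigma = 30, delta = delta)
    seen <- c(seen, list(o))
  }
  expect_true(trace$source %in% cand)
})
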