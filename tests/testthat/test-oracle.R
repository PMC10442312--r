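test_that("outbreak detection returns the earliest hospitalization, id tie-break", {
  p <- dde_default_params()
  # isolated symptomatic-hospitalized source: detection at day 12
  tr <- manual_trace(3, p, c(0, NA, NA), rep(NA_integer_, 3),
                     c(FALSE, NA, NA), c(TRUE, NA, NA), 1L)
  expect_equal(detect_outbreak(tr), list(node = 1L, day = 12))
  # two hospitalizations on the same day: smaller id wins
  tr2 <- manual_trace(3, p, c(5, 0, 0), c(NA, NA, NA),
                      c(TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE), 2L)
  expect_equal(detect_outbreak(tr2)$node, 2L)
  # no hospitalization: the run is discarded upstream
  tr3 <- manual_trace(2, p, c(0, NA), c(NA, NA), c(TRUE, NA), c(FALSE, NA), 1L)
  expect_error(detect_outbreak(tr3), "discard")
})

test_that("daily budget is 1% of the population, minimum one", {
  expect_equal(test_budget(400), 4L)
  expect_equal(test_budget(9054), 90L)
  expect_equal(test_budget(50), 1L)
})

test_that("test results reflect the disease state on the administration day", {
  p <- dde_default_params()
  net <- path_net(7)
  # node states engineered via infection times; day of testing = 20
  # 1: susceptible, 2: exposed (inf 19), 3: presymptomatic (inf 16),
  # 4: symptomatic (inf 10), 5: asymptomatic current (inf 10),
  # 6: recovered symptomatic (inf 2), 7: recovered asymptomatic (inf 2)
  tr <- manual_trace(7, p,
                     c(NA, 19, 16, 10, 10, 2, 2),
                     rep(NA_integer_, 7),
                     c(NA, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
                     c(NA, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
                     6L)
  # give the trace a detectable case without disturbing the others
  tr$infection_time[1] <- NA
  tr$hospitalization_time[4] <- NA
  tr$first_hospitalized <- list(node = 6L, day = 20)
  orc <- sictf_oracle(tr, net, budget = 10)
  for (v in c(1, 2, 3, 4, 5, 7)) submit_test(orc, v)
  advance_day(orc)
  res <- collect_results(orc)
  res <- res[order(res$node), ]
  expect_equal(res$kind,
               c("negative", "negative", "positive_no_time", "onset_revealed",
                 "positive_no_time", "positive_no_time"))
  expect_equal(res$onset[res$node == 4], 15)   # inf 10 + T_E + T_P
  # asymptomatic results never disclose current vs recovered
  expect_equal(res$kind[res$node == 5], res$kind[res$node == 7])
})

test_that("results are delivered the next day and spill over the budget", {
  run <- conditioned_hnm_run(N = 60, seed = 7)
  orc <- sictf_oracle(run$trace, run$net, budget = 2)
  expect_equal(orc$day, orc$detection_day)
  for (v in setdiff(1:5, orc$detection_node)) submit_test(orc, v)
  expect_equal(nrow(collect_results(orc)), 0L)    # nothing before a day passes
  advance_day(orc)
  expect_equal(nrow(collect_results(orc)), 2L)    # budget-limited
  advance_day(orc)
  expect_equal(nrow(collect_results(orc)), 2L)
  advance_day(orc)
  expect_lte(nrow(collect_results(orc)), 1L)
  # duplicate submissions are rejected with a signal
  v0 <- setdiff(1:5, orc$detection_node)[1]
  expect_false(submit_test(orc, v0))
  led <- oracle_ledger(orc)
  expect_equal(led$tests_submitted, length(setdiff(1:5, orc$detection_node)))
  expect_equal(led$days_elapsed, 3)
})

test_that("contact queries count each edge once; household queries recount", {
  run <- conditioned_hnm_run(N = 60, seed = 12)
  orc <- sictf_oracle(run$trace, run$net)
  v <- orc$detection_node
  nb <- contact_query(orc, v)
  expect_setequal(nb, run$net$adj[[v]])
  expect_equal(orc$edges_revealed, length(nb))
  contact_query(orc, v)                        # same edges: no increment
  expect_equal(orc$edges_revealed, length(nb))
  u <- nb[1]
  contact_query(orc, u)
  # the edge (v, u) was already revealed from v's side
  expect_equal(orc$edges_revealed,
               length(nb) + length(run$net$adj[[u]]) - 1L)
  expect_setequal(household_query(orc, v), household_of(run$net, v))
  household_query(orc, v)
  expect_equal(orc$household_queries, 2L)      # unlimited, but recounted
})

test_that("the epidemic advances in real time whether or not queries arrive", {
  run <- conditioned_tree_run(seed = 200)
  sim <- run$sim
  orc <- sictf_oracle(sim)
  d0 <- orc$day
  n0 <- sum(!is.na(sim$infection_time[1:sim$n]))
  for (i in 1:12) advance_day(orc)
  expect_equal(orc$day, d0 + 12)
  expect_equal(sim$day, d0 + 12)
  n1 <- sum(!is.na(sim$infection_time[1:sim$n]))
  expect_gt(n1, n0)    # growth continued with no queries at all
  # newly hospitalized nodes are announced on their hospitalization day
  ann <- announced_hospitalizations(orc)
  expect_true(orc$detection_node %in% ann)
  ht <- sim$hospitalization_time[ann]
  expect_true(all(ht <= orc$day))
})

test_that("ledger counters equal an independent recount from the query log", {
  run <- conditioned_hnm_run(N = 60, seed = 21)
  orc <- sictf_oracle(run$trace, run$net)
  res <- run_local_search(orc, "LS+")
  log <- query_log(orc)
  led <- oracle_ledger(orc)
  expect_equal(led$household_queries, sum(log$type == "household"))
  expect_equal(led$tests_submitted,
               sum(log$type == "test_submit" & log$response == "queued"))
  # recount unique revealed edges from the contact-query responses
  new_edges <- as.integer(sub(".*new_edges=(\\d+).*", "\\1",
                              log$response[log$type == "contact"]))
  expect_equal(led$edges_revealed, sum(new_edges))
  expect_equal(res$tests_used, led$tests_submitted)
  expect_equal(res$edges_revealed, led$edges_revealed)
})

test_that("tree oracles reveal households and contacts lazily but consistently", {
  run <- conditioned_tree_run(seed = 300)
  sim <- run$sim
  orc <- sictf_oracle(sim)
  h <- orc$detection_node
  hh <- household_query(orc, h)
  head <- sim$house_head[h]
  expect_true(head %in% hh)
  expect_length(hh, 1 + 2)          # red head plus d_h = 2 blue members
  nb <- contact_query(orc, h)
  # neighbors are the parent (unless root) plus all realized children
  if (!is.na(sim$parent[h])) expect_true(sim$parent[h] %in% nb)
  kids <- sim$children[[h]]
  expect_setequal(setdiff(nb, sim$parent[h]), kids)
  # red nodes have d_c - 1 + d_h children realized (root: d_c + d_h)
  n_expect <- if (h == 1L) 5L else if (sim$color[h] == 1L) 4L else 3L
  expect_length(kids, n_expect)
})
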