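# shared fixtures: tiny graphs and conditioned simulation draws

# path graph 1-2-...-n as a household network (singleton households)
path_net <- function(n) {
  as_household_network(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), N = n)
}

# star with centre 1 and k leaves; singleton households
star_net <- function(k) {
  as_household_network(cbind(rep(1L, k), 1L + seq_len(k)), N = k + 1L)
}

# a DDE+HNM run conditioned on detection; NULL if no seed in the range works
conditioned_hnm_run <- function(N = 60, d_h = 2, d_c = 3,
                                params = dde_default_params(),
                                seed = 1, tries = 50) {
  for (s in seed + seq_len(tries) - 1L) {
    net <- generate_hnm(N, d_h, d_c, seed = s,
                        allow_remainder = N %% (d_h + 1) != 0)
    src <- sample.int(N, 1L)
    tr <- simulate_dde(net, src, params)
    if (!is.null(tr$first_hospitalized))
      return(list(net = net, trace = tr, seed = s))
  }
  NULL
}

# a DDE_NR tree run conditioned on detection
conditioned_tree_run <- function(d_c = 3, d_h = 2,
                                 params = dde_default_params(),
                                 seed = 1, tries = 50) {
  for (s in seed + seq_len(tries) - 1L) {
    sim <- simulate_dde_nr(list(d_c = d_c, d_h = d_h), params, seed = s)
    if (!is.null(sim$first_hospitalized)) return(list(sim = sim, seed = s))
  }
  NULL
}

# hand-built trace on a given net: everything explicit, for oracle tests
manual_trace <- function(N, params, infection_time, infector, asym, hospc,
                         source) {
  onset <- ifelse(!is.na(infection_time) & !asym,
                  infection_time + params$T_E + params$T_P, NA_real_)
  hosp <- ifelse(!is.na(onset) & hospc, onset + params$T_H, NA_real_)
  recov <- ifelse(is.na(infection_time), NA_real_,
                  ifelse(hospc, NA_real_,
                         infection_time + params$T_E + params$T_I))
  recov[is.infinite(recov)] <- NA_real_
  fh <- NULL
  if (any(!is.na(hosp))) {
    d <- min(hosp, na.rm = TRUE)
    fh <- list(node = min(which(!is.na(hosp) & hosp == d)), day = d)
  }
  structure(list(model = "dde", N = N, source = source, params = params,
                 infection_time = infection_time, infector = infector,
                 is_asymptomatic = asym, is_hospitalized_course = hospc,
                 onset_time = onset, hospitalization_time = hosp,
                 recovery_time = recov, first_hospitalized = fh,
                 horizon = 200, stop = "horizon"),
            class = "epidemic_trace")
}

# independent breadth-first-search distance oracle (no igraph)
bfs_distance <- function(adj, u, v) {
  if (u == v) return(0)
  dist <- rep(NA_integer_, length(adj))
  dist[u] <- 0L
  frontier <- u
  while (length(frontier)) {
    nxt <- integer(0)
    for (w in frontier) for (x in adj[[w]]) {
      if (is.na(dist[x])) { dist[x] <- dist[w] + 1L; nxt <- c(nxt, x) }
    }
    if (!is.na(dist[v])) return(dist[v])
    frontier <- nxt
  }
  Inf
}
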