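#' Generate a household network (household configuration model)
#'
#' Partitions `N` nodes into households of size `d_h + 1`, connects every
#' within-household pair (households are cliques), and joins households by a
#' configuration model: each node carries `d_c` external half-edges which are
#' paired uniformly at random. Pairings that would create a self-loop, a
#' duplicate external edge, or duplicate a household edge are discarded, so
#' the resulting graph is simple and every external degree is at most `d_c`.
#'
#' @param N Number of nodes; must be divisible by `d_h + 1`.
#' @param d_h Household contacts per node (household size is `d_h + 1`).
#' @param d_c External half-edges per node; `N * d_c` must be even and
#'   `d_c >= 1`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param allow_remainder If `TRUE`, an `N` not divisible by `d_h + 1` is
#'   accepted and the final household holds the `N %% (d_h + 1)` leftover
#'   nodes (still a clique). The default rejects such `N`, keeping every
#'   household at exactly `d_h + 1` members; the relaxation exists because
#'   the study's standard population sizes (400, 1000) are not multiples
#'   of 3.
#' @return An object of class `household_network`: a list with node count
#'   `N`, parameters `d_h`, `d_c`, the household id of every node
#'   (`household`), the household membership blocks (`households`), the
#'   adjacency list (`adj`), the edge matrix (`edges`, one row per
#'   undirected edge with `u < v`), per-category edge counts, the number of
#'   discarded pairings, and an [igraph][igraph::graph_from_edgelist] graph
#'   used for shortest-path computations.
#' @examples
#' net <- generate_hnm(N = 12, d_h = 2, d_c = 3, seed = 1)
#' length(net$households)  # 4 households of size 3
#' @export
generate_hnm <- function(N, d_h, d_c, seed = NULL, allow_remainder = FALSE) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1, N == round(N))
  stopifnot(is.numeric(d_h), length(d_h) == 1L, d_h >= 0, d_h == round(d_h))
  stopifnot(is.numeric(d_c), length(d_c) == 1L, d_c == round(d_c))
  N <- as.integer(N); d_h <- as.integer(d_h); d_c <- as.integer(d_c)
  if (d_c < 1)
    stop("d_c must be at least 1: with no external half-edges the ",
         "households cannot be joined into one network")
  rem <- N %% (d_h + 1L)
  if (rem != 0L && !allow_remainder)
    stop("N = ", N, " is not divisible by the household size d_h + 1 = ",
         d_h + 1L, "; households must partition the nodes exactly ",
         "(set allow_remainder = TRUE to keep one smaller household)")
  if ((as.numeric(N) * d_c) %% 2 != 0)
    stop("N * d_c must be even so that the ", N * d_c,
         " external half-edges can be paired")
  if (!is.null(seed)) set.seed(seed)

  hh_size <- d_h + 1L
  n_house <- N %/% hh_size
  household <- rep(seq_len(n_house), each = hh_size)
  if (rem != 0L) household <- c(household, rep(n_house + 1L, rem))

  # within-household cliques
  clique_edges <- function(members) {
    k <- length(members)
    if (k < 2L) return(NULL)
    idx <- utils::combn(members, 2L)
    cbind(idx[1L, ], idx[2L, ])
  }
  hh_edges <- NULL
  if (d_h > 0L) {
    base <- clique_edges(seq_len(hh_size))
    offs <- rep((seq_len(n_house) - 1L) * hh_size, each = nrow(base))
    hh_edges <- cbind(rep(base[, 1L], n_house) + offs,
                      rep(base[, 2L], n_house) + offs)
    if (rem > 1L)
      hh_edges <- rbind(hh_edges,
                        clique_edges(n_house * hh_size + seq_len(rem)))
  }

  # configuration-model pairing of external half-edges
  stubs <- rep(seq_len(N), each = d_c)
  stubs <- stubs[sample.int(length(stubs))]
  u <- stubs[c(TRUE, FALSE)]
  v <- stubs[c(FALSE, TRUE)]
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  keep <- u != v                                   # self-loops
  keep <- keep & household[u] != household[v]      # household duplicates
  key <- (as.numeric(u) - 1) * N + as.numeric(v)
  keep <- keep & !duplicated(key)                  # multi-edges
  ext_edges <- cbind(u[keep], v[keep])
  n_discarded <- length(u) - nrow(ext_edges)

  edges <- rbind(hh_edges, ext_edges)
  storage.mode(edges) <- "integer"
  adj <- vector("list", N)
  both <- c(edges[, 1L], edges[, 2L])
  other <- c(edges[, 2L], edges[, 1L])
  ord <- order(both, other)
  adj <- split(other[ord], factor(both[ord], levels = seq_len(N)))
  adj <- unname(lapply(adj, as.integer))

  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))

  structure(list(
    N = N, d_h = d_h, d_c = d_c,
    household = household,
    households = split(seq_len(N), household),
    adj = adj,
    edges = edges,
    n_household_edges = if (is.null(hh_edges)) 0L else nrow(hh_edges),
    n_external_edges = nrow(ext_edges),
    n_discarded = n_discarded,
    graph = g
  ), class = "household_network")
}

#' Build a household network from explicit edge and household assignments
#'
#' Used for user-supplied static contact networks: any simple undirected
#' graph together with a household partition. Household cliques are not
#' enforced here, so this is also the entry point for arbitrary test
#' topologies (paths, stars).
#'
#' @param edges Two-column matrix of node pairs (1-based ids).
#' @param household Integer vector: household id of each node. Defaults to
#'   singleton households.
#' @param N Number of nodes; defaults to the largest id mentioned.
#' @return A `household_network` object.
#' @export
as_household_network <- function(edges, household = NULL, N = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (is.null(N)) N <- max(edges, if (is.null(household)) 0L else length(household))
  N <- as.integer(N)
  if (is.null(household)) household <- seq_len(N)
  stopifnot(length(household) == N, all(edges >= 1L), all(edges <= N))
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, 2:1, drop = FALSE]
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  key <- (as.numeric(edges[, 1L]) - 1) * N + edges[, 2L]
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  both <- c(edges[, 1L], edges[, 2L]); other <- c(edges[, 2L], edges[, 1L])
  ord <- order(both, other)
  adj <- split(other[ord], factor(both[ord], levels = seq_len(N)))
  adj <- unname(lapply(adj, as.integer))
  hh <- as.integer(factor(household))
  is_hh <- hh[edges[, 1L]] == hh[edges[, 2L]]
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  structure(list(
    N = N, d_h = NA_integer_, d_c = NA_integer_,
    household = hh,
    households = split(seq_len(N), hh),
    adj = adj, edges = edges,
    n_household_edges = sum(is_hh),
    n_external_edges = sum(!is_hh),
    n_discarded = 0L,
    graph = g
  ), class = "household_network")
}

#' @export
print.household_network <- function(x, ...) {
  cat(sprintf("Household network: %d nodes, %d households, %d edges\n",
              x$N, length(x$households),
              x$n_household_edges + x$n_external_edges))
  cat(sprintf("  %d household edges, %d external edges (%d pairings discarded)\n",
              x$n_household_edges, x$n_external_edges, x$n_discarded))
  invisible(x)
}

#' Household of a node
#'
#' @param net A `household_network`.
#' @param v Node id.
#' @return Integer vector of the nodes in `v`'s household, `v` included.
#' @export
household_of <- function(net, v) {
  check_node(net, v)
  net$households[[net$household[v]]]
}

#' Shortest-path distance between two nodes
#'
#' Hop count of the shortest path; `Inf` when `u` and `v` are in different
#' connected components (connectivity is not enforced by the generator).
#'
#' @param net A `household_network`.
#' @param u,v Node ids.
#' @return A nonnegative number of hops, or `Inf` if unreachable.
#' @export
graph_distance <- function(net, u, v) {
  check_node(net, u); check_node(net, v)
  if (u == v) return(0)
  as.numeric(igraph::distances(net$graph, v = u, to = v))
}

check_node <- function(net, v) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v > net$N ||
      v != round(v))
    stop("unknown node id: ", format(v))
  invisible(TRUE)
}

#' Write / read a network as plain-text edge list and household file
#'
#' The edge list is a two-column comma-separated file of 0-based node id
#' pairs, one undirected edge per line, each edge listed once; the household
#' file maps 0-based node ids to 0-based household ids.
#'
#' @param net A `household_network`.
#' @param edge_file,household_file File paths.
#' @return `write_network` returns `net` invisibly; `read_network` returns a
#'   `household_network`.
#' @export
write_network <- function(net, edge_file, household_file) {
  utils::write.table(net$edges - 1L, edge_file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(seq_len(net$N) - 1L, net$household - 1L),
                     household_file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(net)
}

#' @rdname write_network
#' @export
read_network <- function(edge_file, household_file) {
  e <- as.matrix(utils::read.table(edge_file, sep = ",")) + 1L
  h <- utils::read.table(household_file, sep = ",")
  hh <- integer(nrow(h))
  hh[h[[1L]] + 1L] <- h[[2L]] + 1L
  as_household_network(e, household = hh, N = nrow(h))
}
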