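#' Build a red-blue tree
#'
#' The red-blue (RB) tree is the deterministic two-type branching tree that
#' locally approximates the household network around a uniformly chosen
#' node. The root is red and has `d_c` red and `d_h` blue children; every
#' other red node has `d_c - 1` red and `d_h` blue children; blue nodes have
#' `d_c` red children and no blue child. A household is a red node together
#' with its `d_h` blue children.
#'
#' @param d_c External-contact branching parameter, at least 1.
#' @param d_h Household branching parameter, at least 0.
#' @param max_depth Depth to which the tree is realized (level of the
#'   deepest generation; the root is level 0).
#' @return An object of class `rb_tree`: parallel vectors `color`
#'   (`"red"`/`"blue"`), `level`, `parent` (`NA` for the root),
#'   `house_head` (id of the red node heading each node's household), a
#'   `children` list, and the parameters. Node 1 is the root; nodes are in
#'   breadth-first order.
#' @examples
#' tr <- build_rb_tree(d_c = 3, d_h = 2, max_depth = 3)
#' tabulate(tr$level + 1L)  # 1 5 18 66
#' @export
build_rb_tree <- function(d_c, d_h, max_depth) {
  stopifnot(d_c >= 1, d_c == round(d_c), d_h >= 0, d_h == round(d_h),
            max_depth >= 0, max_depth == round(max_depth))
  d_c <- as.integer(d_c); d_h <- as.integer(d_h)
  n_total <- sum(vapply(0:max_depth, function(l) rb_level_count(d_c, d_h, l),
                        numeric(1)))
  if (n_total > 5e6) stop("requested RB tree would have more than 5e6 nodes")
  n_total <- as.integer(n_total)
  color <- integer(n_total)   # 1 red, 2 blue
  level <- integer(n_total)
  parent <- rep(NA_integer_, n_total)
  house_head <- integer(n_total)
  children <- vector("list", n_total)
  color[1L] <- 1L; level[1L] <- 0L; house_head[1L] <- 1L
  n <- 1L
  frontier <- 1L
  l <- 0L
  while (l < max_depth) {
    new_frontier <- integer(0)
    for (v in frontier) {
      n_red <- if (color[v] == 2L) d_c else if (v == 1L) d_c else d_c - 1L
      n_blue <- if (color[v] == 2L) 0L else d_h
      k <- n_red + n_blue
      if (k > 0L) {
        ids <- n + seq_len(k)
        color[ids] <- rep(c(1L, 2L), c(n_red, n_blue))
        level[ids] <- l + 1L
        parent[ids] <- v
        # red children start their own household; blue children join v's
        house_head[ids] <- c(ids[seq_len(n_red)], rep(v, n_blue))
        children[[v]] <- ids
        n <- n + k
        new_frontier <- c(new_frontier, ids)
      }
    }
    frontier <- new_frontier
    l <- l + 1L
  }
  structure(list(d_c = d_c, d_h = d_h, max_depth = as.integer(max_depth),
                 n = n, color = c("red", "blue")[color], level = level,
                 parent = parent, house_head = house_head,
                 children = children),
            class = "rb_tree")
}

#' @export
print.rb_tree <- function(x, ...) {
  cat(sprintf("RB tree (d_c = %d, d_h = %d) realized to depth %d: %d nodes\n",
              x$d_c, x$d_h, x$max_depth, x$n))
  invisible(x)
}

#' Number of RB-tree nodes at a given level
#'
#' Integer-exact count via the two-type recurrence
#' `r[l+1] = (d_c - 1) r[l] + d_c b[l]`, `b[l+1] = d_h r[l]`, seeded by the
#' root exception `r[1] = d_c`, `b[1] = d_h`.
#'
#' @param d_c,d_h RB branching parameters.
#' @param n Level (0 is the root).
#' @return The number of nodes at level `n` (a double, integer-valued).
#' @examples
#' rb_level_count(3, 2, 2)  # 18
#' @export
rb_level_count <- function(d_c, d_h, n) {
  stopifnot(n >= 0, n == round(n))
  if (n == 0) return(1)
  r <- d_c; b <- d_h
  if (n == 1) return(r + b)
  for (l in 2:n) {
    r_new <- (d_c - 1) * r + d_c * b
    b <- d_h * r
    r <- r_new
  }
  r + b
}

#' Household of an RB-tree node
#'
#' A household is a red node plus its `d_h` blue children; a blue node's
#' household is headed by its (red) parent.
#'
#' @param tree An `rb_tree`.
#' @param v Node id.
#' @return Integer vector: the household members (head first).
#' @export
rb_household_of <- function(tree, v) {
  stopifnot(v >= 1, v <= tree$n)
  head <- tree$house_head[v]
  kids <- tree$children[[head]]
  blue_kids <- kids[tree$color[kids] == "blue"]
  c(head, blue_kids)
}
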