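# Fixtures and independent oracles used across the suite.
#
# The oracles deliberately avoid the package's own path machinery: they
# enumerate paths with igraph on the undirected tree and evaluate the
# passability products and distances by walking the node sequence.

# the 7-reach dendritic example: root s1 with children s2, s3; s2 -> {s4,
# s5}; s3 -> {s6, s7}; barriers b2..b7 on the edges to the parents
fig1_network <- function(alpha_up = rep(0.5, 7), alpha_down = alpha_up,
                         length = rep(1, 7)) {
  river_network(length = length,
                parent = c(NA, 1, 1, 2, 2, 3, 3),
                alpha_up = c(NA, alpha_up[-1]),
                alpha_down = c(NA, alpha_down[-1]))
}

# random rooted tree with topologically ordered ids (parent[k] < k),
# random lengths on (0.5, 1) and passabilities on (0, 1)
random_network <- function(n, symmetric = TRUE) {
  parent <- c(NA_integer_,
              if (n > 1L) vapply(2:n, function(k) {
                sample.int(k - 1L, 1L)
              }, integer(1)))
  a <- runif(n, 0.05, 0.99)
  river_network(length = runif(n, 0.5, 1), parent = parent,
                alpha_up = c(NA, a[-1]),
                alpha_down = if (symmetric) c(NA, a[-1])
                else c(NA, runif(n - 1, 0.05, 0.99)))
}

# igraph handle on the undirected tree (independent of as_igraph)
oracle_graph <- function(net) {
  n <- net$n_reaches
  el <- if (n > 1L) cbind(2:n, net$parent[2:n]) else matrix(integer(), 0, 2)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

# the unique simple path between two reaches as a node id sequence,
# found by exhaustive enumeration of simple paths
oracle_path_nodes <- function(net, from, to) {
  if (from == to) return(from)
  g <- oracle_graph(net)
  paths <- igraph::all_simple_paths(g, from = from, to = to)
  stopifnot(length(paths) == 1L)  # trees have exactly one simple path
  as.integer(paths[[1L]])
}

# walk the node sequence and multiply passabilities; the barrier between
# consecutive reaches a, b is labelled by whichever of the two is the child
oracle_c <- function(net, i, j) {
  nodes <- oracle_path_nodes(net, i, j)
  out <- 1
  for (s in seq_len(length(nodes) - 1L)) {
    a <- nodes[s]; b <- nodes[s + 1L]
    k <- if (!is.na(net$parent[a]) && net$parent[a] == b) a else b
    out <- out * net$alpha_up[k] * net$alpha_down[k]
  }
  out
}

# directed product from source to recipient: upstream steps (into a child)
# use alpha_up, downstream steps (into the parent) use alpha_down
oracle_cdir <- function(net, source, recipient) {
  nodes <- oracle_path_nodes(net, source, recipient)
  out <- 1
  for (s in seq_len(length(nodes) - 1L)) {
    a <- nodes[s]; b <- nodes[s + 1L]
    if (!is.na(net$parent[a]) && net$parent[a] == b) {
      out <- out * net$alpha_down[a]       # stepping down into the parent
    } else {
      out <- out * net$alpha_up[b]         # stepping up into the child
    }
  }
  out
}

# midpoint-to-midpoint distance along the enumerated path
oracle_d <- function(net, i, j) {
  if (i == j) return(0)
  nodes <- oracle_path_nodes(net, i, j)
  inner <- nodes[-c(1L, length(nodes))]
  net$length[i] / 2 + sum(net$length[inner]) + net$length[j] / 2
}
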