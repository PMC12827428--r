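#' Unique tree path between two reaches
#'
#' On a rooted tree there is exactly one (and therefore shortest) path
#' between any two reaches. The path first descends from the source toward
#' the lowest common ancestor (each step crosses a barrier in the
#' downstream direction) and then ascends to the target (upstream steps).
#' Barrier `b_k` sits on the edge between reach `k` and its parent.
#'
#' @param net a `river_network`.
#' @param source_id,target_id reach ids.
#' @return list with `source_id`, `target_id`, `n_barriers`, and `steps`, a
#'   data frame with columns `barrier` (the reach id labelling the barrier)
#'   and `direction` (`"downstream"` or `"upstream"`), in travel order.
#' @export
tree_path <- function(net, source_id, target_id) {
  validate_river_network(net)
  n <- net$n_reaches
  source_id <- as.integer(source_id); target_id <- as.integer(target_id)
  for (id in c(source_id, target_id)) {
    if (is.na(id) || id < 1L || id > n) {
      stop("unknown reach id: ", id, call. = FALSE)
    }
  }
  up <- root_chain(net, source_id)   # source, ..., root
  vp <- root_chain(net, target_id)
  lca <- max(intersect(up, vp))      # BFS ids: ancestors have smaller ids,
                                     # the deepest common one is the largest
  down_part <- up[seq_len(match(lca, up) - 1L)]            # barriers left going down
  up_part <- rev(vp[seq_len(match(lca, vp) - 1L)])         # barriers crossed going up
  steps <- data.frame(
    barrier = c(down_part, up_part),
    direction = rep(c("downstream", "upstream"),
                    c(base::length(down_part), base::length(up_part))),
    stringsAsFactors = FALSE)
  list(source_id = source_id, target_id = target_id,
       n_barriers = nrow(steps), steps = steps)
}

# reach id chain from a reach to the root, endpoints included
root_chain <- function(net, id) {
  chain <- id
  while (!is.na(net$parent[id])) {
    id <- net$parent[id]
    chain <- c(chain, id)
  }
  chain
}

#' Undirected cumulative passability between two reaches
#'
#' Product of `alpha_up * alpha_down` over every barrier on the unique path
#' between the reaches; the empty product (a reach to itself) is 1. This is
#' the quantity the DCI is built from and it ignores the travel direction at
#' each barrier.
#'
#' @param net a `river_network`.
#' @param i,j reach ids.
#' @return scalar in (0, 1].
#' @export
cumulative_passability <- function(net, i, j) {
  p <- tree_path(net, i, j)
  b <- p$steps$barrier
  prod(net$alpha_up[b] * net$alpha_down[b])
}

#' Directed cumulative passability from a source to a recipient reach
#'
#' Colonization is directional: for each barrier along the path from the
#' occupied source reach `source_j` to the empty recipient reach
#' `recipient_i`, the passability in the direction the fish swims is used —
#' `alpha_down` while descending toward the common confluence, `alpha_up`
#' while ascending.
#'
#' @param net a `river_network`.
#' @param source_j source (occupied) reach id.
#' @param recipient_i recipient (empty) reach id.
#' @return scalar in (0, 1].
#' @export
directed_cumulative_passability <- function(net, source_j, recipient_i) {
  p <- tree_path(net, source_j, recipient_i)
  if (p$n_barriers == 0L) return(1)
  a <- ifelse(p$steps$direction == "downstream",
              net$alpha_down[p$steps$barrier],
              net$alpha_up[p$steps$barrier])
  prod(a)
}

#' Along-channel swim distance between two reaches
#'
#' Distance "as the fish swims": from the midpoint of one reach, along the
#' channel through any intermediate reaches, to the midpoint of the other —
#' `l_i / 2 + (intermediate lengths) + l_j / 2`, and 0 for a reach to
#' itself. The midpoint convention is symmetric and vanishes on the
#' diagonal; it is the package default (the endpoint convention is not
#' offered because all uses here only need a symmetric metric).
#'
#' @param net a `river_network`.
#' @param i,j reach ids.
#' @return nonnegative scalar.
#' @export
swim_distance <- function(net, i, j) {
  validate_river_network(net)
  i <- as.integer(i); j <- as.integer(j)
  for (id in c(i, j)) {
    if (is.na(id) || id < 1L || id > net$n_reaches) {
      stop("unknown reach id: ", id, call. = FALSE)
    }
  }
  if (i == j) return(0)
  up <- root_chain(net, i)
  vp <- root_chain(net, j)
  lca <- max(intersect(up, vp))
  nodes <- union(up[seq_len(match(lca, up))], vp[seq_len(match(lca, vp))])
  inner <- setdiff(nodes, c(i, j))
  net$length[i] / 2 + sum(net$length[inner]) + net$length[j] / 2
}

#' All pairwise connectivity structure of a river network
#'
#' Computes, in one rooted traversal, the three pairwise matrices the
#' indices and the metapopulation model need, plus both DCI indices:
#' * `c` — undirected cumulative passabilities `c[i, j]` (symmetric, unit
#'   diagonal);
#' * `c_dir` — directed cumulative passabilities, `c_dir[i, j]` being the
#'   passability from source `j` to recipient `i`;
#' * `d` — midpoint-to-midpoint swim distances;
#' * `dci_p` — network-scale Dendritic Connectivity Index (0, 100];
#' * `dci_s` — per-reach segmental index (0, 100].
#'
#' Everything is filled by one tree traversal per source reach: factors are
#' multiplied outward from the source in traversal order, so networks that
#' share topology, lengths, and per-barrier passability products (the
#' paired symmetric/asymmetric scenarios) get bit-identical undirected
#' matrices and DCI values.
#'
#' @param net a `river_network`.
#' @return An object of class `river_connectivity` (list of the five
#'   elements above).
#' @export
river_connectivity <- function(net) {
  validate_river_network(net)
  n <- net$n_reaches
  both <- net$alpha_up * net$alpha_down      # per-barrier product, NA at root
  adj <- network_adjacency(net)
  cmat <- cdir <- matrix(1, n, n)
  dmat <- matrix(0, n, n)
  half <- net$length / 2
  for (src in seq_len(n)) {
    cval <- cdval <- rep(1, n)
    dval <- numeric(n)
    visited <- logical(n)
    visited[src] <- TRUE
    stack <- src
    while (base::length(stack)) {
      x <- stack[base::length(stack)]
      stack <- stack[-base::length(stack)]
      for (nb in adj[[x]]) {
        if (visited[nb]) next
        visited[nb] <- TRUE
        if (!is.na(net$parent[nb]) && net$parent[nb] == x) {
          # moving upstream into child nb, crossing barrier b_nb
          cval[nb] <- cval[x] * both[nb]
          cdval[nb] <- cdval[x] * net$alpha_up[nb]
        } else {
          # moving downstream from x into its parent, crossing b_x
          cval[nb] <- cval[x] * both[x]
          cdval[nb] <- cdval[x] * net$alpha_down[x]
        }
        dval[nb] <- dval[x] + half[x] + half[nb]
        stack <- c(stack, nb)
      }
    }
    cmat[, src] <- cval
    cdir[, src] <- cdval      # [recipient, source]: travel direction src -> i
    dmat[, src] <- dval
  }
  w <- net$length / total_length(net)
  dci_s <- as.numeric(100 * (w %*% cmat))       # sum_i c_ij * l_i / L
  dci_p <- as.numeric(dci_s %*% w)              # length-weighted average
  structure(list(c = cmat, c_dir = cdir, d = dmat,
                 dci_p = dci_p, dci_s = dci_s),
            class = "river_connectivity")
}

# undirected adjacency lists (parent plus children of each reach)
network_adjacency <- function(net) {
  adj <- vector("list", net$n_reaches)
  if (net$n_reaches > 1L) {
    for (k in 2:net$n_reaches) {
      p <- net$parent[k]
      adj[[p]] <- c(adj[[p]], k)
      adj[[k]] <- c(adj[[k]], p)
    }
  }
  adj
}

#' Network-scale Dendritic Connectivity Index
#'
#' The length-weighted average probability that a potamodromous fish can
#' move between two reaches of the network, on a 0-100 scale:
#' `DCIp = sum_ij c_ij (l_i / L)(l_j / L) x 100`, with the double sum over
#' all ordered pairs including `i = j` (`c_ii = 1`). A network whose
#' barriers are all fully passable scores exactly 100.
#'
#' @param net a `river_network`.
#' @return scalar in (0, 100].
#' @examples
#' dci_p(build_topology("binary", 7)) # no barriers: 100
#' @export
dci_p <- function(net) river_connectivity(net)$dci_p

#' Reach-scale (segmental) Dendritic Connectivity Index
#'
#' How connected one reach is to the rest of the network:
#' `DCIs(j) = sum_i c_ij (l_i / L) x 100`. The length-weighted average of
#' `DCIs` over reaches equals `DCIp`.
#'
#' @param net a `river_network`.
#' @param j reach id, or `NULL` for all reaches.
#' @return scalar, or vector of length `n_reaches` when `j` is `NULL`.
#' @export
dci_s <- function(net, j = NULL) {
  v <- river_connectivity(net)$dci_s
  if (is.null(j)) return(v)
  j <- as.integer(j)
  if (is.na(j) || j < 1L || j > net$n_reaches) {
    stop("unknown reach id: ", j, call. = FALSE)
  }
  v[j]
}
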