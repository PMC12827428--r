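#' Construct a river network
#'
#' A river network is a rooted metric tree: each reach (stream segment) is a
#' node, the river mouth is the root (reach 1), and each edge carries a
#' potential movement barrier. Reaches are numbered breadth-first from the
#' mouth, so the edge from reach `k` (k >= 2) to its parent carries barrier
#' `b_k` with an upstream and a downstream passability.
#'
#' Lengths are quality-adjusted habitat lengths, dimensionless after scaling
#' the maximal length to one. Passabilities are success probabilities of
#' crossing the barrier in the given direction; a value of 1 means "no
#' barrier". Impassable barriers (alpha = 0) are excluded: reaches behind
#' them are not part of the accessible network.
#'
#' @param length numeric vector of positive reach lengths, one per reach,
#'   indexed by reach id.
#' @param parent integer vector of parent reach ids; `NA` for the root
#'   (reach 1). Ids must be topologically ordered: `parent[k] < k`.
#' @param alpha_up,alpha_down numeric vectors of barrier passabilities in
#'   (0, 1] for the edge from each reach to its parent; entry 1 (the root)
#'   is ignored and stored as `NA`.
#' @return An object of class `river_network`: a list with elements
#'   `n_reaches`, `length`, `parent`, `alpha_up`, `alpha_down`.
#' @examples
#' # two reaches joined by a half-passable barrier
#' net <- river_network(length = c(1, 1), parent = c(NA, 1),
#'                      alpha_up = c(NA, 0.5), alpha_down = c(NA, 0.5))
#' @seealso [build_topology()] for linear and full binary skeletons.
#' @export
river_network <- function(length, parent, alpha_up = NULL, alpha_down = NULL) {
  n <- base::length(length)
  if (n < 1L) stop("a river network needs at least one reach", call. = FALSE)
  if (is.null(alpha_up)) alpha_up <- rep(1, n)
  if (is.null(alpha_down)) alpha_down <- rep(1, n)
  parent <- as.integer(parent)
  if (base::length(parent) != n || base::length(alpha_up) != n ||
      base::length(alpha_down) != n) {
    stop("length, parent, alpha_up and alpha_down must all have one entry per reach",
         call. = FALSE)
  }
  alpha_up[1L] <- NA_real_
  alpha_down[1L] <- NA_real_
  net <- structure(
    list(n_reaches = n, length = as.numeric(length), parent = parent,
         alpha_up = as.numeric(alpha_up), alpha_down = as.numeric(alpha_down)),
    class = "river_network")
  validate_river_network(net)
}

#' Validate river network invariants
#'
#' Checks that the object encodes a connected rooted tree with breadth-first
#' compatible reach ids, strictly positive lengths, and barrier
#' passabilities in (0, 1]. Errors name the offending reach.
#'
#' @param net a `river_network`.
#' @return `net`, invisibly unchanged, if valid.
#' @export
validate_river_network <- function(net) {
  stopifnot(inherits(net, "river_network"))
  n <- net$n_reaches
  if (!is.na(net$parent[1L])) {
    stop("reach 1 must be the root (river mouth) and have no parent", call. = FALSE)
  }
  if (n > 1L) {
    k <- 2:n
    bad <- k[is.na(net$parent[k]) | net$parent[k] < 1L | net$parent[k] >= k]
    if (base::length(bad)) {
      stop("reach ", bad[1L], ": parent id must be a smaller reach id ",
           "(breadth-first numbering from the mouth); cycles and extra roots ",
           "are not allowed", call. = FALSE)
    }
    a_u <- net$alpha_up[k]; a_d <- net$alpha_down[k]
    bad <- k[!is.finite(a_u) | !is.finite(a_d) | a_u <= 0 | a_d <= 0 |
               a_u > 1 | a_d > 1]
    if (base::length(bad)) {
      stop("barrier b", bad[1L], ": passabilities must lie in (0, 1]",
           call. = FALSE)
    }
  }
  bad <- which(!is.finite(net$length) | net$length <= 0)
  if (base::length(bad)) {
    stop("reach ", bad[1L], ": length must be positive", call. = FALSE)
  }
  invisible(net)
}

#' Build a linear or full binary network skeleton
#'
#' Generates the two limiting tree topologies used in the simulation study:
#' a linear chain of reaches rooted at the mouth, and a full binary tree.
#' For sizes that do not give a perfect binary tree, the complete binary
#' tree filled left-to-right in breadth-first order is used, so reach `k`
#' flows into reach `floor(k / 2)`. Lengths default to 1 and all edges are
#' fully passable placeholders; see [assign_attributes()].
#'
#' @param shape `"linear"` or `"binary"`.
#' @param n_reaches number of reaches, at least 1.
#' @return A `river_network` skeleton.
#' @examples
#' build_topology("binary", 7) # the classic 7-reach dendritic example
#' @export
build_topology <- function(shape = c("linear", "binary"), n_reaches) {
  shape <- match.arg(shape)
  n_reaches <- as.integer(n_reaches)
  if (base::length(n_reaches) != 1L || is.na(n_reaches) || n_reaches < 1L) {
    stop("n_reaches must be a single integer >= 1", call. = FALSE)
  }
  parent <- if (n_reaches == 1L) {
    NA_integer_
  } else if (shape == "linear") {
    c(NA_integer_, seq_len(n_reaches - 1L))
  } else {
    c(NA_integer_, as.integer(seq(2L, n_reaches) %/% 2L))
  }
  river_network(length = rep(1, n_reaches), parent = parent)
}

#' Children lists of a river network
#'
#' @param net a `river_network`.
#' @return list of integer vectors, children of each reach (upstream
#'   neighbours), in increasing id order.
#' @keywords internal
#' @noRd
network_children <- function(net) {
  kids <- vector("list", net$n_reaches)
  if (net$n_reaches > 1L) {
    for (k in 2:net$n_reaches) {
      p <- net$parent[k]
      kids[[p]] <- c(kids[[p]], k)
    }
  }
  kids
}

#' Total network length
#'
#' @param net a `river_network`.
#' @return sum of reach lengths `L`.
#' @export
total_length <- function(net) sum(net$length)

#' @export
print.river_network <- function(x, ...) {
  n <- x$n_reaches
  cat("<river_network> ", n, " reach", if (n != 1L) "es", ", ",
      max(0L, n - 1L), " barrier", if (n != 2L) "s", "\n", sep = "")
  cat("  total length L = ", format(total_length(x)), "\n", sep = "")
  if (n > 1L) {
    a <- x$alpha_up[-1L] * x$alpha_down[-1L]
    cat("  barrier passability products in [",
        format(min(a), digits = 3), ", ", format(max(a), digits = 3), "]\n",
        sep = "")
  }
  invisible(x)
}
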