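#' Latin hypercube sample on the unit cube
#'
#' Stratified design: for each dimension the n samples occupy the n
#' equal-width strata of (0, 1), one sample per stratum, with independent
#' random permutations across dimensions. Values are guarded away from 0
#' and 1 so that downstream passabilities stay on the open interval (an
#' impassable barrier would disconnect the network; a value of exactly 1
#' is reserved for "no barrier").
#'
#' @param n_samples number of design points (rows).
#' @param n_dims number of variables (columns).
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return `n_samples` x `n_dims` numeric matrix with entries in (0, 1).
#' @export
lhs_matrix <- function(n_samples, n_dims, seed) {
  n_samples <- as.integer(n_samples); n_dims <- as.integer(n_dims)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("n_samples must be a positive integer", call. = FALSE)
  }
  if (is.na(n_dims) || n_dims < 1L) {
    stop("n_dims must be a positive integer", call. = FALSE)
  }
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  m <- vapply(seq_len(n_dims), function(d) {
    (sample.int(n_samples) - 1L + stats::runif(n_samples)) / n_samples
  }, numeric(n_samples))
  m <- matrix(m, nrow = n_samples, ncol = n_dims)
  eps <- .Machine$double.eps
  pmin(pmax(m, eps), 1 - eps)
}

#' Assign randomized lengths and barrier passabilities to a skeleton
#'
#' Fills a topology skeleton with one Latin-hypercube design row. The row
#' has `2 N - 1` entries: the first `N` drive reach lengths (by reach id),
#' the remaining `N - 1` drive barrier passabilities (by barrier label
#' `b_2 .. b_N`). Lengths are uniform between half the maximal length and
#' the maximal length, with the maximal length normalized to one:
#' `l = 0.5 + 0.5 u`.
#'
#' Barrier passabilities are built in one of two modes from the same base
#' draw `a`:
#' * `symmetric`: `alpha_up = alpha_down = a`;
#' * `asymmetric`: all barriers fully passable downstream (`alpha_down = 1`)
#'   and `alpha_up = a^2`.
#'
#' The asymmetric upstream value is the square of the symmetric draw so the
#' per-barrier product `alpha_up * alpha_down` — and with it every undirected
#' cumulative passability and both DCI indices — is identical between the
#' paired scenarios. Only the directed passabilities seen by the
#' metapopulation model differ.
#'
#' @param skeleton a `river_network` (typically from [build_topology()]).
#' @param mode `"symmetric"` or `"asymmetric"` barrier passability.
#' @param lhs_row numeric vector in (0,1) of length `2 * n_reaches - 1`.
#' @return A fully attributed `river_network`.
#' @export
assign_attributes <- function(skeleton, mode = c("symmetric", "asymmetric"),
                              lhs_row) {
  mode <- match.arg(mode)
  validate_river_network(skeleton)
  n <- skeleton$n_reaches
  need <- 2L * n - 1L
  if (base::length(lhs_row) != need) {
    stop("lhs_row must have ", need, " entries (", n, " lengths + ",
         n - 1L, " barriers), got ", base::length(lhs_row), call. = FALSE)
  }
  u <- lhs_row[seq_len(n)]
  lengths <- 0.5 + 0.5 * u
  alpha_up <- rep(NA_real_, n)
  alpha_down <- rep(NA_real_, n)
  if (n > 1L) {
    a <- lhs_row[(n + 1L):need]
    if (mode == "symmetric") {
      alpha_up[-1L] <- a
      alpha_down[-1L] <- a
    } else {
      # a * a (not a^2) so the barrier product is bit-identical to the
      # symmetric pairing
      alpha_up[-1L] <- a * a
      alpha_down[-1L] <- 1
    }
  }
  river_network(length = lengths, parent = skeleton$parent,
                alpha_up = alpha_up, alpha_down = alpha_down)
}

#' Mean dispersal distance for a dispersal scenario
#'
#' Global dispersal sets the mean dispersal distance to the whole network
#' length (`D = L`); local dispersal sets it to the average reach length
#' (`D = L / N`), confining most colonization attempts to neighbouring
#' reaches.
#'
#' @param net a `river_network`.
#' @param mode `"global"` or `"local"`.
#' @return positive scalar `D` in the same (dimensionless) length units as
#'   the reach lengths.
#' @export
dispersal_distance <- function(net, mode = c("global", "local")) {
  mode <- match.arg(mode)
  validate_river_network(net)
  L <- total_length(net)
  if (mode == "global") L else L / net$n_reaches
}

#' Scenario configuration for the simulation design
#'
#' Bundles the four scenario axes of the simulation design: topology
#' (linear vs branching), barrier symmetry, dispersal range, and network
#' size, plus the replicate count and master seed.
#'
#' @param topology `"linear"` or `"binary"`.
#' @param passability_mode `"symmetric"` or `"asymmetric"`.
#' @param dispersal_mode `"global"` or `"local"`.
#' @param n_reaches network size, 3 to 50 reaches.
#' @param n_replicates Latin hypercube sample size (default 60).
#' @param seed master seed for the scenario cell.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(topology = c("binary", "linear"),
                            passability_mode = c("symmetric", "asymmetric"),
                            dispersal_mode = c("global", "local"),
                            n_reaches = 7L, n_replicates = 60L, seed = 1L) {
  topology <- match.arg(topology)
  passability_mode <- match.arg(passability_mode)
  dispersal_mode <- match.arg(dispersal_mode)
  n_reaches <- as.integer(n_reaches)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_reaches) || n_reaches < 3L || n_reaches > 50L) {
    stop("n_reaches must lie in [3, 50]", call. = FALSE)
  }
  if (is.na(n_replicates) || n_replicates < 2L) {
    stop("n_replicates must be at least 2", call. = FALSE)
  }
  structure(list(topology = topology, passability_mode = passability_mode,
                 dispersal_mode = dispersal_mode, n_reaches = n_reaches,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Deterministic sub-seed for a scenario cell
#'
#' Derived from the master seed, topology, and network size only: paired
#' symmetric/asymmetric (and global/local) cells share the same Latin
#' hypercube draw, so their replicates differ only in how the base
#' passabilities are turned into directed ones.
#'
#' @keywords internal
#' @noRd
cell_seed <- function(config) {
  topo <- if (config$topology == "binary") 2L else 1L
  s <- (as.double(config$seed) * 2654435761 + 97561 * config$n_reaches +
          7919 * topo) %% 2147483647
  as.integer(s)
}

#' Generate the replicate networks of one scenario cell
#'
#' Draws one joint Latin hypercube design of size `n_replicates` over the
#' `2 N - 1` attribute dimensions (N lengths, N - 1 barrier passabilities)
#' and attributes one network per design row. The design seed depends only
#' on the master seed, topology and size, so symmetric and asymmetric cells
#' are paired draw-for-draw.
#'
#' @param config a [scenario_config()].
#' @return list of `n_replicates` attributed `river_network` objects.
#' @export
generate_networks <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  skeleton <- build_topology(config$topology, config$n_reaches)
  design <- lhs_matrix(config$n_replicates, 2L * config$n_reaches - 1L,
                       seed = cell_seed(config))
  lapply(seq_len(config$n_replicates), function(r) {
    assign_attributes(skeleton, config$passability_mode, design[r, ])
  })
}
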