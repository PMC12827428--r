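#' Spearman rank correlation with an explicit undefined flag
#'
#' Pearson correlation of average-ranked data (ties get average ranks).
#' When either variable is constant the correlation is undefined; this is
#' reported as `NA` rather than 0 or an error, so degenerate scenario cells
#' (e.g. all-passable smoke runs) stay visible as "undefined" instead of
#' silently contributing a number.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values
#'   are dropped.
#' @return scalar in `[-1, 1]`, or `NA` if fewer than two complete pairs
#'   remain or a variable is constant.
#' @export
spearman_rho <- function(x, y) {
  if (base::length(x) != base::length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (base::length(x) < 2L) return(NA_real_)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y), method = "pearson")
}

#' Barrier-removal sensitivity of DCIp and the reproduction number
#'
#' Removes one barrier (sets both of its passabilities to 1), recomputes
#' the network-scale index and the basic reproduction number, and returns
#' the relative change of each as the ratio removed / in-place. Removing a
#' barrier can only improve connectivity and persistence, so both ratios
#' are >= 1; a ratio of exactly 1 means the barrier was already fully
#' passable. The removed/in-place orientation makes "large ratio" mean
#' "high priority for removal".
#'
#' @param net a `river_network`.
#' @param params a [species_params()] (with `D` already set for `net`).
#' @param barrier barrier label = reach id `k >= 2` whose edge to its
#'   parent carries the barrier.
#' @param conn optional precomputed [river_connectivity()] of `net`.
#' @param R_present optional precomputed [reproduction_number()] of `net`
#'   (shared across barriers when sweeping a whole network).
#' @return named numeric vector `c(rho_dci = ..., rho_R = ...)`, both >= 1.
#' @export
removal_ratios <- function(net, params, barrier,
                           conn = river_connectivity(net),
                           R_present = reproduction_number(net, params, conn)) {
  validate_river_network(net)
  barrier <- as.integer(barrier)
  if (is.na(barrier) || barrier < 2L || barrier > net$n_reaches) {
    stop("unknown barrier label: b", barrier, call. = FALSE)
  }
  removed <- net
  removed$alpha_up[barrier] <- 1
  removed$alpha_down[barrier] <- 1
  conn_rm <- river_connectivity(removed)
  R_after <- reproduction_number(removed, params, conn_rm)
  c(rho_dci = conn_rm$dci_p / conn$dci_p, rho_R = R_after / R_present)
}

#' Run one scenario cell of the simulation design
#'
#' Generates `n_replicates` networks ([generate_networks()]), and for each
#' computes the connectivity indices, the relative persistence metrics
#' against the barrier-free baseline, and (optionally) the
#' barrier-removal ratios for every barrier. The mean dispersal distance is
#' set per replicate from the network and the dispersal mode, overriding
#' `params$D`. Replicates on which the solver fails are flagged in the
#' `status` column and keep `NA` metrics rather than being dropped.
#'
#' @param config a [scenario_config()].
#' @param params a [species_params()]; `D` is overridden per replicate.
#' @param removal if `TRUE` (default) also compute barrier-removal ratios.
#' @return An object of class `replicate_table`: list of three data frames
#'   sharing the scenario key columns `topology`, `passability_mode`,
#'   `dispersal_mode`, `n_reaches`, `replicate`:
#'   * `networks` — one row per replicate: `dci_p`, `lambda`, `lambda_0`,
#'     `R`, `R_0`, `p_bar`, `p_bar_0`, `G_s`, `R_s`, `P_s`, `status`;
#'   * `reaches` — long format, one row per replicate x reach: `reach`,
#'     `dci_s`, `O_s`, `V_s`;
#'   * `removals` — long format, one row per replicate x barrier:
#'     `barrier`, `rho_dci`, `rho_R` (empty if `removal = FALSE`).
#' @export
run_scenario <- function(config, params = species_params(),
                         removal = TRUE) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(params, "species_params"))
  nets <- generate_networks(config)
  n <- config$n_reaches
  keys <- data.frame(topology = config$topology,
                     passability_mode = config$passability_mode,
                     dispersal_mode = config$dispersal_mode,
                     n_reaches = n,
                     stringsAsFactors = FALSE)
  net_rows <- vector("list", config$n_replicates)
  reach_rows <- vector("list", config$n_replicates)
  rem_rows <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    net <- nets[[r]]
    p_r <- params
    p_r$D <- dispersal_distance(net, config$dispersal_mode)
    conn <- river_connectivity(net)
    res <- tryCatch(relative_metrics(net, p_r, conn),
                    error = function(e) e)
    if (inherits(res, "error")) {
      net_rows[[r]] <- cbind(keys, data.frame(
        replicate = r, dci_p = conn$dci_p, lambda = NA_real_,
        lambda_0 = NA_real_, R = NA_real_, R_0 = NA_real_,
        p_bar = NA_real_, p_bar_0 = NA_real_, G_s = NA_real_,
        R_s = NA_real_, P_s = NA_real_,
        status = paste0("error: ", conditionMessage(res))))
      reach_rows[[r]] <- cbind(keys, data.frame(
        replicate = r, reach = seq_len(n), dci_s = conn$dci_s,
        O_s = NA_real_, V_s = NA_real_))
      next
    }
    net_rows[[r]] <- cbind(keys, data.frame(
      replicate = r, dci_p = conn$dci_p, lambda = res$lambda,
      lambda_0 = res$lambda_0, R = res$R, R_0 = res$R_0,
      p_bar = res$p_bar, p_bar_0 = res$p_bar_0, G_s = res$G_s,
      R_s = res$R_s, P_s = res$P_s, status = "ok"))
    reach_rows[[r]] <- cbind(keys, data.frame(
      replicate = r, reach = seq_len(n), dci_s = conn$dci_s,
      O_s = res$O_s, V_s = res$V_s))
    if (removal && n > 1L) {
      R_present <- res$R
      ratios <- vapply(2:n, function(k) {
        removal_ratios(net, p_r, k, conn, R_present = R_present)
      }, numeric(2))
      rem_rows[[r]] <- cbind(keys, data.frame(
        replicate = r, barrier = 2:n,
        rho_dci = ratios["rho_dci", ], rho_R = ratios["rho_R", ]))
    }
  }
  empty_rem <- cbind(keys[0, , drop = FALSE],
                     data.frame(replicate = integer(), barrier = integer(),
                                rho_dci = numeric(), rho_R = numeric()))
  structure(list(networks = do.call(rbind, net_rows),
                 reaches = do.call(rbind, reach_rows),
                 removals = if (base::length(Filter(Negate(is.null), rem_rows)))
                   do.call(rbind, rem_rows) else empty_rem),
            class = "replicate_table")
}

#' Combine replicate tables from several scenario cells
#'
#' @param ... `replicate_table` objects.
#' @return a single `replicate_table` with rows stacked.
#' @export
bind_replicate_tables <- function(...) {
  tabs <- list(...)
  if (base::length(tabs) == 1L && is.list(tabs[[1L]]) &&
      !inherits(tabs[[1L]], "replicate_table")) tabs <- tabs[[1L]]
  stopifnot(all(vapply(tabs, inherits, logical(1), "replicate_table")))
  structure(list(
    networks = do.call(rbind, lapply(tabs, `[[`, "networks")),
    reaches = do.call(rbind, lapply(tabs, `[[`, "reaches")),
    removals = do.call(rbind, lapply(tabs, `[[`, "removals"))),
    class = "replicate_table")
}

scenario_key_cols <- c("topology", "passability_mode", "dispersal_mode",
                       "n_reaches")

#' Network-scale correlations between DCIp and persistence metrics
#'
#' Spearman correlation, within each scenario cell, between the
#' network-scale index `DCIp` and each of the three relative metrics:
#' growth (`G_s`), reproduction (`R_s`), and mean steady-state occupancy
#' (`P_s`).
#'
#' @param table a `replicate_table` (possibly spanning several cells).
#' @return data frame: scenario keys, `metric`, `rho`, `n` (complete pairs
#'   used; `rho` is `NA` where undefined).
#' @export
network_scale_correlations <- function(table) {
  tab <- table$networks
  split_apply(tab, scenario_key_cols, function(cell) {
    do.call(rbind, lapply(c("G_s", "R_s", "P_s"), function(m) {
      ok <- is.finite(cell$dci_p) & is.finite(cell[[m]])
      data.frame(metric = m,
                 rho = spearman_rho(cell$dci_p, cell[[m]]),
                 n = sum(ok), stringsAsFactors = FALSE)
    }))
  })
}

#' Reach-scale correlations between DCIs and reach metrics
#'
#' Spearman correlation, within each scenario cell and for each reach
#' (reaches are comparable across replicates because the topology is fixed
#' within a cell), between the segmental index `DCIs` and the reach
#' occupancy ratio `O_s` or reproductive-value ratio `V_s`.
#'
#' @param table a `replicate_table`.
#' @return data frame: scenario keys, `reach` (breadth-first id),
#'   `metric`, `rho`, `n`.
#' @export
reach_scale_correlations <- function(table) {
  tab <- table$reaches
  out <- split_apply(tab, c(scenario_key_cols, "reach"), function(cell) {
    do.call(rbind, lapply(c("O_s", "V_s"), function(m) {
      ok <- is.finite(cell$dci_s) & is.finite(cell[[m]])
      data.frame(metric = m,
                 rho = spearman_rho(cell$dci_s, cell[[m]]),
                 n = sum(ok), stringsAsFactors = FALSE)
    }))
  })
  out[order(out$topology, out$passability_mode, out$dispersal_mode,
            out$n_reaches, out$reach, out$metric), , drop = FALSE]
}

#' Correlations between barrier-removal sensitivities
#'
#' For each barrier (breadth-first label), the Spearman correlation across
#' replicates between the relative change in `DCIp` and the relative
#' change in the basic reproduction number when that barrier is removed.
#' High correlations mean the structural index ranks barriers for removal
#' the same way the population-dynamic metric does.
#'
#' @param table a `replicate_table` with removal ratios.
#' @return data frame: scenario keys, `barrier`, `rho`, `n`.
#' @export
sensitivity_correlations <- function(table) {
  tab <- table$removals
  out <- split_apply(tab, c(scenario_key_cols, "barrier"), function(cell) {
    ok <- is.finite(cell$rho_dci) & is.finite(cell$rho_R)
    data.frame(rho = spearman_rho(cell$rho_dci, cell$rho_R),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out[order(out$topology, out$passability_mode, out$dispersal_mode,
            out$n_reaches, out$barrier), , drop = FALSE]
}

# split a data frame by key columns, apply f to each group, and bind the
# results back with the keys (deterministic ordering)
split_apply <- function(tab, keys, f) {
  idx <- interaction(tab[keys], drop = TRUE, lex.order = TRUE)
  parts <- lapply(split(seq_len(nrow(tab)), idx), function(rows) {
    cell <- tab[rows, , drop = FALSE]
    res <- f(cell)
    cbind(cell[rep(1L, nrow(res)), keys, drop = FALSE], res,
          row.names = NULL)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Default sweep configuration
#'
#' The full simulation design: both topologies, both passability modes,
#' both dispersal modes, network sizes spanning 3 to 50 reaches, and 60
#' Latin hypercube replicates per cell. The exact size grid within the
#' 3-50 range is configurable; the default covers it on a roughly
#' geometric ladder.
#'
#' @param sizes network sizes to sweep.
#' @param n_replicates replicates (LHS sample size) per scenario cell.
#' @param seed master seed.
#' @return a list understood by [run_sweep()].
#' @export
default_sweep_config <- function(sizes = c(3, 5, 7, 10, 15, 20, 30, 40, 50),
                                 n_replicates = 60L, seed = 1L) {
  list(topologies = c("binary", "linear"),
       passability_modes = c("symmetric", "asymmetric"),
       dispersal_modes = c("global", "local"),
       sizes = as.integer(sizes),
       n_replicates = as.integer(n_replicates),
       seed = as.integer(seed))
}

#' Run the full scenario sweep
#'
#' Crosses all scenario axes of a sweep configuration, runs every cell
#' with [run_scenario()], and returns the stacked replicate table together
#' with the three correlation analyses (network scale, reach scale,
#' barrier-removal sensitivity). Deterministic for a fixed master seed.
#'
#' @param sweep a list as produced by [default_sweep_config()] or read by
#'   [read_sweep_config()].
#' @param params a [species_params()]; `D` is set per replicate.
#' @param removal compute barrier-removal ratios (default `TRUE`).
#' @param verbose print one progress line per scenario cell.
#' @return list with `replicates` (a `replicate_table`), `network_scale`,
#'   `reach_scale`, `sensitivity` (correlation data frames), and `config`.
#' @export
run_sweep <- function(sweep = default_sweep_config(),
                      params = species_params(), removal = TRUE,
                      verbose = FALSE) {
  cells <- expand.grid(topology = sweep$topologies,
                       passability_mode = sweep$passability_modes,
                       dispersal_mode = sweep$dispersal_modes,
                       n_reaches = sweep$sizes,
                       stringsAsFactors = FALSE)
  tabs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- scenario_config(topology = cells$topology[i],
                           passability_mode = cells$passability_mode[i],
                           dispersal_mode = cells$dispersal_mode[i],
                           n_reaches = cells$n_reaches[i],
                           n_replicates = sweep$n_replicates,
                           seed = sweep$seed)
    if (verbose) {
      message(sprintf("[%d/%d] %s/%s/%s N=%d", i, nrow(cells),
                      cfg$topology, cfg$passability_mode,
                      cfg$dispersal_mode, cfg$n_reaches))
    }
    tabs[[i]] <- run_scenario(cfg, params, removal = removal)
  }
  reps <- bind_replicate_tables(tabs)
  list(replicates = reps,
       network_scale = network_scale_correlations(reps),
       reach_scale = reach_scale_correlations(reps),
       sensitivity = if (removal) sensitivity_correlations(reps) else NULL,
       config = sweep)
}
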