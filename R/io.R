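#' Read a river network from a node table or GraphML file
#'
#' The node-table CSV has one row per reach with columns
#' `id, parent_id, length, alpha_up, alpha_down`; `parent_id` is empty for
#' the root (the river mouth) and the passabilities describe the barrier
#' on the edge to the parent. GraphML files are read with igraph and must
#' carry the same attributes (`length` on vertices; `alpha_up`,
#' `alpha_down` on edges directed child -> parent). All network invariants
#' are enforced at parse time: cycles, extra roots, out-of-range
#' passabilities or nonpositive lengths fail with an error naming the
#' offending element.
#'
#' @param path file to read.
#' @param format `"csv"` or `"graphml"`; guessed from the extension by
#'   default.
#' @return a validated `river_network`.
#' @export
read_network <- function(path, format = c("auto", "csv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") read_network_csv(path) else read_network_graphml(path)
}

read_network_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "parent_id", "length", "alpha_up", "alpha_down")
  miss <- setdiff(need, names(tab))
  if (base::length(miss)) {
    stop("node table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[order(tab$id), , drop = FALSE]
  n <- nrow(tab)
  if (!identical(as.integer(tab$id), seq_len(n))) {
    stop("reach ids must be 1..N without gaps", call. = FALSE)
  }
  parent <- suppressWarnings(as.integer(tab$parent_id))
  roots <- which(is.na(parent))
  if (base::length(roots) != 1L) {
    stop("expected exactly one root reach (empty parent_id), found ",
         base::length(roots), call. = FALSE)
  }
  if (roots != 1L) stop("the root (river mouth) must be reach 1", call. = FALSE)
  check_acyclic(parent)
  river_network(length = tab$length, parent = parent,
                alpha_up = tab$alpha_up, alpha_down = tab$alpha_down)
}

# detect cycles / unreachable reaches before handing to the constructor,
# so malformed files fail with a graph-level message
check_acyclic <- function(parent) {
  n <- base::length(parent)
  for (k in seq_len(n)) {
    seen <- logical(n)
    i <- k
    while (!is.na(parent[i])) {
      if (seen[i]) {
        stop("cycle detected involving reach ", i, call. = FALSE)
      }
      seen[i] <- TRUE
      i <- parent[i]
      if (is.na(i) || i < 1L || i > n) break
    }
  }
  invisible(TRUE)
}

read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  lens <- igraph::vertex_attr(g, "length")
  if (is.null(lens)) stop("GraphML vertices need a 'length' attribute",
                          call. = FALSE)
  parent <- rep(NA_integer_, n)
  a_up <- rep(NA_real_, n)
  a_down <- rep(NA_real_, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  e_up <- igraph::edge_attr(g, "alpha_up")
  e_down <- igraph::edge_attr(g, "alpha_down")
  if (is.null(e_up) || is.null(e_down)) {
    stop("GraphML edges need 'alpha_up' and 'alpha_down' attributes",
         call. = FALSE)
  }
  for (e in seq_len(nrow(el))) {
    child <- el[e, 1L]; par <- el[e, 2L]
    if (!is.na(parent[child])) {
      stop("reach ", child, " has more than one parent", call. = FALSE)
    }
    parent[child] <- par
    a_up[child] <- e_up[e]
    a_down[child] <- e_down[e]
  }
  check_acyclic(parent)
  river_network(length = lens, parent = parent,
                alpha_up = a_up, alpha_down = a_down)
}

#' Write a river network to a node table or GraphML file
#'
#' Inverse of [read_network()]; a round trip reproduces the network
#' exactly (numbers are written in full precision).
#'
#' @param net a `river_network`.
#' @param path output file.
#' @param format `"csv"` or `"graphml"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "csv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "csv"
  }
  validate_river_network(net)
  if (format == "csv") {
    tab <- data.frame(id = seq_len(net$n_reaches),
                      parent_id = net$parent,
                      length = format_full(net$length),
                      alpha_up = format_full(net$alpha_up),
                      alpha_down = format_full(net$alpha_down))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

format_full <- function(x) ifelse(is.na(x), NA, sprintf("%.17g", x))

#' Convert a river network to an igraph object
#'
#' Directed edges point child -> parent (downstream); vertices carry
#' `length`, edges carry `alpha_up` and `alpha_down`.
#'
#' @param net a `river_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  validate_river_network(net)
  n <- net$n_reaches
  el <- if (n > 1L) cbind(2:n, net$parent[2:n]) else
    matrix(integer(), 0L, 2L)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$length <- net$length
  if (n > 1L) {
    igraph::E(g)$alpha_up <- net$alpha_up[2:n]
    igraph::E(g)$alpha_down <- net$alpha_down[2:n]
  }
  g
}

#' Read a sweep configuration from JSON
#'
#' The file is a JSON object with the scenario axes:
#' `topologies`, `passability_modes`, `dispersal_modes` (arrays of
#' strings), `sizes` (array of integers in `[3, 50]`), `n_replicates`,
#' `seed`, and optionally `params` (object with any of `c`, `e`, `omega`,
#' `gamma`, `epsilon`). Missing fields fall back to the defaults of
#' [default_sweep_config()] and [species_params()].
#'
#' @param path JSON file.
#' @return list with elements `sweep` and `params`.
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- default_sweep_config()
  sweep <- def
  for (field in names(def)) {
    if (!is.null(raw[[field]])) sweep[[field]] <- raw[[field]]
  }
  sweep$sizes <- as.integer(sweep$sizes)
  sweep$n_replicates <- as.integer(sweep$n_replicates)
  sweep$seed <- as.integer(sweep$seed)
  pdef <- formals(species_params)
  pargs <- list()
  for (field in setdiff(names(pdef), "D")) {
    if (!is.null(raw$params[[field]])) pargs[[field]] <- raw$params[[field]]
  }
  list(sweep = sweep, params = do.call(species_params, pargs))
}

#' Write sweep results and a run manifest
#'
#' Writes the tidy result tables of [run_sweep()] as CSV files
#' (`replicates.csv`, `reach_replicates.csv`, `removal_replicates.csv`,
#' `network_scale.csv`, `reach_scale.csv`, `sensitivity.csv`) with a fixed
#' column order, plus `manifest.json` recording the configuration
#' snapshot, package version and file list — enough to reproduce the run
#' exactly.
#'
#' @param results list from [run_sweep()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(tab, name) {
    if (is.null(tab) || !nrow(tab)) return(invisible(NULL))
    f <- file.path(out_dir, name)
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE, na = "NA")
    files <<- c(files, name)
  }
  emit(results$replicates$networks, "replicates.csv")
  emit(results$replicates$reaches, "reach_replicates.csv")
  emit(results$replicates$removals, "removal_replicates.csv")
  emit(results$network_scale, "network_scale.csv")
  emit(results$reach_scale, "reach_scale.csv")
  emit(results$sensitivity, "sensitivity.csv")
  manifest <- list(
    package = "riverdci",
    version = as.character(utils::packageVersion("riverdci")),
    config = results$config,
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
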