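#' Sort edges into tie groups by decreasing association strength
#'
#' The percolation sweep admits edges in decreasing order of an ordering key
#' (the raw strength, or its absolute value for signed measures such as
#' correlations). Edges sharing an identical key form one tie group and are
#' admitted as a single step, so results never depend on an arbitrary
#' within-tie order. Key comparison is exact on the parsed values: fuzzy
#' grouping would make results depend on file precision.
#'
#' @param net An [association_network()] or edge data frame.
#' @param rank_by `"value"` (default; decreasing raw strength, matching
#'   positive association statistics) or `"abs_value"` (decreasing
#'   `|strength|`, for signed measures).
#' @return A tibble of edges in admission order with columns `a`, `b`,
#'   `strength`, `key` (the ordering key) and `step` (1-based tie-group
#'   index; keys strictly decrease with `step`).
#' @export
sort_edges <- function(net, rank_by = c("value", "abs_value")) {
  net <- as_association_network(net, "net")
  rank_by <- match.arg(rank_by)
  edges <- net$edges
  key <- if (rank_by == "abs_value") abs(edges$strength) else edges$strength
  ord <- order(-key, edges$a, edges$b, method = "radix")
  edges <- edges[ord, ]
  key <- key[ord]
  edges$key <- key
  edges$step <- if (nrow(edges) == 0) integer() else cumsum(c(TRUE, key[-1] != key[-length(key)]))
  as_tibble(edges)
}

#' Compute the full percolation clustering trajectory of a network
#'
#' Admits edges in decreasing strength order through a union-find merge
#' process. The first admitted edge joins its two nodes as a cluster of size
#' two; each further edge either starts a new pair, absorbs an unclustered
#' node into an existing cluster, merges two clusters, or falls inside one
#' cluster (changing its density and mean strength but not the partition).
#' One trajectory step is recorded per distinct ordering key, giving the
#' complete clustering state at every possible strength cutoff. Nodes not yet
#' touched by an admitted edge are *unclustered* — they are never singleton
#' clusters. Runs in `O(E log E)`, dominated by the sort.
#'
#' @inheritParams sort_edges
#' @return A `percolation` object. Use [tidy()] for the per-step statistics
#'   table, [glance()] for a one-row summary, [subgraphs_at()] /
#'   [subgraphs_at_step()] for the subgraph snapshot at any cutoff,
#'   [optimal_threshold()] for the smallest–largest rule, and [autoplot()]
#'   for the trajectory line plots.
#' @examples
#' edges <- data.frame(
#'   a = c("A", "B", "D", "C", "A"),
#'   b = c("B", "C", "E", "D", "C"),
#'   strength = c(0.9, 0.8, 0.7, 0.5, 0.4)
#' )
#' traj <- percolate(edges)
#' tidy(traj)
#' optimal_threshold(traj)
#' @export
percolate <- function(net, rank_by = c("value", "abs_value")) {
  net <- as_association_network(net, "net")
  rank_by <- match.arg(rank_by)
  edges <- sort_edges(net, rank_by)
  node_ids <- net$nodes$id
  n_nodes <- length(node_ids)

  if (nrow(edges) == 0) {
    edges$kind <- character()
    steps <- tibble(
      step_index = integer(), threshold = double(), edges_added = integer(),
      n_edges = integer(), n_subgraphs = integer(), n_triples = integer(),
      avg_size = double(), avg_density = double(), max_size = integer(),
      n_clustered = integer(), rel_max_size = double()
    )
  } else {
    ai <- match(edges$a, node_ids)
    bi <- match(edges$b, node_ids)
    sw <- percolate_sweep(ai, bi, edges$step, edges$strength, n_nodes)
    edges$kind <- c("new_pair", "absorb", "merge", "intra")[sw$kind]
    ns <- length(sw$cumulative_edges)
    thresholds <- edges$key[!duplicated(edges$step)]
    steps <- tibble(
      step_index = seq_len(ns),
      threshold = thresholds,
      edges_added = sw$edges_added,
      n_edges = sw$cumulative_edges,
      n_subgraphs = sw$n_subgraphs,
      n_triples = sw$n_triples,
      avg_size = sw$n_clustered / sw$n_subgraphs,
      avg_density = sw$sum_density / sw$n_subgraphs,
      max_size = sw$max_size,
      n_clustered = sw$n_clustered,
      rel_max_size = sw$max_size / pmax(1L, sw$n_clustered - sw$max_size)
    )
  }

  structure(
    list(network = net, rank_by = rank_by, edges = edges, steps = steps,
         node_ids = node_ids,
         edge_index = cbind(a = match(edges$a, node_ids),
                            b = match(edges$b, node_ids))),
    class = "percolation"
  )
}

#' @export
print.percolation <- function(x, ...) {
  cat(sprintf("<percolation> %d nodes, %d edges, %d steps (rank_by = %s)\n",
              length(x$node_ids), nrow(x$edges), nrow(x$steps), x$rank_by))
  if (nrow(x$steps) > 0) {
    cat(sprintf("  thresholds: %g (strongest) ... %g (weakest)\n",
                x$steps$threshold[1], x$steps$threshold[nrow(x$steps)]))
    opt <- tryCatch(optimal_threshold(x), error = function(e) NULL)
    if (!is.null(opt)) {
      cat(sprintf("  smallest-largest optimum: threshold %g at step %d\n",
                  opt$threshold, opt$step_index))
    }
  }
  invisible(x)
}

#' Subgraph snapshot after a given trajectory step
#'
#' Reconstructs the partition of clustered nodes into isolated subgraphs
#' after admitting all edges of steps `1..step_index`, together with
#' per-subgraph statistics (size, internal edge count, density, mean
#' strength) and the set of still-unclustered nodes. Subgraphs are numbered
#' by decreasing size, ties broken by smallest member identifier.
#'
#' @param traj A `percolation` object from [percolate()].
#' @param step_index Step number, between 1 and `nrow(traj$steps)`.
#' @return A `subgraph_snapshot`: list with `threshold`, `step_index`,
#'   `subgraphs` (tibble: `subgraph`, `size`, `n_edges`, `density`,
#'   `mean_strength`), `members` (tibble: `id`, `subgraph`) and
#'   `unclustered` (character vector).
#' @export
subgraphs_at_step <- function(traj, step_index) {
  stopifnot(inherits(traj, "percolation"))
  ns <- nrow(traj$steps)
  if (!is.numeric(step_index) || length(step_index) != 1 ||
      is.na(step_index) || step_index < 1 || step_index > ns) {
    abort(sprintf("`step_index` must be a single value in [1, %d]", ns),
          class = "percolink_range_error")
  }
  step_index <- as.integer(step_index)
  build_snapshot(traj, k = traj$steps$n_edges[step_index],
                 threshold = traj$steps$threshold[step_index],
                 step_index = step_index)
}

#' Subgraph snapshot at a strength threshold
#'
#' Includes exactly the edges whose ordering key is `>= threshold` (a closed
#' cutoff): the clustering state "up to the threshold just below" the weakest
#' admitted edge. A threshold above the strongest edge yields an empty
#' snapshot with every node unclustered.
#'
#' @inheritParams subgraphs_at_step
#' @param threshold Strength cutoff on the ordering key (raw strength for
#'   `rank_by = "value"`, `|strength|` for `"abs_value"`).
#' @return A `subgraph_snapshot` (see [subgraphs_at_step()]).
#' @export
subgraphs_at <- function(traj, threshold) {
  stopifnot(inherits(traj, "percolation"), is.numeric(threshold),
            length(threshold) == 1, is.finite(threshold))
  idx <- which(traj$steps$threshold >= threshold)
  if (length(idx) == 0) {
    return(build_snapshot(traj, k = 0L, threshold = threshold, step_index = NA_integer_))
  }
  step_index <- max(idx)
  build_snapshot(traj, k = traj$steps$n_edges[step_index],
                 threshold = threshold, step_index = step_index)
}

build_snapshot <- function(traj, k, threshold, step_index) {
  node_ids <- traj$node_ids
  edges <- traj$edges
  if (k == 0L) {
    return(structure(
      list(threshold = threshold, step_index = step_index,
           rank_by = traj$rank_by,
           subgraphs = tibble(subgraph = integer(), size = integer(),
                              n_edges = integer(), density = double(),
                              mean_strength = double()),
           members = tibble(id = character(), subgraph = integer()),
           unclustered = node_ids),
      class = "subgraph_snapshot"))
  }
  n <- length(node_ids)
  ai <- traj$edge_index[, "a"]
  bi <- traj$edge_index[, "b"]
  lab <- components_upto(ai, bi, k, n)

  clustered_idx <- which(!is.na(lab))      # ascending, so ids already sorted
  comp <- lab[clustered_idx]
  sizes <- tabulate(comp, nbins = n)
  ecomp <- lab[ai[seq_len(k)]]
  m_per <- tabulate(ecomp, nbins = n)
  ssum <- numeric(n)
  agg <- rowsum(edges$strength[seq_len(k)], ecomp)
  ssum[as.integer(rownames(agg))] <- agg[, 1]

  roots <- which(sizes >= 2)
  # subgraphs numbered by decreasing size, ties by smallest member id;
  # node_ids are sorted, so the first occurrence index orders the tie break
  first_idx <- clustered_idx[match(roots, comp)]
  roots <- roots[order(-sizes[roots], first_idx)]
  sgid <- integer(n)
  sgid[roots] <- seq_along(roots)

  subgraphs <- tibble(
    subgraph = seq_along(roots),
    size = sizes[roots],
    n_edges = m_per[roots],
    density = m_per[roots] / (sizes[roots] * (sizes[roots] - 1) / 2),
    mean_strength = ssum[roots] / m_per[roots]
  )
  members <- tibble(id = node_ids[clustered_idx], subgraph = sgid[comp])
  members <- members[order(members$subgraph), ]  # stable: ids stay sorted
  structure(
    list(threshold = threshold, step_index = step_index, rank_by = traj$rank_by,
         subgraphs = subgraphs, members = members,
         unclustered = node_ids[is.na(lab)]),
    class = "subgraph_snapshot")
}

#' @export
print.subgraph_snapshot <- function(x, ...) {
  cat(sprintf("<subgraph_snapshot> threshold %g: %d subgraphs, %d clustered, %d unclustered\n",
              x$threshold, nrow(x$subgraphs), nrow(x$members), length(x$unclustered)))
  if (nrow(x$subgraphs) > 0) print(x$subgraphs, ...)
  invisible(x)
}

#' @describeIn subgraphs_at_step `tidy()` returns the per-subgraph statistics
#'   tibble of a snapshot.
#' @param x A `subgraph_snapshot`.
#' @param ... Unused.
#' @export
tidy.subgraph_snapshot <- function(x, ...) x$subgraphs

#' Per-subgraph statistics for an explicit node set and edge list
#'
#' Density is the number of admitted internal edges relative to the maximum
#' possible among the members, `m / (n (n - 1) / 2)`; mean strength is the
#' unweighted mean of internal edge strengths. The members must form a single
#' connected subgraph of size at least two.
#'
#' @param members Character vector of node identifiers (size >= 2).
#' @param edges Data frame `a`, `b`, `strength` of edges internal to
#'   `members`, connecting them.
#' @return One-row tibble: `size`, `n_edges`, `density`, `mean_strength`.
#' @examples
#' # a 6-cycle: 6 nodes, 6 edges -> density 0.4
#' ring <- data.frame(a = letters[1:6], b = letters[c(2:6, 1)], strength = 1)
#' subgraph_stats(letters[1:6], ring)
#' @export
subgraph_stats <- function(members, edges) {
  members <- as.character(members)
  edges <- as_tibble(edges)
  n <- length(members)
  if (n < 2 || anyDuplicated(members)) {
    abort("`members` must be >= 2 distinct node identifiers",
          class = "percolink_contract_error")
  }
  if (!all(c(edges$a, edges$b) %in% members)) {
    abort("all edges must be internal to `members`",
          class = "percolink_contract_error")
  }
  lab <- components_upto(match(edges$a, members), match(edges$b, members),
                         nrow(edges), n)
  if (any(is.na(lab)) || length(unique(lab)) != 1) {
    abort("`members` are not connected by `edges`",
          class = "percolink_contract_error")
  }
  tibble(size = n, n_edges = nrow(edges),
         density = nrow(edges) / (n * (n - 1) / 2),
         mean_strength = mean(edges$strength))
}
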