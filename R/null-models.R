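#' Random complete network with i.i.d. uniform strengths
#'
#' Admitting the edges of this network in decreasing strength order is
#' exactly the edge-addition view of the Erdos–Renyi random-graph process:
#' after `k` steps the admitted edges are a uniform random `k`-subset of all
#' pairs. This is the naive null model against which structured association
#' networks are compared.
#'
#' @param n Number of nodes (>= 2).
#' @param seed Integer seed; the network is bit-reproducible given the seed.
#' @return An [association_network()] on nodes `v0001, v0002, ...` with all
#'   `n (n - 1) / 2` edges and strengths drawn i.i.d. uniform(0, 1).
#' @export
random_complete_network <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 2) {
    abort("`n` must be a single integer >= 2", class = "percolink_range_error")
  }
  n <- as.integer(n)
  ids <- sprintf("v%0*d", max(4L, nchar(n)), seq_len(n))
  pairs <- complete_pairs(n)
  strengths <- withr::with_seed(seed, runif(nrow(pairs)))
  association_network(
    tibble(a = ids[pairs[, 1]], b = ids[pairs[, 2]], strength = strengths)
  )
}

# all unordered pairs (i < j), upper-triangle column order
complete_pairs <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  cbind(i, j)
}

#' Permute edge strengths, preserving topology
#'
#' A topology-preserving null for sparse networks: the node set and edge
#' pairs are unchanged while the strengths are reassigned by a uniformly
#' random permutation of the original multiset.
#'
#' @param net An [association_network()] or edge data frame.
#' @param seed Integer seed (deterministic given the seed).
#' @return An [association_network()] with permuted strengths.
#' @export
permute_strengths <- function(net, seed) {
  net <- as_association_network(net, "net")
  ne <- nrow(net$edges)
  perm <- withr::with_seed(seed, sample.int(ne))
  net$edges$strength <- net$edges$strength[perm]
  net
}

#' Random-graph phase-transition reference
#'
#' Classifies a (node count, admitted edge count) pair by the three
#' phase regimes of the largest component in a random graph: with `e < n`
#' edges many small subgraphs are expected, the largest of order `log(n)`;
#' at `e = n` still many subgraphs with an expected largest of size
#' `n^(2/3)`; with `e > n` essentially all nodes join one giant subgraph.
#' Real association networks deviate from this — the giant component
#' typically forms well after `e` passes `n` — and that deviation is what
#' the smallest–largest rule exploits.
#'
#' @param n Number of nodes (>= 2).
#' @param e Number of admitted edges (>= 0).
#' @return A one-row tibble: `regime` (`"subcritical"`, `"critical"` or
#'   `"supercritical"`), `n`, `e`, `expected_max_size_scale`.
#' @export
phase_transition_reference <- function(n, e) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 2,
            is.numeric(e), length(e) == 1, e >= 0)
  regime <- if (e < n) "subcritical" else if (e == n) "critical" else "supercritical"
  scale <- switch(regime,
    subcritical = log(n),
    critical = n^(2 / 3),
    supercritical = n
  )
  tibble(regime = regime, n = as.integer(n), e = as.integer(e),
         expected_max_size_scale = scale)
}

#' Percolation statistics of an ensemble of random networks
#'
#' Builds `reps` independent random complete networks (child seeds derived
#' deterministically from `seed`), percolates each, and summarises the
#' largest-subgraph size and its relative size per step across replicates.
#' With continuous i.i.d. strengths every step admits exactly one edge, so
#' step `k` corresponds to cumulative edge count `k` and replicates align by
#' step index; in the measure-zero event of a tie the summary is truncated
#' to the shortest replicate.
#'
#' @param n Nodes per replicate network (>= 2).
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed for the whole ensemble.
#' @param probs Quantile levels summarised per step.
#' @return A `null_ensemble` object: list with `n`, `reps`, `seed` and
#'   `summary`, a tibble with one row per step holding the per-step mean and
#'   quantiles of `max_size` and `rel_max_size` across replicates.
#' @export
null_stats_ensemble <- function(n, reps, seed, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(is.numeric(reps), length(reps) == 1, reps >= 1)
  reps <- as.integer(reps)
  child_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, reps))
  runs <- purrr::map(child_seeds, function(s) {
    tidy(percolate(random_complete_network(n, s)))
  })
  ns <- min(vapply(runs, nrow, integer(1)))
  max_mat <- vapply(runs, function(r) r$max_size[seq_len(ns)], numeric(ns))
  rel_mat <- vapply(runs, function(r) r$rel_max_size[seq_len(ns)], numeric(ns))
  if (ns == 1) {  # vapply drops to vector shape consistency
    max_mat <- matrix(max_mat, nrow = 1)
    rel_mat <- matrix(rel_mat, nrow = 1)
  }
  qnames <- sprintf("q%g", probs * 100)
  qtib <- function(mat, prefix) {
    q <- matrix(apply(mat, 1, quantile, probs = probs, names = FALSE),
                ncol = length(probs), byrow = TRUE)
    out <- tibble(.rows = nrow(mat))
    out[[paste0(prefix, "_mean")]] <- rowMeans(mat)
    for (i in seq_along(probs)) {
      out[[paste0(prefix, "_", qnames[i])]] <- q[, i]
    }
    out
  }
  summary <- dplyr::bind_cols(
    tibble(step_index = seq_len(ns), n_edges = seq_len(ns)),
    qtib(max_mat, "max_size"),
    qtib(rel_mat, "rel_max_size")
  )
  structure(list(n = as.integer(n), reps = reps, seed = seed, summary = summary),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> n = %d, %d replicates, %d aligned steps\n",
              x$n, x$reps, nrow(x$summary)))
  print(head(x$summary), ...)
  invisible(x)
}

#' @describeIn null_stats_ensemble `tidy()` returns the per-step ensemble
#'   summary tibble.
#' @param x A `null_ensemble`.
#' @param ... Unused.
#' @export
tidy.null_ensemble <- function(x, ...) x$summary

#' Planted-partition modular network
#'
#' A synthetic stand-in for the block structure of real association
#' matrices (e.g. groups of mutually comorbid phenotypes): a complete graph
#' on `k_modules * module_size` nodes where within-module strengths are
#' drawn from `Normal(within_mean, sd)` and between-module strengths from
#' `Normal(between_mean, sd)`. With well-separated means the percolation
#' optimum recovers the planted modules exactly. Node metadata records the
#' planted module of each node in the `group` column.
#'
#' @param k_modules Number of planted modules (>= 1).
#' @param module_size Nodes per module (>= 2).
#' @param within_mean,between_mean Mean strength of within- and
#'   between-module edges; `within_mean` must exceed `between_mean`. The
#'   defaults give a ten-standard-deviation separation, a high-signal regime
#'   where recovery at the optimal threshold is essentially certain.
#' @param sd Common strength standard deviation (> 0).
#' @param seed Integer seed (deterministic given the seed).
#' @return An [association_network()] with `group` metadata `m1, m2, ...`.
#' @export
synthetic_modular_network <- function(k_modules, module_size,
                                      within_mean = 10, between_mean = 0,
                                      sd = 1, seed = 1) {
  ok <- is.numeric(k_modules) && k_modules >= 1 &&
    is.numeric(module_size) && module_size >= 2 &&
    is.numeric(within_mean) && is.numeric(between_mean) &&
    within_mean > between_mean && is.numeric(sd) && sd > 0
  if (!ok) {
    abort(paste0("need k_modules >= 1, module_size >= 2, ",
                 "within_mean > between_mean, sd > 0"),
          class = "percolink_range_error")
  }
  k_modules <- as.integer(k_modules)
  module_size <- as.integer(module_size)
  n <- k_modules * module_size
  ids <- sprintf("m%d_n%02d", rep(seq_len(k_modules), each = module_size),
                 rep(seq_len(module_size), k_modules))
  module <- rep(seq_len(k_modules), each = module_size)
  pairs <- complete_pairs(n)
  within <- module[pairs[, 1]] == module[pairs[, 2]]
  mu <- ifelse(within, within_mean, between_mean)
  strengths <- withr::with_seed(seed, rnorm(nrow(pairs), mean = mu, sd = sd))
  association_network(
    tibble(a = ids[pairs[, 1]], b = ids[pairs[, 2]], strength = strengths),
    metadata = tibble(id = ids, label = ids, group = paste0("m", module))
  )
}
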