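#' Per-step trajectory statistics
#'
#' One row per percolation step (distinct strength cutoff), in step order —
#' the table behind the trajectory line plots. Columns: `step_index`,
#' `threshold`, `n_edges` (cumulative admitted edges), `n_subgraphs`,
#' `n_triples` (subgraphs with >= 3 members), `avg_size`, `avg_density`
#' (unweighted mean of per-subgraph densities), `max_size`, `n_clustered`
#' and `rel_max_size` — the size of the largest subgraph relative to the
#' combined size of all other subgraphs, `max_size / max(1, n_clustered -
#' max_size)`; its minimum over the trajectory locates the optimal threshold.
#'
#' @param x A `percolation` object from [percolate()].
#' @param ... Unused.
#' @return A tibble with the columns above, one row per step.
#' @export
tidy.percolation <- function(x, ...) {
  dplyr::select(x$steps, "step_index", "threshold", "n_edges", "n_subgraphs",
                "n_triples", "avg_size", "avg_density", "max_size",
                "n_clustered", "rel_max_size")
}

#' One-row trajectory summary
#'
#' @inheritParams tidy.percolation
#' @return A one-row tibble: node/edge/step counts, `rank_by`, and the
#'   smallest–largest optimum (`NA` when no step has two or more subgraphs).
#' @export
glance.percolation <- function(x, ...) {
  opt <- tryCatch(optimal_threshold(x), error = function(e) NULL)
  tibble(
    n_nodes = length(x$node_ids),
    n_edges = nrow(x$edges),
    n_steps = nrow(x$steps),
    rank_by = x$rank_by,
    optimal_threshold = if (is.null(opt)) NA_real_ else opt$threshold,
    optimal_step = if (is.null(opt)) NA_integer_ else opt$step_index,
    rel_max_size_at_min = if (is.null(opt)) NA_real_ else opt$rel_max_size_at_min
  )
}

#' Smallest–largest optimal threshold
#'
#' In a random graph a giant component forms almost as soon as the number of
#' admitted edges passes the number of nodes; in structured association
#' networks it forms later, once the informative edges are exhausted and
#' further edges arrive essentially at random. The smallest–largest rule
#' places the optimal cutoff just before the giant component starts to form:
#' where the size of the largest subgraph relative to all other subgraphs
#' combined (`rel_max_size`) bottoms out and starts its terminal rise.
#' Operationally the curve is restricted to its maximal non-decreasing
#' suffix — the terminal rise of the giant component; transient balanced
#' dips earlier in the assembly are not giant-component onsets — and the
#' last (lowest-threshold, most inclusive) eligible step attaining the
#' minimum there is returned. For the common declining-then-rising curve
#' this is simply the last global minimiser. Steps with fewer than two
#' subgraphs are ineligible ("largest relative to the others" is undefined
#' with no others).
#'
#' @param x A `percolation` object, or a per-step statistics data frame with
#'   columns `step_index`, `threshold`, `n_subgraphs`, `rel_max_size` (as
#'   produced by [tidy()]).
#' @return An `optimal_threshold` object: list with `threshold`,
#'   `step_index`, `rel_max_size_at_min` and `eligible_steps`.
#' @export
optimal_threshold <- function(x) {
  stats <- if (inherits(x, "percolation")) x$steps else as_tibble(x)
  required <- c("step_index", "threshold", "n_subgraphs", "rel_max_size")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols) > 0) {
    abort(paste0("stats table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "percolink_format_error")
  }
  eligible <- which(stats$n_subgraphs >= 2)
  if (length(eligible) == 0) {
    abort(paste0("no step has two or more subgraphs: the network is too ",
                 "sparse or degenerate for the smallest-largest rule"),
          class = "percolink_selection_error")
  }
  rel <- stats$rel_max_size
  # bottom of the terminal rise: maximal suffix over which the curve never falls
  s0 <- length(rel)
  while (s0 > 1 && rel[s0 - 1] <= rel[s0]) s0 <- s0 - 1
  cand <- eligible[eligible >= s0]
  if (length(cand) == 0) cand <- eligible
  best <- min(rel[cand])
  at <- cand[max(which(rel[cand] == best))]
  structure(
    list(threshold = stats$threshold[at],
         step_index = stats$step_index[at],
         rel_max_size_at_min = best,
         eligible_steps = length(eligible)),
    class = "optimal_threshold")
}

#' @export
print.optimal_threshold <- function(x, ...) {
  cat(sprintf(paste0("<optimal_threshold> threshold %g at step %d ",
                     "(min rel_max_size %g over %d eligible steps)\n"),
              x$threshold, x$step_index, x$rel_max_size_at_min, x$eligible_steps))
  invisible(x)
}

#' @describeIn optimal_threshold `tidy()` returns the selection as a one-row
#'   tibble.
#' @param ... Unused.
#' @export
tidy.optimal_threshold <- function(x, ...) {
  tibble(threshold = x$threshold, step_index = x$step_index,
         rel_max_size_at_min = x$rel_max_size_at_min,
         eligible_steps = x$eligible_steps)
}
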