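#' Export a trajectory as a visualization payload (JSON)
#'
#' Serialises everything an interactive front-end needs to display the
#' clustering dynamics: the annotated node list, the deterministically
#' sorted edge list, the full per-step statistics table, the
#' smallest–largest optimum (when defined) and, optionally, the subgraph
#' snapshot at one threshold. The document conforms to the JSON schema
#' shipped at `system.file("schema", "viz-payload.schema.json", package =
#' "percolink")`; numbers are written at full precision so that reloading
#' the payload and re-deriving the statistics reproduces them exactly.
#'
#' @param traj A `percolation` object from [percolate()].
#' @param file Output path for the JSON document.
#' @param at_threshold Optional strength cutoff; when given, the snapshot at
#'   that threshold is embedded.
#' @return `file`, invisibly.
#' @seealso [read_viz_payload()], [validate_viz_payload()]
#' @export
export_viz_payload <- function(traj, file, at_threshold = NULL) {
  stopifnot(inherits(traj, "percolation"))
  payload <- build_viz_payload(traj, at_threshold)
  validate_viz_payload(payload)
  # digits = I(17): 17 significant digits guarantee doubles survive the trip
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(file)
}

build_viz_payload <- function(traj, at_threshold = NULL) {
  nodes <- traj$network$nodes
  for (col in c("group", "color")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
  }
  nodes <- dplyr::select(nodes, "id", "label", "group", "color",
                         dplyr::everything())
  edges <- dplyr::select(
    dplyr::rename(traj$edges, source = "a", target = "b"),
    "source", "target", "strength")
  opt <- tryCatch(optimal_threshold(traj), error = function(e) NULL)
  payload <- list(
    schema_version = "1.0",
    rank_by = traj$rank_by,
    nodes = nodes,
    edges = edges,
    steps = tidy(traj),
    optimal = if (is.null(opt)) NULL else
      unclass(opt)[c("threshold", "step_index", "rel_max_size_at_min",
                     "eligible_steps")]
  )
  if (!is.null(at_threshold)) {
    snap <- subgraphs_at(traj, at_threshold)
    payload$snapshot <- list(
      threshold = snap$threshold,
      subgraphs = snap$subgraphs,
      members = snap$members,
      unclustered = as.list(snap$unclustered)
    )
  }
  payload
}

#' Reload a visualization payload
#'
#' Parses a payload written by [export_viz_payload()] and reconstructs the
#' association network it describes, so the trajectory and statistics can be
#' re-derived: `percolate(read_viz_payload(f)$network, rank_by)` reproduces
#' the stored `steps` table exactly.
#'
#' @param file Path to a payload JSON document.
#' @return A list with the parsed payload fields (`steps`, `optimal`, ...)
#'   plus `network`, the reconstructed [association_network()].
#' @export
read_viz_payload <- function(file) {
  payload <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  edges <- as_tibble(payload$edges)
  net <- association_network(
    tibble(a = as.character(edges$source), b = as.character(edges$target),
           strength = as.numeric(edges$strength)),
    nodes = as.character(payload$nodes$id),
    metadata = as_tibble(payload$nodes)
  )
  payload$steps <- as_tibble(payload$steps)
  payload$network <- net
  payload
}

#' Structurally validate a visualization payload
#'
#' Checks a payload (an R list, or a path to a JSON file) against the
#' shipped schema's required fields and types: identifier/strength columns
#' in `edges`, the ten statistics columns in `steps`, optimum and snapshot
#' shape when present. Errors on the first violation, returns `TRUE`
#' invisibly otherwise.
#'
#' @param payload A payload list as built by [export_viz_payload()], or a
#'   file path.
#' @return `TRUE`, invisibly.
#' @export
validate_viz_payload <- function(payload) {
  if (is.character(payload) && length(payload) == 1) {
    payload <- jsonlite::fromJSON(payload, simplifyVector = TRUE)
  }
  fail <- function(msg) abort(paste0("invalid viz payload: ", msg),
                              class = "percolink_schema_error")
  need <- c("schema_version", "rank_by", "nodes", "edges", "steps")
  miss <- setdiff(need, names(payload))
  if (length(miss) > 0) fail(paste0("missing field(s) ", paste(miss, collapse = ", ")))
  if (!payload$rank_by %in% c("value", "abs_value")) fail("bad rank_by")
  nodes <- as_tibble(payload$nodes)
  if (!all(c("id", "label") %in% names(nodes))) fail("nodes need id and label")
  edges <- as_tibble(payload$edges)
  if (nrow(edges) > 0) {
    if (!all(c("source", "target", "strength") %in% names(edges))) {
      fail("edges need source, target, strength")
    }
    if (!is.numeric(edges$strength)) fail("non-numeric strengths")
  }
  steps <- as_tibble(payload$steps)
  stat_cols <- c("step_index", "threshold", "n_edges", "n_subgraphs",
                 "n_triples", "avg_size", "avg_density", "max_size",
                 "n_clustered", "rel_max_size")
  miss <- setdiff(stat_cols, names(steps))
  if (nrow(steps) > 0 && length(miss) > 0) {
    fail(paste0("steps missing column(s) ", paste(miss, collapse = ", ")))
  }
  if (!is.null(payload$optimal)) {
    if (!all(c("threshold", "step_index") %in% names(payload$optimal))) {
      fail("optimal needs threshold and step_index")
    }
  }
  if (!is.null(payload$snapshot)) {
    snap <- payload$snapshot
    if (!all(c("threshold", "subgraphs", "members", "unclustered") %in% names(snap))) {
      fail("snapshot needs threshold, subgraphs, members, unclustered")
    }
    sub <- as_tibble(snap$subgraphs)
    sub_cols <- c("subgraph", "size", "n_edges", "density", "mean_strength")
    if (nrow(sub) > 0 && !all(sub_cols %in% names(sub))) {
      fail("snapshot subgraphs columns incomplete")
    }
  }
  invisible(TRUE)
}

#' Write the per-step statistics table as CSV
#'
#' @param x A `percolation` object or its [tidy()] statistics table.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_stats_csv <- function(x, file) {
  stats <- if (inherits(x, "percolation")) tidy(x) else as_tibble(x)
  stats <- dplyr::mutate(stats, dplyr::across(dplyr::where(is.double), fmt_double))
  readr::write_csv(stats, file, progress = FALSE)
  invisible(file)
}

#' Render a static summary report of a trajectory
#'
#' Writes a one-page PDF with the trajectory line plots — threshold, number
#' of subgraphs, triples, average size, average density and relative maximum
#' size versus step — with the smallest–largest optimum marked.
#'
#' @param stats A per-step statistics table ([tidy()] of a `percolation`),
#'   or the `percolation` object itself.
#' @param optimal Optional [optimal_threshold()] result to mark; computed
#'   from `stats` when possible if omitted.
#' @param file Output PDF path.
#' @return `file`, invisibly.
#' @export
render_summary_report <- function(stats, optimal = NULL, file) {
  if (inherits(stats, "percolation")) stats <- tidy(stats)
  stats <- as_tibble(stats)
  if (nrow(stats) == 0) {
    abort("cannot render a report from an empty statistics table",
          class = "percolink_contract_error")
  }
  if (is.null(optimal)) {
    optimal <- tryCatch(optimal_threshold(stats), error = function(e) NULL)
  }
  p <- plot_trajectory_stats(stats, optimal)
  grDevices::pdf(file, width = 8, height = 9, onefile = TRUE, useDingbats = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(file)
}
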