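#' Read an association network from a delimited edge list
#'
#' Reads a CSV/TSV file with a header row and one row per weighted edge. Rows
#' whose strength is missing or non-numeric are dropped with a warning that
#' counts them; exact duplicate pairs are deduplicated with a warning, while
#' duplicate pairs carrying conflicting strengths are an error (silent
#' averaging would hide upstream bugs).
#'
#' @param file Path to a delimited text file (or connection).
#' @param col_names Character vector of length 3 naming the two identifier
#'   columns and the strength column, in that order.
#' @param delim Field delimiter; `NULL` (default) infers `"\t"` for
#'   `.tsv`/`.txt` files and `","` otherwise.
#' @param drop_zeros If `TRUE`, edges with strength exactly 0 are dropped at
#'   ingestion. By default zero-strength edges are kept: zero is information,
#'   absence means "no edge".
#' @param nodes_file Optional path to a companion node table (as written by
#'   [write_edge_list()]): its ids are added to the node set (restoring
#'   isolated nodes) and its remaining columns attached as metadata.
#'
#' @return An [association_network()].
#' @seealso [read_association_matrix()], [write_edge_list()]
#' @export
read_edge_list <- function(file, col_names = c("a", "b", "strength"),
                           delim = NULL, drop_zeros = FALSE,
                           nodes_file = NULL) {
  stopifnot(length(col_names) == 3)
  delim <- delim %||% infer_delim(file)
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing_cols <- setdiff(col_names, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("edge list is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "percolink_format_error")
  }
  edges <- tibble(
    a = raw[[col_names[1]]],
    b = raw[[col_names[2]]],
    strength = suppressWarnings(as.numeric(raw[[col_names[3]]]))
  )
  bad <- !is.finite(edges$strength)
  if (any(bad)) {
    warn(sprintf("dropped %d row(s) with missing or non-numeric strength", sum(bad)))
    edges <- edges[!bad, ]
  }
  if (any(edges$a == edges$b)) {
    loops <- unique(edges$a[edges$a == edges$b])
    abort(paste0("self-loop row(s) for node(s): ", paste(loops, collapse = ", ")),
          class = "percolink_data_error")
  }
  edges <- canonicalise_pairs(edges)
  key <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(key)) {
    split_s <- split(edges$strength, key)
    conflict <- names(split_s)[vapply(split_s, function(s) length(unique(s)) > 1, logical(1))]
    if (length(conflict) > 0) {
      abort(paste0("duplicate pair(s) with conflicting strengths: ",
                   paste(gsub("\r", "--", conflict), collapse = ", ")),
            class = "percolink_data_error")
    }
    warn(sprintf("deduplicated %d exact duplicate edge row(s)", sum(duplicated(key))))
    edges <- edges[!duplicated(key), ]
  }
  if (drop_zeros) edges <- edges[edges$strength != 0, ]
  if (is.null(nodes_file)) return(association_network(edges))
  meta <- readr::read_delim(nodes_file, delim = infer_delim(nodes_file),
                            show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(id = readr::col_character()))
  association_network(edges, nodes = meta$id, metadata = meta)
}

#' Read an association network from a square symmetric matrix
#'
#' The canonical input for phenome-wide association exploration is a square
#' association matrix with identical row and column identifiers. One edge is
#' created per strictly-upper-triangle cell holding a finite value; the
#' diagonal is ignored and empty/`NA`/`NaN` cells produce no edge (missing
#' means "no edge", never "strength 0"). Asymmetric matrices are rejected
#' rather than averaged.
#'
#' @param file Path to a delimited text file whose first column holds row
#'   identifiers and whose header holds column identifiers.
#' @param tolerance Maximum allowed `|m[i,j] - m[j,i]|` before a symmetry
#'   error is raised.
#' @inheritParams read_edge_list
#'
#' @return An [association_network()] whose node set is all header
#'   identifiers (nodes with only missing cells are kept, edgeless).
#' @export
read_association_matrix <- function(file, tolerance = 1e-8, delim = NULL,
                                    drop_zeros = FALSE) {
  delim <- delim %||% infer_delim(file)
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, name_repair = "minimal")
  ids_col <- as.character(raw[[1]])
  ids_row <- names(raw)[-1]
  if (length(ids_col) != length(ids_row)) {
    abort(sprintf("matrix is not square: %d rows vs %d columns",
                  length(ids_col), length(ids_row)),
          class = "percolink_format_error")
  }
  if (!identical(ids_col, ids_row)) {
    abort("row and column identifiers do not match (same names, same order, required)",
          class = "percolink_format_error")
  }
  n <- length(ids_col)
  m <- matrix(suppressWarnings(as.numeric(as.matrix(raw[, -1, drop = FALSE]))),
              nrow = n, ncol = n)
  # NaN counts as missing alongside NA; infinities are rejected
  if (any(is.infinite(m))) {
    abort("matrix contains non-finite strengths (Inf)", class = "percolink_data_error")
  }
  present <- !is.na(m)
  both <- present & t(present)
  mism <- which((present != t(present)) | (both & abs(m - t(m)) > tolerance),
                arr.ind = TRUE)
  mism <- mism[mism[, 1] < mism[, 2], , drop = FALSE]
  if (nrow(mism) > 0) {
    pair <- sprintf("(%s, %s)", ids_col[mism[1, 1]], ids_col[mism[1, 2]])
    abort(paste0("matrix is not symmetric within tolerance at pair ", pair),
          class = "percolink_data_error")
  }
  ut <- which(upper.tri(m) & present, arr.ind = TRUE)
  edges <- tibble(
    a = ids_col[ut[, 1]],
    b = ids_col[ut[, 2]],
    strength = m[ut]
  )
  if (drop_zeros) edges <- edges[edges$strength != 0, ]
  association_network(edges, nodes = ids_col)
}

#' Attach node metadata to an association network
#'
#' @param net An [association_network()] (or edge data frame).
#' @param source A data frame, or path to a CSV/TSV file, with an `id` column
#'   and optional `label`, `group`, `color` columns; any further columns are
#'   carried along as extra annotations. Metadata rows whose id matches no
#'   network node are reported and ignored; nodes without metadata keep the
#'   default `label = id`.
#' @param delim Field delimiter when `source` is a path (inferred by default).
#'
#' @return The network with its `nodes` tibble annotated.
#' @export
attach_metadata <- function(net, source, delim = NULL) {
  net <- as_association_network(net, "net")
  if (is.character(source) && length(source) == 1) {
    delim <- delim %||% infer_delim(source)
    source <- readr::read_delim(source, delim = delim, show_col_types = FALSE,
                                progress = FALSE)
  }
  meta <- as_tibble(source)
  if (!"id" %in% names(meta)) {
    abort("metadata must have an `id` column", class = "percolink_format_error")
  }
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) {
    dup <- unique(meta$id[duplicated(meta$id)])
    abort(paste0("duplicate metadata row(s) for id(s): ", paste(dup, collapse = ", ")),
          class = "percolink_data_error")
  }
  unmatched <- setdiff(meta$id, net$nodes$id)
  if (length(unmatched) > 0) {
    inform(sprintf("ignoring %d metadata row(s) with no matching node: %s",
                   length(unmatched), paste(unmatched, collapse = ", ")))
    meta <- meta[meta$id %in% net$nodes$id, ]
  }
  nodes <- dplyr::left_join(tibble(id = net$nodes$id), meta, by = "id")
  if (!"label" %in% names(nodes)) nodes$label <- NA_character_
  nodes$label <- dplyr::coalesce(as.character(nodes$label), nodes$id)
  nodes <- dplyr::relocate(nodes, "id", "label")
  net$nodes <- nodes
  net
}

#' Write an association network as a delimited edge list
#'
#' Rows are sorted descending by strength, ties broken lexicographically by
#' the identifier pair, so output is deterministic. Reading the file back
#' with [read_edge_list()] reproduces pairs and strengths exactly; isolated
#' nodes (no edges) do not appear in an edge list, so they are written to a
#' companion node file when `nodes_file` is given.
#'
#' @param net An [association_network()] (or edge data frame).
#' @param file Output path; `.tsv`/`.txt` extension writes tab-separated,
#'   anything else comma-separated.
#' @param nodes_file Optional path for the full node table (id + metadata);
#'   required to round-trip networks with isolated nodes.
#' @return `file`, invisibly.
#' @export
write_edge_list <- function(net, file, nodes_file = NULL) {
  net <- as_association_network(net, "net")
  edges <- net$edges[order(-net$edges$strength,
                           net$edges$a, net$edges$b, method = "radix"), ]
  edges$strength <- fmt_double(edges$strength)
  delim <- infer_delim(file)
  readr::write_delim(edges, file, delim = delim, progress = FALSE)
  iso <- setdiff(net$nodes$id, c(edges$a, edges$b))
  if (!is.null(nodes_file)) {
    readr::write_delim(net$nodes, nodes_file, delim = infer_delim(nodes_file),
                       progress = FALSE)
  } else if (length(iso) > 0) {
    inform(sprintf(
      "%d isolated node(s) are not representable in an edge list; supply `nodes_file` to keep them",
      length(iso)))
  }
  invisible(file)
}

# shortest decimal representation that parses back to the identical double
fmt_double <- function(x) {
  out <- sprintf("%.15g", x)
  for (d in 16:17) {
    bad <- as.numeric(out) != x
    if (!any(bad)) break
    out[bad] <- sprintf("%.*g", d, x[bad])
  }
  out
}

infer_delim <- function(file) {
  if (!is.character(file)) return(",")
  if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
}
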