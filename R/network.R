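#' Build an association network from an edge table
#'
#' An association network is an undirected weighted graph whose nodes are
#' variables (genes, phenotypes, topics, ...) and whose edge weights are
#' precomputed pairwise association strengths. This constructor validates the
#' edge table (no self-loops, no duplicate unordered pairs, finite strengths)
#' and canonicalises each pair so that `a` is the lexicographically smaller
#' identifier.
#'
#' @param edges Data frame with columns `a`, `b` (character node identifiers)
#'   and `strength` (finite numeric association strength). Zero is a valid
#'   strength: "no edge" is expressed by absence, never by 0.
#' @param nodes Optional character vector of node identifiers. Defaults to the
#'   identifiers appearing in `edges`; supply it to carry nodes with no edges,
#'   which stay unclustered at every threshold.
#' @param metadata Optional data frame of node annotations with an `id` column
#'   (see [attach_metadata()]).
#'
#' @return An `association_network`: a list with `nodes` (tibble with at least
#'   `id` and `label`) and `edges` (tibble `a`, `b`, `strength`).
#' @examples
#' net <- association_network(data.frame(
#'   a = c("A", "B", "D", "C", "A"),
#'   b = c("B", "C", "E", "D", "C"),
#'   strength = c(0.9, 0.8, 0.7, 0.5, 0.4)
#' ))
#' net
#' @export
association_network <- function(edges, nodes = NULL, metadata = NULL) {
  edges <- as_tibble(edges)
  required <- c("a", "b", "strength")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    abort(paste0("`edges` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "percolink_format_error")
  }
  edges <- dplyr::select(edges, dplyr::all_of(required))
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$strength <- as.numeric(edges$strength)

  if (any(!nzchar(edges$a)) || any(!nzchar(edges$b))) {
    abort("node identifiers must be non-empty strings",
          class = "percolink_data_error")
  }
  if (any(!is.finite(edges$strength))) {
    abort("all edge strengths must be finite (no NA/NaN/Inf)",
          class = "percolink_data_error")
  }
  loops <- edges$a == edges$b
  if (any(loops)) {
    abort(paste0("self-loop edge(s) not allowed: ",
                 paste(unique(edges$a[loops]), collapse = ", ")),
          class = "percolink_data_error")
  }
  edges <- canonicalise_pairs(edges)
  key <- paste(edges$a, edges$b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0("duplicate unordered pair(s): ",
                 paste(gsub("\r", "--", dup), collapse = ", ")),
          class = "percolink_data_error")
  }

  node_ids <- sort(unique(c(edges$a, edges$b, as.character(nodes %||% character()))))
  if (any(!nzchar(node_ids))) {
    abort("node identifiers must be non-empty strings",
          class = "percolink_data_error")
  }
  net <- structure(
    list(nodes = tibble(id = node_ids, label = node_ids), edges = edges),
    class = "association_network"
  )
  if (!is.null(metadata)) net <- attach_metadata(net, metadata)
  net
}

# store each unordered pair with a <= b (C-locale string order)
canonicalise_pairs <- function(edges) {
  swap <- str_gt_c(edges$a, edges$b)
  if (any(swap)) {
    tmp <- edges$a[swap]
    edges$a[swap] <- edges$b[swap]
    edges$b[swap] <- tmp
  }
  edges
}

# locale-independent string comparison (C collation via sort method = "radix")
str_gt_c <- function(x, y) {
  xr <- rank_c_locale(c(x, y))
  n <- length(x)
  xr[seq_len(n)] > xr[n + seq_len(n)]
}

rank_c_locale <- function(x) {
  u <- unique(x)
  ord <- order(u, method = "radix")
  match(x, u[ord])
}

#' @export
print.association_network <- function(x, ...) {
  n_iso <- sum(!x$nodes$id %in% c(x$edges$a, x$edges$b))
  cat(sprintf("<association_network> %d nodes, %d edges (%d isolated nodes)\n",
              nrow(x$nodes), nrow(x$edges), n_iso))
  if (nrow(x$edges) > 0) {
    rng <- range(x$edges$strength)
    cat(sprintf("  strength range: [%g, %g]\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' @export
format.association_network <- function(x, ...) {
  sprintf("<association_network: %d nodes, %d edges>", nrow(x$nodes), nrow(x$edges))
}

is_association_network <- function(x) inherits(x, "association_network")

as_association_network <- function(x, arg = "x") {
  if (is_association_network(x)) return(x)
  if (is.data.frame(x)) return(association_network(x))
  abort(paste0("`", arg, "` must be an association_network or an edge data frame"),
        class = "percolink_format_error")
}
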