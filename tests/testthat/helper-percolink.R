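# Shared fixtures and the independent connected-components oracle.

# hand-traceable 5-node worked example used throughout the suite
w1_edges <- function() {
  tibble::tibble(
    a = c("A", "B", "D", "C", "A"),
    b = c("B", "C", "E", "D", "C"),
    strength = c(0.9, 0.8, 0.7, 0.5, 0.4)
  )
}

w1_network <- function() association_network(w1_edges())

# random Erdos-Renyi-style test network: each pair kept with probability p;
# rounding strengths to few digits forces tie groups
random_test_network <- function(n, p, seed, tie_digits = NULL,
                                signed = FALSE) {
  withr::with_seed(seed, {
    ids <- sprintf("n%03d", seq_len(n))
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    s <- stats::runif(nrow(pairs))
    if (signed) s <- s - 0.5
    if (!is.null(tie_digits)) s <- round(s, tie_digits)
    edges <- tibble::tibble(a = ids[pairs[, 1]], b = ids[pairs[, 2]],
                            strength = s)
    if (!is.null(tie_digits)) {
      edges <- edges[!duplicated(paste(edges$a, edges$b)), ]
    }
    association_network(edges, nodes = ids)
  })
}

# independent oracle: components of the thresholded graph via igraph,
# singleton components are "unclustered", never clusters.
# Returns a membership vector over net$nodes$id (NA = unclustered).
oracle_membership <- function(net, threshold, rank_by = "value") {
  key <- if (rank_by == "abs_value") abs(net$edges$strength) else net$edges$strength
  kept <- which(key >= threshold)
  ids <- net$nodes$id
  ai <- match(net$edges$a[kept], ids)
  bi <- match(net$edges$b[kept], ids)
  g <- igraph::make_graph(as.vector(rbind(ai, bi)), n = length(ids),
                          directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  memb[comp$csize[memb] < 2] <- NA_integer_
  canon_membership(memb)
}

oracle_partition <- function(net, threshold, rank_by = "value") {
  memb <- oracle_membership(net, threshold, rank_by)
  ids <- net$nodes$id
  list(
    partition = canonical_partition(split(ids[!is.na(memb)], memb[!is.na(memb)])),
    unclustered = ids[is.na(memb)]
  )
}

# relabel component ids by first occurrence so two membership vectors over the
# same (sorted) node order describe the same partition iff they are identical
canon_membership <- function(m) {
  m <- as.integer(m)
  match(m, unique(m[!is.na(m)]))
}

snapshot_membership <- function(snap, ids) {
  v <- rep(NA_integer_, length(ids))
  v[match(snap$members$id, ids)] <- snap$members$subgraph
  canon_membership(v)
}

canonical_partition <- function(sets) {
  sets <- unname(lapply(sets, function(m) sort(as.character(m))))
  sets[order(vapply(sets, `[`, character(1), 1))]
}

snapshot_partition <- function(snap) {
  canonical_partition(split(snap$members$id, snap$members$subgraph))
}

expect_matches_oracle <- function(net, traj = percolate(net)) {
  ids <- net$nodes$id
  ok <- TRUE
  for (th in traj$steps$threshold) {
    snap <- subgraphs_at(traj, th)
    got <- snapshot_membership(snap, ids)
    want <- oracle_membership(net, th, traj$rank_by)
    if (!identical(got, want)) {
      ok <- FALSE
      break
    }
  }
  expect_true(ok, label = sprintf(
    "snapshot partitions match the components oracle at every threshold (n=%d, E=%d)",
    length(ids), nrow(net$edges)))
  invisible(ok)
}
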