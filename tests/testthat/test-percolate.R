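test_that("edges sort into strictly decreasing tie groups", {
  s <- sort_edges(w1_network())
  expect_identical(s$step, 1:5)
  expect_identical(s$key, c(0.9, 0.8, 0.7, 0.5, 0.4))

  tied <- association_network(tibble::tibble(
    a = c("A", "C", "E"), b = c("B", "D", "F"), strength = c(0.9, 0.9, 0.5)))
  st <- sort_edges(tied)
  expect_identical(st$step, c(1L, 1L, 2L))
  expect_identical(st$a, c("A", "C", "E"))  # within-tie lexicographic order

  signed <- association_network(tibble::tibble(
    a = c("A", "C"), b = c("B", "D"), strength = c(-0.95, 0.9)))
  expect_identical(sort_edges(signed, "abs_value")$strength, c(-0.95, 0.9))
  expect_identical(sort_edges(signed, "value")$strength, c(0.9, -0.95))
})

test_that("the percolation sweep reproduces the hand-traced merge kinds", {
  traj <- percolate(w1_network())
  expect_identical(traj$edges$kind,
                   c("new_pair", "absorb", "new_pair", "merge", "intra"))
  expect_identical(nrow(traj$steps), 5L)
  expect_identical(traj$steps$threshold, c(0.9, 0.8, 0.7, 0.5, 0.4))
  expect_identical(traj$steps$n_edges, 1:5)

  # tied step: both edges admitted in one step, two new pairs
  tied <- percolate(tibble::tibble(a = c("A", "C"), b = c("B", "D"),
                                   strength = c(0.9, 0.9)))
  expect_identical(nrow(tied$steps), 1L)
  expect_identical(tied$edges$kind, c("new_pair", "new_pair"))
  expect_identical(tied$steps$n_subgraphs, 2L)

  # empty network
  empty <- percolate(association_network(
    tibble::tibble(a = character(), b = character(), strength = double())))
  expect_identical(nrow(empty$steps), 0L)
})

test_that("snapshots at a step match the hand trace", {
  traj <- percolate(w1_network())

  s1 <- subgraphs_at_step(traj, 1)
  expect_identical(snapshot_partition(s1), list(c("A", "B")))
  expect_identical(sort(s1$unclustered), c("C", "D", "E"))

  s3 <- subgraphs_at_step(traj, 3)
  expect_identical(snapshot_partition(s3), list(c("A", "B", "C"), c("D", "E")))
  expect_identical(s3$unclustered, character(0))
  abc <- s3$subgraphs[s3$subgraphs$size == 3, ]
  expect_identical(abc$n_edges, 2L)
  expect_equal(abc$density, 2 / 3)
  expect_equal(abc$mean_strength, 0.85)
  de <- s3$subgraphs[s3$subgraphs$size == 2, ]
  expect_identical(de$density, 1)
  expect_identical(de$mean_strength, 0.7)

  s5 <- subgraphs_at_step(traj, 5)
  expect_identical(s5$subgraphs$size, 5L)
  expect_identical(s5$subgraphs$n_edges, 5L)
  expect_identical(s5$subgraphs$density, 0.5)
  expect_equal(s5$subgraphs$mean_strength, 0.66)

  expect_error(subgraphs_at_step(traj, 0), class = "percolink_range_error")
  expect_error(subgraphs_at_step(traj, 6), class = "percolink_range_error")
})

test_that("threshold snapshots use a closed (key >= t) cutoff", {
  traj <- percolate(w1_network())
  expect_identical(snapshot_partition(subgraphs_at(traj, 0.7)),
                   snapshot_partition(subgraphs_at_step(traj, 3)))
  expect_identical(snapshot_partition(subgraphs_at(traj, 0.75)),
                   list(c("A", "B", "C")))
  above <- subgraphs_at(traj, 1.1)
  expect_identical(nrow(above$subgraphs), 0L)
  expect_identical(sort(above$unclustered), c("A", "B", "C", "D", "E"))
})

test_that("snapshot partitions equal the independent oracle on random networks", {
  for (seed in 1:25) {
    net <- random_test_network(n = sample(4:30, 1), p = stats::runif(1, 0.1, 0.9),
                               seed = seed,
                               tie_digits = if (seed %% 3 == 0) 1L,
                               signed = seed %% 4 == 0)
    rank_by <- if (seed %% 4 == 0) "abs_value" else "value"
    expect_matches_oracle(net, percolate(net, rank_by))
  }
})

test_that("partitions only coarsen and conservation holds along the trajectory", {
  for (seed in c(7, 19, 23)) {
    net <- random_test_network(n = 20, p = 0.4, seed = seed,
                               tie_digits = if (seed == 19) 1L)
    traj <- percolate(net)
    prev <- NULL
    for (k in seq_len(nrow(traj$steps))) {
      snap <- subgraphs_at_step(traj, k)
      # conservation of nodes and edges
      expect_identical(nrow(snap$members) + length(snap$unclustered),
                       nrow(net$nodes))
      expect_identical(sum(snap$subgraphs$n_edges), traj$steps$n_edges[k])
      # every earlier subgraph is contained in exactly one current subgraph
      if (!is.null(prev)) {
        cur_of <- setNames(snap$members$subgraph, snap$members$id)
        for (m in prev) {
          expect_length(unique(cur_of[m]), 1L)
        }
      }
      prev <- snapshot_partition(snap)
    }
  }
})

test_that("results are invariant to input row order and tie order", {
  net <- random_test_network(n = 15, p = 0.6, seed = 11, tie_digits = 1L)
  traj <- percolate(net)
  for (shuffle_seed in 1:5) {
    shuffled <- withr::with_seed(shuffle_seed, {
      e <- net$edges[sample.int(nrow(net$edges)), ]
      # also swap endpoint orientation of a random subset
      flip <- sample(c(TRUE, FALSE), nrow(e), replace = TRUE)
      tibble::tibble(a = ifelse(flip, e$b, e$a), b = ifelse(flip, e$a, e$b),
                     strength = e$strength)
    })
    traj2 <- percolate(association_network(shuffled, nodes = net$nodes$id))
    expect_identical(tidy(traj2), tidy(traj))
    expect_identical(traj2$edges, traj$edges)
  }
})

test_that("isolated nodes stay unclustered at every step", {
  net <- association_network(w1_edges(), nodes = c(LETTERS[1:5], "ZZ"))
  traj <- percolate(net)
  for (k in seq_len(nrow(traj$steps))) {
    expect_true("ZZ" %in% subgraphs_at_step(traj, k)$unclustered)
  }
})
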