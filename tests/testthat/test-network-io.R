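test_that("edge-list reader validates, counts and drops rows as specified", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(w1_edges(), f)
  net <- read_edge_list(f)
  expect_s3_class(net, "association_network")
  expect_identical(sort(net$nodes$id), c("A", "B", "C", "D", "E"))
  expect_identical(nrow(net$edges), 5L)

  # header only -> empty network
  writeLines("a,b,strength", f)
  empty <- read_edge_list(f)
  expect_identical(nrow(empty$nodes), 0L)
  expect_identical(nrow(empty$edges), 0L)

  # non-numeric / missing strengths dropped with a counting warning
  writeLines(c("a,b,strength", "A,B,0.9", "B,C,oops", "C,D,"), f)
  expect_warning(net2 <- read_edge_list(f), "2 row")
  expect_identical(nrow(net2$edges), 1L)

  # self-loop row is a data error
  writeLines(c("a,b,strength", "X,X,1.0"), f)
  expect_error(read_edge_list(f), class = "percolink_data_error")

  # conflicting duplicate pair is a data error (either orientation)
  writeLines(c("a,b,strength", "A,B,0.9", "B,A,0.7"), f)
  expect_error(read_edge_list(f), class = "percolink_data_error")
  # exact duplicate is deduplicated with a warning
  writeLines(c("a,b,strength", "A,B,0.9", "B,A,0.9"), f)
  expect_warning(net3 <- read_edge_list(f), "duplicate")
  expect_identical(nrow(net3$edges), 1L)

  # missing required column names the column
  writeLines(c("a,b,weight", "A,B,0.9"), f)
  expect_error(read_edge_list(f), "strength", class = "percolink_format_error")
  # configurable column names
  expect_identical(
    nrow(read_edge_list(f, col_names = c("a", "b", "weight"))$edges), 1L)
})

test_that("matrix reader takes the upper triangle and enforces symmetry", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,A,B,C",
               "A,1,0.5,0.2",
               "B,0.5,1,NaN",
               "C,0.2,NA,1"), f)
  net <- read_association_matrix(f)
  expect_identical(net$nodes$id, c("A", "B", "C"))
  expect_identical(nrow(net$edges), 2L)
  expect_identical(net$edges$strength[net$edges$a == "A" & net$edges$b == "B"], 0.5)

  # all off-diagonal missing -> nodes but no edges
  writeLines(c("id,A,B,C", "A,1,,", "B,,1,", "C,,,1"), f)
  iso <- read_association_matrix(f)
  expect_identical(nrow(iso$nodes), 3L)
  expect_identical(nrow(iso$edges), 0L)

  # asymmetry beyond tolerance names the pair
  writeLines(c("id,A,B", "A,1,0.5", "B,0.7,1"), f)
  expect_error(read_association_matrix(f, tolerance = 1e-8), "\\(A, B\\)",
               class = "percolink_data_error")
  expect_identical(nrow(read_association_matrix(f, tolerance = 0.5)$edges), 1L)

  # one-sided missing value is also a symmetry violation
  writeLines(c("id,A,B", "A,1,0.5", "B,,1"), f)
  expect_error(read_association_matrix(f), class = "percolink_data_error")

  writeLines(c("id,A,B,C", "A,1,0.5,0.2", "B,0.5,1,0.1"), f)
  expect_error(read_association_matrix(f), "square",
               class = "percolink_format_error")
  writeLines(c("id,A,B", "A,1,0.5", "Z,0.5,1"), f)
  expect_error(read_association_matrix(f), class = "percolink_format_error")
})

test_that("zero strengths are kept by default and droppable at ingest", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,strength", "A,B,0", "B,C,0.5"), f)
  expect_identical(nrow(read_edge_list(f)$edges), 2L)
  expect_identical(nrow(read_edge_list(f, drop_zeros = TRUE)$edges), 1L)
})

test_that("metadata attaches by id, defaults labels and reports strays", {
  net <- association_network(tibble::tibble(a = "A", b = "B", strength = 1))
  meta <- tibble::tibble(id = c("A", "Z"), label = c("alpha", "zeta"),
                         group = c("g1", "g2"))
  expect_message(net2 <- attach_metadata(net, meta), "Z")
  expect_identical(net2$nodes$label[net2$nodes$id == "A"], "alpha")
  expect_identical(net2$nodes$label[net2$nodes$id == "B"], "B")  # defaulted
  expect_identical(net2$nodes$group[net2$nodes$id == "A"], "g1")

  # empty metadata -> all defaulted
  net3 <- attach_metadata(net, tibble::tibble(id = character(), label = character()))
  expect_identical(net3$nodes$label, net3$nodes$id)

  expect_error(attach_metadata(net, tibble::tibble(id = c("A", "A"))),
               class = "percolink_data_error")

  # extra columns are carried along
  net4 <- attach_metadata(net, tibble::tibble(id = "A", phecode = "594.10"))
  expect_identical(net4$nodes$phecode[net4$nodes$id == "A"], "594.10")
})

test_that("edge-list writer sorts deterministically and round-trips exactly", {
  net <- w1_network()
  f <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(net, f)
  lines <- readLines(f)
  expect_length(lines, 6L)  # header + 5 edges
  expect_identical(lines[2], "A,B,0.9")
  expect_identical(lines[6], "A,C,0.4")

  # property: write -> read reproduces pairs and strengths bit-exactly
  for (seed in 1:100) {
    n <- sample(3:25, 1)
    rt_net <- random_test_network(n, p = stats::runif(1, 0.1, 0.9), seed = seed,
                                  tie_digits = if (seed %% 2 == 0) 2L)
    nf <- withr::local_tempfile(fileext = ".csv")
    suppressMessages(write_edge_list(rt_net, f, nodes_file = nf))
    back <- suppressMessages(read_edge_list(f, nodes_file = nf))
    key <- function(e) e[order(e$a, e$b, method = "radix"), ]
    expect_identical(key(back$edges), key(rt_net$edges))
    expect_identical(back$nodes$id, rt_net$nodes$id)
  }
})

test_that("matrix ingestion preserves the sum of finite upper-triangle cells", {
  m <- matrix(NA_real_, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  set.seed(42)
  for (i in 1:4) for (j in (i + 1):5) {
    if (stats::runif(1) < 0.7) m[i, j] <- m[j, i] <- stats::rnorm(1)
  }
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, f, na = "")
  net <- read_association_matrix(f)
  ut <- m[upper.tri(m)]
  expect_identical(sum(net$edges$strength), sum(ut[!is.na(ut)]))
  expect_identical(nrow(net$edges), sum(!is.na(ut)))
})

test_that("network constructor rejects malformed edge tables", {
  expect_error(association_network(data.frame(a = "A", b = "A", strength = 1)),
               class = "percolink_data_error")
  expect_error(
    association_network(data.frame(a = c("A", "B"), b = c("B", "A"),
                                   strength = c(1, 2))),
    class = "percolink_data_error")
  expect_error(association_network(data.frame(a = "A", b = "B", strength = NA)),
               class = "percolink_data_error")
  expect_error(association_network(data.frame(a = "A", b = "B")),
               class = "percolink_format_error")
  # nodes argument keeps edgeless nodes
  net <- association_network(data.frame(a = "A", b = "B", strength = 1),
                             nodes = c("A", "B", "C"))
  expect_identical(nrow(net$nodes), 3L)
})
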