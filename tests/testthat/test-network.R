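write_edge_file <- function(df) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  readr::write_delim(df, f, delim = " ", progress = FALSE)
  f
}

edge_row <- function(a, b, ...) {
  scores <- list(...)
  row <- tibble::tibble(protein1 = a, protein2 = b)
  for (ch in all_interaction_channels()) {
    row[[ch]] <- if (ch %in% names(scores)) as.integer(scores[[ch]]) else 0L
  }
  row$combined_score <- max(0L, unlist(scores))
  row
}

test_that("the channel filter keeps evidence edges and ignores unselected channels", {
  f <- write_edge_file(dplyr::bind_rows(
    edge_row("A", "B", coexpression = 450),
    edge_row("A", "C", textmining = 900),
    edge_row("B", "C", coexpression = 399, experiments = 399)
  ))
  kept <- read_interactions(f)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$node_a, "A")
  expect_equal(kept$node_b, "B")

  # the AND reading requires every selected channel to reach the threshold
  f2 <- write_edge_file(dplyr::bind_rows(
    edge_row("A", "B", coexpression = 450, coexpression_transferred = 500,
             database = 900, database_transferred = 777,
             experiments = 410, experiments_transferred = 402),
    edge_row("A", "C", coexpression = 450, coexpression_transferred = 500,
             database = 900, database_transferred = 777,
             experiments = 410, experiments_transferred = 399)
  ))
  expect_equal(nrow(read_interactions(f2, combine = "all")), 1L)
  expect_equal(nrow(read_interactions(f2, combine = "any")), 2L)

  expect_error(read_interactions(f, channels = c("coexpression", "snail_mail")),
               "Valid channels")
})

test_that("the edge reader accepts arbitrary column order and ignores unknown columns", {
  df <- edge_row("A", "B", experiments = 600)
  df$mystery_channel <- 999L
  df <- df[, rev(names(df))]
  f <- write_edge_file(df)
  kept <- read_interactions(f)
  expect_equal(nrow(kept), 1L)
  expect_false("mystery_channel" %in% names(kept))

  # a selected channel column missing from the file is a format error
  df2 <- edge_row("A", "B", experiments = 600)
  df2$experiments_transferred <- NULL
  expect_error(read_interactions(write_edge_file(df2)), "experiments_transferred")
})

test_that("network induction simplifies edges and keeps the main component", {
  ints <- tibble::tibble(
    node_a = c("A", "B", "C", "X"),
    node_b = c("B", "A", "C", "Y")
  )
  net <- induce_ppi_network(c("A", "B", "C", "D"), ints)
  expect_setequal(network_nodes(net), c("A", "B"))
  expect_equal(nrow(tidy(net)), 1L)

  ints2 <- tibble::tibble(
    node_a = c("A", "B", "C", "D"),
    node_b = c("B", "C", "A", "E")
  )
  net2 <- induce_ppi_network(LETTERS[1:5], ints2)
  expect_setequal(network_nodes(net2), c("A", "B", "C"))

  # gene outside the set never contributes an edge
  net3 <- induce_ppi_network(c("A", "B"), tibble::tibble(
    node_a = c("A", "X"), node_b = c("B", "A")
  ))
  expect_setequal(network_nodes(net3), c("A", "B"))

  # equal-size components: the one holding the smallest symbol wins
  tie <- tibble::tibble(node_a = c("B", "A"), node_b = c("C", "D"))
  net4 <- induce_ppi_network(c("A", "B", "C", "D"), tie)
  expect_setequal(network_nodes(net4), c("A", "D"))

  expect_error(
    induce_ppi_network(c("Q", "R"), ints, sample_id = "P1", condition = "pre"),
    "P1"
  )
})

test_that("centralities match hand-derived values on canonical graphs", {
  path <- centralities_by_index(graph_from_pairs("A", "B", "B", "C"))
  expect_equal(path$degree, c(1L, 2L, 1L))
  expect_equal(path$betweenness, c(0, 1, 0))

  star <- centralities_by_index(graph_from_pairs("c", "l1", "c", "l2", "c", "l3"))
  expect_equal(star$betweenness[star$node == "c"], 3)
  expect_equal(star$eigenvector[star$node == "c"], 1, tolerance = 1e-9)
  expect_equal(star$eigenvector[star$node != "c"], rep(1 / sqrt(3), 3),
               tolerance = 1e-8)

  k3 <- centralities_by_index(graph_from_pairs("A", "B", "B", "C", "C", "A"))
  expect_equal(k3$degree, rep(2L, 3))
  expect_equal(k3$betweenness, rep(0, 3))
  expect_equal(k3$eigenvector, rep(1, 3), tolerance = 1e-9)
})

test_that("centralities agree with independent oracles and igraph on random graphs", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      g <- random_connected_graph(sample(4:10, 1), 0.4)
      ct <- centralities_by_index(g)
      A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
      A <- A[order(rownames(A)), order(colnames(A))]
      expect_equal(ct$betweenness, oracle_betweenness(A), tolerance = 1e-9)
      expect_equal(ct$eigenvector, oracle_eigenvector(A), tolerance = 1e-8)
      # sum of degrees is twice the edge count; leaves never score betweenness
      expect_equal(sum(ct$degree), 2L * igraph::ecount(g))
      expect_true(all(ct$betweenness[ct$degree == 1L] == 0))
      # cross-check against the graph library's implementation
      ig_btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
      expect_equal(ct$betweenness, unname(ig_btw[order(names(ig_btw))]),
                   tolerance = 1e-9)
    }
  })
})

test_that("adding an edge never decreases endpoint degrees", {
  withr::with_seed(5, {
    g <- random_connected_graph(8, 0.3)
    ct <- centralities_by_index(g)
    missing <- which(igraph::as_adjacency_matrix(g, sparse = FALSE) == 0 &
                       upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
    pick <- missing[1, ]
    g2 <- igraph::add_edges(g, c(pick[1], pick[2]))
    ct2 <- centralities_by_index(g2)
    expect_true(all(ct2$degree >= ct$degree))
  })
})

test_that("centrality preconditions are enforced", {
  loopy <- igraph::graph_from_edgelist(matrix(c("A", "A"), ncol = 2), directed = FALSE)
  expect_error(node_centralities(loopy), "simple")
  disconnected <- graph_from_pairs("A", "B", "C", "D")
  expect_error(node_centralities(disconnected), "connected")
})

test_that("HBS classification uses strict above-mean rules and their conjunction", {
  # vertex-transitive graphs have constant centralities: no labels at all
  for (g in list(igraph::make_ring(5), igraph::make_full_graph(4))) {
    h <- classify_hbs(node_centralities(g))
    expect_equal(sum(h$is_hub) + sum(h$is_bottleneck) + sum(h$is_switch), 0L)
    expect_length(hbs_members(h), 0L)
  }

  star <- classify_hbs(node_centralities(
    graph_from_pairs("c", "l1", "c", "l2", "c", "l3")
  ))
  expect_equal(hbs_members(star), "c")
  thr <- attr(star, "thresholds")
  expect_equal(thr$degree, 6 / 4)

  # a node above the degree mean only is a hub but not an HBS
  fake <- tibble::tibble(node = c("a", "b"), degree = c(3L, 1L),
                         betweenness = c(1, 1), eigenvector = c(0.5, 0.5))
  h2 <- classify_hbs(fake)
  expect_true(h2$is_hub[1])
  expect_false(any(h2$is_hbs))

  withr::with_seed(23, {
    for (rep in 1:20) {
      g <- random_connected_graph(sample(5:12, 1))
      h <- classify_hbs(node_centralities(g))
      expect_equal(h$is_hbs, h$is_hub & h$is_bottleneck & h$is_switch)
      expect_lte(sum(h$is_hbs),
                 min(sum(h$is_hub), sum(h$is_bottleneck), sum(h$is_switch)))
    }
  })
})
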