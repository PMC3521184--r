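graph_of <- function(edges, n = NULL, directed = TRUE) {
  igraph::graph_from_data_frame(edges, directed = directed,
    vertices = if (is.null(n)) NULL else data.frame(name = as.character(seq_len(n))))
}

test_that("closed-form graphs pin the centralization and clustering metrics", {
  # undirected star: maximal degree centralization
  star <- igraph::make_star(8, mode = "undirected", center = 1)
  p_star <- metric_panel(star)
  expect_equal(p_star$degree_centralization, 1)

  # complete graph: perfect clustering, zero centralization
  k4 <- igraph::make_full_graph(4, directed = FALSE)
  p_k4 <- metric_panel(k4)
  expect_equal(p_k4$average_clustering, 1)
  expect_equal(p_k4$degree_centralization, 0)
  expect_equal(p_k4$betweenness_centralization, 0)
})

test_that("path-graph distances match brute-force all-pairs enumeration", {
  # directed 5-cycle so strong connectivity holds; distances enumerable
  ring <- igraph::make_ring(5, directed = TRUE)
  p <- metric_panel(ring)
  # brute force: distance i->j along the cycle is (j - i) mod 5
  dists <- c()
  for (i in 0:4) for (j in 0:4) if (i != j) dists <- c(dists, (j - i) %% 5)
  expect_equal(p$average_distance, mean(dists))
  expect_equal(p$maximum_distance, max(dists))
})

test_that("metric panel equals brute-force definitions on random graphs", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    n <- 12
    g <- igraph::sample_gnp(n, 0.25, directed = TRUE)
    p <- metric_panel(g)
    gu <- igraph::as_undirected(g, "collapse")
    A <- as.matrix(igraph::as_adjacency_matrix(gu))
    expect_equal(p$average_degree, mean(rowSums(A)))
    # brute-force local clustering: triangles / possible pairs
    cc <- vapply(seq_len(n), function(v) {
      nb <- which(A[v, ] > 0)
      k <- length(nb)
      if (k < 2) return(0)
      sum(A[nb, nb]) / (k * (k - 1))
    }, numeric(1))
    expect_equal(p$average_clustering, mean(cc), tolerance = 1e-12)
  }
})

test_that("centralization is invariant under node relabeling", {
  withr::local_seed(42)
  g <- igraph::sample_gnp(10, 0.3, directed = TRUE)
  perm <- sample(10)
  g2 <- igraph::permute(g, perm)
  p1 <- metric_panel(g)
  p2 <- metric_panel(g2)
  expect_equal(p2$degree_centralization, p1$degree_centralization)
  expect_equal(p2$betweenness_centralization, p1$betweenness_centralization)
  expect_equal(p2$redundancy, p1$redundancy)
})

test_that("redundancy is zero on trees and 1/3 on the shortcut triangle", {
  tree <- graph_of(data.frame(from = c(1, 1, 2, 2), to = c(2, 3, 4, 5)))
  expect_equal(redundancy_score(tree), 0)
  tri <- graph_of(data.frame(from = c(1, 2, 1), to = c(2, 3, 3)))
  expect_equal(redundancy_score(tri), 1 / 3)
  # scoring an already-reduced graph returns 0 (reduction idempotence)
  path <- graph_of(data.frame(from = 1:4, to = 2:5))
  expect_equal(redundancy_score(path), 0)
  empty <- igraph::make_empty_graph(3)
  expect_equal(redundancy_score(empty), 0)
})

test_that("tiny graphs report zero centralization with the small flag", {
  g <- graph_of(data.frame(from = 1, to = 2))
  p <- metric_panel(g)
  expect_true(p$small_graph)
  expect_equal(p$degree_centralization, 0)
  expect_equal(p$betweenness_centralization, 0)
})

test_that("reaction-graph edges follow product-to-substrate sharing", {
  m <- chain_model()
  g <- build_graph(m, currency_exclusions = character())
  el <- igraph::as_edgelist(g$graph)
  expect_true(any(el[, 1] == "T_a" & el[, 2] == "R1"))   # a_c links them
  expect_true(any(el[, 1] == "R1" & el[, 2] == "R_bio")) # b_c links them
  expect_false(any(el[, 1] == el[, 2]))                  # no self-loops
  # the reversible exchange counts as a producer of its species
  expect_true(any(el[, 1] == "EX_a" & el[, 2] == "T_a"))
})

test_that("the single-cell leaf is denser and less redundant than the two-cell leaf", {
  p3 <- metric_panel(build_graph(make_toy_c3()))
  p4 <- metric_panel(build_graph(make_toy_c4()))
  expect_gt(p3$average_degree, p4$average_degree)
  expect_lt(p3$redundancy, p4$redundancy)
  expect_true(all(c(p3$degree_centralization, p4$degree_centralization,
                    p3$betweenness_centralization,
                    p4$betweenness_centralization) >= 0))
  expect_lte(p3$average_distance, p3$maximum_distance)
  expect_lte(p4$average_distance, p4$maximum_distance)
})
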