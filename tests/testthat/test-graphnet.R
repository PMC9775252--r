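# Binarization and network metrics, cross-checked against brute force.

hand_matrix <- function() {
  m <- matrix(c(1, 0.9, 0.2,
                0.9, 1, 0.73,
                0.2, 0.73, 1), 3, byrow = TRUE,
              dimnames = rep(list(c("a", "b", "c")), 2))
  m
}

test_that("binarize cuts at fraction x off-diagonal maximum, strictly", {
  g <- binarize(hand_matrix(), 0.8)
  expect_equal(g$threshold_used, 0.72)
  expect_true(g$adjacency["a", "b"])     # 0.9  > 0.72
  expect_true(g$adjacency["b", "c"])     # 0.73 > 0.72
  expect_false(g$adjacency["a", "c"])    # 0.2
  expect_false(any(diag(g$adjacency)))
  expect_identical(g$adjacency, t(g$adjacency))

  m <- hand_matrix()
  m["b", "c"] <- m["c", "b"] <- 0.72     # exactly at the cut: excluded
  expect_false(binarize(m, 0.8)$adjacency["b", "c"])
})

test_that("binarize boundary semantics: equal entries and fraction 1", {
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  # fraction < 1: cut sits below the common value, complete graph
  expect_true(all(binarize(m, 0.8)$adjacency[upper.tri(m)]))
  # fraction 1: every entry ties with the maximum and the strict
  # inequality excludes them all -> empty graph
  expect_warning(g1 <- binarize(m, 1), class = "plvnet_empty_graph")
  expect_false(any(g1$adjacency))
  z <- matrix(0, 3, 3); diag(z) <- 1
  expect_warning(gz <- binarize(z, 0.8), class = "plvnet_empty_graph")
  expect_false(any(gz$adjacency))
  expect_error(binarize(hand_matrix(), 0), class = "plvnet_invalid_input")
})

test_that("diagonal handling of the threshold maximum is selectable", {
  m <- hand_matrix()
  expect_equal(binarize(m, 0.8)$threshold_used, 0.8 * 0.9)
  expect_equal(binarize(m, 0.8, diagonal = "include")$threshold_used, 0.8)
})

test_that("clustering coefficient matches hand-computed cases", {
  k5 <- matrix(TRUE, 5, 5); diag(k5) <- FALSE
  expect_equal(clustering_coefficient(k5)$mean_cc, 1)

  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  expect_equal(clustering_coefficient(star)$mean_cc, 0)

  # triangle a-b-c plus pendant d attached to a: (1/4)(1/3 + 1 + 1 + 0)
  tri <- matrix(FALSE, 4, 4)
  tri[1, 2] <- tri[2, 1] <- TRUE
  tri[1, 3] <- tri[3, 1] <- TRUE
  tri[2, 3] <- tri[3, 2] <- TRUE
  tri[1, 4] <- tri[4, 1] <- TRUE
  expect_equal(clustering_coefficient(tri)$mean_cc, 7 / 12)
  expect_equal(unname(clustering_coefficient(tri)$cc), c(1 / 3, 1, 1, 0))
})

test_that("shortest paths and CPL match hand-computed cases", {
  path3 <- matrix(FALSE, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- TRUE
  D <- shortest_path_matrix(path3)
  expect_equal(D[1, 3], 2)
  expect_equal(characteristic_path_length(path3), 4 / 3)

  two_edges <- matrix(FALSE, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- TRUE
  two_edges[3, 4] <- two_edges[4, 3] <- TRUE
  D2 <- shortest_path_matrix(two_edges)
  expect_identical(D2[1, 3], Inf)
  expect_equal(characteristic_path_length(two_edges), 1)  # reachable pairs

  empty <- matrix(FALSE, 3, 3)
  expect_warning(cpl <- characteristic_path_length(empty),
                 class = "plvnet_undefined_cpl")
  expect_true(is.na(cpl))

  kn <- matrix(TRUE, 7, 7); diag(kn) <- FALSE
  expect_equal(characteristic_path_length(kn), 1)
})

test_that("node degrees: star, complete graph, handshake lemma", {
  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  expect_identical(unname(node_degrees(star)), c(4L, 1L, 1L, 1L, 1L))

  k19 <- matrix(TRUE, 19, 19); diag(k19) <- FALSE
  expect_true(all(node_degrees(k19) == 18L))

  set.seed(21)
  for (r in 1:100) {
    a <- random_adjacency(8, runif(1, 0.1, 0.9))
    n_edges <- sum(a[upper.tri(a)])
    expect_identical(sum(node_degrees(a)), as.integer(2 * n_edges))
  }
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(22)
  for (r in 1:60) {
    n <- sample(4:10, 1)
    a <- random_adjacency(n, runif(1, 0.1, 0.9))
    expect_equal(unname(clustering_coefficient(a)$cc), oracle_clustering(a))
    expect_equal(unname(shortest_path_matrix(a)), oracle_floyd_warshall(a))
    got <- suppressWarnings(characteristic_path_length(a))
    expect_equal(got, oracle_cpl(a))
  }
})

test_that("edge sets are nested in the binarization fraction", {
  set.seed(23)
  for (r in 1:25) {
    v <- matrix(runif(19 * 19), 19)
    v <- (v + t(v)) / 2; diag(v) <- 1
    g_high <- binarize(v, 0.8)$adjacency
    g_low <- binarize(v, 0.6)$adjacency
    expect_true(all(g_low[g_high]))  # every 0.8-edge survives at 0.6
  }
})

test_that("metrics are permutation-equivariant", {
  set.seed(24)
  a <- random_adjacency(9, 0.4)
  rownames(a) <- colnames(a) <- paste0("c", 1:9)
  perm <- sample(9)
  b <- a[perm, perm]
  expect_equal(clustering_coefficient(b)$mean_cc,
               clustering_coefficient(a)$mean_cc)
  expect_equal(suppressWarnings(characteristic_path_length(b)),
               suppressWarnings(characteristic_path_length(a)))
  expect_identical(unname(node_degrees(b)), unname(node_degrees(a)[perm]))
})

test_that("network_metrics bundles consistent values", {
  g <- binarize(hand_matrix(), 0.8)
  nm <- network_metrics(g)
  expect_identical(sum(nm$degrees), 2L * as.integer(sum(g$adjacency) / 2))
  expect_equal(nm$mean_cc, clustering_coefficient(g)$mean_cc)
  expect_equal(nm$cpl, suppressWarnings(characteristic_path_length(g)))
  expect_identical(nm$n_nodes, 3L)
})
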