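test_that("node vectors read the matrix rows with self dropped", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.8
  F <- connectivity_matrix(m, c("x", "y", "z"))
  v <- node_vectors(F)
  expect_equal(unname(v), rbind(c(0.2, 0.5), c(0.2, 0.8), c(0.5, 0.8)))
  F6 <- random_connectivity(6, seed = 31)
  v6 <- node_vectors(F6)
  for (i in 1:6) expect_equal(unname(v6[i, ]), unname(F6$values[i, -i]))
})

test_that("agglomeration reproduces a naive from-scratch re-implementation", {
  for (linkage in c("single", "complete", "average")) {
    for (s in 1:25) {
      F <- random_connectivity(6, seed = 1000 + s)
      v <- node_vectors(F)
      got <- agglomerate(v, linkage)$merges
      want <- naive_agglomerate(v, linkage)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("agglomeration agrees with stats::hclust on tie-free data", {
  set.seed(77)
  v <- matrix(rnorm(12 * 5), 12, 5)
  rownames(v) <- paste0("n", 1:12)
  for (linkage in c("single", "complete", "average")) {
    dend <- agglomerate(v, linkage)
    h <- hclust(dist(v), method = linkage)
    expect_equal(dend$merges$height, h$height, tolerance = 1e-10)
    for (Z in c(2, 4, 6)) {
      mine <- cut_dendrogram(dend, Z)$members
      ref <- split(rownames(v), cutree(h, k = Z))
      norm <- function(p) unname(sort(vapply(p, function(g)
        paste(sort(g), collapse = ","), "")))
      expect_identical(norm(mine), norm(ref))
    }
  }
})

test_that("small agglomeration cases behave analytically", {
  v2 <- matrix(c(0, 3), ncol = 1, dimnames = list(c("a", "b"), NULL))
  d2 <- agglomerate(v2)
  expect_equal(nrow(d2$merges), 1L)
  expect_equal(d2$merges$height, 3)
  v3 <- matrix(c(0, 1, 10), ncol = 1,
               dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(agglomerate(v3)$merges$left[1], 1L)
  expect_equal(agglomerate(v3)$merges$right[1], 2L)
})

test_that("single-linkage merge heights are non-decreasing", {
  for (s in 1:10) {
    F <- random_connectivity(8, seed = 300 + s)
    h <- agglomerate(node_vectors(F), "single")$merges$height
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("scaling attributes scales heights but not merge order or classes", {
  F <- random_connectivity(7, seed = 55)
  v <- node_vectors(F)
  a <- 4.2
  d1 <- agglomerate(v)
  d2 <- agglomerate(v * a)
  expect_identical(d1$merges[c("left", "right", "new")],
                   d2$merges[c("left", "right", "new")])
  expect_equal(d2$merges$height, a * d1$merges$height, tolerance = 1e-10)
  expect_identical(assign_classes(d1, 4)$labels,
                   assign_classes(d2, 4)$labels)
})

test_that("cutting undoes the last Z - 1 merges", {
  dend <- agglomerate(chain_instance())
  expect_length(cut_dendrogram(dend, 1)$members, 1L)
  expect_length(cut_dendrogram(dend, 5)$members, 5L)
  cut4 <- cut_dendrogram(dend, 4)
  expect_setequal(cut4$cluster_ids, c("6", "3", "4", "5"))
  expect_setequal(cut4$members[["6"]], c("N1", "N2"))
  expect_error(cut_dendrogram(dend, 0), "between")
  expect_error(cut_dendrogram(dend, 6), "between")
})

test_that("merge-order classes rank clusters by absorption step", {
  # chain dendrogram: the cluster merged below the cut is absorbed first
  # (with its partner) and the most remote leaf is absorbed last
  dend <- agglomerate(chain_instance())
  a <- assign_classes(dend, 4)
  expect_identical(a$clusters$class[match(c(6, 3, 4, 5),
                                          a$clusters$cluster_id)],
                   1:4)
  expect_identical(unname(a$labels),
                   c(1L, 1L, 2L, 3L, 4L))
  expect_identical(sort(unique(a$clusters$class)), 1:4)
  a1 <- assign_classes(dend, 1)
  expect_true(all(a1$labels == 1L))
  aN <- assign_classes(dend, 5)
  expect_identical(sort(unique(unname(aN$labels))), 1:5)
})

test_that("clustering is invariant to the presentation order of the node vectors", {
  # reordering the rows of the attribute matrix (the attribute space itself
  # unchanged) leaves inter-node distances, the cut partition and each
  # cluster's absorption step untouched; classes of clusters with a unique
  # absorption step are identical, while clusters absorbed at the same step
  # (they merge with each other) are ranked by the lowest row index, which
  # legitimately follows the presentation order
  F <- random_connectivity(8, seed = 91)
  v <- node_vectors(F)
  dend <- agglomerate(v)
  a <- assign_classes(dend, 4)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  dendp <- agglomerate(v[perm, , drop = FALSE])
  ap <- assign_classes(dendp, 4)
  part <- function(asg) sort(vapply(split(names(asg$labels), asg$labels),
                                    function(g) paste(sort(g), collapse = ","),
                                    ""))
  expect_identical(unname(part(ap)), unname(part(a)))
  step_of <- function(asg) {
    s <- setNames(asg$clusters$absorbed_step,
                  asg$clusters$class)[as.character(asg$labels)]
    setNames(as.integer(s), names(asg$labels))
  }
  expect_identical(step_of(ap)[F$labels], step_of(a)[F$labels])
})

test_that("class trajectories stack assignments in canonical node order", {
  F <- random_connectivity(6, seed = 17)
  a <- assign_classes(agglomerate(node_vectors(F)), 3)
  tr <- class_trajectory(list(a, a, a))
  expect_identical(dim(tr), c(6L, 3L))
  expect_true(all(tr[, 1] == tr[, 2] & tr[, 2] == tr[, 3]))
  tr1 <- class_trajectory(list(a))
  expect_identical(unname(tr1[, 1]), unname(a$labels))
  b <- assign_classes(agglomerate(node_vectors(
    random_connectivity(6, seed = 18, labels = paste0("W", 1:6)))), 3)
  expect_error(class_trajectory(list(a, b)), "node set")
})

test_that("louvain recovers two disconnected cliques with Q = 0.5", {
  m <- matrix(0, 10, 10)
  m[1:5, 1:5] <- 1
  m[6:10, 6:10] <- 1
  diag(m) <- 0
  F <- connectivity_matrix(m, paste0("V", 1:10))
  res <- louvain_communities(F, seed = 5)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_identical(unname(res$membership), rep(1:2, each = 5))
})

test_that("any single-community partition of a uniform complete graph has Q = 0", {
  m <- matrix(0.6, 8, 8); diag(m) <- 0
  F <- connectivity_matrix(m, paste0("V", 1:8))
  expect_equal(modularity_q(F, rep(1L, 8)), 0, tolerance = 1e-12)
})

test_that("reported modularity matches brute-force evaluation", {
  for (s in 1:10) {
    F <- random_connectivity(9, seed = 400 + s)
    res <- louvain_communities(F, seed = s)
    expect_equal(res$Q, brute_modularity(F$values, res$membership),
                 tolerance = 1e-12)
    expect_equal(modularity_q(F, res$membership),
                 brute_modularity(F$values, res$membership),
                 tolerance = 1e-12)
  }
})

test_that("modularity agrees with igraph on the same partition", {
  F <- random_connectivity(10, seed = 23)
  res <- louvain_communities(F, seed = 2)
  g <- igraph::graph_from_adjacency_matrix(F$values, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(res$Q,
               igraph::modularity(g, res$membership,
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-10)
})

test_that("louvain is deterministic given a seed and handles empty graphs", {
  F <- random_connectivity(12, seed = 62)
  r1 <- louvain_communities(F, seed = 9)
  r2 <- louvain_communities(F, seed = 9)
  expect_identical(r1, r2)
  z <- connectivity_matrix(matrix(0, 4, 4), paste0("V", 1:4))
  rz <- louvain_communities(z, seed = 1)
  expect_identical(unname(rz$membership), rep(1L, 4))
  expect_identical(rz$Q, 0)
})
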