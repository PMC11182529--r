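# Common-neighbor subgraphs, virtual node, adjacency normalization.

test_that("hhop_neighbors follows shortest-path hops", {
  p4 <- toy_net("a-b", "b-c", "c-d")
  expect_identical(hhop_neighbors(p4, "a", 1), "b")
  expect_setequal(hhop_neighbors(p4, "a", 2), c("b", "c"))
  expect_error(hhop_neighbors(p4, "zz", 1), class = "ddigcl_lookup_error")
})

test_that("hhop_neighbors equals a BFS oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:10) {
    n <- 50
    g <- igraph::sample_gnp(n, 0.06)
    el <- igraph::as_edgelist(g)
    ids <- as.character(seq_len(n))
    net <- ddi_network(ids[el[, 1]], ids[el[, 2]], nodes = ids)
    d <- igraph::distances(g)
    for (H in 1:2) {
      v <- sample(n, 1)
      want <- ids[which(d[v, ] >= 1 & d[v, ] <= H)]
      expect_setequal(hhop_neighbors(net, ids[v], H), want)
    }
  }
})

test_that("sample_common_subgraph induces the right nodes and edges", {
  fp <- matrix(rep(0:1, length.out = 166 * 4), 4, 166, byrow = TRUE,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  net <- toy_net("a-b", "a-c", "b-c", "c-d")  # triangle abc plus c-d
  sg <- sample_common_subgraph(net, "a", "b", fp, H = 1)
  expect_identical(sg$node_ids, c("a", "b", "c", "<virtual>"))
  A <- sg$adjacency
  expect_equal(A[1, 2], 0)  # target edge excluded
  expect_equal(A[1, 3], 1)  # a-c
  expect_equal(A[2, 3], 1)  # b-c
  expect_true(all(A[4, 1:3] == 1) && A[4, 4] == 0)  # virtual fully connected
  # with the flag off, the target edge is kept
  sg2 <- sample_common_subgraph(net, "a", "b", fp, H = 1,
                                exclude_target_edge = FALSE)
  expect_equal(sg2$adjacency[1, 2], 1)
  # virtual feature is the mean of the others
  expect_equal(sg$features[4, ], colMeans(fp[c("a", "b", "c"), ]))
})

test_that("pairs without common neighbors reduce to the two endpoints", {
  fp <- matrix(0.5, 4, 166, dimnames = list(c("a", "b", "c", "d"), NULL))
  net <- toy_net("a-b", "c-d")
  sg <- sample_common_subgraph(net, "a", "d", fp, H = 2)
  expect_identical(sg$node_ids, c("a", "d", "<virtual>"))
  expect_true(all(sg$adjacency[1:2, 1:2] == 0))
  # drugs absent from the network are treated as isolated
  fp2 <- rbind(fp, zz = rep(1, 166))
  sg2 <- sample_common_subgraph(net, "a", "zz", fp2, H = 2)
  expect_identical(sg2$node_ids, c("a", "zz", "<virtual>"))
  expect_error(sample_common_subgraph(net, "a", "a", fp),
               class = "ddigcl_input_error")
  expect_error(sample_common_subgraph(net, "a", "nofp", fp),
               class = "ddigcl_featurization_error")
})

test_that("add_virtual_node appends a fully connected mean-feature node", {
  x <- matrix(1:5, 1)
  one <- add_virtual_node(x, matrix(0, 1, 1))
  expect_equal(one$features[2, ], as.numeric(x))
  xy <- matrix(c(1, 0, 0, 2), 2)
  two <- add_virtual_node(xy, matrix(c(0, 1, 1, 0), 2))
  expect_equal(two$features[3, ], colMeans(xy))
  set.seed(4)
  f5 <- matrix(rnorm(10), 5)
  out <- add_virtual_node(f5, random_adj(5))
  expect_equal(sum(out$adjacency[6, ]), 5)
  expect_equal(out$adjacency[6, 6], 0)
  expect_equal(out$adjacency, t(out$adjacency))
  expect_error(add_virtual_node(matrix(0, 0, 3), matrix(0, 0, 0)),
               class = "ddigcl_degenerate_error")
})

test_that("normalize_adjacency matches hand values and is contractive", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalize_adjacency(matrix(c(0, 1, 1, 0), 2)),
               matrix(0.5, 2, 2))
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2)),
               class = "ddigcl_contract_error")
  expect_error(normalize_adjacency(diag(2)), class = "ddigcl_contract_error")
  set.seed(7)
  for (rep in 1:10) {
    A <- random_adj(sample(2:15, 1))
    Ah <- normalize_adjacency(A)
    expect_equal(Ah, t(Ah))
    expect_lte(max(abs(eigen(Ah, symmetric = TRUE,
                             only.values = TRUE)$values)), 1 + 1e-12)
  }
})

test_that("anti-leakage: no-common-neighbor subgraphs hide the label", {
  # an edge pair and a non-edge pair, both without common neighbors, give
  # identical adjacency structure when the target edge is excluded
  fp <- matrix(0.5, 4, 166, dimnames = list(c("a", "b", "c", "d"), NULL))
  net <- toy_net("a-b", "c-a")  # a-b is an edge; b-d is not
  sg_edge <- sample_common_subgraph(net, "a", "b", fp, H = 1)
  sg_non <- sample_common_subgraph(net, "b", "d", fp, H = 1)
  expect_equal(dim(sg_edge$adjacency), dim(sg_non$adjacency))
  expect_equal(sg_edge$adjacency, sg_non$adjacency)
})

test_that("subgraph export writes the virtual sentinel", {
  fp <- matrix(0.5, 3, 166, dimnames = list(c("a", "b", "c"), NULL))
  net <- toy_net("a-b", "a-c", "b-c")
  sg <- sample_common_subgraph(net, "a", "b", fp, H = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_subgraph(sg, f)
  txt <- readLines(f)
  expect_true(any(grepl("<virtual>", txt)))
})
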