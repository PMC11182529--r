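# Synthetic world: valid class-structured SMILES, block-model network with
# substructure coupling, deterministic fixtures, planted signal.

test_that("drug libraries are parseable, class-balanced and seed-stable", {
  spec <- synth_spec(n_drugs = 10L, n_classes = 2L, seed = 5)
  lib <- generate_drug_library(spec)
  expect_equal(nrow(lib), 10L)
  expect_equal(unname(table(lib$class)), array(c(5L, 5L)))
  expect_false(anyDuplicated(lib$smiles) > 0)
  mols <- featurize_drugs(lib)      # all SMILES parse
  expect_length(mols$dropped, 0L)
  lib2 <- generate_drug_library(synth_spec(n_drugs = 10L, n_classes = 2L,
                                           seed = 5))
  expect_identical(lib, lib2)
  expect_error(synth_spec(n_classes = 1L), class = "ddigcl_spec_error")
  expect_error(synth_spec(p_in = 0.1, p_out = 0.2),
               class = "ddigcl_spec_error")
})

test_that("generated SMILES round-trip through canonicalization", {
  fx <- get_fixture("tiny")
  canon <- vapply(fx$mols$graphs, `[[`, "", "canonical")
  tab <- data.frame(drug_id = names(canon), smiles = unname(canon))
  mols2 <- featurize_drugs(tab)
  expect_length(mols2$dropped, 0L)
  canon2 <- vapply(mols2$graphs, `[[`, "", "canonical")
  expect_identical(unname(canon2), unname(canon))
})

test_that("pure block model hits its designated structure", {
  spec <- synth_spec(n_drugs = 20L, n_classes = 2L, p_in = 1, p_out = 1e-9,
                     interact_pairs = list(c(1L, 2L)),
                     structure_coupling = FALSE, seed = 6)
  lib <- generate_drug_library(spec)
  net <- generate_network(lib, spec)
  # complete bipartite between the two classes: 10 x 10 edges
  expect_equal(nrow(net$edges), 100L)
  cls <- setNames(lib$class, lib$drug_id)
  expect_true(all(cls[net$nodes[net$edges[, "i"]]] !=
                    cls[net$nodes[net$edges[, "j"]]]))
  # p_in = p_out: expected edge count p * C(n,2) within 3 binomial sd
  spec2 <- synth_spec(n_drugs = 60L, n_classes = 3L, p_in = 0.2001,
                      p_out = 0.2, structure_coupling = FALSE, seed = 7)
  lib2 <- generate_drug_library(spec2)
  net2 <- generate_network(lib2, spec2)
  npairs <- choose(60, 2)
  expect_lt(abs(nrow(net2$edges) - 0.2 * npairs),
            3 * sqrt(npairs * 0.2 * 0.8) + 1)
  expect_identical(edge_df(generate_network(lib2, spec2)), edge_df(net2))
})

test_that("coupled generator calibrates the marginal density", {
  fx <- get_fixture("default")
  n_int_pairs <- 4 * choose(100, 2)
  n_cross <- choose(400, 2) - n_int_pairs
  expected <- 0.3 * n_int_pairs + 0.02 * n_cross
  # calibration holds the block-model marginal within ~10%
  expect_lt(abs(nrow(fx$net$edges) - expected) / expected, 0.1)
  # no edge joins drugs without shared substituents
  S <- as.matrix(fx$lib[, grep("^sub_", names(fx$lib))])
  shared <- S[match(edge_df(fx$net)$a, fx$lib$drug_id), ] *
    S[match(edge_df(fx$net)$b, fx$lib$drug_id), ]
  expect_true(all(rowSums(shared) >= 1))
})

test_that("fixtures regenerate byte-identically on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture("tiny", d1)
  p2 <- make_fixture("tiny", d2)
  expect_equal(length(readLines(p1["drugs"])), 20L)
  for (k in c("edges", "drugs", "manifest")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  man <- jsonlite::fromJSON(p1[["manifest"]])
  expect_equal(man$n_drugs, 20L)
  expect_equal(man$spec$p_in, 0.3)
  suppressMessages({
    net <- read_network(p1[["edges"]])
  })
  expect_equal(nrow(net$edges), man$n_edges)
})

test_that("a linear probe recovers drug classes from fingerprints", {
  spec <- synth_spec(n_drugs = 200L, n_classes = 2L, seed = 9)
  lib <- generate_drug_library(spec)
  mols <- featurize_drugs(lib)
  X <- mols$fp[lib$drug_id, ]
  y <- factor(lib$class)
  set.seed(9)
  tr <- sample(200, 140)
  fit <- glmnet::glmnet(X[tr, ], y[tr], family = "binomial", alpha = 0,
                        lambda = 1e-2)
  pred <- drop(predict(fit, X[-tr, ], type = "class"))
  expect_gte(mean(pred == as.character(y[-tr])), 0.9)
})

test_that("both views carry planted signal (baseline AUCs)", {
  fx <- get_fixture("default")
  samples <- make_pair_dataset(fx$net, seed = 50)
  split <- random_split(samples, seed = 50)
  te <- split$test
  # topology-only baseline: common-neighbor counts on the training network
  net_tr <- ddigcl:::training_network(split, fx$mols$ids)
  pos_of <- function(d) match(d, net_tr$nodes)
  cn <- mapply(function(a, b) {
    length(intersect(net_tr$adj[[pos_of(a)]], net_tr$adj[[pos_of(b)]]))
  }, te$drug_i, te$drug_j)
  set.seed(50)
  expect_gte(binary_metrics(cn + runif(length(cn)) * 1e-6, te$label)$auc,
             0.7)
  # structure-only baseline: logistic regression on pair fingerprints
  tr <- split$train
  pair_x <- function(df) {
    cbind(fx$mols$fp[df$drug_i, ], fx$mols$fp[df$drug_j, ],
          fx$mols$fp[df$drug_i, ] * fx$mols$fp[df$drug_j, ])
  }
  fit <- glmnet::glmnet(pair_x(tr), factor(tr$label), family = "binomial",
                        alpha = 0, lambda = 1e-3)
  p <- drop(predict(fit, pair_x(te), type = "response"))
  expect_gte(binary_metrics(p, te$label)$auc, 0.7)
})
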