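# Fusion head, loss arithmetic, training loop behaviour, checkpointing.

test_that("fuse_features builds the 4-block concatenation", {
  v <- c(0.5, -1, 2)
  blocks <- fuse_features(matrix(v, 1), matrix(v, 1))
  expect_equal(drop(blocks), c(2 * v, v^2, v, v))
  z <- matrix(0, 1, 4)
  expect_equal(drop(fuse_features(z, z)), rep(0, 16))
  expect_error(fuse_features(matrix(0, 1, 3), matrix(0, 1, 4)),
               class = "ddigcl_shape_error")
})

test_that("swapping the views permutes only the last two fusion blocks", {
  set.seed(6)
  e <- 5L
  a <- matrix(rnorm(3 * e), 3)
  b <- matrix(rnorm(3 * e), 3)
  fab <- fuse_features(a, b)
  fba <- fuse_features(b, a)
  expect_equal(fab[, 1:(2 * e)], fba[, 1:(2 * e)])        # sum and product
  expect_equal(fab[, 2 * e + 1:e], fba[, 3 * e + 1:e])    # blocks 3/4 swap
  # a head whose weights tie the last two blocks is swap-invariant
  par <- ddigcl:::new_mlp(4L * e, 8L)
  par$W1[3 * e + 1:e, ] <- par$W1[2 * e + 1:e, ]
  expect_equal(ddigcl:::mlp_forward(par, fab)$p,
               ddigcl:::mlp_forward(par, fba)$p)
})

test_that("MLP heads output calibrated probabilities", {
  set.seed(2)
  par <- ddigcl:::new_mlp(16, 8)
  X <- matrix(rnorm(5 * 16), 5)
  p <- ddigcl:::mlp_forward(par, X)$p
  expect_true(all(p > 0 & p < 1))
  # zeroed final layer -> logit 0 -> probability exactly 0.5
  par0 <- par
  par0$W2[] <- 0
  par0$b2[] <- 0
  expect_equal(ddigcl:::mlp_forward(par0, X)$p, rep(0.5, 5))
  # batch order preserved
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(ddigcl:::mlp_forward(par, X[perm, ])$p, p[perm])
})

test_that("binary cross-entropy matches hand evaluations", {
  expect_equal(binary_cross_entropy(rep(0.5, 7), rep(c(0, 1), length.out = 7)),
               log(2))
  expect_equal(binary_cross_entropy(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_lt(abs(binary_cross_entropy(c(0.9, 0.2), c(1, 0)) - 0.1643), 1e-4)
  expect_lt(binary_cross_entropy(c(1, 0), c(1, 0)), 1e-5)  # p -> y
  expect_error(binary_cross_entropy(c(0.5, 0.5), 1),
               class = "ddigcl_input_error")
})

test_that("total_loss is the weighted four-term sum", {
  expect_equal(total_loss(1, 1, 1, 1), 3.1)
  w0 <- list(alpha = 0, beta = 1, lambda = 1, eta = 1)
  expect_equal(total_loss(99, 1, 2, 3, w0), 6)  # contrastive ablated
  set.seed(8)
  for (rep in 1:20) {
    ls <- runif(4)
    w <- as.list(runif(4))
    names(w) <- c("alpha", "beta", "lambda", "eta")
    expect_equal(total_loss(ls[1], ls[2], ls[3], ls[4], w),
                 sum(unlist(w) * ls))
  }
  expect_error(total_loss(1, 1, 1, 1, list(alpha = -1, beta = 1,
                                           lambda = 1, eta = 1)),
               class = "ddigcl_config_error")
})

test_that("training reduces the objective and is seed-reproducible", {
  sm <- get_small_views()
  cfg <- modifyList(sm$cfg, list(epochs = 6L))  # views are epoch-agnostic
  m1 <- ddigcl:::train_model_on_views(sm$views, sm$mols, cfg, seed = 42)
  l <- m1$history$l_total
  expect_true(all(diff(l[1:5]) < 0))  # strictly decreasing early on
  m2 <- ddigcl:::train_model_on_views(sm$views, sm$mols, cfg, seed = 42)
  expect_identical(m1$history$l_total[1], m2$history$l_total[1])
  expect_identical(m1$history, m2$history)
  m3 <- ddigcl:::train_model_on_views(sm$views, sm$mols, cfg, seed = 43)
  expect_false(identical(m1$history$l_total[1], m3$history$l_total[1]))
})

test_that("with alpha=beta=lambda=0 the objective is the joint trace", {
  sm <- get_small_views()
  cfg <- modifyList(sm$cfg, list(alpha = 0, beta = 0, lambda = 0,
                                 epochs = 2L))
  m <- ddigcl:::train_model_on_views(sm$views, sm$mols, cfg, seed = 1)
  expect_equal(m$history$l_total, m$history$l_joint, tolerance = 1e-7)
})

test_that("empty or degenerate training inputs error cleanly", {
  fx <- get_fixture("tiny")
  samples <- make_pair_dataset(fx$net, seed = 1)
  sp <- random_split(samples, seed = 1)
  sp$train <- sp$train[0, ]
  expect_error(ddi_train(sp, fx$mols), class = "ddigcl_input_error")
  sp2 <- random_split(samples, seed = 1)
  expect_error(ddi_train(sp2, fx$mols, default_config(epochs = 0L)),
               class = "ddigcl_config_error")
  expect_error(ddi_train(sp2, fx$mols, default_config(batch_size = 1L)),
               class = "ddigcl_config_error")
})

test_that("checkpoints round-trip to identical predictions", {
  fx <- get_fixture("tiny")
  samples <- make_pair_dataset(fx$net, seed = 2)
  split <- random_split(samples, seed = 2)
  cfg <- default_config(epochs = 2L, hop_count = 1L, batch_size = 16L)
  m <- ddi_train(split, fx$mols, cfg, seed = 5)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  p1 <- predict(m, split$test, fx$mols)
  p2 <- predict(m2, split$test, fx$mols)
  expect_identical(p1, p2)
  # history logs all four losses and validation metrics per epoch
  expect_named(m$history,
               c("epoch", "l_total", "l_contr", "l_const", "l_sub",
                 "l_joint", "val_auc", "val_aupr", "val_f1"))
  expect_equal(nrow(m$history), 2L)
})

test_that("weight sharing: identical molecules give identical halves", {
  # two distinct ids with the same SMILES: after training steps the two
  # branches must still produce identical readouts (same shared weights)
  tab <- data.frame(drug_id = c("x1", "x2", "y1", "z1"),
                    smiles = c("CCOC(=O)c1ccccc1", "CCOC(=O)c1ccccc1",
                               "CCCCCCN", "C1CCCCC1O"))
  mols <- featurize_drugs(tab)
  net <- toy_net("x1-y1", "x2-z1", "y1-z1")
  samples <- make_pair_dataset(net, seed = 3)
  split <- random_split(samples, c(0.5, 0.25, 0.25), seed = 3)
  cfg <- default_config(epochs = 2L, batch_size = 4L, hop_count = 1L)
  m <- ddi_train(split, mols, cfg, seed = 1)
  pair <- data.frame(drug_i = "x1", drug_j = "x2", label = 0L)
  cfg_m <- modifyList(m$config, list(use_subgraph = FALSE))
  b <- ddigcl:::build_batch(1L, pair, NULL, ddigcl:::mol_view_cache(mols),
                            mols, cfg_m)
  fw <- ddigcl:::model_forward(m$params, b, cfg_m)
  e <- ncol(fw$Z_C) / 2
  # Z_C = [readout(x2) || readout(x1)]; identical molecules through the
  # shared (post-update) weights give identical halves
  expect_equal(fw$Z_C[, 1:e], fw$Z_C[, e + 1:e])
  pr <- predict(m, pair, mols)  # smoke: full predict path works
  expect_true(pr$p_ct > 0 && pr$p_ct < 1)
})

test_that("pair order covariance: swapping drugs swaps the halves", {
  fx <- get_fixture("tiny")
  mols <- fx$mols
  cfg <- default_config()
  set.seed(12)
  params <- ddigcl:::init_params(cfg)
  mcache <- ddigcl:::mol_view_cache(mols)
  ids <- mols$ids[1:4]
  mk <- function(i, j) {
    s <- data.frame(drug_i = i, drug_j = j, label = 0L)
    b <- ddigcl:::build_batch(1L, s, NULL, mcache, mols,
                              modifyList(cfg, list(use_subgraph = FALSE)))
    fw <- ddigcl:::model_forward(params, b,
                                 modifyList(cfg, list(use_subgraph = FALSE)))
    fw$Z_C
  }
  ab <- mk(ids[1], ids[2])
  ba <- mk(ids[2], ids[1])
  e <- ncol(ab) / 2
  expect_equal(ab[, 1:e], ba[, e + 1:e])
  expect_equal(ab[, e + 1:e], ba[, 1:e])
})
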