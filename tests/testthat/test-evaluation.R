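# Experimental protocols: edge attack, cold-start routing, ablations,
# embedding export.

test_that("edge_attack removes exactly round(f * |E|) edges, reproducibly", {
  set.seed(30)
  ids <- sprintf("d%02d", 1:30)
  a <- sample(ids, 200, TRUE); b <- sample(ids, 200, TRUE)
  net <- ddi_network(a[a != b], b[a != b], nodes = ids)
  m <- nrow(net$edges)
  for (f in c(0.1, 0.3, 0.5)) {
    atk <- edge_attack(net, f, seed = 4)
    expect_equal(nrow(atk$edges), m - round(f * m))
    # surviving edges are a subset; removed + surviving = original
    e0 <- paste(edge_df(net)$a, edge_df(net)$b)
    e1 <- paste(edge_df(atk)$a, edge_df(atk)$b)
    expect_true(all(e1 %in% e0))
    expect_length(setdiff(e0, e1), round(f * m))
  }
  expect_identical(edge_df(edge_attack(net, 0.5, seed = 9)),
                   edge_df(edge_attack(net, 0.5, seed = 9)))
  expect_false(identical(edge_df(edge_attack(net, 0.5, seed = 9)),
                         edge_df(edge_attack(net, 0.5, seed = 10))))
  expect_error(edge_attack(net, 1.2), class = "ddigcl_config_error")
  expect_error(edge_attack(net, 0), class = "ddigcl_config_error")
})

routing_violations <- function(part) {
  cold <- part$drugs_cold
  nc <- function(df) (df$drug_i %in% cold) + (df$drug_j %in% cold)
  sum(nc(part$ddi_train) != 0) + sum(nc(part$ddi_drugwise) != 1) +
    sum(nc(part$ddi_pairwise) != 2)
}

test_that("cold-start routing matches hand enumeration on a toy instance", {
  set.seed(31)
  ids <- letters[1:20]
  a <- sample(ids, 45, TRUE); b <- sample(ids, 45, TRUE)
  net <- ddi_network(a[a != b], b[a != b], nodes = ids)
  part <- suppressWarnings(
    cold_start_partition(net, ids, cold_fraction = 0.3, seed = 2))
  expect_length(part$drugs_cold, 6L)
  expect_setequal(c(part$drugs_train, part$drugs_cold), ids)
  expect_equal(routing_violations(part), 0)
  # positive pairs across the three subsets exhaust the network's edges
  pos <- rbind(part$ddi_train, part$ddi_drugwise, part$ddi_pairwise)
  pos <- pos[pos$label == 1, ]
  expect_setequal(paste(pos$drug_i, pos$drug_j),
                  paste(edge_df(net)$a, edge_df(net)$b))
  # negatives are 1:1 within each subset and are non-edges
  for (s in list(part$ddi_train, part$ddi_drugwise, part$ddi_pairwise)) {
    expect_equal(sum(s$label == 0), sum(s$label == 1))
    expect_length(intersect(paste(s$drug_i, s$drug_j)[s$label == 0],
                            paste(edge_df(net)$a, edge_df(net)$b)), 0L)
  }
  expect_error(cold_start_partition(net, ids, 1.5),
               class = "ddigcl_config_error")
})

test_that("ablation variants run and adjust the objective", {
  sm <- get_small_views()
  cfg <- modifyList(sm$cfg, list(epochs = 2L))
  out <- lapply(c("full", "no_molecular", "no_subgraph", "no_contrastive"),
                function(v) run_ablation(v, sm$split, sm$mols, cfg,
                                         seed = 1, views = sm$views))
  for (r in out) {
    expect_true(r$metrics$auc > 0 && r$metrics$auc <= 1)
    expect_true(all(is.finite(unlist(r$metrics))))
  }
  # no_contrastive: l_total excludes l_contr exactly
  h <- out[[4]]$model$history
  expect_equal(h$l_total, h$l_const + h$l_sub + h$l_joint, tolerance = 1e-7)
  expect_true(all(h$l_contr == 0))
  # no_molecular trains no molecular parameters (they stay at init)
  m_nm <- out[[2]]$model
  set.seed(m_nm$seed + 1L)
  init <- ddigcl:::init_params(m_nm$config)
  expect_identical(m_nm$final_params$mol$W[[1]], init$mol$W[[1]])
  expect_false(identical(m_nm$final_params$sub$W[[1]], init$sub$W[[1]]))
  expect_error(run_ablation("nope", sm$split, sm$mols, cfg, seed = 1))
})

test_that("cold-start evaluation with frozen encoders returns both reports", {
  fx <- get_fixture("small")
  samples <- make_pair_dataset(fx$net, seed = 7)
  split <- random_split(samples, seed = 7)
  cfg <- default_config(epochs = 3L, hop_count = 1L)
  model <- ddi_train(split, fx$mols, cfg, seed = 7)
  part <- cold_start_partition(fx$net, fx$mols$ids, 0.2, seed = 7)
  rep <- cold_start_eval(model, part, fx$mols)
  for (r in rep) {
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_true(r$aupr >= 0 && r$aupr <= 1)
  }
})

test_that("export_embeddings writes one named row per sample", {
  fx <- get_fixture("tiny")
  samples <- make_pair_dataset(fx$net, seed = 3)
  split <- random_split(samples, seed = 3)
  cfg <- default_config(epochs = 2L, hop_count = 1L, batch_size = 16L)
  model <- ddi_train(split, fx$mols, cfg, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  k <- min(8L, nrow(split$test))
  export_embeddings(model, split$test[seq_len(k), ], fx$mols, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), k)
  expect_true(all(c("zt_1", "zt_128", "zc_128", "fused_512") %in%
                    names(tab)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_embeddings(model, split$test[seq_len(k), ], fx$mols, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("edge removal degrades validation AUC (soft, statistical)", {
  # scaled-down instantiation: small fixture, short runs, 3 seeds
  fx <- get_fixture("small")
  fracs <- c(0, 0.25, 0.5)
  aucs <- matrix(NA_real_, 3, length(fracs))
  for (s in 1:3) {
    samples <- make_pair_dataset(fx$net, seed = 40 + s)
    split <- random_split(samples, seed = 40 + s)
    for (fi in seq_along(fracs)) {
      sp <- split
      if (fracs[fi] > 0) {
        pos <- sp$train[sp$train$label == 1, ]
        net_tr <- ddi_network(pos$drug_i, pos$drug_j, nodes = fx$mols$ids)
        atk <- edge_attack(net_tr, fracs[fi], seed = 40 + s)
        sp$train <- rbind(
          data.frame(drug_i = atk$nodes[atk$edges[, "i"]],
                     drug_j = atk$nodes[atk$edges[, "j"]], label = 1L),
          sp$train[sp$train$label == 0, ])
      }
      cfg <- default_config(epochs = 6L, hop_count = 1L)
      m <- ddi_train(sp, fx$mols, cfg, seed = 40 + s)
      aucs[s, fi] <- m$best_val_auc
    }
  }
  mean_auc <- colMeans(aucs)
  expect_true(all(diff(mean_auc) <= 0.02),
              label = paste("mean val AUC by removal fraction:",
                            paste(round(mean_auc, 4), collapse = " ")))
})
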