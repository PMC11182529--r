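# Experimental protocols: ablation variants, cold-start CV, embedding
# export. (The edge-removal attack lives in network.R next to the network
# type.)

#' Train and evaluate one ablation variant
#'
#' `full` trains all four loss terms and scores with the fusion head;
#' `no_molecular` drops the structure branch (topology head only);
#' `no_subgraph` drops the topology branch (structure head only);
#' `no_contrastive` keeps the full fusion but sets the contrastive weight
#' to zero.
#'
#' @param variant one of `"full"`, `"no_molecular"`, `"no_subgraph"`,
#'   `"no_contrastive"`.
#' @param split a `ddi_split`.
#' @param mols a `ddi_mols`.
#' @param config base configuration (the variant adjusts it).
#' @param seed training seed.
#' @param views optional precomputed views from an earlier run on the same
#'   split (shared across variants for speed).
#' @return list with `variant`, `metrics` (test-set [binary_metrics()]),
#'   `model`.
#' @export
run_ablation <- function(variant = c("full", "no_molecular", "no_subgraph",
                                     "no_contrastive"),
                         split, mols, config = default_config(), seed = 1L,
                         views = NULL) {
  variant <- match.arg(variant)
  config <- switch(variant,
    full = config,
    no_molecular = modifyList(config, list(use_molecular = FALSE,
                                           use_contrastive = FALSE)),
    no_subgraph = modifyList(config, list(use_subgraph = FALSE,
                                          use_contrastive = FALSE)),
    no_contrastive = modifyList(config, list(use_contrastive = FALSE,
                                             alpha = 0)))
  if (is.null(views)) {
    net_train <- training_network(split, all_nodes = mols$ids)
    views <- precompute_split_views(split, net_train, mols, config, seed)
  }
  model <- train_model_on_views(views, mols, config, seed)
  sc <- score_batches(model$params, views$test, config)
  list(variant = variant, metrics = binary_metrics(sc$p, sc$y),
       model = model)
}

#' Partition drugs and pairs for cold-start cross-validation
#'
#' Drugs are split at random into training drugs and cold-start drugs.
#' Every interaction is routed to exactly one subset: `ddi_train` (both
#' endpoints known), `ddi_drugwise` (exactly one cold endpoint),
#' `ddi_pairwise` (both endpoints cold). Negatives are sampled per subset
#' at 1:1 from non-edges whose endpoints satisfy the same routing rule.
#'
#' @param net a `ddi_network`.
#' @param drug_ids drugs eligible for the partition (default: network
#'   nodes).
#' @param cold_fraction fraction of drugs held out as cold, in (0, 1).
#' @param seed integer seed.
#' @param max_retries re-draws allowed when a subset comes up empty.
#' @return an object of class `ddi_coldstart`: list with `drugs_train`,
#'   `drugs_cold`, and data.frames `ddi_train`, `ddi_drugwise`,
#'   `ddi_pairwise` (columns `drug_i`, `drug_j`, `label`).
#' @export
cold_start_partition <- function(net, drug_ids = NULL, cold_fraction = 0.2,
                                 seed = 1L, max_retries = 10L) {
  stopifnot(inherits(net, "ddi_network"))
  if (!is_scalar_number(cold_fraction) || cold_fraction <= 0 ||
      cold_fraction >= 1) {
    stop_ddi("cold_fraction must be in (0, 1)", class = "ddigcl_config_error")
  }
  drug_ids <- drug_ids %||% net$nodes
  for (attempt in seq_len(max_retries)) {
    set.seed(seed + attempt - 1L)
    n_cold <- max(1L, round(cold_fraction * length(drug_ids)))
    cold <- sort(sample(drug_ids, n_cold))
    train_drugs <- setdiff(drug_ids, cold)
    ei <- net$nodes[net$edges[, "i"]]
    ej <- net$nodes[net$edges[, "j"]]
    n_cold_ends <- (ei %in% cold) + (ej %in% cold)
    route <- function(k) {
      cp <- canonical_pairs(ei[n_cold_ends == k], ej[n_cold_ends == k])
      data.frame(drug_i = cp$i, drug_j = cp$j, label = rep(1L, length(cp$i)),
                 stringsAsFactors = FALSE)
    }
    pos <- list(train = route(0L), drugwise = route(1L), pairwise = route(2L))
    if (all(vapply(pos, nrow, integer(1)) > 0L)) {
      neg <- tryCatch(
        mapply(function(p, kind) {
          sample_negatives_routed(net, nrow(p), cold, kind,
                                  seed = seed + attempt + 1000L)
        }, pos, names(pos), SIMPLIFY = FALSE),
        ddigcl_capacity_error = function(e) NULL)
      if (is.null(neg)) {
        warning(sprintf(
          "cold-start partition attempt %d lacked routed non-edges; retrying",
          attempt))
        next
      }
      return(structure(
        list(drugs_train = train_drugs, drugs_cold = cold,
             ddi_train = rbind(pos$train, neg$train),
             ddi_drugwise = rbind(pos$drugwise, neg$drugwise),
             ddi_pairwise = rbind(pos$pairwise, neg$pairwise),
             seed = seed),
        class = "ddi_coldstart"))
    }
    warning(sprintf("cold-start partition attempt %d left a subset empty; retrying",
                    attempt))
  }
  stop_ddi("could not build a non-degenerate cold-start partition in %d tries",
           max_retries, class = "ddigcl_partition_error")
}

# Negatives restricted to pairs whose endpoints match one routing rule:
# kind = "train" (0 cold ends), "drugwise" (1), "pairwise" (2).
sample_negatives_routed <- function(net, n_neg, cold, kind, seed) {
  n <- length(net$nodes)
  is_cold <- net$nodes %in% cold
  codes <- edge_codes(net)
  set.seed(seed)
  need <- c(train = 0L, drugwise = 1L, pairwise = 2L)[[kind]]
  ii <- jj <- integer(0)
  got <- numeric(0)
  tries <- 0L
  while (length(got) < n_neg && tries < 200L) {
    tries <- tries + 1L
    m <- 4L * (n_neg - length(got)) + 32L
    a <- sample.int(n, m, replace = TRUE)
    b <- sample.int(n, m, replace = TRUE)
    keep <- a != b & (is_cold[a] + is_cold[b]) == need
    lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
    code <- pair_code(lo, hi, n)
    ok <- !(code %in% codes) & !(code %in% got) & !duplicated(code)
    got <- c(got, code[ok])
    ii <- c(ii, lo[ok]); jj <- c(jj, hi[ok])
  }
  if (length(got) < n_neg) {
    stop_ddi("could not sample %d routed negatives (%s)", n_neg, kind,
             class = "ddigcl_capacity_error")
  }
  cp <- canonical_pairs(net$nodes[ii[seq_len(n_neg)]],
                        net$nodes[jj[seq_len(n_neg)]])
  data.frame(drug_i = cp$i, drug_j = cp$j, label = rep(0L, n_neg),
             stringsAsFactors = FALSE)
}

#' Cold-start evaluation with frozen encoders
#'
#' Freezes a trained model's encoders, computes fused pair embeddings, fits
#' a ridge-regularised logistic regression on the `ddi_train` embeddings,
#' and evaluates it on the drug-wise and pairwise subsets. Subgraphs are
#' built on the network spanned by `ddi_train` positives, so cold drugs are
#' genuinely unseen topology.
#'
#' @param model a trained `ddi_model` (both views active).
#' @param partition a `ddi_coldstart` from [cold_start_partition()].
#' @param mols a `ddi_mols` covering all drugs.
#' @param lambda ridge penalty for the logistic probe (default 1e-3).
#' @return list with `drugwise` and `pairwise` [binary_metrics()] reports.
#' @export
cold_start_eval <- function(model, partition, mols, lambda = 1e-3) {
  stopifnot(inherits(model, "ddi_model"), inherits(partition, "ddi_coldstart"))
  pos <- partition$ddi_train[partition$ddi_train$label == 1L, ]
  net_cs <- ddi_network(pos$drug_i, pos$drug_j, nodes = mols$ids)
  emb <- function(samples) {
    pair_embeddings(model, samples, mols, net_cs)$fused
  }
  Xtr <- emb(partition$ddi_train)
  fit <- glmnet::glmnet(Xtr, factor(partition$ddi_train$label),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  probe <- function(samples) {
    p <- drop(predict(fit, emb(samples), type = "response"))
    binary_metrics(p, samples$label)
  }
  list(drugwise = probe(partition$ddi_drugwise),
       pairwise = probe(partition$ddi_pairwise))
}

# Frozen-encoder embeddings for arbitrary pairs.
pair_embeddings <- function(model, samples, mols, net = NULL) {
  config <- model$config
  if (!(config$use_subgraph && config$use_molecular)) {
    stop_ddi("pair embeddings need both views active",
             class = "ddigcl_config_error")
  }
  net <- net %||% model$net_train
  if (is.null(samples$label)) samples$label <- 0L
  mcache <- mol_view_cache(mols)
  sub_views <- pair_subgraph_views(samples, net, mols, config)
  idxs <- make_batches(nrow(samples), 512L, shuffle = FALSE)
  e <- config$sub_widths[length(config$sub_widths)]
  Z_T <- matrix(0, nrow(samples), e)
  Zc_p <- matrix(0, nrow(samples), e)
  fused <- matrix(0, nrow(samples), 4L * e)
  for (ix in idxs) {
    b <- build_batch(ix, samples, sub_views, mcache, mols, config)
    fw <- model_forward(model$params, b, config, training = FALSE)
    Z_T[ix, ] <- fw$Z_T
    Zc_p[ix, ] <- fw$Zc_p
    fused[ix, ] <- fw$Fmat
  }
  list(Z_T = Z_T, Zc_p = Zc_p, fused = fused)
}

#' Export per-pair embeddings as TSV
#'
#' One row per sample: the pair, its topology embedding, projected
#' structure embedding, and fused feature vector; the header names the
#' widths (`zt_1..`, `zc_1..`, `fused_1..`). Intended for downstream
#' t-SNE / silhouette tooling.
#'
#' @param model a trained `ddi_model`.
#' @param samples data.frame of pairs.
#' @param mols a `ddi_mols`.
#' @param path output TSV path.
#' @param net optional sampling network (default: training network).
#' @return the path, invisibly.
#' @export
export_embeddings <- function(model, samples, mols, path, net = NULL) {
  emb <- pair_embeddings(model, samples, mols, net)
  df <- data.frame(drug_i = samples$drug_i, drug_j = samples$drug_j,
                   stringsAsFactors = FALSE)
  add <- function(M, prefix) {
    colnames(M) <- paste0(prefix, "_", seq_len(ncol(M)))
    M
  }
  df <- cbind(df, add(emb$Z_T, "zt"), add(emb$Zc_p, "zc"),
              add(emb$fused, "fused"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
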