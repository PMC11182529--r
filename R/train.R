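# Training loop: epoch iteration over precomputed batches, Adam updates,
# per-epoch validation metrics and best-checkpoint retention.

#' Train the dual-view DDI model
#'
#' Builds the sampling network from TRAINING positives only, precomputes
#' both views for every sample, and minimises the four-term objective with
#' Adam. Per-epoch, logs the four loss components and validation
#' AUC/AUPR/F1; the parameters with the best validation AUC are retained as
#' the model's checkpoint.
#'
#' @param split a `ddi_split` from [random_split()].
#' @param mols a `ddi_mols` from [featurize_drugs()].
#' @param config configuration list from [default_config()].
#' @param seed integer seed controlling initialisation, batch order and
#'   dropout.
#' @param verbose print one line per epoch.
#' @return an object of class `ddi_model`: list with `params` (best
#'   checkpoint), `final_params`, `history` (data.frame), `config`, the
#'   training network and bookkeeping needed to embed new pairs.
#' @export
ddi_train <- function(split, mols, config = default_config(), seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(split, "ddi_split"), inherits(mols, "ddi_mols"))
  if (nrow(split$train) == 0L) {
    stop_ddi("empty training split", class = "ddigcl_input_error")
  }
  if (config$epochs < 1L) {
    stop_ddi("epochs must be >= 1", class = "ddigcl_config_error")
  }
  if (config$use_contrastive && config$alpha > 0 && config$batch_size < 2L) {
    stop_ddi("batch_size must be >= 2 when the contrastive loss is enabled",
             class = "ddigcl_config_error")
  }
  net_train <- training_network(split, all_nodes = mols$ids)
  views <- precompute_split_views(split, net_train, mols, config, seed)
  train_model_on_views(views, mols, config, seed, verbose,
                       net_train = net_train)
}

# Precompute per-split batches once (reused across ablation variants).
precompute_split_views <- function(split, net_train, mols, config, seed) {
  full <- default_config()
  full[names(config)] <- config
  config <- full
  config$use_subgraph <- config$use_molecular <- TRUE  # cache both views
  mcache <- mol_view_cache(mols)
  mk <- function(samples, shuffle) {
    sub_views <- if (nrow(samples)) {
      pair_subgraph_views(samples, net_train, mols, config)
    } else list()
    idxs <- make_batches(nrow(samples), config$batch_size, shuffle = shuffle)
    lapply(idxs, build_batch, samples = samples, sub_views = sub_views,
           mcache = mcache, mols = mols, config = config)
  }
  set.seed(seed)
  list(train = mk(split$train, shuffle = TRUE),
       val = if (nrow(split$val)) mk(split$val, shuffle = FALSE) else list(),
       test = if (nrow(split$test)) mk(split$test, shuffle = FALSE) else list(),
       split_seed = split$seed)
}

# Core loop, separated so ablation variants can share precomputed views.
train_model_on_views <- function(views, mols, config, seed, verbose = FALSE,
                                 net_train = NULL) {
  set.seed(seed + 1L)
  params <- init_params(config)
  adam <- new_adam(params, lr = config$lr)
  history <- NULL
  best_auc <- -Inf
  best_params <- params
  use_cpp <- identical(config$engine %||% "cpp", "cpp")
  for (epoch in seq_len(config$epochs)) {
    tot <- c(l_contr = 0, l_const = 0, l_sub = 0, l_joint = 0, l_total = 0)
    n_seen <- 0L
    for (bi in seq_along(views$train)) {
      batch <- views$train[[bi]]
      step <- if (use_cpp) {
        model_backward_cpp(params, batch, config,
                           step_seed = (seed * 100003 + epoch * 1009 + bi) %%
                             .Machine$integer.max)
      } else {
        model_backward(params, batch, config, training = TRUE)
      }
      if (!is.finite(step$losses$l_total)) {
        stop_ddi("non-finite training loss at epoch %d (diverged)", epoch,
                 class = "ddigcl_numeric_error")
      }
      upd <- adam_step(params, step$grads, adam)
      params <- upd$params
      adam <- upd$state
      w <- batch$B
      tot <- tot + w * unlist(step$losses)
      n_seen <- n_seen + w
    }
    tot <- tot / n_seen
    vm <- c(auc = NA_real_, aupr = NA_real_, f1 = NA_real_)
    if (length(views$val)) {
      sc <- score_batches(params, views$val, config)
      if (length(unique(sc$y)) == 2L) {
        bm <- binary_metrics(sc$p, sc$y)
        vm <- c(auc = bm$auc, aupr = bm$aupr, f1 = bm$f1)
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, l_total = tot["l_total"], l_contr = tot["l_contr"],
      l_const = tot["l_const"], l_sub = tot["l_sub"],
      l_joint = tot["l_joint"], val_auc = vm["auc"], val_aupr = vm["aupr"],
      val_f1 = vm["f1"], row.names = NULL))
    if (verbose) {
      message(sprintf(
        "epoch %3d | total %.4f contr %.4f const %.4f sub %.4f joint %.4f | val auc %.4f aupr %.4f f1 %.4f",
        epoch, tot["l_total"], tot["l_contr"], tot["l_const"], tot["l_sub"],
        tot["l_joint"], vm["auc"], vm["aupr"], vm["f1"]))
    }
    if (!is.na(vm["auc"]) && vm["auc"] > best_auc) {
      best_auc <- vm["auc"]
      best_params <- params
    }
  }
  if (!length(views$val)) best_params <- params
  structure(
    list(params = best_params, final_params = params, history = history,
         config = config, best_val_auc = best_auc, seed = seed,
         net_train = net_train, fingerprint = mols$fingerprint),
    class = "ddi_model"
  )
}

# Model score for ranking/classification: fused probability when both views
# are active, otherwise the single active head.
batch_scores <- function(fw, config) {
  if (config$use_subgraph && config$use_molecular) fw$p_ct
  else if (config$use_subgraph) fw$p_sub
  else fw$p_const
}

score_batches <- function(params, batches, config) {
  p <- numeric(0); y <- numeric(0)
  for (b in batches) {
    fw <- model_forward(params, b, config, training = FALSE)
    p <- c(p, batch_scores(fw, config))
    y <- c(y, b$y)
  }
  list(p = p, y = y)
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf(
    "<ddi_model> %d epochs trained, best validation AUC %.4f\n",
    nrow(x$history), x$best_val_auc))
  invisible(x)
}

#' Predict interaction probabilities for drug pairs
#'
#' Rebuilds both views for the given pairs against the model's training
#' network (new drugs are treated as isolated) and applies the trained
#' checkpoint in inference mode.
#'
#' @param object a `ddi_model`.
#' @param samples data.frame with `drug_i`, `drug_j` (a `label` column is
#'   carried through if present).
#' @param mols the `ddi_mols` featurization (must cover all drugs).
#' @param net optional sampling network (defaults to the training network).
#' @param use `"best"` (default) or `"final"` parameters.
#' @param ... unused.
#' @return `samples` with columns `p_ct`, `p_sub`, `p_const` appended
#'   (NA for heads absent from the trained variant).
#' @export
predict.ddi_model <- function(object, samples, mols, net = NULL,
                              use = c("best", "final"), ...) {
  use <- match.arg(use)
  params <- if (use == "best") object$params else object$final_params
  config <- object$config
  net <- net %||% object$net_train
  if (is.null(samples$label)) samples$label <- 0L
  mcache <- mol_view_cache(mols)
  sub_views <- if (config$use_subgraph) {
    pair_subgraph_views(samples, net, mols, config)
  } else NULL
  idxs <- make_batches(nrow(samples), 512L, shuffle = FALSE)
  p_ct <- p_sub <- p_const <- rep(NA_real_, nrow(samples))
  for (ix in idxs) {
    b <- build_batch(ix, samples, sub_views, mcache, mols, config)
    fw <- model_forward(params, b, config, training = FALSE)
    if (!is.null(fw$p_ct)) p_ct[ix] <- fw$p_ct
    if (!is.null(fw$p_sub)) p_sub[ix] <- fw$p_sub
    if (!is.null(fw$p_const)) p_const[ix] <- fw$p_const
  }
  samples$p_ct <- p_ct
  samples$p_sub <- p_sub
  samples$p_const <- p_const
  samples$score <- if (config$use_subgraph && config$use_molecular) p_ct
                   else if (config$use_subgraph) p_sub else p_const
  samples
}

#' Save / load a trained model checkpoint
#'
#' Round-trip safe: a reloaded checkpoint produces bit-identical
#' predictions.
#'
#' @param model a `ddi_model`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ddi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ddi_model"))
  model
}
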