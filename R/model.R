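# The dual-view model: parameter initialisation, batched view
# precomputation, forward/backward passes and prediction.
#
# Views per pair sample:
#   topology view  : GCN over the common-neighbor subgraph (+ virtual node);
#                    Z_T = final-layer virtual-node row (width 128)
#   structure view : shared-weight GCN over each drug's atom graph, max
#                    readout per drug, concatenated in canonical pair order;
#                    Z_C = [readout(drug_j) || readout(drug_i)] (width 256)
# A learned projection maps Z_C to the topology width before the
# contrastive term and the fusion head (the two losses require equal
# widths). The fusion input is [Zc+Zt, Zc*Zt, Zc, Zt] (width 512).

#' Default model and training configuration
#'
#' @param ... named overrides of any default value.
#' @return a named list: `hop_count` (2), `exclude_target_edge` (TRUE),
#'   `sub_widths` (166, 332, 128) and `mol_widths` (78, 156, 128) — the
#'   dimension sequence of each GCN stack including its input width, i.e.
#'   two convolution layers each,
#'   `mlp_hidden` (64), `dropout` (0.2, from the grid 0.2/0.5/0.8),
#'   `temperature` (0.5), `contrastive_mode` ("as_printed"), loss weights
#'   `alpha` = 0.1, `beta` = `lambda` = `eta` = 1, `lr` (1e-3),
#'   `batch_size` (128), `epochs` (100), `fingerprint` ("maccs"), and the
#'   ablation switches `use_molecular`, `use_subgraph`, `use_contrastive`.
#' @export
default_config <- function(...) {
  cfg <- list(
    hop_count = 2L,
    exclude_target_edge = TRUE,
    # dimension sequences including the input width: two conv layers each
    sub_widths = c(166L, 332L, 128L),
    mol_widths = c(78L, 156L, 128L),
    mlp_hidden = 64L,
    dropout = 0.2,
    temperature = 0.5,
    contrastive_mode = "as_printed",
    alpha = 0.1, beta = 1, lambda = 1, eta = 1,
    lr = 1e-3,
    batch_size = 128L,
    epochs = 100L,
    fingerprint = "maccs",
    engine = "cpp",
    use_molecular = TRUE,
    use_subgraph = TRUE,
    use_contrastive = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_ddi("unknown config key(s): %s", paste(unknown, collapse = ", "),
             class = "ddigcl_config_error")
  }
  cfg[names(over)] <- over
  cfg
}

#' Read a configuration file (YAML or JSON)
#'
#' Keys mirror [default_config()]; unknown keys are rejected.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a full config list with the file's overrides applied.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  over <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_ddi("the 'yaml' package is required for YAML configs",
               class = "ddigcl_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  do.call(default_config, over)
}

init_params <- function(config) {
  if (config$sub_widths[1] != FINGERPRINT_DIM ||
      config$mol_widths[1] != ATOM_FEATURE_DIM) {
    stop_ddi("width sequences must start at the input dims (%d / %d)",
             FINGERPRINT_DIM, ATOM_FEATURE_DIM, class = "ddigcl_config_error")
  }
  sub_out <- config$sub_widths[length(config$sub_widths)]
  mol_out <- config$mol_widths[length(config$mol_widths)]
  zc_dim <- 2L * mol_out
  list(
    sub = new_gcn(config$sub_widths[1], config$sub_widths[-1]),
    mol = new_gcn(config$mol_widths[1], config$mol_widths[-1]),
    proj = list(W = glorot(zc_dim, sub_out), b = numeric(sub_out)),
    head_sub = new_mlp(sub_out, config$mlp_hidden),
    head_const = new_mlp(zc_dim, config$mlp_hidden),
    head_joint = new_mlp(4L * sub_out, config$mlp_hidden)
  )
}

#' Build the 4-block fusion features for a batch
#'
#' Concatenates `[Z_C + Z_T, Z_C * Z_T, Z_C, Z_T]` (elementwise product),
#' the input of the fusion head.
#'
#' @param Z_C,Z_T matrices of equal dimension (projected structure and
#'   topology embeddings).
#' @return matrix with four times the input width.
#' @export
fuse_features <- function(Z_C, Z_T) {
  Z_C <- as.matrix(Z_C); Z_T <- as.matrix(Z_T)
  if (!all(dim(Z_C) == dim(Z_T))) {
    stop_ddi("fuse_features: view widths differ (%d vs %d)",
             ncol(Z_C), ncol(Z_T), class = "ddigcl_shape_error")
  }
  cbind(Z_C + Z_T, Z_C * Z_T, Z_C, Z_T)
}

# ---- view precomputation --------------------------------------------------

# Per-drug cache of normalized adjacency + atom features.
mol_view_cache <- function(mols) {
  lapply(mols$graphs, function(g) {
    Ahat <- normalize_adjacency(g$adjacency)
    list(Ahat = methods::as(methods::as(Ahat, "generalMatrix"), "CsparseMatrix"),
         X = g$atom_features, m = g$n_atoms)
  })
}

# Precompute the subgraph view of every sample: sparse normalized adjacency,
# fingerprint row indices and the (static) virtual-node feature.
pair_subgraph_views <- function(samples, net, mols, config) {
  fp <- mols$fp
  n <- nrow(samples)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sg <- sample_common_subgraph(
      net, samples$drug_i[k], samples$drug_j[k], fp,
      H = config$hop_count,
      exclude_target_edge = config$exclude_target_edge)
    Ahat <- normalize_adjacency(sg$adjacency)
    nn <- length(sg$node_ids)
    out[[k]] <- list(
      Ahat = methods::as(methods::as(Ahat, "generalMatrix"), "CsparseMatrix"),
      nidx = match(sg$node_ids[-nn], rownames(fp)),
      virt = sg$features[nn, ],
      size = nn)
  }
  out
}

# Assemble index batches: shuffled consecutive chunks; a trailing chunk of
# size 1 is merged into its predecessor (the contrastive term needs N >= 2).
make_batches <- function(n, batch_size, shuffle = TRUE) {
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  starts <- seq(1L, n, by = batch_size)
  chunks <- lapply(starts, function(s) ord[s:min(s + batch_size - 1L, n)])
  k <- length(chunks)
  if (k > 1L && length(chunks[[k]]) == 1L) {
    chunks[[k - 1L]] <- c(chunks[[k - 1L]], chunks[[k]])
    chunks[[k]] <- NULL
  }
  chunks
}

# Precompute everything static for one batch of sample indices, including
# the first-layer products Ahat %*% X (constant across epochs). `keep_X`
# retains the raw feature blocks (used by invariant tests).
build_batch <- function(idx, samples, sub_views, mcache, mols, config,
                        keep_X = FALSE) {
  B <- length(idx)
  out <- list(idx = idx, B = B,
              y = as.numeric(samples$label[idx]))
  if (config$use_subgraph) {
    sv <- sub_views[idx]
    sizes <- vapply(sv, `[[`, integer(1), "size")
    offs <- cumsum(c(0L, sizes[-B]))
    rows <- sum(sizes)
    X <- matrix(0, rows, FINGERPRINT_DIM)
    for (k in seq_len(B)) {
      s <- sv[[k]]
      X[offs[k] + seq_len(s$size - 1L), ] <- mols$fp[s$nidx, , drop = FALSE]
      X[offs[k] + s$size, ] <- s$virt
    }
    Ahat <- methods::as(Matrix::bdiag(lapply(sv, `[[`, "Ahat")),
                        "CsparseMatrix")
    out$sub <- list(Ahat = Ahat, M1 = dense_spmm(Ahat, X),
                    n_rows = rows, virt_rows = offs + sizes)
    if (keep_X) out$sub$X <- X
  }
  if (config$use_molecular) {
    did <- unique(c(samples$drug_i[idx], samples$drug_j[idx]))
    mv <- mcache[did]
    sizes <- vapply(mv, `[[`, integer(1), "m")
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    Ahat <- methods::as(Matrix::bdiag(lapply(mv, `[[`, "Ahat")),
                        "CsparseMatrix")
    X <- do.call(rbind, lapply(mv, `[[`, "X"))
    out$mol <- list(
      Ahat = Ahat, M1 = dense_spmm(Ahat, X), n_rows = nrow(X),
      offs = c(0L, cumsum(sizes)),
      rows = mapply(function(o, s) o + seq_len(s), offs, sizes,
                    SIMPLIFY = FALSE),
      pi = match(samples$drug_i[idx], did),
      pj = match(samples$drug_j[idx], did),
      n_drugs = length(did))
    if (keep_X) out$mol$X <- X
  }
  out
}

# ---- forward / backward ---------------------------------------------------

# Max readout over each drug's atom rows; records argmax rows for backprop.
readout_blocks <- function(H, rows) {
  U <- length(rows)
  d <- ncol(H)
  tH <- t(H)  # transpose once; per-graph slices are then column selections
  R <- matrix(0, U, d)
  amax <- vector("list", U)
  cols <- seq_len(d)
  for (u in seq_len(U)) {
    r <- rows[[u]]
    if (length(r) == 1L) {
      R[u, ] <- tH[, r]
      amax[[u]] <- rep.int(r, d)
    } else {
      Xg <- tH[, r, drop = FALSE]
      w <- max.col(Xg, ties.method = "first")
      R[u, ] <- Xg[cbind(cols, w)]
      amax[[u]] <- r[w]
    }
  }
  list(R = R, amax = amax)
}

#' Column-wise max readout
#'
#' Permutation-invariant pooling of node embeddings into a graph embedding.
#'
#' @param node_embeddings m x d matrix (m >= 1).
#' @return numeric vector of length d (column maxima).
#' @export
readout_max <- function(node_embeddings) {
  node_embeddings <- as.matrix(node_embeddings)
  if (nrow(node_embeddings) == 0L) {
    stop_ddi("readout of an empty graph", class = "ddigcl_degenerate_error")
  }
  apply(node_embeddings, 2, max)
}

# Full forward pass on a precomputed batch. Returns predictions, losses and
# (when training) all caches needed for the backward pass.
model_forward <- function(params, batch, config, training = FALSE) {
  out <- list()
  dropout <- if (training) config$dropout else 0
  if (config$use_subgraph) {
    fs <- gcn_forward(params$sub, batch$sub$Ahat, NULL,
                      dropout, training, M1 = batch$sub$M1)
    out$Z_T <- fs$H[batch$sub$virt_rows, , drop = FALSE]
    out$sub_cache <- fs$cache
    hs <- mlp_forward(params$head_sub, out$Z_T, dropout, training)
    out$p_sub <- hs$p
    out$head_sub_cache <- hs$cache
  }
  if (config$use_molecular) {
    fm <- gcn_forward(params$mol, batch$mol$Ahat, NULL,
                      dropout, training, M1 = batch$mol$M1)
    ro <- readout_blocks(fm$H, batch$mol$rows)
    # Z_C = [readout(second drug) || readout(first drug)]: the f-branch is
    # the first drug of the canonical pair.
    out$Z_C <- cbind(ro$R[batch$mol$pj, , drop = FALSE],
                     ro$R[batch$mol$pi, , drop = FALSE])
    out$mol_cache <- fm$cache
    out$amax <- ro$amax
    hc <- mlp_forward(params$head_const, out$Z_C, dropout, training)
    out$p_const <- hc$p
    out$head_const_cache <- hc$cache
  }
  if (config$use_subgraph && config$use_molecular) {
    out$Zc_p <- sweep(out$Z_C %*% params$proj$W, 2, params$proj$b, `+`)
    out$Fmat <- fuse_features(out$Zc_p, out$Z_T)
    hj <- mlp_forward(params$head_joint, out$Fmat, dropout, training)
    out$p_ct <- hj$p
    out$head_joint_cache <- hj$cache
  }
  out
}

# Scalar losses for a forward pass (0 for disabled paths).
model_losses <- function(fw, batch, config, contr = NULL) {
  y <- batch$y
  l_sub <- if (!is.null(fw$p_sub)) binary_cross_entropy(fw$p_sub, y) else 0
  l_const <- if (!is.null(fw$p_const)) binary_cross_entropy(fw$p_const, y) else 0
  l_joint <- if (!is.null(fw$p_ct)) binary_cross_entropy(fw$p_ct, y) else 0
  l_contr <- if (!is.null(contr)) contr$loss else 0
  list(l_contr = l_contr, l_const = l_const, l_sub = l_sub,
       l_joint = l_joint,
       l_total = config$alpha * l_contr + config$beta * l_const +
         config$lambda * l_sub + config$eta * l_joint)
}

# One training step: forward, four-term loss, hand-derived backward pass.
# Returns losses and the full gradient tree.
model_backward <- function(params, batch, config, training = TRUE) {
  fw <- model_forward(params, batch, config, training = training)
  y <- batch$y
  B <- batch$B
  both <- config$use_subgraph && config$use_molecular
  contr <- NULL
  if (both && config$use_contrastive && config$alpha > 0) {
    contr <- contrastive_core(fw$Z_T, fw$Zc_p, config$temperature,
                              config$contrastive_mode, want_grad = TRUE)
  }
  losses <- model_losses(fw, batch, config, contr)

  grads <- tree_zero(params)
  dZ_T <- if (config$use_subgraph) matrix(0, B, ncol(fw$Z_T)) else NULL
  dZ_C <- if (config$use_molecular) matrix(0, B, ncol(fw$Z_C)) else NULL

  # BCE through sigmoid: dlogit = (p - y)/B, scaled by the term weight.
  if (config$use_subgraph && config$lambda > 0) {
    pcl <- clamp(fw$p_sub, 1e-7, 1 - 1e-7)
    bs <- mlp_backward(params$head_sub, fw$head_sub_cache,
                       config$lambda * (pcl - y) / B)
    grads$head_sub <- bs$grads
    dZ_T <- dZ_T + bs$dX
  }
  if (config$use_molecular && config$beta > 0) {
    pcc <- clamp(fw$p_const, 1e-7, 1 - 1e-7)
    bc <- mlp_backward(params$head_const, fw$head_const_cache,
                       config$beta * (pcc - y) / B)
    grads$head_const <- bc$grads
    dZ_C <- dZ_C + bc$dX
  }
  if (both) {
    dZc_p <- matrix(0, B, ncol(fw$Zc_p))
    if (config$eta > 0) {
      pcj <- clamp(fw$p_ct, 1e-7, 1 - 1e-7)
      bj <- mlp_backward(params$head_joint, fw$head_joint_cache,
                         config$eta * (pcj - y) / B)
      grads$head_joint <- bj$grads
      dF <- bj$dX
      e <- ncol(fw$Zc_p)
      d1 <- dF[, seq_len(e), drop = FALSE]
      d2 <- dF[, e + seq_len(e), drop = FALSE]
      d3 <- dF[, 2 * e + seq_len(e), drop = FALSE]
      d4 <- dF[, 3 * e + seq_len(e), drop = FALSE]
      dZc_p <- dZc_p + d1 + d2 * fw$Z_T + d3
      dZ_T <- dZ_T + d1 + d2 * fw$Zc_p + d4
    }
    if (!is.null(contr)) {
      dZc_p <- dZc_p + config$alpha * contr$dZ_C
      dZ_T <- dZ_T + config$alpha * contr$dZ_T
    }
    grads$proj$W <- crossprod(fw$Z_C, dZc_p)
    grads$proj$b <- colSums(dZc_p)
    dZ_C <- dZ_C + tcrossprod(dZc_p, params$proj$W)
  }

  if (config$use_subgraph) {
    L <- length(params$sub$W)
    dH <- matrix(0, batch$sub$n_rows, ncol(params$sub$W[[L]]))
    dH[batch$sub$virt_rows, ] <- dZ_T
    gb <- gcn_backward(params$sub, batch$sub$Ahat, fw$sub_cache, dH)
    grads$sub$W <- gb$dW
  }
  if (config$use_molecular) {
    e <- ncol(fw$Z_C) / 2L
    dR <- rowsum(rbind(dZ_C[, seq_len(e), drop = FALSE],
                       dZ_C[, e + seq_len(e), drop = FALSE]),
                 group = c(batch$mol$pj, batch$mol$pi))
    # rowsum orders rows by sorted group value; groups not present in the
    # batch cannot occur (every cached drug belongs to some pair).
    L <- length(params$mol$W)
    dHm <- matrix(0, batch$mol$n_rows, ncol(params$mol$W[[L]]))
    for (u in seq_len(batch$mol$n_drugs)) {
      tgt <- cbind(fw$amax[[u]], seq_len(e))
      dHm[tgt] <- dHm[tgt] + dR[u, ]
    }
    gm <- gcn_backward(params$mol, batch$mol$Ahat, fw$mol_cache, dHm)
    grads$mol$W <- gm$dW
  }
  list(losses = losses, grads = grads, fw = fw)
}

# Overlay the (sparse) gradient tree returned by the C++ step onto a
# zero-initialised full parameter tree.
merge_grad_tree <- function(base, upd) {
  if (is.null(upd)) return(base)
  keys <- names(upd) %||% seq_along(upd)
  for (k in seq_along(upd)) {
    key <- if (is.character(keys)) keys[k] else k
    u <- upd[[k]]
    if (is.null(u)) next
    base[[key]] <- if (is.list(u)) merge_grad_tree(base[[key]], u) else u
  }
  base
}

# One step through the float32 C++ kernel; mirrors model_backward().
model_backward_cpp <- function(params, batch, config, step_seed) {
  cfg <- config[c("use_subgraph", "use_molecular", "use_contrastive",
                  "dropout", "temperature", "contrastive_mode",
                  "alpha", "beta", "lambda", "eta")]
  cfg$training <- TRUE
  res <- .cpp_train_step(batch, params, cfg, as.integer(step_seed))
  list(losses = res$losses,
       grads = merge_grad_tree(tree_zero(params), res$grads))
}
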