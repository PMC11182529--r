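# Minimal dense NN primitives: Glorot init, MLP heads, GCN stacks and Adam.
# All gradients are hand-derived and verified against finite differences in
# the test suite (test-gradients.R).

glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# ---- GCN stack ------------------------------------------------------------
# widths = output widths of successive layers; input width given by data.

new_gcn <- function(d_in, widths) {
  dims <- c(d_in, widths)
  W <- vector("list", length(widths))
  for (l in seq_along(widths)) W[[l]] <- glorot(dims[l], dims[l + 1])
  list(W = W)
}

# Forward through L layers of relu(Ahat %*% H %*% W), with inverted dropout
# after each ReLU during training. Ahat is a sparse (block-diagonal)
# normalized adjacency. `M1` may carry the precomputed first-layer product
# Ahat %*% X (static across epochs). Each layer caches a single combined
# "gradmask" (ReLU derivative times inverted-dropout mask), so activation
# and backprop each cost one elementwise multiply.
gcn_forward <- function(stack, Ahat, X, dropout = 0, training = FALSE,
                        M1 = NULL) {
  L <- length(stack$W)
  cache <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    M <- if (l == 1L && !is.null(M1)) M1 else dense_spmm(Ahat, H)
    P <- M %*% stack$W[[l]]
    gradmask <- (P > 0) * 1
    if (training && dropout > 0) {
      keep <- (runif(length(P)) >= dropout) / (1 - dropout)
      gradmask <- gradmask * keep
    }
    H <- P * gradmask
    cache[[l]] <- list(M = M, gradmask = gradmask)
  }
  list(H = H, cache = cache)
}

# sparse %*% dense as a base matrix without an extra copy
dense_spmm <- function(Ahat, H) {
  M <- Ahat %*% H
  out <- M@x
  dim(out) <- M@Dim
  out
}

# Backprop; dH is the gradient w.r.t. the top activation. Returns per-layer
# weight gradients and (optionally) the gradient w.r.t. the input features.
gcn_backward <- function(stack, Ahat, cache, dH, need_dX = FALSE) {
  L <- length(stack$W)
  dW <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    dP <- dH * cc$gradmask
    dW[[l]] <- crossprod(cc$M, dP)
    if (l > 1L || need_dX) {
      dM <- tcrossprod(dP, stack$W[[l]])
      dH <- dense_spmm(Ahat, dM)  # Ahat symmetric
    }
  }
  list(dW = dW, dX = if (need_dX) dH else NULL)
}

# ---- MLP head -------------------------------------------------------------
# 2-layer: relu(X W1 + b1) -> dropout -> sigmoid(. W2 + b2); scalar output.

new_mlp <- function(d_in, hidden = 64L, d_out = 1L) {
  list(W1 = glorot(d_in, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, d_out), b2 = numeric(d_out))
}

mlp_forward <- function(par, X, dropout = 0, training = FALSE) {
  P1 <- sweep(X %*% par$W1, 2, par$b1, `+`)
  gradmask <- (P1 > 0) * 1
  if (training && dropout > 0) {
    keep <- (runif(length(P1)) >= dropout) / (1 - dropout)
    gradmask <- gradmask * keep
  }
  H1 <- P1 * gradmask
  logit <- sweep(H1 %*% par$W2, 2, par$b2, `+`)
  p <- sigmoid(logit)
  list(p = drop(p), logit = logit,
       cache = list(X = X, H1 = H1, gradmask = gradmask))
}

# dlogit: gradient w.r.t. the pre-sigmoid output (B x 1).
mlp_backward <- function(par, cache, dlogit) {
  dlogit <- matrix(dlogit, ncol = ncol(par$W2))
  dW2 <- crossprod(cache$H1, dlogit)
  db2 <- colSums(dlogit)
  dH1 <- tcrossprod(dlogit, par$W2) * cache$gradmask
  dW1 <- crossprod(cache$X, dH1)
  db1 <- colSums(dH1)
  dX <- tcrossprod(dH1, par$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dX = dX)
}

# ---- parameter trees and Adam --------------------------------------------

# Apply f elementwise over parallel nested lists of numeric arrays.
tree_map <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (k in seq_along(first)) {
      out[[k]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, k)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

new_adam <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  lr <- state$lr
  eps <- state$eps
  params <- tree_map(
    function(p, m, v) p - lr * (m / corr1) / (sqrt(v / corr2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of labels under predicted probabilities,
#' with probabilities clamped at 1e-7 from both ends.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y 0/1 labels of the same length.
#' @return scalar loss.
#' @export
binary_cross_entropy <- function(p, y) {
  if (length(p) != length(y)) {
    stop_ddi("lengths of p and y differ", class = "ddigcl_input_error")
  }
  p <- clamp(p, 1e-7, 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Weighted four-term training objective
#'
#' \eqn{l_{total} = \alpha l_{contr} + \beta l_{const} + \lambda l_{sub} +
#' \eta l_{joint}}.
#'
#' @param l_contr,l_const,l_sub,l_joint finite scalar loss components.
#' @param weights named list/vector with `alpha`, `beta`, `lambda`, `eta`
#'   (non-negative).
#' @return scalar total loss.
#' @export
total_loss <- function(l_contr, l_const, l_sub, l_joint,
                       weights = list(alpha = 0.1, beta = 1, lambda = 1,
                                      eta = 1)) {
  w <- as.list(weights)
  vals <- unlist(w[c("alpha", "beta", "lambda", "eta")])
  if (any(vals < 0)) {
    stop_ddi("loss weights must be non-negative", class = "ddigcl_config_error")
  }
  stopifnot(is.finite(l_contr), is.finite(l_const), is.finite(l_sub),
            is.finite(l_joint))
  w$alpha * l_contr + w$beta * l_const + w$lambda * l_sub + w$eta * l_joint
}
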