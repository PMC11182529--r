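# Batchwise contrastive alignment of the two views.
#
# For sample i with topology embedding Z_T^i and (projected) structure
# embedding Z_C^i, the per-sample loss is, as printed in the source model,
#   l_i = -log( exp(s_ii/tau) / sum_k [ exp(s_ik/tau) + exp(s_ii/tau) ] )
# with s_ik the cosine similarity, so the positive term appears N+1 times
# in the denominator. The batch loss is the MEAN of the l_i (the sign that
# makes minimisation align the views). `standard_infonce` mode uses the
# conventional denominator sum_k exp(s_ik/tau) instead.

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar in [-1, 1]; zero-norm inputs are epsilon-guarded with a
#'   warning.
#' @export
cosine_sim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    warning("cosine_sim: zero-norm vector, epsilon-stabilized")
  }
  sum(u * v) / max(nu, 1e-12) / max(nv, 1e-12)
}

row_normalize <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  nrm <- pmax(nrm, 1e-12)
  list(U = Z / nrm, nrm = nrm)
}

# Core: loss and (optionally) gradients w.r.t. both embedding matrices.
contrastive_core <- function(Z_T, Z_C, temperature, mode, want_grad = FALSE) {
  if (!is_scalar_number(temperature) || temperature <= 0) {
    stop_ddi("temperature must be a positive scalar",
             class = "ddigcl_config_error")
  }
  stopifnot(nrow(Z_T) == nrow(Z_C), ncol(Z_T) == ncol(Z_C))
  N <- nrow(Z_T)
  a <- row_normalize(Z_T)
  b <- row_normalize(Z_C)
  S <- tcrossprod(a$U, b$U)
  # log-sum-exp stabilisation per row
  mx <- apply(S, 1, max) / temperature
  E <- exp(S / temperature - mx)       # scaled by exp(-mx) per row
  dE <- diag(E)                        # length N (E_ii scaled)
  denom <- switch(mode,
    as_printed = rowSums(E) + N * dE,
    standard_infonce = rowSums(E))
  li <- -(diag(S) / temperature - mx) + log(denom)
  loss <- mean(li)
  if (!want_grad) return(list(loss = loss))
  # dl_i/ds_ik for the scaled-E formulation (scale cancels in ratios)
  dS <- E / denom / temperature
  extra <- if (mode == "as_printed") N * dE / denom / temperature else 0
  diag(dS) <- diag(dS) + extra - 1 / temperature
  dS <- dS / N
  dU <- dS %*% b$U
  dV <- crossprod(dS, a$U)
  dZ_T <- (dU - a$U * rowSums(dU * a$U)) / a$nrm
  dZ_C <- (dV - b$U * rowSums(dV * b$U)) / b$nrm
  list(loss = loss, dZ_T = dZ_T, dZ_C = dZ_C)
}

#' Batch contrastive loss between the two views
#'
#' Anchored on the topology view: each sample's topology embedding is
#' pulled toward its own structure embedding and pushed away from the other
#' samples' structure embeddings in the batch, with temperature-scaled
#' cosine similarities. Computed in log-sum-exp form.
#'
#' @param Z_T N x e matrix of topology embeddings.
#' @param Z_C N x e matrix of (projected) structure embeddings.
#' @param temperature positive temperature coefficient (default 0.5).
#' @param mode `"as_printed"` (default; positive term repeated inside the
#'   denominator sum) or `"standard_infonce"`.
#' @return scalar loss (strictly positive).
#' @export
contrastive_loss <- function(Z_T, Z_C, temperature = 0.5,
                             mode = c("as_printed", "standard_infonce")) {
  mode <- match.arg(mode)
  Z_T <- as.matrix(Z_T); Z_C <- as.matrix(Z_C)
  contrastive_core(Z_T, Z_C, temperature, mode)$loss
}
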