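# H-hop common-neighbor subgraphs with a virtual pooling node.
#
# For a query pair (i, j) the non-virtual node set is
# {i, j} union (N_i(H) intersect N_j(H)) on the sampling network; the edge
# (i, j) itself is removed by default (anti-leakage), and a virtual node
# connected to every other node is appended, its feature initialised to the
# mean of the other nodes' features.

#' H-hop neighborhood of a node
#'
#' All nodes at shortest-path distance 1..H from `v` (excluding `v`).
#'
#' @param net a `ddi_network`.
#' @param v a drug id present in the network.
#' @param H hop count (>= 1).
#' @return character vector of drug ids.
#' @export
hhop_neighbors <- function(net, v, H = 2L) {
  stopifnot(inherits(net, "ddi_network"), H >= 1)
  vi <- match(v, net$nodes)
  if (is.na(vi)) {
    stop_ddi("node '%s' not in network", v, class = "ddigcl_lookup_error")
  }
  net$nodes[hhop_idx(net, vi, H)]
}

# integer-index BFS truncated at depth H; excludes the start node
hhop_idx <- function(net, vi, H) {
  seen <- vi
  frontier <- vi
  out <- integer(0)
  for (h in seq_len(H)) {
    nxt <- unique(unlist(net$adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    out <- c(out, nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(out)
}

#' Append a virtual node to a featured graph
#'
#' The virtual node is connected to all `n` existing nodes and its feature
#' vector is the arithmetic mean of the other nodes' features.
#'
#' @param features n x d feature matrix (n >= 1).
#' @param adjacency symmetric n x n 0/1 matrix.
#' @return list with `features` ((n+1) x d) and `adjacency` ((n+1) x (n+1)).
#' @export
add_virtual_node <- function(features, adjacency) {
  n <- nrow(features)
  if (is.null(n) || n == 0L) {
    stop_ddi("cannot add a virtual node to an empty graph",
             class = "ddigcl_degenerate_error")
  }
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  vfeat <- colMeans(features)
  A <- rbind(cbind(adjacency, 1), c(rep(1, n), 0))
  X <- rbind(features, vfeat)
  list(features = unname(X), adjacency = unname(A))
}

#' Symmetric GCN adjacency normalization
#'
#' Returns \eqn{\tilde{D}^{-1/2} (A + I) \tilde{D}^{-1/2}} where
#' \eqn{\tilde{D}} is the degree matrix of \eqn{A + I}. The result is
#' symmetric with spectrum in \eqn{[-1, 1]}.
#'
#' @param A square symmetric 0/1 matrix with zero diagonal.
#' @return dense normalized matrix of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || any(abs(A - t(A)) > 1e-12)) {
    stop_ddi("adjacency must be square and symmetric",
             class = "ddigcl_contract_error")
  }
  if (any(diag(A) != 0)) {
    stop_ddi("adjacency must have zero diagonal",
             class = "ddigcl_contract_error")
  }
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  unname(At * outer(dinv, dinv))
}

#' Build the common-neighbor subgraph of a drug pair
#'
#' Non-virtual nodes are the endpoints plus the intersection of their H-hop
#' neighborhoods; edges are induced from the sampling network. The target
#' edge (i, j) is removed by default so the label is not readable from the
#' input. A pair with no common neighbors yields just the two endpoints
#' (drugs absent from the network are treated as isolated).
#'
#' @param net the sampling `ddi_network` (training edges only, typically).
#' @param i,j drug ids (i != j).
#' @param fp fingerprint matrix with rownames = drug ids (e.g. from
#'   [featurize_drugs()]); both endpoints must be present.
#' @param H hop count (default 2).
#' @param exclude_target_edge drop the (i, j) edge from the induced
#'   adjacency (default TRUE).
#' @return an object of class `ddi_subgraph`: list with `node_ids`
#'   (endpoints first, `"<virtual>"` last), `adjacency` ((n+1) x (n+1),
#'   virtual node connected to all others), and `features` ((n+1) x 166,
#'   virtual feature = mean of the rest).
#' @export
sample_common_subgraph <- function(net, i, j, fp, H = 2L,
                                   exclude_target_edge = TRUE) {
  if (identical(i, j)) {
    stop_ddi("pair endpoints must differ", class = "ddigcl_input_error")
  }
  if (!all(c(i, j) %in% rownames(fp))) {
    stop_ddi("no fingerprint for '%s'", setdiff(c(i, j), rownames(fp))[1],
             class = "ddigcl_featurization_error")
  }
  ii <- match(i, net$nodes)
  jj <- match(j, net$nodes)
  common <- if (is.na(ii) || is.na(jj)) integer(0) else {
    intersect(hhop_idx(net, ii, H), hhop_idx(net, jj, H))
  }
  common <- setdiff(common, c(ii, jj))
  ids <- c(i, j, net$nodes[common])
  n <- length(ids)
  idx <- match(ids, net$nodes)  # NA for absent endpoints
  A <- matrix(0, n, n)
  for (a in seq_len(n)) {
    if (is.na(idx[a])) next
    nb <- match(net$adj[[idx[a]]], idx)
    nb <- nb[!is.na(nb)]
    A[a, nb] <- 1
  }
  if (exclude_target_edge) A[1, 2] <- A[2, 1] <- 0
  X <- fp[ids, , drop = FALSE]
  aug <- add_virtual_node(X, A)
  structure(
    list(node_ids = c(ids, "<virtual>"), adjacency = aug$adjacency,
         features = aug$features),
    class = "ddi_subgraph"
  )
}

#' Export a pair subgraph as an edge-list TSV (debug aid)
#'
#' The virtual node appears under the sentinel id `"<virtual>"`.
#'
#' @param sub a `ddi_subgraph`.
#' @param path output path.
#' @export
export_subgraph <- function(sub, path) {
  A <- sub$adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(a = sub$node_ids[idx[, 1]], b = sub$node_ids[idx[, 2]])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
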