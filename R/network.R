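# The drug interaction network G_I = (V, E): undirected, no self-loops,
# each edge stored once in canonical (lexicographic) order.

new_ddi_network <- function(nodes, edge_i, edge_j) {
  # edge_i/edge_j are integer indices into `nodes`, already deduplicated,
  # self-loop free, with edge_i < edge_j impossible to assume: canonicalise.
  swap <- edge_i > edge_j
  tmp <- edge_i[swap]; edge_i[swap] <- edge_j[swap]; edge_j[swap] <- tmp
  ord <- order(edge_i, edge_j)
  edge_i <- edge_i[ord]; edge_j <- edge_j[ord]
  n <- length(nodes)
  adj <- vector("list", n)
  if (length(edge_i)) {
    half <- data.frame(a = c(edge_i, edge_j), b = c(edge_j, edge_i))
    adj_split <- split(half$b, factor(half$a, levels = seq_len(n)))
    adj <- lapply(adj_split, function(v) sort(unique(v)))
  } else {
    adj <- rep(list(integer(0)), n)
  }
  structure(
    list(nodes = nodes, edges = cbind(i = edge_i, j = edge_j), adj = adj),
    class = "ddi_network"
  )
}

#' Build an interaction network from two vectors of drug ids
#'
#' Self-loops and duplicate (unordered) edges are dropped.
#'
#' @param drug_i,drug_j character vectors of equal length; each position is
#'   one interacting pair.
#' @param nodes optional superset of node ids (isolated drugs allowed).
#' @return an object of class `ddi_network`.
#' @export
ddi_network <- function(drug_i, drug_j, nodes = NULL) {
  stopifnot(length(drug_i) == length(drug_j))
  ids <- sort(unique(c(nodes, drug_i, drug_j)))
  a <- match(drug_i, ids)
  b <- match(drug_j, ids)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(pair_code(lo, hi, length(ids)))
  new_ddi_network(ids, lo[!dup], hi[!dup])
}

#' Read a DDI edge list from a tab-separated file
#'
#' Each non-comment line holds at least two whitespace/tab-separated tokens
#' (drug_i, drug_j); extra columns are ignored and lines starting with `#`
#' are comments. Duplicate edges and self-loops are dropped with a report.
#'
#' @param path path to the edge-list file.
#' @return a `ddi_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    stop_ddi("cannot read edge list '%s'", path, class = "ddigcl_io_error")
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop_ddi("edge list '%s': line %d has fewer than 2 fields", path,
             lineno[bad[1]], class = "ddigcl_parse_error")
  }
  if (!length(toks)) {
    warning("edge list '", path, "' contains no edges")
    return(ddi_network(character(0), character(0)))
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  n_self <- sum(a == b)
  net <- ddi_network(a, b)
  n_dup <- sum(a != b) - nrow(net$edges)
  message(sprintf(
    "read_network: %d nodes, %d edges (%d duplicate(s) and %d self-loop(s) dropped)",
    length(net$nodes), nrow(net$edges), n_dup, n_self))
  net
}

#' Write a network as a canonical edge-list TSV
#'
#' @param net a `ddi_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ddi_network"))
  df <- data.frame(a = net$nodes[net$edges[, "i"]],
                   b = net$nodes[net$edges[, "j"]])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.ddi_network <- function(x, ...) {
  cat(sprintf("<ddi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

has_edge <- function(net, i, j) {
  # i, j integer indices
  any(net$adj[[i]] == j)
}

edge_codes <- function(net) {
  pair_code(net$edges[, "i"], net$edges[, "j"], length(net$nodes))
}

#' Sample negative (non-interacting) drug pairs
#'
#' Draws `n_neg` distinct unordered non-edge pairs uniformly at random.
#'
#' @param net a `ddi_network`.
#' @param n_neg number of negatives to draw.
#' @param seed integer seed (reproducible draws).
#' @return a data.frame with columns `drug_i`, `drug_j`, `label` (all 0),
#'   pairs in canonical lexicographic order.
#' @export
sample_negatives <- function(net, n_neg, seed = 1L) {
  stopifnot(inherits(net, "ddi_network"))
  n <- length(net$nodes)
  capacity <- choose(n, 2) - n_edges(net)
  if (n_neg > capacity) {
    stop_ddi("requested %d negatives but only %.0f non-edges exist",
             n_neg, capacity, class = "ddigcl_capacity_error")
  }
  if (n_neg == 0) {
    return(data.frame(drug_i = character(0), drug_j = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  codes <- edge_codes(net)
  set.seed(seed)
  if (choose(n, 2) <= 5e6) {
    # enumerate all unordered pairs, drop edges, sample exactly
    lens <- rev(seq_len(n - 1L))
    i <- rep(seq_len(n - 1L), times = lens)
    j <- sequence(lens, from = 2L) + i - 1L
    all_codes <- pair_code(i, j, n)
    ok <- !(all_codes %in% codes)
    pick <- which(ok)[sample.int(sum(ok), n_neg)]
    ii <- i[pick]; jj <- j[pick]
  } else {
    got <- integer(0)
    ii <- jj <- integer(0)
    while (length(got) < n_neg) {
      m <- 2L * (n_neg - length(got)) + 16L
      a <- sample.int(n, m, replace = TRUE)
      b <- sample.int(n, m, replace = TRUE)
      keep <- a != b
      lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
      code <- pair_code(lo, hi, n)
      keep2 <- !(code %in% codes) & !(code %in% got) & !duplicated(code)
      got <- c(got, code[keep2])
      ii <- c(ii, lo[keep2]); jj <- c(jj, hi[keep2])
    }
    ii <- ii[seq_len(n_neg)]; jj <- jj[seq_len(n_neg)]
  }
  cp <- canonical_pairs(net$nodes[ii], net$nodes[jj])
  data.frame(drug_i = cp$i, drug_j = cp$j, label = 0L,
             stringsAsFactors = FALSE)
}

#' Randomly remove a fraction of edges (robustness attack)
#'
#' Removes `round(fraction * |E|)` edges uniformly at random; intended to be
#' applied to the training network only, leaving evaluation pairs untouched.
#'
#' @param net a `ddi_network`.
#' @param fraction fraction of edges to remove, in (0, 1).
#' @param seed integer seed.
#' @return the degraded `ddi_network` (same node set).
#' @export
edge_attack <- function(net, fraction, seed = 1L) {
  stopifnot(inherits(net, "ddi_network"))
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1) {
    stop_ddi("fraction must be in (0, 1)", class = "ddigcl_config_error")
  }
  m <- n_edges(net)
  k <- round(fraction * m)
  set.seed(seed)
  drop <- sample.int(m, k)
  keep <- setdiff(seq_len(m), drop)
  new_ddi_network(net$nodes, net$edges[keep, "i"], net$edges[keep, "j"])
}
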