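# Pair samples, drug tables and random splits.

#' Read a drug table (drug_id <TAB> SMILES)
#'
#' Lines starting with `#` are comments; extra columns are ignored.
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns `drug_id` and `smiles`.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) {
    stop_ddi("cannot read drug table '%s'", path, class = "ddigcl_io_error")
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  toks <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop_ddi("drug table '%s': line %d has fewer than 2 fields", path,
             which(keep)[bad[1]], class = "ddigcl_parse_error")
  }
  data.frame(
    drug_id = vapply(toks, `[[`, character(1), 1L),
    smiles = vapply(toks, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

#' Write a drug table as TSV
#' @param drugs data.frame with `drug_id`, `smiles`.
#' @param path output path.
#' @export
write_drug_table <- function(drugs, path) {
  write.table(drugs[, c("drug_id", "smiles")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a balanced pair-sample dataset from a network
#'
#' Positives are the network's edges; negatives are sampled uniformly from
#' non-edges at a 1:1 ratio (drawn once, then split alongside positives so
#' validation/test negatives stay fixed across epochs).
#'
#' @param net a `ddi_network`.
#' @param seed integer seed for negative sampling.
#' @param neg_ratio negatives per positive (default 1).
#' @return a data.frame with columns `drug_i`, `drug_j`, `label`, pairs in
#'   canonical lexicographic order.
#' @export
make_pair_dataset <- function(net, seed = 1L, neg_ratio = 1) {
  stopifnot(inherits(net, "ddi_network"))
  cp <- canonical_pairs(net$nodes[net$edges[, "i"]], net$nodes[net$edges[, "j"]])
  pos <- data.frame(drug_i = cp$i, drug_j = cp$j, label = 1L,
                    stringsAsFactors = FALSE)
  neg <- sample_negatives(net, round(neg_ratio * nrow(pos)), seed = seed)
  rbind(pos, neg)
}

#' Randomly split pair samples into train/validation/test
#'
#' A plain shuffled partition at the given ratios (8:1:1 by default); the
#' same seed reproduces the same split.
#'
#' @param samples data.frame of pair samples (`drug_i`, `drug_j`, `label`).
#' @param ratios length-3 numeric vector summing to 1.
#' @param seed integer seed.
#' @return an object of class `ddi_split`: list with `train`, `val`, `test`
#'   data.frames and the `seed`.
#' @export
random_split <- function(samples, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9) {
    stop_ddi("ratios must be three numbers summing to 1",
             class = "ddigcl_config_error")
  }
  n <- nrow(samples)
  set.seed(seed)
  ord <- sample.int(n)
  n_tr <- round(ratios[1] * n)
  n_val <- round(ratios[2] * n)
  n_val <- min(n_val, n - n_tr)
  idx_tr <- ord[seq_len(n_tr)]
  idx_val <- ord[n_tr + seq_len(n_val)]
  idx_te <- ord[setdiff(seq_len(n), seq_len(n_tr + n_val))]
  structure(
    list(train = samples[idx_tr, , drop = FALSE],
         val = samples[idx_val, , drop = FALSE],
         test = samples[idx_te, , drop = FALSE],
         seed = seed),
    class = "ddi_split"
  )
}

#' @export
print.ddi_split <- function(x, ...) {
  cat(sprintf("<ddi_split> train %d / val %d / test %d (seed %d)\n",
              nrow(x$train), nrow(x$val), nrow(x$test), x$seed))
  invisible(x)
}

#' Write a split manifest as JSON
#' @param split a `ddi_split`.
#' @param path output path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed, train = split$train, val = split$val,
         test = split$test),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split manifest written by [write_split()]
#' @param path JSON manifest path.
#' @return a `ddi_split`.
#' @export
read_split <- function(path) {
  m <- jsonlite::fromJSON(path)
  structure(list(train = m$train, val = m$val, test = m$test, seed = m$seed),
            class = "ddi_split")
}

# Training network: the interaction network spanned by TRAINING positives
# only (the sampling network for subgraph extraction; avoids label leakage
# from validation/test edges).
training_network <- function(split, all_nodes) {
  pos <- split$train[split$train$label == 1L, , drop = FALSE]
  ddi_network(pos$drug_i, pos$drug_j, nodes = all_nodes)
}
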