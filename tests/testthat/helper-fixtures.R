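# Shared fixtures, memoized so RDKit featurization and fixture generation
# run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    fx <- make_fixture_data(name)
    mols <- featurize_drugs(fx$library)
    .fixture_cache[[name]] <- list(lib = fx$library, net = fx$network,
                                   spec = fx$spec, mols = mols)
  }
  .fixture_cache[[name]]
}

# tiny deterministic split + precomputed views on the small fixture,
# reused by trainer/gradient tests (override cfg$epochs per test; the
# precomputed views are epoch-agnostic)
get_small_views <- function(dropout = 0.2) {
  key <- paste0("views_", dropout)
  if (is.null(.fixture_cache[[key]])) {
    fx <- get_fixture("small")
    samples <- make_pair_dataset(fx$net, seed = 11)
    split <- random_split(samples, seed = 11)
    cfg <- default_config(epochs = 4L, hop_count = 1L, dropout = dropout)
    net_tr <- ddigcl:::training_network(split, fx$mols$ids)
    views <- ddigcl:::precompute_split_views(split, net_tr, fx$mols, cfg, 11L)
    .fixture_cache[[key]] <- list(split = split, cfg = cfg, views = views,
                                  net_tr = net_tr, mols = fx$mols)
  }
  .fixture_cache[[key]]
}

# build a ddi_network from "a-b" edge strings
toy_net <- function(..., nodes = NULL) {
  e <- strsplit(c(...), "-", fixed = TRUE)
  ddi_network(vapply(e, `[[`, "", 1L), vapply(e, `[[`, "", 2L),
              nodes = nodes)
}

edge_df <- function(net) {
  data.frame(a = net$nodes[net$edges[, "i"]], b = net$nodes[net$edges[, "j"]])
}

# dense symmetric 0/1 adjacency of a random graph
random_adj <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A + t(A)
}

to_csc <- function(x) {
  methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
}
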