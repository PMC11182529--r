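# Synthetic fixtures: a drug library with valid, class-structured SMILES
# and an interaction network whose edges are driven jointly by latent drug
# classes (topology signal) and shared substituents (structure signal).
#
# The world emulated here: drugs fall into mechanism classes (scaffolds);
# two drugs can interact only when their classes are designated partners
# AND they share at least one functional-group substituent, with the odds
# escalating geometrically in the number shared. Per designated class pair
# the mean edge probability is calibrated to p_in (p_out elsewhere), so
# the marginal density matches a plain stochastic block model.

# Shared substituent pool: chemically distinctive functional groups with
# distinct MACCS signatures. All fragments are valid when appended to a
# carbon/aromatic attachment point or wrapped in a branch.
SUBSTITUENT_POOL <- c(
  "C", "CC", "C(C)C", "F", "Cl", "Br", "I", "O", "OC", "OCC",
  "N", "NC", "N(C)C", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N",
  "S(=O)(=O)N", "[N+](=O)[O-]", "C=C"
)

# One scaffold template per class; {A}/{B}/{C} are substituent slots.
CLASS_SCAFFOLDS <- c(
  "c1cc({A})cc({B})c1{C}",          # benzene core
  "C({A})CC({B})CCC{C}",            # aliphatic chain
  "C1CC({A})CC({B})C1{C}",          # cyclohexane core
  "CC(=O)NC({A})CC({B})C{C}",       # acetamide-bearing chain
  "c1cc({A})cnc1C({B})C{C}",        # pyridine core
  "C1OC({A})CC1C({B})C{C}"          # tetrahydrofuran core
)

#' Specification of a synthetic DDI world
#'
#' @param n_drugs total number of drugs (split evenly across classes).
#' @param n_classes number of latent classes (>= 2; each uses one scaffold
#'   from the built-in pool).
#' @param p_in mean edge probability within a designated interacting class
#'   pair (default 0.3).
#' @param p_out mean edge probability elsewhere (default 0.02).
#' @param interact_pairs list of length-2 integer vectors of class indices
#'   designated as interacting (self-pairs allowed). Default: every class
#'   with itself.
#' @param structure_coupling if TRUE (default), edges additionally require
#'   at least one shared substituent and escalate geometrically
#'   (factor `coupling_lambda`) in the number shared, calibrated so the
#'   mean probability per class-pair type stays p_in / p_out; if FALSE the
#'   generator is a plain stochastic block model.
#' @param coupling_lambda geometric escalation per extra shared
#'   substituent (default 2).
#' @param n_substituents substituents attached per drug (default 3).
#' @param seed integer seed.
#' @return an object of class `ddi_synth_spec`.
#' @export
synth_spec <- function(n_drugs = 400L, n_classes = 4L, p_in = 0.3,
                       p_out = 0.02, interact_pairs = NULL,
                       structure_coupling = TRUE, coupling_lambda = 2,
                       n_substituents = 3L, seed = 1L) {
  if (n_classes < 2L || n_classes > length(CLASS_SCAFFOLDS)) {
    stop_ddi("n_classes must be between 2 and %d", length(CLASS_SCAFFOLDS),
             class = "ddigcl_spec_error")
  }
  if (!(p_in > p_out)) {
    stop_ddi("p_in must exceed p_out", class = "ddigcl_spec_error")
  }
  if (p_in > 1 || p_out <= 0) {
    stop_ddi("p_in, p_out must lie in (0, 1]", class = "ddigcl_spec_error")
  }
  interact_pairs <- interact_pairs %||%
    lapply(seq_len(n_classes), function(c) c(c, c))
  structure(
    list(n_drugs = n_drugs, n_classes = n_classes, p_in = p_in,
         p_out = p_out, interact_pairs = interact_pairs,
         structure_coupling = structure_coupling,
         coupling_lambda = coupling_lambda,
         n_substituents = n_substituents, seed = seed),
    class = "ddi_synth_spec"
  )
}

fill_template <- function(template, subs) {
  out <- template
  slots <- c("{A}", "{B}", "{C}")
  for (k in seq_along(slots)) {
    out <- sub(slots[k], if (k <= length(subs)) subs[k] else "",
               out, fixed = TRUE)
  }
  out
}

#' Generate a synthetic drug library
#'
#' Each drug's SMILES decorates its class scaffold with `n_substituents`
#' distinct substituents drawn from a fixed 20-fragment pool; the
#' (class, substituent-set, slot-assignment) combination is unique per
#' drug, so every SMILES is distinct and parses by construction.
#'
#' @param spec a `ddi_synth_spec`.
#' @return data.frame with columns `drug_id`, `smiles`, `class`, and one
#'   logical column per substituent (`sub_1` .. `sub_20`).
#' @export
generate_drug_library <- function(spec) {
  stopifnot(inherits(spec, "ddi_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_drugs
  classes <- rep(seq_len(spec$n_classes), length.out = n)
  classes <- sort(classes)
  npool <- length(SUBSTITUENT_POOL)
  seen <- character(0)
  smiles <- character(n)
  submat <- matrix(FALSE, n, npool,
                   dimnames = list(NULL, paste0("sub_", seq_len(npool))))
  for (k in seq_len(n)) {
    for (try in 1:1000) {
      subs <- sample.int(npool, spec$n_substituents)
      key <- paste(classes[k], paste(subs, collapse = ","))
      if (!(key %in% seen)) break
    }
    if (key %in% seen) {
      stop_ddi("substituent pool exhausted for class %d", classes[k],
               class = "ddigcl_spec_error")
    }
    seen <- c(seen, key)
    smiles[k] <- fill_template(CLASS_SCAFFOLDS[classes[k]],
                               SUBSTITUENT_POOL[subs])
    submat[k, subs] <- TRUE
  }
  ids <- sprintf("D%04d", seq_len(n))
  cbind(data.frame(drug_id = ids, smiles = smiles, class = classes,
                   stringsAsFactors = FALSE),
        as.data.frame(submat))
}

# Calibrate the base rate b of p(m) = min(cap, b * lambda^(m-1)) for m >= 1
# so that E[p] over the shared-count distribution equals the target mean.
calibrate_gate <- function(target, m_counts, lambda, cap = 0.95) {
  if (!length(m_counts)) return(cap)
  pm <- tabulate(m_counts + 1L)  # counts of m = 0, 1, 2, ...
  pm <- pm / sum(pm)
  mean_p <- function(b) {
    m <- seq_along(pm) - 1L
    p <- ifelse(m == 0, 0, pmin(cap, b * lambda^(m - 1)))
    sum(pm * p)
  }
  if (mean_p(cap) < target) return(cap)  # saturated; mean falls short
  lo <- 0; hi <- cap
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mean_p(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic interaction network
#'
#' Without structure coupling: a stochastic block model (edge probability
#' `p_in` inside designated interacting class pairs, `p_out` elsewhere).
#' With coupling (the default world): an edge additionally requires at
#' least one shared substituent, with probability escalating geometrically
#' in the number shared, calibrated per type so the mean stays
#' p_in / p_out.
#'
#' @param library a drug library from [generate_drug_library()].
#' @param spec the `ddi_synth_spec` used to generate it.
#' @return a `ddi_network` over all drugs in the library.
#' @export
generate_network <- function(library, spec) {
  stopifnot(inherits(spec, "ddi_synth_spec"))
  n <- nrow(library)
  set.seed(spec$seed + 7L)
  lens <- rev(seq_len(n - 1L))
  i <- rep(seq_len(n - 1L), times = lens)
  j <- sequence(lens, from = 2L) + i - 1L
  ci <- library$class[i]
  cj <- library$class[j]
  key <- paste(pmin(ci, cj), pmax(ci, cj))
  ikeys <- vapply(spec$interact_pairs,
                  function(p) paste(min(p), max(p)), character(1))
  interacting <- key %in% ikeys
  if (!spec$structure_coupling) {
    p <- ifelse(interacting, spec$p_in, spec$p_out)
  } else {
    S <- as.matrix(library[, grep("^sub_", names(library)), drop = FALSE])
    storage.mode(S) <- "double"
    shared <- tcrossprod(S)
    m <- shared[cbind(i, j)]
    b_in <- calibrate_gate(spec$p_in, m[interacting], spec$coupling_lambda)
    b_out <- calibrate_gate(spec$p_out, m[!interacting], spec$coupling_lambda)
    base <- ifelse(interacting, b_in, b_out)
    p <- ifelse(m == 0, 0, pmin(0.95, base * spec$coupling_lambda^(m - 1)))
  }
  hit <- runif(length(p)) < p
  ddi_network(library$drug_id[i[hit]], library$drug_id[j[hit]],
              nodes = library$drug_id)
}

FIXTURE_PRESETS <- list(
  tiny = list(n_drugs = 20L, n_classes = 2L, seed = 101L),
  small = list(n_drugs = 100L, n_classes = 4L, seed = 102L),
  default = list(n_drugs = 400L, n_classes = 4L, seed = 103L)
)

#' Build a named synthetic fixture in memory
#'
#' Presets: `tiny` (20 drugs, 2 classes), `small` (100 drugs, 4 classes),
#' `default` (400 drugs, 4 classes). Each preset has a fixed seed, so
#' regeneration is deterministic.
#'
#' @param name preset name.
#' @return list with `library`, `network`, `spec`.
#' @export
make_fixture_data <- function(name = c("tiny", "small", "default")) {
  name <- match.arg(name)
  ps <- FIXTURE_PRESETS[[name]]
  spec <- synth_spec(n_drugs = ps$n_drugs, n_classes = ps$n_classes,
                     seed = ps$seed)
  library <- generate_drug_library(spec)
  network <- generate_network(library, spec)
  list(library = library, network = network, spec = spec)
}

#' Write a named synthetic fixture to disk
#'
#' Emits `edges.tsv` (canonical edge list), `drugs.tsv` (drug_id, SMILES)
#' and `manifest.json` (the generating spec plus summary statistics and the
#' fixture's expected end-to-end performance band).
#'
#' @param name preset name (`tiny`, `small`, `default`).
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
make_fixture <- function(name = c("tiny", "small", "default"),
                         dir = tempfile("fixture_")) {
  name <- match.arg(name)
  fx <- make_fixture_data(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- file.path(dir, "edges.tsv")
  drugs <- file.path(dir, "drugs.tsv")
  manifest <- file.path(dir, "manifest.json")
  write_network(fx$network, edges)
  write_drug_table(fx$library, drugs)
  jsonlite::write_json(
    list(name = name,
         spec = unclass(fx$spec),
         n_drugs = nrow(fx$library),
         n_edges = n_edges(fx$network),
         class_sizes = as.integer(table(fx$library$class)),
         expected = list(
           # pilot-run acceptance band for the default preset: a 30-epoch
           # training run should reach test AUC >= 0.85
           min_test_auc_30_epochs = if (name == "default") 0.85 else NULL)),
    manifest, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(edges = edges, drugs = drugs, manifest = manifest))
}
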