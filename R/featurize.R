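# Molecular featurization via RDKit (bundled Python helper).
#
# Atom features follow the DeepDDS/GraphDTA 78-dim scheme: one-hot atom
# symbol over a fixed 44-symbol alphabet (last slot = "other"), one-hot
# degree 0..10, one-hot total H count 0..10, one-hot implicit valence
# 0..10, and a single aromaticity bit. Heavy atoms only (implicit H).

ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "other"
)
ATOM_FEATURE_DIM <- 78L   # 44 + 11 + 11 + 11 + 1
FINGERPRINT_DIM <- 166L

python_binary <- function() {
  bin <- getOption("ddigcl.python", Sys.getenv("DDIGCL_PYTHON", "python"))
  path <- Sys.which(bin)
  if (!nzchar(path)) {
    stop_ddi("python binary '%s' not found on PATH", bin, class = "ddigcl_python_error")
  }
  path
}

# Run the bundled RDKit helper on a vector of SMILES; returns the parsed
# JSON records (one per input, order preserved).
run_featurizer <- function(ids, smiles) {
  stopifnot(length(ids) == length(smiles))
  script <- system.file("python", "mol_features.py", package = "ddigcl")
  if (!nzchar(script)) {
    stop_ddi("bundled featurizer script not found; is the package installed?",
             class = "ddigcl_python_error")
  }
  infile <- tempfile(fileext = ".tsv")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(ids, smiles, sep = "\t"), infile)
  out <- suppressWarnings(
    system2(python_binary(), c(shQuote(script), shQuote(infile)),
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop_ddi("featurizer helper failed (exit %d)", status,
             class = "ddigcl_python_error")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

one_hot <- function(index, width) {
  v <- numeric(width)
  v[index] <- 1
  v
}

# Expand one helper record into the 78-dim atom feature matrix + adjacency.
expand_molgraph <- function(rec) {
  atoms <- rec$atoms
  m <- length(atoms)
  feats <- matrix(0, m, ATOM_FEATURE_DIM)
  for (k in seq_len(m)) {
    a <- atoms[[k]]
    sym <- match(a[[1]], ATOM_SYMBOLS)
    if (is.na(sym)) sym <- length(ATOM_SYMBOLS)  # "other" bucket
    deg <- min(as.integer(a[[2]]), 10L)
    nh <- min(as.integer(a[[3]]), 10L)
    val <- min(as.integer(a[[4]]), 10L)
    feats[k, ] <- c(
      one_hot(sym, 44L),
      one_hot(deg + 1L, 11L),
      one_hot(nh + 1L, 11L),
      one_hot(val + 1L, 11L),
      as.numeric(a[[5]])
    )
  }
  adj <- matrix(0, m, m)
  for (b in rec$bonds) {
    i <- as.integer(b[[1]]); j <- as.integer(b[[2]])
    adj[i, j] <- 1
    adj[j, i] <- 1
  }
  structure(
    list(atom_features = feats, adjacency = adj, n_atoms = m,
         canonical = rec$canonical),
    class = "ddi_molgraph"
  )
}

#' Convert a SMILES string to an atom-level molecular graph
#'
#' Parses the SMILES with RDKit and returns the heavy-atom graph: a
#' \eqn{m \times 78} atom-feature matrix (one-hot symbol / degree /
#' total-H / implicit valence, plus an aromaticity bit) and the symmetric
#' 0/1 covalent-bond adjacency.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `ddi_molgraph` with elements `atom_features`,
#'   `adjacency`, `n_atoms` and `canonical`.
#' @examples
#' \dontrun{
#' g <- smiles_to_molgraph("CC")
#' g$adjacency   # [[0,1],[1,0]]
#' }
#' @export
smiles_to_molgraph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  rec <- run_featurizer("x", smiles)[[1]]
  if (!isTRUE(rec$ok)) {
    stop_ddi("SMILES '%s' could not be parsed", smiles,
             class = "ddigcl_featurization_error")
  }
  expand_molgraph(rec)
}

#' Compute a 166-bit structural fingerprint for a molecule
#'
#' Node features for the pair-subgraph view. The default is the MACCS key
#' set (RDKit bits 1..166); `type = "morgan"` selects a radius-2 Morgan
#' fingerprint hashed to 166 bits instead.
#'
#' @param smiles a single SMILES string.
#' @param type `"maccs"` (default) or `"morgan"`.
#' @return a numeric 0/1 vector of length 166.
#' @export
node_fingerprint <- function(smiles, type = c("maccs", "morgan")) {
  type <- match.arg(type)
  stopifnot(is.character(smiles), length(smiles) == 1L)
  rec <- run_featurizer("x", smiles)[[1]]
  if (!isTRUE(rec$ok)) {
    stop_ddi("SMILES '%s' could not be parsed", smiles,
             class = "ddigcl_featurization_error")
  }
  bits <- unlist(rec[[type]])
  v <- numeric(FINGERPRINT_DIM)
  if (length(bits)) v[bits] <- 1
  v
}

#' Featurize a drug table in one batch
#'
#' Runs RDKit once over all drugs, drops records whose SMILES fail to parse
#' (with a message), and returns molecular graphs plus the fingerprint
#' matrix used as subgraph node features.
#'
#' @param drugs a data.frame with columns `drug_id` and `smiles`.
#' @param fingerprint `"maccs"` (default) or `"morgan"`.
#' @return an object of class `ddi_mols`: list with `ids`, `graphs` (named
#'   list of `ddi_molgraph`), `fp` (matrix n x 166, rownames = drug ids),
#'   and `dropped` (ids excluded by parsing failures).
#' @export
featurize_drugs <- function(drugs, fingerprint = c("maccs", "morgan")) {
  fingerprint <- match.arg(fingerprint)
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  if (anyDuplicated(drugs$drug_id)) {
    stop_ddi("duplicate drug_id in drug table", class = "ddigcl_input_error")
  }
  recs <- run_featurizer(drugs$drug_id, drugs$smiles)
  ok <- vapply(recs, function(r) isTRUE(r$ok), logical(1))
  dropped <- drugs$drug_id[!ok]
  if (length(dropped)) {
    message(sprintf("featurize_drugs: dropped %d drug(s) with unparseable SMILES",
                    length(dropped)))
  }
  recs <- recs[ok]
  ids <- vapply(recs, function(r) r$id, character(1))
  graphs <- lapply(recs, expand_molgraph)
  names(graphs) <- ids
  fp <- matrix(0, length(ids), FINGERPRINT_DIM, dimnames = list(ids, NULL))
  for (k in seq_along(recs)) {
    bits <- unlist(recs[[k]][[fingerprint]])
    if (length(bits)) fp[k, bits] <- 1
  }
  structure(
    list(ids = ids, graphs = graphs, fp = fp, dropped = dropped,
         fingerprint = fingerprint),
    class = "ddi_mols"
  )
}

#' @export
print.ddi_mols <- function(x, ...) {
  cat(sprintf("<ddi_mols> %d drugs featurized (%s fingerprints), %d dropped\n",
              length(x$ids), x$fingerprint, length(x$dropped)))
  invisible(x)
}
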