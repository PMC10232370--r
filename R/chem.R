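# Chemical-novelty profiling of hit compounds: fingerprint Tanimoto
# similarity against reference binder sets, physicochemical descriptors
# (TPSA, hydrogen-bond donors/acceptors) and scaffold-class grouping.
# SMILES handling, descriptors and raw fingerprints are delegated to
# ChemmineR/ChemmineOB (OpenBabel); the similarity and scaffold logic lives
# here. Fingerprints are OpenBabel FP2 (1024-bit path-based), recorded in
# output metadata.

.FP_TYPE <- "FP2"
.FP_BITS <- 1024L
.HBA_DEF <- "openbabel-HBA2"

#' Parse a SMILES file
#'
#' One compound per line: `SMILES` followed by whitespace and an id
#' (id optional; missing ids become `cmpd<N>`). Lines starting with `#` are
#' skipped.
#' @param path File path.
#' @return Data frame `compound_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("cmpd", i),
    character(1))
  data.frame(compound_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

.parse_smiles_set <- function(smiles, ids = names(smiles)) {
  if (is.null(ids)) ids <- paste0("cmpd", seq_along(smiles))
  names(smiles) <- ids
  sdf <- tryCatch(ChemmineR::smiles2sdf(smiles), error = function(e)
    stop("unparseable SMILES in set: ", conditionMessage(e), call. = FALSE))
  sdf
}

#' Binary structural fingerprints for a compound set
#'
#' @param smiles Character vector of SMILES (names used as compound ids).
#' @return 0/1 matrix, one row per compound, `fp_type`/`fp_bits` attributes.
#' @export
compound_fingerprints <- function(smiles) {
  sdf <- .parse_smiles_set(smiles)
  m <- ChemmineR::fingerprintOB(sdf, .FP_TYPE)@fpma
  storage.mode(m) <- "integer"
  attr(m, "fp_type") <- .FP_TYPE
  attr(m, "fp_bits") <- ncol(m)
  m
}

#' Tanimoto similarity of two fingerprint bitsets
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both sets are empty.
#' @param a,b Equal-length 0/1 (or logical) vectors.
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint length mismatch (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Chemical novelty of compounds against a reference binder set
#'
#' For each query compound, the maximum and mean Tanimoto similarity to the
#' reference set; a compound is dissimilar (novel) when its maximum
#' similarity is strictly below the threshold. The summary reports
#' mean +/- s.d. over the per-compound mean similarities.
#'
#' @param fps Query fingerprint matrix (rows = compounds), from
#'   [compound_fingerprints()].
#' @param ref_fps Reference fingerprint matrix (same bit length).
#' @param threshold Dissimilarity threshold (default 0.7; `max_sim <
#'   threshold` means dissimilar).
#' @return Data frame `compound_id`, `max_sim`, `mean_sim`, `dissimilar`;
#'   attributes `mean_of_means`, `sd_of_means`, `fp_type`, `threshold`.
#' @export
novelty_vs_reference <- function(fps, ref_fps, threshold = 0.7) {
  if (!nrow(ref_fps)) stop("empty reference set", call. = FALSE)
  if (ncol(fps) != ncol(ref_fps))
    stop("fingerprint length mismatch between query and reference",
         call. = FALSE)
  sims <- t(apply(fps, 1L, function(a)
    apply(ref_fps, 1L, function(b) tanimoto(a, b))))
  if (nrow(ref_fps) == 1L) sims <- matrix(sims, ncol = 1L)
  out <- data.frame(compound_id = rownames(fps),
                    max_sim = apply(sims, 1L, max),
                    mean_sim = rowMeans(sims), stringsAsFactors = FALSE)
  out$dissimilar <- out$max_sim < threshold
  attr(out, "mean_of_means") <- mean(out$mean_sim)
  attr(out, "sd_of_means") <- stats::sd(out$mean_sim)
  attr(out, "fp_type") <- attr(fps, "fp_type")
  attr(out, "threshold") <- threshold
  out
}

#' Physicochemical descriptors
#'
#' TPSA by the standard atom-contribution method, hydrogen-bond donor and
#' acceptor counts, all computed by OpenBabel; the acceptor definition set
#' is recorded in the `hba_definition` attribute.
#'
#' @param smiles Character vector of SMILES (names used as compound ids).
#' @return Data frame `compound_id`, `tpsa`, `hbd`, `hba`.
#' @export
compound_descriptors <- function(smiles) {
  ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("cmpd", seq_along(smiles))
  sdf <- .parse_smiles_set(smiles, ids)
  p <- ChemmineR::propOB(sdf)
  out <- data.frame(compound_id = ids, tpsa = p$TPSA, hbd = p$HBD,
                    hba = p$HBA2, stringsAsFactors = FALSE)
  attr(out, "hba_definition") <- .HBA_DEF
  out
}

# Molecular graph (heavy atoms) from a ChemmineR SDF object.
.mol_graph <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  elements <- sub("_.*$", "", rownames(ab))
  g <- igraph::make_empty_graph(n = nrow(ab), directed = FALSE)
  igraph::V(g)$element <- elements
  if (nrow(bb)) {
    g <- igraph::add_edges(g, rbind(bb[, 1L], bb[, 2L]))
    igraph::E(g)$order <- bb[, 3L]
  }
  g
}

# Iteratively prune terminal (degree <= 1) atoms: what remains is the
# ring-system framework (rings plus linkers), the Bemis-Murcko-style
# scaffold.
.framework <- function(g) {
  repeat {
    leaves <- which(igraph::degree(g) <= 1L)
    if (!length(leaves) || length(leaves) == igraph::vcount(g))
      return(if (length(leaves) == igraph::vcount(g))
               igraph::make_empty_graph(0, directed = FALSE) else g)
    g <- igraph::delete_vertices(g, leaves)
  }
}

# Canonical string of a vertex-labelled graph via BLISS canonical
# labelling; integer colors are the ranks of the labels (deterministic for
# a given label multiset) and the labels themselves go into the string so
# keys are comparable across molecules.
.canon_string <- function(g, labels) {
  n <- igraph::vcount(g)
  if (n == 0L) return("acyclic")
  colors <- as.integer(factor(labels))
  cp <- igraph::canonical_permutation(g, colors = colors)
  gp <- igraph::permute(g, cp$labeling)
  labs <- character(n); labs[cp$labeling] <- labels
  el <- igraph::as_edgelist(gp)
  el <- t(apply(el, 1L, sort))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  paste0("n", n, ";c", paste(labs, collapse = ","),
         ";e", paste(el[, 1L], el[, 2L], sep = "-", collapse = ","))
}

#' Scaffold and scaffold-class assignment
#'
#' The scaffold of a compound is its ring-system framework: rings plus the
#' linkers between them, obtained by iteratively removing terminal atoms.
#' Frameworks are compared by graph isomorphism with atoms coloured by
#' element and saturation (whether the atom carries a multiple bond), which
#' is invariant to Kekule phase; identical frameworks share one
#' `scaffold_id`. The coarser `class_id` compares the bare ring-linker
#' skeleton (all atoms equivalent), merging scaffolds of the same shape.
#' Acyclic compounds get the sentinel scaffold `"acyclic"`.
#'
#' @param smiles Character vector of SMILES (names used as compound ids).
#' @return Data frame `compound_id`, `scaffold_id`, `class_id`; attributes
#'   `n_scaffolds` and `n_classes` (acyclic sentinel excluded from both
#'   counts when no cyclic compound shares it).
#' @export
scaffold_classes <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- paste0("cmpd", seq_along(smiles))
  sdf <- .parse_smiles_set(smiles)
  keys <- vapply(seq_along(smiles), function(i) {
    g <- .framework(.mol_graph(sdf[[i]]))
    if (igraph::vcount(g) == 0L) return(c("acyclic", "acyclic"))
    el <- igraph::V(g)$element
    unsat <- vapply(seq_len(igraph::vcount(g)), function(v) {
      eids <- igraph::incident(g, v)
      any(igraph::E(g)$order[as.integer(eids)] > 1L)
    }, logical(1))
    c(.canon_string(g, paste0(el, ifelse(unsat, "*", ""))),
      .canon_string(g, rep("A", igraph::vcount(g))))
  }, character(2))
  skey <- keys[1L, ]; ckey <- keys[2L, ]
  sid <- ifelse(skey == "acyclic", "acyclic",
                paste0("S", match(skey, sort(unique(skey[skey != "acyclic"])))))
  cid <- ifelse(ckey == "acyclic", "acyclic",
                paste0("K", match(ckey, sort(unique(ckey[ckey != "acyclic"])))))
  out <- data.frame(compound_id = names(smiles), scaffold_id = sid,
                    class_id = cid, stringsAsFactors = FALSE)
  attr(out, "n_scaffolds") <- length(unique(skey[skey != "acyclic"]))
  attr(out, "n_classes") <- length(unique(ckey[ckey != "acyclic"]))
  out
}

#' Single-compound scaffold id
#'
#' @param smiles One SMILES string.
#' @return Canonical scaffold key (or `"acyclic"`).
#' @export
scaffold_class <- function(smiles) {
  sdf <- .parse_smiles_set(c(x = smiles))
  g <- .framework(.mol_graph(sdf[[1L]]))
  if (igraph::vcount(g) == 0L) return("acyclic")
  el <- igraph::V(g)$element
  unsat <- vapply(seq_len(igraph::vcount(g)), function(v) {
    eids <- igraph::incident(g, v)
    any(igraph::E(g)$order[as.integer(eids)] > 1L)
  }, logical(1))
  .canon_string(g, paste0(el, ifelse(unsat, "*", "")))
}
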