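# Canonical labeling and hashing.
#
# A molecule is hashed by its canonical plain SMILES; atom order is fixed by
# a BLISS canonical permutation (via igraph) of an auxiliary vertex-colored
# graph in which atoms are colored by element and every bond is represented
# by an extra vertex colored by its bond order (BLISS has no edge colors, so
# bond orders are pushed onto subdivision vertices). Isomorphic graphs --
# in particular any atom reindexing or atom-map relabeling -- therefore
# produce identical hashes, and distinct constitutional species produce
# distinct strings (the hash IS the canonical SMILES, so collisions would
# require two non-isomorphic graphs with the same canonical string, which
# the round-trip property rules out).

# isomorphism-invariant atom ranks (a permutation of 1..n)
canonical_ranks <- function(g) {
  n <- length(g$elements)
  if (n == 1) return(1L)
  elid <- match(g$elements, c("C", "H", "O", "N"))
  ut <- which(upper.tri(g$bonds) & g$bonds > 0L, arr.ind = TRUE)
  nb <- nrow(ut)
  if (nb == 0) return(rank(elid, ties.method = "first"))
  bond_v <- n + seq_len(nb)
  edges <- c(rbind(ut[, 1], bond_v), rbind(ut[, 2], bond_v))
  ig <- igraph::make_graph(edges = edges, n = n + nb, directed = FALSE)
  colors <- c(elid, 4L + g$bonds[ut])
  lab <- igraph::canonical_permutation(ig, colors = colors)$labeling
  rank(lab[seq_len(n)])
}

#' Canonical hash of a molecule
#'
#' An opaque string key that is invariant to atom reindexing and atom-map
#' relabeling: two graphs get the same hash if and only if they are
#' isomorphic as element-labeled bond-order graphs. The key is the
#' canonical plain SMILES of the molecule (fragments sorted), so it is
#' also human-readable.
#'
#' @param g a [molgraph()].
#' @return a string.
#' @export
#' @examples
#' canonical_hash(parse_smiles("OCC")) == canonical_hash(parse_smiles("CCO"))
canonical_hash <- function(g) {
  write_smiles(g, with_maps = FALSE, canonical = TRUE)
}

#' Canonical, direction-invariant hash of a reaction
#'
#' Hashes each side by its canonical SMILES (fragments sorted
#' lexicographically), then joins the two side strings in sorted order, so a
#' reaction and its reverse hash identically and each transformation is
#' counted once during enumeration dedup. The hash is species-level: it keys
#' on the constitutional identity of reactants and products, not on the atom
#' mapping.
#'
#' @param r a [mapped_reaction()].
#' @return a string of the form `"<side>>><side>"`.
#' @export
reaction_hash <- function(r) {
  stopifnot(inherits(r, "mapped_reaction"))
  sides <- c(canonical_hash(r$reactant), canonical_hash(r$product))
  paste(sort(sides), collapse = ">>")
}
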