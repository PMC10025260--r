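# SMILES writer. Two modes:
#   * plain (with_maps = FALSE): hydrogens are folded into their heavy
#     neighbor and atoms are written as bare organic-subset symbols; since
#     every atom sits at its standard neutral valence, implicit-H arithmetic
#     reconstructs the folded hydrogens exactly on re-parse.
#   * mapped (with_maps = TRUE): every atom, including hydrogen, is written
#     as a bracket atom carrying its atom-map number (the convention used in
#     atom-mapped reaction SMILES of TS datasets).
# Canonical output orders atoms by an isomorphism-invariant labeling, so the
# string doubles as a dedup key (see canonical_hash).

#' Write a molecular graph as SMILES
#'
#' @param g a [molgraph()].
#' @param with_maps write every atom (hydrogens included) as a bracket atom
#'   with an atom-map number; existing maps are kept, missing ones are
#'   assigned sequentially.
#' @param canonical order atoms by the canonical labeling so isomorphic
#'   graphs produce identical strings (fragments sorted lexicographically).
#' @return a SMILES string; fragments are joined with `.`.
#' @export
#' @examples
#' write_smiles(parse_smiles("OCC"))       # canonical ethanol
#' write_smiles(parse_smiles("CC"), with_maps = TRUE)
write_smiles <- function(g, with_maps = FALSE, canonical = TRUE) {
  validate_molgraph(g)
  n <- length(g$elements)
  ranks <- if (canonical) canonical_ranks(g) else seq_len(n)

  maps <- NULL
  if (with_maps) {
    maps <- if (is.null(g$maps)) rep(NA_integer_, n) else g$maps
    if (any(is.na(maps))) {
      free <- setdiff(seq_len(n + sum(is.na(maps))), maps[!is.na(maps)])
      maps[is.na(maps)] <- free[seq_len(sum(is.na(maps)))]
    }
  }

  # fold hydrogens into heavy neighbors in plain mode
  shown <- rep(TRUE, n)
  nfold <- integer(n)
  if (!with_maps) {
    for (a in which(g$elements == "H")) {
      nb <- which(g$bonds[a, ] > 0L)
      if (length(nb) == 1 && g$elements[nb] != "H") {
        shown[a] <- FALSE
        nfold[nb] <- nfold[nb] + 1L
      }
    }
  }

  comp <- fragment_ids(g)
  out <- character(0)
  for (k in sort(unique(comp))) {
    at <- which(comp == k & shown)
    start <- at[which.min(ranks[at])]
    out <- c(out, smiles_fragment(g, start, shown, nfold, ranks, maps))
  }
  if (canonical) out <- sort(out)
  paste(out, collapse = ".")
}

# DFS writer over the shown atoms of one fragment
smiles_fragment <- function(g, start, shown, nfold, ranks, maps) {
  bonds <- g$bonds
  el <- g$elements
  visited <- rep(FALSE, length(el))
  ring_no <- 0L
  ring_open <- list()  # key "a-b" -> number
  ring_at <- lapply(seq_along(el), function(i) character(0))

  # first pass: spanning tree + ring edges, in rank order
  tree_children <- lapply(seq_along(el), function(i) integer(0))
  ring_edges <- list()
  visit <- function(v, parent) {
    visited[v] <<- TRUE
    nbs <- which(bonds[v, ] > 0L & shown)
    nbs <- nbs[order(ranks[nbs])]
    for (w in nbs) {
      if (w == parent) next
      if (visited[w]) {
        key <- paste(sort(c(v, w)), collapse = "-")
        if (is.null(ring_open[[key]])) {
          ring_open[[key]] <<- TRUE
          ring_edges[[length(ring_edges) + 1]] <<- c(w, v)
        }
      } else {
        tree_children[[v]] <<- c(tree_children[[v]], w)
        visit(w, v)
      }
    }
  }
  visit(start, 0L)

  ring_token <- function(num) if (num > 9) sprintf("%%%02d", num) else as.character(num)
  bond_token <- function(ord) c("", "", "=", "#")[ord + 1L]
  for (k in seq_along(ring_edges)) {
    e <- ring_edges[[k]]
    tok <- paste0(bond_token(bonds[e[1], e[2]]), ring_token(k))
    ring_at[[e[1]]] <- c(ring_at[[e[1]]], tok)
    ring_at[[e[2]]] <- c(ring_at[[e[2]]], tok)
  }

  atom_token <- function(v) {
    if (!is.null(maps)) {
      paste0("[", el[v], ":", maps[v], "]")
    } else if (el[v] == "H") {
      "[H]"
    } else {
      el[v]
    }
  }
  emit <- function(v) {
    s <- paste0(atom_token(v), paste(ring_at[[v]], collapse = ""))
    ch <- tree_children[[v]]
    if (length(ch) > 0) {
      parts <- vapply(ch, function(w) paste0(bond_token(bonds[v, w]), emit(w)), "")
      if (length(parts) > 1)
        s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""))
      s <- paste0(s, parts[length(parts)])
    }
    s
  }
  emit(start)
}
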