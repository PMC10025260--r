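# Atom-mapped reactions: a reactant and a product molgraph over the SAME
# atom index set. Broken/formed bond sets are derived from the difference of
# the two bond matrices (the reaction matrix of the bond-electron formalism),
# so they are always consistent with the graphs and never overlap.

#' Construct an atom-mapped reaction
#'
#' @param reactant,product [molgraph()] objects over the same atom index set
#'   (atom `i` of the reactant is atom `i` of the product); element vectors
#'   must match position by position, which enforces atom conservation.
#' @param validate check both graphs and the index alignment.
#' @return an object of class `mapped_reaction` with fields `reactant`,
#'   `product`, `broken` and `formed`; the latter two are integer matrices
#'   with columns `i`, `j`, `units` giving the atom pair and the bond-order
#'   decrement/increment.
#' @export
#' @examples
#' g <- parse_smiles("CC")  # ethane -> ethene + H2
#' h1 <- which(g$elements == "H")[1]; h2 <- which(g$elements == "H")[4]
#' r <- apply_ers(g, breaks = rbind(c(1, h1 + 0L), c(2, h2 + 0L)),
#'                forms = rbind(c(1, 2), c(h1, h2)))
#' r
mapped_reaction <- function(reactant, product, validate = TRUE) {
  if (validate) {
    validate_molgraph(reactant)
    validate_molgraph(product)
    if (length(reactant$elements) != length(product$elements) ||
        any(reactant$elements != product$elements))
      stop("reactant and product must share one atom index set (same elements in the same positions)")
  }
  delta <- product$bonds - reactant$bonds
  ut <- upper.tri(delta)
  br <- which(ut & delta < 0L, arr.ind = TRUE)
  fo <- which(ut & delta > 0L, arr.ind = TRUE)
  broken <- cbind(i = br[, 1], j = br[, 2], units = -delta[br])
  formed <- cbind(i = fo[, 1], j = fo[, 2], units = delta[fo])
  structure(list(reactant = reactant, product = product,
                 broken = broken, formed = formed),
            class = "mapped_reaction")
}

#' Reverse a reaction
#' @param r a [mapped_reaction()].
#' @return the reaction with reactant and product sides swapped.
#' @export
reverse_reaction <- function(r) {
  mapped_reaction(r$product, r$reactant, validate = FALSE)
}

#' Apply an elementary-step edit to a molecular graph
#'
#' Decrements the bond order of each pair in `breaks` by one unit and
#' increments each pair in `forms` by one unit (a pair may appear several
#' times for multi-unit changes), then validates the resulting product graph.
#' This is the primitive both the enumerator and the model-reaction
#' generator are built on.
#'
#' @param g reactant [molgraph()].
#' @param breaks,forms two-column integer matrices of atom index pairs (or
#'   `NULL` for none).
#' @return a [mapped_reaction()] from `g` to the edited graph.
#' @export
apply_ers <- function(g, breaks = NULL, forms = NULL) {
  b <- g$bonds
  ed <- function(m, d) {
    if (is.null(m) || nrow(m) == 0) return(invisible(NULL))
    for (k in seq_len(nrow(m))) {
      i <- m[k, 1]; j <- m[k, 2]
      if (i == j) stop("self-bond edit")
      b[i, j] <<- b[i, j] + d
      b[j, i] <<- b[i, j]
    }
  }
  ed(breaks, -1L); ed(forms, +1L)
  if (any(b < 0L)) stop("bond edit drives a bond order below zero")
  if (any(b > 3L)) stop("bond edit drives a bond order above three")
  p <- molgraph(g$elements, b, maps = g$maps, validate = TRUE)
  mapped_reaction(g, p, validate = FALSE)
}

#' Parse an atom-mapped reaction SMILES
#'
#' Reads a `"reactant(s)>>product(s)"` string. When both sides carry complete
#' atom maps the product atoms are aligned to the reactant atom order through
#' the maps; unmapped input is accepted only if the two sides list the same
#' elements in the same order.
#'
#' @param text reaction SMILES.
#' @param keep_maps keep the atom-map numbers on the returned graphs.
#' @return a [mapped_reaction()].
#' @export
parse_reaction_smiles <- function(text, keep_maps = TRUE) {
  sides <- strsplit(text, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop("reaction SMILES must have exactly one '>>': ", text)
  r <- parse_smiles_graph(sides[1], keep_maps = TRUE)
  p <- parse_smiles_graph(sides[2], keep_maps = TRUE)
  n <- length(r$elements)
  if (length(p$elements) != n)
    stop("reactant and product sides have different atom counts")
  rm_ <- r$maps; pm <- p$maps
  if (!is.null(rm_) && !is.null(pm) && !anyNA(rm_) && !anyNA(pm)) {
    perm <- match(rm_, pm)
    if (anyNA(perm)) stop("atom maps of the two sides do not match")
    p <- permute_molgraph(p, perm)
  } else if (any(r$elements != p$elements)) {
    stop("unmapped reaction SMILES: cannot align atoms across '>>'")
  }
  if (!keep_maps) { r$maps <- NULL; p$maps <- NULL }
  mapped_reaction(r, p)
}

#' Write a reaction as atom-mapped reaction SMILES
#'
#' @param r a [mapped_reaction()].
#' @param with_maps write atom-map numbers on every atom (default `TRUE`;
#'   maps are what make the two sides alignable on re-parse).
#' @return a `"reactants>>products"` string.
#' @export
write_reaction_smiles <- function(r, with_maps = TRUE) {
  n <- length(r$reactant$elements)
  if (with_maps) {
    maps <- r$reactant$maps
    if (is.null(maps) || anyNA(maps)) maps <- seq_len(n)
    rg <- r$reactant; rg$maps <- maps
    pg <- r$product;  pg$maps <- maps
    paste0(write_smiles(rg, with_maps = TRUE),
           ">>",
           write_smiles(pg, with_maps = TRUE))
  } else {
    paste0(write_smiles(r$reactant), ">>", write_smiles(r$product))
  }
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat("mapped_reaction:", write_smiles(x$reactant), ">>",
      write_smiles(x$product), "\n")
  cat(sprintf("  %d broken / %d formed bond-order units\n",
              sum(x$broken[, "units"]), sum(x$formed[, "units"])))
  invisible(x)
}

#' @export
format.mapped_reaction <- function(x, ...) {
  paste0(write_smiles(x$reactant), ">>", write_smiles(x$product))
}
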