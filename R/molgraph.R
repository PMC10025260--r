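# Molecular graphs over C, H, O, N with integer bond orders (the
# bond-electron matrix representation). Only neutral closed-shell species
# are representable: every atom sits at its fixed neutral valence
# (H = 1, O = 2, N = 3, C = 4) and lone electrons are a function of the
# element, so the whole Lewis structure is determined by the bond matrix.

CHON_VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L)
CHON_LONE    <- c(H = 0L, C = 0L, N = 2L, O = 4L)

#: CODATA Hartree -> kcal/mol
HARTREE_TO_KCAL <- 627.509474

#' Construct a molecular graph
#'
#' A `molgraph` is an explicit-hydrogen molecular graph over the elements
#' C, H, O and N with integer bond orders 0--3. It may contain several
#' disconnected fragments (e.g. the full reactant side of a reaction).
#' Hydrogens are always explicit atoms, and every atom must sit at its
#' neutral closed-shell valence (H 1, O 2, N 3, C 4); lone-electron counts
#' follow from the element (O keeps two lone pairs, N one, C and H none).
#'
#' @param elements character vector of element symbols in `c("C","H","O","N")`.
#' @param bonds integer matrix of bond orders (symmetric, zero diagonal,
#'   entries 0--3), one row/column per atom.
#' @param maps optional integer vector of atom-map numbers (unique, >= 1)
#'   carried from atom-mapped SMILES; `NA` entries mean "unmapped".
#' @param validate check the closed-shell invariants (default `TRUE`).
#' @return an object of class `molgraph` with fields `elements`, `bonds`
#'   and `maps`.
#' @seealso [parse_smiles()], [be_matrix()], [canonical_hash()]
#' @export
#' @examples
#' # methane built by hand
#' el <- c("C", "H", "H", "H", "H")
#' b <- matrix(0L, 5, 5); b[1, 2:5] <- b[2:5, 1] <- 1L
#' g <- molgraph(el, b)
#' heavy_atoms(g)
molgraph <- function(elements, bonds, maps = NULL, validate = TRUE) {
  elements <- as.character(elements)
  storage.mode(bonds) <- "integer"
  if (!is.null(maps)) maps <- as.integer(maps)
  g <- structure(list(elements = elements, bonds = bonds, maps = maps),
                 class = "molgraph")
  if (validate) validate_molgraph(g)
  g
}

#' Validate the closed-shell invariants of a molecular graph
#'
#' Checks that the bond matrix is symmetric with zero diagonal and entries
#' in 0--3, that every element is one of C, H, O, N, that every atom's total
#' bond order equals its fixed neutral valence (which also forces an even
#' total electron count), and that atom maps, when present, are unique
#' positive integers.
#'
#' @param g a [molgraph()].
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_molgraph <- function(g) {
  if (!inherits(g, "molgraph")) stop("not a molgraph")
  el <- g$elements
  b <- g$bonds
  n <- length(el)
  bad <- setdiff(unique(el), names(CHON_VALENCE))
  if (length(bad) > 0)
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (!is.matrix(b) || nrow(b) != n || ncol(b) != n)
    stop("bond matrix dimensions do not match atom count")
  if (any(diag(b) != 0L)) stop("bond matrix has nonzero diagonal")
  if (!identical(b, t(b))) stop("bond matrix is not symmetric")
  if (any(b < 0L) || any(b > 3L)) stop("bond orders must lie in 0..3")
  deg <- rowSums(b)
  want <- CHON_VALENCE[el]
  if (any(deg != want)) {
    i <- which(deg != want)[1]
    stop(sprintf(
      "open-shell or charged species: atom %d (%s) has total bond order %d, expected %d",
      i, el[i], deg[i], want[i]))
  }
  if (!is.null(g$maps)) {
    m <- g$maps[!is.na(g$maps)]
    if (any(m < 1L)) stop("atom maps must be >= 1")
    if (anyDuplicated(m)) stop("duplicate atom-map numbers")
  }
  invisible(g)
}

#' Bond-electron (BE) matrix of a molecule
#'
#' The BE matrix in the Dugundji--Ugi sense: off-diagonal entries are bond
#' orders, diagonal entries are lone (non-bonding) electron counts. For the
#' neutral closed-shell CHON subset the diagonal is fixed per element
#' (C 0, H 0, N 2, O 4), so every row satisfies the octet/duet count
#' 2 * (bond order sum) + lone electrons = 8 (or 2 for H).
#'
#' @param g a [molgraph()].
#' @return integer matrix with lone electrons on the diagonal.
#' @export
#' @examples
#' w <- parse_smiles("O")   # water
#' be_matrix(w)             # O diagonal 4, two O-H entries of 1
be_matrix <- function(g) {
  validate_molgraph(g)
  m <- g$bonds
  diag(m) <- CHON_LONE[g$elements]
  dimnames(m) <- list(g$elements, g$elements)
  m
}

#' Count heavy (non-hydrogen) atoms
#' @param g a [molgraph()].
#' @return integer count.
#' @export
heavy_atoms <- function(g) sum(g$elements != "H")

# connected-component labels over atoms (any bond order >= 1 connects)
fragment_ids <- function(g) {
  n <- length(g$elements)
  comp <- integer(n)
  cur <- 0L
  adj <- g$bonds > 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# split a (possibly multi-fragment) molgraph into connected fragments
split_fragments <- function(g) {
  comp <- fragment_ids(g)
  lapply(seq_len(max(comp)), function(k) {
    idx <- which(comp == k)
    molgraph(g$elements[idx], g$bonds[idx, idx, drop = FALSE],
             maps = if (is.null(g$maps)) NULL else g$maps[idx],
             validate = FALSE)
  })
}

# concatenate molgraphs into one multi-fragment graph
combine_molgraphs <- function(gs) {
  els <- unlist(lapply(gs, `[[`, "elements"))
  n <- length(els)
  b <- matrix(0L, n, n)
  maps <- rep(NA_integer_, n)
  off <- 0L
  any_maps <- FALSE
  for (g in gs) {
    k <- length(g$elements)
    b[off + seq_len(k), off + seq_len(k)] <- g$bonds
    if (!is.null(g$maps)) { maps[off + seq_len(k)] <- g$maps; any_maps <- TRUE }
    off <- off + k
  }
  molgraph(els, b, maps = if (any_maps) maps else NULL, validate = FALSE)
}

#' @export
print.molgraph <- function(x, ...) {
  nfrag <- max(fragment_ids(x))
  cat(sprintf("molgraph: %d atoms (%d heavy), %d fragment%s\n",
              length(x$elements), heavy_atoms(x), nfrag,
              if (nfrag == 1) "" else "s"))
  cat("  ", write_smiles(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.molgraph <- function(x, ...) write_smiles(x)

# permute atom order (used by tests and canonical writer)
permute_molgraph <- function(g, perm) {
  molgraph(g$elements[perm], g$bonds[perm, perm, drop = FALSE],
           maps = if (is.null(g$maps)) NULL else g$maps[perm],
           validate = FALSE)
}
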