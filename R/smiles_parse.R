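# SMILES reader for the neutral closed-shell CHON subset.
#
# Supported: C/N/O/H atoms (plain or bracketed), atom maps ([CH3:4]),
# explicit bonds - = # :, branches, ring closures (1-9 and %nn), dots,
# aromatic lowercase c/n/o (kekulized to integer bond orders on input).
# Rejected: charges, radicals/under-coordinated bracket atoms, isotopes,
# stereo marks, and any element outside C, H, O, N.

#' Parse SMILES into molecular graph(s)
#'
#' Builds an explicit-hydrogen [molgraph()] from a SMILES string. Implicit
#' hydrogens are expanded into real atoms at parse time (an elementary-step
#' enumerator must be able to break bonds to hydrogen). Aromatic input is
#' kekulized to alternating integer bond orders, since the bond-electron
#' matrix requires integer orders. Atom maps are preserved when
#' `keep_maps = TRUE`.
#'
#' Only neutral closed-shell species over C, H, O and N are accepted:
#' charged or radical species (e.g. charge-separated nitro groups) raise an
#' error, as does any other element.
#'
#' @param text a SMILES string; fragments may be separated by `.`.
#' @param keep_maps keep bracket atom-map numbers (default `TRUE`).
#' @return a [molgraph()] for single-fragment input, or a list of
#'   `molgraph` objects for dot-separated multi-fragment input.
#' @export
#' @examples
#' parse_smiles("C")          # methane, 1 C + 4 H
#' parse_smiles("O=CCCOO")    # gamma-ketohydroperoxide
#' length(parse_smiles("C.O"))  # two fragments -> list of 2
parse_smiles <- function(text, keep_maps = TRUE) {
  g <- parse_smiles_graph(text, keep_maps = keep_maps)
  frags <- split_fragments(g)
  if (length(frags) == 1) frags[[1]] else frags
}

# parse a SMILES string into ONE molgraph (fragments kept together)
parse_smiles_graph <- function(text, keep_maps = TRUE) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || nchar(text) == 0)
    stop("SMILES parse error: input must be a single non-empty string")
  chars <- strsplit(text, "")[[1]]
  np <- length(chars)

  el <- character(0)       # element symbol
  arom <- logical(0)       # written lowercase?
  hcount <- integer(0)     # bracket H count, NA = implicit (plain atom)
  amap <- integer(0)       # atom map, NA if absent
  bond_a <- integer(0); bond_b <- integer(0)
  bond_ord <- integer(0)   # NA = unspecified
  bond_arom <- logical(0)  # written with ':' or default between aromatic atoms

  prev <- NA_integer_
  pending <- NA_integer_   # explicit bond order waiting for next atom
  pending_set <- FALSE
  stack <- integer(0)
  rings <- list()          # key: ring number, value: list(atom, ord)

  err <- function(...) stop("SMILES parse error in '", text, "': ", ...)

  add_atom <- function(sym, aromatic, h, map) {
    el <<- c(el, sym); arom <<- c(arom, aromatic)
    hcount <<- c(hcount, h); amap <<- c(amap, map)
    idx <- length(el)
    if (!is.na(prev)) {
      ord <- if (pending_set) pending else NA_integer_
      add_bond(prev, idx, ord)
    }
    pending <<- NA_integer_; pending_set <<- FALSE
    prev <<- idx
    idx
  }
  add_bond <- function(a, b, ord) {
    is_ar <- FALSE
    if (is.na(ord)) {
      if (arom[a] && arom[b]) { is_ar <- TRUE; ord <- 1L } else ord <- 1L
    } else if (ord == -1L) {  # ':' aromatic bond token
      is_ar <- TRUE; ord <- 1L
    }
    bond_a <<- c(bond_a, a); bond_b <<- c(bond_b, b)
    bond_ord <<- c(bond_ord, ord); bond_arom <<- c(bond_arom, is_ar)
  }
  ring_event <- function(num) {
    key <- as.character(num)
    ord <- if (pending_set) pending else NA_integer_
    pending <<- NA_integer_; pending_set <<- FALSE
    if (is.na(prev)) err("ring-closure digit before any atom")
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, ord = ord)
    } else {
      op <- rings[[key]]
      use <- if (!is.na(ord)) ord else op$ord
      if (!is.na(ord) && !is.na(op$ord) && ord != op$ord)
        err("conflicting bond orders on ring closure ", key)
      add_bond(op$atom, prev, if (is.na(use)) NA_integer_ else use)
      rings[[key]] <<- NULL
    }
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    if (ch %in% c("C", "N", "O")) {
      nxt <- if (i < np) chars[i + 1] else ""
      if (ch == "C" && nxt == "l") err("unsupported element: Cl")
      add_atom(ch, FALSE, NA_integer_, NA_integer_)
    } else if (ch %in% c("c", "n", "o")) {
      add_atom(toupper(ch), TRUE, NA_integer_, NA_integer_)
    } else if (ch == "[") {
      j <- i
      while (j <= np && chars[j] != "]") j <- j + 1L
      if (j > np) err("unterminated bracket atom")
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      i <- j
      m <- regmatches(body,
        regexec("^([0-9]+)?([A-Za-z][a-z]?)(@+)?(H([0-9]*))?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:([0-9]+))?$",
                body))[[1]]
      if (length(m) == 0) err("malformed bracket atom [", body, "]")
      if (nzchar(m[2])) err("isotope labels not supported: [", body, "]")
      if (nzchar(m[4])) err("stereochemistry not supported: [", body, "]")
      if (nzchar(m[7]))
        stop("open-shell/charged species not supported: [", body, "]")
      sym <- m[3]
      aromatic <- sym %in% c("c", "n", "o")
      usym <- toupper(sym)
      if (!usym %in% c("C", "N", "O", "H"))
        stop("unsupported element: ", sym)
      h <- 0L
      if (nzchar(m[5])) h <- if (nzchar(m[6])) as.integer(m[6]) else 1L
      if (usym == "H" && h > 0) err("[H] atom cannot carry hydrogens")
      map <- if (nzchar(m[9])) as.integer(m[9]) else NA_integer_
      add_atom(usym, aromatic, h, map)
    } else if (ch == "-") { pending <- 1L; pending_set <- TRUE
    } else if (ch == "=") { pending <- 2L; pending_set <- TRUE
    } else if (ch == "#") { pending <- 3L; pending_set <- TRUE
    } else if (ch == ":") { pending <- -1L; pending_set <- TRUE
    } else if (ch == "/" || ch == "\\") { pending <- 1L; pending_set <- TRUE
    } else if (ch == "(") {
      if (is.na(prev)) err("branch open before any atom")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (length(stack) == 0) err("unbalanced branch close")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else if (ch == ".") {
      prev <- NA_integer_
      if (pending_set) err("bond symbol before '.'")
    } else if (ch == "%") {
      if (i + 2 > np || !all(grepl("[0-9]", chars[i + 1:2])))
        err("malformed %nn ring closure")
      ring_event(as.integer(paste(chars[i + 1:2], collapse = "")))
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      ring_event(as.integer(ch))
    } else {
      if (grepl("[A-Za-z]", ch)) stop("unsupported element: ", ch)
      err("unexpected character '", ch, "'")
    }
    i <- i + 1L
  }
  if (length(stack) > 0) err("unbalanced branch open")
  if (length(rings) > 0)
    err("unclosed ring bond(s): ", paste(names(rings), collapse = ", "))
  n <- length(el)
  if (n == 0) err("no atoms")

  bonds <- matrix(0L, n, n)
  for (k in seq_along(bond_a)) {
    a <- bond_a[k]; b <- bond_b[k]
    if (a == b) err("self-bond")
    if (bonds[a, b] != 0L) err("duplicate bond between atoms ", a, " and ", b)
    bonds[a, b] <- bonds[b, a] <- bond_ord[k]
  }

  # kekulize aromatic systems and settle implicit hydrogen counts
  kek <- kekulize(el, arom, hcount, bonds, bond_a, bond_b, bond_arom, err)
  bonds <- kek$bonds
  nH <- kek$nH

  # expand hydrogens into explicit atoms
  heavy_n <- n
  extra <- sum(nH)
  tot <- heavy_n + extra
  full <- matrix(0L, tot, tot)
  full[seq_len(n), seq_len(n)] <- bonds
  el_full <- c(el, rep("H", extra))
  map_full <- c(amap, rep(NA_integer_, extra))
  hi <- heavy_n
  for (a in seq_len(n)) {
    if (nH[a] > 0) {
      for (k in seq_len(nH[a])) {
        hi <- hi + 1L
        full[a, hi] <- full[hi, a] <- 1L
      }
    }
  }
  maps <- if (keep_maps && any(!is.na(map_full))) map_full else NULL
  g <- molgraph(el_full, full, maps = maps, validate = FALSE)
  validate_molgraph(g)
  g
}

# Kekulization: aromatic bonds start at order 1; every aromatic atom that is
# one bond short of its fixed valence must receive exactly one double bond,
# and those atoms must admit a perfect matching along aromatic bonds.
# Deterministic backtracking (atoms in index order) breaks ties between
# kekule forms. Returns integer bond matrix and per-atom implicit H counts.
kekulize <- function(el, arom, hcount, bonds, bond_a, bond_b, bond_arom, err) {
  n <- length(el)
  val <- CHON_VALENCE[el]
  expl <- rowSums(bonds)
  nH <- integer(n)
  needs <- logical(n)
  for (a in seq_len(n)) {
    if (!arom[a]) {
      if (!is.na(hcount[a])) nH[a] <- hcount[a]
      else {
        nH[a] <- val[a] - expl[a]
        if (nH[a] < 0) err("valence of atom ", a, " (", el[a], ") exceeded")
      }
    } else {
      if (!is.na(hcount[a])) {                   # bracketed aromatic, e.g. [nH]
        gap <- val[a] - expl[a] - hcount[a]
        if (!gap %in% c(0L, 1L))
          err("cannot kekulize aromatic atom ", a, " (", el[a], ")")
        needs[a] <- gap == 1L
        nH[a] <- hcount[a]
      } else {
        h <- val[a] - expl[a] - 1L               # prefer one double bond
        if (h >= 0) { needs[a] <- TRUE; nH[a] <- h }
        else {
          h <- val[a] - expl[a]
          if (h < 0) err("valence of aromatic atom ", a, " exceeded")
          needs[a] <- FALSE; nH[a] <- h
        }
      }
    }
  }
  if (any(needs)) {
    # aromatic-bond adjacency restricted to atoms needing a double bond
    ar_edges <- cbind(bond_a, bond_b)[bond_arom, , drop = FALSE]
    keep <- needs[ar_edges[, 1]] & needs[ar_edges[, 2]]
    ar_edges <- ar_edges[keep, , drop = FALSE]
    match_res <- kekule_matching(which(needs), ar_edges)
    if (is.null(match_res))
      err("kekulization failed: no alternating bond assignment exists")
    for (k in seq_len(nrow(match_res))) {
      a <- match_res[k, 1]; b <- match_res[k, 2]
      bonds[a, b] <- bonds[b, a] <- 2L
    }
  }
  list(bonds = bonds, nH = nH)
}

# deterministic backtracking perfect matching; returns matrix of pairs or NULL
kekule_matching <- function(nodes, edges) {
  if (length(nodes) %% 2L != 0L) return(NULL)
  adj <- lapply(seq_len(max(c(nodes, 1L))), function(i) integer(0))
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  matched <- integer(0)
  recurse <- function(todo, acc) {
    if (length(todo) == 0) return(acc)
    v <- todo[1]
    for (w in sort(adj[[v]])) {
      if (w %in% todo[-1]) {
        res <- recurse(setdiff(todo[-1], w), rbind(acc, c(v, w)))
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  recurse(sort(nodes), matrix(integer(0), 0, 2))
}
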