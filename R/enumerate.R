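# Exhaustive elementary-reaction-step (ERS) enumeration on the
# bond-electron matrix. An ERS "bnfm" breaks n bond-order units and forms m.
# The workhorse is b2f2 (break two, form two): for every pair of distinct
# bonds (A,B) and (C,D) both rearrangements {(A,C),(B,D)} and {(A,D),(B,C)}
# are attempted; re-forming the broken pair is the null transformation and
# is dropped, as is any self-bond. "Breaking" decrements one unit of bond
# order (a double bond breaks to a single bond) and "forming" increments by
# one, including between already-bonded atoms, so pi-bond formation falls
# out of the same arithmetic.
#
# Generalization to bnfm: the broken bond units contribute 2n endpoint
# slots; formed bonds are pairings of those slots (a perfect matching for
# bnfn, a near-perfect matching leaving two slots open for bnf(n-1)). A
# pairing conserves every atom's total bond order by construction; the
# near-perfect case leaves two atoms under-coordinated and is therefore
# always rejected by the closed-shell valence filter on CHON -- the spec of
# such families is accepted and enumerated, and the filter decides.

#' ERS specification
#'
#' @param n_break number of bond-order units to break (1--6).
#' @param n_form number of bond-order units to form; the families observed
#'   in depth-1 TS datasets are `n_form == n_break` (bnfn) and
#'   `n_form == n_break - 1` (bnf(n-1)).
#' @return an object of class `ers_spec`.
#' @export
#' @examples
#' ers_spec(2, 2)  # the default b2f2 rule
ers_spec <- function(n_break = 2L, n_form = 2L) {
  n_break <- as.integer(n_break); n_form <- as.integer(n_form)
  if (is.na(n_break) || n_break < 1L || n_break > 6L)
    stop("n_break must be in 1..6")
  if (is.na(n_form) || !(n_form %in% c(n_break, n_break - 1L)) || n_form < 1L)
    stop("n_form must equal n_break or n_break - 1 (and be >= 1)")
  structure(list(n_break = n_break, n_form = n_form,
                 label = sprintf("b%df%d", n_break, n_form)),
            class = "ers_spec")
}

#' Enumerate b2f2 elementary reaction steps
#'
#' Exhaustively applies the break-two/form-two rule to a reactant graph and
#' returns every valence-valid, non-null product, deduplicated by the
#' direction-invariant [reaction_hash()] and sorted by hash (so runs are
#' reproducible without seeds).
#'
#' @param reactant a [molgraph()] (possibly multi-fragment), a SMILES
#'   string, or a list of `molgraph` fragments for a bimolecular seed.
#' @param max_candidates safety cap on the number of raw candidates.
#' @return a list of [mapped_reaction()] objects, named by reaction hash.
#' @export
#' @examples
#' length(enumerate_b2f2("C"))    # methane admits no b2f2 reaction
#' rxns <- enumerate_b2f2("CC")   # ethane: includes ethene + H2
enumerate_b2f2 <- function(reactant, max_candidates = 2e5) {
  enumerate_ers(reactant, ers_spec(2L, 2L), max_candidates = max_candidates)
}

#' Enumerate general bnfm elementary reaction steps
#'
#' @inheritParams enumerate_b2f2
#' @param spec an [ers_spec()]; `ers_spec(2, 2)` reproduces
#'   [enumerate_b2f2()] exactly.
#' @return a list of [mapped_reaction()] objects, named by reaction hash,
#'   each with exactly `n_break` net bond-order decrements and `n_form` net
#'   increments.
#' @export
enumerate_ers <- function(reactant, spec = ers_spec(),
                          max_candidates = 2e5) {
  stopifnot(inherits(spec, "ers_spec"))
  g <- as_reactant_graph(reactant)
  validate_molgraph(g)  # open-shell input errors here

  ut <- which(upper.tri(g$bonds) & g$bonds > 0L, arr.ind = TRUE)
  nb <- nrow(ut)
  if (nb == 0) return(structure(list(), names = character(0)))
  orders <- g$bonds[ut]

  breaks_sets <- multiset_combinations(nb, spec$n_break, orders)
  pairings <- slot_pairings(2L * spec$n_break, spec$n_form)
  n_cand <- length(breaks_sets) * length(pairings)
  if (n_cand > max_candidates)
    stop(sprintf("combinatorial budget exceeded: %d candidates > max_candidates = %g",
                 n_cand, max_candidates))

  out <- list()
  for (bs in breaks_sets) {
    slots <- as.vector(t(ut[bs, , drop = FALSE]))  # 2*n_break endpoint atoms
    for (pr in pairings) {
      r <- try_ers_candidate(g, ut[bs, , drop = FALSE], slots, pr, spec)
      if (is.null(r)) next
      h <- reaction_hash(r)
      if (is.null(out[[h]])) out[[h]] <- r
    }
  }
  if (length(out) == 0) return(structure(list(), names = character(0)))
  out[order(names(out))]
}

# coerce SMILES / molgraph / list of molgraphs to one reactant graph
as_reactant_graph <- function(x) {
  if (is.character(x)) return(parse_smiles_graph(x))
  if (inherits(x, "molgraph")) return(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "molgraph")))
    return(combine_molgraphs(x))
  stop("reactant must be a SMILES string, a molgraph, or a list of molgraphs")
}

# build and filter one candidate; returns mapped_reaction or NULL
try_ers_candidate <- function(g, broken_pairs, slots, pairing, spec) {
  b <- g$bonds
  for (k in seq_len(nrow(broken_pairs))) {
    i <- broken_pairs[k, 1]; j <- broken_pairs[k, 2]
    b[i, j] <- b[j, i] <- b[i, j] - 1L
  }
  if (any(b < 0L)) return(NULL)
  if (!is.null(pairing)) {
    for (k in seq_len(nrow(pairing))) {
      a <- slots[pairing[k, 1]]; c_ <- slots[pairing[k, 2]]
      if (a == c_) return(NULL)                 # self-bond
      b[a, c_] <- b[c_, a] <- b[a, c_] + 1L
    }
  }
  if (any(b > 3L)) return(NULL)
  if (any(rowSums(b) != CHON_VALENCE[g$elements])) return(NULL)  # open shell
  d <- b - g$bonds
  if (all(d == 0L)) return(NULL)                # null transformation
  # net signature must match the spec (cancellations demote the reaction)
  net_broken <- -sum(d[upper.tri(d) & d < 0L])
  net_formed <- sum(d[upper.tri(d) & d > 0L])
  if (net_broken != spec$n_break || net_formed != spec$n_form) return(NULL)
  p <- molgraph(g$elements, b, maps = g$maps, validate = FALSE)
  mapped_reaction(g, p, validate = FALSE)
}

# multisets of k bond indices from 1..n, with per-bond multiplicity caps
multiset_combinations <- function(n, k, caps) {
  res <- list()
  recurse <- function(start, left, acc) {
    if (left == 0L) { res[[length(res) + 1L]] <<- acc; return(invisible(NULL)) }
    for (i in start:n) {
      if (sum(acc == i) < caps[i]) recurse(i, left - 1L, c(acc, i))
    }
  }
  if (n >= 1 && k >= 1) recurse(1L, k, integer(0))
  res
}

# all pairings of `m` slots into `n_pairs` unordered pairs (remaining slots,
# if any, stay unmatched); returns list of two-column matrices (or list(NULL)
# for zero pairs)
slot_pairings <- function(m, n_pairs) {
  res <- list()
  recurse <- function(avail, left, acc) {
    if (left == 0L) {
      res[[length(res) + 1L]] <<- if (is.null(acc)) NULL else acc
      return(invisible(NULL))
    }
    a <- avail[1]
    for (b in avail[-1]) {
      recurse(setdiff(avail, c(a, b)), left - 1L, rbind(acc, c(a, b)))
    }
  }
  n_single <- m - 2L * n_pairs
  if (n_single == 0L) {
    recurse(seq_len(m), n_pairs, NULL)
  } else {
    # choose the unmatched slots, then pair the rest
    singles <- utils::combn(m, n_single, simplify = FALSE)
    for (s in singles) {
      recurse(setdiff(seq_len(m), s), n_pairs, NULL)
    }
    res <- unique(res)
  }
  res
}
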