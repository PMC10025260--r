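# Graphically-defined model reactions: the smallest reaction with the same
# number and type of bond changes as a parent reaction, where bond types are
# made unique out to `depth` bonded neighbors of the reacting atoms
# (depth 1 is the convention behind depth-1 TS datasets).
#
# Truncation keeps the reactive atoms (every atom incident to a broken or
# formed bond) plus their neighbors out to `depth` in the union of the
# reactant and product graphs. Truncation severs only single bonds: a
# neighbor attached to a retained atom through a bond of order >= 2 (on
# either side) is itself retained regardless of depth, so every severed bond
# can be replaced 1-for-1 by a cap hydrogen and the sigma framework -- hence
# the hybridization -- of every retained atom is preserved exactly.

#' Model reaction of a parent reaction
#'
#' @param parent a [mapped_reaction()].
#' @param depth how many bonds away from the reactive atoms the chemical
#'   environment is preserved (default 1).
#' @return an object of class `model_reaction`: a list with `reaction` (the
#'   truncated [mapped_reaction()]), `parent_map` (for each model atom, the
#'   index of the parent atom it came from; `NA` for added cap hydrogens)
#'   and `depth`.
#' @details The operation is a fixed point: reapplying it at the same depth
#'   returns the same reaction (a cap hydrogen is truncated back to a cap
#'   hydrogen). The multiset of bond changes of the model equals that of the
#'   parent, and each reactive atom keeps its bonded-neighbor count and
#'   (element-implied) lone pairs on both sides.
#' @export
#' @examples
#' r <- enumerate_b2f2("CC")[[1]]
#' m <- model_reaction(r)
#' heavy_atoms(m$reaction$reactant) <= heavy_atoms(r$reactant)
model_reaction <- function(parent, depth = 1L) {
  stopifnot(inherits(parent, "mapped_reaction"))
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 0L) stop("depth must be a non-negative integer")
  R <- parent$reactant$bonds
  P <- parent$product$bonds
  el <- parent$reactant$elements
  n <- length(el)

  changed <- rbind(parent$broken[, 1:2, drop = FALSE],
                   parent$formed[, 1:2, drop = FALSE])
  if (nrow(changed) == 0) stop("parent reaction has no bond changes")
  reactive <- sort(unique(as.vector(changed)))

  union_adj <- (R > 0L) | (P > 0L)
  multi_adj <- (R >= 2L) | (P >= 2L)

  keep <- rep(FALSE, n)
  keep[reactive] <- TRUE
  frontier <- reactive
  d <- 0L
  while (d < depth && length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(union_adj[v, ] & !keep)
      keep[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
    d <- d + 1L
  }
  # closure: atoms attached to a retained atom by a multiple bond (on either
  # side) are retained regardless of depth, so caps are always single bonds
  repeat {
    add <- which(!keep & apply(multi_adj[, keep, drop = FALSE], 1, any))
    if (length(add) == 0) break
    keep[add] <- TRUE
  }

  kept <- which(keep)
  m <- length(kept)
  # severed bonds: kept--removed pairs; by the closure rule they are single
  # bonds and identical on both sides (a changed bond has both ends reactive)
  sev_from <- integer(0)
  for (v in kept) {
    cut <- which(R[v, ] > 0L & !keep)
    if (length(cut) > 0) {
      stopifnot(all(R[v, cut] == 1L), all(P[v, cut] == R[v, cut]))
      sev_from <- c(sev_from, rep(v, length(cut)))
    }
  }
  ncap <- length(sev_from)

  tot <- m + ncap
  Rb <- matrix(0L, tot, tot); Pb <- matrix(0L, tot, tot)
  Rb[seq_len(m), seq_len(m)] <- R[kept, kept]
  Pb[seq_len(m), seq_len(m)] <- P[kept, kept]
  for (k in seq_len(ncap)) {
    v <- match(sev_from[k], kept)
    w <- m + k
    Rb[v, w] <- Rb[w, v] <- 1L
    Pb[v, w] <- Pb[w, v] <- 1L
  }
  el_m <- c(el[kept], rep("H", ncap))
  rg <- molgraph(el_m, Rb)
  pg <- molgraph(el_m, Pb)
  structure(list(reaction = mapped_reaction(rg, pg, validate = FALSE),
                 parent_map = c(kept, rep(NA_integer_, ncap)),
                 depth = depth),
            class = "model_reaction")
}

#' @export
print.model_reaction <- function(x, ...) {
  cat(sprintf("model_reaction (depth %d): ", x$depth))
  cat(write_smiles(x$reaction$reactant), ">>", write_smiles(x$reaction$product), "\n")
  cat(sprintf("  %d atoms, of which %d cap hydrogen%s\n",
              length(x$parent_map), sum(is.na(x$parent_map)),
              if (sum(is.na(x$parent_map)) == 1) "" else "s"))
  invisible(x)
}

#' Model-reaction saturation curve over a molecule stream
#'
#' Processes molecules in order, enumerating b2f2 reactions of each,
#' reducing every reaction to its depth-`depth` model reaction, and tracking
#' how many distinct model reactions (keyed by the direction-invariant
#' [reaction_hash()]) have been seen. Counts are reported at fixed intervals
#' of processed reactants, mirroring how reaction-space saturation is
#' monitored when a large compound library is swept.
#'
#' @param molecules list of [molgraph()] objects and/or SMILES strings.
#' @param interval report every this many reactants (default 10).
#' @param depth model-reaction depth (default 1).
#' @return a data.frame with columns `reactants_processed`,
#'   `cumulative_unique` and `new_models` (one row per completed interval
#'   plus a final partial interval if needed). Unparseable entries are
#'   skipped; their count is in `attr(, "n_skipped")`.
#' @export
saturation_curve <- function(molecules, interval = 10L, depth = 1L) {
  interval <- as.integer(interval)
  stopifnot(interval >= 1L)
  seen <- new.env(parent = emptyenv())
  total <- 0L
  n_skipped <- 0L
  rows <- list()
  processed <- 0L
  new_in_interval <- 0L
  for (mol in molecules) {
    g <- tryCatch(as_reactant_graph(mol), error = function(e) NULL)
    if (is.null(g)) {
      n_skipped <- n_skipped + 1L
      next
    }
    processed <- processed + 1L
    for (r in enumerate_b2f2(g)) {
      h <- reaction_hash(model_reaction(r, depth = depth)$reaction)
      if (!exists(h, envir = seen, inherits = FALSE)) {
        assign(h, TRUE, envir = seen)
        total <- total + 1L
        new_in_interval <- new_in_interval + 1L
      }
    }
    if (processed %% interval == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        reactants_processed = processed,
        cumulative_unique = total,
        new_models = new_in_interval)
      new_in_interval <- 0L
    }
  }
  if (processed %% interval != 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      reactants_processed = processed,
      cumulative_unique = total,
      new_models = new_in_interval)
  }
  out <- if (length(rows) == 0) {
    data.frame(reactants_processed = integer(0),
               cumulative_unique = integer(0),
               new_models = integer(0))
  } else do.call(rbind, rows)
  if (n_skipped > 0)
    message(n_skipped, " unparseable entr",
            if (n_skipped == 1) "y" else "ies", " skipped")
  attr(out, "n_skipped") <- n_skipped
  out
}
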