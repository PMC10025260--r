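# Seeded synthetic data and brute-force oracles: random valence-valid CHON
# molecules (emulating a curated neutral closed-shell compound library),
# exhaustive small-molecule enumeration, a naive reference enumerator, and
# fully self-consistent synthetic dataset records with optional planted
# defects for validator tests. A single seed is threaded through every
# stochastic step; there are no hidden entropy sources, and the caller's RNG
# state is left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the random-molecule generator
#'
#' @param seed integer seed; runs with equal seeds are identical.
#' @param heavy_atom_range integer `c(min, max)` heavy atoms per molecule.
#' @param element_weights sampling weights for the heavy elements C, N, O.
#' @param count number of molecules to draw.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, heavy_atom_range = c(3L, 6L),
                             element_weights = c(C = 0.7, N = 0.15, O = 0.15),
                             count = 10L) {
  stopifnot(length(heavy_atom_range) == 2,
            heavy_atom_range[1] >= 1,
            heavy_atom_range[2] >= heavy_atom_range[1],
            all(c("C", "N", "O") %in% names(element_weights)),
            count >= 1)
  structure(list(seed = as.integer(seed),
                 heavy_atom_range = as.integer(heavy_atom_range),
                 element_weights = element_weights[c("C", "N", "O")],
                 count = as.integer(count)),
            class = "generator_config")
}

# one random connected valence-valid heavy-atom skeleton, H-filled
random_molecule_once <- function(n_heavy, weights) {
  el <- sample(c("C", "N", "O"), n_heavy, replace = TRUE, prob = weights)
  val <- CHON_VALENCE[el]
  b <- matrix(0L, n_heavy, n_heavy)
  if (n_heavy > 1) {
    free <- val
    for (i in 2:n_heavy) {
      cand <- which(free[seq_len(i - 1)] >= 1L)
      if (length(cand) == 0) return(NULL)
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      b[i, j] <- b[j, i] <- 1L
      free[i] <- free[i] - 1L; free[j] <- free[j] - 1L
    }
    # sprinkle unsaturation and rings
    n_extra <- sample(0:2, 1, prob = c(0.5, 0.35, 0.15))
    for (k in seq_len(n_extra)) {
      free <- val - rowSums(b)
      pairs <- which(upper.tri(b), arr.ind = TRUE)
      ok <- free[pairs[, 1]] >= 1L & free[pairs[, 2]] >= 1L &
        b[pairs] < 3L
      pairs <- pairs[ok, , drop = FALSE]
      if (nrow(pairs) == 0) break
      p <- pairs[sample.int(nrow(pairs), 1), ]
      b[p[1], p[2]] <- b[p[2], p[1]] <- b[p[1], p[2]] + 1L
    }
  }
  # hydrogen fill
  free <- val - rowSums(b)
  if (any(free < 0)) return(NULL)
  nH <- sum(free)
  if (n_heavy == 1 && nH == 0) return(NULL)
  tot <- n_heavy + nH
  full <- matrix(0L, tot, tot)
  full[seq_len(n_heavy), seq_len(n_heavy)] <- b
  hi <- n_heavy
  for (a in seq_len(n_heavy)) {
    for (z in seq_len(free[a])) {
      hi <- hi + 1L
      full[a, hi] <- full[hi, a] <- 1L
    }
  }
  molgraph(c(el, rep("H", nH)), full)
}

#' Draw random valence-valid CHON molecules
#'
#' Generates connected neutral closed-shell molecules by growing a random
#' heavy-atom tree, optionally adding ring bonds or upgrading bond orders
#' where free valence permits, and filling the remaining valence with
#' explicit hydrogens. Every emitted graph passes [validate_molgraph()].
#'
#' @param cfg a [generator_config()].
#' @return list of [molgraph()] objects of length `cfg$count`.
#' @export
#' @examples
#' mols <- random_molecules(generator_config(seed = 7, count = 3))
#' vapply(mols, write_smiles, "")
random_molecules <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    out <- vector("list", cfg$count)
    for (k in seq_len(cfg$count)) {
      g <- NULL
      for (try in 1:100) {
        n_heavy <- sample(cfg$heavy_atom_range[1]:cfg$heavy_atom_range[2], 1)
        g <- random_molecule_once(n_heavy, cfg$element_weights)
        if (!is.null(g)) break
      }
      if (is.null(g))
        stop("could not generate a valid molecule after 100 attempts ",
             "(infeasible configuration)")
      out[[k]] <- g
    }
    out
  })
}

#' Enumerate all distinct small CHON molecules
#'
#' Complete, up-to-isomorphism enumeration of connected neutral closed-shell
#' molecules with at most `max_heavy` heavy atoms (explicit hydrogens fill
#' the remaining valence). Used as the ground set for hash-collision and
#' enumeration-oracle tests.
#'
#' @param max_heavy maximum heavy atoms, at most 5 (the combinatorics grow
#'   steeply beyond that; larger requests are refused).
#' @return named list of [molgraph()] objects, names = [canonical_hash()].
#' @export
#' @examples
#' names(exhaustive_small_molecules(1))  # the one-heavy-atom hydrides
exhaustive_small_molecules <- function(max_heavy) {
  max_heavy <- as.integer(max_heavy)
  if (is.na(max_heavy) || max_heavy < 1)
    stop("max_heavy must be a positive integer")
  if (max_heavy > 5)
    stop("refusing max_heavy > 5: the exhaustive set grows too fast; ",
         "use random_molecules() for larger sizes")
  out <- list()
  for (n in seq_len(max_heavy)) {
    el_sets <- multiset_combinations(3L, n, rep(n, 3))
    for (es in el_sets) {
      el <- c("C", "N", "O")[es]
      val <- CHON_VALENCE[el]
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      np <- nrow(pairs)
      assign_orders <- function(k, b) {
        if (k > np) {
          if (n > 1) {
            g0 <- molgraph(el, b, validate = FALSE)
            if (max(fragment_ids(g0)) != 1) return(invisible(NULL))
          }
          free <- val - rowSums(b)
          nH <- sum(free)
          tot <- n + nH
          full <- matrix(0L, tot, tot)
          full[seq_len(n), seq_len(n)] <- b
          hi <- n
          for (a in seq_len(n)) for (z in seq_len(free[a])) {
            hi <- hi + 1L
            full[a, hi] <- full[hi, a] <- 1L
          }
          g <- molgraph(c(el, rep("H", nH)), full, validate = FALSE)
          h <- canonical_hash(g)
          if (is.null(out[[h]])) out[[h]] <<- g
          return(invisible(NULL))
        }
        i <- pairs[k, 1]; j <- pairs[k, 2]
        for (o in 0:3) {
          b[i, j] <- b[j, i] <- o
          if (rowSums(b)[i] <= val[i] && rowSums(b)[j] <= val[j])
            assign_orders(k + 1L, b)
        }
      }
      assign_orders(1L, matrix(0L, n, n))
    }
  }
  out[order(names(out))]
}

#' Naive brute-force elementary-step enumerator (oracle)
#'
#' Reference implementation against which the optimized enumerator is
#' checked: it materializes every combination of broken bond units and every
#' set of formed pairs drawn from the endpoint atoms -- with no structural
#' pruning at all -- then filters by graph validity at the end and
#' deduplicates by sorting serialized reactions. Slow on purpose; use only
#' on small molecules.
#'
#' @param mol a [molgraph()] or SMILES string.
#' @param spec an [ers_spec()].
#' @param max_candidates refuse larger searches.
#' @return list of [mapped_reaction()] objects named by hash, sorted by
#'   hash (comparable 1:1 with [enumerate_ers()] output).
#' @export
brute_force_ers <- function(mol, spec = ers_spec(), max_candidates = 1e6) {
  g <- as_reactant_graph(mol)
  validate_molgraph(g)
  ut <- which(upper.tri(g$bonds) & g$bonds > 0L, arr.ind = TRUE)
  if (nrow(ut) == 0) return(structure(list(), names = character(0)))
  orders <- g$bonds[ut]

  breaks_sets <- multiset_combinations(nrow(ut), spec$n_break, orders)
  results <- list()
  for (bs in breaks_sets) {
    endpoints <- unique(as.vector(ut[bs, , drop = FALSE]))
    # every unordered pair of endpoint atoms, self-pairs included (filtered
    # later by validity), chosen n_form times with repetition
    cand_pairs <- expand.grid(a = endpoints, b = endpoints)
    cand_pairs <- cand_pairs[cand_pairs$a <= cand_pairs$b, , drop = FALSE]
    form_sets <- multiset_combinations(nrow(cand_pairs), spec$n_form,
                                       rep(spec$n_form, nrow(cand_pairs)))
    if (length(form_sets) * length(breaks_sets) > max_candidates)
      stop("brute-force candidate budget exceeded")
    for (fs in form_sets) {
      b <- g$bonds
      ok <- TRUE
      for (bi in bs) {
        i <- ut[bi, 1]; j <- ut[bi, 2]
        b[i, j] <- b[j, i] <- b[i, j] - 1L
      }
      for (fi in fs) {
        p <- cand_pairs$a[fi]; q <- cand_pairs$b[fi]
        if (p == q) { ok <- FALSE; break }
        b[p, q] <- b[q, p] <- b[p, q] + 1L
      }
      if (!ok) next
      if (any(b < 0L) || any(b > 3L)) next
      if (any(rowSums(b) != CHON_VALENCE[g$elements])) next
      d <- b - g$bonds
      if (all(d == 0L)) next
      if (-sum(d[upper.tri(d) & d < 0L]) != spec$n_break) next
      if (sum(d[upper.tri(d) & d > 0L]) != spec$n_form) next
      p <- molgraph(g$elements, b, maps = g$maps, validate = FALSE)
      r <- mapped_reaction(g, p, validate = FALSE)
      h <- reaction_hash(r)
      if (is.null(results[[h]])) results[[h]] <- r
    }
  }
  if (length(results) == 0)
    return(structure(list(), names = character(0)))
  results[order(names(results))]
}

#' Generate self-consistent synthetic dataset records
#'
#' Builds records in the csv/HDF5 dataset layout from reactions enumerated
#' on seeded random molecules: reaction SMILES come from depth-1 model
#' reactions of b2f2 enumeration, Hartree energies are drawn so that every
#' derived kcal/mol field reproduces exactly, clean barriers stay inside
#' (0, 200) kcal/mol (mirroring the observed range of such datasets), and
#' geometries are placeholder coordinates with the correct atom counts. A
#' configurable fraction of records receives a planted defect (anomalous
#' barrier, duplicate TS conformer, or a broken kcal/mol ledger) for
#' validator tests.
#'
#' @param n_records number of records.
#' @param seed integer seed.
#' @param corrupt_fraction fraction of records (rounded down) given one
#'   planted defect each, cycling through the three defect types.
#' @param out_dir if non-`NULL`, write `synthetic_rgd1.csv` and
#'   `synthetic_rgd1.h5` (via the python/h5py bridge) into this directory.
#' @return list with `records` (list of record lists), `csv` (data.frame in
#'   the csv schema), `truth` (data.frame `Rind`, `flag` of planted defects
#'   -- for duplicates both partners are listed), and `paths` (if written).
#' @export
synthetic_dataset <- function(n_records, seed = 1L, corrupt_fraction = 0,
                              out_dir = NULL) {
  stopifnot(n_records >= 1, corrupt_fraction >= 0, corrupt_fraction <= 1)
  k <- HARTREE_TO_KCAL
  with_seed(seed, {
    # reaction pool from b2f2 enumeration of random molecules
    pool <- list()
    tries <- 0L
    while (length(pool) < n_records && tries < 200L) {
      tries <- tries + 1L
      cfg_seed <- sample.int(.Machine$integer.max, 1)
      mols <- random_molecules(generator_config(seed = cfg_seed,
                                                heavy_atom_range = c(3, 5),
                                                count = 5))
      for (m in mols) {
        for (r in enumerate_b2f2(m)) {
          mr <- model_reaction(r)$reaction
          h <- reaction_hash(mr)
          if (is.null(pool[[h]])) pool[[h]] <- mr
        }
        if (length(pool) >= n_records) break
      }
    }
    if (length(pool) < n_records)
      stop("could not assemble a large enough reaction pool")
    pool <- pool[sample.int(length(pool), n_records)]

    n_corrupt <- floor(corrupt_fraction * n_records)
    defect <- rep("", n_records)
    if (n_corrupt > 0) {
      idx <- sample.int(n_records, n_corrupt)
      defect[idx] <- rep(c("anomalous_barrier", "duplicate_conformer",
                           "ledger_inconsistent"), length.out = n_corrupt)
    }

    records <- list()
    truth <- list()
    chain_coords <- function(n) cbind(1.1 * seq_len(n),
                                      round(stats::runif(n, -0.5, 0.5), 4),
                                      0)
    for (i in seq_len(n_records)) {
      r <- pool[[i]]
      nat <- length(r$reactant$elements)
      rs <- write_reaction_smiles(r)
      sides <- strsplit(rs, ">>", fixed = TRUE)[[1]]
      R_E <- stats::runif(1, -300, -100)
      DE_F <- stats::runif(1, 5, 150)
      DE_B <- stats::runif(1, 5, 150)
      TS_E <- R_E + DE_F / k
      P_E <- TS_E - DE_B / k
      hc <- stats::runif(3, 0.05, 0.15)   # thermal corrections, Hartree
      gc_ <- stats::runif(3, -0.05, 0.02)
      R_H <- R_E + hc[1]; P_H <- P_E + hc[2]; TS_H <- TS_E + hc[3]
      R_F <- R_E + gc_[1]; P_F <- P_E + gc_[2]; TS_F <- TS_E + gc_[3]
      rec <- list(Rind = sprintf("MR_%d_0", i),
                  Rsmiles = sides[1], Psmiles = sides[2],
                  R_E = R_E, R_H = R_H, R_F = R_F,
                  P_E = P_E, P_H = P_H, P_F = P_F,
                  TS_E = TS_E, TS_H = TS_H, TS_F = TS_F,
                  RG = chain_coords(nat), PG = chain_coords(nat),
                  TSG = chain_coords(nat))
      rec$DE_F <- (TS_E - R_E) * k
      rec$DE_B <- (TS_E - P_E) * k
      rec$DG_F <- (TS_F - R_F) * k
      rec$DG_B <- (TS_F - P_F) * k
      rec$DH <- (P_H - R_H) * k
      if (defect[i] == "anomalous_barrier") {
        rec$TS_E <- rec$R_E - 5 / k        # DE_F = -5 kcal/mol, ledger intact
        rec$DE_F <- (rec$TS_E - rec$R_E) * k
        rec$DE_B <- (rec$TS_E - rec$P_E) * k
        truth[[length(truth) + 1]] <- data.frame(Rind = rec$Rind,
                                                 flag = "anomalous_barrier")
      } else if (defect[i] == "ledger_inconsistent") {
        rec$DE_F <- rec$DE_F + 0.5         # stored value drifts from Hartrees
        truth[[length(truth) + 1]] <- data.frame(Rind = rec$Rind,
                                                 flag = "ledger_inconsistent")
      }
      records[[rec$Rind]] <- rec
    }
    # duplicate-conformer defects are extra Y=1 records cloning the energies
    for (i in which(defect == "duplicate_conformer")) {
      src <- records[[sprintf("MR_%d_0", i)]]
      dup <- src
      dup$Rind <- sprintf("MR_%d_1", i)
      records[[dup$Rind]] <- dup
      truth[[length(truth) + 1]] <- data.frame(Rind = src$Rind,
                                               flag = "duplicate_conformer")
      truth[[length(truth) + 1]] <- data.frame(Rind = dup$Rind,
                                               flag = "duplicate_conformer")
    }
    csv <- do.call(rbind, lapply(records, function(rec)
      data.frame(Rind = rec$Rind, Rsmiles = rec$Rsmiles,
                 Psmiles = rec$Psmiles, DE_F = rec$DE_F, DE_B = rec$DE_B,
                 DG_F = rec$DG_F, DG_B = rec$DG_B, DH = rec$DH)))
    rownames(csv) <- NULL
    truth <- if (length(truth) > 0) do.call(rbind, truth) else
      data.frame(Rind = character(0), flag = character(0))
    truth <- truth[order(truth$Rind, truth$flag), , drop = FALSE]
    rownames(truth) <- NULL
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      csv_path <- file.path(out_dir, "synthetic_rgd1.csv")
      h5_path <- file.path(out_dir, "synthetic_rgd1.h5")
      write_rgd1_csv(csv, csv_path)
      write_rgd1_hdf5(records, h5_path)
      paths <- c(csv = csv_path, hdf5 = h5_path)
    }
    list(records = records, csv = csv, truth = truth, paths = paths)
  })
}
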