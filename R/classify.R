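# Reaction-feature classifiers: bond-change signatures (bnfm), reactant/
# product molecularity (mrnp), reactive-atom and bond-type censuses,
# heavy-atom histograms, identity-reaction detection and activation-energy
# summaries. All features except the forward/backward labeling of energies
# are direction-invariant.

#' Bond-change signature (bnfm) of a reaction
#'
#' Counts bond-order units broken and formed between the two bond-electron
#' matrices. Units, not atom pairs: a double bond breaking to a single bond
#' counts as one broken bond, a C-C single bond becoming a double counts as
#' one formed bond. Bond-type labels are unordered element pairs
#' (`"C-H"` is the same as `"H-C"`) with bond orders pooled.
#'
#' @param r a [mapped_reaction()].
#' @return a list with `n_break`, `n_form`, `label` (e.g. `"b2f2"`),
#'   `broken_types` and `formed_types` (character vectors with one entry per
#'   bond-order unit, e.g. `c("C-H","C-H")`), and `changes` (a data.frame of
#'   atom pairs with columns `i`, `j`, `kind`, `bond`, `units`).
#' @export
#' @examples
#' r <- parse_reaction_smiles(
#'   "[C:1]([H:3])([H:4])([H:5])[C:2]([H:6])([H:7])[H:8]>>[C:1](=[C:2]([H:7])[H:8])([H:4])[H:5].[H:3][H:6]")
#' bond_change_signature(r)$label  # "b2f2"
bond_change_signature <- function(r) {
  stopifnot(inherits(r, "mapped_reaction"))
  el <- r$reactant$elements
  pair_label <- function(i, j) paste(sort(c(el[i], el[j])), collapse = "-")
  mk <- function(m, kind) {
    if (nrow(m) == 0)
      return(data.frame(i = integer(0), j = integer(0), kind = character(0),
                        bond = character(0), units = integer(0)))
    data.frame(i = m[, "i"], j = m[, "j"], kind = kind,
               bond = mapply(pair_label, m[, "i"], m[, "j"]),
               units = m[, "units"])
  }
  ch <- rbind(mk(r$broken, "broken"), mk(r$formed, "formed"))
  n_break <- sum(ch$units[ch$kind == "broken"])
  n_form <- sum(ch$units[ch$kind == "formed"])
  if (n_break + n_form == 0)
    stop("degenerate reaction: no bond changes")
  list(n_break = n_break, n_form = n_form,
       label = sprintf("b%df%d", n_break, n_form),
       broken_types = sort(rep(ch$bond[ch$kind == "broken"],
                               ch$units[ch$kind == "broken"])),
       formed_types = sort(rep(ch$bond[ch$kind == "formed"],
                               ch$units[ch$kind == "formed"])),
       changes = ch)
}

#' Molecularity classification (mrnp)
#'
#' Counts the molecules (connected components) on each side and normalizes
#' direction so that the product count is at least the reactant count, the
#' convention that avoids double counting a reaction and its reverse. Ties
#' keep the direction as given.
#'
#' @param r a [mapped_reaction()].
#' @return integer vector `c(m = reactants, n = products)` with `n >= m`.
#' @export
mrnp <- function(r) {
  stopifnot(inherits(r, "mapped_reaction"))
  a <- max(fragment_ids(r$reactant))
  b <- max(fragment_ids(r$product))
  if (b >= a) c(m = a, n = b) else c(m = b, n = a)
}

#' Reactive atoms of a reaction
#'
#' The atoms incident to any broken or formed bond. Cap hydrogens introduced
#' by model-reaction truncation count like any other atom if they take part
#' in a change.
#'
#' @param r a [mapped_reaction()].
#' @return integer vector of atom indices.
#' @export
reactive_atoms <- function(r) {
  sort(unique(c(as.vector(r$broken[, 1:2]), as.vector(r$formed[, 1:2]))))
}

#' Is a reaction an identity reaction?
#'
#' An identity reaction has the same molecules on both sides (equal
#' canonical species multisets) but a non-trivial atom mapping with real
#' bond changes -- e.g. a symmetric double hydrogen transfer. Its reaction
#' enthalpy is structurally zero, which makes the class a useful stress test
#' for ML featurizations that only see net bond changes. Conformer pairs
#' (no bond changes at all) do not qualify.
#'
#' @param r a [mapped_reaction()].
#' @return logical.
#' @export
is_identity_reaction <- function(r) {
  if (nrow(r$broken) + nrow(r$formed) == 0) return(FALSE)
  canonical_hash(r$reactant) == canonical_hash(r$product)
}

#' Full feature record for one reaction
#'
#' @param r a [mapped_reaction()].
#' @return a one-row data.frame with columns `bnfm`, `n_break`, `n_form`,
#'   `m`, `n`, `heavy_atoms`, `reactive_elements` (a comma-separated count
#'   string such as `"C:2,H:2"`), `bond_changes` (comma-separated pooled
#'   change types), and `is_identity`.
#' @export
reaction_features <- function(r) {
  sig <- bond_change_signature(r)
  mn <- mrnp(r)
  ra <- reactive_atoms(r)
  tab <- table(r$reactant$elements[ra])
  data.frame(
    bnfm = sig$label,
    n_break = sig$n_break,
    n_form = sig$n_form,
    m = unname(mn["m"]),
    n = unname(mn["n"]),
    heavy_atoms = heavy_atoms(r$reactant),
    reactive_elements = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                              collapse = ","),
    bond_changes = paste(sort(c(sig$broken_types, sig$formed_types)),
                         collapse = ","),
    is_identity = is_identity_reaction(r),
    stringsAsFactors = FALSE)
}

#' Classify a collection of reactions
#'
#' Applies [reaction_features()] to every entry. Entries may be
#' [mapped_reaction()] objects or atom-mapped reaction SMILES strings;
#' unparseable entries are skipped and reported in the attached QC summary.
#'
#' @param rxns list (or character vector) of reactions.
#' @param ids optional identifiers used in the output and QC report.
#' @return a data.frame of features, one row per parseable reaction, with an
#'   `attr(, "qc")` data.frame listing skipped entries and reasons.
#' @export
classify_reactions <- function(rxns, ids = NULL) {
  if (is.character(rxns)) rxns <- as.list(rxns)
  if (is.null(ids)) ids <- as.character(seq_along(rxns))
  rows <- vector("list", length(rxns))
  qc <- list()
  for (k in seq_along(rxns)) {
    res <- tryCatch({
      r <- rxns[[k]]
      if (is.character(r)) r <- parse_reaction_smiles(r)
      cbind(id = ids[k], reaction_features(r), stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      qc[[length(qc) + 1]] <- data.frame(id = ids[k],
                                         reason = conditionMessage(res))
    } else rows[[k]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "qc") <- if (length(qc) > 0) do.call(rbind, qc) else
    data.frame(id = character(0), reason = character(0))
  out
}

census_from_counts <- function(counts, key) {
  if (length(counts) == 0)
    return(data.frame(key = character(0), count = integer(0),
                      fraction = numeric(0)) |>
             stats::setNames(c(key, "count", "fraction")))
  df <- data.frame(names(counts), count = as.integer(counts),
                   fraction = as.numeric(counts) / sum(counts))
  names(df)[1] <- key
  df[order(df[[key]]), , drop = FALSE]
}

#' Reactive-atom element census over a reaction collection
#'
#' @param rs list of [mapped_reaction()] objects (or reaction SMILES).
#' @return data.frame with `element`, `count`, `fraction` (fractions sum
#'   to 1 over the collection); censuses are additive over any partition of
#'   the collection.
#' @export
reactive_atom_census <- function(rs) {
  counts <- integer(0)
  for (r in rs) {
    if (is.character(r)) r <- parse_reaction_smiles(r)
    tab <- table(r$reactant$elements[reactive_atoms(r)])
    for (e in names(tab))
      counts[e] <- (if (is.na(counts[e])) 0L else counts[e]) + tab[[e]]
  }
  census_from_counts(counts, "element")
}

#' Bond-type change census over a reaction collection
#'
#' Counts how many times each bond type (unordered element pair, bond orders
#' pooled) is broken or formed across the collection.
#'
#' @inheritParams reactive_atom_census
#' @return data.frame with `bond`, `count`, `fraction`.
#' @export
bond_change_census <- function(rs) {
  counts <- integer(0)
  for (r in rs) {
    if (is.character(r)) r <- parse_reaction_smiles(r)
    sig <- bond_change_signature(r)
    for (b in c(sig$broken_types, sig$formed_types))
      counts[b] <- (if (is.na(counts[b])) 0L else counts[b]) + 1L
  }
  census_from_counts(counts, "bond")
}

#' Heavy-atom-count histogram over a reaction collection
#'
#' @inheritParams reactive_atom_census
#' @return data.frame with `heavy_atoms`, `count`, `fraction`.
#' @export
heavy_atom_histogram <- function(rs) {
  counts <- integer(0)
  for (r in rs) {
    if (is.character(r)) r <- parse_reaction_smiles(r)
    k <- as.character(heavy_atoms(r$reactant))
    counts[k] <- (if (is.na(counts[k])) 0L else counts[k]) + 1L
  }
  df <- census_from_counts(counts, "heavy_atoms")
  df$heavy_atoms <- as.integer(df$heavy_atoms)
  df[order(df$heavy_atoms), , drop = FALSE]
}

#' Select the identity reactions of a collection
#'
#' @inheritParams reactive_atom_census
#' @return the subset (same type as the input elements) for which
#'   [is_identity_reaction()] is `TRUE`.
#' @export
identity_reactions <- function(rs) {
  keep <- vapply(rs, function(r) {
    if (is.character(r)) r <- parse_reaction_smiles(r)
    is_identity_reaction(r)
  }, TRUE)
  rs[keep]
}

#' Activation-energy summary and Bell-Evans-Polanyi fit
#'
#' Summarizes forward/backward activation energies per bond-change class and
#' fits the Bell-Evans-Polanyi (BEP) relation, the empirical linear
#' correlation between activation energy and reaction enthalpy. For each
#' reaction the larger and smaller of the forward and backward activation
#' energies are treated as `dE_max` and `dE_min`. The BEP fit is an ordinary
#' least squares of the activation energy on the enthalpy of reaction over
#' both directions, i.e. points `(dH, dE_fwd)` and `(-dH, dE_bwd)`.
#'
#' @param df data.frame with numeric columns `dE_fwd`, `dE_bwd`, `dH`
#'   (kcal/mol), a `bnfm` label column, and optionally a logical
#'   `is_identity` column.
#' @param exclude_identity drop identity reactions from the BEP fit (their
#'   `dH = 0` spike otherwise distorts the regression); default `TRUE`.
#' @return a list with `per_class` (data.frame of n, median and quartiles of
#'   `dE_max`/`dE_min` per bnfm class; classes with fewer than 2 members get
#'   counts only) and `bep` (list with `slope`, `intercept`, `r`, `n`).
#' @export
energy_summary <- function(df, exclude_identity = TRUE) {
  stopifnot(all(c("dE_fwd", "dE_bwd", "dH", "bnfm") %in% names(df)))
  dE_max <- pmax(df$dE_fwd, df$dE_bwd)
  dE_min <- pmin(df$dE_fwd, df$dE_bwd)
  per_class <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$bnfm), function(i) {
    if (length(i) < 2) {
      data.frame(bnfm = df$bnfm[i][1], n = length(i),
                 dE_max_q25 = NA_real_, dE_max_median = NA_real_,
                 dE_max_q75 = NA_real_, dE_min_q25 = NA_real_,
                 dE_min_median = NA_real_, dE_min_q75 = NA_real_)
    } else {
      qx <- stats::quantile(dE_max[i], c(.25, .5, .75), names = FALSE)
      qn <- stats::quantile(dE_min[i], c(.25, .5, .75), names = FALSE)
      data.frame(bnfm = df$bnfm[i][1], n = length(i),
                 dE_max_q25 = qx[1], dE_max_median = qx[2], dE_max_q75 = qx[3],
                 dE_min_q25 = qn[1], dE_min_median = qn[2], dE_min_q75 = qn[3])
    }
  }))
  rownames(per_class) <- NULL

  use <- rep(TRUE, nrow(df))
  if (exclude_identity && "is_identity" %in% names(df))
    use <- !df$is_identity
  x <- c(df$dH[use], -df$dH[use])
  y <- c(df$dE_fwd[use], df$dE_bwd[use])
  bep <- if (length(x) >= 2 && stats::sd(x) > 0) {
    fit <- stats::lm(y ~ x)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = stats::cor(x, y), n = length(x))
  } else list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
              n = length(x))
  list(per_class = per_class, bep = bep)
}
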