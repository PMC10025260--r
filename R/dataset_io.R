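# Readers, writers and validators for the two distribution formats used by
# depth-1 model-reaction TS datasets (RGD1 layout):
#   * csv: columns Rind, Rsmiles, Psmiles, DE_F, DE_B, DG_F, DG_B, DH
#     (energies in kcal/mol),
#   * HDF5: one group per reaction index with keys Rsmiles, Psmiles,
#     R_E/R_H/R_F, P_E/P_H/P_F, TS_E/TS_H/TS_F (Hartree) and RG/PG/TSG
#     (N x 3 Angstrom geometries).
# Units are kept exactly as stored; energy differences are recomputed with
# the CODATA conversion 627.509474 kcal/mol per Hartree.
#
# HDF5 access goes through a small bundled python/h5py helper (no R HDF5
# binding is required at runtime beyond a `python` with h5py on the PATH),
# exchanging records as JSON.

RGD1_CSV_COLUMNS <- c("Rind", "Rsmiles", "Psmiles",
                      "DE_F", "DE_B", "DG_F", "DG_B", "DH")
RGD1_H5_KEYS <- c("Rsmiles", "Psmiles",
                  "R_E", "R_H", "R_F", "P_E", "P_H", "P_F",
                  "TS_E", "TS_H", "TS_F", "RG", "PG", "TSG")

#' Split a reaction index "MR_X_Y" into model-reaction and conformer parts
#' @param rind character vector of reaction identifiers.
#' @return data.frame with `X` (model-reaction index) and `Y` (conformer
#'   index) as integers; malformed identifiers give `NA`.
#' @export
parse_rind <- function(rind) {
  m <- regmatches(rind, regexec("^MR_([0-9]+)_([0-9]+)$", rind))
  data.frame(
    X = vapply(m, function(z) if (length(z) == 3) as.integer(z[2]) else NA_integer_, 1L),
    Y = vapply(m, function(z) if (length(z) == 3) as.integer(z[3]) else NA_integer_, 1L))
}

#' Read a reaction-dataset csv
#'
#' Reads the kcal/mol energy table (one row per reaction conformer). The
#' expected columns are `Rind, Rsmiles, Psmiles, DE_F, DE_B, DG_F, DG_B, DH`;
#' a missing column is a schema error naming the column. Rows with
#' non-numeric energies are dropped into the attached QC report instead of
#' crashing the read.
#'
#' @param path csv file path.
#' @return data.frame of records; attributes `qc` (data.frame of skipped
#'   rows with reasons), `n_rows` (rows read) and `n_distinct_X` (distinct
#'   model-reaction indices, since a dataset may hold several TS conformers
#'   per model reaction).
#' @export
read_rgd1_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(RGD1_CSV_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("csv schema error: missing column ", paste(missing, collapse = ", "))
  qc <- list()
  num_cols <- c("DE_F", "DE_B", "DG_F", "DG_B", "DH")
  bad <- rep(FALSE, nrow(df))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    nb <- !is.na(df[[cc]]) & df[[cc]] != "" & is.na(v)
    if (any(nb))
      qc[[length(qc) + 1]] <- data.frame(Rind = df$Rind[nb],
                                         reason = paste("non-numeric", cc))
    bad <- bad | nb | is.na(v)
    df[[cc]] <- v
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- if (length(qc) > 0) do.call(rbind, qc) else
    data.frame(Rind = character(0), reason = character(0))
  attr(out, "n_rows") <- nrow(df)
  attr(out, "n_distinct_X") <- length(unique(parse_rind(out$Rind)$X))
  out
}

#' Write a reaction-dataset csv
#' @param df data.frame with the standard columns (see [read_rgd1_csv()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgd1_csv <- function(df, path) {
  missing <- setdiff(RGD1_CSV_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("csv schema error: missing column ", paste(missing, collapse = ", "))
  utils::write.csv(df[, RGD1_CSV_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

find_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no `python` found on PATH; HDF5 access needs python with h5py")
  py
}

h5_bridge <- function(args) {
  script <- system.file("python", "h5bridge.py", package = "rxnspace")
  if (!nzchar(script)) stop("bundled h5bridge.py not found")
  out <- suppressWarnings(system2(find_python(), c(shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("HDF5 bridge failed: ", paste(out, collapse = "\n"))
  out
}

#' Read records from a reaction-dataset HDF5 file
#'
#' The canonical layout is one group per reaction index holding the keys
#' `Rsmiles, Psmiles, R_E, R_H, R_F, P_E, P_H, P_F, TS_E, TS_H, TS_F`
#' (Hartree) and `RG, PG, TSG` (N x 3 geometry arrays, Angstrom). A flat
#' single-record layout (the keys at the file root) is auto-detected as a
#' fallback; the detected dialect is reported in `attr(, "dialect")`. No
#' unit conversion is performed on read.
#'
#' @param path HDF5 file.
#' @param ids optional character vector of reaction indices to read
#'   (default: all).
#' @return a named list of records; each record is a list carrying the
#'   Table-2 keys plus `Rind`, with geometries as numeric matrices.
#' @export
read_rgd1_hdf5 <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  args <- c("read", shQuote(path), shQuote(tmp))
  if (!is.null(ids)) args <- c(args, ids)
  msg <- h5_bridge(args)
  dat <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  recs <- lapply(dat$records, function(rec) {
    for (k in c("RG", "PG", "TSG"))
      if (!is.null(rec[[k]])) rec[[k]] <- matrix(as.numeric(unlist(rec[[k]])),
                                                 ncol = 3, byrow = TRUE)
    for (k in intersect(names(rec), RGD1_H5_KEYS[3:11]))
      rec[[k]] <- as.numeric(rec[[k]])
    rec
  })
  names(recs) <- vapply(recs, `[[`, "", "Rind")
  attr(recs, "dialect") <- dat$dialect
  if (length(msg) > 0) message(paste(msg, collapse = "\n"))
  recs
}

#' Write records to a reaction-dataset HDF5 file
#'
#' @param records list of record lists (fields as in [read_rgd1_hdf5()]);
#'   geometries as N x 3 matrices.
#' @param path output HDF5 file.
#' @return `path`, invisibly.
#' @export
write_rgd1_hdf5 <- function(records, path) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  payload <- lapply(unname(records), function(rec) {
    for (k in c("RG", "PG", "TSG"))
      if (!is.null(rec[[k]]))
        rec[[k]] <- lapply(seq_len(nrow(rec[[k]])),
                           function(i) as.numeric(rec[[k]][i, ]))
    rec
  })
  jsonlite::write_json(list(records = payload), tmp,
                       auto_unbox = TRUE, digits = NA)
  h5_bridge(c("write", shQuote(tmp), shQuote(path)))
  invisible(path)
}

#' Recompute derived energies of a record
#'
#' Rebuilds the kcal/mol ledger from the Hartree fields: forward/backward
#' activation energies from TS minus reactant/product single-point energies,
#' free-energy barriers from the Gibbs fields, and the reaction enthalpy
#' from the enthalpy fields, using 627.509474 kcal/mol per Hartree. When the
#' record also carries stored kcal/mol fields, per-field deviations are
#' reported.
#'
#' @param rec a record list with (some of) `R_E, P_E, TS_E, R_H, P_H, R_F,
#'   P_F, TS_F` and optionally stored `DE_F, DE_B, DG_F, DG_B, DH`.
#' @return list with `derived` (named numeric vector; `NA` where the needed
#'   Hartree fields are absent, with the missing fields named in `flags`),
#'   `deviations` (derived minus stored, where stored values exist) and
#'   `flags` (character vector of missing-input notes).
#' @export
recompute_energies <- function(rec) {
  k <- HARTREE_TO_KCAL
  need <- list(DE_F = c("TS_E", "R_E"), DE_B = c("TS_E", "P_E"),
               DG_F = c("TS_F", "R_F"), DG_B = c("TS_F", "P_F"),
               DH = c("P_H", "R_H"))
  derived <- c(DE_F = NA_real_, DE_B = NA_real_, DG_F = NA_real_,
               DG_B = NA_real_, DH = NA_real_)
  flags <- character(0)
  for (f in names(need)) {
    a <- rec[[need[[f]][1]]]; b <- rec[[need[[f]][2]]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) {
      flags <- c(flags, sprintf("%s: missing %s", f,
                                paste(need[[f]], collapse = "/")))
    } else derived[f] <- (a - b) * k
  }
  deviations <- vapply(names(derived), function(f) {
    s <- rec[[f]]
    if (is.null(s) || is.na(derived[f])) NA_real_ else derived[f] - s
  }, 0)
  list(derived = derived, deviations = deviations, flags = flags)
}

#' Validate dataset records
#'
#' Report-only quality control over a set of records (no record is modified
#' or removed). Flags raised:
#' \describe{
#'   \item{anomalous_barrier}{an activation energy below 0 or above 500
#'     kcal/mol in either direction (the bounds used to weed out abnormal
#'     geometry optimizations).}
#'   \item{duplicate_conformer}{two conformers of the same model-reaction
#'     index whose forward and backward activation energies agree within
#'     `dup_tol` (duplicated TS conformations); both records are reported.}
#'   \item{ledger_inconsistent}{a stored kcal/mol field deviating from the
#'     value recomputed from the Hartree fields by more than `tol`.}
#'   \item{geometry_mismatch}{a geometry row count that does not match the
#'     atom count of the corresponding parsed SMILES (the TS shares the
#'     reactant atom set).}
#' }
#'
#' The report is idempotent and order-independent: it is sorted by record
#' id and flag, and depends only on the record set.
#'
#' @param recs a list of record lists (HDF5-style, with Hartree fields and
#'   optionally stored kcal/mol fields) or a csv-style data.frame (kcal/mol
#'   fields only; ledger and geometry checks are then skipped).
#' @param tol stored-vs-recomputed tolerance, kcal/mol (default 0.01,
#'   matching csv rounding).
#' @param dup_tol activation-energy equality tolerance for duplicate
#'   conformers, kcal/mol (default 1e-4).
#' @return data.frame with columns `Rind`, `flag`, `detail` (zero rows if
#'   everything is clean).
#' @export
validate_records <- function(recs, tol = 0.01, dup_tol = 1e-4) {
  if (is.data.frame(recs)) {
    recs <- lapply(seq_len(nrow(recs)), function(i) as.list(recs[i, ]))
  }
  flags <- list()
  add <- function(rind, flag, detail)
    flags[[length(flags) + 1L]] <<- data.frame(Rind = rind, flag = flag,
                                               detail = detail)
  de <- data.frame(Rind = character(0), DE_F = numeric(0), DE_B = numeric(0))
  for (rec in recs) {
    rind <- rec$Rind
    rc <- recompute_energies(rec)
    def <- if (!is.null(rec$DE_F) && !is.na(rec$DE_F)) rec$DE_F else rc$derived["DE_F"]
    deb <- if (!is.null(rec$DE_B) && !is.na(rec$DE_B)) rec$DE_B else rc$derived["DE_B"]
    if (!is.na(def) && (def < 0 || def > 500))
      add(rind, "anomalous_barrier", sprintf("DE_F = %.4f kcal/mol", def))
    if (!is.na(deb) && (deb < 0 || deb > 500))
      add(rind, "anomalous_barrier", sprintf("DE_B = %.4f kcal/mol", deb))
    dev <- rc$deviations[!is.na(rc$deviations)]
    bad <- dev[abs(dev) > tol]
    if (length(bad) > 0)
      add(rind, "ledger_inconsistent",
          paste(sprintf("%s off by %.4g kcal/mol", names(bad), bad),
                collapse = "; "))
    geom_checks <- list(c("RG", "Rsmiles"), c("PG", "Psmiles"),
                        c("TSG", "Rsmiles"))
    for (gc in geom_checks) {
      G <- rec[[gc[1]]]; smi <- rec[[gc[2]]]
      if (is.null(G) || is.null(smi)) next
      nat <- tryCatch(length(parse_smiles_graph(smi)$elements),
                      error = function(e) NA_integer_)
      if (!is.na(nat) && nrow(G) != nat)
        add(rind, "geometry_mismatch",
            sprintf("%s has %d rows, %s has %d atoms",
                    gc[1], nrow(G), gc[2], nat))
    }
    if (!is.na(def) && !is.na(deb))
      de <- rbind(de, data.frame(Rind = rind, DE_F = def, DE_B = deb))
  }
  # duplicate TS conformers within one model-reaction index
  de$X <- parse_rind(de$Rind)$X
  for (grp in split(de, de$X)) {
    if (nrow(grp) < 2) next
    for (a in seq_len(nrow(grp) - 1)) for (b in (a + 1):nrow(grp)) {
      if (abs(grp$DE_F[a] - grp$DE_F[b]) <= dup_tol &&
          abs(grp$DE_B[a] - grp$DE_B[b]) <= dup_tol) {
        add(grp$Rind[a], "duplicate_conformer",
            sprintf("matches %s within %g kcal/mol", grp$Rind[b], dup_tol))
        add(grp$Rind[b], "duplicate_conformer",
            sprintf("matches %s within %g kcal/mol", grp$Rind[a], dup_tol))
      }
    }
  }
  out <- if (length(flags) > 0) do.call(rbind, flags) else
    data.frame(Rind = character(0), flag = character(0), detail = character(0))
  out <- unique(out)
  out <- out[order(out$Rind, out$flag, out$detail), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a record geometry as an XYZ file
#'
#' Standard XYZ: atom-count line, a comment line with the record id and the
#' corresponding Hartree energy, then one `element x y z` row per atom
#' (Angstrom). Element order follows the atom order of the parsed SMILES
#' with explicit hydrogens (the TS shares the reactant atom set).
#'
#' @param rec record list with geometry.
#' @param which one of `"R"`, `"P"`, `"TS"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(rec, which = c("R", "P", "TS"), path) {
  which <- match.arg(which)
  gkey <- paste0(which, "G")
  G <- rec[[gkey]]
  if (is.null(G)) stop("record has no ", gkey, " geometry")
  smi <- if (which == "P") rec$Psmiles else rec$Rsmiles
  el <- parse_smiles_graph(smi)$elements
  if (length(el) != nrow(G))
    stop("geometry/SMILES atom count mismatch for ", gkey)
  ekey <- paste0(which, "_E")
  en <- if (!is.null(rec[[ekey]])) sprintf(" %s=%.8f Hartree", ekey, rec[[ekey]]) else ""
  lines <- c(as.character(nrow(G)),
             sprintf("%s %s%s", rec$Rind, gkey, en),
             sprintf("%-2s %14.8f %14.8f %14.8f", el, G[, 1], G[, 2], G[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#' @param path XYZ file.
#' @return list with `elements`, `coords` (N x 3 matrix) and `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  rows <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  list(elements = vapply(rows, `[[`, "", 1),
       coords = matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))),
                       ncol = 3, byrow = TRUE),
       comment = lines[2])
}
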