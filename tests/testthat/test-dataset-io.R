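# csv/HDF5 dataset layout: readers, energy ledger, validators, XYZ export

make_csv_fixture <- function(path) {
  d <- synthetic_dataset(3, seed = 101)
  write_rgd1_csv(d$csv, path)
  d
}

test_that("csv reader maps the schema by name and flags schema errors", {
  path <- tempfile(fileext = ".csv")
  d <- make_csv_fixture(path)
  df <- read_rgd1_csv(path)
  expect_equal(nrow(df), 3)
  expect_equal(sort(df$Rind), sort(d$csv$Rind))
  expect_equal(attr(df, "n_distinct_X"), 3)

  broken <- d$csv[, setdiff(names(d$csv), "DG_B")]
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_rgd1_csv(p2), "DG_B")

  # a non-numeric energy demotes the row to the QC report, not a crash
  bad <- d$csv
  bad$DE_F[2] <- "oops"
  p3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, p3, row.names = FALSE)
  df3 <- read_rgd1_csv(p3)
  expect_equal(nrow(df3), 2)
  expect_equal(attr(df3, "qc")$Rind, bad$Rind[2])
})

test_that("energy recomputation uses the Hartree -> kcal/mol conversion", {
  rec <- list(R_E = -100.0, TS_E = -99.9, P_E = -100.05,
              R_H = -99.9, P_H = -99.95, R_F = -100.1, P_F = -100.2,
              TS_F = -99.95)
  rc <- recompute_energies(rec)
  expect_equal(unname(rc$derived["DE_F"]), 0.1 * 627.509474, tolerance = 1e-10)
  expect_equal(unname(rc$derived["DE_F"]), 62.7509474, tolerance = 1e-6)
  # identity-energy record: DH = 0 and DE_F = DE_B
  ident <- list(R_E = -100, P_E = -100, TS_E = -99.9,
                R_H = -99.9, P_H = -99.9)
  ric <- recompute_energies(ident)
  expect_equal(unname(ric$derived["DH"]), 0)
  expect_equal(unname(ric$derived["DE_F"]), unname(ric$derived["DE_B"]))
  # missing Hartree fields give flagged partial results
  part <- recompute_energies(list(R_E = -100, TS_E = -99.9))
  expect_true(is.na(part$derived["DH"]))
  expect_true(any(grepl("DH", part$flags)))
})

test_that("self-consistent records recompute to stored values and the ledger identity holds", {
  d <- synthetic_dataset(25, seed = 7)
  k <- 627.509474
  for (rec in d$records) {
    rc <- recompute_energies(rec)
    expect_lt(max(abs(rc$deviations)), 1e-6)
    # DE_F - DE_B + (R_E - P_E)*k = 0
    expect_lt(abs(rec$DE_F - rec$DE_B + (rec$R_E - rec$P_E) * k), 1e-6)
  }
  expect_equal(nrow(validate_records(d$records)), 0)
})

test_that("validator flags anomalous barriers at the 0 and 500 kcal/mol bounds", {
  rec_neg <- list(Rind = "MR_1_0", DE_F = -5, DE_B = 40)
  rec_hi <- list(Rind = "MR_2_0", DE_F = 501, DE_B = 40)
  rec_ok <- list(Rind = "MR_3_0", DE_F = 0.5, DE_B = 499.9)
  qc <- validate_records(list(rec_neg, rec_hi, rec_ok))
  expect_setequal(unique(qc$Rind), c("MR_1_0", "MR_2_0"))
  expect_true(all(qc$flag == "anomalous_barrier"))
})

test_that("validator flags duplicate conformers and ledger drift; it is idempotent and order-independent", {
  base <- synthetic_dataset(4, seed = 13)$records
  dup <- base[[2]]
  dup$Rind <- sub("_0$", "_1", dup$Rind)
  drift <- base[[3]]
  drift$DE_F <- drift$DE_F + 0.2
  recs <- c(base, list(dup), list(drift = drift))
  qc <- validate_records(recs)
  expect_setequal(
    paste(qc$Rind, qc$flag),
    c(paste(base[[2]]$Rind, "duplicate_conformer"),
      paste(dup$Rind, "duplicate_conformer"),
      paste(drift$Rind, "ledger_inconsistent")))
  expect_identical(validate_records(recs), qc)
  expect_identical(validate_records(rev(recs)), qc)
})

test_that("validator flags geometry/SMILES atom-count mismatches", {
  rec <- synthetic_dataset(1, seed = 3)$records[[1]]
  rec$PG <- rec$PG[-1, , drop = FALSE]
  qc <- validate_records(list(rec))
  expect_true("geometry_mismatch" %in% qc$flag)
})

test_that("HDF5 write/read round trip preserves records (grouped layout)", {
  d <- synthetic_dataset(4, seed = 19)
  h5 <- tempfile(fileext = ".h5")
  write_rgd1_hdf5(d$records, h5)
  back <- suppressMessages(read_rgd1_hdf5(h5))
  expect_equal(attr(back, "dialect"), "grouped")
  expect_setequal(names(back), names(d$records))
  for (nm in names(back)) {
    a <- d$records[[nm]]; b <- back[[nm]]
    expect_identical(b$Rsmiles, a$Rsmiles)
    expect_identical(b$Psmiles, a$Psmiles)
    for (f in c("R_E", "R_H", "R_F", "P_E", "P_H", "P_F",
                "TS_E", "TS_H", "TS_F"))
      expect_equal(b[[f]], a[[f]], tolerance = 1e-12)
    for (f in c("RG", "PG", "TSG"))
      expect_equal(b[[f]], a[[f]], tolerance = 1e-12, ignore_attr = TRUE)
  }
  # selective read by id
  one <- suppressMessages(read_rgd1_hdf5(h5, ids = names(d$records)[2]))
  expect_length(one, 1)
  expect_equal(names(one), names(d$records)[2])
})

test_that("XYZ export writes standard blocks that reparse exactly", {
  rec <- synthetic_dataset(1, seed = 23)$records[[1]]
  path <- tempfile(fileext = ".xyz")
  export_xyz(rec, "TS", path)
  lines <- readLines(path)
  nat <- nrow(rec$TSG)
  expect_length(lines, nat + 2)
  expect_equal(as.integer(lines[1]), nat)
  expect_match(lines[2], rec$Rind, fixed = TRUE)
  back <- read_xyz(path)
  expect_equal(back$coords, rec$TSG, tolerance = 1e-6, ignore_attr = TRUE)
  # element order matches the SMILES atom order with explicit hydrogens
  expect_identical(back$elements,
                   rxnspace:::parse_smiles_graph(rec$Rsmiles)$elements)
  expect_error(export_xyz(list(Rind = "x", Rsmiles = "C"), "R", tempfile()),
               "geometry")
})
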