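# reaction-feature classifiers

test_that("bond-change signature counts bond-order units with pooled labels", {
  r <- ethane_dehydrogenation()
  sig <- bond_change_signature(r)
  expect_equal(sig$label, "b2f2")
  expect_identical(sig$broken_types, c("C-H", "C-H"))
  expect_identical(sig$formed_types, c("C-C", "H-H"))

  # all b2f2 enumeration output is (2,2) by construction
  for (r2 in enumerate_b2f2("CCO")) {
    s <- bond_change_signature(r2)
    expect_equal(c(s$n_break, s$n_form), c(2L, 2L))
  }

  # a retro-[4+2]-style double fragmentation written with full order changes
  # is b3f3: cyclohexene -> butadiene + ethene (2 sigma broken, 1 pi->2 pi)
  # ring atoms of C1CCC=CC1: 1-2, 2-3, 3-4, 4=5, 5-6, 6-1; ethene leaves as
  # atoms 1,2; the pi system shifts onto 3=4 and 5=6
  g <- parse_smiles("C1CCC=CC1")
  r3 <- apply_ers(g,
                  breaks = rbind(c(2L, 3L), c(1L, 6L), c(4L, 5L)),
                  forms = rbind(c(3L, 4L), c(5L, 6L), c(1L, 2L)))
  expect_equal(bond_change_signature(r3)$label, "b3f3")
  expect_equal(mrnp(r3), c(m = 1L, n = 2L))

  # degenerate (no-change) reactions are rejected
  expect_error(bond_change_signature(mapped_reaction(g, g)), "degenerate")
})

test_that("mrnp counts molecules per side and normalizes direction", {
  r <- ethane_dehydrogenation()
  expect_equal(mrnp(r), c(m = 1L, n = 2L))
  expect_equal(mrnp(reverse_reaction(r)), c(m = 1L, n = 2L))
  # a 2r2p metathesis stays 2r2p and keeps its direction on ties
  rxns <- enumerate_b2f2(list(parse_smiles("C"), parse_smiles("O")))
  mn <- vapply(rxns, mrnp, c(m = 0L, n = 0L))
  expect_true(all(mn["n", ] >= mn["m", ]))
})

test_that("censuses add up and handle empty collections", {
  r <- ethane_dehydrogenation()
  ra <- reactive_atom_census(list(r))
  expect_equal(ra$count[ra$element == "C"], 2L)
  expect_equal(ra$count[ra$element == "H"], 2L)
  expect_equal(sum(ra$fraction), 1)

  expect_equal(nrow(reactive_atom_census(list())), 0)
  expect_equal(nrow(bond_change_census(list())), 0)

  # additivity over a partition
  pool <- random_reaction_pool(seed = 14, n_reactions = 30)
  whole <- bond_change_census(pool)
  part1 <- bond_change_census(pool[1:10])
  part2 <- bond_change_census(pool[11:length(pool)])
  merged <- merge(part1, part2, by = "bond", all = TRUE)
  merged[is.na(merged)] <- 0
  tot <- merged$count.x + merged$count.y
  expect_equal(tot[order(merged$bond)], whole$count[order(whole$bond)])

  hh <- heavy_atom_histogram(pool)
  expect_equal(sum(hh$count), length(pool))
})

test_that("identity reactions are detected; conformer pairs are not", {
  # symmetric H swap on ethane: same species, real bond changes
  g <- parse_smiles("CC")
  h1 <- which(g$bonds[1, ] > 0 & g$elements == "H")[1]
  h2 <- which(g$bonds[2, ] > 0 & g$elements == "H")[1]
  ident <- apply_ers(g, breaks = rbind(c(1L, h1), c(2L, h2)),
                     forms = rbind(c(1L, h2), c(2L, h1)))
  expect_true(is_identity_reaction(ident))
  expect_false(is_identity_reaction(ethane_dehydrogenation()))
  got <- identity_reactions(list(ident, ethane_dehydrogenation()))
  expect_length(got, 1)
  expect_identical(reaction_hash(got[[1]]), reaction_hash(ident))
})

test_that("classify_reactions survives bad rows and reports them", {
  rxns <- c(write_reaction_smiles(ethane_dehydrogenation()),
            "not a reaction",
            write_reaction_smiles(enumerate_b2f2("CO")[[1]]))
  f <- classify_reactions(rxns, ids = c("a", "bad", "c"))
  expect_equal(nrow(f), 2)
  expect_equal(attr(f, "qc")$id, "bad")
})

test_that("energy summary: dE_max/dE_min and identity-aware BEP recovery", {
  df <- data.frame(dE_fwd = c(10, 50), dE_bwd = c(30, 20),
                   dH = c(-20, 30), bnfm = "b2f2",
                   is_identity = c(FALSE, FALSE))
  es <- energy_summary(df)
  expect_equal(es$per_class$n, 2L)
  expect_equal(es$per_class$dE_max_median, stats::median(c(30, 50)))
  expect_equal(es$per_class$dE_min_median, stats::median(c(10, 20)))

  # identity reaction: forward = backward, max = min
  df1 <- data.frame(dE_fwd = 25, dE_bwd = 25, dH = 0, bnfm = "b2f2",
                    is_identity = TRUE)
  es1 <- energy_summary(df1, exclude_identity = FALSE)
  expect_equal(es1$per_class$n, 1L)          # counts only below 2 members
  expect_true(is.na(es1$per_class$dE_max_median))

  # parameter recovery: dE = 0.5 * dH + 40 + noise(sd = 1)
  set.seed(77)
  n <- 400
  dH <- stats::runif(n, -60, 60)
  dE_f <- 0.5 * dH + 40 + stats::rnorm(n, 0, 1)
  dE_b <- dE_f - dH            # ledger-consistent backward barrier
  df2 <- data.frame(dE_fwd = dE_f, dE_bwd = dE_b, dH = dH, bnfm = "b2f2",
                    is_identity = FALSE)
  fit <- energy_summary(df2)$bep
  expect_lt(abs(fit$slope - 0.5), 0.05)
  expect_lt(abs(fit$intercept - 40), 2)
  expect_gt(fit$r, 0.9)
})

test_that("direction invariance of all structural features", {
  pool <- random_reaction_pool(seed = 8, n_reactions = 15)
  for (r in pool) {
    rr <- reverse_reaction(r)
    f1 <- reaction_features(r); f2 <- reaction_features(rr)
    expect_equal(f1$bnfm, f2$bnfm)
    expect_equal(c(f1$m, f1$n), c(f2$m, f2$n))
    expect_equal(f1$heavy_atoms, f2$heavy_atoms)
    expect_equal(f1$bond_changes, f2$bond_changes)
    expect_equal(f1$is_identity, f2$is_identity)
  }
})
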