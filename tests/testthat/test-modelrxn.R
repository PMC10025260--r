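# model-reaction truncation and saturation tracking

test_that("a reaction whose atoms are all within depth 1 is its own model", {
  r <- ethane_dehydrogenation()
  m <- model_reaction(r, depth = 1)
  expect_identical(reaction_hash(m$reaction), reaction_hash(r))
  expect_equal(sum(is.na(m$parent_map)), 0)
})

test_that("truncation removes remote atoms and caps with hydrogens", {
  # enolization at the aldehyde end of a long chain: the far tail is trimmed
  g <- parse_smiles("O=CCCCCCO")
  o1 <- 1L  # carbonyl O written first
  c2 <- which(g$bonds[o1, ] == 2L)
  c3 <- which(g$bonds[c2, ] == 1L & g$elements == "C")[1]
  h_on_c3 <- which(g$bonds[c3, ] == 1L & g$elements == "H")[1]
  r <- apply_ers(g,
                 breaks = rbind(c(o1, c2), c(c3, h_on_c3)),
                 forms = rbind(c(o1, h_on_c3), c(c2, c3)))
  m <- model_reaction(r, depth = 1)
  expect_lt(heavy_atoms(m$reaction$reactant), heavy_atoms(r$reactant))
  sig_p <- bond_change_signature(r)
  sig_m <- bond_change_signature(m$reaction)
  expect_identical(sig_p$broken_types, sig_m$broken_types)
  expect_identical(sig_p$formed_types, sig_m$formed_types)
  # caps restore the original coordination
  expect_silent(validate_molgraph(m$reaction$reactant))
  expect_silent(validate_molgraph(m$reaction$product))
})

test_that("model generation is idempotent, preserves bond-change types and hybridization", {
  pool <- random_reaction_pool(seed = 21, n_reactions = 200)
  expect_gte(length(pool), 200)
  for (r in pool) {
    m <- model_reaction(r, depth = 1)
    # idempotence (fixed point under the reaction hash)
    m2 <- model_reaction(m$reaction, depth = 1)
    expect_identical(reaction_hash(m2$reaction), reaction_hash(m$reaction))
    # same number and type of bond changes
    sp <- bond_change_signature(r); sm <- bond_change_signature(m$reaction)
    expect_identical(c(sp$n_break, sp$n_form), c(sm$n_break, sm$n_form))
    expect_identical(sp$broken_types, sm$broken_types)
    expect_identical(sp$formed_types, sm$formed_types)
    # heavy atoms never increase
    expect_lte(heavy_atoms(m$reaction$reactant), heavy_atoms(r$reactant))
    # hybridization (sigma framework: bonded-neighbor count, lone pairs are
    # element-implied) of each reactive atom is preserved on both sides
    ra_parent <- reactive_atoms(r)
    map <- m$parent_map
    for (ap in ra_parent) {
      am <- match(ap, map)
      expect_false(is.na(am))
      expect_equal(sum(m$reaction$reactant$bonds[am, ] > 0),
                   sum(r$reactant$bonds[ap, ] > 0))
      expect_equal(sum(m$reaction$product$bonds[am, ] > 0),
                   sum(r$product$bonds[ap, ] > 0))
    }
    # the model of a b2f2 reaction is itself a valid b2f2 mapped reaction
    expect_silent(validate_molgraph(m$reaction$reactant))
    expect_silent(validate_molgraph(m$reaction$product))
  }
})

test_that("saturation curve tracks cumulative and new model reactions", {
  # duplicates add nothing after the first interval
  mol <- parse_smiles("CCO")
  curve <- saturation_curve(rep(list(mol), 30), interval = 10)
  expect_equal(nrow(curve), 3)
  expect_gt(curve$new_models[1], 0)
  expect_equal(curve$new_models[2:3], c(0, 0))
  expect_true(all(diff(curve$cumulative_unique) >= 0))
  expect_equal(sum(curve$new_models), curve$cumulative_unique[3])

  # empty stream -> empty curve
  empty <- saturation_curve(list())
  expect_equal(nrow(empty), 0)

  # final cumulative equals the brute-force union of model hashes
  mols <- random_molecules(generator_config(seed = 31,
                                            heavy_atom_range = c(2, 5),
                                            count = 20))
  curve <- saturation_curve(mols, interval = 10)
  union_hashes <- unique(unlist(lapply(mols, function(g)
    vapply(enumerate_b2f2(g),
           function(r) reaction_hash(model_reaction(r)$reaction), ""))))
  expect_equal(curve$cumulative_unique[nrow(curve)], length(union_hashes))
  expect_equal(sum(curve$new_models), curve$cumulative_unique[nrow(curve)])

  # unparseable entries are skipped and counted
  curve2 <- suppressMessages(
    saturation_curve(list("C", "not a molecule", "O"), interval = 1))
  expect_equal(attr(curve2, "n_skipped"), 1L)
  expect_equal(max(curve2$reactants_processed), 2L)
})
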