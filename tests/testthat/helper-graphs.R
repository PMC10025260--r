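# shared fixtures, built in code

# methane as a hand-built graph (independent of the SMILES parser)
methane_graph <- function() {
  b <- matrix(0L, 5, 5)
  b[1, 2:5] <- b[2:5, 1] <- 1L
  molgraph(c("C", "H", "H", "H", "H"), b)
}

# N2 built directly (no SMILES needed): N#N
n2_graph <- function() {
  b <- matrix(c(0L, 3L, 3L, 0L), 2, 2)
  molgraph(c("N", "N"), b)
}

khp_smiles <- "O=CCCOO"  # gamma-ketohydroperoxide (3-hydroperoxypropanal)

# the ethane -> ethene + H2 double dehydrogenation, built by explicit edits
ethane_dehydrogenation <- function() {
  g <- parse_smiles("CC")
  h_on_1 <- which(g$bonds[1, ] > 0 & g$elements == "H")[1]
  h_on_2 <- which(g$bonds[2, ] > 0 & g$elements == "H")[1]
  apply_ers(g,
            breaks = rbind(c(1L, h_on_1), c(2L, h_on_2)),
            forms = rbind(c(1L, 2L), c(h_on_1, h_on_2)))
}

# random mapped_reaction pool drawn from b2f2 enumeration of seeded molecules
random_reaction_pool <- function(seed, n_reactions,
                                 heavy_atom_range = c(3, 6)) {
  mols <- random_molecules(generator_config(
    seed = seed, heavy_atom_range = heavy_atom_range,
    count = max(4, ceiling(n_reactions / 6))))
  pool <- list()
  for (m in mols) {
    for (r in enumerate_b2f2(m)) {
      pool[[length(pool) + 1]] <- r
      if (length(pool) >= n_reactions) return(pool)
    }
  }
  pool
}

expect_isomorphic <- function(a, b) {
  expect_identical(canonical_hash(a), canonical_hash(b))
}
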