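# Atom typing, atom pairs, fingerprints, descriptors, Tanimoto.

test_that("atom typing distinguishes environment and respects symmetry", {
  # ethanol: the two carbons differ (one is oxygen-bonded)
  eth <- single_mol_graph("CCO")
  t_eth <- type_atoms(eth)
  expect_false(t_eth[1] == t_eth[2])
  # benzene: all six carbons share one code
  bz <- single_mol_graph("c1ccccc1")
  expect_length(unique(type_atoms(bz)), 1)
  # acetone: carbonyl carbon differs from the methyls
  ac <- single_mol_graph("CC(=O)C")
  t_ac <- type_atoms(ac)
  carbonyl <- which(ac$elem == "C" & ac$hyb == "sp2")
  methyl <- which(ac$elem == "C" & ac$hyb == "sp3")
  expect_false(t_ac[carbonyl][1] %in% t_ac[methyl])
})

test_that("atom typing is invariant to atom-index permutation", {
  # the same molecule written with different atom orders
  variants <- c("CCOc1ccccc1", "c1ccccc1OCC", "c1ccc(OCC)cc1")
  typesets <- lapply(variants, function(s) sort(type_atoms(single_mol_graph(s))))
  expect_equal(typesets[[1]], typesets[[2]])
  expect_equal(typesets[[1]], typesets[[3]])
})

test_that("atom-pair enumeration handles range bounds", {
  expect_length(enumerate_atom_pairs(single_mol_graph("CC")), 0)
  pairs <- enumerate_atom_pairs(single_mol_graph("CCC"))
  expect_length(pairs, 1)
  expect_match(pairs, "\\|2$")
  # an unbranched C25 chain has no feature beyond 20 bonds
  chain <- single_mol_graph(paste(rep("C", 25), collapse = ""))
  feats <- enumerate_atom_pairs(chain)
  dists <- as.integer(sub(".*\\|", "", feats))
  expect_true(all(dists >= 2 & dists <= 20))
})

test_that("atom-pair enumeration matches the brute-force BFS oracle", {
  smis <- unique(random_small_smiles(40, seed = 913))
  for (s in smis) {
    g <- single_mol_graph(s)
    expect_equal(enumerate_atom_pairs(g), oracle_atom_pairs(g), info = s)
  }
})

test_that("circular fingerprints are deterministic and structure-sensitive", {
  bz1 <- morgan_fingerprint(single_mol_graph("c1ccccc1"))
  bz2 <- morgan_fingerprint(single_mol_graph("c1ccccc1"))
  ch <- morgan_fingerprint(single_mol_graph("C1CCCCC1"))
  expect_identical(bz1, bz2)
  expect_false(identical(bz1, ch))
  expect_true(all(bz1 >= 1 & bz1 <= 4096))
  expect_lte(length(bz1), 4096)
  # the feature variant differs from the connectivity variant
  q <- single_mol_graph("c1ccccc1CCN")
  expect_false(identical(morgan_fingerprint(q, variant = "morgan"),
                         morgan_fingerprint(q, variant = "feature")))
})

test_that("fingerprint similarity ranking agrees with OpenBabel's circular fingerprint", {
  smis <- c("c1ccccc1CCN(C)C", "c1ccccc1CCN(C)CC", "c1ccccc1CCO",
            "C1CCCCC1", "CC(=O)Nc1ccccc1", "c1ccncc1CCCN(C)C")
  ms <- mol_set(data.frame(id = paste0("m", seq_along(smis)), smiles = smis))
  own <- fingerprint_matrix(ms, "morgan")
  sim_own <- tanimoto_matrix(own, own)
  ob <- ChemmineR::fingerprintOB(ms$sdf, "ECFP8")
  obm <- methods::as(Matrix::Matrix(ob@fpma > 0, sparse = TRUE), "nMatrix")
  sim_ob <- tanimoto_matrix(obm, obm)
  # different hashing, same notion of neighbourhood: strong rank agreement
  lower <- lower.tri(sim_own)
  expect_gt(cor(sim_own[lower], sim_ob[lower], method = "spearman"), 0.7)
})

test_that("tanimoto matches hand-computed values and properties", {
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto(c(1L, 2L), c(5L, 6L)), 0)
  expect_equal(tanimoto(c(7L, 9L), c(7L, 9L)), 1)
  expect_warning(z <- tanimoto(logical(4), logical(4)), "empty")
  expect_equal(z, 0)
  expect_error(tanimoto(logical(4), logical(5)), "width")
  set.seed(5)
  for (i in 1:20) {
    a <- sample(100, sample(1:20, 1))
    b <- sample(100, sample(1:20, 1))
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0)
    expect_lte(tanimoto(a, b), 1)
    expect_equal(tanimoto(a, a), 1)
  }
})

test_that("tanimoto_matrix agrees with the scalar definition", {
  ms <- toy_labelled_molset()
  fp <- fingerprint_matrix(ms, "morgan")
  sims <- tanimoto_matrix(fp[1:4, ], fp[5:8, ])
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(sims[i, j],
                   tanimoto(which(fp[i, ]), which(fp[4 + j, ])))
    }
  }
})

test_that("physchem descriptors are fixed-length, finite and sane", {
  ms <- mol_set(data.frame(id = c("me", "bz", "amine"),
                           smiles = c("CO", "c1ccccc1", "CCN(C)C")))
  pc <- physchem_descriptors(ms)
  expect_equal(dim(pc), c(3, length(PHYSCHEM_DESCRIPTORS)))
  expect_true(all(is.finite(pc)))
  # methanol: molecular weight from atomic-mass summation (CH4O = 32.04)
  expect_equal(pc["me", "MW"], 32.04, tolerance = 1e-3)
  expect_equal(unname(pc["bz", "heavy_atoms"]), 6)
  expect_equal(unname(pc["bz", "n_aromatic_atoms"]), 6)
  expect_equal(unname(pc["amine", "n_basic_N"]), 1)
  sub <- physchem_descriptors(ms, c("MW", "n_rings"))
  expect_equal(colnames(sub), c("MW", "n_rings"))
  expect_error(physchem_descriptors(ms, "not_a_descriptor"), "unknown")
})

test_that("feature cache reproduces on-the-fly computation", {
  ms <- toy_labelled_molset()
  msc <- featurize_mol_set(ms)
  expect_equal(msc$cache$morgan, fingerprint_matrix(ms, "morgan"))
  expect_equal(msc$cache$pc, physchem_descriptors(ms))
  idx <- c(3, 1, 7)
  sub <- subset_mol_set(msc, idx)
  expect_equal(sub$cache$morgan,
               fingerprint_matrix(subset_mol_set(ms, idx), "morgan"))
})
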