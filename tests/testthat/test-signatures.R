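test_that("height-0 signatures are bare atom tokens", {
  ph <- mg_add_hydrogens(smi1("CCC"))
  expect_equal(atom_signature(ph, 1, 0)$canonical_string, "[C]")
  b <- mg_add_hydrogens(smi1("c1ccccc1"))
  expect_equal(atom_signature(b, 1, 0)$canonical_string, "[c]")
  expect_equal(atom_signature(b, 7, 0)$canonical_string, "[H]")
  expect_error(atom_signature(ph, 99, 2), "invalid atom index")
})

test_that("symmetric atoms share signatures, distinct atoms do not", {
  b <- mg_add_hydrogens(smi1("c1ccccc1"))
  sigs <- vapply(seq_len(mg_n_atoms(b)),
                 function(i) atom_signature(b, i, 2)$canonical_string, "")
  c_sigs <- sigs[b$elem == "C"]
  h_sigs <- sigs[b$elem == "H"]
  expect_length(unique(c_sigs), 1L)
  expect_length(unique(h_sigs), 1L)
  expect_false(c_sigs[1] == h_sigs[1])

  p <- mg_add_hydrogens(smi1("CCC"))
  carbons <- which(p$elem == "C")
  ends <- vapply(carbons, function(i) {
    s <- atom_signature(p, i, 2)
    expect_equal(s$center_element, "C")
    s$canonical_string
  }, "")
  # two methyl carbons equal, central carbon different
  expect_equal(sum(ends == ends[1]), 2L)
  expect_length(unique(ends), 2L)
})

test_that("molecular signature counts every atom once", {
  sig <- molecular_signature(smi1("c1ccccc1"), 2)
  expect_length(sig, 2L)
  expect_equal(sort(as.integer(sig)), c(6L, 6L))
  expect_setequal(unname(attr(sig, "center_element")), c("C", "H"))

  m <- smi1("CC(N)C(=O)O")
  expect_equal(sum(molecular_signature(m, 2)), mg_total_atoms(m))
  # single heavy atom: counts sum to the full atom tally
  methane <- smi1("C")
  expect_equal(sum(molecular_signature(methane, 2)), 5L)
})

test_that("distinct signatures are monotone in height", {
  for (s in c("CCO", "c1ccc2ccccc2c1", "CC(C)Cc1ccc(C)cc1C(C)C(=O)O",
              "OCC1OC(O)C(O)C(O)C1O")) {
    mg <- mg_add_hydrogens(smi1(s))
    n_prev <- 0L
    for (h in 0:3) {
      n_h <- length(molecular_signature(mg, h))
      expect_gte(n_h, n_prev)
      n_prev <- n_h
    }
  }
})

test_that("signatures are invariant under atom relabelling", {
  set.seed(11)
  for (s in c("c1ccccc1O", "CC(=O)Nc1ccccc1", "OCC1OC(O)C(O)C(O)C1O",
              "Clc1ccc(S(N)(=O)=O)cc1", "CC(C)CCCC(C)C",
              "c1ccc2[nH]ccc2c1")) {
    mg <- mg_add_hydrogens(smi1(s))
    ref <- molecular_signature(mg, 2)
    for (k in 1:3) {
      perm <- sample(mg_n_atoms(mg))
      got <- molecular_signature(mg_permute(mg, perm), 2)
      expect_true(sig_identical(ref, got), info = s)
    }
  }
})

test_that("string equality agrees with a VF2 neighbourhood-isomorphism oracle", {
  set.seed(5)
  mols <- lapply(c("CC(C)O", "c1ccoc1", "C1CCO1", "OCC=O", "CC(=O)O",
                   "c1ccncc1", "C1CC1", "NCCO"),
                 function(s) mg_add_hydrogens(smi1(s)))
  for (mg in mols) {
    n <- mg_n_atoms(mg)
    sigs <- vapply(seq_len(n),
                   function(i) atom_signature(mg, i, 2)$canonical_string, "")
    balls <- lapply(seq_len(n), function(i) ball_graph(mg, i, 2))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      expect_equal(sigs[i] == sigs[j], balls_isomorphic(balls[[i]], balls[[j]]),
                   info = sprintf("%s atoms %d/%d", mg_canonical_smiles(mg),
                                  i, j))
    }
  }
})

test_that("centre element is recoverable from the canonical string", {
  mg <- mg_add_hydrogens(smi1("ClCC(=O)Nc1ccccc1"))
  for (i in seq_len(mg_n_atoms(mg))) {
    s <- atom_signature(mg, i, 2)
    expect_equal(sig_center_element(s$canonical_string), s$center_element)
  }
})
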