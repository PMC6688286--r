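test_that("fragment scores reproduce hand-computed log ratios", {
  expect_equal(fragment_score(10, 10, 100, 100, pseudocount = 1), 0)
  expect_equal(fragment_score(20, 5, 100, 100, pseudocount = 0), log(4))
  expect_equal(fragment_score(5, 0, 100, 100, pseudocount = 1), log(6))
  expect_equal(fragment_score(20, 5, 100, 100, pseudocount = 0,
                              log_base = "10"), log10(4))
  # imbalance correction: SMt/NPt term
  expect_equal(fragment_score(10, 10, 50, 100, pseudocount = 1), log(2))
  expect_error(fragment_score(0, 0, 10, 10), "at least one class")
  expect_error(fragment_score(1, 1, 0, 10), "totals")
})

test_that("ratio-scale invariance holds exactly at pseudocount 0", {
  grid <- expand.grid(np = c(1, 3, 17), sm = c(2, 5, 40), k = c(2, 3, 10))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    expect_equal(
      fragment_score(g$np * g$k, g$sm * g$k, 100 * g$k, 100 * g$k,
                     pseudocount = 0),
      fragment_score(g$np, g$sm, 100, 100, pseudocount = 0))
  }
})

test_that("occurrence counting respects multiplicity", {
  # mesitylene: the methyl-bearing aromatic environment occurs 3 times
  mes <- list(smi1("Cc1cc(C)cc(C)c1"))
  ref <- list(smi1("c1ccccc1"))
  cf <- count_fragments(mes, ref, height = 2, sugar_mode = "WITH_SUGAR")
  expect_equal(cf$np_total, 1L)
  expect_equal(cf$sm_total, 1L)
  sig <- molecular_signature(mes[[1]], 2)
  expect_equal(cf$counts$np_count[match(names(sig), cf$counts$canonical_string)],
               unname(as.integer(sig)))
  expect_true(any(cf$counts$np_count == 3L))
})

test_that("molecules whose fragments share one score get exactly that score", {
  tab <- train_fragment_table(list(smi1("c1ccccc1")),
                              list(smi1("C1CCCCC1")),
                              sugar_mode = "WITH_SUGAR")
  # every benzene fragment has np=6, sm=0: score ln((6+1)/1 * 1) = ln 7
  r <- score_molecule(smi1("c1ccccc1"), tab, "benz")
  expect_equal(r$np_likeness, log(7))
  expect_equal(r$n_unknown_fragments, 0L)
  r2 <- score_molecule(smi1("C1CCCCC1"), tab, "chx")
  expect_lt(r2$np_likeness, 0)
})

test_that("unknown fragments are excluded, alerted, and bound the average", {
  np <- lapply(c("c1ccccc1O", "Oc1ccc(O)cc1", "OCCO"), smi1)
  sm <- lapply(c("Clc1ccccc1", "ClCCl", "FC(F)(F)c1ccccc1"), smi1)
  tab <- train_fragment_table(np, sm, sugar_mode = "WITH_SUGAR")
  # a molecule with both known and unknown fragments
  mixed <- score_molecule(smi1("Oc1ccc(CBr)cc1"), tab, "mixed")
  expect_gt(mixed$n_unknown_fragments, 0L)
  expect_gt(mixed$n_fragments_used, 0L)
  expect_match(paste(mixed$alerts, collapse = " "), "not in the table")
  expect_gte(mixed$np_likeness, min(tab$score))
  expect_lte(mixed$np_likeness, max(tab$score))
  # entirely unknown: null score, everything counted unknown
  alien <- smi1("O=S(=O)(N)CCN")
  ra <- score_molecule(alien, tab, "alien")
  expect_true(is.na(ra$np_likeness))
  expect_equal(ra$n_fragments_used, 0L)
  expect_equal(ra$n_unknown_fragments, mg_total_atoms(alien))
  expect_match(paste(ra$alerts, collapse = " "), "undefined")
})

test_that("swapping the corpora negates every fragment and molecule score", {
  fx <- fixture_dir(15, 15, seed = 3)
  np <- smi_graphs(fx$np_file)
  sm <- smi_graphs(fx$sm_file)
  fwd <- train_fragment_table(np, sm, sugar_mode = "WITH_SUGAR")
  rev <- train_fragment_table(sm, np, sugar_mode = "WITH_SUGAR")
  m <- match(fwd$canonical_string, rev$canonical_string)
  expect_false(anyNA(m))
  expect_equal(rev$score[m], -fwd$score)
  probe <- smi1("Oc1ccc(Cl)cc1")
  s1 <- score_molecule(probe, fwd)$np_likeness
  s2 <- score_molecule(probe, rev)$np_likeness
  expect_equal(s2, -s1)
})

test_that("sugar-mode scoring works on aglycones and skips pure sugars", {
  np <- lapply(c("Oc1ccc(OC9OC(CO)C(O)C(O)C9O)cc1O", "Oc1ccc(CO)cc1O"), smi1)
  sm <- lapply(c("Clc1ccc(Cl)cc1", "Clc1ccccc1Cl"), smi1)
  tab <- train_fragment_table(np, sm, sugar_mode = "WITHOUT_SUGAR")
  # glucose alone has no aglycone: NA score plus an explanatory alert
  r <- score_molecule(smi1("OCC1OC(O)C(O)C(O)C1O"), tab, "glc")
  expect_true(is.na(r$np_likeness))
  expect_match(paste(r$alerts, collapse = " "), "entirely sugar")
  # the glycoside and its aglycone score identically in this mode
  glyco <- score_molecule(np[[1]], tab)$np_likeness
  agly <- score_molecule(remove_sugars(np[[1]])$aglycone, tab)$np_likeness
  expect_equal(glyco, agly)
})

test_that("fragment tables round-trip losslessly through TSV", {
  fx <- fixture_dir(15, 15, seed = 3)
  tab <- train_fragment_table(smi_graphs(fx$np_file),
                              smi_graphs(fx$sm_file),
                              sugar_mode = "WITHOUT_SUGAR")
  path <- tempfile(fileext = ".tsv")
  write_fragment_table(tab, path)
  tab2 <- read_fragment_table(path)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  for (a in c("np_total", "sm_total", "sugar_mode", "log_base",
              "pseudocount"))
    expect_identical(attr(tab, a), attr(tab2, a), info = a)
})

test_that("count_fragments rejects empty classes", {
  expect_error(count_fragments(list(), list(smi1("CCO"))), "non-empty")
})
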