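test_that("stereochemistry stripping collapses stereoisomers", {
  l_ala <- strip_stereochemistry("C[C@H](N)C(=O)O")
  flat <- strip_stereochemistry("CC(N)C(=O)O")
  expect_equal(mg_canonical_smiles(l_ala), mg_canonical_smiles(flat))
  expect_equal(structural_key(l_ala), structural_key(flat))
  trans <- strip_stereochemistry("C/C=C/C")
  expect_equal(structural_key(trans), structural_key(smi1("CC=CC")))
  # achiral input unchanged, atom/bond counts preserved
  achiral <- smi1("CCOCC")
  expect_identical(strip_stereochemistry(achiral), achiral)
  expect_equal(mg_n_atoms(l_ala), 6L)
})

test_that("largest component keeps the biggest fragment", {
  salt <- smi1("CC(=O)[O-].[Na+]")
  lc <- largest_component(salt)
  expect_equal(mg_n_heavy(lc), 4L)
  expect_equal(sort(lc$elem), c("C", "C", "O", "O"))
  hydrate <- largest_component(smi1("O.O.c1ccccc1"))
  expect_equal(structural_key(hydrate), structural_key(smi1("c1ccccc1")))
  whole <- smi1("c1ccncc1")
  expect_identical(largest_component(whole), whole)
})

test_that("element and size filter applies the documented boundary", {
  expect_true(filter_elements_and_size(smi1("c1ccccc1")))    # exactly 6
  expect_false(filter_elements_and_size(smi1("C[Sn](C)(C)C"))) # Sn banned
  expect_false(filter_elements_and_size(smi1("CCO")))        # 3 heavy atoms
  expect_true(filter_elements_and_size(smi1("CC(=O)NCC")))
  # hydrogen counting is available as an option
  expect_true(filter_elements_and_size(smi1("CCO"), min_atoms = 6L,
                                       count_hydrogens = TRUE))
})

test_that("structural keys identify graphs ignoring representation", {
  expect_equal(structural_key(smi1("c1ccccc1")),
               structural_key(smi1("C1=CC=CC=C1")))
  expect_false(structural_key(smi1("c1ccccc1")) ==
               structural_key(smi1("Cc1ccccc1")))
})

records_df <- function(smiles, status,
                       ids = sprintf("r%d", seq_along(smiles))) {
  data.frame(record_id = ids,
             source_db = rep("t", length(smiles)),
             source_id = ids, smiles = smiles, status = status,
             submission_date = rep("2026-01-01", length(smiles)),
             stringsAsFactors = FALSE)
}

test_that("curate merges duplicates, rejects and counts correctly", {
  recs <- records_df(c("c1ccccc1", "C1=CC=CC=C1", "CCO", "C[Sn](C)(C)C",
                       "c1ccncc1"),
                     c("NP", "NP", "NP", "NP", "SM"))
  cur <- curate(recs)
  expect_equal(cur$report$parsed, 5L)
  expect_equal(cur$report$rejected_size, 1L)
  expect_equal(cur$report$rejected_element, 1L)
  expect_equal(cur$report$unique, 2L)
  benz <- cur$molecules[cur$molecules$smiles == "c1ccccc1", ]
  expect_equal(benz$n_sources, 2L)
  expect_true(benz$is_np)
  pyr <- cur$molecules[cur$molecules$n_sources == 1L, ]
  expect_equal(pyr$train_class, "SM")
  # bookkeeping identity: every record accounted for
  r <- cur$report
  expect_equal(r$parsed,
               r$rejected_parse + r$rejected_size + r$rejected_element +
                 sum(cur$molecules$n_sources))
})

test_that("curate is order-invariant and idempotent", {
  smiles <- c("c1ccccc1O", "OC1=CC=CC=C1", "CC(=O)[O-].[Na+]",
              "CC(C)Cc1ccccc1", "C[C@H](N)C(=O)c1ccccc1",
              "CC(N)C(=O)c1ccccc1")
  recs <- records_df(smiles, rep("NP", 6))
  cur1 <- curate(recs)
  perm <- c(4, 1, 6, 3, 2, 5)
  cur2 <- curate(records_df(smiles[perm], rep("NP", 6),
                            ids = paste0("r", perm)))
  expect_setequal(cur1$molecules$structural_key,
                  cur2$molecules$structural_key)
  expect_equal(cur1$report[1:5], cur2$report[1:5])
  k <- order(cur1$molecules$structural_key)
  k2 <- order(cur2$molecules$structural_key)
  expect_equal(cur1$molecules$n_sources[k], cur2$molecules$n_sources[k2])
  # idempotence: re-curating the curated smiles reproduces keys/counts
  cur3 <- curate(records_df(cur1$molecules$smiles,
                            rep("NP", nrow(cur1$molecules))))
  expect_setequal(cur3$molecules$structural_key,
                  cur1$molecules$structural_key)
  expect_equal(cur3$report$unique, cur1$report$unique)
})

test_that("label conflicts resolve to NP with a warning; biogenic is excluded", {
  recs <- records_df(c("Cc1ccccc1", "Cc1ccccc1", "OCCCCCO"),
                     c("NP", "SM", "BIOGENIC"))
  expect_warning(cur <- curate(recs), "label conflict")
  tol <- cur$molecules[cur$molecules$n_sources == 2L, ]
  expect_true(tol$is_np)
  expect_equal(tol$train_class, "NP")
  bio <- cur$molecules[cur$molecules$n_sources == 1L, ]
  expect_equal(bio$train_class, "NONE")
  expect_false(bio$is_np)
})

test_that("curated descriptors satisfy their invariants", {
  recs <- records_df(c("OCC1=CC=CC=C1OC1OC(CO)C(O)C(O)C1O",  # salicin
                       "c1ccc2ccccc2c1", "CCCCCC(=O)O"),
                     rep("NP", 3))
  cur <- curate(recs)
  m <- cur$molecules
  expect_true(all(m$heavy_atom_count >= 6L))
  expect_false(any(duplicated(m$structural_key)))
  nosugar <- m[!m$contains_sugar, ]
  expect_equal(nosugar$heavy_atom_count_no_sugar,
               nosugar$heavy_atom_count)
  expect_equal(nosugar$total_atom_count_no_sugar,
               nosugar$total_atom_count)
  sal <- m[m$contains_sugar, ]
  expect_equal(nrow(sal), 1L)
  expect_equal(sal$heavy_atom_count_no_sugar, 8L)
  expect_equal(sal$ring_count, 2L)
})

test_that("curating zero records yields an empty set with zero counters", {
  cur <- curate(records_df(character(0), character(0)))
  expect_null(cur$molecules)
  expect_equal(cur$report$parsed, 0L)
  expect_equal(cur$report$unique, 0L)
})
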