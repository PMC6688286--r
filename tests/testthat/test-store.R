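records_df2 <- function(smiles, status, db = "t") {
  data.frame(record_id = paste0("r", seq_along(smiles)), source_db = db,
             source_id = paste0("r", seq_along(smiles)), smiles = smiles,
             status = status, submission_date = "2026-01-01",
             stringsAsFactors = FALSE)
}

store_hashes <- function(store) {
  files <- list.files(store$path, full.names = TRUE)
  stats::setNames(vapply(files, function(f) {
    paste(tools::md5sum(f))
  }, ""), basename(files))
}

test_that("ingest deduplicates molecules but keeps raw records redundant", {
  db <- file.path(tempdir(), "st1")
  st <- store_create(db, overwrite = TRUE)
  recs <- records_df2(c("c1ccccc1", "C1=CC=CC=C1"), c("NP", "NP"))
  cur <- curate(recs)
  ingest(st, cur, raw = recs)
  expect_equal(nrow(store_table(st, "ori_molecule")), 2L)
  expect_equal(nrow(store_table(st, "molecule")), 1L)
  # re-ingest: ori grows, molecule unchanged
  ingest(st, cur, raw = recs)
  expect_equal(nrow(store_table(st, "ori_molecule")), 4L)
  expect_equal(nrow(store_table(st, "molecule")), 1L)
  # ingest with empty curated set touches ori_molecule only
  st2 <- store_create(file.path(tempdir(), "st1b"), overwrite = TRUE)
  ingest(st2, NULL, raw = recs)
  expect_equal(nrow(store_table(st2, "ori_molecule")), 2L)
  expect_equal(nrow(store_table(st2, "molecule")), 0L)
})

test_that("occurrence relations sum to the molecules' atom counts", {
  db <- file.path(tempdir(), "st2")
  st <- store_create(db, overwrite = TRUE)
  recs <- records_df2(c("Oc1ccc(O)cc1", "CC(=O)NCCC"), c("NP", "SM"))
  ingest(st, curate(recs), raw = recs)
  expect_true(validate_store(st))
  cpd <- store_table(st, "molecule_fragment_cpd")
  mol <- store_table(st, "molecule")
  ws <- cpd[cpd$sugar_mode == "WITH_SUGAR", ]
  sums <- tapply(ws$occurrence, ws$molecule_id, sum)
  expect_equal(as.integer(sums[as.character(mol$molecule_id)]),
               mol$total_atom_count)
  expect_true(all(cpd$occurrence >= 1L))
})

test_that("training, rescoring and score lookups are consistent", {
  db <- file.path(tempdir(), "st3")
  st <- store_create(db, overwrite = TRUE)
  recs <- records_df2(c("Oc1ccc(O)cc1", "Oc1ccc(CO)cc1O", "OCCc1ccc(O)cc1",
                        "Clc1ccc(Cl)cc1", "ClCc1ccccc1",
                        "FC(F)(F)c1ccccc1"),
                      rep(c("NP", "SM"), each = 3))
  ingest(st, curate(recs), raw = recs)
  retrain_scores(st)
  meta <- store_meta(st)
  expect_true(meta$trained)
  expect_equal(meta$totals$WITH_SUGAR$np_total, 3L)
  tab <- store_fragment_table(st, "WITHOUT_SUGAR")
  expect_true(all(tab$np_count + tab$sm_count >= 1L))
  expect_equal(tab$score,
               fragment_score(tab$np_count, tab$sm_count,
                              attr(tab, "np_total"), attr(tab, "sm_total"),
                              attr(tab, "pseudocount")))
  # lookups: stored signatures found, unknown absent, empty query empty
  q <- query_fragment_scores(st, tab$canonical_string[1:3], "WITHOUT_SUGAR")
  expect_equal(unname(q), tab$score[1:3])
  expect_length(query_fragment_scores(st, "[Xx]", "WITHOUT_SUGAR"), 0L)
  expect_length(query_fragment_scores(st, character(0), "WITHOUT_SUGAR"), 0L)
  # retraining an unchanged store is byte-stable
  h1 <- store_hashes(st)
  retrain_scores(st)
  expect_identical(store_hashes(st), h1)
  # adding one NP molecule increments the class total
  more <- records_df2("OCCCc1ccc(O)c(O)c1", "NP", db = "extra")
  ingest(st, curate(more), raw = more)
  retrain_scores(st)
  expect_equal(store_meta(st)$totals$WITH_SUGAR$np_total, 4L)
  expect_true(validate_store(st))
})

test_that("dump and load reproduce identical tables", {
  db <- file.path(tempdir(), "st4")
  st <- store_create(db, overwrite = TRUE)
  recs <- records_df2(c("Oc1ccc(O)cc1", "Clc1ccc(Cl)cc1"), c("NP", "SM"))
  ingest(st, curate(recs), raw = recs)
  retrain_scores(st)
  dump <- file.path(tempdir(), "st4_dump")
  unlink(dump, recursive = TRUE)
  store_dump(st, dump)
  target <- file.path(tempdir(), "st4_loaded")
  unlink(target, recursive = TRUE)
  st2 <- store_load(dump, target)
  for (tb in npscore:::.STORE_TABLES) {
    a <- store_table(st, tb)
    b <- store_table(st2, tb)
    expect_identical(a[do.call(order, a), , drop = FALSE],
                     b[do.call(order, b), , drop = FALSE], info = tb)
  }
})

test_that("biogenic-only fragments stay unscored and are excluded", {
  db <- file.path(tempdir(), "st5")
  st <- store_create(db, overwrite = TRUE)
  recs <- records_df2(c("Oc1ccc(O)cc1", "Clc1ccc(Cl)cc1", "NCCCCCN"),
                      c("NP", "SM", "BIOGENIC"))
  ingest(st, curate(recs), raw = recs)
  retrain_scores(st)
  full <- store_table(st, "fragment_with_sugar")
  expect_true(any(is.na(full$score)))          # diamine-only fragments
  tab <- store_fragment_table(st, "WITH_SUGAR")
  expect_false(any(is.na(tab$score)))
  # the biogenic molecule still gets scored from known fragments (or NA)
  mol <- store_table(st, "molecule")
  bio <- mol[mol$train_class == "NONE", ]
  expect_equal(nrow(bio), 1L)
})
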