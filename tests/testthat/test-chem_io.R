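test_that("SMILES files are read in order with ids and skip logging", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benz", "CCO eth"), f)
  r <- read_molecules(f, "smi", "NP", "testdb")
  expect_equal(r$record_id, c("benz", "eth"))
  expect_equal(r$status, c("NP", "NP"))
  expect_equal(attr(r, "n_skipped"), 0L)

  # malformed line among valid ones: parsed records keep input order
  f2 <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1", "C1CC broken", "CCO", "# comment", "CCN"), f2)
  expect_message(r2 <- read_molecules(f2, "smi", "SM"), "skipped 1")
  expect_equal(nrow(r2), 3L)
  expect_equal(attr(r2, "n_skipped"), 1L)
  expect_equal(attr(r2, "skipped")$reason, "unparseable SMILES")
  # generated ids use the 1-based record position (comments don't count)
  expect_equal(r2$record_id, c("m1", "m3", "m4"))

  expect_error(read_molecules(tempfile(), "smi"), "does not exist")
  f3 <- tempfile(fileext = ".smi")
  writeLines("C1CC only-bad", f3)
  expect_error(suppressMessages(read_molecules(f3, "smi")), "no parseable")
})

test_that("SDF records round-trip to the same structural keys", {
  mgs <- parse_smiles(c("CC(N)C(=O)O", "c1ccncc1"))
  txt <- paste0(vapply(seq_along(mgs), function(i)
    npscore:::mg_to_molblock(mgs[[i]], paste0("mol", i)), ""),
    collapse = "")
  f <- tempfile(fileext = ".sdf")
  writeLines(txt, f)
  r <- read_molecules(f, "sdf", "NP", "sdfdb")
  expect_equal(nrow(r), 2L)
  expect_equal(r$record_id, c("mol1", "mol2"))
  g <- attr(r, "graphs")
  expect_equal(structural_key(g[[1]]), structural_key(mgs[[1]]))
  expect_equal(structural_key(g[[2]]), structural_key(mgs[[2]]))
})

test_that("smi round trip preserves record count and structural keys", {
  smiles <- c("c1ccccc1O", "CC(=O)Nc1ccccc1", "OCC(O)CO")
  f <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, c("a", "b", "c")), f)
  r1 <- read_molecules(f, "smi")
  g1 <- attr(r1, "graphs")
  f2 <- tempfile(fileext = ".smi")
  writeLines(paste(r1$smiles, r1$record_id), f2)
  r2 <- read_molecules(f2, "smi")
  g2 <- attr(r2, "graphs")
  expect_equal(nrow(r2), nrow(r1))
  expect_equal(vapply(g2, structural_key, ""),
               vapply(g1, structural_key, ""))
  # determinism
  r3 <- read_molecules(f, "smi")
  expect_identical(as.data.frame(r1), as.data.frame(r3))
})

test_that("write_results emits the contract columns and refuses empty input", {
  res <- data.frame(record_id = "a", smiles = "c1ccccc1", np_likeness = 1.2,
                    np_likeness_with_sugar = 1.1, heavy_atom_count = 6L,
                    total_atom_count = 12L, ring_count = 1L,
                    n_unknown_fragments = 2L,
                    alerts = "2 fragment occurrences not in the table",
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_results(res, f)
  got <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(got), 1L)
  expect_equal(names(got),
               c("record_id", "smiles", "np_likeness",
                 "np_likeness_with_sugar", "heavy_atom_count",
                 "total_atom_count", "ring_count", "n_unknown_fragments",
                 "alerts"))
  expect_true(nzchar(got$alerts[1]))

  f2 <- tempfile(fileext = ".csv")
  expect_error(write_results(res[0, ], f2), "no results")
  expect_false(file.exists(f2))
})
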