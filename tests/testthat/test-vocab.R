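test_that("vocabulary construction reserves pad/unk and is deterministic", {
  v <- build_vocab(list(c("AAA", "BBB")))
  expect_equal(v$size, 4L)
  expect_equal(v$pad_id, 0L)
  expect_equal(v$unk_id, 1L)
  expect_identical(build_vocab(list(c("AAA", "BBB"))), v)
  # first-seen order from id 2
  v2 <- build_vocab(list(c("x", "y"), c("y", "z")))
  expect_equal(v2$tokens, c("x", "y", "z"))
  expect_error(build_vocab(list()), "empty corpus")
})

test_that("min_count filters singletons to unk at encode time", {
  v <- build_vocab(list(c("a", "a", "b")), min_count = 2)
  expect_equal(v$tokens, "a")
  expect_equal(encode_fragments(c("a", "b"), v, 3), c(2L, 1L, 0L))
})

test_that("encoding pads, truncates and maps unknowns", {
  v <- build_vocab(list(c("AAA", "BBB")))
  expect_equal(encode_fragments("AAA", v, 3), c(2L, 0L, 0L))
  expect_equal(encode_fragments("zzz", v, 2), c(1L, 0L))
  expect_equal(encode_fragments(c("AAA", "BBB", "AAA", "BBB", "AAA"), v, 3),
               c(2L, 3L, 2L))
  ids <- encode_fragments(c("AAA", "zzz", "BBB"), v, 5)
  expect_length(ids, 5L)
  # padding only as a contiguous suffix
  expect_equal(ids, c(2L, 1L, 3L, 0L, 0L))
  expect_equal(decode_fragments(ids, v), c("AAA", "<unk>", "BBB"))
})

test_that("fragment sequences encode end to end", {
  fs <- fragment_drug("CC(=O)Oc1ccccc1")
  v <- build_vocab(list(fs))
  ids <- encode_fragments(fs, v, 10)
  expect_length(ids, 10L)
  expect_true(all(ids < v$size))
  expect_equal(decode_fragments(ids, v), fs$fragments$text)
})

test_that("test-only fragments hit unk by construction", {
  train_frags <- list(c("AAA", "BBB"), c("AAA", "CCC"))
  v <- build_vocab(train_frags)
  test_frags <- c("AAA", "DDD", "EEE")
  ids <- encode_fragments(test_frags, v, 3)
  expect_equal(ids[2:3], c(1L, 1L))
})

test_that("vocab and DTI tables round-trip through files", {
  v <- build_vocab(list(c("AAA", "BBB", "CCC")))
  f <- withr::local_tempfile(fileext = ".json")
  write_vocab(v, f)
  expect_identical(read_vocab(f), v)

  pairs <- data.frame(smiles = c("CCO", "CC(=O)O"),
                      sequence = c("GAVRKD", "MKTAYI"),
                      label = c(1L, 0L), stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dti_table(pairs, tsv)
  expect_identical(read_dti_table(tsv), pairs)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_dti_table(pairs, csv)
  expect_identical(read_dti_table(csv), pairs)
})

test_that("encode_dti_pairs stacks id matrices", {
  pairs <- data.frame(smiles = c("CCO", "CC(=O)Oc1ccccc1"),
                      sequence = c("GAVRKD", "MKTAYIGAV"),
                      label = c(1L, 0L), stringsAsFactors = FALSE)
  dv <- build_vocab(lapply(pairs$smiles, fragment_drug))
  pv <- build_vocab(lapply(pairs$sequence, fragment_protein))
  enc <- encode_dti_pairs(pairs, dv, pv, max_len_drug = 5L,
                          max_len_protein = 4L)
  expect_equal(dim(enc$drug_ids), c(2L, 5L))
  expect_equal(dim(enc$protein_ids), c(2L, 4L))
  expect_equal(enc$labels, c(1L, 0L))
  expect_true(all(enc$drug_ids < dv$size))
})
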