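test_that("branch chains are the maximal outermost parenthesised spans", {
  expect_equal(extract_branch_chains("CCO"),
               list(branch_fragments = character(0), main_chain = "CCO"))
  expect_equal(extract_branch_chains("CC(=O)O"),
               list(branch_fragments = "=O", main_chain = "CCO"))
  # nested parentheses stay inside the single outermost fragment
  expect_equal(extract_branch_chains("CC(C(=O)O)N"),
               list(branch_fragments = "C(=O)O", main_chain = "CCN"))
  expect_equal(extract_branch_chains("CC(C)(C)N")$branch_fragments,
               c("C", "C"))
  expect_error(extract_branch_chains("CC(C"), class = "fcadti_malformed_smiles")
  expect_error(extract_branch_chains("CC)C"), class = "fcadti_malformed_smiles")
})

test_that("common substructures are removed left-to-right, non-overlapping", {
  expect_equal(extract_common_substructures("CCC"),
               list(common_fragments = character(0), residual = "CCC"))
  expect_equal(extract_common_substructures("c1ccccc1CCN"),
               list(common_fragments = "c1ccccc1", residual = "CCN"))
  # leftmost token-level match of "COC" in C C O C O C starts at token 2;
  # the single-pass residual "C"+"OC" is not re-scanned
  expect_equal(extract_common_substructures("CCOCOC"),
               list(common_fragments = "COC", residual = "COC"))
  # token boundaries: "Cl O C" must not fake a C-O-C match
  expect_equal(extract_common_substructures("ClOC")$common_fragments,
               character(0))
  expect_equal(extract_common_substructures("C(=O)O")$common_fragments,
               "C(=O)O")
  expect_equal(
    extract_common_substructures("Cc1ccccc1COCN")$common_fragments,
    c("c1ccccc1", "COC"))
})

test_that("synthetic fragments chunk atom runs with bond/ring attachment", {
  expect_equal(split_synthetic_fragments(""), character(0))
  expect_equal(split_synthetic_fragments("CCN"), "CCN")
  expect_equal(split_synthetic_fragments("CCCCC"), c("CCC", "CC"))
  # bonds attach to the following atom, ring digits to the preceding one
  expect_equal(split_synthetic_fragments("C=CC=C"), c("C=CC", "=C"))
  expect_equal(split_synthetic_fragments("C1CCC1"), c("C1CC", "C1"))
  expect_equal(split_synthetic_fragments("CCCCC", max_synthetic_len = 2L),
               c("CC", "CC", "C"))
  expect_error(split_synthetic_fragments("C(C)O"))
})

test_that("fragment_drug composes the three stages", {
  fs <- fragment_drug("CCO")
  expect_s3_class(fs, "fragment_sequence")
  expect_equal(fs$fragments$text, "CCO")
  expect_equal(fs$fragments$ftype, "synthetic")

  fs <- fragment_drug("CC(=O)Oc1ccccc1")
  expect_setequal(fs$fragments$text, c("=O", "c1ccccc1", "CCO"))
  expect_equal(
    fs$fragments$ftype[match(c("=O", "c1ccccc1", "CCO"), fs$fragments$text)],
    c("branch_chain", "common_substructure", "synthetic"))

  # a branch containing a common substructure is decomposed, not duplicated
  fs <- fragment_drug("CC(C(=O)O)N")
  expect_equal(sum(fs$fragments$text == "C(=O)O"), 1L)
  expect_equal(
    fs$fragments$ftype[fs$fragments$text == "C(=O)O"], "common_substructure")
})

test_that("atom multiset is conserved and order is deterministic", {
  set.seed(42)
  for (r in 1:50) {
    s <- generate_smiles(with_motif = r %% 2 == 0)
    fs <- fragment_drug(s)
    frag_atoms <- sort(unlist(lapply(fs$fragments$text, atom_multiset)))
    expect_equal(frag_atoms, atom_multiset(s), info = s)
    expect_true(all(nzchar(fs$fragments$text)))
    expect_identical(fragment_drug(s)$fragments, fs$fragments)
  }
})

test_that("scan flags and positional order change the output as documented", {
  s <- "CC(=O)Oc1ccccc1"
  fs_nomain <- fragment_drug(s, scan_main = FALSE)
  expect_false("c1ccccc1" %in% fs_nomain$fragments$text[
    fs_nomain$fragments$ftype == "common_substructure"])
  fs_pos <- fragment_drug(s, positional_order = TRUE)
  # branch "=O" precedes the main-chain benzene in string position
  expect_true(which(fs_pos$fragments$text == "=O") <
                which(fs_pos$fragments$text == "c1ccccc1"))
  # atom conservation holds in positional mode too
  expect_equal(sort(unlist(lapply(fs_pos$fragments$text, atom_multiset))),
               atom_multiset(s))
})

test_that("pattern tables round-trip through JSON", {
  tab <- default_pattern_table()
  f <- withr::local_tempfile(fileext = ".json")
  write_pattern_table(tab, f)
  expect_equal(read_pattern_table(f), tab)
})
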