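test_that("generators are seed-deterministic and contain their motifs", {
  set.seed(7); s1 <- generate_smiles(TRUE)
  set.seed(7); s2 <- generate_smiles(TRUE)
  expect_identical(s1, s2)
  expect_match(s1, "C\\(=O\\)O", fixed = FALSE)
  set.seed(7); p1 <- generate_protein(TRUE)
  set.seed(7); p2 <- generate_protein(TRUE)
  expect_identical(p1, p2)
  expect_match(p1, "RKD")
  expect_match(p1, "^[ARNDCQEGHILKMFPSTWVY]+$")
  expect_true(nchar(p1) >= 50 && nchar(p1) <= 400)
})

test_that("protein motif lands k-gram-aligned in one category fragment", {
  set.seed(13)
  for (r in 1:25) {
    p <- generate_protein(TRUE)
    frags <- fragment_protein(p)$fragments$text
    expect_true("EEF" %in% frags, info = p)
  }
})

test_that("every generated molecule and protein passes both fragmenters", {
  set.seed(19)
  for (r in 1:200) {
    s <- generate_smiles(r %% 2 == 0)
    expect_no_error(fragment_drug(s))
    expect_no_error(fragment_protein(generate_protein(r %% 2 == 0)))
  }
})

test_that("datasets are balanced, labelled by the rule and byte-stable", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  d <- generate_dataset(400, planted_rule(), seed = 11, path = f1)
  expect_equal(nrow(d), 400L)
  # binomial bound: positive fraction within 0.07 of one half
  expect_lt(abs(mean(d$label) - 0.5), 0.07)
  expect_lt(abs(mean(d$has_motif) - 0.5), 0.07)
  # labels track motif presence under the default rule
  expect_gt(mean(d$label[d$has_motif]), 0.85)
  expect_lt(mean(d$label[!d$has_motif]), 0.15)
  generate_dataset(400, planted_rule(), seed = 11, path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(generate_dataset(3), "n must be >= 4")
})

test_that("a flat rule makes labels independent of motifs", {
  flat <- planted_rule(p_signal = 0.5, p_noise = 0.499999)
  d <- generate_dataset(2000, flat, seed = 23)
  tab <- table(d$label, d$has_motif)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("bayes_auc matches the hand-derived closed form", {
  # defaults: a = b-complement symmetry gives 0.9025 + 0.0475 = 0.95
  expect_equal(bayes_auc(), 0.95, tolerance = 1e-12)
  # degenerate rule carries no signal
  expect_equal(bayes_auc(planted_rule(p_signal = 0.5001, p_noise = 0.4999)),
               0.5, tolerance = 1e-3)
  # perfect determinism separates completely
  expect_equal(bayes_auc(planted_rule(p_signal = 1, p_noise = 0)), 1)
})
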