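test_that("stratified split is exact, disjoint and reproducible", {
  pairs <- data.frame(smiles = sprintf("C%d", 1:100),
                      sequence = sprintf("S%d", 1:100),
                      label = rep(c(0L, 1L), 50))
  sp <- split_dataset(pairs, ratio = 0.8, seed = 4)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_equal(as.vector(table(sp$train$label)), c(40L, 40L))
  expect_equal(as.vector(table(sp$test$label)), c(10L, 10L))
  expect_identical(split_dataset(pairs, 0.8, 4)$test_idx, sp$test_idx)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:100)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_error(split_dataset(pairs[1:4, ], 0.8, 1), "at least 5")
})

test_that("cv folds rotate, balance and reproduce", {
  labels <- rep(c(0L, 1L), 50)
  f <- make_cv_folds(labels, folds = 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 20))           # each pair validated once
  expect_true(max(table(f, labels)) - min(table(f, labels)) <= 1)
  expect_identical(make_cv_folds(labels, 5, 2), f)
  expect_error(make_cv_folds(labels[1:3], folds = 5), "fewer pairs")
})

test_that("metrics match hand-computed and brute-force values", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$aupr, 1)
  # 4 positive-negative pairs, 3 ordered correctly
  m <- compute_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 0.75)
  expect_equal(m$precision, 1 / 2)
  expect_equal(m$recall, 1 / 2)
  # ties at the 0.5 threshold count positive
  m <- compute_metrics(c(0.5, 0.5), c(1, 0))
  expect_equal(m$recall, 1)
  expect_equal(m$accuracy, 0.5)
  expect_true(is.na(compute_metrics(c(0.2, 0.9), c(1, 1))$auc))
  expect_equal(compute_metrics(c(0.2, 0.9), c(1, 1))$accuracy, 0.5)
})

test_that("rank AUC equals brute-force pair counting and reverses cleanly", {
  set.seed(77)
  for (r in 1:20) {
    n <- sample(6:30, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), 2)            # duplicates induce ties
    auc <- compute_metrics(scores, labels)$auc
    expect_equal(auc, auc_brute(scores, labels), tolerance = 1e-9)
    expect_equal(compute_metrics(-scores, labels)$auc, 1 - auc,
                 tolerance = 1e-9)
  }
})

# short-sequence memorization fixture keeps the network tiny and fast
memorize_pairs <- function(n, seed) {
  local({
    set.seed(seed)
    data.frame(
      smiles = vapply(1:n, function(i) generate_smiles(i %% 2 == 0), ""),
      sequence = vapply(1:n, function(i)
        substr(generate_protein(i %% 2 == 0), 1, 45), ""),
      label = sample(0:1, n, TRUE),
      stringsAsFactors = FALSE)
  })
}

test_that("the network memorizes a 32-pair task (overfitting oracle)", {
  pairs <- memorize_pairs(32, seed = 6)
  dv <- build_vocab(lapply(pairs$smiles, fragment_drug))
  pv <- build_vocab(lapply(pairs$sequence, fragment_protein))
  cfg <- small_model_config(max_len_protein = 15L, dropout = 0)
  enc <- encode_dti_pairs(pairs, dv, pv, max_len_drug = 30L,
                          max_len_protein = 15L)
  model <- new_dti_model(dv, pv, cfg, seed = 1)
  model <- train_dti(model, enc, val_data = NULL,
                     small_train_config(seed = 1, batch_size = 16L,
                                        max_epochs = 200L, patience = 200L,
                                        dropout = 0))
  expect_lt(tail(model$history$train_loss, 1), 0.05)
})

test_that("training is seed-deterministic and weight decay is observable", {
  pairs <- memorize_pairs(24, seed = 8)
  dv <- build_vocab(lapply(pairs$smiles, fragment_drug))
  pv <- build_vocab(lapply(pairs$sequence, fragment_protein))
  enc <- encode_dti_pairs(pairs, dv, pv, 30L, 15L)
  val <- lapply(enc, function(x) if (is.matrix(x)) x[1:8, , drop = FALSE]
                else x[1:8])
  cfg <- small_model_config(max_len_protein = 15L)
  run <- function(wd) {
    m <- new_dti_model(dv, pv, cfg, seed = 2)
    train_dti(m, enc, val, small_train_config(seed = 2, batch_size = 12L,
                                              max_epochs = 5L, patience = 5L,
                                              weight_decay = wd))
  }
  m1 <- run(1e-4); m2 <- run(1e-4); m0 <- run(0)
  expect_identical(tail(m1$history$val_auc, 1), tail(m2$history$val_auc, 1))
  expect_identical(m1$params$fc1_W, m2$params$fc1_W)
  norm1 <- sqrt(sum(m1$params$fc1_W^2))
  norm0 <- sqrt(sum(m0$params$fc1_W^2))
  expect_false(isTRUE(all.equal(norm1, norm0)))
})

test_that("cross-validation rotates every pair through validation once", {
  pairs <- memorize_pairs(20, seed = 9)
  cv <- cross_validate_dti(
    pairs, folds = 4,
    model_cfg = small_model_config(max_len_protein = 15L),
    train_cfg = small_train_config(seed = 3, batch_size = 8L,
                                   max_epochs = 2L, patience = 2L))
  expect_equal(nrow(cv$fold_metrics), 4L)
  expect_true(all(table(cv$fold_assignment) == 5))
  expect_named(cv$mean_metrics,
               c("auc", "aupr", "accuracy", "precision", "recall"))
})

test_that("held-out performance approaches the Bayes ceiling (end-to-end)", {
  res <- e2e_run()
  expect_gte(res$full_metrics$auc, 0.95 * bayes_auc())
})
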