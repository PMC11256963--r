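test_that("elu matches its closed form", {
  expect_equal(elu(2, 1), 2)
  expect_equal(elu(0, 1), 0)
  expect_equal(elu(-1, 1), exp(-1) - 1, tolerance = 1e-12)
  expect_equal(elu(-2, 0.5), 0.5 * (exp(-2) - 1), tolerance = 1e-12)
  # continuity at 0
  expect_lt(abs(elu(1e-10) - elu(-1e-10)), 1e-9)
})

test_that("cross-attention matches the naive loop oracle", {
  set.seed(5)
  w <- random_weights(8, seed = 5)
  D <- matrix(rnorm(7 * 8), 7, 8)
  P <- matrix(rnorm(11 * 8), 11, 8)
  got <- cross_attention(D, P, w, h = 2)
  want <- naive_cross_attention(D, P, w, h = 2)
  expect_lt(max(abs(got$M_D - want$M_D)), 1e-5)
  expect_lt(max(abs(got$M_P - want$M_P)), 1e-5)
})

test_that("attention rows normalise and degenerate keys reduce to values", {
  w <- random_weights(8, seed = 9)
  D <- matrix(rnorm(5 * 8), 5, 8)
  P <- matrix(rnorm(3 * 8), 3, 8)
  out <- cross_attention(D, P, w, h = 2)
  for (A in c(out$A_D, out$A_P)) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  }
  # L_P = 1: softmax over a single key is 1, so Z_D = P %*% WV per head
  P1 <- matrix(rnorm(8), 1, 8)
  out1 <- cross_attention(D, P1, w, h = 2)
  ZD_expected <- cbind((P1 %*% w$WV[, 1:4])[rep(1, 5), ],
                       (P1 %*% w$WV[, 5:8])[rep(1, 5), ]) %*% w$W0
  expect_equal(out1$M_D, ZD_expected, tolerance = 1e-10)
})

test_that("drug and protein passes share the same projection parameters", {
  m <- tiny_model()
  did <- matrix(c(2L, 3L, 4L, 0L, 0L, 0L), 1)
  pid <- matrix(c(2L, 3L, 4L, 5L, 6L, 0L, 0L, 0L, 0L), 1)
  base <- model_forward(m, did, pid, return_attention = TRUE)
  # one in-place perturbation of WQ must move BOTH attention directions
  m2 <- m
  m2$params$attn_WQ[1, 1] <- m2$params$attn_WQ[1, 1] + 0.5
  pert <- model_forward(m2, did, pid, return_attention = TRUE)
  expect_gt(max(abs(base$attention$AD - pert$attention$AD)), 0)
  expect_gt(max(abs(base$attention$AP - pert$attention$AP)), 0)
})

test_that("residual mix is the stated convex combination", {
  M <- matrix(c(2, 1, -1, 4), 2)
  orig <- matrix(c(4, 0, 3, 2), 2)
  expect_equal(residual_mix(M, M), M)
  expect_equal(residual_mix(matrix(0, 2, 2), orig), 0.5 * orig)
  expect_equal(residual_mix(matrix(2), matrix(4), w = 0.5), matrix(3))
  expect_equal(residual_mix(M, orig, w = 0.25), 0.25 * M + 0.75 * orig)
  expect_identical(residual_mix(M, orig, ablation = "no_original_feature"), M)
  expect_error(residual_mix(M, matrix(0, 3, 2)), "shape")
})

test_that("bce loss matches closed forms", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(1 - 1e-7, 1), 1e-6)
  expect_equal(bce_loss(0.3, 0), bce_loss(0.7, 1), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               mean(-c(log(0.9), log(0.8))), tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("forward pass is deterministic, batch-consistent and bounded", {
  m <- tiny_model()
  set.seed(21)
  did <- matrix(sample(0:7, 3 * 6, TRUE), 3)
  pid <- matrix(sample(0:6, 3 * 9, TRUE), 3)
  p1 <- model_forward(m, did, pid)$prob
  p2 <- model_forward(m, did, pid)$prob
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # batched forward equals per-sample forward (eval mode, running stats)
  p_ind <- vapply(1:3, function(i)
    model_forward(m, did[i, , drop = FALSE], pid[i, , drop = FALSE])$prob, 0)
  expect_lt(max(abs(p1 - p_ind)), 1e-6)
})

test_that("ablations change the computation", {
  set.seed(22)
  did <- matrix(sample(0:7, 6, TRUE), 1)
  pid <- matrix(sample(0:6, 9, TRUE), 1)
  p_full <- model_forward(tiny_model(), did, pid)$prob
  p_noattn <- model_forward(tiny_model(ablation = "no_cross_attention"),
                            did, pid)$prob
  p_noorig <- model_forward(tiny_model(ablation = "no_original_feature"),
                            did, pid)$prob
  expect_false(isTRUE(all.equal(p_full, p_noattn)))
  expect_false(isTRUE(all.equal(p_full, p_noorig)))
})

test_that("analytic gradients agree with central finite differences", {
  m <- tiny_model(dropout = 0)
  set.seed(31)
  did <- matrix(sample(0:7, 2 * 6, TRUE), 2)
  pid <- matrix(sample(0:6, 2 * 9, TRUE), 2)
  y <- c(1, 0)
  fwd <- model_forward(m, did, pid, training = TRUE, return_cache = TRUE)
  grads <- model_backward(m, fwd, y)
  lossfun <- function(params) {
    m2 <- m; m2$params <- params
    bce_loss(model_forward(m2, did, pid, training = TRUE)$prob, y)
  }
  h <- 1e-5
  set.seed(7)
  for (nm in names(m$params)) {
    g <- grads[[nm]]
    for (ii in sample(length(g), min(4, length(g)))) {
      p1 <- m$params; p1[[nm]][ii] <- p1[[nm]][ii] + h
      p2 <- m$params; p2[[nm]][ii] <- p2[[nm]][ii] - h
      fd <- (lossfun(p1) - lossfun(p2)) / (2 * h)
      expect_lt(abs(fd - g[ii]) / max(1e-8, abs(fd) + abs(g[ii])), 1e-3,
                label = sprintf("grad check %s[%d]", nm, ii))
    }
  }
})

test_that("model config validates its invariants", {
  expect_error(model_config(conv_channels = 30L, heads = 4L))
  expect_error(model_config(dropout = 1))
  expect_error(model_config(mix_weight = 1.5))
  expect_error(model_config(ablation = "bogus"))
  cfg <- small_model_config(heads = 8L)
  expect_equal(cfg$heads, 8L)
  expect_equal(cfg$emb_dim, 32L)
  # full-scale defaults
  full <- model_config()
  expect_equal(full$emb_dim, 512L)
  expect_equal(full$protein_kernels, c(4L, 6L, 8L))
})
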