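#' Model configuration
#'
#' Architecture hyperparameters of the fragment cross-attention interaction
#' model.  Defaults follow the full-scale setting (embedding width 512,
#' drug conv kernels 3/3/3, protein conv kernels 4/6/8, 4 attention heads);
#' [small_model_config()] gives a desk-scale preset used throughout the
#' tests and the synthetic end-to-end run.
#'
#' @param emb_dim Embedding width.
#' @param conv_channels Convolution output channels \code{d_CNN}; must be
#'   divisible by \code{heads} (head width \code{d_h = d_CNN / heads}).
#' @param drug_kernels,protein_kernels Kernel sizes of the three conv
#'   layers per branch.
#' @param heads Number of attention heads.
#' @param dropout Dropout fraction in the FCN head (training only).
#' @param fcn_hidden Widths of the two hidden FCN layers.
#' @param alpha_elu ELU negative-saturation scale.
#' @param mix_weight Residual mix weight \code{w} in
#'   \code{w * M + (1 - w) * original} (default 0.5).
#' @param ablation One of \code{"full"}, \code{"no_cross_attention"}
#'   (attention module removed, CNN features pass straight through) or
#'   \code{"no_original_feature"} (residual mix disabled, attention output
#'   used alone).
#' @param max_len_drug,max_len_protein Fixed encoded fragment-sequence
#'   lengths (positions beyond are truncated, shorter sequences padded).
#' @return A \code{model_config} list.
#' @export
model_config <- function(emb_dim = 512L, conv_channels = 128L,
                         drug_kernels = c(3L, 3L, 3L),
                         protein_kernels = c(4L, 6L, 8L),
                         heads = 4L, dropout = 0.1,
                         fcn_hidden = c(512L, 128L),
                         alpha_elu = 1, mix_weight = 0.5,
                         ablation = c("full", "no_cross_attention",
                                      "no_original_feature"),
                         max_len_drug = 100L, max_len_protein = 545L) {
  ablation <- match.arg(ablation)
  stopifnot(length(drug_kernels) == 3L, length(protein_kernels) == 3L,
            length(fcn_hidden) == 2L,
            conv_channels %% heads == 0L,
            dropout >= 0, dropout < 1,
            mix_weight >= 0, mix_weight <= 1,
            alpha_elu > 0, max_len_drug >= 1L, max_len_protein >= 1L)
  structure(list(emb_dim = as.integer(emb_dim),
                 conv_channels = as.integer(conv_channels),
                 drug_kernels = as.integer(drug_kernels),
                 protein_kernels = as.integer(protein_kernels),
                 heads = as.integer(heads), dropout = dropout,
                 fcn_hidden = as.integer(fcn_hidden),
                 alpha_elu = alpha_elu, mix_weight = mix_weight,
                 ablation = ablation,
                 max_len_drug = as.integer(max_len_drug),
                 max_len_protein = as.integer(max_len_protein)),
            class = "model_config")
}

#' @rdname model_config
#' @param ... Overrides passed on to [model_config()].
#' @export
small_model_config <- function(...) {
  args <- utils::modifyList(
    list(emb_dim = 32L, conv_channels = 32L, heads = 4L,
         fcn_hidden = c(64L, 32L), dropout = 0.1,
         max_len_drug = 30L, max_len_protein = 134L),
    list(...))
  do.call(model_config, args)
}

#' Initialise a fragment cross-attention interaction model
#'
#' Creates the parameter set (embeddings, two conv/batch-norm/ELU stacks,
#' shared-weight attention projections, FCN head) with seeded Glorot
#' initialisation.
#'
#' @param drug_vocab,protein_vocab \code{fragment_vocab} objects.
#' @param config A [model_config()].
#' @param seed Integer seed for the initialisation RNG (local; the global
#'   RNG state is preserved).
#' @return A \code{dti_model} object.
#' @export
new_dti_model <- function(drug_vocab, protein_vocab,
                          config = model_config(), seed = 1L) {
  stopifnot(inherits(drug_vocab, "fragment_vocab"),
            inherits(protein_vocab, "fragment_vocab"))
  C <- config$conv_channels
  params <- local_rng(seed, {
    p <- list()
    p$emb_drug <- matrix(stats::rnorm(drug_vocab$size * config$emb_dim,
                                      sd = 0.1),
                         drug_vocab$size, config$emb_dim)
    p$emb_prot <- matrix(stats::rnorm(protein_vocab$size * config$emb_dim,
                                      sd = 0.1),
                         protein_vocab$size, config$emb_dim)
    for (branch in c("drug", "prot")) {
      kernels <- if (branch == "drug") config$drug_kernels else
        config$protein_kernels
      cin <- config$emb_dim
      for (j in 1:3) {
        K <- kernels[j]
        lim <- sqrt(6 / (K * cin + K * C))
        p[[sprintf("conv_%s%d_W", branch, j)]] <-
          array(stats::runif(K * cin * C, -lim, lim), c(K, cin, C))
        p[[sprintf("conv_%s%d_b", branch, j)]] <- numeric(C)
        p[[sprintf("bn_%s%d_gamma", branch, j)]] <- rep(1, C)
        p[[sprintf("bn_%s%d_beta", branch, j)]] <- numeric(C)
        cin <- C
      }
    }
    glorot <- function(nin, nout) {
      lim <- sqrt(6 / (nin + nout))
      matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
    }
    p$attn_WQ <- glorot(C, C); p$attn_WK <- glorot(C, C)
    p$attn_WV <- glorot(C, C); p$attn_W0 <- glorot(C, C)
    h1 <- config$fcn_hidden[1L]; h2 <- config$fcn_hidden[2L]
    p$fc1_W <- glorot(2L * C, h1); p$fc1_b <- numeric(h1)
    p$fc2_W <- glorot(h1, h2); p$fc2_b <- numeric(h2)
    p$fc3_W <- glorot(h2, 1L); p$fc3_b <- numeric(1L)
    p
  })
  state <- list()
  for (branch in c("drug", "prot")) {
    for (j in 1:3) {
      state[[sprintf("bn_%s%d_mean", branch, j)]] <- numeric(C)
      state[[sprintf("bn_%s%d_var", branch, j)]] <- rep(1, C)
    }
  }
  structure(list(config = config, params = params, state = state,
                 drug_vocab = drug_vocab, protein_vocab = protein_vocab),
            class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0("<dti_model> emb %d, d_CNN %d, heads %d, ablation %s\n",
                     "  drug vocab %d, protein vocab %d, %d parameters\n"),
              x$config$emb_dim, x$config$conv_channels, x$config$heads,
              x$config$ablation, x$drug_vocab$size, x$protein_vocab$size,
              n_par))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

# One CNN branch: 3 x (conv -> batchnorm -> ELU)
cnn_branch_forward <- function(params, state, config, X, branch, training) {
  kernels <- if (branch == "drug") config$drug_kernels else
    config$protein_kernels
  caches <- vector("list", 3L)
  new_state <- list()
  for (j in 1:3) {
    cv <- conv1d_forward(X, params[[sprintf("conv_%s%d_W", branch, j)]],
                         params[[sprintf("conv_%s%d_b", branch, j)]])
    bn <- bn_forward(cv$out,
                     params[[sprintf("bn_%s%d_gamma", branch, j)]],
                     params[[sprintf("bn_%s%d_beta", branch, j)]],
                     training,
                     state[[sprintf("bn_%s%d_mean", branch, j)]],
                     state[[sprintf("bn_%s%d_var", branch, j)]])
    act <- elu_forward(bn$out, config$alpha_elu)
    Y <- act$out
    caches[[j]] <- list(conv = cv, bn = bn, act = act, post = Y)
    new_state[[sprintf("bn_%s%d_mean", branch, j)]] <- bn$new_mean
    new_state[[sprintf("bn_%s%d_var", branch, j)]] <- bn$new_var
    X <- Y
  }
  list(out = X, caches = caches, new_state = new_state)
}

cnn_branch_backward <- function(params, config, dY, caches, branch) {
  grads <- list()
  for (j in 3:1) {
    ch <- caches[[j]]
    dpre <- elu_backward(dY, ch$post, ch$act, config$alpha_elu)
    bnb <- bn_backward(dpre, params[[sprintf("bn_%s%d_gamma", branch, j)]],
                       ch$bn)
    grads[[sprintf("bn_%s%d_gamma", branch, j)]] <- bnb$dgamma
    grads[[sprintf("bn_%s%d_beta", branch, j)]] <- bnb$dbeta
    cvb <- conv1d_backward(bnb$dX, params[[sprintf("conv_%s%d_W", branch, j)]],
                           ch$conv)
    grads[[sprintf("conv_%s%d_W", branch, j)]] <- cvb$dW
    grads[[sprintf("conv_%s%d_b", branch, j)]] <- cvb$db
    dY <- cvb$dX
  }
  list(dX = dY, grads = grads)
}

#' Forward pass of the interaction model
#'
#' Runs embedding, the two CNN blocks, shared-weight cross-attention (unless
#' ablated), residual mixing, max-pooling and the FCN head on a batch of
#' encoded pairs.  In evaluation mode (\code{training = FALSE}) the pass is
#' deterministic (no dropout, batch-norm running statistics).
#'
#' @param model A \code{dti_model}.
#' @param drug_ids,protein_ids Integer id matrices (rows = pairs).
#' @param training Logical; enables dropout and batch statistics.
#' @param return_cache Keep intermediate activations for [model_backward()].
#' @param return_attention Also return the attention weight arrays
#'   \code{AD} (B x L_D x L_P x heads) and \code{AP}.
#' @return List with \code{prob} (vector of interaction probabilities),
#'   \code{logits}, optionally \code{cache}, \code{attention} and the
#'   updated batch-norm \code{new_state}.
#' @export
model_forward <- function(model, drug_ids, protein_ids, training = FALSE,
                          return_cache = FALSE, return_attention = FALSE) {
  params <- model$params; config <- model$config; state <- model$state
  if (is.vector(drug_ids)) drug_ids <- matrix(drug_ids, nrow = 1L)
  if (is.vector(protein_ids)) protein_ids <- matrix(protein_ids, nrow = 1L)
  stopifnot(nrow(drug_ids) == nrow(protein_ids))

  embD <- embed_forward(params$emb_drug, drug_ids)
  embP <- embed_forward(params$emb_prot, protein_ids)
  cnnD <- cnn_branch_forward(params, state, config, embD$out, "drug", training)
  cnnP <- cnn_branch_forward(params, state, config, embP$out, "prot", training)
  DCNN <- cnnD$out; PCNN <- cnnP$out

  attn <- NULL
  if (config$ablation == "no_cross_attention") {
    Df <- DCNN; Pf <- PCNN
  } else {
    attn <- attn_forward(DCNN, PCNN, params$attn_WQ, params$attn_WK,
                         params$attn_WV, params$attn_W0, config$heads)
    Df <- residual_mix(attn$MD, DCNN, config$mix_weight, config$ablation)
    Pf <- residual_mix(attn$MP, PCNN, config$mix_weight, config$ablation)
  }

  poolD <- maxpool_forward(Df)
  poolP <- maxpool_forward(Pf)
  Fc <- cbind(poolD$out, poolP$out)

  do1 <- dropout_forward(Fc, config$dropout, training)
  fc1 <- dense_forward(do1$out, params$fc1_W, params$fc1_b)
  a1 <- leaky_relu(fc1$out)
  do2 <- dropout_forward(a1, config$dropout, training)
  fc2 <- dense_forward(do2$out, params$fc2_W, params$fc2_b)
  a2 <- leaky_relu(fc2$out)
  fc3 <- dense_forward(a2, params$fc3_W, params$fc3_b)
  logits <- as.vector(fc3$out)
  prob <- sigmoid(logits)

  out <- list(prob = prob, logits = logits,
              new_state = c(cnnD$new_state, cnnP$new_state))
  if (return_attention) {
    # stored (L_D, L_P, B, head); expose batch-first (B, L_D, L_P, head)
    out$attention <- if (is.null(attn)) NULL else
      list(AD = aperm(attn$ADs, c(3L, 1L, 2L, 4L)),
           AP = aperm(attn$APs, c(3L, 1L, 2L, 4L)))
  }
  if (return_cache) {
    out$cache <- list(embD = embD, embP = embP, cnnD = cnnD, cnnP = cnnP,
                      DCNN = DCNN, PCNN = PCNN, attn = attn,
                      poolD = poolD, poolP = poolP,
                      do1 = do1, fc1 = fc1, a1 = a1,
                      do2 = do2, fc2 = fc2, a2 = a2, fc3 = fc3,
                      C = config$conv_channels)
  }
  out
}

#' Backward pass: gradients of the mean BCE loss
#'
#' @param model A \code{dti_model}.
#' @param fwd Result of [model_forward()] with \code{return_cache = TRUE}.
#' @param labels 0/1 vector, one per pair.
#' @return Named list of gradients matching \code{model$params}.
#' @export
model_backward <- function(model, fwd, labels) {
  params <- model$params; config <- model$config; cache <- fwd$cache
  n <- length(fwd$prob)
  stopifnot(length(labels) == n)
  # combined sigmoid + BCE gradient
  dlogits <- matrix((fwd$prob - labels) / n, n, 1L)

  g3 <- dense_backward(dlogits, params$fc3_W, cache$fc3)
  da2 <- leaky_relu_backward(g3$dX, cache$fc2$out)
  g2 <- dense_backward(da2, params$fc2_W, cache$fc2)
  ddo2 <- dropout_backward(g2$dX, cache$do2)
  da1 <- leaky_relu_backward(ddo2, cache$fc1$out)
  g1 <- dense_backward(da1, params$fc1_W, cache$fc1)
  dFc <- dropout_backward(g1$dX, cache$do1)

  C <- cache$C
  dpoolD <- dFc[, seq_len(C), drop = FALSE]
  dpoolP <- dFc[, C + seq_len(C), drop = FALSE]
  dDf <- maxpool_backward(dpoolD, cache$poolD)
  dPf <- maxpool_backward(dpoolP, cache$poolP)

  grads <- list(fc3_W = g3$dW, fc3_b = g3$db,
                fc2_W = g2$dW, fc2_b = g2$db,
                fc1_W = g1$dW, fc1_b = g1$db)

  if (config$ablation == "no_cross_attention") {
    dDCNN <- dDf; dPCNN <- dPf
  } else {
    w <- if (config$ablation == "no_original_feature") 1 else
      config$mix_weight
    dMD <- w * dDf; dMP <- w * dPf
    ab <- attn_backward(dMD, dMP, params$attn_WQ, params$attn_WK,
                        params$attn_WV, params$attn_W0, cache$attn)
    grads$attn_WQ <- ab$dWQ; grads$attn_WK <- ab$dWK
    grads$attn_WV <- ab$dWV; grads$attn_W0 <- ab$dW0
    resid <- if (config$ablation == "no_original_feature") 0 else (1 - w)
    dDCNN <- ab$dD + resid * dDf
    dPCNN <- ab$dP + resid * dPf
  }

  bD <- cnn_branch_backward(params, config, dDCNN, cache$cnnD$caches, "drug")
  bP <- cnn_branch_backward(params, config, dPCNN, cache$cnnP$caches, "prot")
  grads <- c(grads, bD$grads, bP$grads)
  grads$emb_drug <- embed_backward(bD$dX, cache$embD)
  grads$emb_prot <- embed_backward(bP$dX, cache$embP)
  grads
}

# ---- public ops -------------------------------------------------------------

#' Shared-weight multihead cross-attention on a single pair
#'
#' Computes the attended feature matrices for one drug / protein feature
#' pair.  Queries for the drug come from the drug features and keys/values
#' from the protein features; the protein direction swaps the roles but uses
#' the \emph{same} projection weights.
#'
#' @param D,P Feature matrices (rows = sequence positions, cols = channels).
#' @param weights List with projection matrices \code{WQ}, \code{WK},
#'   \code{WV}, \code{W0} (all channels x channels).
#' @param h Number of heads (must divide the channel dimension).
#' @return List with \code{M_D}, \code{M_P} (attended features) and
#'   \code{A_D}, \code{A_P} (lists of per-head attention weight matrices,
#'   rows summing to 1).
#' @export
cross_attention <- function(D, P, weights, h) {
  D3 <- array(D, c(1L, nrow(D), ncol(D)))
  P3 <- array(P, c(1L, nrow(P), ncol(P)))
  out <- attn_forward(D3, P3, weights$WQ, weights$WK, weights$WV,
                      weights$W0, h)
  list(M_D = matrix(out$MD[1L, , ], nrow(D), ncol(D)),
       M_P = matrix(out$MP[1L, , ], nrow(P), ncol(P)),
       A_D = lapply(seq_len(h), function(i)
         matrix(out$ADs[, , 1L, i], nrow(D), nrow(P))),
       A_P = lapply(seq_len(h), function(i)
         matrix(out$APs[, , 1L, i], nrow(P), nrow(D))))
}

#' Residual mix of attended and original features
#'
#' \code{w * M + (1 - w) * original}; with
#' \code{ablation = "no_original_feature"} the attended features are
#' returned unchanged.
#'
#' @param M Attended feature matrix.
#' @param original Original (CNN) feature matrix of identical shape.
#' @param w Mix weight in \code{[0, 1]} (default 0.5).
#' @param ablation See [model_config()].
#' @return Matrix of the same shape.
#' @export
residual_mix <- function(M, original, w = 0.5, ablation = "full") {
  if (!identical(dim(M), dim(original))) {
    stop("shape error: residual_mix requires identical shapes")
  }
  if (ablation == "no_original_feature") return(M)
  w * M + (1 - w) * original
}

#' Binary cross-entropy loss
#'
#' Mean over samples of \code{-(y * log(p) + (1 - y) * log(1 - p))} with the
#' probabilities clamped to \code{[eps, 1 - eps]}.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels.
#' @param eps Clamp width (default 1e-7).
#' @return Scalar mean loss.
#' @examples
#' bce_loss(0.5, 1)   # log(2)
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y)) stop("invalid input: length mismatch")
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Predict interaction probabilities
#'
#' @param object A trained \code{dti_model}.
#' @param pairs data.frame with columns \code{smiles} and \code{sequence}
#'   (a \code{label} column, if present, is ignored).
#' @param ... Unused.
#' @return Numeric vector of interaction probabilities.
#' @export
predict.dti_model <- function(object, pairs, ...) {
  cfg <- object$config
  enc <- encode_dti_pairs(
    data.frame(smiles = pairs$smiles, sequence = pairs$sequence,
               label = if ("label" %in% names(pairs)) pairs$label else
                 rep(0L, nrow(pairs)),
               stringsAsFactors = FALSE),
    object$drug_vocab, object$protein_vocab,
    max_len_drug = cfg$max_len_drug, max_len_protein = cfg$max_len_protein)
  model_forward(object, enc$drug_ids, enc$protein_ids,
                training = FALSE)$prob
}

# run code under a local RNG seed, restoring the caller's RNG state
local_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
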