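#' Training configuration
#'
#' Optimisation hyperparameters.  The defaults (learning rate 1e-5, batch
#' size 64, weight decay 1e-4, dropout 0.1) are the full-scale settings;
#' desk-scale runs on the synthetic dataset use a larger learning rate
#' (see [small_train_config()]).
#'
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param weight_decay Decoupled (AdamW) weight decay applied to weight
#'   matrices (not biases or batch-norm scale/shift).
#' @param dropout FCN dropout used during training; overrides the model
#'   config when not \code{NULL}.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation AUC (epochs);
#'   set \code{>= max_epochs} to disable.
#' @param seed Integer seed controlling shuffling, dropout and
#'   initialisation order.
#' @param split_ratio Train fraction used by callers that split internally.
#' @return A \code{train_config} list.
#' @export
train_config <- function(lr = 1e-5, batch_size = 64L, weight_decay = 1e-4,
                         dropout = NULL, max_epochs = 100L, patience = 10L,
                         seed = 1L, split_ratio = 0.8) {
  stopifnot(lr > 0, batch_size >= 1L, weight_decay >= 0,
            split_ratio > 0, split_ratio < 1,
            patience <= max_epochs)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 split_ratio = split_ratio),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed on to [train_config()].
#' @export
small_train_config <- function(...) {
  args <- utils::modifyList(
    list(lr = 3e-3, batch_size = 64L, max_epochs = 50L, patience = 10L),
    list(...))
  do.call(train_config, args)
}

#' Train an interaction model on encoded pairs
#'
#' Mini-batch AdamW optimisation of the binary cross-entropy with optional
#' early stopping on validation AUC.  Fully seeded: two runs with the same
#' seed, data and configs produce identical parameters and history.
#'
#' @param model A \code{dti_model} (freshly initialised or warm).
#' @param train_data List with \code{drug_ids}, \code{protein_ids},
#'   \code{labels} as from [encode_dti_pairs()].
#' @param val_data Same structure, or \code{NULL} to disable validation and
#'   early stopping.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch to stderr.
#' @return The trained \code{dti_model} with a \code{history} data.frame
#'   attached (epoch, train_loss, and validation metrics when available).
#' @export
train_dti <- function(model, train_data, val_data = NULL,
                      config = train_config(), verbose = FALSE) {
  n <- length(train_data$labels)
  stopifnot(n >= 1L)
  if (!is.null(config$dropout)) model$config$dropout <- config$dropout

  opt <- adam_init(model$params)
  best <- list(auc = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  bad_epochs <- 0L
  hist <- list()

  local_rng(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        fwd <- model_forward(model, train_data$drug_ids[idx, , drop = FALSE],
                             train_data$protein_ids[idx, , drop = FALSE],
                             training = TRUE, return_cache = TRUE)
        loss <- bce_loss(fwd$prob, train_data$labels[idx])
        if (!is.finite(loss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d",
                       epoch))
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        grads <- model_backward(model, fwd, train_data$labels[idx])
        model$state[names(fwd$new_state)] <- fwd$new_state
        upd <- adam_step(model$params, grads, opt, config$lr,
                         config$weight_decay)
        model$params <- upd$params
        opt <- upd$opt
      }
      row <- list(epoch = epoch, train_loss = epoch_loss / n)
      if (!is.null(val_data)) {
        val_fwd <- model_forward(model, val_data$drug_ids,
                                 val_data$protein_ids, training = FALSE)
        vm <- compute_metrics(val_fwd$prob, val_data$labels)
        row$val_loss <- bce_loss(val_fwd$prob, val_data$labels)
        row$val_auc <- vm$auc
        row$val_accuracy <- vm$accuracy
        if (is.na(vm$auc) || vm$auc > best$auc) {
          best <- list(auc = if (is.na(vm$auc)) -Inf else vm$auc,
                       params = model$params, state = model$state,
                       epoch = epoch)
          bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
        }
      }
      hist[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d  train_loss %.4f%s", epoch, row$train_loss,
                        if (!is.null(row$val_auc))
                          sprintf("  val_auc %.4f", row$val_auc) else ""))
      }
      if (!is.null(val_data) && bad_epochs >= config$patience) break
    }
  })

  if (!is.null(val_data) && best$epoch > 0L) {
    model$params <- best$params
    model$state <- best$state
  }
  model$history <- do.call(rbind, lapply(hist, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  model
}

#' Fit a model from raw interaction pairs
#'
#' Convenience wrapper: carves a validation subset out of the training
#' pairs, builds the two fragment vocabularies on the remaining training
#' pairs only, encodes, initialises and trains.
#'
#' @param pairs data.frame with columns \code{smiles}, \code{sequence},
#'   \code{label}.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param val_fraction Fraction of \code{pairs} held out for early
#'   stopping (stratified; default 0.1).
#' @param verbose Passed to [train_dti()].
#' @return Trained \code{dti_model} (with vocabularies and history).
#' @export
fit_dti <- function(pairs, model_cfg = small_model_config(),
                    train_cfg = small_train_config(),
                    val_fraction = 0.1, verbose = FALSE) {
  sp <- split_dataset(pairs, ratio = 1 - val_fraction,
                      seed = train_cfg$seed + 1L)
  tr <- sp$train; va <- sp$test
  drug_vocab <- build_vocab(lapply(tr$smiles, fragment_drug))
  protein_vocab <- build_vocab(lapply(tr$sequence, fragment_protein))
  enc <- function(df) encode_dti_pairs(df, drug_vocab, protein_vocab,
                                       max_len_drug = model_cfg$max_len_drug,
                                       max_len_protein = model_cfg$max_len_protein)
  model <- new_dti_model(drug_vocab, protein_vocab, model_cfg,
                         seed = train_cfg$seed)
  train_dti(model, enc(tr), enc(va), train_cfg, verbose = verbose)
}

#' Evaluate a trained model on interaction pairs
#'
#' @param model A trained \code{dti_model}.
#' @param pairs data.frame with \code{smiles}, \code{sequence}, \code{label}.
#' @return An \code{eval_metrics} list.
#' @export
evaluate_dti <- function(model, pairs) {
  compute_metrics(predict(model, pairs), as.integer(pairs$label))
}

#' Stratified k-fold cross-validation
#'
#' Rotates each fold through the validation role exactly once, training a
#' fresh model (vocabularies rebuilt from the training folds only) each
#' time, and reports per-fold metrics plus their mean.  Emits a warning and
#' \code{NA} ranking metrics for folds missing a class.
#'
#' @param pairs data.frame with \code{smiles}, \code{sequence}, \code{label}.
#' @param folds Number of folds (default 5).
#' @param model_cfg,train_cfg Model and training configurations.
#' @param verbose Passed to [train_dti()].
#' @return List with \code{fold_metrics} (data.frame, one row per fold),
#'   \code{mean_metrics} (named numeric vector, NA folds dropped) and
#'   \code{fold_assignment}.
#' @export
cross_validate_dti <- function(pairs, folds = 5L,
                               model_cfg = small_model_config(),
                               train_cfg = small_train_config(),
                               verbose = FALSE) {
  assignment <- make_cv_folds(pairs$label, folds = folds,
                              seed = train_cfg$seed)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- pairs[assignment != f, , drop = FALSE]
    va <- pairs[assignment == f, , drop = FALSE]
    if (length(unique(va$label)) < 2L || length(unique(tr$label)) < 2L) {
      warning(sprintf("fold %d is missing a class; ranking metrics NA", f))
    }
    drug_vocab <- build_vocab(lapply(tr$smiles, fragment_drug))
    protein_vocab <- build_vocab(lapply(tr$sequence, fragment_protein))
    enc <- function(df) encode_dti_pairs(
      df, drug_vocab, protein_vocab,
      max_len_drug = model_cfg$max_len_drug,
      max_len_protein = model_cfg$max_len_protein)
    model <- new_dti_model(drug_vocab, protein_vocab, model_cfg,
                           seed = train_cfg$seed + f)
    model <- train_dti(model, enc(tr), enc(va), train_cfg, verbose = verbose)
    pr <- model_forward(model, enc(va)$drug_ids, enc(va)$protein_ids)$prob
    m <- compute_metrics(pr, va$label)
    rows[[f]] <- data.frame(fold = f, auc = m$auc, aupr = m$aupr,
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall)
  }
  fold_metrics <- do.call(rbind, rows)
  mean_metrics <- colMeans(fold_metrics[, -1L], na.rm = TRUE)
  list(fold_metrics = fold_metrics, mean_metrics = mean_metrics,
       fold_assignment = assignment)
}

# ---- AdamW ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    decay <- if (grepl("_b$|_beta$|_gamma$", nm)) 0 else
      lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step - decay
  }
  list(params = params, opt = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
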