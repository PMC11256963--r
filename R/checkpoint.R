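#' Save / load a model checkpoint as JSON
#'
#' Serialises the full model (configuration, parameters, batch-norm state,
#' both vocabularies) to a plain-text JSON file at full double precision,
#' so \code{load_checkpoint(save_checkpoint(m, f))} restores a model whose
#' eval-mode predictions are bitwise identical.
#'
#' @param model A \code{dti_model}.
#' @param path File path.
#' @return \code{save_checkpoint} returns \code{path} invisibly;
#'   \code{load_checkpoint} returns the \code{dti_model}.
#' @export
save_checkpoint <- function(model, path) {
  ser <- function(p) lapply(p, function(x)
    list(dim = dim(x) %||% length(x), data = as.vector(x)))
  obj <- list(
    format = "fcadti-checkpoint-1",
    config = unclass(model$config),
    params = ser(model$params),
    state = ser(model$state),
    drug_vocab = model$drug_vocab$tokens,
    protein_vocab = model$protein_vocab$tokens)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fcadti-checkpoint-1")) {
    stop("not an fcadti checkpoint: ", path)
  }
  deser <- function(lst) lapply(lst, function(x) {
    d <- as.integer(x$dim)
    if (length(d) > 1L) array(as.numeric(x$data), d) else as.numeric(x$data)
  })
  cfg <- obj$config
  config <- model_config(
    emb_dim = cfg$emb_dim, conv_channels = cfg$conv_channels,
    drug_kernels = cfg$drug_kernels, protein_kernels = cfg$protein_kernels,
    heads = cfg$heads, dropout = as.numeric(cfg$dropout),
    fcn_hidden = cfg$fcn_hidden,
    alpha_elu = as.numeric(cfg$alpha_elu),
    mix_weight = as.numeric(cfg$mix_weight),
    ablation = cfg$ablation, max_len_drug = cfg$max_len_drug,
    max_len_protein = cfg$max_len_protein)
  mk_vocab <- function(tokens) {
    tokens <- as.character(tokens)
    structure(list(tokens = tokens, pad_id = 0L, unk_id = 1L,
                   size = length(tokens) + 2L),
              class = "fragment_vocab")
  }
  structure(list(config = config,
                 params = deser(obj$params),
                 state = deser(obj$state),
                 drug_vocab = mk_vocab(obj$drug_vocab),
                 protein_vocab = mk_vocab(obj$protein_vocab)),
            class = "dti_model")
}
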