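#' Build a fragment vocabulary from a training corpus
#'
#' Assigns contiguous integer ids to fragment strings seen in a corpus of
#' fragment sequences.  Ids 0 and 1 are reserved for padding and unknown
#' fragments; corpus tokens with frequency >= \code{min_count} get ids from
#' 2 upwards in first-seen order, so the vocabulary is deterministic for a
#' fixed corpus order.  Build vocabularies from the training split only:
#' fragments seen only at test time then encode to the unknown id.
#'
#' @param corpus List of \code{fragment_sequence} objects (or character
#'   vectors of fragment strings).
#' @param min_count Minimum corpus frequency for a fragment to get its own
#'   id (default 1).
#' @return A \code{fragment_vocab} object with fields \code{tokens}
#'   (character vector, index = id - 1), \code{pad_id = 0}, \code{unk_id = 1}
#'   and \code{size}.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  if (length(corpus) == 0L) stop("invalid input: empty corpus")
  all_tokens <- unlist(lapply(corpus, function(x) {
    if (inherits(x, "fragment_sequence")) x$fragments$text else as.character(x)
  }), use.names = FALSE)
  if (length(all_tokens) == 0L) stop("invalid input: corpus has no fragments")
  counts <- table(factor(all_tokens, levels = unique(all_tokens)))
  keep <- names(counts)[counts >= min_count]
  structure(list(tokens = keep, pad_id = 0L, unk_id = 1L,
                 size = length(keep) + 2L),
            class = "fragment_vocab")
}

#' Encode a fragment sequence as fixed-length integer ids
#'
#' The first \code{max_len} fragments are mapped to their vocabulary ids
#' (unknown fragments to the unknown id); shorter sequences are right-padded
#' with the padding id, so the result always has length \code{max_len}.
#'
#' @param fragseq A \code{fragment_sequence} or character vector of fragments.
#' @param vocab A \code{fragment_vocab}.
#' @param max_len Output length (>= 1).
#' @return Integer vector of length \code{max_len}.
#' @export
encode_fragments <- function(fragseq, vocab, max_len) {
  stopifnot(inherits(vocab, "fragment_vocab"), max_len >= 1L)
  texts <- if (inherits(fragseq, "fragment_sequence")) {
    fragseq$fragments$text
  } else {
    as.character(fragseq)
  }
  texts <- utils::head(texts, max_len)
  ids <- match(texts, vocab$tokens) + 1L      # first corpus token gets id 2
  ids[is.na(ids)] <- vocab$unk_id
  c(ids, rep(vocab$pad_id, max_len - length(ids)))
}

#' Decode integer ids back to fragment strings
#'
#' Padding ids are dropped; the unknown id decodes to \code{"<unk>"}.
#'
#' @inheritParams encode_fragments
#' @param ids Integer vector of fragment ids.
#' @return Character vector of fragment strings.
#' @export
decode_fragments <- function(ids, vocab) {
  ids <- ids[ids != vocab$pad_id]
  out <- character(length(ids))
  out[ids == vocab$unk_id] <- "<unk>"
  known <- ids >= 2L
  out[known] <- vocab$tokens[ids[known] - 1L]
  out
}

#' @export
print.fragment_vocab <- function(x, ...) {
  cat(sprintf("<fragment_vocab> size %d (pad=0, unk=1, tokens 2..%d)\n",
              x$size, x$size - 1L))
  invisible(x)
}

#' Read / write a fragment vocabulary as JSON
#'
#' @param vocab A \code{fragment_vocab}.
#' @param path File path.
#' @return \code{read_vocab} returns the \code{fragment_vocab}.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tokens <- as.character(obj$tokens)
  structure(list(tokens = tokens, pad_id = 0L, unk_id = 1L,
                 size = length(tokens) + 2L),
            class = "fragment_vocab")
}

#' Read / write a drug-target interaction table
#'
#' Tab- or comma-separated file with header columns \code{smiles},
#' \code{sequence}, \code{label} (0/1).
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (\code{.csv} -> comma, otherwise tab).
#' @param pairs data.frame with columns \code{smiles}, \code{sequence},
#'   \code{label}.
#' @return \code{read_dti_table} returns the data.frame.
#' @export
read_dti_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "character", "integer"),
                          quote = "", comment.char = "")
  need <- c("smiles", "sequence", "label")
  if (!all(need %in% names(df))) {
    stop("invalid input: DTI table needs columns smiles, sequence, label")
  }
  if (!all(df$label %in% c(0L, 1L))) {
    stop("invalid input: labels must be 0/1")
  }
  df[, need]
}

#' @rdname read_dti_table
#' @export
write_dti_table <- function(pairs, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(pairs, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Encode a DTI table into model-ready id matrices
#'
#' Fragments every drug and protein, encodes with the two vocabularies and
#' stacks the ids into matrices (one row per pair).
#'
#' @param pairs data.frame with columns \code{smiles}, \code{sequence},
#'   \code{label}.
#' @param drug_vocab,protein_vocab \code{fragment_vocab} objects.
#' @param max_len_drug,max_len_protein Fixed encoded lengths.
#' @param patterns,k Fragmentation settings (see [fragment_drug()],
#'   [fragment_protein()]).
#' @return List with integer matrices \code{drug_ids}
#'   (n x \code{max_len_drug}), \code{protein_ids}
#'   (n x \code{max_len_protein}) and integer vector \code{labels}.
#' @export
encode_dti_pairs <- function(pairs, drug_vocab, protein_vocab,
                             max_len_drug = 100L, max_len_protein = 545L,
                             patterns = default_pattern_table(), k = 3L) {
  n <- nrow(pairs)
  drug_ids <- matrix(0L, n, max_len_drug)
  protein_ids <- matrix(0L, n, max_len_protein)
  for (i in seq_len(n)) {
    drug_ids[i, ] <- encode_fragments(
      fragment_drug(pairs$smiles[i], patterns = patterns),
      drug_vocab, max_len_drug)
    protein_ids[i, ] <- encode_fragments(
      fragment_protein(pairs$sequence[i], k = k),
      protein_vocab, max_len_protein)
  }
  list(drug_ids = drug_ids, protein_ids = protein_ids,
       labels = as.integer(pairs$label))
}
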