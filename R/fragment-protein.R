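#' Default amino-acid category table
#'
#' Maps the 20 standard amino-acid letters onto eight physicochemical
#' categories \code{A}-\code{H} used by category-fragment mining:
#' \code{A} small aliphatic (A, G, V); \code{B} large hydrophobic
#' (I, L, F, P); \code{C} polar / hydroxyl (Y, M, T, S); \code{D}
#' amide / aromatic-N (H, N, Q, W); \code{E} basic (R, K); \code{F} acidic
#' (D, E); \code{G} cysteine (C); \code{H} fallback for nonstandard letters
#' (B, J, O, U, X, Z).  The grouping is a documented, editable default
#' (persist a custom one with [write_category_table()]); it is a standard
#' 8-class scheme, not a canonical constant.
#'
#' @return Named character vector: amino-acid letter -> category letter.
#' @export
default_category_table <- function() {
  tab <- c(A = "A", G = "A", V = "A",
           I = "B", L = "B", F = "B", P = "B",
           Y = "C", M = "C", T = "C", S = "C",
           H = "D", N = "D", Q = "D", W = "D",
           R = "E", K = "E",
           D = "F", E = "F",
           C = "G",
           B = "H", J = "H", O = "H", U = "H", X = "H", Z = "H")
  tab
}

#' Map an amino-acid sequence to its category string
#'
#' @param sequence Uppercase amino-acid string (letters A-Z).
#' @param table Category table as from [default_category_table()].
#' @return String of equal length over the category alphabet \code{A}-\code{H}.
#' @examples
#' map_categories("GAVRKDE")   # "AAAEEFF"
#' @export
map_categories <- function(sequence, table = default_category_table()) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop_invalid_sequence("protein sequence must be one non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !grepl("^[A-Z]$", chars)
  if (any(bad)) {
    stop_invalid_sequence(sprintf("character '%s' at position %d is not A-Z",
                                  chars[bad][1L], which(bad)[1L]))
  }
  cats <- unname(table[chars])
  cats[is.na(cats)] <- "H"   # letters absent from a custom table
  paste(cats, collapse = "")
}

#' Partition a category string into k-grams
#'
#' Non-overlapping consecutive windows of length \code{k}; a trailing
#' remainder shorter than \code{k} is kept as a final fragment, so the
#' concatenation of the fragments reproduces the input.
#'
#' @param catseq Category string.
#' @param k Window length (default 3).
#' @param stride Step between window starts; the default \code{stride = k}
#'   gives the non-overlapping partition, smaller values give sliding
#'   windows (reconstruction then no longer holds).
#' @return Character vector of fragments.
#' @examples
#' kgram_split("AAABBBC", 3)   # "AAA" "BBB" "C"
#' @export
kgram_split <- function(catseq, k = 3L, stride = k) {
  if (!is.numeric(k) || k < 1L) stop("invalid parameter: k must be >= 1")
  if (!is.numeric(stride) || stride < 1L) stop("invalid parameter: stride must be >= 1")
  if (!nzchar(catseq)) stop_invalid_sequence("empty category string")
  n <- nchar(catseq)
  starts <- seq(1L, n, by = as.integer(stride))
  substring(catseq, starts, pmin(starts + as.integer(k) - 1L, n))
}

#' Category-fragment mining: fragment a protein sequence
#'
#' Maps the amino-acid sequence to the eight-letter category alphabet, then
#' partitions the category string into k-grams.
#'
#' @inheritParams map_categories
#' @inheritParams kgram_split
#' @param source_id Identifier stored on the returned sequence.
#' @return A \code{fragment_sequence} whose fragments all have
#'   \code{ftype = "kgram"}.
#' @examples
#' fragment_protein("GAVGAV")     # fragments "AAA" "AAA"
#' @export
fragment_protein <- function(sequence, table = default_category_table(),
                             k = 3L, stride = k, source_id = NA_character_) {
  catseq <- map_categories(sequence, table)
  frags <- kgram_split(catseq, k = k, stride = stride)
  new_fragment_sequence(source_id,
                        data.frame(text = frags,
                                   ftype = rep("kgram", length(frags)),
                                   stringsAsFactors = FALSE))
}

#' Read / write an amino-acid category table as JSON
#'
#' @param path File path.
#' @param table Named character vector (amino acid -> category).
#' @return \code{read_category_table} returns the named character vector.
#' @export
read_category_table <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(tab)
}

#' @rdname read_category_table
#' @export
write_category_table <- function(table, path) {
  jsonlite::write_json(as.list(table), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around \pkg{Biostrings}; returns plain uppercase character
#' sequences named by the first word of each record header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_protein_fasta requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  seqs
}

stop_invalid_sequence <- function(msg) {
  err <- structure(
    class = c("fcadti_invalid_sequence", "error", "condition"),
    list(message = paste0("invalid sequence: ", msg), call = NULL))
  stop(err)
}
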