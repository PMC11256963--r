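#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atomic tokens: organic-subset atoms (the
#' two-letter halogens \code{Cl} and \code{Br} are single tokens), bracket
#' atoms \code{[...]} kept whole, bond symbols, ring-closure digits
#' (including \code{\%nn} two-digit closures), and branch parentheses.
#' Concatenating the returned token texts reproduces the input exactly.
#'
#' @param smiles A single non-empty SMILES string (ASCII).
#' @return A data.frame with columns \code{text} (token string) and
#'   \code{kind} (one of \code{atom}, \code{bracket_atom}, \code{bond},
#'   \code{ring_digit}, \code{branch_open}, \code{branch_close}).
#' @examples
#' tokenize_smiles("CC(Cl)Br")
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      nchar(smiles) == 0L) {
    stop_malformed_smiles("SMILES must be one non-empty string", pos = 0L)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  texts <- character(0)
  kinds <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[[j]] != "]") {
        if (chars[[j]] == "[") {
          stop_malformed_smiles("nested '[' in bracket atom", pos = j)
        }
        j <- j + 1L
      }
      if (j > n) stop_malformed_smiles("unbalanced '['", pos = i)
      texts <- c(texts, paste(chars[i:j], collapse = ""))
      kinds <- c(kinds, "bracket_atom")
      i <- j + 1L
    } else if (ch == "]") {
      stop_malformed_smiles("unbalanced ']'", pos = i)
    } else if (ch %in% c("C", "B") && i < n &&
               ((ch == "C" && chars[[i + 1L]] == "l") ||
                (ch == "B" && chars[[i + 1L]] == "r"))) {
      texts <- c(texts, paste0(ch, chars[[i + 1L]]))
      kinds <- c(kinds, "atom")
      i <- i + 2L
    } else if (ch %in% .smiles_atom_chars) {
      texts <- c(texts, ch)
      kinds <- c(kinds, "atom")
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "/", "\\", ":", "~", ".")) {
      texts <- c(texts, ch)
      kinds <- c(kinds, "bond")
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      texts <- c(texts, ch)
      kinds <- c(kinds, "ring_digit")
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]$", chars[[i + 1L]]) ||
          !grepl("^[0-9]$", chars[[i + 2L]])) {
        stop_malformed_smiles("'%' must be followed by two digits", pos = i)
      }
      texts <- c(texts, paste(chars[i:(i + 2L)], collapse = ""))
      kinds <- c(kinds, "ring_digit")
      i <- i + 3L
    } else if (ch == "(") {
      texts <- c(texts, ch)
      kinds <- c(kinds, "branch_open")
      i <- i + 1L
    } else if (ch == ")") {
      texts <- c(texts, ch)
      kinds <- c(kinds, "branch_close")
      i <- i + 1L
    } else {
      stop_malformed_smiles(sprintf("character '%s' outside SMILES alphabet", ch),
                            pos = i)
    }
  }
  data.frame(text = texts, kind = kinds, stringsAsFactors = FALSE)
}

# single-character atoms accepted outside brackets (organic subset + aromatic)
.smiles_atom_chars <- c("B", "C", "N", "O", "P", "S", "F", "I",
                        "b", "c", "n", "o", "p", "s")

stop_malformed_smiles <- function(msg, pos) {
  err <- structure(
    class = c("fcadti_malformed_smiles", "error", "condition"),
    list(message = sprintf("malformed SMILES at position %d: %s", pos, msg),
         call = NULL, position = pos))
  stop(err)
}

#' @keywords internal
untokenize <- function(tokens) paste(tokens$text, collapse = "")
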