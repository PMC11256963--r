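#' Branch-chain mining: fragment a drug SMILES string
#'
#' Rule-based fragmentation of a SMILES string into three typed fragment
#' classes used as the drug-side input units of the interaction model:
#' \itemize{
#'   \item \emph{branch chains}: maximal outermost parenthesised spans
#'     (parentheses stripped; nested parentheses stay inside the fragment);
#'   \item \emph{common substructures}: literal matches of a pattern table
#'     (by default benzene rings, oxygen chains and carboxyl groups),
#'     scanned left-to-right and non-overlapping on the spliced main chain
#'     and on each branch chain;
#'   \item \emph{synthetic fragments}: what remains of the main chain,
#'     chunked into short runs of at most \code{max_synthetic_len} atoms.
#' }
#' A branch chain containing a common substructure is decomposed into the
#' matched fragments plus its residual spans; an unmatched branch is kept
#' whole.  Every atom token of the input ends up in exactly one fragment
#' (bond and ring-closure symbols attach to their neighbouring atom).
#'
#' @param smiles Drug SMILES string.
#' @param patterns Named list of character vectors of literal SMILES
#'   substrings, as returned by [default_pattern_table()].
#' @param max_synthetic_len Maximum number of atoms per synthetic fragment.
#' @param scan_main,scan_branches Scan the main chain / the branch chains
#'   for common substructures (both default \code{TRUE}).
#' @param positional_order If \code{TRUE}, branch fragments are interleaved
#'   at their original string position among the main-chain fragments
#'   (pattern matching then runs per main-chain segment); the default emits
#'   all main-chain fragments first, then branch fragments in positional
#'   order.
#' @param source_id Identifier stored on the returned sequence.
#' @return A \code{fragment_sequence} object: list with \code{source_id},
#'   \code{fragments} (data.frame of \code{text}, \code{ftype}) and
#'   \code{n_fragments}.
#' @examples
#' fragment_drug("CC(=O)Oc1ccccc1")
#' @export
fragment_drug <- function(smiles, patterns = default_pattern_table(),
                          max_synthetic_len = 3L,
                          scan_main = TRUE, scan_branches = TRUE,
                          positional_order = FALSE,
                          source_id = NA_character_) {
  tokens <- tokenize_smiles(smiles)
  parsed <- .split_branches(tokens)
  pats <- .compile_patterns(patterns)

  frag_branch <- function(btok) {
    # one branch chain -> common fragments + residual spans kept as
    # branch_chain fragments (never synthetic-split, so nested parentheses
    # survive intact inside a fragment)
    if (scan_branches) {
      sc <- .scan_patterns(btok, pats)
    } else {
      sc <- list(order = list(list(what = "span", tokens = btok)))
    }
    texts <- character(0)
    ftypes <- character(0)
    for (piece in sc$order) {
      if (piece$what == "match") {
        texts <- c(texts, piece$text)
        ftypes <- c(ftypes, "common_substructure")
      } else {
        texts <- c(texts, paste(piece$tokens$text, collapse = ""))
        ftypes <- c(ftypes, "branch_chain")
      }
    }
    data.frame(text = texts, ftype = ftypes, stringsAsFactors = FALSE)
  }

  frag_main_tokens <- function(mtok) {
    if (nrow(mtok) == 0L) {
      return(data.frame(text = character(0), ftype = character(0),
                        stringsAsFactors = FALSE))
    }
    if (scan_main) {
      sc <- .scan_patterns(mtok, pats)
    } else {
      sc <- list(order = list(list(what = "span", tokens = mtok)))
    }
    common <- character(0)
    residual_tokens <- list()
    for (piece in sc$order) {
      if (piece$what == "match") common <- c(common, piece$text)
      else residual_tokens <- c(residual_tokens, list(piece$tokens))
    }
    residual <- paste(vapply(residual_tokens,
                             function(tk) paste(tk$text, collapse = ""), ""),
                      collapse = "")
    synth <- if (nzchar(residual)) {
      split_synthetic_fragments(residual, max_synthetic_len)
    } else character(0)
    data.frame(
      text = c(common, synth),
      ftype = c(rep("common_substructure", length(common)),
                rep("synthetic", length(synth))),
      stringsAsFactors = FALSE)
  }

  if (!positional_order) {
    main_df <- frag_main_tokens(parsed$main_tokens)
    branch_df <- do.call(rbind, c(
      list(data.frame(text = character(0), ftype = character(0),
                      stringsAsFactors = FALSE)),
      lapply(parsed$branches, frag_branch)))
    frags <- rbind(main_df, branch_df)
  } else {
    # walk segments in original order; main-chain runs are fragmented
    # per-segment, so patterns cannot match across a branch gap
    frags <- data.frame(text = character(0), ftype = character(0),
                        stringsAsFactors = FALSE)
    for (seg in parsed$segments) {
      frags <- rbind(frags, if (seg$what == "main") {
        frag_main_tokens(seg$tokens)
      } else {
        frag_branch(seg$tokens)
      })
    }
  }
  rownames(frags) <- NULL
  stopifnot(all(nzchar(frags$text)))
  new_fragment_sequence(source_id, frags)
}

#' Extract outermost branch chains from a SMILES string
#'
#' Each maximal outermost-level parenthesised span becomes one branch-chain
#' fragment (parentheses stripped, nested parentheses kept inside); the
#' remaining tokens are spliced in order into the main chain.
#'
#' @inheritParams fragment_drug
#' @return List with \code{branch_fragments} (character vector) and
#'   \code{main_chain} (string).
#' @examples
#' extract_branch_chains("CC(C(=O)O)N")
#' @export
extract_branch_chains <- function(smiles) {
  parsed <- .split_branches(tokenize_smiles(smiles))
  list(
    branch_fragments = vapply(parsed$branches,
                              function(tk) paste(tk$text, collapse = ""), ""),
    main_chain = paste(parsed$main_tokens$text, collapse = ""))
}

#' Extract common substructures from a chain
#'
#' Left-to-right, non-overlapping, token-boundary-respecting scan of a main
#' chain or branch chain for literal pattern-table entries.  Matched spans
#' are removed; the residual is the concatenation of the unmatched spans in
#' order.
#'
#' @param chain SMILES substring (a main chain or one branch chain).
#' @inheritParams fragment_drug
#' @return List with \code{common_fragments} (character vector) and
#'   \code{residual} (string).
#' @examples
#' extract_common_substructures("c1ccccc1CCN")
#' @export
extract_common_substructures <- function(chain,
                                         patterns = default_pattern_table()) {
  if (!nzchar(chain)) return(list(common_fragments = character(0),
                                  residual = ""))
  sc <- .scan_patterns(tokenize_smiles(chain), .compile_patterns(patterns))
  common <- character(0)
  residual <- character(0)
  for (piece in sc$order) {
    if (piece$what == "match") common <- c(common, piece$text)
    else residual <- c(residual, paste(piece$tokens$text, collapse = ""))
  }
  list(common_fragments = common, residual = paste(residual, collapse = ""))
}

#' Split a residual chain into synthetic fragments
#'
#' Groups the residual into atom units (a bond symbol attaches to the
#' following atom; ring-closure digits attach to the preceding atom) and
#' chunks them into consecutive windows of at most \code{max_synthetic_len}
#' atoms, with a shorter tail.
#'
#' @param residual Residual chain (no branch parentheses).
#' @inheritParams fragment_drug
#' @return Character vector of synthetic fragment strings.
#' @examples
#' split_synthetic_fragments("CCCCC")   # "CCC" "CC"
#' @export
split_synthetic_fragments <- function(residual, max_synthetic_len = 3L) {
  stopifnot(max_synthetic_len >= 1L)
  if (!nzchar(residual)) return(character(0))
  tokens <- tokenize_smiles(residual)
  if (any(tokens$kind %in% c("branch_open", "branch_close"))) {
    stop("residual must not contain branch parentheses")
  }
  units <- .atom_units(tokens)
  if (length(units) == 0L) return(character(0))
  starts <- seq(1L, length(units), by = max_synthetic_len)
  vapply(starts, function(s) {
    paste(units[s:min(s + max_synthetic_len - 1L, length(units))],
          collapse = "")
  }, "")
}

#' Default common-substructure pattern table
#'
#' Literal SMILES substrings for the three substructure classes extracted
#' during branch-chain mining: benzene (aromatic and Kekule spellings),
#' oxygen chain, and carboxyl group.  Users can extend or replace the table
#' and persist it with [write_pattern_table()].
#'
#' @return Named list of character vectors.
#' @export
default_pattern_table <- function() {
  list(benzene = c("c1ccccc1", "C1=CC=CC=C1"),
       oxygen_chain = "COC",
       carboxyl = "C(=O)O")
}

#' Read / write a pattern table as JSON
#'
#' @param path File path.
#' @param patterns Named list of character vectors.
#' @return \code{read_pattern_table} returns the named list.
#' @export
read_pattern_table <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(tab, as.character)
}

#' @rdname read_pattern_table
#' @export
write_pattern_table <- function(patterns, path) {
  jsonlite::write_json(patterns, path, pretty = TRUE)
  invisible(path)
}

# ---- internals --------------------------------------------------------------

new_fragment_sequence <- function(source_id, fragments) {
  structure(list(source_id = source_id, fragments = fragments,
                 n_fragments = nrow(fragments)),
            class = "fragment_sequence")
}

#' @export
print.fragment_sequence <- function(x, ...) {
  cat(sprintf("<fragment_sequence> %s: %d fragments\n",
              ifelse(is.na(x$source_id), "(unnamed)", x$source_id),
              x$n_fragments))
  print(x$fragments)
  invisible(x)
}

#' @export
length.fragment_sequence <- function(x) x$n_fragments

# split token df into top-level branches and spliced main chain;
# segments preserves original left-to-right structure for positional order
.split_branches <- function(tokens) {
  n <- nrow(tokens)
  depth <- 0L
  branch_start <- NA_integer_
  main_idx <- integer(0)
  branches <- list()
  segments <- list()
  seg_main <- integer(0)
  flush_main <- function() {
    if (length(seg_main) > 0L) {
      segments[[length(segments) + 1L]] <<-
        list(what = "main", tokens = tokens[seg_main, , drop = FALSE])
      seg_main <<- integer(0)
    }
  }
  for (i in seq_len(n)) {
    kind <- tokens$kind[[i]]
    if (kind == "branch_open") {
      if (depth == 0L) branch_start <- i
      depth <- depth + 1L
    } else if (kind == "branch_close") {
      depth <- depth - 1L
      if (depth < 0L) stop_malformed_smiles("unbalanced ')'", pos = i)
      if (depth == 0L) {
        btok <- tokens[(branch_start + 1L):(i - 1L), , drop = FALSE]
        if (nrow(btok) == 0L) stop_malformed_smiles("empty branch '()'",
                                                    pos = branch_start)
        branches[[length(branches) + 1L]] <- btok
        flush_main()
        segments[[length(segments) + 1L]] <- list(what = "branch",
                                                  tokens = btok)
      }
    } else if (depth == 0L) {
      main_idx <- c(main_idx, i)
      seg_main <- c(seg_main, i)
    }
  }
  if (depth != 0L) stop_malformed_smiles("unbalanced '('", pos = branch_start)
  flush_main()
  list(main_tokens = tokens[main_idx, , drop = FALSE],
       branches = branches, segments = segments)
}

.compile_patterns <- function(patterns) {
  out <- list()
  for (nm in names(patterns)) {
    for (p in patterns[[nm]]) {
      out[[length(out) + 1L]] <- list(class = nm, text = p,
                                      tokens = tokenize_smiles(p)$text)
    }
  }
  out
}

# left-to-right non-overlapping scan at token granularity; at each position
# the first pattern in table order that matches wins.  Returns the pieces in
# original order: list of list(what = "match"/"span", ...).
.scan_patterns <- function(tokens, pats) {
  n <- nrow(tokens)
  order <- list()
  span_start <- NA_integer_
  flush_span <- function(end) {
    if (!is.na(span_start)) {
      order[[length(order) + 1L]] <<-
        list(what = "span", tokens = tokens[span_start:end, , drop = FALSE])
      span_start <<- NA_integer_
    }
  }
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (p in pats) {
      m <- length(p$tokens)
      if (i + m - 1L <= n &&
          identical(tokens$text[i:(i + m - 1L)], p$tokens)) {
        hit <- p
        break
      }
    }
    if (!is.null(hit)) {
      flush_span(i - 1L)
      order[[length(order) + 1L]] <- list(what = "match", class = hit$class,
                                          text = hit$text)
      i <- i + length(hit$tokens)
    } else {
      if (is.na(span_start)) span_start <- i
      i <- i + 1L
    }
  }
  flush_span(n)
  list(order = order)
}

# group tokens into atom units: bonds prefix the next atom, ring digits
# suffix the previous atom; dangling bonds/digits are dropped (recorded
# design decision: fragments stay locally valid substrings)
.atom_units <- function(tokens) {
  units <- character(0)
  pending <- ""
  for (i in seq_len(nrow(tokens))) {
    kind <- tokens$kind[[i]]
    text <- tokens$text[[i]]
    if (kind %in% c("atom", "bracket_atom")) {
      units <- c(units, paste0(pending, text))
      pending <- ""
    } else if (kind == "bond") {
      pending <- paste0(pending, text)
    } else if (kind == "ring_digit") {
      if (length(units) > 0L) {
        units[length(units)] <- paste0(units[length(units)], text)
      }
    }
  }
  units
}
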