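#' Planted interaction rule for synthetic data
#'
#' Describes the ground truth of the synthetic benchmark: a pair interacts
#' with probability \code{p_signal} when the drug carries the carboxyl
#' branch motif \emph{and} the protein carries the category trigram motif,
#' and with probability \code{p_noise} otherwise.  The defaults give a
#' Bayes-optimal AUC of exactly 0.95 (see [bayes_auc()]).
#'
#' @param drug_motif SMILES substring spliced into motif-positive drugs
#'   (default \code{"C(=O)O"}, a carboxyl group: exercises both the
#'   branch-chain and common-substructure fragment types).
#' @param protein_motif Amino-acid trigram spliced into motif-positive
#'   proteins (default \code{"RKD"}, whose category image \code{"EEF"}
#'   spans the basic/acidic category boundary).
#' @param p_signal,p_noise Interaction probabilities with / without both
#'   motifs; \code{0 <= p_noise < p_signal <= 1}.
#' @return A \code{planted_rule} list.
#' @export
planted_rule <- function(drug_motif = "C(=O)O", protein_motif = "RKD",
                         p_signal = 0.95, p_noise = 0.05) {
  stopifnot(p_noise >= 0, p_signal <= 1, p_noise < p_signal,
            nchar(protein_motif) >= 1L)
  structure(list(drug_motif = drug_motif, protein_motif = protein_motif,
                 p_signal = p_signal, p_noise = p_noise),
            class = "planted_rule")
}

#' Bayes-optimal AUC of a planted rule
#'
#' Closed form for the AUC of the oracle that knows motif presence: with
#' motif prevalence \code{q}, the fraction of positives that carry the
#' motif is \code{a = q p_s / (q p_s + (1-q) p_n)} and the fraction of
#' negatives that carry it is \code{b = q (1-p_s) / (q (1-p_s) +
#' (1-q)(1-p_n))}; ties between equal scores count one half, so
#' \code{AUC = a (1-b) + (a b + (1-a)(1-b)) / 2}.  No trained model can
#' beat this in expectation.
#'
#' @param rule A [planted_rule()].
#' @param prevalence Fraction of pairs carrying both motifs (default 0.5).
#' @return Scalar AUC.
#' @export
bayes_auc <- function(rule = planted_rule(), prevalence = 0.5) {
  q <- prevalence; ps <- rule$p_signal; pn <- rule$p_noise
  a <- q * ps / (q * ps + (1 - q) * pn)
  b <- q * (1 - ps) / (q * (1 - ps) + (1 - q) * (1 - pn))
  a * (1 - b) + 0.5 * (a * b + (1 - a) * (1 - b))
}

#' Generate a random SMILES string
#'
#' Random linear/branched chain over C, N, O with occasional benzene-ring
#' insertions and short parenthesised branches, 8-40 tokens long.  Branch
#' interiors never contain double bonds, so the \code{"=O"} branch fragment
#' occurs only via the planted drug motif.  Uses the current RNG stream
#' (seed with \code{set.seed} for determinism); every output tokenizes
#' without error.
#'
#' @param with_motif Splice \code{motif} at a random top-level position.
#' @param motif SMILES substring to splice (default carboxyl).
#' @return A SMILES string.
#' @export
generate_smiles <- function(with_motif = FALSE, motif = "C(=O)O") {
  target <- sample(8:40, 1L)
  atoms <- c("C", "N", "O")
  units <- sample(atoms, 1L)         # cannot start with a branch
  ntok <- 1L
  while (ntok < target) {
    r <- stats::runif(1)
    if (r < 0.15) {
      units <- c(units, "c1ccccc1")
      ntok <- ntok + 8L
    } else if (r < 0.35) {
      blen <- sample(1:3, 1L)
      br <- paste0("(", paste(sample(atoms, blen, replace = TRUE),
                              collapse = ""), ")")
      units <- c(units, br)
      ntok <- ntok + blen + 2L
    } else {
      units <- c(units, sample(atoms, 1L))
      ntok <- ntok + 1L
    }
  }
  if (with_motif) {
    pos <- sample(seq_along(units), 1L)
    units <- append(units, motif, after = pos)
  }
  paste(units, collapse = "")
}

#' Generate a random protein sequence
#'
#' Uniform draws over the 20 standard amino-acid letters, length 50-400.
#' The motif is spliced (by replacement) at a k-gram-aligned offset, so its
#' category image lands in a single k-gram fragment of the default
#' fragmenter.
#'
#' @param with_motif Splice \code{motif} in.
#' @param motif Amino-acid motif (default \code{"RKD"}).
#' @param k Alignment grid (default 3, matching [fragment_protein()]).
#' @return An amino-acid string.
#' @export
generate_protein <- function(with_motif = FALSE, motif = "RKD", k = 3L) {
  len <- sample(50:400, 1L)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")
  chars <- sample(aa, len, replace = TRUE)
  if (with_motif) {
    m <- strsplit(motif, "")[[1L]]
    n_slots <- (len - length(m)) %/% k
    start <- k * sample.int(n_slots + 1L, 1L) - k + 1L
    chars[start:(start + length(m) - 1L)] <- m
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic drug-target interaction dataset
#'
#' Each pair carries both motifs with probability 1/2; its label is drawn
#' with probability \code{p_signal} (both motifs) or \code{p_noise}
#' (otherwise).  Deterministic for a fixed seed; the caller's RNG state is
#' preserved.
#'
#' @param n Number of pairs (>= 4).
#' @param rule A [planted_rule()].
#' @param seed Integer seed.
#' @param path Optional file path; when given the table is also written as
#'   TSV (columns \code{smiles}, \code{sequence}, \code{label}).
#' @return data.frame with columns \code{smiles}, \code{sequence},
#'   \code{label} and \code{has_motif} (logical; the hidden ground truth,
#'   dropped from the written file).
#' @export
generate_dataset <- function(n, rule = planted_rule(), seed = 1L,
                             path = NULL) {
  if (n < 4L) stop("invalid input: n must be >= 4")
  df <- local_rng(seed, {
    has_motif <- stats::runif(n) < 0.5
    smiles <- character(n)
    sequence <- character(n)
    label <- integer(n)
    for (i in seq_len(n)) {
      smiles[i] <- generate_smiles(has_motif[i], rule$drug_motif)
      sequence[i] <- generate_protein(has_motif[i], rule$protein_motif)
      p <- if (has_motif[i]) rule$p_signal else rule$p_noise
      label[i] <- as.integer(stats::runif(1) < p)
    }
    data.frame(smiles = smiles, sequence = sequence, label = label,
               has_motif = has_motif, stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    write_dti_table(df[, c("smiles", "sequence", "label")], path)
  }
  df
}
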