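#' Global alignment score between two mature miRNA sequences
#'
#' End-to-end (Needleman-Wunsch) pairwise alignment with a +1/-1
#' match/mismatch substitution scheme and affine gap penalties, computed with
#' `Biostrings::pairwiseAlignment()`.  `T` is mapped to `U` before alignment;
#' characters outside A/C/G/U are rejected.
#'
#' Two affine-gap conventions circulate: under `"open-plus-extend"` (default,
#' the `pairwiseAlignment` convention) a gap of length k costs
#' `gap_open + k * gap_extend`; under `"open-includes-first"` the first gap
#' position costs `gap_open` and each further one `gap_extend`.
#'
#' @param seq_i,seq_j Non-empty nucleotide strings over A/C/G/U (or T).
#' @param match,mismatch Substitution scores (defaults +1 / -1).
#' @param gap_open,gap_extend Non-negative gap penalties (defaults 5 / 2).
#' @param gap_convention Affine-gap cost convention, see Details.
#' @return The raw alignment score (a scalar; symmetric in the sequences).
#' @export
#' @examples
#' align_score("ACGU", "ACGA") # 3 matches - 1 mismatch = 2
align_score <- function(seq_i, seq_j, match = 1, mismatch = -1,
                        gap_open = 5, gap_extend = 2,
                        gap_convention = c("open-plus-extend",
                                           "open-includes-first")) {
  gap_convention <- match.arg(gap_convention)
  if (gap_open < 0 || gap_extend < 0) abort("Gap penalties must be non-negative.")
  si <- normalize_rna(seq_i)
  sj <- normalize_rna(seq_j)
  sub <- matrix(mismatch, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                                c("A", "C", "G", "U")))
  diag(sub) <- match
  opening <- if (gap_convention == "open-plus-extend") gap_open else gap_open - gap_extend
  if (opening < 0) {
    abort("Under 'open-includes-first', gap_open must be >= gap_extend.")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(si), Biostrings::RNAString(sj),
    substitutionMatrix = sub, gapOpening = opening, gapExtension = gap_extend,
    type = "global", scoreOnly = TRUE
  )
  as.numeric(pa)
}

normalize_rna <- function(s) {
  s <- toupper(as.character(s))
  if (length(s) != 1 || is.na(s) || nchar(s) == 0) {
    abort("Sequences must be single non-empty strings.")
  }
  s <- gsub("T", "U", s, fixed = TRUE)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "U"))
  if (length(bad) > 0) {
    abort(sprintf("Non-ACGU character(s) in sequence: %s",
                  paste(bad, collapse = ", ")))
  }
  s
}

#' Min-max normalisation of a raw score matrix to \[0, 1\]
#'
#' Affinely rescales so the smallest score over all pairs (including
#' self-alignments, which then attain 1 on the diagonal) maps to 0 and the
#' largest to 1.  Invariant to positive affine transformations of the input.
#'
#' @param raw Square numeric matrix of raw alignment scores.
#' @param space,name Passed to [similarity_view()].
#' @return A [similarity_view()] with entries in \[0, 1\].
#' @export
normalize_scores <- function(raw, space = "mirna", name = "sequence") {
  if (!all(is.finite(raw))) abort("Score matrix must be finite.")
  lo <- min(raw)
  hi <- max(raw)
  if (hi == lo) abort("Degenerate score matrix: all scores identical.")
  similarity_view((raw - lo) / (hi - lo), ids = rownames(raw),
                  space = space, name = name)
}

#' Pairwise sequence-similarity view for a set of miRNAs
#'
#' All-pairs global alignment scores (see [align_score()]) min-max normalised
#' to \[0, 1\] via [normalize_scores()].
#'
#' @param seqs Named character vector of mature sequences (names = miRNA ids).
#' @inheritParams align_score
#' @return A miRNA-space [similarity_view()].
#' @export
sequence_similarity_matrix <- function(seqs, match = 1, mismatch = -1,
                                       gap_open = 5, gap_extend = 2,
                                       gap_convention = "open-plus-extend") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("`seqs` must be named with unique miRNA identifiers.")
  }
  n <- length(seqs)
  raw <- matrix(0, n, n, dimnames = list(tolower(names(seqs)),
                                         tolower(names(seqs))))
  for (i in seq_len(n)) {
    for (j in i:n) {
      raw[i, j] <- raw[j, i] <- align_score(
        seqs[[i]], seqs[[j]], match, mismatch, gap_open, gap_extend,
        gap_convention
      )
    }
  }
  normalize_scores(raw)
}
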