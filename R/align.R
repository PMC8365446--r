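# Pairwise global alignment used for anchoring queries onto the annotated
# reference. Standard protein scoring: BLOSUM62 with affine gaps (open 11,
# extend 1 per gapped residue). The DP engine is Biostrings'
# Needleman-Wunsch; this wrapper fixes the conventions and validates input.

# BLOSUM62 with X scored 0 against everything (ambiguity is tolerated but
# carries no signal).
scoring_matrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      keep <- c(AA_ALPHABET, "X")
      m <- m[keep, keep]
      m["X", ] <- 0L
      m[, "X"] <- 0L
      mat <<- m
    }
    mat
  }
})

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties: a gap of length L costs `gap_opening + L * gap_extension`.
#' `X` is tolerated and scored 0 against every residue.
#'
#' @param a,b Protein sequences (single strings over the 20-letter alphabet,
#'   `X` allowed).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return A list of class `global_alignment` with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings) and `score` (the DP optimum).
#' @examples
#' global_align("PNSP", "PNSP")$score  # sum of BLOSUM62 diagonal entries
#' @export
global_align <- function(a, b, gap_opening = 11, gap_extension = 1) {
  a <- check_protein(a, "sequence a")
  b <- check_protein(b, "sequence b")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = scoring_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  structure(list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
                 aligned_b = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa)),
            class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", "score: ", x$score, "\n", sep = "")
  invisible(x)
}

# Self-alignment score of a sequence (sum of diagonal substitution scores);
# used for the UNMAPPED score floor.
self_score <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  sum(scoring_matrix()[cbind(chars, chars)])
}
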