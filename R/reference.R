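#' Annotated reference for apical-loop anchoring
#'
#' A `reference_anchor` bundles a reference NrdJ-like protein sequence with
#' the 1-based, inclusive residue spans of the two phosphate-binding-site
#' loops: the apical loop, whose 4-5-residue motif determines whether the
#' enzyme reduces ribonucleoside diphosphates (NDP) or triphosphates (NTP),
#' and the distal loop, which is conserved across both specificities and is
#' carried as annotation only. All pairwise motif extraction maps query
#' residues into this coordinate system.
#'
#' The default reference is a synthetic 150-residue NrdJ-like backbone with
#' the triphosphate-type apical loop P-A-G-R at residues 66-69, mirroring the
#' residue numbering of the Thermus virus P74-23 enzyme in which positions
#' 67-69 (A, G, R) were mutated to switch specificity.
#'
#' @param sequence Reference protein sequence (single string).
#' @param apical_span Integer length-2 vector, 1-based inclusive span of the
#'   apical loop; its length must be 4 or 5.
#' @param distal_span Integer length-2 vector, 1-based inclusive span of the
#'   distal loop. Annotation only; must not overlap the apical span.
#' @param reference_id Identifier for the reference sequence.
#' @return An object of class `reference_anchor`.
#' @examples
#' ref <- reference_anchor()
#' substr(ref$sequence, ref$apical_span[1], ref$apical_span[2])  # "PAGR"
#' @export
reference_anchor <- function(sequence = nrdj_scaffold(),
                             apical_span = c(66L, 69L),
                             distal_span = c(96L, 103L),
                             reference_id = "synthetic_NrdJm_ref") {
  sequence <- check_protein(sequence, "reference sequence")
  n <- nchar(sequence)
  span_ok <- function(s) length(s) == 2L && all(s >= 1) && all(s <= n) && s[1] <= s[2]
  if (!span_ok(apical_span)) stop("apical_span out of range for the reference sequence")
  if (!span_ok(distal_span)) stop("distal_span out of range for the reference sequence")
  len <- apical_span[2] - apical_span[1] + 1L
  if (!len %in% c(4L, 5L)) stop("apical span must cover 4 or 5 residues")
  if (max(apical_span[1], distal_span[1]) <= min(apical_span[2], distal_span[2]))
    stop("apical and distal spans must not overlap")
  structure(
    list(reference_id = reference_id, sequence = sequence,
         apical_span = as.integer(apical_span),
         distal_span = as.integer(distal_span)),
    class = "reference_anchor")
}

#' Synthetic NrdJ-like scaffold sequence
#'
#' A fixed 150-residue backbone used by the synthetic family generator and as
#' the default [reference_anchor()] sequence. The apical loop occupies
#' residues 66-69 (P-A-G-R in the scaffold itself) inside a conserved
#' proline-context flank (residues 60-75); residues 96-103 stand in for the
#' conserved distal loop. Everything outside these blocks is unconstrained
#' background that the generator is free to mutate.
#'
#' @param motif Optional replacement apical-loop motif (4 or 5 residues).
#'   With a 5-residue motif the returned sequence is 151 residues long and
#'   all downstream coordinates shift by one.
#' @return A protein sequence string.
#' @export
nrdj_scaffold <- function(motif = NULL) {
  base <- paste0(
    "TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKN",
    "GWLPEDPAGREVLPGVEEHLVPWSTNKMSIGAPQFKSNLCSEIHQRGRMFSTTVCGGGY",
    "RCLNKACCMQCCLFLTTFDQQAFDPMYTYEYM")
  if (is.null(motif)) return(base)
  motif <- check_protein(motif, "motif")
  if (!nchar(motif) %in% c(4L, 5L)) stop("planted motif must have 4 or 5 residues")
  paste0(substr(base, 1L, 65L), motif, substr(base, 70L, nchar(base)))
}

# Residue positions of the scaffold that mutation/indel placement must leave
# intact: apical loop plus +/- 6 of conserved flank, and the distal block
# widened by 2. Returned for a given planted motif length (4 or 5).
scaffold_protected <- function(motif_len) {
  shift <- motif_len - 4L
  c(60:(69L + shift + 6L), (94:105) + shift)
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat("Reference anchor:", x$reference_id, "\n")
  cat("  length:", nchar(x$sequence), "residues\n")
  cat(sprintf("  apical loop %d-%d: %s\n", x$apical_span[1], x$apical_span[2],
              substr(x$sequence, x$apical_span[1], x$apical_span[2])))
  cat(sprintf("  distal loop %d-%d: %s\n", x$distal_span[1], x$distal_span[2],
              substr(x$sequence, x$distal_span[1], x$distal_span[2])))
  invisible(x)
}
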