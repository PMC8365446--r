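#' Extract the apical-loop motif from a query by pairwise anchoring
#'
#' Globally aligns the query to the annotated reference and extracts the
#' query residues occupying the reference apical-loop span. The loop is
#' delimited by the two anchor columns immediately flanking the span: every
#' query residue strictly between them belongs to the motif. Delimiting by
#' the flanks rather than by the span columns themselves makes the
#' extraction robust to gap sliding — the optimal affine-gap alignment of a
#' 5-residue P-Q-G-S-P loop onto a 4-residue P-A-G-R span can park the
#' insertion gap at the span boundary, and the inserted residue must still
#' count as loop. If a flanking anchor is itself deleted in the query, the
#' extraction falls back to the residues aligned to the span columns plus
#' insertions strictly inside the span. Coverage is flagged `FULL` when every span column receives
#' a query residue, `PARTIAL` when any span column aligns to a gap, and
#' `UNMAPPED` (empty motif) when the alignment score falls below
#' `score_floor` times the reference self-alignment score — the query is
#' then judged too diverged for the coordinate transfer to mean anything.
#'
#' @param query Query protein sequence (single string).
#' @param ref A [reference_anchor()].
#' @param query_id Identifier recorded in the output.
#' @param gap_opening,gap_extension Affine gap penalties (see
#'   [global_align()]).
#' @param score_floor Fraction of the reference self-score below which the
#'   query is reported `UNMAPPED`.
#' @return A one-row `data.frame` (a "motif call") with columns `query_id`,
#'   `motif`, `start`, `end` (1-based query coordinates, `NA` if unmapped),
#'   `score`, `flag`.
#' @export
extract_motif_pairwise <- function(query, ref, query_id = "query",
                                   gap_opening = 11, gap_extension = 1,
                                   score_floor = 0.25) {
  stopifnot(inherits(ref, "reference_anchor"))
  aln <- global_align(ref$sequence, query,
                      gap_opening = gap_opening, gap_extension = gap_extension)
  floor_score <- score_floor * self_score(ref$sequence)
  if (aln$score < floor_score)
    return(motif_call(query_id, "", NA_integer_, NA_integer_, aln$score, "UNMAPPED"))

  rc <- strsplit(aln$aligned_a, "")[[1]]
  qc <- strsplit(aln$aligned_b, "")[[1]]
  span <- ref$apical_span
  n_ref <- nchar(ref$sequence)

  # per alignment column: reference position consumed (0 = insertion) and
  # query position consumed (0 = deletion)
  ref_pos <- cumsum(rc != "-") * (rc != "-")
  query_pos <- cumsum(qc != "-") * (qc != "-")

  # query positions aligned to the anchor columns that flank the loop span;
  # everything strictly between them is the loop, which keeps the extraction
  # stable when the optimal alignment slides an in-loop insertion gap to the
  # span boundary (the way a 5-residue P-Q-G-S-P loop aligns onto P-A-G-R)
  anchor_q <- function(p) {
    i <- which(ref_pos == p)
    if (length(i) == 1L && qc[i] != "-") query_pos[i] else NA_integer_
  }
  qa <- if (span[1] > 1L) anchor_q(span[1] - 1L) else 0L
  qb <- if (span[2] < n_ref) anchor_q(span[2] + 1L) else max(query_pos) + 1L

  span_cols <- which(ref_pos >= span[1] & ref_pos <= span[2])
  partial <- any(qc[span_cols] == "-")

  if (!is.na(qa) && !is.na(qb) && qb > qa) {
    qpos <- seq_len(nchar(query))
    qpos <- qpos[qpos > qa & qpos < qb]
  } else {
    # flank anchor lost to a gap: fall back to the residues aligned to the
    # span columns plus insertions strictly inside them
    keep <- (ref_pos >= span[1] & ref_pos <= span[2]) |
      (ref_pos == 0 & cummax(ref_pos) >= span[1] & cummax(ref_pos) < span[2])
    qpos <- query_pos[keep & qc != "-"]
  }
  motif <- if (length(qpos))
    paste(strsplit(toupper(query), "")[[1]][qpos], collapse = "") else ""
  flag <- if (partial || length(qpos) == 0) "PARTIAL" else "FULL"
  motif_call(query_id, motif,
             if (length(qpos)) min(qpos) else NA_integer_,
             if (length(qpos)) max(qpos) else NA_integer_,
             aln$score, flag)
}

#' Extract apical-loop motifs for a set of query sequences
#'
#' Vectorised front end to [extract_motif_pairwise()].
#'
#' @param queries Named character vector of protein sequences (or an
#'   `AAStringSet`).
#' @inheritParams extract_motif_pairwise
#' @return A `data.frame` of motif calls, one row per query, in input order.
#' @export
extract_motifs <- function(queries, ref, gap_opening = 11, gap_extension = 1,
                           score_floor = 0.25) {
  if (methods::is(queries, "AAStringSet"))
    queries <- stats::setNames(as.character(queries), names(queries))
  if (is.null(names(queries)))
    names(queries) <- sprintf("query_%04d", seq_along(queries))
  out <- lapply(seq_along(queries), function(i)
    extract_motif_pairwise(queries[[i]], ref, query_id = names(queries)[i],
                           gap_opening = gap_opening,
                           gap_extension = gap_extension,
                           score_floor = score_floor))
  do.call(rbind, out)
}

#' Extract motifs from designated columns of a multiple sequence alignment
#'
#' When an MSA with known apical-loop columns is available (the situation of
#' a curated alignment with a marked phosphate-binding-motif selection), the
#' motif is read directly from those columns: per sequence, the characters
#' at the designated columns with gaps removed. A sequence gapped at any
#' designated column is flagged `PARTIAL`; one gapped at all of them yields
#' an empty motif.
#'
#' @param msa Named character vector of aligned sequences (equal lengths,
#'   `-` for gaps), or an `AAStringSet`, or a path to an aligned FASTA file.
#' @param apical_columns Integer vector of 1-based alignment column indices
#'   (need not be contiguous).
#' @return A `data.frame` of motif calls with `start`/`end` in ungapped
#'   sequence coordinates.
#' @export
extract_motif_msa <- function(msa, apical_columns) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- read_fasta(msa)
  if (methods::is(msa, "AAStringSet"))
    msa <- stats::setNames(as.character(msa), names(msa))
  if (length(msa) == 0) stop("empty alignment")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(widths), collapse = "-"), ")")
  if (any(apical_columns < 1) || any(apical_columns > widths[1]))
    stop("apical_columns out of range 1..", widths[1])
  if (is.null(names(msa)))
    names(msa) <- sprintf("seq_%04d", seq_along(msa))

  out <- lapply(seq_along(msa), function(i) {
    chars <- strsplit(msa[[i]], "")[[1]]
    sel <- chars[apical_columns]
    gap <- sel %in% c("-", ".")
    motif <- paste(sel[!gap], collapse = "")
    # ungapped coordinate of each designated column
    ungapped <- cumsum(!chars %in% c("-", "."))
    pos <- ungapped[apical_columns][!gap]
    motif_call(names(msa)[i], motif,
               if (length(pos)) min(pos) else NA_integer_,
               if (length(pos)) max(pos) else NA_integer_,
               NA_real_,
               if (any(gap)) "PARTIAL" else "FULL")
  })
  do.call(rbind, out)
}

motif_call <- function(query_id, motif, start, end, score, flag) {
  data.frame(query_id = query_id, motif = motif,
             start = as.integer(start), end = as.integer(end),
             score = score, flag = flag)
}

#' Write motif calls to CSV
#' @param calls Motif-call `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}
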