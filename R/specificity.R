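#' The motif lexicon mapping apical-loop motifs to phosphate specificity
#'
#' The lexicon is a small, versioned table shipped with the package rather
#' than hard-coded: each row is a regular-expression pattern over the motif
#' string together with the specificity label it implies. The default
#' lexicon covers the experimentally calibrated NrdJ motifs:
#' \itemize{
#'   \item `[P/F]-N-S-P` — diphosphate (NDP) reducers; positions 2-4 are
#'     fully conserved, position 1 admits phenylalanine;
#'   \item `P-[A/S/G]-G-R` — triphosphate (NTP) reducers;
#'   \item `P-S-M-R` — NTP (methionine variant);
#'   \item `P-[Q/A]-G-S-P` — NTP (five-residue variant).
#' }
#' Anything else — including the engineered-but-inactive P-A-G-S variant,
#' which carries no specificity evidence — classifies as `UNKNOWN`.
#'
#' @param path Optional path to a lexicon CSV with columns `pattern_id`,
#'   `pattern`, `label`; defaults to the shipped lexicon.
#' @return A `data.frame` with columns `pattern_id`, `pattern`, `label`
#'   (and free-text `note` if present). Row order is match priority.
#' @export
motif_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motif_lexicon.csv", package = "rnrspec",
                        mustWork = TRUE)
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pattern_id", "pattern", "label")
  if (!all(need %in% names(lex)))
    stop("lexicon must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(lex$label), c("NDP", "NTP"))
  if (length(bad) > 0)
    stop("lexicon labels must be NDP or NTP; found: ", paste(bad, collapse = ", "))
  lex
}

#' Classify apical-loop motifs into phosphate-specificity labels
#'
#' Matches each motif (case-insensitively) against the lexicon patterns in
#' priority order; the first matching pattern determines the label. Motifs
#' matching nothing — including the empty motif — are `UNKNOWN`.
#' Classification is a pure function of the motif string.
#'
#' @param motif Character vector of motif strings.
#' @param lexicon A lexicon table from [motif_lexicon()].
#' @return A `data.frame` with columns `motif`, `label`
#'   (`NDP`/`NTP`/`UNKNOWN`), `pattern` (matched `pattern_id`, `NA` for
#'   `UNKNOWN`), one row per input motif.
#' @examples
#' classify_motif(c("PNSP", "FNSP", "PSGR", "PQGSP", "PAGS"))
#' @export
classify_motif <- function(motif, lexicon = motif_lexicon()) {
  motif <- toupper(as.character(motif))
  label <- rep("UNKNOWN", length(motif))
  pattern <- rep(NA_character_, length(motif))
  open <- rep(TRUE, length(motif))
  for (i in seq_len(nrow(lexicon))) {
    hit <- open & grepl(lexicon$pattern[i], motif)
    label[hit] <- lexicon$label[i]
    pattern[hit] <- lexicon$pattern_id[i]
    open <- open & !hit
  }
  data.frame(motif = motif, label = label, pattern = pattern)
}

#' Classify a table of motif calls
#'
#' Joins [classify_motif()] onto a motif-call table from [extract_motifs()]
#' or [extract_motif_msa()]. Calls that are not `FULL` (partially covered or
#' unmapped queries) are labelled `UNKNOWN` regardless of their residual
#' motif string, since the extraction itself is not trusted.
#'
#' @param calls Motif-call `data.frame` (columns `query_id`, `motif`,
#'   `flag`).
#' @param lexicon A lexicon table from [motif_lexicon()].
#' @return `calls` with `label` and `pattern` columns appended.
#' @export
classify_calls <- function(calls, lexicon = motif_lexicon()) {
  stopifnot(all(c("query_id", "motif", "flag") %in% names(calls)))
  cl <- classify_motif(calls$motif, lexicon)
  cl$label[calls$flag != "FULL"] <- "UNKNOWN"
  cl$pattern[calls$flag != "FULL"] <- NA_character_
  cbind(calls, cl[, c("label", "pattern")])
}

#' Census of motif patterns and specificity labels over a sequence set
#'
#' Tabulates, over a set of motif calls (or bare motif strings), how many
#' sequences match each lexicon pattern and what fraction of the set falls
#' to each specificity label. This is the summary behind statements of the
#' form "x% of sequences carry the diphosphate motif".
#'
#' @param motifs A motif-call `data.frame`, a classified-call table, or a
#'   character vector of motif strings. Non-`FULL` calls count as `UNKNOWN`.
#' @param lexicon A lexicon table from [motif_lexicon()].
#' @return An object of class `motif_census`: list with `total`,
#'   `per_pattern_counts` (named integer, lexicon patterns only),
#'   `per_label_counts` and `per_label_fractions` (over `NDP`, `NTP`,
#'   `UNKNOWN`; fractions sum to 1).
#' @export
census <- function(motifs, lexicon = motif_lexicon()) {
  if (is.data.frame(motifs)) {
    cl <- if (all(c("label", "pattern") %in% names(motifs))) motifs
          else classify_calls(motifs, lexicon)
  } else {
    cl <- classify_motif(motifs, lexicon)
  }
  total <- nrow(cl)
  labels <- c("NDP", "NTP", "UNKNOWN")
  if (total == 0) {
    return(structure(list(total = 0L,
                          per_pattern_counts = integer(0),
                          per_label_counts = stats::setNames(integer(3), labels),
                          per_label_fractions = stats::setNames(numeric(3), labels)),
                     class = "motif_census"))
  }
  pat <- factor(cl$pattern, levels = lexicon$pattern_id)
  lab <- factor(cl$label, levels = labels)
  structure(list(total = total,
                 per_pattern_counts = table(pat) |> as.integer() |>
                   stats::setNames(lexicon$pattern_id),
                 per_label_counts = table(lab) |> as.integer() |>
                   stats::setNames(labels),
                 per_label_fractions = (table(lab) / total) |> as.numeric() |>
                   stats::setNames(labels)),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("Motif census over", x$total, "sequences\n")
  if (x$total > 0) {
    for (p in names(x$per_pattern_counts))
      cat(sprintf("  %-7s %6d (%5.1f%%)\n", p, x$per_pattern_counts[[p]],
                  100 * x$per_pattern_counts[[p]] / x$total))
    for (l in names(x$per_label_fractions))
      cat(sprintf("  label %-8s %5.1f%%\n", l, 100 * x$per_label_fractions[[l]]))
  }
  invisible(x)
}
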