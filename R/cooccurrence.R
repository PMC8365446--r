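#' Categorise a genome by the specificities of its NrdJ copies
#'
#' A genome's NrdJ complement is reduced to one of five categories.
#' `UNKNOWN` labels are dropped first (an unclassifiable copy is missing
#' evidence, not evidence of a class): with fewer than two classified copies
#' remaining the genome is `SINGLE` (or `UNDETERMINED` when every copy was
#' unclassifiable); with two or more, it is `MIXED` when both NDP and NTP
#' predictions co-occur, otherwise `NTP_ONLY` or `NDP_ONLY`.
#'
#' @param labels Character vector of specificity labels (`NDP`, `NTP`,
#'   `UNKNOWN`) for one genome's NrdJ copies; must be non-empty. Identical
#'   duplicate copies count separately (gene occurrences, not unique
#'   sequences).
#' @return A single category string.
#' @examples
#' categorize_genome(c("NDP", "NTP"))            # "MIXED"
#' categorize_genome(c("NTP", "NTP", "UNKNOWN")) # "NTP_ONLY"
#' @export
categorize_genome <- function(labels) {
  if (length(labels) == 0) stop("genome has no NrdJ labels")
  bad <- setdiff(unique(labels), c("NDP", "NTP", "UNKNOWN"))
  if (length(bad) > 0)
    stop("unrecognised label(s): ", paste(bad, collapse = ", "))
  known <- labels[labels != "UNKNOWN"]
  if (length(known) == 0) return("UNDETERMINED")
  if (length(known) == 1) return("SINGLE")
  has_ndp <- "NDP" %in% known
  has_ntp <- "NTP" %in% known
  if (has_ndp && has_ntp) "MIXED" else if (has_ntp) "NTP_ONLY" else "NDP_ONLY"
}

#' Summarise NrdJ specificity co-occurrence across genomes
#'
#' Counts, over all genomes, how many carry two or more classified NrdJ
#' copies and how those multi-copy genomes split between mixed and
#' single-specificity complements. The headline number is the percentage of
#' multi-copy genomes whose copies differ in predicted phosphate
#' specificity.
#'
#' @param genomes Either a `data.frame` with columns `genome_id` and `label`
#'   (one row per NrdJ copy), or a named list of per-genome label vectors.
#' @return An object of class `cooccurrence_summary`: list with
#'   `n_genomes_total`, `n_multi`, `n_mixed`, `n_ntp_only`, `n_ndp_only`,
#'   `n_single`, `n_undetermined`, `pct_mixed` (full precision, `NA` when no
#'   multi-copy genomes) and `per_genome` (`data.frame` of categories).
#' @examples
#' g <- data.frame(genome_id = c("g1", "g1", "g2", "g2", "g3"),
#'                 label = c("NDP", "NTP", "NTP", "NTP", "NDP"))
#' summarize_cooccurrence(g)
#' @export
summarize_cooccurrence <- function(genomes) {
  if (is.data.frame(genomes)) {
    stopifnot(all(c("genome_id", "label") %in% names(genomes)))
    genomes <- split(genomes$label, genomes$genome_id)
  }
  n_total <- length(genomes)
  cats <- vapply(genomes, categorize_genome, character(1))
  cnt <- function(x) sum(cats == x)
  n_mixed <- cnt("MIXED"); n_ntp <- cnt("NTP_ONLY"); n_ndp <- cnt("NDP_ONLY")
  n_multi <- n_mixed + n_ntp + n_ndp
  structure(list(
    n_genomes_total = n_total,
    n_multi = n_multi,
    n_mixed = n_mixed,
    n_ntp_only = n_ntp,
    n_ndp_only = n_ndp,
    n_single = cnt("SINGLE"),
    n_undetermined = cnt("UNDETERMINED"),
    pct_mixed = if (n_multi > 0) 100 * n_mixed / n_multi else NA_real_,
    per_genome = data.frame(genome_id = names(cats), category = unname(cats))),
    class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("NrdJ co-occurrence over", x$n_genomes_total, "genomes\n")
  cat("  multi-copy (>=2 classified NrdJ):", x$n_multi, "\n")
  cat(sprintf("    mixed specificity: %d (%s%%)\n", x$n_mixed,
              if (is.na(x$pct_mixed)) "-" else round(x$pct_mixed)))
  cat("    NTP only:", x$n_ntp_only, " NDP only:", x$n_ndp_only, "\n")
  cat("  single-copy:", x$n_single, " undetermined:", x$n_undetermined, "\n")
  invisible(x)
}

#' JSON-ready form of a co-occurrence summary
#'
#' @param x A `cooccurrence_summary`.
#' @param path Optional JSON output path.
#' @param digits Rounding for the headline percentage (`NULL` = full
#'   precision).
#' @return A plain list (invisibly written to `path` if given).
#' @export
cooccurrence_json <- function(x, path = NULL, digits = NULL) {
  out <- x[c("n_genomes_total", "n_multi", "n_mixed", "n_ntp_only",
             "n_ndp_only", "n_single", "n_undetermined", "pct_mixed")]
  if (!is.null(digits) && !is.na(out$pct_mixed))
    out$pct_mixed_rounded <- round(out$pct_mixed, digits)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
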