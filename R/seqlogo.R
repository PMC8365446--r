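#' Per-column residue frequencies of an alignment
#'
#' Observed amino-acid probabilities at one alignment column. Gaps are
#' excluded from the denominator (they lower occupancy, they are not a 21st
#' symbol); an optional pseudocount is added uniformly to all 20 residues:
#' `p_r = (n_r + pc) / (N + 20 pc)`.
#'
#' @param msa Named character vector of aligned sequences (equal length) or
#'   an `AAStringSet`.
#' @param column 1-based column index.
#' @param pseudocount Non-negative uniform pseudocount (default 0).
#' @return Named numeric vector of length 20 summing to 1, plus attribute
#'   `occupancy` (non-gap fraction of the column).
#' @export
column_frequencies <- function(msa, column, pseudocount = 0) {
  if (methods::is(msa, "AAStringSet")) msa <- as.character(msa)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("ragged alignment")
  if (column < 1 || column > widths[1]) stop("column out of range")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  chars <- toupper(substr(msa, column, column))
  gap <- chars %in% c("-", ".")
  res <- chars[!gap]
  res <- res[res %in% AA_ALPHABET]
  n <- length(res)
  if (n == 0 && pseudocount == 0)
    stop("all-gap column ", column, " with zero pseudocount")
  counts <- table(factor(res, levels = AA_ALPHABET))
  p <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
  structure(stats::setNames(p, AA_ALPHABET),
            occupancy = length(res) / length(chars))
}

#' Information content of a residue distribution
#'
#' Shannon information of an alignment column in bits:
#' `IC = log2(20) - H(p)` with `H` the Shannon entropy, clipped at 0. A
#' fully conserved column scores `log2(20) ~ 4.322` bits, a uniform column
#' 0 bits.
#'
#' @param p Probability vector over the 20 residues (must sum to 1).
#' @param small_sample_n Optional number of observed sequences; if given,
#'   the standard small-sample correction `(20 - 1) / (2 ln(2) n)` is
#'   subtracted.
#' @return Information content in bits.
#' @export
information_content <- function(p, small_sample_n = NULL) {
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- p[p > 0]
  h <- -sum(nz * log2(nz))
  ic <- log2(20) - h
  if (!is.null(small_sample_n))
    ic <- ic - (20 - 1) / (2 * log(2) * small_sample_n)
  max(ic, 0)
}

#' Build a sequence-logo matrix for designated alignment columns
#'
#' Computes, for each designated column of the (sub)alignment, the residue
#' frequencies, occupancy, information content and letter heights. Letter
#' heights follow the WebLogo convention scaled by occupancy:
#' `height_r = p_r * IC * occupancy`, so heights in a column sum to
#' `IC * occupancy` and gappy columns shrink.
#'
#' @param msa Named character vector of aligned sequences or `AAStringSet`
#'   (e.g. the subset of an alignment carrying one motif class).
#' @param columns Integer vector of 1-based column indices (default: all).
#' @param pseudocount Uniform pseudocount passed to [column_frequencies()].
#' @param small_sample Apply the small-sample correction using the per-
#'   column occupancy count (default off; class subsets are usually large).
#' @return An object of class `logo_matrix`: list with `columns`,
#'   `frequencies` (20 x ncol matrix), `heights` (20 x ncol matrix, bits),
#'   `ic` and `occupancy` (per-column vectors).
#' @export
build_logo <- function(msa, columns = NULL, pseudocount = 0,
                       small_sample = FALSE) {
  if (methods::is(msa, "AAStringSet")) msa <- as.character(msa)
  if (length(msa) == 0) stop("empty alignment subset")
  if (is.null(columns)) columns <- seq_len(nchar(msa[[1]]))
  freqs <- matrix(0, nrow = 20, ncol = length(columns),
                  dimnames = list(AA_ALPHABET, columns))
  ic <- numeric(length(columns))
  occ <- numeric(length(columns))
  for (j in seq_along(columns)) {
    p <- column_frequencies(msa, columns[j], pseudocount)
    occ[j] <- attr(p, "occupancy")
    freqs[, j] <- p
    ic[j] <- information_content(p,
      small_sample_n = if (small_sample) max(1, round(occ[j] * length(msa))) else NULL)
  }
  heights <- sweep(freqs, 2, ic * occ, `*`)
  structure(list(columns = columns, frequencies = freqs, heights = heights,
                 ic = ic, occupancy = occ, n_sequences = length(msa)),
            class = "logo_matrix")
}

#' Build one logo per specificity class
#'
#' Splits an alignment by per-sequence specificity label (from
#' [classify_calls()]) and builds a [build_logo()] matrix for each class
#' present, mirroring the per-motif-class logos used to display apical-loop
#' conservation.
#'
#' @param msa Named character vector of aligned sequences.
#' @param labels Named character vector or classified-call `data.frame`
#'   mapping sequence names to labels.
#' @param columns Columns passed to [build_logo()].
#' @param ... Further arguments to [build_logo()].
#' @return Named list of `logo_matrix` objects, one per label with >= 1
#'   sequence.
#' @export
logo_by_class <- function(msa, labels, columns = NULL, ...) {
  if (methods::is(msa, "AAStringSet")) msa <- as.character(msa)
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$query_id)
  labels <- labels[names(msa)]
  lapply(split(names(msa), labels), function(ids)
    build_logo(msa[ids], columns, ...))
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("Logo matrix over", x$n_sequences, "sequences,",
      length(x$columns), "columns\n")
  top <- apply(x$frequencies, 2, function(p) AA_ALPHABET[which.max(p)])
  cat("  consensus:", paste(top, collapse = ""), "\n")
  cat("  IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Serialise a logo matrix to a data frame / CSV
#'
#' @param logo A `logo_matrix`.
#' @param path Optional CSV output path.
#' @return Long-format `data.frame` with `column`, `residue`, `frequency`,
#'   `height_bits`, `ic_bits`, `occupancy`.
#' @export
logo_table <- function(logo, path = NULL) {
  df <- data.frame(
    column = rep(logo$columns, each = 20),
    residue = rep(AA_ALPHABET, times = length(logo$columns)),
    frequency = as.vector(logo$frequencies),
    height_bits = as.vector(logo$heights),
    ic_bits = rep(logo$ic, each = 20),
    occupancy = rep(logo$occupancy, each = 20))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
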