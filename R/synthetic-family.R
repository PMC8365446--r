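#' Specification for a synthetic motif-planted protein family
#'
#' Describes a family of NrdJ-like sequences in which each member carries a
#' known apical-loop motif planted at a recorded position on the common
#' scaffold (see [nrdj_scaffold()]), with background substitution and indel
#' noise applied outside the loop regions. Because the generator records the
#' planted motif of every sequence, downstream anchoring and classification
#' can be scored against exact ground truth.
#'
#' @param n_sequences Number of sequences (>= 1).
#' @param motif_fractions Named numeric vector mapping motif strings (4 or 5
#'   residues) to their fractions in the family; must sum to 1. Counts are
#'   apportioned deterministically (largest remainder), so at `sub_rate = 0`
#'   a census of the family recovers the fractions exactly.
#' @param background_length Scaffold length in residues (>= 110; the default
#'   150 is the full scaffold).
#' @param substitution_rate Per-site substitution probability outside the
#'   protected loop blocks, in `[0, 1]`.
#' @param indel_rate Per-site probability of a single-residue insertion or
#'   deletion (equally likely) outside the protected blocks.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_sequences,
                        motif_fractions = c(PNSP = 0.44, PAGR = 0.522,
                                            PSMR = 0.021, PQGSP = 0.017),
                        background_length = 150L,
                        substitution_rate = 0.1,
                        indel_rate = 0.01,
                        seed = 1L) {
  if (!is.numeric(n_sequences) || n_sequences < 1)
    stop("n_sequences must be >= 1")
  check_prob_map(motif_fractions, "motif_fractions")
  for (m in names(motif_fractions)) {
    check_protein(m, paste0("motif '", m, "'"))
    if (!nchar(m) %in% c(4L, 5L))
      stop("motif '", m, "' must have 4 or 5 residues")
  }
  if (background_length < 110)
    stop("background_length must be >= 110 to contain the loop blocks")
  check_fraction(substitution_rate, "substitution_rate")
  check_fraction(indel_rate, "indel_rate")
  structure(list(n_sequences = as.integer(n_sequences),
                 motif_fractions = motif_fractions,
                 background_length = as.integer(background_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic NrdJ-like protein family with planted motifs
#'
#' Each sequence is the scaffold with its assigned apical-loop motif planted
#' at scaffold positions 66 onward, then mutated: substitutions and
#' single-residue indels are drawn per site, but never inside the apical or
#' distal loop blocks (including a flanking margin), so the planted motif and
#' its ground-truth coordinates stay well defined.
#'
#' @param spec A [family_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{sequences}{Named character vector of protein sequences.}
#'     \item{truth}{`data.frame` with columns `seq_id`, `motif`, `start`,
#'       `end` — the planted motif and its 1-based span in each (possibly
#'       indel-shifted) sequence.}
#'   }
#' @examples
#' fam <- generate_family(family_spec(10, c(PNSP = 0.5, PAGR = 0.5),
#'                                    substitution_rate = 0, seed = 7))
#' table(fam$truth$motif)
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  counts <- allocate_counts(spec$n_sequences, spec$motif_fractions)
  motifs <- rep(names(counts), counts)
  ids <- sprintf("seq_%04d", seq_len(spec$n_sequences))

  base <- nrdj_scaffold()
  if (spec$background_length < nchar(base))
    base <- substr(base, 1L, spec$background_length)
  else if (spec$background_length > nchar(base))
    base <- paste0(base, substr(strrep(base, ceiling(spec$background_length / nchar(base))),
                                1L, spec$background_length - nchar(base)))

  with_seed(spec$seed, {
    seqs <- character(spec$n_sequences)
    start <- integer(spec$n_sequences)
    end <- integer(spec$n_sequences)
    for (i in seq_len(spec$n_sequences)) {
      r <- plant_and_mutate(base, motifs[i], spec$substitution_rate, spec$indel_rate)
      seqs[i] <- r$sequence
      start[i] <- r$start
      end[i] <- r$end
    }
  })
  names(seqs) <- ids
  list(sequences = seqs,
       truth = data.frame(seq_id = ids, motif = motifs,
                          start = start, end = end))
}

# Plant `motif` at scaffold positions 66.., then apply per-site substitutions
# and indels outside the protected loop blocks. Returns the mutated sequence
# and the realised 1-based motif span.
plant_and_mutate <- function(base, motif, sub_rate, indel_rate) {
  mlen <- nchar(motif)
  chars <- strsplit(paste0(substr(base, 1L, 65L), motif,
                           substr(base, 70L, nchar(base))), "")[[1]]
  n <- length(chars)
  protected <- scaffold_protected(mlen)
  protected <- protected[protected <= n]
  free <- setdiff(seq_len(n), protected)

  if (sub_rate > 0 && length(free) > 0) {
    hit <- free[runif(length(free)) < sub_rate]
    for (i in hit) chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  }

  motif_start <- 66L
  if (indel_rate > 0 && length(free) > 0) {
    u <- runif(length(free))
    del <- free[u < indel_rate / 2]
    ins <- free[u >= indel_rate / 2 & u < indel_rate]
    pieces <- as.list(chars)
    for (i in del) pieces[[i]] <- character(0)
    if (length(ins) > 0) {
      new_res <- sample(AA_ALPHABET, length(ins), replace = TRUE)
      for (k in seq_along(ins)) {
        i <- ins[k]
        pieces[[i]] <- c(new_res[k], pieces[[i]])
      }
    }
    before <- sum(lengths(pieces[seq_len(motif_start - 1L)]))
    chars <- unlist(pieces)
    motif_start <- before + 1L
  }
  list(sequence = paste(chars, collapse = ""),
       start = motif_start, end = motif_start + mlen - 1L)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of protein sequences (or an
#'   `AAStringSet`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (plain or aligned; gaps are preserved).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
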