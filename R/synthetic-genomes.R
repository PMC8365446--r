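#' Specification for synthetic multi-copy NrdJ genomes
#'
#' Describes a collection of genomes, each carrying one or more NrdJ copies
#' whose apical-loop motifs are chosen according to a per-genome specificity
#' category: `MIXED` genomes carry at least one diphosphate-type (P-N-S-P)
#' and one triphosphate-type (P-A-G-R) copy, `NTP_ONLY` and `NDP_ONLY`
#' genomes carry a single specificity. Emulates a genome-database screen in
#' which multi-copy genomes are categorised by the co-occurring predicted
#' specificities of their NrdJ genes.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param copy_number_distribution Named numeric vector mapping copy number
#'   (as names, e.g. `"1"`, `"2"`) to probability; must sum to 1, copy
#'   numbers >= 1.
#' @param specificity_mix Named numeric vector over categories `MIXED`,
#'   `NTP_ONLY`, `NDP_ONLY` giving their probabilities among multi-copy
#'   genomes; must sum to 1.
#' @param substitution_rate Background substitution rate applied when copy
#'   sequences are materialised.
#' @param seed Integer seed.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_genomes,
                        copy_number_distribution = c(`1` = 0.5, `2` = 0.35, `3` = 0.15),
                        specificity_mix = c(MIXED = 0.686, NTP_ONLY = 0.102,
                                            NDP_ONLY = 0.212),
                        substitution_rate = 0.05,
                        seed = 1L) {
  if (!is.numeric(n_genomes) || n_genomes < 1) stop("n_genomes must be >= 1")
  check_prob_map(copy_number_distribution, "copy_number_distribution")
  ks <- suppressWarnings(as.integer(names(copy_number_distribution)))
  if (any(is.na(ks)) || any(ks < 1))
    stop("copy_number_distribution names must be integer copy numbers >= 1")
  check_prob_map(specificity_mix, "specificity_mix")
  if (!setequal(names(specificity_mix), c("MIXED", "NTP_ONLY", "NDP_ONLY")))
    stop("specificity_mix must cover exactly MIXED, NTP_ONLY, NDP_ONLY")
  check_fraction(substitution_rate, "substitution_rate")
  structure(list(n_genomes = as.integer(n_genomes),
                 copy_number_distribution = copy_number_distribution,
                 specificity_mix = specificity_mix,
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate synthetic genomes with known NrdJ specificity categories
#'
#' In the default deterministic mode, copy numbers and multi-copy categories
#' are apportioned by largest remainder, so the realised category counts
#' match the spec's probabilities exactly (up to rounding) and do not depend
#' on the seed — only sequence content does. In `mode = "sample"` both are
#' drawn at random.
#'
#' Motif assignment per category is fixed: `NDP_ONLY` copies carry P-N-S-P,
#' `NTP_ONLY` copies carry P-A-G-R, and `MIXED` genomes carry one P-N-S-P
#' copy with the remainder P-A-G-R. Single-copy genomes alternate between
#' the two motifs.
#'
#' @param spec A [genome_spec()].
#' @param mode `"deterministic"` (exact counts) or `"sample"`.
#' @param emit_sequences Materialise mutated protein sequences for every
#'   copy (`TRUE`), or return motif assignments only (`FALSE`; much faster
#'   for large screens where only the category arithmetic is needed).
#' @return A list with components:
#'   \describe{
#'     \item{copies}{`data.frame` with `genome_id`, `copy_id`, `motif`, and
#'       (if requested) `sequence`.}
#'     \item{truth}{`data.frame` with `genome_id`, `n_copies`, `category`
#'       (`SINGLE` for single-copy genomes).}
#'   }
#' @export
generate_genomes <- function(spec, mode = c("deterministic", "sample"),
                             emit_sequences = TRUE) {
  stopifnot(inherits(spec, "genome_spec"))
  mode <- match.arg(mode)
  n <- spec$n_genomes
  ks <- as.integer(names(spec$copy_number_distribution))

  with_seed(spec$seed, {
    if (mode == "deterministic") {
      kc <- allocate_counts(n, spec$copy_number_distribution)
      copy_n <- rep(ks, kc)
    } else {
      copy_n <- ks[sample.int(length(ks), n, replace = TRUE,
                              prob = spec$copy_number_distribution)]
    }
    multi <- which(copy_n >= 2)
    category <- rep("SINGLE", n)
    if (length(multi) > 0) {
      if (mode == "deterministic") {
        cc <- allocate_counts(length(multi), spec$specificity_mix)
        category[multi] <- rep(names(cc), cc)
      } else {
        category[multi] <- sample(names(spec$specificity_mix), length(multi),
                                  replace = TRUE, prob = spec$specificity_mix)
      }
    }

    ids <- sprintf("genome_%05d", seq_len(n))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- copy_n[i]
      motifs <- switch(category[i],
        SINGLE = if (i %% 2 == 0) "PNSP" else "PAGR",
        MIXED = c("PNSP", rep("PAGR", k - 1L)),
        NTP_ONLY = rep("PAGR", k),
        NDP_ONLY = rep("PNSP", k))
      rows[[i]] <- data.frame(genome_id = ids[i],
                              copy_id = sprintf("%s_nrdJ_%d", ids[i], seq_len(k)),
                              motif = motifs)
    }
    copies <- do.call(rbind, rows)
    if (emit_sequences) {
      base <- nrdj_scaffold()
      copies$sequence <- vapply(copies$motif, function(m)
        plant_and_mutate(base, m, spec$substitution_rate, 0)$sequence, character(1))
    }
  })
  list(copies = copies,
       truth = data.frame(genome_id = sprintf("genome_%05d", seq_len(n)),
                          n_copies = copy_n, category = category))
}
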