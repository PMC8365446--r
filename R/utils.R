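# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user RNG flow.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Largest-remainder apportionment of `n` items to `fractions` (which must sum
# to 1). Deterministic: ties broken by listing order. Guarantees sum == n.
allocate_counts <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# Validate a probability map (named numeric, sums to 1).
check_prob_map <- function(p, what) {
  if (length(p) == 0 || is.null(names(p)) || any(!nzchar(names(p))))
    stop(what, " must be a named numeric vector")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(what, " probabilities must be non-negative and sum to 1")
  invisible(p)
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single value in [0, 1]")
  invisible(x)
}

# Validate a protein sequence; X is tolerated. Errors name the offending
# position so malformed FASTA records are easy to locate.
check_protein <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " must be a non-empty character string")
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% c(AA_ALPHABET, "X"))
  if (length(bad) > 0)
    stop(what, ": illegal character '", chars[bad[1]], "' at position ", bad[1])
  invisible(toupper(seq))
}

md5_of <- function(paths) unname(tools::md5sum(paths))
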