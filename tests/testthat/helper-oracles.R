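# Independent oracles used to check the package's computations.

# BLOSUM62 with X zeroed, matching the package's documented scoring.
oracle_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mm <- e$BLOSUM62
      keep <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
      mm <- mm[keep, keep]
      mm["X", ] <- 0L; mm[, "X"] <- 0L
      m <<- mm
    }
    m
  }
})

# Enumerate every global alignment of a and b as pairs of gapped strings.
enumerate_alignments <- function(a, b) {
  if (nchar(a) == 0 && nchar(b) == 0) return(list(c("", "")))
  out <- list()
  if (nchar(a) > 0 && nchar(b) > 0) {
    for (al in enumerate_alignments(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))))
      out <- c(out, list(c(paste0(substr(a, 1, 1), al[1]),
                           paste0(substr(b, 1, 1), al[2]))))
  }
  if (nchar(a) > 0) {
    for (al in enumerate_alignments(substr(a, 2, nchar(a)), b))
      out <- c(out, list(c(paste0(substr(a, 1, 1), al[1]), paste0("-", al[2]))))
  }
  if (nchar(b) > 0) {
    for (al in enumerate_alignments(a, substr(b, 2, nchar(b))))
      out <- c(out, list(c(paste0("-", al[1]), paste0(substr(b, 1, 1), al[2]))))
  }
  out
}

# Score one gapped alignment under affine gaps: a run of L gaps costs
# open + L * ext (the package's convention).
score_alignment <- function(aligned_a, aligned_b, open = 11, ext = 1) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  m <- oracle_matrix()
  s <- 0
  for (i in seq_along(ca))
    if (ca[i] != "-" && cb[i] != "-") s <- s + m[ca[i], cb[i]]
  gap_cost <- function(x) {
    r <- rle(x == "-")
    runs <- r$lengths[r$values]
    sum(open + ext * runs)
  }
  s - gap_cost(ca) - gap_cost(cb)
}

# Brute-force optimal global alignment score.
oracle_align_score <- function(a, b, open = 11, ext = 1) {
  max(vapply(enumerate_alignments(a, b),
             function(al) score_alignment(al[1], al[2], open, ext), numeric(1)))
}

# Brute-force small parsimony: minimum changes over all internal labelings.
oracle_fitch <- function(tree, states) {
  states <- states[!is.na(states) & states != "UNKNOWN"]
  keep <- intersect(tree$tip.label, names(states))
  if (length(keep) < length(tree$tip.label)) tree <- ape::keep.tip(tree, keep)
  states <- states[tree$tip.label]
  alph <- unique(unname(states))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  node_state <- function(assign_int, v)
    if (v <= n_tip) states[[tree$tip.label[v]]] else assign_int[v - n_tip]
  best <- Inf
  grid <- expand.grid(rep(list(alph), n_int), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    assign_int <- as.character(grid[r, ])
    ch <- sum(vapply(seq_len(nrow(tree$edge)), function(e)
      node_state(assign_int, tree$edge[e, 1]) !=
        node_state(assign_int, tree$edge[e, 2]), logical(1)))
    best <- min(best, ch)
  }
  best
}

# All strings of length 1..max_len over an alphabet.
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (len in seq_len(max_len)) {
    g <- expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE)
    out <- c(out, apply(g, 1, paste, collapse = ""))
  }
  out
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
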