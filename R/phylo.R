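#' Parse a Newick string or file into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]: checks parenthesis
#' balance (reporting the offending character position), rejects duplicate
#' tip labels, and allows polytomies.
#'
#' @param text A Newick string, or `NULL` when `file` is given.
#' @param file Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced '(': ", depth, " unclosed at end of input")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("not a parseable Newick tree")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0)
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  tree
}

# Drop tips whose state is missing/ignored; validate that every named state
# refers to a real tip. Returns list(tree, states) on the pruned tree.
prune_to_states <- function(tree, states, ignore_states) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("states must be a named vector (tip label -> state)")
  unknown_tip <- setdiff(names(states), tree$tip.label)
  if (length(unknown_tip) > 0)
    stop("state given for tip(s) not in tree: ",
         paste(unknown_tip, collapse = ", "))
  states <- states[tree$tip.label[tree$tip.label %in% names(states)]]
  keep <- names(states)[!is.na(states) & !states %in% ignore_states]
  if (length(keep) < 2)
    stop("fewer than 2 tips carry a non-ignored state")
  if (length(keep) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, keep)
  list(tree = tree, states = states[tree$tip.label])
}

#' Minimum number of character-state changes on a tree (Fitch parsimony)
#'
#' Computes the small-parsimony minimum number of state changes required to
#' explain the tip states on the given topology. Tips whose state is in
#' `ignore_states` (by default `UNKNOWN`, i.e. unclassifiable motifs) are
#' treated as missing and pruned, not as a third character state. Polytomies
#' are handled exactly via a unit-cost dynamic programme over the observed
#' state alphabet, and the count is invariant to root placement. A count of
#' 1 for a binary character is the parsimony signature of a single
#' evolutionary origin of the derived state.
#'
#' @param tree A `phylo` object (rooted or unrooted; polytomies allowed).
#' @param states Named character vector mapping tip labels to states.
#' @param ignore_states States treated as missing data.
#' @return Integer: the minimum number of changes.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' fitch_count(tr, c(A = "0", B = "0", C = "1", D = "1"))  # 1
#' @export
fitch_count <- function(tree, states, ignore_states = "UNKNOWN") {
  pr <- prune_to_states(tree, states, ignore_states)
  tree <- pr$tree; states <- pr$states
  alph <- unique(unname(states))
  if (length(alph) == 1L) return(0L)

  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ns <- length(alph)
  # cost[v, s] = min changes in the subtree below v given state s at v
  cost <- matrix(Inf, nrow = n_node, ncol = ns)
  tip_state <- match(states[tree$tip.label], alph)
  cost[cbind(seq_len(n_tip), tip_state)] <- 0
  inner <- unique(tree$edge[, 1])
  for (v in inner) cost[v, ] <- 0
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    trans <- vapply(seq_len(ns), function(s)
      min(cost[child, ] + (seq_len(ns) != s)), numeric(1))
    cost[parent, ] <- cost[parent, ] + trans
  }
  root <- tree$edge[nrow(tree$edge), 1]
  as.integer(min(cost[root, ]))
}

#' Test whether the tips carrying a state form a monophyletic group
#'
#' Monophyly is assessed in the unrooted sense: the state's tips are
#' monophyletic if some edge bipartition of the tree separates exactly those
#' tips from all others. Tips with ignored states are pruned first. Also
#' returns the smallest clade (bipartition side) containing all tips of the
#' state, which is the witnessing clade when the test succeeds.
#'
#' @inheritParams fitch_count
#' @param state The focal state (e.g. `"NDP"`).
#' @return A list with `monophyletic` (logical), `tips` (tips carrying the
#'   state), and `clade` (tip labels of the smallest bipartition side
#'   containing them).
#' @export
is_monophyletic <- function(tree, states, state, ignore_states = "UNKNOWN") {
  pr <- prune_to_states(tree, states, ignore_states)
  tree <- pr$tree; states <- pr$states
  focal <- names(states)[states == state]
  if (length(focal) == 0) stop("state '", state, "' absent from the tree tips")
  all_tips <- tree$tip.label
  if (length(focal) %in% c(1L, length(all_tips)))
    return(list(monophyletic = TRUE, tips = focal,
                clade = if (length(focal) == 1L) focal else all_tips))

  sides <- bipartition_sides(tree)
  containing <- Filter(function(s) all(focal %in% s), sides)
  smallest <- containing[[which.min(lengths(containing))]]
  list(monophyletic = setequal(smallest, focal),
       tips = focal, clade = sort(smallest))
}

# All bipartition sides of the tree: for every edge, the tip set below the
# child node and its complement. Includes trivial (single-tip) sides.
bipartition_sides <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  tree <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  sides <- below[tree$edge[, 2]]
  c(sides, lapply(sides, function(s) setdiff(tree$tip.label, s)))
}

#' Summarise motif-state structure on a phylogeny
#'
#' Convenience report combining [fitch_count()] and per-state
#' [is_monophyletic()] over all non-ignored states.
#'
#' @inheritParams fitch_count
#' @return A list with `n_tips_used`, `states_present`, `changes`,
#'   `monophyletic_states`, and `witness_clades`.
#' @export
phylo_state_report <- function(tree, states, ignore_states = "UNKNOWN") {
  pr <- prune_to_states(tree, states, ignore_states)
  present <- sort(unique(unname(pr$states)))
  mono <- lapply(present, function(s)
    is_monophyletic(tree, states, s, ignore_states))
  names(mono) <- present
  list(n_tips_used = length(pr$tree$tip.label),
       states_present = present,
       changes = fitch_count(tree, states, ignore_states),
       monophyletic_states = present[vapply(mono, `[[`, logical(1), "monophyletic")],
       witness_clades = lapply(mono, `[[`, "clade"))
}
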