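test_that("newick parsing validates structure and labels", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(length(tr$tip.label), 4)
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("(A,B));"), "position 6")
  expect_error(parse_newick("((A,A),(C,D));"), "duplicate")
})

test_that("newick round-trips preserve topology", {
  set.seed(3)
  for (i in 1:10) {
    tr <- ape::rtree(sample(5:15, 1))
    back <- parse_newick(ape::write.tree(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back))[1], 0)
  }
})

test_that("fitch_count reproduces hand-checked small cases", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_count(tr, c(A = "0", B = "0", C = "0", D = "0")), 0L)
  expect_equal(fitch_count(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  tr2 <- parse_newick("((A,C),(B,D));")
  expect_equal(fitch_count(tr2, c(A = "0", C = "1", B = "0", D = "1")), 2L)
})

test_that("fitch_count equals exhaustive enumeration on small trees", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    # a third of the cases get a polytomy by collapsing an internal edge
    if (i %% 3 == 0 && tr$Nnode > 2) tr <- ape::di2multi(tr, tol = 2)
    k <- sample(2:3, 1)
    states <- setNames(sample(as.character(seq_len(k)), n, replace = TRUE),
                       tr$tip.label)
    if (length(unique(states)) < 2) next
    expect_equal(fitch_count(tr, states), oracle_fitch(tr, states),
                 info = paste("case", i))
  }
})

test_that("fitch_count agrees with phangorn on binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(c("NDP", "NTP"), n, replace = TRUE),
                       tr$tip.label)
    if (length(unique(states)) < 2) next
    pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("NDP", "NTP"))
    expect_equal(fitch_count(tr, states),
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("fitch_count is invariant under rerooting", {
  set.seed(31)
  tr <- ape::rtree(20)
  states <- setNames(sample(c("NDP", "NTP"), 20, replace = TRUE), tr$tip.label)
  base <- fitch_count(tr, states)
  for (tip in sample(tr$tip.label, 5)) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_count(rerooted, states), base)
  }
  expect_equal(fitch_count(ape::unroot(tr), states), base)
})

test_that("fitch_count is bounded by the rarer state's tip count", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(c("NDP", "NTP"), n, replace = TRUE), tr$tip.label)
    if (length(unique(states)) < 2) next
    fc <- fitch_count(tr, states)
    expect_gte(fc, 1L)
    expect_lte(fc, min(table(states)))
  }
})

test_that("UNKNOWN tips are treated as missing, not a third state", {
  tr <- parse_newick("((A,B),(C,(D,E)));")
  states <- c(A = "NDP", B = "NDP", C = "UNKNOWN", D = "NTP", E = "NTP")
  expect_equal(fitch_count(tr, states), 1L)
  expect_error(fitch_count(tr, c(A = "UNKNOWN", B = "UNKNOWN", C = "UNKNOWN",
                                 D = "UNKNOWN", E = "UNKNOWN")),
               "fewer than 2")
  expect_error(fitch_count(tr, c(Z = "NDP", A = "NTP", B = "NTP")), "not in tree")
})

test_that("monophyly follows the unrooted bipartition definition", {
  tr <- parse_newick("((A,C),(B,D));")
  states <- c(A = "x", B = "x", C = "y", D = "y")
  res <- is_monophyletic(tr, states, "x")
  expect_false(res$monophyletic)
  expect_setequal(res$tips, c("A", "B"))

  tr2 <- parse_newick("((A,B),(C,D));")
  res2 <- is_monophyletic(tr2, states, "x")
  expect_true(res2$monophyletic)
  expect_setequal(res2$clade, c("A", "B"))
  # single-tip and all-tip states are trivially monophyletic
  expect_true(is_monophyletic(tr2, c(A = "z", B = "x", C = "x", D = "x"),
                              "z")$monophyletic)
  expect_error(is_monophyletic(tr2, states, "w"), "absent")
})

test_that("binary character: count 1 iff a state's tips are monophyletic", {
  set.seed(53)
  for (i in 1:200) {
    n <- sample(5:14, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(c("NDP", "NTP"), n, replace = TRUE), tr$tip.label)
    if (length(unique(states)) < 2) next
    fc <- fitch_count(tr, states)
    mono <- is_monophyletic(tr, states, "NDP")$monophyletic
    expect_equal(fc == 1L, mono, info = paste("case", i))
  }
})

test_that("phylo_state_report combines counts and monophyly", {
  ts <- generate_tree_states(tree_scenario(24, "SINGLE_ORIGIN", seed = 8))
  rpt <- phylo_state_report(ts$tree, ts$states)
  expect_equal(rpt$changes, 1L)
  expect_setequal(rpt$monophyletic_states, c("NDP", "NTP"))
  expect_setequal(rpt$witness_clades$NDP,
                  names(ts$states)[ts$states == "NDP"])
})
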