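test_that("column frequencies follow observed counts and pseudocounts", {
  msa <- c(a = "P", b = "P", c = "P")
  p <- column_frequencies(msa, 1)
  expect_equal(p[["P"]], 1)
  expect_equal(attr(p, "occupancy"), 1)

  msa2 <- c(a = "P", b = "P", c = "S", d = "S")
  p2 <- column_frequencies(msa2, 1)
  expect_equal(p2[["P"]], 0.5)
  expect_equal(p2[["S"]], 0.5)

  # pseudocount 1 on {P:3}: P gets (3+1)/(3+20), the rest 1/23
  p3 <- column_frequencies(c(a = "P", b = "P", c = "P"), 1, pseudocount = 1)
  expect_equal(p3[["P"]], 4 / 23)
  expect_equal(p3[["A"]], 1 / 23)
  expect_equal(sum(p3), 1)
})

test_that("gaps lower occupancy and an all-gap column needs a pseudocount", {
  msa <- c(a = "P-", b = "--", c = "P-", d = "--")
  p <- column_frequencies(msa, 1)
  expect_equal(attr(p, "occupancy"), 0.5)
  expect_equal(p[["P"]], 1)
  expect_error(column_frequencies(msa, 2), "all-gap")
  p2 <- column_frequencies(msa, 2, pseudocount = 1)
  expect_equal(as.numeric(p2), rep(1 / 20, 20))
})

test_that("information content matches closed forms", {
  one <- c(1, rep(0, 19))
  expect_equal(information_content(one), log2(20), tolerance = 1e-12)
  expect_equal(information_content(one), 4.3219, tolerance = 1e-4)
  expect_equal(information_content(rep(1 / 20, 20)), 0)
  expect_equal(information_content(c(0.5, 0.5, rep(0, 18))),
               log2(20) - 1, tolerance = 1e-12)
  # clipped at zero when the correction overshoots
  expect_equal(information_content(rep(1 / 20, 20), small_sample_n = 5), 0)
})

test_that("IC is bounded and grows as mass concentrates", {
  ics <- sapply(seq(0.05, 1, by = 0.05), function(w) {
    p <- c(w, rep((1 - w) / 19, 19))
    information_content(p)
  })
  expect_true(all(ics >= 0 & ics <= log2(20) + 1e-12))
  expect_true(all(diff(ics) > -1e-12))
})

test_that("logo of identical motif rows is full-height single letters", {
  msa <- setNames(rep("PNSP", 58), paste0("s", 1:58))
  logo <- build_logo(msa)
  expect_equal(logo$ic, rep(log2(20), 4), tolerance = 1e-12)
  expect_equal(logo$occupancy, rep(1, 4))
  expect_equal(unname(logo$heights["N", 2]), log2(20), tolerance = 1e-12)
  expect_equal(unname(colSums(logo$heights)), logo$ic * logo$occupancy)
})

test_that("logo heights match analytic values for planted frequencies", {
  # column 1: P/S at 0.5 each -> IC = log2(20) - 1, heights split evenly
  msa <- c(a = "PA", b = "PA", c = "SA", d = "SA")
  logo <- build_logo(msa)
  expect_equal(logo$ic[1], log2(20) - 1, tolerance = 1e-12)
  expect_equal(unname(logo$heights["P", 1]), (log2(20) - 1) / 2,
               tolerance = 1e-12)
  expect_equal(logo$ic[2], log2(20), tolerance = 1e-12)
})

test_that("logos are invariant to row order and heights are non-negative", {
  set.seed(5)
  msa <- setNames(replicate(30, random_protein(6)), paste0("s", 1:30))
  l1 <- build_logo(msa)
  l2 <- build_logo(rev(msa))
  expect_equal(l1$heights, l2$heights)
  expect_true(all(l1$heights >= 0))
  expect_equal(unname(colSums(l1$heights)), l1$ic * l1$occupancy)
})

test_that("per-class logos split the alignment by specificity label", {
  msa <- c(s1 = "PNSP", s2 = "PNSP", s3 = "PAGR", s4 = "PSGR")
  labels <- c(s1 = "NDP", s2 = "NDP", s3 = "NTP", s4 = "NTP")
  logos <- logo_by_class(msa, labels)
  expect_setequal(names(logos), c("NDP", "NTP"))
  expect_equal(logos$NDP$n_sequences, 2)
  expect_equal(unname(logos$NDP$frequencies["N", 2]), 1)
  expect_equal(unname(logos$NTP$frequencies["G", 3]), 1)
  tab <- logo_table(logos$NTP)
  expect_equal(nrow(tab), 80)
  expect_equal(sum(tab$height_bits), sum(logos$NTP$ic * logos$NTP$occupancy),
               tolerance = 1e-12)
})
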