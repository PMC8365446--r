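ref <- reference_anchor()

test_that("reference anchor validates its spans", {
  expect_equal(substr(ref$sequence, ref$apical_span[1], ref$apical_span[2]),
               "PAGR")
  expect_error(reference_anchor(apical_span = c(66, 72)), "4 or 5")
  expect_error(reference_anchor(apical_span = c(140, 160)), "out of range")
  expect_error(reference_anchor(apical_span = c(96, 99),
                                distal_span = c(98, 105)), "overlap")
})

test_that("pairwise anchoring extracts the loop for reference-like queries", {
  self <- extract_motif_pairwise(ref$sequence, ref)
  expect_equal(self$motif, "PAGR")
  expect_equal(self$flag, "FULL")
  expect_equal(c(self$start, self$end), c(66L, 69L))

  swapped <- extract_motif_pairwise(nrdj_scaffold("PNSP"), ref)
  expect_equal(swapped$motif, "PNSP")
  expect_equal(swapped$flag, "FULL")

  # a 5-residue loop maps onto the 4-residue reference span via an in-span
  # insertion and must come back whole
  ins <- extract_motif_pairwise(nrdj_scaffold("PQGSP"), ref)
  expect_equal(ins$motif, "PQGSP")
  expect_equal(ins$flag, "FULL")
  expect_equal(c(ins$start, ins$end), c(66L, 70L))
})

test_that("queries below the score floor are UNMAPPED with empty motif", {
  junk <- strrep("A", 150)
  call <- extract_motif_pairwise(junk, ref)
  expect_equal(call$flag, "UNMAPPED")
  expect_equal(call$motif, "")
  expect_true(is.na(call$start))
})

test_that("MSA column extraction reads designated columns, gaps removed", {
  msa <- c(s1 = "GG-PNSP-KL", s2 = "GGAPAGR-KL", s3 = "GG------KL")
  calls <- extract_motif_msa(msa, 4:7)
  expect_equal(calls$motif, c("PNSP", "PAGR", ""))
  expect_equal(calls$flag, c("FULL", "FULL", "PARTIAL"))
  # ungapped coordinates: s1 has a gap at column 3, so the loop starts at 3
  expect_equal(calls$start[1], 3L)
  expect_equal(calls$start[2], 4L)

  expect_error(extract_motif_msa(c(a = "PNSP", b = "PNSPA"), 1:4), "ragged")
  expect_error(extract_motif_msa(msa, 9:12), "out of range")
})

test_that("a sequence gapped at one designated column is PARTIAL", {
  msa <- c(s1 = "PN-P", s2 = "PNSP")
  calls <- extract_motif_msa(msa, 1:4)
  expect_equal(calls$flag, c("PARTIAL", "FULL"))
  expect_equal(calls$motif, c("PNP", "PNSP"))
})

test_that("zero-indel families round-trip through MSA column extraction", {
  fam <- generate_family(family_spec(
    40, c(PNSP = 0.5, PAGR = 0.5), substitution_rate = 0.1,
    indel_rate = 0, seed = 3))
  # without indels the family is already aligned; loop columns are 66-69
  calls <- extract_motif_msa(fam$sequences, 66:69)
  expect_equal(calls$motif, fam$truth$motif)
  expect_true(all(calls$flag == "FULL"))
})

test_that("pairwise extraction recovers planted motifs at default noise", {
  fam <- generate_family(family_spec(200, seed = 17))
  calls <- extract_motifs(fam$sequences, ref)
  expect_gte(mean(calls$motif == fam$truth$motif), 0.99)
  ok <- calls$flag == "FULL"
  expect_true(all(calls$start[ok] == fam$truth$start[ok]))
})

test_that("extraction is idempotent and independent of record order", {
  fam <- generate_family(family_spec(30, seed = 9))
  fwd <- extract_motifs(fam$sequences, ref)
  rev_calls <- extract_motifs(rev(fam$sequences), ref)
  reordered <- rev_calls[match(fwd$query_id, rev_calls$query_id), ]
  rownames(reordered) <- NULL
  expect_equal(reordered, fwd)
  expect_equal(extract_motifs(fam$sequences, ref), fwd)
})
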