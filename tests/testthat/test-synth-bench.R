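test_that("background generation is seeded and composition-faithful", {
  a <- generateBackground(220, 200, seed = 3)
  expect_length(a, 220L)
  expect_true(all(nchar(a) == 200L))
  b <- generateBackground(220, 200, seed = 3)
  expect_identical(a, b)

  onlyA <- stats::setNames(c(1, rep(0, 19)),
                           c("A", setdiff(aminoAcidAlphabet(), "A")))
  degenerate <- generateBackground(3, 50, composition = onlyA, seed = 1)
  expect_true(all(degenerate == strrep("A", 50)))
  expect_error(generateBackground(0, 10), "n must be")
  expect_error(generateBackground(2, 10, composition = c(A = 0.5)), "sum to 1")
})

test_that("implantation writes the designed motif at the recorded interval", {
  pos <- generateBackground(219, 200, seed = 5, prefix = "p")
  spec <- implantSpec("hydrophobicCharged", trueRatio = 0.4)
  imp <- implantMotifs(pos, spec, seed = 6)
  truth <- imp$truth
  expect_equal(sum(truth$implanted), 88L)       # round(0.4 * 219)
  impl <- truth[truth$implanted, ]
  expect_true(all(impl$end - impl$start + 1L == 20L))
  expect_true(all(impl$end <= 100L))
  # ground truth round-trips: the anchor sits 9 residues into each implant
  for (k in seq_len(nrow(impl))) {
    s <- imp$sequences[[impl$id[k]]]
    expect_identical(substring(s, impl$start[k] + 9L, impl$start[k] + 10L),
                     "AA")
    flank <- substring(s, impl$start[k], impl$start[k] + 8L)
    expect_false(grepl(sprintf("[^%s]",
                               paste(spec@flankAlphabet, collapse = "")),
                       flank))
  }
  # sequence lengths are unchanged by substitution
  expect_true(all(nchar(imp$sequences) == 200L))
  # non-implanted sequences are untouched
  expect_identical(imp$sequences[!truth$implanted], pos[!truth$implanted])

  expect_error(implantMotifs(pos[1:4], implantSpec(trueRatio = 0.1)),
               "below 1")
  expect_error(implantMotifs(c(x = "SHORT"), implantSpec("hydrophobic")),
               "position range")
})

test_that("full-purity implants put the designed anchor at full support", {
  toy <- makeToyImplant(nPos = 20, nNeg = 20, len = 120, seed = 71)
  tab <- enumerateAnchors(toy$pos, toy$neg, n = 2, minSupport = 0.3)
  expect_equal(tab$posFreq[tab$label == "AA"], 1)
  # and the implanted anchor ranks first
  expect_equal(anchorLiteral(rankAnchors(tab, 1)[[1]]), "AA")
})

test_that("benchmark bookkeeping: single replicate has zero sd", {
  res <- runBenchmark(
    list(list(flank = "hydrophobic", trueRatio = 1, removal = FALSE)),
    replicates = 1, seed = 4, nPos = 40, nNeg = 40, seqLength = 120)
  expect_equal(nrow(res$details), 1L)
  expect_true(res$details$found)
  expect_equal(res$summary$sdScore, 0)
  expect_equal(res$summary$sdLength, 0)
  expect_error(runBenchmark(list(list(flank = "hydrophobic", trueRatio = 1,
                                      removal = FALSE)), replicates = 0),
               "replicates")
  expect_error(runBenchmark(list(list(flank = "hydrophobic")),
                            replicates = 1), "condition")
})
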