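test_that("information content matches analytic cases and the oracle", {
  # a fully conserved column contributes log2(20) bits
  expect_equal(informationContent(c("A", "A", "A")), log2(20))
  expect_equal(informationContent(c("AA", "AA", "AA")), 2 * log2(20))
  # a 50/50 column contributes log2(20) - 1
  expect_equal(informationContent(c("CA", "CC")), 2 * log2(20) - 1)

  set.seed(13)
  inst <- randomProtein(15, 8)
  expect_equal(informationContent(inst), oracleIC(inst), tolerance = 1e-9)
  # invariant under instance reordering
  expect_equal(informationContent(inst), informationContent(rev(inst)))
  # column additivity: IC of a column subset sums
  left <- substring(inst, 1, 4); right <- substring(inst, 5, 8)
  expect_equal(informationContent(inst),
               informationContent(left) + informationContent(right),
               tolerance = 1e-9)
  # 'X' residues are excluded from the column counts
  expect_equal(informationContent(c("AX", "AA")), 2 * log2(20))

  expect_error(informationContent(c("AA", "AAA")), "same length")
  expect_error(informationContent("AA"), "at least 2")
  expect_true(informationContent(inst) >= 0 &&
                informationContent(inst) <= 8 * log2(20))
})

test_that("PWM construction renders weak columns as 'x'", {
  out <- buildPWM(c("NPAY", "NPCY", "NPGY"))
  expect_equal(out$consensus, "NPxY")
  expect_equal(colSums(out$pwm), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(out$pwm["N", 1]), 1)
  expect_equal(unname(out$pwm["A", 3]), 1 / 3)
  expect_equal(buildPWM(c("ACD", "ACD"))$consensus, "ACD")
  expect_error(buildPWM("ACD"), "at least 2")
})

test_that("boundary determination respects caps, thresholds and determinism", {
  toy <- makeToyImplant(nPos = 40, nNeg = 40, len = 120, seed = 51)
  anchor <- AnchorPattern("AA")
  ids <- unique(matchAnchor(anchor, toy$pos)$id)

  # maxExtension = 0: the motif is exactly the anchor span
  bd0 <- determineBoundaries(toy$pos[ids], toy$neg, anchor,
                             boundaryConfig(maxExtension = 0, seed = 3))
  expect_true(bd0$found)
  expect_equal(bd0$leftExt + bd0$rightExt, 0L)

  bd <- determineBoundaries(toy$pos[ids], toy$neg, anchor,
                            boundaryConfig(seed = 3))
  bd2 <- determineBoundaries(toy$pos[ids], toy$neg, anchor,
                             boundaryConfig(seed = 3))
  expect_identical(bd[c("leftExt", "rightExt", "seatScore")],
                   bd2[c("leftExt", "rightExt", "seatScore")])

  # raising the accuracy threshold never widens the extents
  bd9 <- determineBoundaries(toy$pos[ids], toy$neg, anchor,
                             boundaryConfig(accuracyThreshold = 0.9,
                                            seed = 3))
  expect_lte(bd9$leftExt, bd$leftExt)
  expect_lte(bd9$rightExt, bd$rightExt)

  # indistinguishable classes: the anchor is rejected at the seat
  set.seed(19)
  bg <- randomProtein(40, 100, prefix = "s")
  ids2 <- unique(matchAnchor(anchor, bg)$id)
  bdBg <- determineBoundaries(bg[ids2], bg, anchor, boundaryConfig(seed = 3))
  expect_false(bdBg$found)
  expect_lt(bdBg$seatScore, 0.5)
})

test_that("motif region scoring delegates exactly to cross-validation", {
  set.seed(61)
  inst <- c(randomProtein(20, 12, prefix = "i"))
  substr(inst, 4, 9) <- "VVLLWW"
  negWin <- randomProtein(25, 12, prefix = "w")  # exactly motif-width
  a <- motifRegionScore(inst, negWin, anchor = NULL, folds = 5, seed = 77)
  b <- crossValidatedScore(inst, negWin, folds = 5, seed = 77)
  expect_identical(a@precision, b@precision)
  expect_identical(a@recall, b@recall)
  expect_equal(a@minPR, min(a@precision, a@recall))
  expect_true(a@minPR >= 0 && a@minPR <= 1)
  expect_error(motifRegionScore(inst[1:3], negWin, folds = 5), "folds")
})
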