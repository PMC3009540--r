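test_that("anchor matching reports all overlapping occurrences", {
  hits <- matchAnchor(AnchorPattern("RR"), c(s = "RRR"))
  expect_equal(hits$start, c(1L, 2L))
  expect_equal(hits$span, c(2L, 2L))

  # gapped anchor: NP x{1} Y, models an NPxY-style core
  hits <- matchAnchor(AnchorPattern("NP", "Y", 1), c(s = "ANPAYC"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$span, 4L)

  expect_equal(nrow(matchAnchor(AnchorPattern("RR"), c(s = "AAAA"))), 0L)

  # 'X' never satisfies a literal position but is allowed in the gap
  expect_equal(matchAnchor(AnchorPattern("RR"), c(s = "RXRR"))$start, 3L)
  expect_equal(matchAnchor(AnchorPattern("NP", "Y", 1),
                           c(s = "ANPXYC"))$start, 2L)
})

test_that("anchor matching agrees with an exhaustive brute-force scan", {
  set.seed(99)
  seqs <- randomProtein(60, 150)
  patterns <- list(AnchorPattern("RR"),
                   AnchorPattern("NP", "Y", 0, 2),
                   AnchorPattern("A", "A", 1, 3))
  for (p in patterns) {
    hits <- matchAnchor(p, seqs)
    for (id in names(seqs)) {
      mine <- hits[hits$id == id, c("start", "gap", "span")]
      ref <- oracleAnchorScan(p@leftLiteral, p@rightLiteral, p@gapMin,
                              p@gapMax, seqs[[id]])
      ref <- ref[order(ref$start, ref$gap), ]
      rownames(mine) <- rownames(ref) <- NULL
      expect_equal(as.data.frame(mine), as.data.frame(ref))
    }
  }
})

test_that("anchor enumeration counts support and occurrences correctly", {
  tab <- enumerateAnchors(c(a = "RRAR"), NULL, n = 2, minSupport = 0)
  expect_setequal(tab$label, c("RR", "RA", "AR"))
  expect_true(all(tab$support == 1L))
  expect_true(all(tab$totalHits == 1L))
  expect_true(all(tab$posFreq == 1))

  # no anchor can exceed 100% support
  expect_equal(nrow(enumerateAnchors(c(a = "RRAR"), NULL, n = 2,
                                     minSupport = 1.01)), 0L)

  # totalHits equals the summed matchAnchor counts; support is monotone
  set.seed(5)
  seqs <- randomProtein(12, 80)
  tab <- enumerateAnchors(seqs, NULL, n = 2, minSupport = 0)
  for (lab in sample(tab$label, 5)) {
    hits <- matchAnchor(AnchorPattern(lab), seqs)
    expect_equal(tab$totalHits[tab$label == lab], nrow(hits))
    expect_equal(tab$support[tab$label == lab], length(unique(hits$id)))
  }
  tab2 <- enumerateAnchors(c(seqs, extra = "RRRRRRRR"), NULL, n = 2,
                           minSupport = 0)
  shared <- intersect(tab$label, tab2$label)
  expect_true(all(tab2$support[match(shared, tab2$label)] >=
                    tab$support[match(shared, tab$label)]))

  # every sequence containing the implanted anchor supports it fully
  toy <- makeToyImplant(nPos = 15, nNeg = 15, len = 120, seed = 3)
  tab3 <- enumerateAnchors(toy$pos, toy$neg, n = 2, minSupport = 0.3)
  expect_equal(tab3$posFreq[tab3$label == "AA"], 1)

  expect_error(enumerateAnchors(c(a = "RRAR"), NULL, n = 6, m = 6,
                                gapMax = 2, maxSpace = 1e5), "cap")
})

test_that("anchor ranking follows support with lexicographic ties", {
  tab <- enumerateAnchors(c(a = "RRAR"), NULL, n = 2, minSupport = 0)
  expect_length(rankAnchors(tab, 5), 3L)
  # all supports equal -> lexicographically smallest literal first
  expect_equal(anchorLiteral(rankAnchors(tab, 1)[[1]]), "AR")
  expect_error(rankAnchors(tab, 0), "topK")
  expect_error(rankAnchors(tab[0, ], 1), "empty")
})
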