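test_that("occurrence choice prefers the model's best hit, leftmost on ties", {
  hits <- data.frame(start = c(5L, 2L), gap = 0L, span = 2L)
  expect_equal(chooseOccurrence(hits, "ACDEFGHIKLMNPQ")$start, 2L)

  # a model trained on hydrophobic-flank windows picks the implanted hit
  seg <- paste0("AA", "DDDDDDDD",                     # decoy anchor at 1
                strrep("V", 4), "AA", strrep("L", 8)) # implant at 15
  model <- trainWindowModel(rep("AAVVLLVVLL", 5), rep("DDSSGGEESS", 5))
  hits <- matchAnchor(AnchorPattern("AA"), c(s = seg))
  chosen <- chooseOccurrence(hits, seg, model)
  expect_equal(chosen$start, 15L)
  expect_error(chooseOccurrence(hits[0, ], seg), "non-empty")
})

test_that("a pure, strongly implanted set survives purification untouched", {
  toy <- makeToyImplant(nPos = 30, nNeg = 30, len = 120, seed = 21)
  anchor <- AnchorPattern("AA")
  ids <- unique(matchAnchor(anchor, toy$pos)$id)
  res <- purifyPositives(toy$pos[ids], toy$neg, anchor,
                         fpRemovalConfig(seed = 4))
  expect_equal(res$iterations, 1L)
  expect_setequal(res$retainedIds, ids)
  expect_true(all(res$audit$action == "retained"))
})

test_that("a zero threshold disables removal", {
  toy <- makeToyImplant(nPos = 12, nNeg = 12, len = 60, trueRatio = 0.5,
                        seed = 8)
  anchor <- AnchorPattern("AA")
  ids <- unique(matchAnchor(anchor, toy$pos)$id)
  res <- purifyPositives(toy$pos[ids], toy$neg, anchor,
                         fpRemovalConfig(scoreThreshold = 0, seed = 4))
  expect_setequal(res$retainedIds, ids)
  expect_equal(res$iterations, 1L)
})

test_that("purification shrinks monotonically, terminates, and is deterministic", {
  toy <- makeToyImplant(nPos = 50, nNeg = 50, len = 120, trueRatio = 0.5,
                        seed = 31, flank = "hydrophobicCharged")
  anchor <- AnchorPattern("AA")
  ids <- unique(matchAnchor(anchor, toy$pos)$id)
  cfg <- fpRemovalConfig(seed = 9)
  res <- purifyPositives(toy$pos[ids], toy$neg, anchor, cfg)
  expect_lte(res$iterations, cfg$maxIterations)
  # retained set is non-increasing across iterations; removals are disjoint
  perIter <- split(res$audit, res$audit$iteration)
  sizes <- vapply(perIter, nrow, integer(1))
  expect_true(all(diff(sizes) <= 0))
  removedIds <- res$audit$id[res$audit$action == "removed"]
  expect_false(anyDuplicated(removedIds) > 0)
  # purity improves over the input
  purityIn <- mean(toy$truth$implanted[match(ids, toy$truth$id)])
  purityOut <- mean(toy$truth$implanted[match(res$retainedIds, toy$truth$id)])
  expect_gt(purityOut, purityIn)

  res2 <- purifyPositives(toy$pos[ids], toy$neg, anchor, cfg)
  expect_identical(res$audit, res2$audit)
  expect_identical(res$retainedIds, res2$retainedIds)
})

test_that("background-only positives with coincidental anchors collapse", {
  pos <- generateBackground(219, 200, seed = 300, prefix = "bg")
  anchor <- AnchorPattern("AA")
  ids <- unique(matchAnchor(anchor, pos)$id)
  neg <- generateBackground(220, 200, seed = 301, prefix = "n")
  out <- tryCatch(
    purifyPositives(pos[ids], neg, anchor, fpRemovalConfig(seed = 2)),
    error = function(e) e)
  if (methods::is(out, "error")) {
    expect_match(conditionMessage(out), "removed")
  } else {
    expect_lt(length(out$retainedIds), 0.5 * length(ids))
  }
})

test_that("purification preconditions are enforced", {
  toy <- makeToyImplant(nPos = 12, nNeg = 12, len = 60, seed = 5)
  anchor <- AnchorPattern("AA")
  ids <- unique(matchAnchor(anchor, toy$pos)$id)
  expect_error(purifyPositives(toy$pos[ids][1:4], toy$neg, anchor),
               "at least 10")
  # a positive without the anchor violates the precondition
  bad <- c(toy$pos[ids], noanchor = strrep("G", 60))
  expect_error(purifyPositives(bad, toy$neg, anchor), "without an anchor")
})
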