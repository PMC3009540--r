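test_that("FASTA reading sanitizes non-standard residues and validates input", {
  path <- writeTempFasta(c(a = "MKR", b = "MKU"))
  expect_message(ds <- readFastaDataset(path, "positive"), "sanitized 1")
  expect_length(ds, 2L)
  expect_identical(as.character(ds)[["b"]], "MKX")
  expect_identical(attr(ds, "label"), "positive")

  expect_error(readFastaDataset(writeTempFasta(c(a = "")), "positive"),
               "empty residues")
  dupPath <- writeTempFasta(c(a = "MKR", b = "MKL", a = "MMM"))
  expect_error(readFastaDataset(dupPath, "positive"), "duplicate record id: a")
  expect_error(readFastaDataset(tempfile(), "positive"), "not found")
})

test_that("SortingDataset enforces unique ids and exposes class accessors", {
  ds <- SortingDataset(positive = c(p1 = "MKRAA", p2 = "MKLVV"),
                       negative = c(n1 = "MSSSS"))
  expect_s4_class(ds, "SortingDataset")
  expect_equal(nPositive(ds), 2L)
  expect_equal(nNegative(ds), 1L)
  expect_identical(names(positiveSet(ds)), c("p1", "p2"))
  expect_error(SortingDataset(positive = c(a = "MK"), negative = c(a = "ML")),
               "duplicate")
})

test_that("terminal extraction takes prefixes and suffixes capped at K", {
  long <- paste(rep("ARNDE", 60), collapse = "")  # 300 residues
  expect_identical(extractTerminal(c(x = long), "N", 200),
                   c(x = substr(long, 1, 200)))
  expect_identical(extractTerminal(c(x = "MKRLL"), "N", 200),
                   c(x = "MKRLL"))
  expect_identical(extractTerminal(c(x = "ACDEF"), "C", 3), c(x = "DEF"))
  ds <- SortingDataset(positive = c(p = long), negative = c(n = "MKRLL"))
  seg <- extractTerminal(ds, "N", 200)
  expect_equal(unname(nchar(as.character(positiveSet(seg)))), 200)
  expect_equal(nNegative(seg), 1L)
  expect_error(extractTerminal(c(x = "AA"), "N", 0), "K must be")
})

test_that("pairwise identity matches a dynamic-programming oracle", {
  expect_equal(pairwiseIdentity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwiseIdentity("AAAA", "AAAC"), 0.75)
  # frozen from the exhaustive global-alignment oracle: AA-- / AAAA
  expect_equal(oracleIdentity("AA", "AAAA"), 0.5)
  expect_equal(pairwiseIdentity("AA", "AAAA"), 0.5)
  expect_equal(pairwiseIdentity("AA", "AAAA", denominator = "shorter"), 1.0)

  set.seed(41)
  for (i in 1:10) {
    a <- paste(sample(aminoAcidAlphabet(), sample(5:20, 1), TRUE),
               collapse = "")
    b <- paste(sample(aminoAcidAlphabet(), sample(5:20, 1), TRUE),
               collapse = "")
    pid <- pairwiseIdentity(a, b)
    expect_equal(pid, pairwiseIdentity(b, a))           # symmetry
    expect_true(pid >= 0 && pid <= 1)
    if (a != b) expect_lt(pid, 1)
    expect_equal(pairwiseIdentity(a, a), 1.0)           # 1 iff identical
  }
})

test_that("greedy redundancy reduction keeps dissimilar representatives", {
  s <- "MKRILKAGDE"; t <- "WWWFFFPPPG"
  r <- reduceRedundancy(c(s1 = s, s2 = s, t = t), threshold = 0.8)
  expect_setequal(names(r$sequences), c("s1", "t"))
  expect_identical(r$report$removed_id, "s2")
  expect_identical(r$report$representative_id, "s1")
  expect_equal(r$report$identity, 1.0)

  # threshold 1 with no exact duplicates: nothing collapses
  set.seed(7)
  x <- randomProtein(8, 30)
  r1 <- reduceRedundancy(x, threshold = 1.0)
  expect_identical(names(r1$sequences), names(x))

  # singleton unchanged
  expect_identical(names(reduceRedundancy(x[1], 0.8)$sequences), names(x)[1])

  # representatives pairwise below threshold; removed above it; idempotent
  y <- c(x, stats::setNames(paste0(substr(x[1], 1, 28), "GG"), "near1"))
  r2 <- reduceRedundancy(y, threshold = 0.8)
  reps <- r2$sequences
  for (i in seq_along(reps)) for (j in seq_len(i - 1L))
    expect_lt(pairwiseIdentity(reps[[i]], reps[[j]]), 0.8)
  for (k in seq_len(nrow(r2$report)))
    expect_gte(pairwiseIdentity(y[[r2$report$removed_id[k]]],
                                y[[r2$report$representative_id[k]]]), 0.8)
  r3 <- reduceRedundancy(reps, threshold = 0.8)
  expect_identical(names(r3$sequences), names(reps))
})
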