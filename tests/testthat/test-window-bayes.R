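test_that("Laplace smoothing follows the stated counting rule", {
  m <- trainWindowModel(rep("AA", 3), rep("CC", 3), alpha = 1)
  expect_equal(exp(m@logLik["A", 1, "motif"]), 4 / 23)
  expect_equal(exp(m@logLik["C", 1, "motif"]), 1 / 23)
  expect_equal(exp(m@logLik["C", 2, "background"]), 4 / 23)
  expect_equal(sum(exp(m@logLik[1:20, 1, "motif"])), 1, tolerance = 1e-12)
  expect_error(trainWindowModel(character(0), rep("CC", 3)), "one window")
})

test_that("posterior matches the explicit-product oracle to 1e-9", {
  # frozen value for the 3-sample toy: (4/23)^2 / ((4/23)^2 + (1/23)^2)
  m <- trainWindowModel(rep("AA", 3), rep("CC", 3), alpha = 1)
  expect_equal(windowPosterior(m, "AA"), 16 / 17, tolerance = 1e-12)
  expect_equal(oraclePosterior(rep("AA", 3), rep("CC", 3), 1, "AA"), 16 / 17)

  set.seed(11)
  for (case in 1:20) {
    W <- sample(2:4, 1)
    np <- sample(2:10, 1); nn <- sample(2:10, 1)
    pos <- vapply(seq_len(np), function(i)
      paste(sample(c(aminoAcidAlphabet(), "X"), W, TRUE), collapse = ""),
      character(1))
    neg <- vapply(seq_len(nn), function(i)
      paste(sample(c(aminoAcidAlphabet(), "X"), W, TRUE), collapse = ""),
      character(1))
    q <- paste(sample(c(aminoAcidAlphabet(), "X"), W, TRUE), collapse = "")
    alpha <- sample(c(0.5, 1, 2), 1)
    model <- trainWindowModel(pos, neg, alpha = alpha)
    expect_equal(windowPosterior(model, q),
                 oraclePosterior(pos, neg, alpha, q), tolerance = 1e-9)
    # motif and background posteriors are complementary
    swapped <- trainWindowModel(neg, pos, alpha = alpha)
    expect_equal(windowPosterior(model, q) + windowPosterior(swapped, q), 1,
                 tolerance = 1e-9)
  }
})

test_that("degenerate models behave symmetrically", {
  # identical class distributions with equal priors: posterior 0.5
  m <- trainWindowModel(c("AC", "CA"), c("AC", "CA"))
  expect_equal(windowPosterior(m, "AA"), 0.5, tolerance = 1e-12)
  # an all-'X' window scores the motif prior
  m2 <- trainWindowModel(rep("AA", 30), rep("CC", 10))
  expect_equal(windowPosterior(m2, "XX"), 0.75, tolerance = 1e-12)
  expect_error(windowPosterior(m2, "AAA"), "width")
})

test_that("cross-validation is exact on separable data and fair on noise", {
  pos <- rep(c("AAAA", "ACAA"), 10)
  neg <- rep(c("WWWW", "WYWW"), 10)
  cv <- crossValidatedScore(pos, neg, folds = 5, seed = 1)
  expect_equal(cv@minPR, 1.0)
  expect_equal(cv@minPR, min(cv@precision, cv@recall))

  # identically distributed classes score ~0.5 over seeds
  set.seed(23)
  scores <- vapply(1:10, function(s) {
    pos <- randomProtein(200, 10, prefix = "p")
    neg <- randomProtein(200, 10, prefix = "n")
    crossValidatedScore(pos, neg, folds = 5, seed = s)@minPR
  }, numeric(1))
  expect_lt(abs(mean(scores) - 0.5), 0.07)

  # determinism given seed
  pos <- randomProtein(30, 8, seed = 5, prefix = "p")
  neg <- randomProtein(30, 8, seed = 6, prefix = "n")
  a <- crossValidatedScore(pos, neg, seed = 42)
  b <- crossValidatedScore(pos, neg, seed = 42)
  expect_identical(a@precision, b@precision)
  expect_identical(a@recall, b@recall)

  expect_error(crossValidatedScore(pos[1:3], neg, folds = 5), "folds")
  expect_error(crossValidatedScore(pos, neg, folds = 1), "folds")
})
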