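# Independent brute-force oracles used to cross-check the implementation.

# Needleman-Wunsch (match 1, mismatch 0, linear gap -1), returning identity
# over the full alignment length. Tracks the match count of one optimal path
# (ties resolved diag > up > left, deterministic).
oracleIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  }
  # traceback
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  matches / len
}

# Exhaustive anchor scan over every start offset and gap length.
oracleAnchorScan <- function(left, right, gapMin, gapMax, s) {
  n <- nchar(left); m <- nchar(right)
  out <- list()
  for (start in seq_len(nchar(s))) {
    for (g in gapMin:gapMax) {
      span <- n + g + m
      if (start + span - 1L > nchar(s)) next
      if (substring(s, start, start + n - 1L) != left) next
      if (m > 0L &&
          substring(s, start + n + g, start + span - 1L) != right) next
      out[[length(out) + 1L]] <- c(start = start, gap = g, span = span)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), gap = integer(0),
                                      span = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# Explicit-product naive Bayes posterior (no logs), Laplace smoothing alpha,
# 'X' contributing 1/20 to both classes.
oraclePosterior <- function(motif, background, alpha, query) {
  classLik <- function(samples, q) {
    W <- nchar(q)
    lik <- 1
    for (j in seq_len(W)) {
      col <- substring(samples, j, j)
      col <- col[col != "X"]
      ch <- substring(q, j, j)
      lik <- lik * if (ch == "X") 1 / 20 else
        (sum(col == ch) + alpha) / (length(col) + 20 * alpha)
    }
    lik
  }
  np <- length(motif); nn <- length(background)
  pm <- np / (np + nn) * classLik(motif, query)
  pb <- nn / (np + nn) * classLik(background, query)
  pm / (pm + pb)
}

# Direct information-content formula.
oracleIC <- function(instances) {
  L <- nchar(instances[1])
  total <- 0
  for (j in seq_len(L)) {
    col <- substring(instances, j, j)
    col <- col[col != "X"]
    if (!length(col)) next
    p <- table(col) / length(col)
    total <- total + log2(20) + sum(p * log2(p))
  }
  total
}

randomProtein <- function(n, len, seed = NULL, prefix = "r") {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(vapply(seq_len(n), function(i) {
    paste(sample(aminoAcidAlphabet(), len, replace = TRUE), collapse = "")
  }, character(1)), paste0(prefix, seq_len(n)))
}

# Small implanted dataset for integration-level tests.
makeToyImplant <- function(nPos = 40, nNeg = 40, len = 120, trueRatio = 1,
                           flank = "hydrophobic", seed = 1) {
  pos <- generateBackground(nPos, len, seed = seed, prefix = "p")
  neg <- generateBackground(nNeg, len, seed = seed + 1000L, prefix = "n")
  imp <- implantMotifs(pos, implantSpec(flank, trueRatio = trueRatio,
                                        positionRange = c(1L, min(100L, len))),
                       seed = seed + 2000L)
  list(pos = imp$sequences, neg = neg, truth = imp$truth)
}

writeTempFasta <- function(entries) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}
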