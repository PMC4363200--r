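test_that("Markov chain training reproduces closed-form frequencies", {
  m <- trainMarkov(list("AAAC"), order = 0, pseudocount = 0)
  expect_equal(m@tables[[1]][[1]][1, ], c(0.75, 0.25, 0, 0))

  m1 <- trainMarkov(list("AAAC"), order = 0, pseudocount = 1)
  expect_equal(m1@tables[[1]][[1]][1, 1], (3 + 1) / (4 + 4))

  ## order-1 three-periodic: hand-tally a 9-nt sequence per codon position.
  ## Sequence ACGTACGTA: order-1 events (prev -> base) at positions 2..9 land
  ## in the table of ((position - 1) mod 3).
  m2 <- trainMarkov(list("ACGTACGTA"), order = 1, periodic = TRUE, pseudocount = 0)
  ## hand tally of ACGTACGTA: codon position 1 sees positions 2,5,8 with
  ## events A->C, T->A, G->T; codon position 2 sees 3,6,9: C->G, A->C, T->A;
  ## codon position 0 sees 4,7: G->T, C->G
  ph1 <- m2@tables[[2]][[2]]
  expect_equal(ph1[1, 2], 1); expect_equal(ph1[4, 1], 1); expect_equal(ph1[3, 4], 1)
  ph2 <- m2@tables[[3]][[2]]
  expect_equal(ph2[2, 3], 1); expect_equal(ph2[1, 2], 1); expect_equal(ph2[4, 1], 1)
  ph0 <- m2@tables[[1]][[2]]
  expect_equal(ph0[3, 4], 1); expect_equal(ph0[2, 3], 1)
})

test_that("Markov scoring uses segment-local backoff and sums per base", {
  m <- trainMarkov(list("AAAC"), order = 0, pseudocount = 0)
  expect_equal(scoreMarkov(m, "AA"), 2 * log(0.75))
  expect_equal(scoreMarkov(m, ""), 0)

  ## concatenation property for an order-0 chain (no context crosses splits)
  m2 <- trainMarkov(list("ACGTGGTACC"), order = 0, pseudocount = 0.5)
  x <- "ACGTAC"; y <- "GGTT"
  expect_equal(scoreMarkov(m2, paste0(x, y)),
               scoreMarkov(m2, x) + scoreMarkov(m2, y), tolerance = 1e-12)

})

test_that("emission arrays reproduce naive segment scores", {
  set.seed(5)
  for (periodic in c(FALSE, TRUE)) {
    m <- trainMarkov(list(paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                                collapse = "")),
                     order = 2, periodic = periodic, pseudocount = 0.05)
    codes <- SporeCall:::encodeDNA(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                         collapse = ""))
    for (e0 in if (periodic) 0:2 else 0) {
      arr <- SporeCall:::.markovEmissionArrays(m, codes, entryPhase = e0)
      for (s in c(1, 2, 5, 11)) for (e in c(s, s + 3, s + 9)) {
        cc <- (s - 1) %% 3
        v <- arr$cum[e + 1, cc + 1] - arr$cum[s, cc + 1]
        kk <- min(ncol(arr$bc), e - s + 1)
        for (r in seq_len(kk)) v <- v + arr$bc[s, r]
        expect_equal(v, scoreMarkov(m, codes[s:e], startPhase = e0),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("weighted array matrices are positional and reject ragged input", {
  w <- trainWAM("ATG", order = 0, pseudocount = 0.01)
  all3 <- apply(expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                            b3 = c("A", "C", "G", "T")), 1, paste, collapse = "")
  scores <- vapply(all3, function(x) scoreWAM(w, x), 0)
  expect_equal(names(which.max(scores)), "ATG")

  expect_error(trainWAM(c("ATG", "ATGA"), order = 0), "ragged")

  ## order-1 tables equal hand-tallied conditionals (pseudocount 0)
  w1 <- trainWAM(c("AAT", "AAT", "ACT", "AGG"), order = 1, pseudocount = 0)
  p2 <- w1@positionTables[[2]][[1]]
  expect_equal(p2[1, ], c(2, 1, 1, 0) / 4)       # after A: A,A,C,G
  p3 <- w1@positionTables[[3]][[1]]
  expect_equal(p3[1, 4], 1)                       # after ..A: always T
  expect_equal(p3[3, 3], 1)                       # after ..G: always G
})

test_that("duration smoothing spreads mass and keeps the tail geometric", {
  d <- smoothDurations(rep(300, 20), bandwidth = 0)
  expect_equal(exp(durationLogProb(d, 300)), 1, tolerance = 2e-3)

  d2 <- smoothDurations(rep(300, 20), bandwidth = 2, support = c(290, 310))
  expect_equal(sum(exp(d2@logp)) + exp(d2@tailLogMass), 1, tolerance = 1e-9)
  expect_gt(exp(durationLogProb(d2, 298)), 0.05)   # spread within +/- 2
  expect_gt(exp(durationLogProb(d2, 305)), 0)      # uniform floor positivity
  expect_lt(exp(durationLogProb(d2, 305)), 1e-4)

  ## geometric tail beyond the support maximum
  d3 <- smoothDurations(c(rep(100, 50), 130, 140), support = c(90, 120),
                        bandwidth = 1)
  lp1 <- durationLogProb(d3, 121); lp2 <- durationLogProb(d3, 122)
  expect_equal(lp2 - lp1, log(1 - d3@tailRate), tolerance = 1e-9)
  expect_true(durationLogProb(d3, 89) < -1e25)
})

test_that("constrained Viterbi equals exhaustive enumeration on random models", {
  set.seed(1234)
  nFail <- 0
  for (rep in 1:60) {
    spec <- randomGhmm(sample(2:4, 1))
    L <- sample(6:12, 1)
    x <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    pen <- if (runif(1) < 0.5) randomPenalties(spec, L) else NULL
    v <- viterbiDecode(spec, x, penalties = pen)
    o <- enumerateParses(spec, x, penalties = pen)
    expect_equal(v$ok, o$ok)
    if (v$ok && o$ok) {
      expect_equal(v$logprob, o$logprob, tolerance = 1e-9)
      if (!identical(v$path$end, o$path$end) ||
          !identical(v$path$state, o$path$state)) nFail <- nFail + 1
    }
  }
  expect_equal(nFail, 0)
})

test_that("adding a constraint never increases the optimal log-probability", {
  set.seed(77)
  for (rep in 1:20) {
    spec <- randomGhmm(3)
    L <- 10
    x <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    free <- viterbiDecode(spec, x)
    pen <- setNames(lapply(spec@states, function(s) {
      v <- numeric(L); v[sample(L, 2)] <- -0.7; v
    }), spec@states)
    con <- viterbiDecode(spec, x, penalties = pen)
    if (free$ok && con$ok) expect_lte(con$logprob, free$logprob + 1e-9)
    if (!free$ok) expect_false(con$ok)
  }
})

test_that("forbidding all states at one position yields no-parse, not an error", {
  set.seed(3)
  spec <- randomGhmm(3)
  L <- 9
  x <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  pen <- setNames(lapply(spec@states, function(s) {
    v <- numeric(L); v[5] <- -1e30; v
  }), spec@states)
  res <- viterbiDecode(spec, x, penalties = pen)
  expect_false(res$ok)
  expect_identical(enumerateParses(spec, x, penalties = pen)$ok, FALSE)
})

test_that("with uniform emissions the parse is dictated by durations alone", {
  uni <- trainMarkov(list("ACGT"), order = 0, pseudocount = 1e6)  # ~uniform
  states <- c("a", "b")
  tr <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
               dimnames = list(states, states))
  spec <- ghmmSpec(states, tr, begin = c(1, 0), end = c(0, 1),
                   emissions = list(a = uni, b = uni),
                   durations = list(a = fixedDuration(4), b = fixedDuration(8)))
  res <- viterbiDecode(spec, strrep("ACGT", 3))
  expect_equal(res$path$state, c("a", "b"))
  expect_equal(res$path$end, c(4L, 12L))
})

test_that("decoding stays finite on long sequences (log-space, no underflow)", {
  set.seed(11)
  m <- trainMarkov(list(paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                              collapse = "")), order = 1, pseudocount = 0.1)
  spec <- ghmmSpec("s", matrix(0.5, 1, 1, dimnames = list("s", "s")),
                   begin = 1, end = 0.5, emissions = list(s = m),
                   durations = list(s = smoothDurations(c(500, 900, 1400),
                                                        support = c(200, 2000))))
  x <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  res <- viterbiDecode(spec, x)
  expect_true(res$ok)
  expect_true(is.finite(res$logprob))
})

test_that("the enumeration oracle enforces its size guards", {
  spec <- randomGhmm(2)
  expect_error(enumerateParses(spec, strrep("A", 31)), "30")
  expect_silent({
    big <- randomGhmm(6)
    r <- enumerateParses(big, "ACGTAC")
  })
  expect_error(enumerateParses(randomGhmm(7), "ACGTAC"), "6 states")
})

test_that("empty sequences parse trivially with log-probability 0", {
  spec <- randomGhmm(2)
  expect_equal(viterbiDecode(spec, "")$logprob, 0)
  expect_equal(enumerateParses(spec, "")$logprob, 0)
})

test_that("model serialization writes a readable flat-text dump", {
  m <- trainMarkov(list("ACGTACGT"), order = 1, pseudocount = 0.1)
  spec <- ghmmSpec("s", matrix(0, 1, 1, dimnames = list("s", "s")),
                   begin = 1, end = 1, emissions = list(s = m),
                   durations = list(s = fixedDuration(4)))
  f <- withr::local_tempfile(fileext = ".txt")
  writeGhmmSpec(spec, f)
  txt <- readLines(f)
  expect_true(any(grepl("^states: s$", txt)))
  expect_true(any(grepl("duration fixed 4", txt)))
})
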