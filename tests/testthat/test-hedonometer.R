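lex <- table1_lexicon()

test_that("tokenization lowercases, strips edge punctuation, keeps emoticons", {
  expect_equal(tokenize("I'm HAPPY!")[[1]], c("i'm", "happy"))
  expect_equal(tokenize("")[[1]], character(0))
  toks <- tokenize("so sad :(", lexicon = lex)[[1]]
  expect_setequal(toks, c("so", "sad", ":("))
  # emoticon glued to punctuation still found; internal apostrophes kept
  expect_true(":(" %in% tokenize("bad day :((", lexicon = lex)[[1]])
  expect_equal(tokenize("don't stop...")[[1]], c("don't", "stop"))
})

test_that("scoring matches the worked lexicon examples", {
  expect_equal(score_counts(c(happy = 1L), lex), 8.30)
  expect_equal(score_text("happy", lex), 8.30)
  # all-neutral text: explicit no-score, never 0
  expect_true(is.na(score_counts(c(and = 5L, the = 3L), lex)))
  expect_true(is.na(score_text("", lex)))
  # (8.30 + 1.76) / 2
  expect_equal(score_counts(c(happy = 1L, jail = 1L), lex), 5.03)
  # neutral band is open: a hypothetical score of exactly 4 or 6 is retained
  lex46 <- lexicon(c("a4", "a6"), c(4, 6))
  expect_equal(score_text("a4 a6", lex46), 5)
})

test_that("scoring is count-scale invariant and monotone in word quality", {
  counts <- c(happy = 2L, down = 3L, war = 1L)
  expect_equal(score_counts(counts, lex), score_counts(counts * 5L, lex),
               tolerance = 1e-12)
  worse <- c(happy = 1L, down = 4L)
  better <- c(happy = 1L, fresh = 4L)  # 'down' 3.66 -> 'fresh' 7.26
  expect_gt(score_counts(better, lex), score_counts(worse, lex))
})

test_that("equal-count bins split sizes differing by at most one", {
  expect_equal(sort(tabulate(equal_count_bins(1:10, 10))), rep(1L, 10))
  sizes <- tabulate(equal_count_bins(rnorm(11), 10))
  expect_equal(sort(sizes, decreasing = TRUE), c(2L, rep(1L, 9)))
  b <- equal_count_bins(c(5, 1, 3, 2, 4, 6), 3)
  expect_equal(b, c(3L, 1L, 2L, 1L, 2L, 3L))  # sorted split, input order out
  expect_error(equal_count_bins(1:3, 4), "cannot split")
  # monotone boundaries
  v <- sort(runif(57))
  bb <- equal_count_bins(v, 10)
  expect_true(!is.unsorted(bb))
})

test_that("pooled bin scores equal the concatenation oracle", {
  withr::with_seed(201, {
    words <- sample(lex$word, 400, replace = TRUE)
    texts <- vapply(split(words, rep(1:80, each = 5)), paste, character(1),
                    collapse = " ")
    d <- rlnorm(80, 8, 1)
  })
  trend <- happiness_by_distance(texts, d, lex, k = 4)
  bins <- equal_count_bins(d, 4)
  for (b in 1:4) {
    oracle <- score_text(paste(texts[bins == b], collapse = " "), lex)
    expect_equal(trend$h_avg[b], oracle, tolerance = 1e-12)
  }
  # identical texts in every bin give a flat trend
  flat <- happiness_by_distance(rep("happy jail", 20), 1:20, lex, k = 5)
  expect_equal(flat$h_avg, rep(5.03, 5))
})

test_that("gyradius binning pools words per user group", {
  texts <- c("happy happy", "jail", "war", "fresh")
  users <- c("a", "a", "b", "c")
  gy <- c(a = 10, b = 100, c = 1000)
  tr <- happiness_by_gyradius(texts, users, gy, lex, k = 3)
  expect_equal(tr$h_avg[1], score_text("happy happy jail", lex), tolerance = 1e-12)
  expect_equal(tr$h_avg[3], 7.26)
  # degenerate single bin equals the corpus-wide score
  tr1 <- happiness_by_gyradius(texts, users, gy, lex, k = 1)
  expect_equal(tr1$h_avg, score_text(paste(texts, collapse = " "), lex),
               tolerance = 1e-12)
})

test_that("log-linear fit recovers constructed trends exactly", {
  d <- 10^(2:7)
  h <- 5.9 + 0.05 * log10(d)
  fit <- fit_log_linear(d, h)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, 5.9, tolerance = 1e-12)
  # closed-form normal-equations oracle
  X <- log10(d)
  slope_oracle <- sum((X - mean(X)) * (h - mean(h))) / sum((X - mean(X))^2)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_error(fit_log_linear(100, 5), "at least 2")
})
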