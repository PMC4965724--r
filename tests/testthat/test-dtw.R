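test_that("aligned basics: self distance, single pairs, symmetry", {
  set.seed(90)
  a <- random_words(10, n = 5)
  expect_equal(dtw_distance(a, a), 0)
  w1 <- random_words(1, n = 5); w2 <- random_words(1, n = 5)
  expect_equal(dtw_distance(w1, w2),
               modified_lexical_distance(w1[1, ], w2[1, ]))
  b <- random_words(12, n = 5)
  expect_equal(dtw_distance(a, b, band = 12), dtw_distance(b, a, band = 12))
})

test_that("banded DTW equals the unbanded dynamic program when wide", {
  set.seed(91)
  for (i in 1:200) {
    la <- sample(1:12, 1); lb <- sample(max(1, la - 4):min(12, la + 4), 1)
    n <- sample(c(5, 11), 1)
    a <- random_words(la, n); b <- random_words(lb, n)
    expect_equal(dtw_distance(a, b, band = 12), dtw_oracle(a, b))
  }
})

test_that("a zero band on equal lengths is the position-wise cost sum", {
  set.seed(92)
  for (i in 1:20) {
    l <- sample(2:10, 1)
    a <- random_words(l, 7); b <- random_words(l, 7)
    want <- sum(vapply(seq_len(l), function(p)
      modified_lexical_distance(a[p, ], b[p, ]), numeric(1)))
    expect_equal(dtw_distance(a, b, band = 0), want)
  }
})

test_that("too-narrow bands on unequal lengths are an error", {
  a <- random_words(10, 5); b <- random_words(3, 5)
  expect_error(dtw_distance(a, b, band = 2), "too narrow")
  expect_silent(dtw_distance(a, b, band = 7))
})

test_that("prefix distances are the diagonal of one dynamic program", {
  set.seed(93)
  a <- random_words(12, 5); b <- random_words(9, 5)
  got <- dtw_prefix_distances(a, b, band = 5)
  expect_length(got, 9)
  for (q in seq_len(9)) {
    expect_equal(got[q],
                 dtw_distance(a[seq_len(q), , drop = FALSE],
                              b[seq_len(q), , drop = FALSE], band = 5))
  }
})

test_that("segment classification finds exact matches at every prefix", {
  set.seed(94)
  train <- list(random_words(20, 5), random_words(15, 5),
                random_words(40, 5))
  labels <- c("HG", "HR", "NR")
  res <- classify_segment(train[[2]], train, labels)
  expect_s3_class(res, "prefix_result")
  expect_equal(nrow(res), 15)
  expect_true(all(res$pred == "HR"))
  expect_true(all(res$distance == 0))
  expect_true(all(res$nn == 2))
})

test_that("disjoint-alphabet classes separate from the first word", {
  lowA <- matrix(0L, 20, 8)   # class 1: all-'A' words
  highE <- matrix(4L, 20, 8)  # class 2: all-'E' words
  test <- matrix(0L, 12, 8)
  res <- classify_segment(test, list(lowA, highE), c("HG", "HR"))
  expect_equal(nrow(res), 12)
  expect_true(all(res$pred == "HG"))
  expect_error(classify_segment(test, list(), character(0)),
               "empty training")
})

test_that("prefix comparisons truncate to the shorter participant", {
  set.seed(95)
  short_train <- random_words(5, 5)
  test <- rbind(short_train, random_words(7, 5))  # length 12, same start
  res <- classify_segment(test, list(short_train), "HG")
  # beyond the training length the comparison freezes at its prefix
  expect_equal(res$distance[5:12], rep(0, 8))
})

test_that("accuracy-by-word-count pools segments long enough", {
  r1 <- structure(data.frame(prefix = 1:10,
                             pred = c(rep("HG", 9), "HR"),
                             nn = 1L, distance = 0),
                  class = c("prefix_result", "data.frame"))
  r2 <- structure(data.frame(prefix = 1:3, pred = rep("HR", 3),
                             nn = 1L, distance = 0),
                  class = c("prefix_result", "data.frame"))
  curve <- accuracy_by_wordcount(list(r1, r2), c("HG", "HR"), max_words = 12)
  expect_equal(curve$accuracy[1], 100)
  expect_equal(curve$n[1:12], c(2, 2, 2, rep(1, 7), 0, 0))
  expect_equal(curve$accuracy[10], 0)  # only r1 reaches 10 and errs there
  expect_true(all(is.na(curve$accuracy[11:12])))
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 100, na.rm = TRUE))
})
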