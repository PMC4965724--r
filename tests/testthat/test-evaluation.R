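# Shared fixture: one labeled synthetic session, reused across blocks.
eval_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- prepare_subject_data(separable_profile(),
                                                       seed = 7000)
    cache
  }
})

test_that("metrics agree with their confusion matrix", {
  set.seed(120)
  truth <- sample(c("HG", "HR", "NR"), 300, TRUE)
  pred <- truth
  flip <- sample(300, 60)
  pred[flip] <- sample(c("HG", "HR", "NR"), 60, TRUE)
  rep_ <- eval_report(pred, truth, classes = c("HG", "HR", "NR"))
  expect_equal(rep_$accuracy,
               100 * sum(diag(rep_$confusion)) / sum(rep_$confusion),
               tolerance = 1e-9)
  expect_equal(rep_$tpr,
               100 * diag(rep_$confusion) / rowSums(rep_$confusion))
  expect_equal(unname(rowSums(rep_$confusion)),
               unname(table(factor(truth, c("HG", "HR", "NR")))),
               ignore_attr = TRUE)

  # an oracle scores 100, a constant predictor scores the prevalence
  expect_equal(eval_report(truth, truth)$accuracy, 100)
  expect_equal(eval_report(rep("NR", 300), truth)$accuracy,
               100 * mean(truth == "NR"))
})

test_that("a labeled session yields the expected structure", {
  data <- eval_data()
  expect_s3_class(data, "subject_data")
  expect_equal(nrow(data$nr_values), 480)
  expect_setequal(unique(data$instance_labels), activity_codes())
  # instance dataset = truncated segment instances + retained NR
  expect_equal(nrow(data$instances), length(data$instance_labels))
  lens <- vapply(data$segments, function(s) nrow(s$values), integer(1))
  expect_true(all(lens >= 1 & lens <= 40))
})

test_that("repetition folds are disjoint, exhaustive and NR-covering", {
  data <- eval_data()
  folds <- make_repetition_folds(data)
  expect_equal(folds$n_folds, 12L)
  expect_setequal(unique(folds$seg_fold), 1:12)
  expect_setequal(unique(folds$nr_fold), 1:12)
  # every fold holds one repetition of every run
  runs <- vapply(data$segments, `[[`, integer(1), "run_id")
  for (k in 1:12)
    expect_setequal(unique(runs[folds$seg_fold == k]), 1:8)
  # NR chunks: 40 instances per fold, disjoint by construction
  expect_equal(unname(tabulate(folds$nr_fold, 12)), rep(40L, 12))
  # NR is roughly 6 % of a fold's words
  for (k in c(1, 12)) {
    seg_words <- sum(vapply(data$segments[folds$seg_fold == k],
                            function(s) nrow(s$values), integer(1)))
    frac <- 40 / (40 + seg_words)
    expect_gt(frac, 0.03); expect_lt(frac, 0.10)
  }
})

test_that("fold assignment is invariant to segment order", {
  data <- eval_data()
  folds <- make_repetition_folds(data)
  set.seed(121)
  perm <- sample(length(data$segments))
  data2 <- data
  data2$segments <- data$segments[perm]
  folds2 <- make_repetition_folds(data2)
  expect_equal(folds2$seg_fold, folds$seg_fold[perm])
})

test_that("a missing repetition is reported by run and index", {
  data <- eval_data()
  data2 <- data
  drop <- vapply(data2$segments, function(s)
    s$run_id == 2 && s$rep == 5, logical(1))
  data2$segments <- data2$segments[!drop]
  expect_error(make_repetition_folds(data2), "tip pinch.*5")
})

test_that("the affinity sweep covers its grid with valid accuracies", {
  data <- eval_data()
  folds <- make_repetition_folds(data)
  grid <- affinity_sweep(data, folds, n_grid = c(5, 11), w_grid = c(3, 30))
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 100))
  # context helps on well-separated data
  for (n in c(5, 11))
    expect_gte(grid$accuracy[grid$n == n & grid$w == 30],
               grid$accuracy[grid$n == n & grid$w == 3] - 1)
})

test_that("sweep ranges collapse for one subject and span for several", {
  g1 <- data.frame(n = c(5, 5), w = c(3, 30), accuracy = c(70, 80))
  g2 <- data.frame(n = c(5, 5), w = c(3, 30), accuracy = c(75, 78))
  g3 <- data.frame(n = c(5, 5), w = c(3, 30), accuracy = c(72, 85))
  rep3 <- sweep_report(list(g1, g2, g3))
  expect_equal(rep3$low, c(70, 78))
  expect_equal(rep3$high, c(75, 85))
  rep1 <- sweep_report(list(g1))
  expect_equal(rep1$low, rep1$high)
})
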