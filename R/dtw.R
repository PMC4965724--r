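# Banded dynamic time warping over word sequences and 1-NN segment
# classification with prefix-length accuracy curves.

#' Banded DTW distance between two word sequences
#'
#' Dynamic-programming alignment distance with the modified lexical word
#' distance as local cost, symmetric match/insert/delete steps (unweighted),
#' boundary-aligned endpoints, and a Sakoe-Chiba band: aligned positions may
#' differ by at most `band` indices. Cells outside the band are unreachable,
#' so sequences whose lengths differ by more than `band` have no alignment.
#'
#' @param a,b Word sequences: integer rank matrices (rows = words) or
#'   character vectors of letter words.
#' @param band Warping window radius (default 5: total width 11).
#' @return Nonnegative alignment cost (an integer-valued double).
#' @export
#' @examples
#' w <- parse_words(c("AAAAAAAA", "AACCBBEE"))
#' dtw_distance(w, w)  # 0
dtw_distance <- function(a, b, band = 5) {
  a <- rank_matrix(a); b <- rank_matrix(b)
  res <- .dtw_band(a, b, as.integer(band))
  if (is.na(res$distance))
    stop("band ", band, " too narrow: lengths ", nrow(a), " and ", nrow(b),
         " admit no alignment", call. = FALSE)
  res$distance
}

#' Distances of all equal-length prefix comparisons
#'
#' For `q = 1..min(nrow(a), nrow(b))`, the banded DTW distance between
#' `a[1:q, ]` and `b[1:q, ]`. These are the diagonal cells of one dynamic
#' program, so the whole curve costs one pass.
#'
#' @inheritParams dtw_distance
#' @return Numeric vector of length `min(nrow(a), nrow(b))`.
#' @export
dtw_prefix_distances <- function(a, b, band = 5) {
  a <- rank_matrix(a); b <- rank_matrix(b)
  .dtw_band(a, b, as.integer(band))$diag
}

#' Classify one activity segment against a training set
#'
#' Prefix-incremental nearest-neighbor classification: for each prefix length
#' `p = 1..m` (`m` = test segment length), the test prefix — truncated to
#' `min(p, training length)` words — is compared with the equally truncated
#' prefix of every training segment using banded DTW, and the prediction at
#' `p` is the label of the minimal-distance training segment (`k = 1`; ties
#' go to the earliest training segment). `k > 1` uses a majority vote among
#' the `k` nearest, ties resolved toward the nearest neighbor's label.
#'
#' @param test Word sequence of the test segment (matrix of ranks).
#' @param train_words List of training word sequences.
#' @param train_labels Character vector of training segment labels.
#' @param band Warping window radius.
#' @param k Number of neighbors.
#' @return Object of class `prefix_result`: data frame with one row per
#'   prefix length: `prefix`, `pred`, `nn` (index of the nearest training
#'   segment), `distance`.
#' @export
classify_segment <- function(test, train_words, train_labels, band = 5,
                             k = 1) {
  if (length(train_words) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(train_words) == length(train_labels), k >= 1)
  test <- rank_matrix(test)
  m <- nrow(test)
  n_train <- length(train_words)

  # prefix-distance matrix: rows = prefix length p, cols = training segments
  D <- matrix(Inf, m, n_train)
  for (j in seq_len(n_train)) {
    tw <- rank_matrix(train_words[[j]])
    diag_d <- .dtw_band(test, tw, as.integer(band))$diag
    q <- pmin(seq_len(m), nrow(tw))
    D[, j] <- diag_d[q]
  }

  pred <- character(m)
  nn <- integer(m)
  dist <- numeric(m)
  for (p in seq_len(m)) {
    ord <- order(D[p, ], seq_len(n_train))  # ties -> earliest segment
    nn[p] <- ord[1L]
    dist[p] <- D[p, ord[1L]]
    if (k == 1L) {
      pred[p] <- train_labels[ord[1L]]
    } else {
      top <- train_labels[ord[seq_len(min(k, n_train))]]
      tab <- table(top)
      winners <- names(tab)[tab == max(tab)]
      pred[p] <- if (train_labels[ord[1L]] %in% winners)
        train_labels[ord[1L]] else winners[1L]
    }
  }
  structure(data.frame(prefix = seq_len(m), pred = pred, nn = nn,
                       distance = dist, stringsAsFactors = FALSE),
            class = c("prefix_result", "data.frame"))
}

#' Accuracy as a function of word count
#'
#' Given prefix results and true labels for a set of test segments, the curve
#' value at word count `p` is the fraction of segments of length at least `p`
#' whose prediction at prefix `p` is correct.
#'
#' @param results List of [classify_segment()] results.
#' @param truth Character vector of true segment labels.
#' @param max_words Curve length (default 40).
#' @return Data frame with `words`, `accuracy` (percent, `NA` where no
#'   segment is long enough) and `n` (segments contributing).
#' @export
accuracy_by_wordcount <- function(results, truth, max_words = 40) {
  stopifnot(length(results) == length(truth))
  words <- seq_len(max_words)
  acc <- rep(NA_real_, max_words)
  n <- integer(max_words)
  for (p in words) {
    has <- vapply(results, function(r) nrow(r) >= p, logical(1))
    if (!any(has)) next
    ok <- vapply(which(has), function(i) results[[i]]$pred[p] == truth[i],
                 logical(1))
    acc[p] <- 100 * mean(ok)
    n[p] <- sum(has)
  }
  data.frame(words = words, accuracy = acc, n = n)
}
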