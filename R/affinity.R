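# The streaming affinity-matrix classifier: a class-by-word co-occurrence
# model, nearest-word imputation for unseen words, and a temporal summation
# window over per-instance affinity rows.

#' Train an affinity model from labeled words
#'
#' Builds the class-by-word count matrix `A` (`A[a, c]` = number of times
#' word `c` occurs with class `a` in training), its row-normalized form
#' `Abar` (each class row sums to 1) and `Ahat`, which is `Abar` with every
#' column scaled to a unit vector. `Ahat` columns are the per-word class
#' evidence used at classification time.
#'
#' @param words Integer rank matrix (instances x 8) or character words.
#' @param labels Character vector of class codes, one per word.
#' @param classes Class universe and row order (default the canonical 25).
#' @param norm `"l2"` (default) or `"l1"`: the norm used both for `Ahat`
#'   columns and for imputed evidence rows.
#' @return Object of class `affinity_model`.
#' @export
affinity_train <- function(words, labels, classes = activity_codes(),
                           norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  words <- rank_matrix(words)
  labels <- as.character(labels)
  if (nrow(words) != length(labels))
    stop("one label per word required", call. = FALSE)
  check_codes(labels)
  missing <- setdiff(classes, unique(labels))
  if (length(missing) > 0L)
    stop("class(es) absent from training data: ",
         paste(missing, collapse = ", "), call. = FALSE)

  keys <- word_strings(words)
  vocab <- sort(unique(keys))
  A <- table(factor(labels, levels = classes),
             factor(keys, levels = vocab))
  A <- matrix(as.numeric(A), nrow = length(classes),
              dimnames = list(classes, vocab))
  Abar <- A / rowSums(A)
  col_norm <- function(M) {
    s <- if (norm == "l2") sqrt(colSums(M^2)) else colSums(abs(M))
    sweep(M, 2, s, "/")
  }
  Ahat <- col_norm(Abar)

  vocab_mat <- parse_words(vocab)
  structure(
    list(classes = classes, vocab = vocab, vocab_mat = vocab_mat,
         A = A, Abar = Abar, Ahat = Ahat, norm = norm,
         n = attr(words, "n")),
    class = "affinity_model"
  )
}

#' @export
print.affinity_model <- function(x, ...) {
  cat("<affinity_model> ", length(x$classes), " classes x ",
      length(x$vocab), " words (", x$norm, " column norm)\n", sep = "")
  invisible(x)
}

# Internal: evidence row for one word. In-vocabulary words return their Ahat
# column; unseen words get the normalized sum of the Ahat columns of all
# vocabulary words at minimal lexical distance. `cache` (an environment)
# makes repeated unseen words reuse their imputed row.
affinity_row <- function(model, word, cache = NULL) {
  key <- word_strings(matrix(word, nrow = 1L))
  j <- match(key, model$vocab)
  if (!is.na(j))
    return(list(row = model$Ahat[, j], imputed = FALSE, key = key))
  if (!is.null(cache) && !is.null(cache[[key]]))
    return(list(row = cache[[key]], imputed = TRUE, key = key))
  if (length(model$vocab) == 0L) stop("empty vocabulary", call. = FALSE)
  d <- rowSums(abs(sweep(model$vocab_mat, 2, as.integer(word))))
  nearest <- which(d == min(d))
  p <- rowSums(model$Ahat[, nearest, drop = FALSE])
  s <- if (model$norm == "l2") sqrt(sum(p^2)) else sum(abs(p))
  p <- p / s
  if (!is.null(cache)) cache[[key]] <- p
  list(row = p, imputed = TRUE, key = key)
}

#' Evidence row(s) for a word
#'
#' Exposed lookup used by [affinity_classify()]: the word's `Ahat` column if
#' it was seen in training, otherwise the unit-normalized sum of the columns
#' of its nearest vocabulary words under plain lexical distance.
#'
#' @param model An [affinity_train()] model.
#' @param word One word (length-8 ranks or a letter string).
#' @return Numeric class-evidence vector (one value per class).
#' @export
affinity_lookup <- function(model, word) {
  stopifnot(inherits(model, "affinity_model"))
  word <- as.integer(rank_matrix(word))
  affinity_row(model, word)$row
}

#' Classify a word stream with temporal affinity summation
#'
#' Per instance `i`, the evidence row `P[i, ]` is looked up (with nearest-word
#' imputation and per-call caching for unseen words); the summed row
#' `Pbar[i, ]` adds the current row and up to `w` preceding rows (fewer at the
#' start of the stream); the prediction is the class with the largest summed
#' evidence, ties broken toward the lower class index.
#'
#' @param model An [affinity_train()] model.
#' @param words Integer rank matrix or character words, in stream order.
#' @param w Summation window: number of preceding instances added (`w = 0`
#'   reduces to per-instance argmax).
#' @return Object of class `affinity_trace`: list with `pred` (character),
#'   `P`, `Pbar` (instances x classes matrices), `imputed` (logical) and
#'   `keys` (matched word strings).
#' @export
affinity_classify <- function(model, words, w = 30) {
  stopifnot(inherits(model, "affinity_model"), w >= 0)
  words <- rank_matrix(words)
  m <- nrow(words)
  if (m == 0L) stop("empty word stream", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  P <- matrix(0, m, length(model$classes),
              dimnames = list(NULL, model$classes))
  imputed <- logical(m)
  keys <- character(m)
  for (i in seq_len(m)) {
    r <- affinity_row(model, words[i, ], cache)
    P[i, ] <- r$row
    imputed[i] <- r$imputed
    keys[i] <- r$key
  }
  if (w == 0) {
    Pbar <- P  # exact: per-instance argmax, no summation round-off
  } else {
    cs <- rbind(0, apply(P, 2, cumsum))
    lo <- pmax(seq_len(m) - w, 1L)
    Pbar <- cs[seq_len(m) + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  pred <- model$classes[apply(Pbar, 1, which.max)]  # ties -> lowest index
  structure(list(pred = pred, P = P, Pbar = Pbar, imputed = imputed,
                 keys = keys),
            class = "affinity_trace")
}
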