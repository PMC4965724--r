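# Equal-probability symbolization of MAV instances into 8-letter words, and
# the two word distances used by the classifiers.

#' Fit per-channel equal-probability breakpoints
#'
#' For each of the 8 channels, the `n - 1` breakpoints are the empirical
#' quantiles at `k/n`, `k = 1..n-1`, of that channel's training values
#' (inverse-empirical-CDF quantiles, type 1), so each of the `n` symbols is
#' (up to ties) equally probable on the training data.
#'
#' @param x Training data: a `mav_stream`, list of them, or matrix.
#' @param n Alphabet size, 2..26.
#' @return Object of class `sax_codebook`: list with `n` and `breakpoints`
#'   (an `(n-1) x channels` matrix, non-decreasing per column).
#' @export
#' @examples
#' cb <- fit_codebook(matrix(runif(800), 100, 8), n = 5)
#' cb$breakpoints
fit_codebook <- function(x, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n > 26)
    stop("alphabet size n must be an integer in 2..26", call. = FALSE)
  n <- as.integer(n)
  vals <- gather_values(x)
  if (nrow(vals) < n)
    stop("need at least n = ", n, " training instances, got ", nrow(vals),
         call. = FALSE)
  bp <- apply(vals, 2, stats::quantile, probs = seq_len(n - 1L) / n,
              type = 1, names = FALSE)
  bp <- matrix(bp, nrow = n - 1L, dimnames = list(NULL, colnames(vals)))
  structure(list(n = n, breakpoints = bp), class = "sax_codebook")
}

#' @export
print.sax_codebook <- function(x, ...) {
  cat("<sax_codebook> alphabet size ", x$n, ", ", ncol(x$breakpoints),
      " channels\n", sep = "")
  invisible(x)
}

#' Encode MAV instances as symbolic words
#'
#' Each instance becomes one word: per channel, the symbol rank is the number
#' of breakpoints strictly below the value (values equal to a breakpoint fall
#' into the lower interval). Ranks are 0-based integers; rank 0 renders as
#' letter `A`.
#'
#' @param x A `mav_stream` or matrix of instances.
#' @param codebook A [fit_codebook()] object with matching channel count.
#' @return Integer matrix (instances x channels) of symbol ranks in
#'   `0..n-1`, with attribute `"n"`.
#' @export
encode_words <- function(x, codebook) {
  stopifnot(inherits(codebook, "sax_codebook"))
  vals <- gather_values(x)
  if (ncol(vals) != ncol(codebook$breakpoints))
    stop("codebook has ", ncol(codebook$breakpoints),
         " channels but data has ", ncol(vals), call. = FALSE)
  out <- vapply(seq_len(ncol(vals)), function(j)
    findInterval(vals[, j], codebook$breakpoints[, j], left.open = TRUE),
    integer(nrow(vals)))
  out <- matrix(as.integer(out), nrow = nrow(vals))
  attr(out, "n") <- codebook$n
  out
}

#' Render integer-rank words as letter strings
#'
#' @param words Integer matrix of symbol ranks (rows = words).
#' @return Character vector, one string per word (`A` = rank 0).
#' @export
word_strings <- function(words) {
  words <- rank_matrix(words)
  apply(words, 1, function(r) paste(LETTERS[r + 1L], collapse = ""))
}

#' Parse letter-string words back to integer ranks
#'
#' @param strings Character vector of equal-length words in `A`-based letters.
#' @return Integer matrix of symbol ranks.
#' @export
parse_words <- function(strings) {
  lens <- nchar(strings)
  if (length(unique(lens)) > 1L) stop("words must have equal length",
                                      call. = FALSE)
  m <- t(vapply(strsplit(strings, ""), function(ch) {
    r <- match(ch, LETTERS) - 1L
    if (anyNA(r)) stop("invalid symbol in word", call. = FALSE)
    r
  }, integer(lens[1L])))
  m
}

# Internal: coerce a single word (vector/string) or matrix to a rank matrix.
rank_matrix <- function(w) {
  if (is.character(w)) return(parse_words(w))
  if (is.null(dim(w))) w <- matrix(as.integer(w), nrow = 1L)
  storage.mode(w) <- "integer"
  w
}

check_word_pair <- function(a, b) {
  a <- rank_matrix(a); b <- rank_matrix(b)
  if (ncol(a) != 8L || ncol(b) != 8L)
    stop("words must have exactly 8 symbols", call. = FALSE)
  if (nrow(a) != 1L || nrow(b) != 1L)
    stop("supply one word on each side", call. = FALSE)
  list(a = as.integer(a), b = as.integer(b))
}

#' Plain lexical distance between two words
#'
#' The sum over the 8 positions of the absolute symbol-rank difference. Used
#' for nearest-word imputation in the affinity classifier.
#'
#' @param a,b Words: length-8 integer rank vectors or letter strings.
#' @return Nonnegative integer.
#' @export
#' @examples
#' lexical_distance("AAAAAAAA", "BBBBBBBB")  # 8
lexical_distance <- function(a, b) {
  w <- check_word_pair(a, b)
  sum(abs(w$a - w$b))
}

#' Modified lexical distance between two words
#'
#' Per position the cost is 0 for identical symbols and `|rank difference| -
#' 1` otherwise, summed over the 8 positions. Adjacent symbols therefore cost
#' nothing: two values close to a shared bin boundary should not be a full
#' symbol apart. This is the local cost of the DTW segment classifier. Note
#' it is not a metric (distinct words built from adjacent symbols are at
#' distance 0).
#'
#' @param a,b Words: length-8 integer rank vectors or letter strings.
#' @return Nonnegative integer.
#' @export
#' @examples
#' modified_lexical_distance("AAAAAAAA", "AACCBBEE")  # 0+0+1+1+0+0+3+3 = 8
modified_lexical_distance <- function(a, b) {
  w <- check_word_pair(a, b)
  d <- abs(w$a - w$b)
  sum(pmax(d - 1L, 0L))
}
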