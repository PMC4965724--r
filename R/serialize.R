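# JSON serialization of fitted artifacts: SAX codebooks and affinity models.
# Affinity models store the raw count matrix; the normalized forms are
# recomputed on read, so the file stays small and the trained artifact
# immutable (imputed columns are never written back).

#' Save / load a SAX codebook
#'
#' @param codebook A [fit_codebook()] object.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `sax_codebook` (read).
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "sax_codebook"))
  jsonlite::write_json(
    list(n = codebook$n,
         breakpoints = as.data.frame(codebook$breakpoints)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n = as.integer(x$n),
                 breakpoints = as.matrix(x$breakpoints)),
            class = "sax_codebook")
}

#' Save / load an affinity model
#'
#' Only classes, vocabulary and raw counts are stored; `Abar` and `Ahat` are
#' rebuilt on read.
#'
#' @param model An [affinity_train()] model.
#' @param path JSON file path.
#' @return `path` invisibly (write); an `affinity_model` (read).
#' @export
write_affinity_model <- function(model, path) {
  stopifnot(inherits(model, "affinity_model"))
  jsonlite::write_json(
    list(classes = model$classes, vocab = model$vocab,
         counts = as.data.frame(model$A), norm = model$norm,
         n = model$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affinity_model
#' @export
read_affinity_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- as.matrix(x$counts)
  dimnames(A) <- list(x$classes, x$vocab)
  Abar <- A / rowSums(A)
  s <- if (x$norm == "l2") sqrt(colSums(Abar^2)) else colSums(abs(Abar))
  structure(
    list(classes = x$classes, vocab = x$vocab,
         vocab_mat = parse_words(x$vocab), A = A, Abar = Abar,
         Ahat = sweep(Abar, 2, s, "/"), norm = x$norm,
         n = if (is.null(x$n)) NULL else as.integer(x$n)),
    class = "affinity_model"
  )
}

#' Build a subject profile from a plain-text JSON configuration
#'
#' The configuration may name a stock subject (`{"subject": 2}`), override
#' any scalar field of [subject_profile()], or supply a full 25 x 8
#' `amplitudes` matrix (rows in [activity_codes()] order). Unknown fields
#' are rejected.
#'
#' @param path JSON configuration file.
#' @return A [subject_profile()].
#' @export
profile_from_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("subject", "amplitudes", "emg_noise_sd", "amp_cv", "rep_cv",
             "rise_ms", "fall_ms", "acc_transient_g", "acc_noise_sd",
             "jitter_ms")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  amp <- if (!is.null(cfg$amplitudes)) {
    m <- as.matrix(cfg$amplitudes)
    rownames(m) <- activity_codes()
    m
  } else {
    subject_amplitudes(if (is.null(cfg$subject)) 1 else cfg$subject)
  }
  args <- cfg[setdiff(names(cfg), c("subject", "amplitudes"))]
  do.call(subject_profile, c(list(amplitudes = amp), args))
}
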