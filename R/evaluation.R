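# Evaluation harness: the leave-one-repetition-out scheme shared by the
# affinity and DTW classifiers, instance-level metrics, confusion matrices,
# and the parameter-sweep reports.

#' Accuracy, per-class recall and confusion matrix
#'
#' @param pred,truth Character vectors of predicted and true class codes.
#' @param classes Class universe and matrix order.
#' @return List with `accuracy` (percent), `tpr` (per-class recall, percent,
#'   `NA` for classes without test instances) and `confusion` (rows = truth,
#'   columns = prediction).
#' @export
eval_report <- function(pred, truth, classes = activity_codes()) {
  stopifnot(length(pred) == length(truth))
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(truth = classes, pred = classes))
  total <- sum(confusion)
  list(accuracy = 100 * sum(diag(confusion)) / total,
       tpr = 100 * diag(confusion) / rowSums(confusion),
       confusion = confusion)
}

#' Simulate, featurize and label one subject's full session
#'
#' Runs the complete front half of the pipeline for one synthetic subject:
#' eight runs are generated, reduced to MAV streams, labeled from the
#' schedule plus ACC evidence, NR-subsampled, and segmented. Raw signals are
#' discarded run by run to keep memory bounded.
#'
#' @param profile A [subject_profile()].
#' @param seed Master seed (per-run seeds derived as in [generate_dataset()]).
#' @param use_truth_labels If `TRUE`, label instances from the simulator's
#'   ground-truth track instead of the ACC labeling path (oracle mode for
#'   diagnostics).
#' @param nr_window NR retention window passed to [subsample_nr()].
#' @return Object of class `subject_data`: list with `segments` (activity
#'   segments from all runs, rest excluded, each carrying its instance
#'   values), `nr_values` / `nr_runs` (retained rest instances and their
#'   source runs), `instances` / `instance_labels` (the pooled instance-level
#'   dataset: truncated segment instances plus retained NR), and counters.
#' @export
prepare_subject_data <- function(profile, seed, use_truth_labels = FALSE,
                                 nr_window = c(1, 4)) {
  segments <- list()
  nr_values <- list()
  nr_runs <- integer(0)
  fallbacks <- 0L
  for (g in seq_along(action_groups())) {
    schedule <- make_schedule(g)
    run <- generate_run(schedule, profile, seed + g)
    mav <- compute_mav(run)
    if (use_truth_labels) {
      lab <- label_from_truth(mav, run$truth)
    } else {
      acc <- summarize_acc(run)
      lab <- label_run(mav, acc, schedule)
      fallbacks <- fallbacks + attr(lab, "fallbacks")
    }
    rm(run)
    segs <- segment_activities(lab, run_id = g)
    for (s in segs) {
      if (s$code == "NR") next
      s$values <- lab$values[s$idx, , drop = FALSE]
      s$idx <- NULL
      segments[[length(segments) + 1L]] <- s
    }
    sub <- subsample_nr(lab, nr_window)
    keep_nr <- sub$label == "NR"
    nr_values[[g]] <- sub$values[keep_nr, , drop = FALSE]
    nr_runs <- c(nr_runs, rep(g, sum(keep_nr)))
  }
  nr_values <- do.call(rbind, nr_values)
  seg_values <- do.call(rbind, lapply(segments, `[[`, "values"))
  seg_labels <- unlist(lapply(segments, function(s)
    rep(s$code, nrow(s$values))))
  structure(
    list(segments = segments,
         nr_values = nr_values, nr_runs = nr_runs,
         instances = rbind(seg_values, nr_values),
         instance_labels = c(seg_labels,
                             rep("NR", nrow(nr_values))),
         fallbacks = fallbacks, seed = seed),
    class = "subject_data"
  )
}

# Internal: oracle labeling straight from a ground-truth interval track.
label_from_truth <- function(mav, truth) {
  lab <- rep("NR", length(mav$time))
  for (i in seq_len(nrow(truth))) {
    sel <- mav$time >= truth$onset[i] & mav$time < truth$offset[i]
    lab[sel] <- truth$code[i]
  }
  mav$label <- lab
  attr(mav, "fallbacks") <- 0L
  mav
}

#' @export
print.subject_data <- function(x, ...) {
  cat("<subject_data> ", length(x$segments), " activity segments, ",
      nrow(x$nr_values), " retained NR instances, ",
      nrow(x$instances), " instances total (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Leave-one-repetition-out folds
#'
#' Twelve folds: fold `k` tests on the `k`-th repetition's segments from all
#' eight runs. The retained run-start NR instances (60 per run, 480 total)
#' are partitioned sequentially into twelve disjoint 40-instance chunks, one
#' per fold, so rest is represented (about 6 % of a fold) in every split and
#' folds stay disjoint.
#'
#' @param data A [prepare_subject_data()] object.
#' @return Object of class `repetition_folds`: list with `n_folds`,
#'   `seg_fold` (fold of each segment) and `nr_fold` (fold of each retained
#'   NR instance).
#' @export
make_repetition_folds <- function(data) {
  stopifnot(inherits(data, "subject_data"))
  reps <- vapply(data$segments, `[[`, integer(1), "rep")
  runs <- vapply(data$segments, `[[`, integer(1), "run_id")
  for (g in unique(runs)) {
    present <- sort(unique(reps[runs == g]))
    miss <- setdiff(1:12, present)
    if (length(miss) > 0L)
      stop("run ", g, " (", action_groups()[g],
           ") is missing repetition(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  n_nr <- nrow(data$nr_values)
  nr_fold <- as.integer(ceiling(seq_len(n_nr) / (n_nr / 12)))
  nr_fold <- pmin(nr_fold, 12L)
  structure(list(n_folds = 12L, seg_fold = reps, nr_fold = nr_fold),
            class = "repetition_folds")
}

# Internal: assemble train/test material for fold k. Segments are ordered by
# run then time, so a fold's test stream follows the collection order.
fold_split <- function(data, folds, k) {
  te_seg <- which(folds$seg_fold == k)
  tr_seg <- which(folds$seg_fold != k)
  ord <- function(ids) {
    runs <- vapply(data$segments[ids], `[[`, integer(1), "run_id")
    starts <- vapply(data$segments[ids], `[[`, numeric(1), "start")
    ids[order(runs, starts)]
  }
  list(train_seg = ord(tr_seg), test_seg = ord(te_seg),
       train_nr = which(folds$nr_fold != k),
       test_nr = which(folds$nr_fold == k))
}

# Internal: per-activity-sequence view of a fold's material: one value
# matrix per sequence (the NR chunk first, then each segment), plus the
# word-level label vector over all sequences.
fold_sequences <- function(data, seg_ids, nr_ids) {
  values <- c(
    if (length(nr_ids) > 0L) list(data$nr_values[nr_ids, , drop = FALSE]),
    lapply(data$segments[seg_ids], `[[`, "values"))
  labels <- c(rep("NR", length(nr_ids)),
              unlist(lapply(data$segments[seg_ids], function(s)
                rep(s$code, nrow(s$values)))))
  list(values = values, labels = labels)
}

# Internal: instance matrix + labels for a set of segments and NR rows.
fold_instances <- function(data, seg_ids, nr_ids) {
  vals <- do.call(rbind, c(
    list(data$nr_values[nr_ids, , drop = FALSE]),
    lapply(data$segments[seg_ids], `[[`, "values")))
  labs <- c(rep("NR", length(nr_ids)),
            unlist(lapply(data$segments[seg_ids], function(s)
              rep(s$code, nrow(s$values)))))
  list(values = vals, labels = labs)
}

#' Evaluate the affinity classifier with leave-one-repetition-out folds
#'
#' Per fold, a SAX codebook is fitted on the training instances, an affinity
#' model is trained on their words, and every test activity sequence (each
#' segment, plus the fold's NR chunk) is classified word by word with
#' summation window `w`; the summation window runs within one activity
#' sequence and resets at its start, mirroring how the affinity stream is
#' consumed one labeled activity at a time. Fold accuracies (over all test
#' words) are averaged; confusion matrices are summed.
#'
#' @param data A [prepare_subject_data()] object.
#' @param folds A [make_repetition_folds()] object.
#' @param n SAX alphabet size.
#' @param w Affinity summation window.
#' @return List with `accuracy` (mean fold accuracy, percent),
#'   `fold_accuracy`, `tpr`, `confusion`.
#' @export
evaluate_affinity <- function(data, folds, n = 11, w = 30) {
  fold_acc <- numeric(folds$n_folds)
  confusion <- NULL
  for (k in seq_len(folds$n_folds)) {
    sp <- fold_split(data, folds, k)
    tr <- fold_instances(data, sp$train_seg, sp$train_nr)
    cb <- fit_codebook(tr$values, n)
    model <- affinity_train(encode_words(tr$values, cb), tr$labels)
    te <- fold_sequences(data, sp$test_seg, sp$test_nr)
    pred <- unlist(lapply(te$values, function(v)
      affinity_classify(model, encode_words(v, cb), w)$pred))
    rep_k <- eval_report(pred, te$labels)
    fold_acc[k] <- rep_k$accuracy
    confusion <- if (is.null(confusion)) rep_k$confusion else
      confusion + rep_k$confusion
  }
  list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       tpr = 100 * diag(confusion) / rowSums(confusion),
       confusion = confusion, n = n, w = w)
}

#' Evaluate the DTW segment classifier with leave-one-repetition-out folds
#'
#' Per fold, training and test segments are encoded with a codebook fitted on
#' the training instances; each fold's NR chunk forms one additional
#' (up to 40-word) rest segment on each side. Every test segment is
#' classified at all prefix lengths; fold accuracy is scored at prefix
#' `min(prefix_words, segment length)` and the full accuracy-by-word-count
#' curve is pooled over folds.
#'
#' @param data A [prepare_subject_data()] object.
#' @param folds A [make_repetition_folds()] object.
#' @param n SAX alphabet size.
#' @param band Warping window radius.
#' @param prefix_words Word count at which fold accuracy is scored.
#' @param k Neighbors for the K-NN vote.
#' @return List with `accuracy`, `fold_accuracy`, `curve` (accuracy by word
#'   count, pooled), `tpr`, `confusion`.
#' @export
evaluate_dtw <- function(data, folds, n = 15, band = 5, prefix_words = 20,
                         k = 1) {
  fold_acc <- numeric(folds$n_folds)
  confusion <- NULL
  all_results <- list()
  all_truth <- character(0)
  max_len <- 40L
  for (kk in seq_len(folds$n_folds)) {
    sp <- fold_split(data, folds, kk)
    tr <- fold_instances(data, sp$train_seg, sp$train_nr)
    cb <- fit_codebook(tr$values, n)

    nr_seg_words <- function(nr_ids) {
      v <- data$nr_values[nr_ids, , drop = FALSE]
      if (nrow(v) == 0L) return(NULL)
      encode_words(utils::head(v, max_len), cb)
    }
    train_words <- c(
      lapply(data$segments[sp$train_seg], function(s)
        encode_words(s$values, cb)),
      Filter(Negate(is.null), list(nr_seg_words(sp$train_nr))))
    train_labels <- c(
      vapply(data$segments[sp$train_seg], `[[`, character(1), "code"),
      if (length(sp$train_nr) > 0L) "NR")

    test_words <- c(
      lapply(data$segments[sp$test_seg], function(s)
        encode_words(s$values, cb)),
      Filter(Negate(is.null), list(nr_seg_words(sp$test_nr))))
    test_labels <- c(
      vapply(data$segments[sp$test_seg], `[[`, character(1), "code"),
      if (length(sp$test_nr) > 0L) "NR")

    res <- lapply(test_words, classify_segment, train_words = train_words,
                  train_labels = train_labels, band = band, k = k)
    at_prefix <- vapply(seq_along(res), function(i) {
      p <- min(prefix_words, nrow(res[[i]]))
      res[[i]]$pred[p]
    }, character(1))
    rep_k <- eval_report(at_prefix, test_labels)
    fold_acc[kk] <- rep_k$accuracy
    confusion <- if (is.null(confusion)) rep_k$confusion else
      confusion + rep_k$confusion
    all_results <- c(all_results, res)
    all_truth <- c(all_truth, test_labels)
  }
  list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       curve = accuracy_by_wordcount(all_results, all_truth),
       tpr = 100 * diag(confusion) / rowSums(confusion),
       confusion = confusion, n = n, band = band,
       prefix_words = prefix_words)
}

#' Sweep the affinity classifier over alphabet sizes and window lengths
#'
#' @param data A [prepare_subject_data()] object.
#' @param folds A [make_repetition_folds()] object.
#' @param n_grid,w_grid Parameter grids.
#' @return Data frame with one row per `(n, w)` cell: mean fold accuracy.
#' @export
affinity_sweep <- function(data, folds, n_grid = c(5, 7, 9, 11, 15),
                           w_grid = c(3, 5, 10, 15, 30)) {
  grid <- expand.grid(n = n_grid, w = w_grid)
  grid$accuracy <- NA_real_
  # reuse per-n fold models across w values
  for (n in n_grid) {
    per_fold <- vector("list", folds$n_folds)
    for (k in seq_len(folds$n_folds)) {
      sp <- fold_split(data, folds, k)
      tr <- fold_instances(data, sp$train_seg, sp$train_nr)
      cb <- fit_codebook(tr$values, n)
      model <- affinity_train(encode_words(tr$values, cb), tr$labels)
      te <- fold_sequences(data, sp$test_seg, sp$test_nr)
      per_fold[[k]] <- list(model = model,
                            words = lapply(te$values, encode_words, cb),
                            labels = te$labels)
    }
    for (w in w_grid) {
      accs <- vapply(per_fold, function(f) {
        pred <- unlist(lapply(f$words, function(ws)
          affinity_classify(f$model, ws, w)$pred))
        mean(pred == f$labels)
      }, numeric(1))
      grid$accuracy[grid$n == n & grid$w == w] <- 100 * mean(accs)
    }
  }
  grid
}

#' Range table across synthetic subjects
#'
#' Reshapes sweep results from several subject profiles into the low-high
#' range per parameter cell, the form in which multi-subject sweeps are
#' conventionally reported.
#'
#' @param sweeps List of [affinity_sweep()] (or similarly shaped) data
#'   frames, one per subject.
#' @return Data frame with the grid columns plus `low` and `high` (percent).
#' @export
sweep_report <- function(sweeps) {
  stopifnot(length(sweeps) >= 1L)
  base <- sweeps[[1L]][, setdiff(names(sweeps[[1L]]), "accuracy"),
                       drop = FALSE]
  accs <- vapply(sweeps, `[[`, numeric(nrow(base)), "accuracy")
  accs <- matrix(accs, nrow = nrow(base))
  base$low <- apply(accs, 1, min)
  base$high <- apply(accs, 1, max)
  base
}
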