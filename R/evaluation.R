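# Leave-one-subject-out evaluation: folds, accuracy, t-based 95% confidence
# intervals, and group summaries.

#' Leave-one-subject-out folds
#'
#' One fold per subject (lexicographic id order): the held-out subject is the
#' test set, all remaining subjects' samples form the class-grouped training
#' set. A training fold missing a class is an error.
#'
#' @param ds a [feature_dataset] with >= 2 subjects
#' @return list of folds: `train` ([training_set]), `test` (subject record),
#'   `subject_id`
#' @export
loso_folds <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  if (length(ds$subjects) < 2L) stopf("LOSO needs at least 2 subjects")
  lapply(seq_along(ds$subjects), function(i) {
    rest <- ds$subjects[-i]
    X <- do.call(cbind, lapply(rest, function(s) s$X))
    labels <- unlist(lapply(rest, function(s) s$labels))
    missing <- setdiff(seq_len(ds$K), unique(labels))
    if (length(missing) > 0L) {
      stopf("training fold for held-out subject %s lacks class %d",
            ds$subjects[[i]]$subject_id, missing[1])
    }
    list(train = training_set(X, labels, ds$K),
         test = ds$subjects[[i]],
         subject_id = ds$subjects[[i]]$subject_id)
  })
}

#' Classification accuracy
#'
#' @param pred predicted labels
#' @param truth true labels, same length
#' @return fraction of matches in `[0, 1]`
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("length mismatch")
  if (length(pred) == 0L) stopf("cannot score an empty prediction")
  mean(pred == truth)
}

#' Student-t 95% confidence interval for a set of per-subject accuracies
#'
#' `mean +/- t_{0.975, n-1} sd / sqrt(n)`, clipped to `[0, 1]`.
#'
#' @param accs numeric vector, length >= 2
#' @return `c(lo, hi)`
#' @export
ci95 <- function(accs) {
  n <- length(accs)
  if (n < 2L) stopf("ci95 needs at least 2 values")
  m <- mean(accs)
  hw <- stats::qt(0.975, n - 1L) * stats::sd(accs) / sqrt(n)
  c(lo = max(0, m - hw), hi = min(1, m + hw))
}

#' Run the full leave-one-subject-out protocol
#'
#' For each fold a PDPL model is trained on the remaining subjects and scored
#' on the held-out one. Deterministic given dataset, params and the seed
#' inside `params`.
#'
#' @param ds a [feature_dataset]
#' @param params a [pdpl_params]
#' @param on_error `"stop"` (default) propagates a fold failure with subject
#'   context; `"zero"` scores the fold 0 with a warning (used by the GA so a
#'   pathological parameter set cannot abort the search)
#' @return object of class `loso_result`: `per_subject` (named accuracies),
#'   `mean`, `sd`, `sem`, `ci95`
#' @export
run_loso <- function(ds, params = pdpl_params(), on_error = c("stop", "zero")) {
  on_error <- match.arg(on_error)
  folds <- loso_folds(ds)
  accs <- vapply(folds, function(fold) {
    r <- tryCatch({
      model <- pdpl_train(fold$train, params)
      accuracy(predict_batch(model, fold$test$X), fold$test$labels)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      if (on_error == "stop") {
        stopf("fold for subject %s failed: %s", fold$subject_id,
              conditionMessage(r))
      }
      warnf("fold for subject %s failed (scored 0): %s", fold$subject_id,
            conditionMessage(r))
      r <- 0
    }
    r
  }, 0)
  names(accs) <- vapply(folds, function(f) f$subject_id, "")
  structure(list(per_subject = accs,
                 mean = mean(accs),
                 sd = stats::sd(accs),
                 sem = stats::sd(accs) / sqrt(length(accs)),
                 ci95 = ci95(accs)),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("LOSO over %d subjects: mean accuracy %.4f (sd %.4f, sem %.4f), 95%% CI [%.4f, %.4f]\n",
              length(x$per_subject), x$mean, x$sd, x$sem,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Summarize per-subject accuracies by group tag
#'
#' @param result a `loso_result`
#' @param groups named character vector mapping subject id to tag (e.g. sex)
#' @return data.frame with one row per tag: `n`, `mean`, `sd`
#' @export
summarize_by_group <- function(result, groups) {
  ids <- names(result$per_subject)
  unknown <- setdiff(ids, names(groups))
  if (length(unknown) > 0L) {
    stopf("no group tag for subject(s): %s", paste(unknown, collapse = ", "))
  }
  tags <- groups[ids]
  out <- do.call(rbind, lapply(sort(unique(tags)), function(tg) {
    a <- result$per_subject[tags == tg]
    data.frame(group = tg, n = length(a), mean = mean(a),
               sd = if (length(a) > 1L) stats::sd(a) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
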