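# Shared data containers: the multi-subject feature dataset every stage
# consumes, and the class-grouped training set PDPL trains on.

#' Assemble a multi-subject feature dataset
#'
#' @param subjects list of records, each with `subject_id`, `X` (features x
#'   samples matrix), `labels` (integer vector in 1..K) and optionally `sex`
#' @param K number of classes (default: max label seen)
#' @param feature_index optional data.frame describing feature rows
#' @return an object of class `feature_dataset`
#' @export
feature_dataset <- function(subjects, K = NULL, feature_index = NULL) {
  if (length(subjects) < 1L) stopf("need at least one subject")
  ids <- vapply(subjects, function(s) as.character(s$subject_id), "")
  if (anyDuplicated(ids)) stopf("duplicate subject ids")
  p <- nrow(subjects[[1]]$X)
  for (s in subjects) {
    check_matrix(s$X, sprintf("subject %s features", s$subject_id))
    if (nrow(s$X) != p) stopf("inconsistent feature dimension across subjects")
    if (length(s$labels) != ncol(s$X)) {
      stopf("subject %s: %d labels for %d samples",
            s$subject_id, length(s$labels), ncol(s$X))
    }
    if (any(s$labels < 1L | s$labels != floor(s$labels))) {
      stopf("subject %s: labels must be integers >= 1", s$subject_id)
    }
  }
  if (is.null(K)) K <- max(unlist(lapply(subjects, function(s) s$labels)))
  # stable lexicographic subject order so fold numbering is machine-independent
  subjects <- subjects[order(ids, method = "radix")]
  structure(list(subjects = subjects, p = p, K = as.integer(K),
                 feature_index = feature_index),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  n <- vapply(x$subjects, function(s) ncol(s$X), 0L)
  cat(sprintf("feature_dataset: %d subjects, p=%d features, K=%d classes, %d samples total\n",
              length(x$subjects), x$p, x$K, sum(n)))
  invisible(x)
}

#' Restrict a dataset to a subset of subjects
#'
#' Useful for nested (leakage-free) hyperparameter searches: run the GA on
#' training subjects only, then evaluate once on the held-out ones. The
#' default fitness deliberately spans all provided subjects, matching the
#' protocol the method was described with.
#'
#' @param ds a [feature_dataset]
#' @param ids subject ids to keep
#' @return a [feature_dataset] containing only `ids`
#' @export
subset_subjects <- function(ds, ids) {
  stopifnot(inherits(ds, "feature_dataset"))
  have <- vapply(ds$subjects, function(s) s$subject_id, "")
  missing <- setdiff(ids, have)
  if (length(missing) > 0L) {
    stopf("unknown subject id(s): %s", paste(missing, collapse = ", "))
  }
  feature_dataset(ds$subjects[have %in% ids], K = ds$K,
                  feature_index = ds$feature_index)
}

#' Group samples by class into a PDPL training set
#'
#' @param X features x samples matrix
#' @param labels integer labels, one per column
#' @param K class count (labels must cover a subset of 1..K)
#' @return an object of class `training_set`: list of `F_blocks` (one p x n_k
#'   matrix per class), `K`, `p`
#' @export
training_set <- function(X, labels, K = max(labels)) {
  check_matrix(X, "training matrix")
  if (length(labels) != ncol(X)) stopf("one label per column required")
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    cols <- which(labels == k)
    if (length(cols) == 0L) {
      stopf("class %d has no training samples", k)
    }
    blocks[[k]] <- X[, cols, drop = FALSE]
  }
  structure(list(F_blocks = blocks, K = as.integer(K), p = nrow(X)),
            class = "training_set")
}

# Complement blocks: for each class k, all training columns not in class k.
complement_blocks <- function(F) {
  lapply(seq_len(F$K), function(k) {
    do.call(cbind, F$F_blocks[-k])
  })
}
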