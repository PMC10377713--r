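# On-disk formats. Everything is plain text: tab-separated numeric matrices,
# one directory per subject, a JSON manifest at the top level; models are a
# single JSON archive with a format-version tag.

DATASET_FORMAT_VERSION <- "1.0"
MODEL_FORMAT_VERSION <- "1.0"

#' Write a feature dataset to a directory
#'
#' Layout: `manifest.json` (p, K, subject ids, optional sex tags, feature
#' index, format version) plus one `subjects/<id>/` directory per subject
#' containing `X.tsv` (features x samples) and `labels.txt`.
#'
#' @param ds a [feature_dataset]
#' @param dir target directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "feature_dataset"))
  dir.create(file.path(dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  ids <- vapply(ds$subjects, function(s) s$subject_id, "")
  sex <- vapply(ds$subjects, function(s) {
    if (is.null(s$sex)) NA_character_ else as.character(s$sex)
  }, "")
  manifest <- list(format_version = DATASET_FORMAT_VERSION,
                   p = ds$p, K = ds$K, subjects = ids, sex = sex,
                   feature_index = ds$feature_index)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  for (s in ds$subjects) {
    sdir <- file.path(dir, "subjects", s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    utils::write.table(s$X, file.path(sdir, "X.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    writeLines(as.character(s$labels), file.path(sdir, "labels.txt"))
  }
  invisible(dir)
}

#' Read a feature dataset written by [write_dataset()]
#'
#' @param dir dataset directory
#' @return a [feature_dataset]
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json under %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  subjects <- lapply(seq_along(manifest$subjects), function(i) {
    id <- manifest$subjects[i]
    sdir <- file.path(dir, "subjects", id)
    X <- as.matrix(utils::read.table(file.path(sdir, "X.tsv"), sep = "\t"))
    dimnames(X) <- NULL
    labels <- as.integer(readLines(file.path(sdir, "labels.txt")))
    sex <- if (!is.null(manifest$sex)) manifest$sex[i] else NA_character_
    list(subject_id = id, X = X, labels = labels, sex = sex)
  })
  fi <- manifest$feature_index
  if (!is.null(fi) && length(fi) > 0) fi <- as.data.frame(fi) else fi <- NULL
  feature_dataset(subjects, K = manifest$K, feature_index = fi)
}

#' Serialize a trained PDPL model to JSON
#'
#' @param model a `pdpl_model`
#' @param path target file
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pdpl_model"))
  obj <- list(format_version = MODEL_FORMAT_VERSION,
              p = model$p, K = model$K,
              D_blocks = model$D_blocks, P_blocks = model$P_blocks,
              params = unclass(model$params),
              energy_trace = model$energy_trace,
              converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a PDPL model saved by [save_model()]
#'
#' Validates shapes and the unit-atom-norm invariant on read.
#'
#' @param path JSON model file
#' @return a `pdpl_model`
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version)) stopf("not a model archive: %s", path)
  take_block <- function(B, k, nr) {
    M <- if (is.list(B)) B[[k]] else array(B[k, , ], dim = dim(B)[2:3])
    matrix(as.numeric(M), nrow = nr)
  }
  m <- obj$params$m
  D <- lapply(seq_len(obj$K), function(k) take_block(obj$D_blocks, k, obj$p))
  P <- lapply(seq_len(obj$K), function(k) take_block(obj$P_blocks, k, m))
  for (k in seq_len(obj$K)) {
    if (nrow(D[[k]]) != obj$p || ncol(P[[k]]) != obj$p) {
      stopf("model block %d has inconsistent shape", k)
    }
    if (max(colSums(D[[k]]^2)) > 1 + 1e-9) {
      stopf("model block %d violates the unit-atom-norm constraint", k)
    }
  }
  pp <- obj$params
  params <- pdpl_params(m = pp$m, tau = pp$tau, lam = pp$lam, gam = pp$gam,
                        outer_tol = pp$outer_tol, max_outer = pp$max_outer,
                        inner_tol = pp$inner_tol, max_inner = pp$max_inner,
                        rho = pp$rho, rho_adapt = pp$rho_adapt,
                        rho_factor = pp$rho_factor, seed = pp$seed)
  structure(list(D_blocks = D, P_blocks = P, params = params,
                 energy_trace = obj$energy_trace,
                 converged = obj$converged, p = obj$p, K = obj$K),
            class = "pdpl_model")
}

#' Read raw trials from a directory
#'
#' Expects `manifest.tsv` with columns `file`, `subject`, `label`, `fs`;
#' each `file` is a tab-separated channels x samples matrix.
#'
#' @param dir trial directory
#' @return list of [raw_trial]
#' @export
read_raw_trials <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stopf("no manifest.tsv under %s", dir)
  man <- utils::read.table(mf, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    M <- as.matrix(utils::read.table(file.path(dir, man$file[i]), sep = "\t"))
    dimnames(M) <- NULL
    raw_trial(M, man$fs[i], man$subject[i], man$label[i])
  })
}

#' Write raw trials plus manifest
#'
#' @param trials list of [raw_trial]
#' @param dir target directory
#' @return `dir`, invisibly
#' @export
write_raw_trials <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    fn <- sprintf("trial%03d.tsv", i)
    utils::write.table(tr$data, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    data.frame(file = fn, subject = tr$subject_id, label = tr$label,
               fs = tr$fs, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
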