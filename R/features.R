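# Log-spectral-power EEG features: band-pass each channel (order-8 zero-phase
# Butterworth), take the RMS over non-overlapping 1 s windows, then the log.

#' Construct a raw multichannel EEG trial
#'
#' @param data channels x samples numeric matrix
#' @param fs sampling rate in Hz
#' @param subject_id subject identifier
#' @param label integer class label (1..K)
#' @return an object of class `raw_trial`
#' @export
raw_trial <- function(data, fs, subject_id, label) {
  check_matrix(data, "trial data")
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0)) stopf("fs must be > 0")
  if (ncol(data) < fs) {
    stopf("trial needs at least one full 1 s window: %d samples < fs=%g",
          ncol(data), fs)
  }
  if (!is_count(label)) stopf("label must be a positive integer")
  structure(list(data = data, fs = fs,
                 subject_id = as.character(subject_id),
                 label = as.integer(label)),
            class = "raw_trial")
}

#' Log-RMS over non-overlapping 1 s windows
#'
#' Trailing partial windows are discarded; a zero-power window is floored at
#' `eps` before the log so silent channels never produce -Inf.
#'
#' @param signal numeric vector, length >= `fs`
#' @param fs sampling rate in Hz (samples per window)
#' @param log_base base of the logarithm (default natural)
#' @param eps RMS floor (default 1e-12)
#' @return one value per complete window
#' @export
window_log_rms <- function(signal, fs, log_base = exp(1), eps = 1e-12) {
  spw <- as.integer(round(fs))
  if (length(signal) < spw) {
    stopf("signal shorter than one window: %d < %d", length(signal), spw)
  }
  nw <- length(signal) %/% spw
  w <- matrix(signal[seq_len(nw * spw)], nrow = spw)
  rms <- sqrt(colMeans(w * w))
  log(pmax(rms, eps), base = log_base)
}

#' Extract log-spectral-power features from a trial
#'
#' For every (band, channel) pair the channel is band-pass filtered with an
#' order-8 zero-phase Butterworth design and reduced to per-window log-RMS
#' values. Rows are ordered band-major (all channels of band 1, then band 2,
#' ...); every window inherits the trial label. Bands that do not survive
#' Nyquist clipping at the trial's sampling rate are dropped with a warning.
#'
#' @param trial a [raw_trial]
#' @param bands list of [band_spec] (default [default_bands()])
#' @param log_base base of the logarithm (default natural)
#' @param order filter order (default 8)
#' @return an object of class `feature_matrix`: list with `values`
#'   ((bands x channels) x windows matrix), `feature_index` (data.frame of
#'   band/channel per row), `subject_id`, `labels`
#' @export
extract_log_spectral_power <- function(trial, bands = default_bands(),
                                       log_base = exp(1), order = 8L) {
  stopifnot(inherits(trial, "raw_trial"))
  filts <- list()
  kept <- list()
  for (b in bands) {
    f <- tryCatch(suppressMessages(design_bandpass(b, trial$fs, order)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warnf("dropping band '%s' for subject %s: %s",
            b$name, trial$subject_id, conditionMessage(f))
    } else {
      filts[[length(filts) + 1L]] <- f
      kept[[length(kept) + 1L]] <- b
    }
  }
  if (length(kept) == 0L) {
    stopf("no band survives Nyquist clipping at fs=%g Hz", trial$fs)
  }
  nch <- nrow(trial$data)
  nw <- ncol(trial$data) %/% as.integer(round(trial$fs))
  vals <- matrix(NA_real_, nrow = length(kept) * nch, ncol = nw)
  idx_band <- character(length(kept) * nch)
  idx_chan <- integer(length(kept) * nch)
  row <- 0L
  for (bi in seq_along(kept)) {
    for (ch in seq_len(nch)) {
      row <- row + 1L
      y <- tryCatch(
        zero_phase_filter(trial$data[ch, ], filts[[bi]]),
        error = function(e) stopf("band '%s', channel %d: %s",
                                  kept[[bi]]$name, ch, conditionMessage(e)))
      vals[row, ] <- window_log_rms(y, trial$fs, log_base = log_base)
      idx_band[row] <- kept[[bi]]$name
      idx_chan[row] <- ch
    }
  }
  structure(list(
    values = vals,
    feature_index = data.frame(band = idx_band, channel = idx_chan,
                               stringsAsFactors = FALSE),
    subject_id = trial$subject_id,
    labels = rep(trial$label, nw)
  ), class = "feature_matrix")
}

#' Extract features from many trials and assemble a per-subject dataset
#'
#' Trials of the same subject are concatenated column-wise (windows) in the
#' order given.
#'
#' @param trials list of [raw_trial]
#' @param ... passed to [extract_log_spectral_power()]
#' @return a `feature_dataset` (see [feature_dataset()])
#' @export
extract_dataset <- function(trials, ...) {
  fms <- lapply(trials, extract_log_spectral_power, ...)
  ids <- vapply(fms, function(f) f$subject_id, "")
  subjects <- lapply(sort(unique(ids)), function(id) {
    part <- fms[ids == id]
    list(subject_id = id,
         X = do.call(cbind, lapply(part, function(f) f$values)),
         labels = unlist(lapply(part, function(f) f$labels)),
         sex = NA_character_)
  })
  K <- max(unlist(lapply(subjects, function(s) s$labels)))
  feature_dataset(subjects, K = K, feature_index = fms[[1]]$feature_index)
}
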