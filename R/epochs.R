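#' Epoched multichannel EEG
#'
#' The universal data container of the toolkit: a 3-D array of epoched trials
#' together with integer class labels, the sampling rate and electrode names.
#' Labels are 0-based internally (class indices in `[0, n_classes)`),
#' regardless of how a source file encodes them; readers translate.
#'
#' @param data numeric 3-D array `[n_trials x n_channels x n_samples]`.
#' @param labels integer vector, one 0-based class index per trial.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of electrode labels (defaults to
#'   `ch1..chN`).
#' @param subject_id opaque subject identifier.
#' @param n_classes number of stimulus classes; defaults to `max(labels) + 1`.
#' @return an object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, labels, fs, channel_names = NULL,
                        subject_id = NA_character_, n_classes = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [trials x channels x samples]")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  labels <- as.integer(labels)
  n_t <- dim(data)[1L]; n_c <- dim(data)[2L]; n_s <- dim(data)[3L]
  if (length(labels) != n_t)
    stop(sprintf("length(labels) == %d but data has %d trials",
                 length(labels), n_t))
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (any(labels < 0L) || any(labels >= n_classes))
    stop(sprintf("labels must lie in [0, %d)", n_classes))
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_c))
  if (length(channel_names) != n_c)
    stop("length(channel_names) must equal the channel dimension of `data`")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = subject_id, n_classes = n_classes),
    class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epoched_eeg: %d trials x %d channels x %d samples @ %g Hz, %d classes\n",
    d[1], d[2], d[3], x$fs, x$n_classes))
  invisible(x)
}

#' Number of trials / channels / samples of an epoched set
#' @param e an `epoched_eeg` object.
#' @return integer count.
#' @export
n_trials <- function(e) dim(e$data)[1L]

#' @rdname n_trials
#' @export
n_channels <- function(e) dim(e$data)[2L]

#' @rdname n_trials
#' @export
n_samples <- function(e) dim(e$data)[3L]

#' Band-pass filter specification
#'
#' Describes a Chebyshev type-I band-pass filter. Defaults follow common
#' SSVEP practice: order 4, 0.5 dB passband ripple, applied forward-backward
#' (zero phase) so that epoch templates are not delayed by filtering.
#'
#' @param low_hz,high_hz passband edges in Hz (`0 < low_hz < high_hz`).
#' @param order filter order.
#' @param ripple_db passband ripple in dB.
#' @param zero_phase apply forward-backward (`filtfilt`) when `TRUE`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 4L, ripple_db = 0.5,
                        zero_phase = TRUE) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 ripple_db = ripple_db, zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Design the Chebyshev-I filter for a given sampling rate.
design_cheby <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$high_hz >= nyq)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 spec$high_hz, nyq))
  signal::cheby1(spec$order, spec$ripple_db,
                 W = c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
}

#' Band-pass filter every trial and channel
#'
#' Each channel of each trial is filtered identically; the array shape is
#' unchanged. With `zero_phase = TRUE` the filter is run forward and backward
#' (`signal::filtfilt`), doubling the effective order and cancelling phase
#' delay.
#'
#' @param e an `epoched_eeg`.
#' @param spec a [filter_spec()].
#' @return a filtered `epoched_eeg`.
#' @export
bandpass <- function(e, spec) {
  stopifnot(inherits(e, "epoched_eeg"), inherits(spec, "filter_spec"))
  filt <- design_cheby(spec, e$fs)
  out <- e$data
  nt <- n_trials(e); nc <- n_channels(e)
  for (i in seq_len(nt)) {
    for (j in seq_len(nc)) {
      x <- e$data[i, j, ]
      out[i, j, ] <- if (spec$zero_phase) signal::filtfilt(filt, x)
                     else signal::filter(filt, x)
    }
  }
  e$data <- out
  e
}

#' Magnitude response of a filter specification
#'
#' Evaluates |H(f)| of the designed filter at the requested frequencies;
#' for zero-phase application the forward-backward magnitude |H(f)|^2 is
#' returned. Used as the independent oracle for attenuation checks.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @param freqs_hz frequencies at which to evaluate.
#' @return numeric vector of linear magnitude gains.
#' @export
filter_response <- function(spec, fs, freqs_hz) {
  filt <- design_cheby(spec, fs)
  w <- 2 * pi * freqs_hz / fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(filt$b * zz^(-(seq_along(filt$b) - 1))),
                complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(-(seq_along(filt$a) - 1))),
                complex(1))
  h <- Mod(num / den)
  if (spec$zero_phase) h^2 else h
}

#' Select and reorder channels
#'
#' Channels are matched case-insensitively and returned in the requested
#' order.
#'
#' @param e an `epoched_eeg`.
#' @param names channel labels to keep.
#' @return an `epoched_eeg` with `length(names)` channels.
#' @export
select_channels <- function(e, names) {
  stopifnot(inherits(e, "epoched_eeg"))
  idx <- match(tolower(names), tolower(e$channel_names))
  if (anyNA(idx)) {
    missing <- names[is.na(idx)]
    stop(sprintf("channel(s) not found: %s", paste(missing, collapse = ", ")))
  }
  e$data <- e$data[, idx, , drop = FALSE]
  e$channel_names <- e$channel_names[idx]
  e
}

#' Crop a time window out of every trial
#'
#' Windows are half-open and 0-based in time: the crop keeps samples
#' `floor(t_start*fs) .. floor(t_start*fs) + floor(t_len*fs) - 1` (R indices
#' shifted by one), so a fractional window length rounds down
#' (`N_s = floor(t_len * fs)`).
#'
#' @param e an `epoched_eeg`.
#' @param t_start window start in seconds from epoch onset.
#' @param t_len window length in seconds.
#' @return an `epoched_eeg` with `floor(t_len * fs)` samples per trial.
#' @export
crop_window <- function(e, t_start, t_len) {
  stopifnot(inherits(e, "epoched_eeg"), t_start >= 0, t_len > 0)
  start <- floor(t_start * e$fs)        # 0-based sample index
  len <- floor(t_len * e$fs)
  if (start + len > n_samples(e))
    stop(sprintf("window [%g, %g) s exceeds trial duration (%g s)",
                 t_start, t_start + t_len, n_samples(e) / e$fs))
  e$data <- e$data[, , (start + 1):(start + len), drop = FALSE]
  e
}

#' Subset trials by index
#' @param e an `epoched_eeg`.
#' @param idx trial indices (1-based).
#' @return an `epoched_eeg` containing the selected trials.
#' @export
subset_trials <- function(e, idx) {
  stopifnot(inherits(e, "epoched_eeg"))
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_trials(e))) stop("trial index out of range")
  e$data <- e$data[idx, , , drop = FALSE]
  e$labels <- e$labels[idx]
  e
}

# Evaluate `expr` under a private RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Trial-level K-fold split plan
#'
#' Builds the cross-validation plan used throughout: the number of folds
#' equals the smallest per-class trial count; in every fold exactly one trial
#' per class is held out as the test set and one further trial per class as
#' the validation set, the remainder forming the training set. The assignment
#' is a seeded per-class permutation, so the plan is deterministic under
#' `seed`.
#'
#' @param e an `epoched_eeg` with at least 3 trials per class.
#' @param seed integer seed.
#' @return an object of class `split_plan`: a list of folds, each with
#'   integer `train`, `val` and `test` trial indices.
#' @export
kfold_trial_split <- function(e, seed = 1L) {
  stopifnot(inherits(e, "epoched_eeg"))
  classes <- sort(unique(e$labels))
  counts <- vapply(classes, function(k) sum(e$labels == k), integer(1))
  if (any(counts < 3L))
    stop("kfold_trial_split needs at least 3 trials per class")
  n_folds <- min(counts)
  perms <- with_seed(seed, lapply(classes, function(k) {
    idx <- which(e$labels == k)
    sample(idx, length(idx))
  }))
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- integer(0); val <- integer(0); train <- integer(0)
    for (ci in seq_along(classes)) {
      p <- perms[[ci]]
      test_i <- p[f]
      val_i <- p[if (f == length(p)) 1L else f + 1L]
      train <- c(train, setdiff(p, c(test_i, val_i)))
      test <- c(test, test_i)
      val <- c(val, val_i)
    }
    list(train = sort(train), val = sort(val), test = sort(test))
  })
  structure(list(folds = folds, n_trials = n_trials(e), seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d folds over %d trials (seed %d)\n",
              length(x$folds), x$n_trials, x$seed))
  invisible(x)
}
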