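#' Build an epoched set from an array with a declared axis layout
#'
#' Public SSVEP recordings are commonly distributed as 4-D arrays with axes
#' `[channels x samples x classes x blocks]` where the class axis itself is
#' the label. This constructor normalizes any permutation of the axes
#' `trials`, `channels`, `samples`, and optionally `classes` + `blocks`
#' (whose product defines the trial axis, with the class axis supplying
#' 0-based labels) into the internal trials-first layout.
#'
#' @param arr numeric 3-D or 4-D array.
#' @param layout character vector naming the axes of `arr`, in order. For a
#'   3-D array a permutation of `c("trials","channels","samples")` (labels
#'   must then be given); for a 4-D array a permutation of
#'   `c("channels","samples","classes","blocks")`.
#' @param fs sampling rate in Hz.
#' @param labels 0-based labels (3-D layouts only).
#' @param channel_names,subject_id passed to [epoched_eeg()].
#' @return an `epoched_eeg`.
#' @export
epochs_from_array <- function(arr, layout, fs, labels = NULL,
                              channel_names = NULL,
                              subject_id = NA_character_) {
  layout <- match.arg(layout, c("trials", "channels", "samples",
                                "classes", "blocks"),
                      several.ok = TRUE)
  if (length(layout) != length(dim(arr)))
    stop("`layout` must name every axis of `arr`")
  if (length(dim(arr)) == 4L) {
    need <- c("channels", "samples", "classes", "blocks")
    if (!setequal(layout, need))
      stop("4-D layout must be a permutation of channels/samples/classes/blocks")
    arr <- aperm(arr, match(need, layout))
    nc <- dim(arr)[1]; ns <- dim(arr)[2]; nk <- dim(arr)[3]; nb <- dim(arr)[4]
    # trial index runs class-fastest within block
    dat <- array(0, dim = c(nk * nb, nc, ns))
    for (b in seq_len(nb))
      for (k in seq_len(nk))
        dat[(b - 1L) * nk + k, , ] <- arr[, , k, b]
    labels <- rep(seq_len(nk) - 1L, times = nb)
    epoched_eeg(dat, labels, fs, channel_names, subject_id, n_classes = nk)
  } else if (length(dim(arr)) == 3L) {
    need <- c("trials", "channels", "samples")
    if (!setequal(layout, need))
      stop("3-D layout must be a permutation of trials/channels/samples")
    if (is.null(labels)) stop("3-D layouts require explicit `labels`")
    arr <- aperm(arr, match(need, layout))
    epoched_eeg(arr, labels, fs, channel_names, subject_id)
  } else stop("`arr` must be 3-D or 4-D")
}

#' Save / load the internal epochs container
#'
#' The internal container stores the full `epoched_eeg` object (data array,
#' labels, sampling rate, channel names) via R's native serialization, so a
#' save/load round trip is bit-exact. A plain-text alternative
#' (`format = "csv"`: a directory with `data.csv`, `labels.csv` and
#' `meta.json`) is provided for interchange with other tools.
#'
#' @param e an `epoched_eeg`.
#' @param path file (rds) or directory (csv) to write.
#' @param format `"rds"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(e, path, format = c("rds", "csv")) {
  stopifnot(inherits(e, "epoched_eeg"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(container = "ssvepmix-epochs", version = 1L, epochs = e),
            path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nt <- n_trials(e); nc <- n_channels(e); ns <- n_samples(e)
    # rows = trial-channel pairs (trial fastest), cols = samples
    m <- matrix(aperm(e$data, c(1, 2, 3)), nrow = nt * nc, ncol = ns)
    utils::write.table(m, file.path(path, "data.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(label = e$labels),
                       file.path(path, "labels.csv"), sep = ",",
                       row.names = FALSE, col.names = TRUE)
    jsonlite::write_json(
      list(container = "ssvepmix-epochs", version = 1L, fs = e$fs,
           n_trials = nt, n_channels = nc, n_samples = ns,
           n_classes = e$n_classes, channel_names = e$channel_names,
           subject_id = e$subject_id),
      file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_epochs
#' @param path2 path previously written by [save_epochs()].
#' @export
load_epochs <- function(path2, format = c("auto", "rds", "csv",
                                          "mat", "edf", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path2)) "csv" else "rds"
  if (format %in% c("mat", "edf", "hdf5"))
    stop(sprintf(paste0(
      "format '%s' is not supported by this toolkit; convert the recording ",
      "to the internal container (save_epochs(); formats 'rds' or 'csv') ",
      "or build it from an array with epochs_from_array()"), format))
  if (!file.exists(path2)) stop(sprintf("no such file or directory: %s", path2))
  if (format == "rds") {
    obj <- readRDS(path2)
    if (!identical(obj$container, "ssvepmix-epochs"))
      stop("not a ssvepmix epochs container")
    e <- obj$epochs
  } else {
    meta <- jsonlite::read_json(file.path(path2, "meta.json"),
                                simplifyVector = TRUE)
    if (!identical(meta$container, "ssvepmix-epochs"))
      stop("not a ssvepmix epochs container")
    m <- as.matrix(utils::read.table(file.path(path2, "data.csv"), sep = ","))
    labels <- utils::read.csv(file.path(path2, "labels.csv"))$label
    dat <- array(m, dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
    e <- epoched_eeg(dat, labels, meta$fs, meta$channel_names,
                     meta$subject_id, n_classes = meta$n_classes)
  }
  # re-validate the contract on anything read from disk
  epoched_eeg(e$data, e$labels, e$fs, e$channel_names, e$subject_id,
              n_classes = e$n_classes)
}
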