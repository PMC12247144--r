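#' Multichannel EEG recording container
#'
#' Bundles a channels x samples data matrix (microvolts) with its sampling
#' rate, channel names, 3D electrode positions, event markers and the set of
#' channels flagged as bad. All pipeline stages consume and return this
#' container, so channel order is fixed once at construction.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz.
#' @param channel_names character vector, one name per row of `data`.
#' @param positions numeric matrix, n_channels x 3, electrode positions in a
#'   head-fixed frame (units arbitrary but consistent).
#' @param events data frame with columns `label` (character) and `onset`
#'   (0-based sample index), or `NULL`.
#' @param bad_channels character vector of channel names flagged as bad.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channel_names = NULL, positions = NULL,
                          events = NULL, bad_channels = character()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  nch <- nrow(data)
  if (is.null(channel_names))
    channel_names <- sprintf("E%02d", seq_len(nch))
  if (length(channel_names) != nch)
    stop("length(channel_names) must equal nrow(data)")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a positive scalar (Hz)")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nch || ncol(positions) != 3L)
      stop("`positions` must be an n_channels x 3 matrix")
    rownames(positions) <- channel_names
  }
  if (!is.null(events)) {
    events <- as.data.frame(events)
    if (!all(c("label", "onset") %in% names(events)))
      stop("`events` needs columns `label` and `onset`")
    if (nrow(events) && (any(events$onset < 0) || any(events$onset >= ncol(data))))
      stop("event onsets must lie in [0, n_samples)")
  }
  rownames(data) <- channel_names
  structure(list(data = data, srate = srate, channel_names = channel_names,
                 positions = positions, events = events,
                 bad_channels = as.character(bad_channels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  if (!is.null(x$events) && nrow(x$events))
    cat(sprintf("  events: %d (%s)\n", nrow(x$events),
                paste(utils::head(unique(x$events$label), 6), collapse = ", ")))
  if (length(x$bad_channels))
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  rng <- range(x$data)
  cat(sprintf("  amplitude range: [%.1f, %.1f] uV\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

# replace the data matrix, keeping metadata
with_data <- function(rec, data) {
  stopifnot(identical(dim(data), dim(rec$data)))
  rec$data <- data
  rownames(rec$data) <- rec$channel_names
  rec
}

chan_index <- function(rec, channels) {
  idx <- match(channels, rec$channel_names)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "))
  idx
}
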