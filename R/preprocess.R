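#' Zero-phase FIR band-pass plus power-line notch
#'
#' Phase-A temporal filtering: a windowed-sinc (Hamming) FIR band-pass
#' between `low` and `high`, followed by an FIR band-stop notch around the
#' power-line frequency (`notch` +/- 2 Hz). Both are applied with zero phase
#' by forward-backward application, realised exactly in the frequency domain
#' (multiplication by the squared magnitude response), so there is no group
#' delay and stop-band attenuation doubles relative to a single pass. The
#' signal is mirror-padded by one kernel length at each end to tame edge
#' transients; output length equals input length.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band-pass edges in Hz (defaults 0.5 and 70).
#' @param notch power-line frequency in Hz (default 50); `NA` disables it.
#' @param transition transition width in Hz of the band-pass design
#'   (default 0.5, i.e. a long kernel with a sharp low edge).
#' @return the filtered recording.
#' @export
bandpass_notch <- function(rec, low = 0.5, high = 70, notch = 50,
                           transition = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  if (low <= 0 || high >= nyq || low >= high)
    stop("band edges must satisfy 0 < low < high < srate/2")
  h_bp <- fir_design(rec$srate, transition, c(low, high), "pass")
  h_nt <- if (!is.na(notch)) {
    if (notch + 2 >= nyq) stop("notch band outside Nyquist range")
    fir_design(rec$srate, 1, c(notch - 2, notch + 2), "stop")
  } else NULL
  with_data(rec, zero_phase_apply(rec$data, h_bp, h_nt))
}

# Hamming windowed-sinc design; order from the 3.3/tw rule, forced even.
fir_design <- function(srate, transition, band, type) {
  ord <- ceiling(3.3 * srate / transition)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, band / (srate / 2), type)
}

# Forward-backward FIR via FFT: multiply the spectrum by the product of the
# squared magnitude responses of all kernels. Mirror padding at both ends.
zero_phase_apply <- function(data, ...) {
  kernels <- Filter(Negate(is.null), list(...))
  n <- ncol(data)
  L <- max(vapply(kernels, length, 1L))
  p <- min(L, n - 1)
  nfft <- 2^ceiling(log2(n + 2 * p + 2 * L))
  gain2 <- rep(1, nfft)
  for (h in kernels)
    gain2 <- gain2 * Mod(stats::fft(c(h, rep(0, nfft - length(h)))))^2
  out <- data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    xp <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
    X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
    y <- Re(stats::fft(X * gain2, inverse = TRUE)) / nfft
    out[ch, ] <- y[(p + 1):(p + n)]
  }
  out
}

#' Flag bad channels by isoelectric or sustained high-amplitude behaviour
#'
#' A channel is flagged when its absolute value stays below `flat_tol`
#' (isoelectric, e.g. a non-operating dry electrode) or above `amp_thresh`
#' for more than a fraction `frac` of all samples.
#'
#' @param rec an [eeg_recording()].
#' @param flat_tol isoelectric tolerance in microvolts.
#' @param amp_thresh high-amplitude threshold in microvolts.
#' @param frac time fraction above which a channel is flagged (default 0.70).
#' @return character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(rec, flat_tol = 0.5, amp_thresh = 100,
                                frac = 0.70) {
  stopifnot(frac > 0, frac <= 1)
  a <- abs(rec$data)
  flat <- rowMeans(a < flat_tol) > frac
  loud <- rowMeans(a > amp_thresh) > frac
  rec$channel_names[flat | loud]
}

#' Drop trials disturbed on too many channels
#'
#' A channel counts as disturbed within a trial if any sample exceeds
#' `disturb_thresh` in magnitude; trials where more than `channel_frac` of
#' the channels are disturbed are removed. Survivor order is preserved.
#'
#' @param epochs list of epochs from [segment_by_task()].
#' @param disturb_thresh amplitude threshold in microvolts (default 150).
#' @param channel_frac maximum tolerated fraction of disturbed channels
#'   (default 0.40).
#' @return the surviving epochs.
#' @export
reject_bad_trials <- function(epochs, disturb_thresh = 150,
                              channel_frac = 0.40) {
  if (!length(epochs)) stop("no epochs supplied")
  keep <- vapply(epochs, function(ep) {
    disturbed <- apply(abs(ep$data), 1, max) > disturb_thresh
    mean(disturbed) <= channel_frac
  }, logical(1))
  epochs[keep]
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over channels from every channel, so the
#' channel mean is zero at every sample. Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced recording.
#' @export
rereference_common_average <- function(rec) {
  if (nrow(rec$data) < 2)
    stop("common average reference needs at least 2 channels")
  with_data(rec, sweep(rec$data, 2, colMeans(rec$data)))
}

#' Spherical-spline interpolation of channels
#'
#' Replaces the time series of the target channels by spherical-spline
#' interpolation (Perrin et al. 1989 style: stiffness order m = 4, 50
#' Legendre terms, electrode positions radially projected onto the unit
#' sphere) from all remaining channels. Exact for spatially constant fields.
#'
#' @param rec an [eeg_recording()] with electrode positions.
#' @param targets character vector of channel names to interpolate.
#' @return the recording with target channels replaced.
#' @export
interpolate_channels <- function(rec, targets) {
  if (!length(targets)) return(rec)
  if (is.null(rec$positions)) stop("recording has no electrode positions")
  bad <- chan_index(rec, targets)
  good <- setdiff(seq_len(nrow(rec$data)), bad)
  if (length(good) < 4)
    stop("need at least 4 source channels for spherical-spline interpolation")
  W <- spline_interp_matrix(unit_sphere_positions(rec$positions), good, bad)
  data <- rec$data
  data[bad, ] <- W %*% data[good, , drop = FALSE]
  with_data(rec, data)
}

# Spherical-spline interpolation operator: rows = target channels, columns =
# source channels, acting on source data. m = 4 stiffness, `nterms` Legendre
# terms, tiny ridge for conditioning (constants still reproduced exactly via
# the constraint block).
spline_interp_matrix <- function(pos_unit, good, bad, m = 4, nterms = 50,
                                 ridge = 1e-8) {
  g_fun <- function(x) {
    # 1/(4 pi) sum_n (2n+1) / (n(n+1))^m P_n(x)
    P_prev <- rep(1, length(x))      # P_0
    P <- x                           # P_1
    acc <- 3 / (1 * 2)^m * P
    for (n in 2:nterms) {
      P_next <- ((2 * n - 1) * x * P - (n - 1) * P_prev) / n
      acc <- acc + (2 * n + 1) / (n * (n + 1))^m * P_next
      P_prev <- P
      P <- P_next
    }
    acc / (4 * pi)
  }
  cosang <- function(A, B) {
    m <- tcrossprod(A, B)
    m[] <- pmin(1, pmax(-1, m))
    m
  }
  Ggg <- g_fun(cosang(pos_unit[good, , drop = FALSE], pos_unit[good, , drop = FALSE]))
  Gbg <- g_fun(cosang(pos_unit[bad, , drop = FALSE], pos_unit[good, , drop = FALSE]))
  ng <- length(good)
  A <- rbind(cbind(Ggg + diag(ridge, ng), 1), c(rep(1, ng), 0))
  X <- solve(A, rbind(diag(ng), 0))
  cbind(Gbg, 1) %*% X
}

#' Segment a recording into task epochs
#'
#' Cuts one fixed-length epoch per event marker. Markers too close to the
#' end of the recording for a full window are skipped with a warning.
#'
#' @param rec an [eeg_recording()] with events.
#' @param window epoch length in seconds (default 7, one motor trial).
#' @return list of epochs; each has `task_label`, `data` (channels x
#'   samples), `trial_index`, `onset`.
#' @export
segment_by_task <- function(rec, window = 7) {
  if (is.null(rec$events) || !nrow(rec$events)) return(list())
  len <- round(window * rec$srate)
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(rec$events))) {
    on <- rec$events$onset[i]
    if (on + len > ncol(rec$data)) {
      skipped <- skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(task_label = rec$events$label[i],
           data = rec$data[, (on + 1):(on + len), drop = FALSE],
           trial_index = length(out) + 1L, onset = on),
      class = "eeg_epoch")
  }
  if (skipped)
    warning(skipped, " trial(s) skipped: marker too close to recording end")
  out
}

#' Phase-A preprocessing in one call
#'
#' Band-pass and notch filtering, bad-channel detection and removal of the
#' flagged channels from the data (they are recorded in `bad_channels` and
#' interpolated back during phase C).
#'
#' @inheritParams bandpass_notch
#' @inheritParams detect_bad_channels
#' @return the preprocessed recording; flagged channels dropped from the
#'   data matrix and listed in `bad_channels`.
#' @export
preprocess_phase_a <- function(rec, low = 0.5, high = 70, notch = 50,
                               flat_tol = 0.5, amp_thresh = 100, frac = 0.70) {
  rec <- bandpass_notch(rec, low, high, notch)
  bad <- detect_bad_channels(rec, flat_tol, amp_thresh, frac)
  if (length(bad)) {
    keep <- setdiff(seq_len(nrow(rec$data)), chan_index(rec, bad))
    rec <- eeg_recording(rec$data[keep, , drop = FALSE], rec$srate,
                         rec$channel_names[keep],
                         rec$positions[keep, , drop = FALSE],
                         rec$events, bad_channels = bad)
  }
  rec
}
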