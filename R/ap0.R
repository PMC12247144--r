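#' Detect high-amplitude jump periods (AP0)
#'
#' Transient electrode-movement jumps are single-channel deflections that
#' can reach hundreds of microvolts; any spatial filter smears them into
#' neighbouring channels, so they are excised before spatial filtering.
#' Detection follows explicit amplitude rules: every exceedance of
#' `jump_thresh` seeds a period whose onset is `pre_onset` ms before the
#' first threshold crossing (extended further back while the signal already
#' sits outside `stable_band`), and whose end is the first sample from which
#' the signal stays within `+/- stable_band` continuously for `stable_dur`
#' ms. Overlapping or nearly adjacent periods (gap below `merge_gap`
#' seconds, the default matching the 0.5 s zeroing taper) are merged.
#' Periods are clipped to the recording bounds.
#'
#' @param rec a phase-A preprocessed [eeg_recording()].
#' @param jump_thresh seed threshold, microvolts (default 150).
#' @param stable_band stabilization band, microvolts (default 80).
#' @param pre_onset onset lead before the first crossing, ms (default 200).
#' @param stable_dur required stable duration, ms (default 200).
#' @param merge_gap merge periods closer than this, seconds (default 0.5).
#' @return data frame of class `ap0_periods`: `channel` (name),
#'   `channel_index`, `start`, `end` (0-based half-open sample interval),
#'   `peak_amplitude` (microvolts), `source` (`"detected"`).
#' @export
detect_ap0 <- function(rec, jump_thresh = 150, stable_band = 80,
                       pre_onset = 200, stable_dur = 200, merge_gap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  srate <- rec$srate
  pre <- as.integer(round(pre_onset / 1000 * srate))
  L <- as.integer(round(stable_dur / 1000 * srate))
  gap <- as.integer(round(merge_gap * srate))
  n <- ncol(rec$data)
  out <- list()
  for (ch in seq_len(nrow(rec$data))) {
    x <- abs(rec$data[ch, ])
    exc <- which(x > jump_thresh)
    if (!length(exc)) next
    ok <- x <= stable_band
    cs <- c(0, cumsum(ok))
    # allok[t]: stable for L samples starting at t (shorter window at the end)
    allok <- function(t) {
      hi <- min(n, t + L - 1)
      cs[hi + 1] - cs[t] == hi - t + 1
    }
    periods <- list()
    pos <- 1L
    repeat {
      i <- exc[exc >= pos]
      if (!length(i)) break
      i <- i[1]
      start <- max(1L, i - pre)
      while (start > 1L && !ok[start]) start <- start - 1L
      t <- i + 1L
      while (t <= n && !allok(t)) t <- t + 1L
      end <- min(t, n + 1L)                 # exclusive, 1-based
      periods[[length(periods) + 1L]] <- c(start, end)
      pos <- end
    }
    pm <- do.call(rbind, periods)
    # merge near-adjacent periods
    merged <- pm[1, , drop = FALSE]
    if (nrow(pm) > 1) for (r in 2:nrow(pm)) {
      last <- nrow(merged)
      if (pm[r, 1] - merged[last, 2] < gap) merged[last, 2] <- pm[r, 2]
      else merged <- rbind(merged, pm[r, ])
    }
    for (r in seq_len(nrow(merged))) {
      s1 <- merged[r, 1]; e1 <- merged[r, 2]
      out[[length(out) + 1L]] <- data.frame(
        channel = rec$channel_names[ch], channel_index = ch,
        start = as.integer(s1) - 1L, end = as.integer(e1) - 1L,
        peak_amplitude = max(x[s1:(e1 - 1)]), source = "detected")
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(channel = character(), channel_index = integer(),
                  start = integer(), end = integer(),
                  peak_amplitude = numeric(), source = character())
  rownames(res) <- NULL
  class(res) <- c("ap0_periods", "data.frame")
  res
}

#' Zero artifactual periods with Hann-tapered transitions
#'
#' Samples inside each period are set to exactly 0 uV. A half-Hann fade-out
#' of `taper/2` seconds precedes the zero core and a half-Hann fade-in of
#' `taper/2` follows it (multiplicative taper on the original signal), so
#' the transition into and out of the zeroed span is smooth. Taper zones
#' that would extend past the recording bounds are truncated. Samples
#' outside the periods and their taper zones are bit-identical to the
#' input; other channels are untouched.
#'
#' @param rec an [eeg_recording()].
#' @param periods an `ap0_periods` data frame (detected or manual labels).
#' @param taper total Hann transition length in seconds (default 0.5,
#'   i.e. 0.25 s on each side).
#' @return the recording with zeroed periods.
#' @export
apply_zeroing <- function(rec, periods, taper = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!nrow(periods)) return(rec)
  n <- ncol(rec$data)
  half <- round(taper / 2 * rec$srate)
  data <- rec$data
  for (r in seq_len(nrow(periods))) {
    ch <- if ("channel_index" %in% names(periods) &&
              !is.na(periods$channel_index[r])) periods$channel_index[r]
          else chan_index(rec, periods$channel[r])
    s0 <- periods$start[r]; e0 <- periods$end[r]     # 0-based half-open
    if (s0 < 0 || e0 > n || s0 >= e0) stop("invalid period bounds")
    data[ch, (s0 + 1):e0] <- 0
    if (half > 0) {
      j <- 0:(half - 1)
      w_out <- 0.5 * (1 + cos(pi * j / half))         # 1 -> ~0 into the core
      idx <- s0 - half + j + 1                        # 1-based
      keep <- idx >= 1
      data[ch, idx[keep]] <- data[ch, idx[keep]] * w_out[keep]
      w_in <- 0.5 * (1 - cos(pi * j / half))          # ~0 -> 1 out of the core
      idx <- e0 + j + 1
      keep <- idx <= n
      data[ch, idx[keep]] <- data[ch, idx[keep]] * w_in[keep]
    }
  }
  with_data(rec, data)
}

#' Interpolate zeroed spans after spatial filtering
#'
#' For each artifact period the affected channel's samples in
#' `[start, end)` are replaced by spherical-spline interpolation from the
#' other channels at those samples (all channels by default, or only
#' mesh-edge neighbours). Samples outside the periods are unchanged.
#'
#' @param rec_filtered the spatially filtered [eeg_recording()].
#' @param periods the `ap0_periods` used for zeroing.
#' @param mesh optional `sensor_mesh`; required for
#'   `from = "neighbors"`.
#' @param from interpolate from `"all"` other channels (default) or from
#'   `"neighbors"` on the mesh.
#' @return the recording with interpolated spans.
#' @export
interpolate_ap0_spans <- function(rec_filtered, periods, mesh = NULL,
                                  from = c("all", "neighbors")) {
  from <- match.arg(from)
  stopifnot(inherits(rec_filtered, "eeg_recording"))
  if (!nrow(periods)) return(rec_filtered)
  if (is.null(rec_filtered$positions))
    stop("recording has no electrode positions")
  if (from == "neighbors" && is.null(mesh))
    stop("neighbor interpolation needs a sensor mesh")
  pu <- unit_sphere_positions(rec_filtered$positions)
  nb <- if (from == "neighbors") mesh_neighbors(mesh)
  data <- rec_filtered$data
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(periods))) {
    ch <- chan_index(rec_filtered, periods$channel[r])
    key <- as.character(ch)
    if (is.null(cache[[key]])) {
      good <- if (from == "all") setdiff(seq_len(nrow(data)), ch) else nb[[ch]]
      if (length(good) < 4)
        stop("need at least 4 source channels to interpolate channel ",
             periods$channel[r])
      cache[[key]] <- list(good = good,
                           W = spline_interp_matrix(pu, good, ch))
    }
    ci <- cache[[key]]
    cols <- (periods$start[r] + 1):periods$end[r]
    data[ch, cols] <- ci$W %*% data[ci$good, cols, drop = FALSE]
  }
  with_data(rec_filtered, data)
}

#' Read / write AP0 period annotations
#'
#' Tab-separated text with columns `channel`, `start_sample`, `end_sample`,
#' `source` (sample indices 0-based, half-open), or an equivalent JSON
#' sidecar; both are compatible with the synthetic generator's ground-truth
#' period table.
#'
#' @param periods an `ap0_periods` data frame.
#' @param path file path.
#' @export
write_ap0_annotations <- function(periods, path) {
  tab <- data.frame(channel = periods$channel, start_sample = periods$start,
                    end_sample = periods$end,
                    source = if ("source" %in% names(periods)) periods$source
                             else "manual")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ap0_annotations
#' @export
read_ap0_annotations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  res <- data.frame(channel = as.character(tab$channel),
                    channel_index = NA_integer_,
                    start = as.integer(tab$start_sample),
                    end = as.integer(tab$end_sample),
                    peak_amplitude = NA_real_,
                    source = tab$source)
  class(res) <- c("ap0_periods", "data.frame")
  res
}

#' @rdname write_ap0_annotations
#' @export
write_ap0_json <- function(periods, path) {
  jsonlite::write_json(as.data.frame(periods), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ap0_annotations
#' @export
read_ap0_json <- function(path) {
  tab <- jsonlite::fromJSON(path)
  class(tab) <- c("ap0_periods", "data.frame")
  tab
}
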