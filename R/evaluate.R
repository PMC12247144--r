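#' Per-channel signal-quality metrics
#'
#' `compute_sd` is the per-channel sample standard deviation over the whole
#' recording. `compute_snr` compares a cleaned signal with the preprocessed
#' reference as `10 log10(sum ref^2 / sum cleaned^2)` per channel (dB): the
#' more power a cleaning method removes, the higher the value, so an
#' increase indicates effective artifact and noise reduction. `compute_rmsd`
#' is the per-channel root mean square difference `sqrt(mean((cleaned -
#' ref)^2))` (uV); larger values mean the method changed the signal more.
#'
#' @param data,ref,cleaned channels x samples matrices in microvolts (or
#'   [eeg_recording()] objects, from which the data are taken).
#' @return named numeric vector, one value per channel.
#' @export
compute_sd <- function(data) {
  data <- as_data_matrix(data)
  if (ncol(data) < 2) stop("need at least 2 samples")
  apply(data, 1, stats::sd)
}

#' @rdname compute_sd
#' @export
compute_snr <- function(ref, cleaned) {
  ref <- as_data_matrix(ref); cleaned <- as_data_matrix(cleaned)
  if (!identical(dim(ref), dim(cleaned))) stop("shape mismatch")
  p_ref <- rowSums(ref^2)
  p_cln <- rowSums(cleaned^2)
  if (any(p_cln == 0)) {
    warning("zero-power cleaned channel(s); SNR set to +Inf")
  }
  out <- 10 * log10(p_ref / p_cln)
  names(out) <- rownames(ref)
  out
}

#' @rdname compute_sd
#' @export
compute_rmsd <- function(ref, cleaned) {
  ref <- as_data_matrix(ref); cleaned <- as_data_matrix(cleaned)
  if (!identical(dim(ref), dim(cleaned))) stop("shape mismatch")
  out <- sqrt(rowMeans((cleaned - ref)^2))
  names(out) <- rownames(ref)
  out
}

as_data_matrix <- function(x) {
  if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
}

#' Pipeline configuration
#'
#' Central list of every tunable threshold of the cleaning pipeline, with
#' the documented defaults. Readable from / writable to YAML when the
#' `yaml` package is available.
#'
#' @param n_components,ica_seed,drop_labels ICA stage settings.
#' @param thresholds a [classifier_thresholds()] list.
#' @param sphara_order,retained_power,sphara_mode spatial filter settings.
#' @param jump_thresh,stable_band,pre_onset,stable_dur,taper AP0 settings.
#' @param bp_low,bp_high,notch phase-A filter settings (Hz).
#' @param flat_tol,amp_thresh,bad_frac bad-channel rule settings.
#' @param disturb_thresh,channel_frac bad-trial rule settings.
#' @param epoch_window trial length for segmentation, seconds.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_components = 50, ica_seed = 1,
                            drop_labels = c("blink", "eye_movement",
                                            "myogenic", "cardiac", "pulse"),
                            thresholds = classifier_thresholds(),
                            sphara_order = 2, retained_power = 0.95,
                            sphara_mode = "butterworth",
                            jump_thresh = 150, stable_band = 80,
                            pre_onset = 200, stable_dur = 200, taper = 0.5,
                            bp_low = 0.5, bp_high = 70, notch = 50,
                            flat_tol = 0.5, amp_thresh = 100, bad_frac = 0.70,
                            disturb_thresh = 150, channel_frac = 0.40,
                            epoch_window = 7) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run one cleaning method chain on a preprocessed recording
#'
#' Dispatches the four method chains compared by the pipeline, all applied
#' to the phase-A preprocessed recording (`Ref`):
#' \describe{
#'   \item{`ref`}{identity.}
#'   \item{`fpa`}{ICA decomposition, artifactual-component removal,
#'     reprojection.}
#'   \item{`sphara`}{SPHARA Butterworth spatial low-pass with the cutoff
#'     derived from the 95% power subset.}
#'   \item{`fpa+sphara`}{both, sequentially.}
#'   \item{`fpa+ap0+sphara`}{ICA stage, then AP0 jump detection and Hann
#'     zeroing, SPHARA filtering, and spherical-spline interpolation of the
#'     zeroed spans.}
#' }
#' Signal-quality metrics compare each chain's output with `Ref` *before*
#' phase C; set `phase_c = TRUE` to additionally re-reference to the common
#' average, interpolate channels removed during preprocessing, and segment
#' by task.
#'
#' @param rec a phase-A preprocessed [eeg_recording()].
#' @param method one of `"ref"`, `"fpa"`, `"sphara"`, `"fpa+sphara"`,
#'   `"fpa+ap0+sphara"`.
#' @param config a [pipeline_config()].
#' @param basis optional precomputed [sphara_basis()] for the recording's
#'   montage.
#' @param dec optional precomputed labeled [eeg_decompose()] result; avoids
#'   refitting ICA when several chains share the FPA stage.
#' @param phase_c apply phase C (re-reference, interpolate removed
#'   channels, segment) after cleaning.
#' @param montage full montage (needed during phase C to restore channels
#'   removed in preprocessing); defaults to the recording's own channels.
#' @return the cleaned recording; when `phase_c = TRUE`, a list with
#'   `recording` and `epochs`. Detected AP0 periods, when relevant, are
#'   attached as attribute `ap0_periods`.
#' @export
run_method_chain <- function(rec, method = c("ref", "fpa", "sphara",
                                             "fpa+sphara", "fpa+ap0+sphara"),
                             config = pipeline_config(), basis = NULL,
                             dec = NULL, phase_c = FALSE, montage = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "eeg_recording"))
  need_sphara <- method %in% c("sphara", "fpa+sphara", "fpa+ap0+sphara")
  need_fpa <- method %in% c("fpa", "fpa+sphara", "fpa+ap0+sphara")
  if (need_sphara && is.null(basis))
    basis <- sphara_basis(sensor_mesh(rec$positions, rec$channel_names))
  out <- rec
  periods <- NULL
  if (need_fpa) {
    if (is.null(dec)) {
      dec <- eeg_decompose(rec, config$n_components, seed = config$ica_seed)
      dec <- classify_components(dec, rec, config$thresholds)
    }
    out <- remove_and_reproject(dec, out, config$drop_labels)
  }
  if (method == "fpa+ap0+sphara") {
    periods <- detect_ap0(out, config$jump_thresh, config$stable_band,
                          config$pre_onset, config$stable_dur,
                          merge_gap = config$taper)
    out <- apply_zeroing(out, periods, config$taper)
  }
  if (need_sphara) {
    spec <- spatial_filter_spec(order = config$sphara_order,
                                retained_power = config$retained_power,
                                mode = config$sphara_mode)
    out <- with_data(out, strip_attrs(sphara_filter(basis, out$data, spec)))
  }
  if (method == "fpa+ap0+sphara" && nrow(periods))
    out <- interpolate_ap0_spans(out, periods)
  if (!is.null(periods)) attr(out, "ap0_periods") <- periods
  if (phase_c) {
    ep <- phase_c_prepare(out, config, montage)
    ep$recording <- keep_attr(ep$recording, out)
    return(ep)
  }
  out
}

strip_attrs <- function(m) {
  attr(m, "cutoff_frequency") <- NULL
  attr(m, "K") <- NULL
  m
}

keep_attr <- function(new, old) {
  attr(new, "ap0_periods") <- attr(old, "ap0_periods")
  new
}

# Phase C: common-average re-reference, spline interpolation of channels
# removed during preprocessing, task segmentation.
phase_c_prepare <- function(rec, config, montage = NULL) {
  if (length(rec$bad_channels) && !is.null(montage)) {
    keep_names <- rec$channel_names
    all_names <- montage$names
    data <- matrix(0, length(all_names), ncol(rec$data),
                   dimnames = list(all_names, NULL))
    data[keep_names, ] <- rec$data
    rec <- eeg_recording(data, rec$srate, all_names, montage$positions,
                         rec$events, bad_channels = rec$bad_channels)
    rec <- interpolate_channels(rec, rec$bad_channels)
  }
  rec <- rereference_common_average(rec)
  epochs <- if (!is.null(rec$events) && nrow(rec$events))
    segment_by_task(rec, config$epoch_window) else list()
  if (length(epochs))
    epochs <- reject_bad_trials(epochs, config$disturb_thresh,
                                config$channel_frac)
  list(recording = rec, epochs = epochs)
}

#' Evaluate all cleaning methods on one recording
#'
#' Runs every method chain on a phase-A preprocessed recording, computes
#' per-channel SD for all methods and SNR/RMSD against `Ref` for the
#' cleaning methods, and returns a tidy per-channel metric table. The ICA
#' decomposition and SPHARA basis are computed once and shared across
#' chains (the chains are defined on identical stage parameters, so this is
#' purely an optimization).
#'
#' @param rec a phase-A preprocessed [eeg_recording()].
#' @param config a [pipeline_config()].
#' @param methods method identifiers, see [run_method_chain()].
#' @return data frame: `method`, `channel`, `sd`, `snr`, `rmsd` (`snr` and
#'   `rmsd` are `NA` for `ref`).
#' @export
evaluate_methods <- function(rec, config = pipeline_config(),
                             methods = c("ref", "fpa", "sphara",
                                         "fpa+sphara", "fpa+ap0+sphara")) {
  basis <- sphara_basis(sensor_mesh(rec$positions, rec$channel_names))
  dec <- NULL
  if (any(methods != "ref" & grepl("fpa", methods))) {
    dec <- eeg_decompose(rec, config$n_components, seed = config$ica_seed)
    dec <- classify_components(dec, rec, config$thresholds)
  }
  res <- lapply(methods, function(m) {
    cleaned <- run_method_chain(rec, m, config, basis = basis, dec = dec)
    data.frame(method = m, channel = rec$channel_names,
               sd = compute_sd(cleaned),
               snr = if (m == "ref") NA_real_ else compute_snr(rec, cleaned),
               rmsd = if (m == "ref") NA_real_ else compute_rmsd(rec, cleaned))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Grand-average metric summary
#'
#' Aggregates a per-channel metric table (possibly spanning several
#' recordings) to per-method means and SDs: channels first, then
#' recordings, equal weights.
#'
#' @param metrics output of [evaluate_methods()], optionally row-bound
#'   across recordings with a `recording` column.
#' @return data frame with per-method `sd_mean`, `sd_sd`, `snr_mean`,
#'   `snr_sd`, `rmsd_mean`, `rmsd_sd`.
#' @export
aggregate_metrics <- function(metrics) {
  if (!"recording" %in% names(metrics)) metrics$recording <- 1L
  per_rec <- stats::aggregate(cbind(sd, snr, rmsd) ~ method + recording,
                              data = metrics, FUN = mean, na.action = stats::na.pass)
  agg <- function(v, f) tapply(v, per_rec$method, f)
  methods <- sort(unique(per_rec$method))
  out <- data.frame(method = methods,
                    sd_mean = as.numeric(agg(per_rec$sd, mean)[methods]),
                    sd_sd = as.numeric(agg(per_rec$sd, stats::sd)[methods]),
                    snr_mean = as.numeric(agg(per_rec$snr, mean)[methods]),
                    snr_sd = as.numeric(agg(per_rec$snr, stats::sd)[methods]),
                    rmsd_mean = as.numeric(agg(per_rec$rmsd, mean)[methods]),
                    rmsd_sd = as.numeric(agg(per_rec$rmsd, stats::sd)[methods]))
  rownames(out) <- NULL
  out
}

#' Synthetic multi-recording benchmark of the cleaning methods
#'
#' Generates `n_recordings` independent synthetic dry-EEG recordings (all
#' artifact classes injected), phase-A preprocesses each, runs all method
#' chains, and returns per-channel metrics per recording together with the
#' ground truth needed for anti-smearing checks.
#'
#' @param n_recordings number of recordings (default 11).
#' @param config a [synth_config()]; recording r uses seed
#'   `config$seed + r - 1`.
#' @param pipeline a [pipeline_config()].
#' @param keep_ground_truth keep each recording's ground truth (memory
#'   permitting) for artifact-level analyses.
#' @return list with `metrics` (row-bound [evaluate_methods()] tables with
#'   a `recording` column) and `summary` ([aggregate_metrics()]).
#' @export
run_benchmark <- function(n_recordings = 11, config = synth_config(),
                          pipeline = pipeline_config(),
                          keep_ground_truth = FALSE) {
  metrics <- list()
  gts <- list()
  for (r in seq_len(n_recordings)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1
    gen <- generate_recording(cfg)
    rec <- preprocess_phase_a(gen$recording, pipeline$bp_low,
                              pipeline$bp_high, pipeline$notch,
                              pipeline$flat_tol, pipeline$amp_thresh,
                              pipeline$bad_frac)
    mt <- suppressWarnings(evaluate_methods(rec, pipeline))
    mt$recording <- r
    metrics[[r]] <- mt
    if (keep_ground_truth) gts[[r]] <- gen$ground_truth
    rm(gen); gc(FALSE)
  }
  metrics <- do.call(rbind, metrics)
  out <- list(metrics = metrics, summary = aggregate_metrics(metrics))
  if (keep_ground_truth) out$ground_truth <- gts
  out
}

#' Export a per-channel metric map for topographic plotting
#'
#' Writes channel name, 2D azimuthal-equidistant projected position and the
#' metric value, one row per channel, as a CSV consumable by any plotting
#' tool; optionally renders a quick QC map.
#'
#' @param values named per-channel metric vector (e.g. from
#'   [compute_snr()]).
#' @param positions n x 3 electrode positions in the same channel order.
#' @param path optional CSV output path.
#' @param plot render a base-graphics QC map.
#' @return data frame with `channel`, `x`, `y`, `value` (invisibly if
#'   written to `path`).
#' @export
topographic_export <- function(values, positions, path = NULL, plot = FALSE) {
  xy <- azimuthal_project(unit_sphere_positions(as.matrix(positions)))
  out <- data.frame(channel = if (!is.null(names(values))) names(values)
                              else sprintf("E%02d", seq_along(values)),
                    x = xy[, 1], y = xy[, 2], value = as.numeric(values))
  rownames(out) <- NULL
  if (plot) {
    pal <- grDevices::hcl.colors(64, "viridis")
    col <- pal[cut(out$value, 64, labels = FALSE)]
    graphics::plot(out$x, out$y, pch = 21, bg = col, cex = 2, asp = 1,
                   xlab = "", ylab = "", main = "channel metric map")
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
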