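#' Decompose a recording into independent components
#'
#' The physiological-artifact stage mirrors the classical structure: the
#' channel data are pre-whitened by PCA, reduced to `n_components`
#' dimensions, and unmixed with the extended Infomax algorithm
#' (sign-switching between super- and sub-Gaussian component densities, via
#' [ica::icaimax()]). The component count is fixed (50 by default) rather
#' than tied to the retained channel count, so decompositions are comparable
#' across recordings whose bad-channel sets differ. Components are
#' sign-fixed so the maximum-magnitude mixing weight of each component is
#' positive, and ordered by explained variance.
#'
#' @param rec an [eeg_recording()].
#' @param n_components number of independent components (default 50).
#' @param seed integer seed for the (random orthogonal) initial rotation;
#'   the decomposition is deterministic given the seed.
#' @param maxit maximum Infomax iterations.
#' @param tol convergence tolerance passed to the unmixer.
#' @return An `eeg_ica` object: `mixing` (channels x n_components),
#'   `sources` (n_components x samples), `center` (channel means),
#'   `n_components`, `labels` (all `NA` until [classify_components()]),
#'   `srate`, `positions`, `channel_names`.
#' @export
eeg_decompose <- function(rec, n_components = 50, seed = 1, maxit = 100,
                          tol = 1e-6) {
  stopifnot(inherits(rec, "eeg_recording"))
  nch <- nrow(rec$data)
  ns <- ncol(rec$data)
  if (nch < n_components)
    stop("recording has ", nch, " channels; cannot extract ", n_components,
         " components")
  if (ns < 20 * n_components^2)
    warning("only ", ns, " samples for ", n_components,
            " components; >= ", 20 * n_components^2,
            " recommended for a stable unmixing")
  ctr <- rowMeans(rec$data)
  X <- rec$data - ctr
  sv <- svd(X, nu = min(n_components, nch), nv = 0)
  rank_eff <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank_eff < n_components) {
    warning("data rank ", rank_eff, " below requested ", n_components,
            " components; extracting ", rank_eff)
    n_components <- rank_eff
  }
  U <- sv$u[, seq_len(n_components), drop = FALSE]  # channels x k
  Y <- crossprod(U, X)                        # k x samples, PCA scores
  R0 <- with_preserved_rng({
    seed_rng(seed)
    qr.Q(qr(matrix(stats::rnorm(n_components^2), n_components)))
  })
  fit <- ica::icaimax(t(Y), nc = n_components, center = TRUE, maxit = maxit,
                      tol = tol, Rmat = R0, alg = "newton", fun = "tanh",
                      signswitch = TRUE)
  sources <- t(fit$S)                         # k x samples
  mixing <- U %*% fit$M                       # channels x k
  ord <- order(colSums(mixing^2) * apply(sources, 1, stats::var),
               decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  sources <- sources[ord, , drop = FALSE]
  for (k in seq_len(n_components)) {
    i <- which.max(abs(mixing[, k]))
    if (mixing[i, k] < 0) {
      mixing[, k] <- -mixing[, k]
      sources[k, ] <- -sources[k, ]
    }
  }
  rownames(mixing) <- rec$channel_names
  structure(list(mixing = mixing, sources = sources, center = ctr,
                 iter = fit$iter, converged = fit$converged,
                 n_components = as.integer(n_components),
                 labels = rep(NA_character_, n_components),
                 srate = rec$srate, positions = rec$positions,
                 channel_names = rec$channel_names),
            class = "eeg_ica")
}

#' @export
print.eeg_ica <- function(x, ...) {
  cat(sprintf("<eeg_ica> %d components over %d channels\n",
              x$n_components, nrow(x$mixing)))
  if (!all(is.na(x$labels)))
    print(table(x$labels))
  invisible(x)
}

#' Feature thresholds of the heuristic component classifier
#'
#' The classifier identifies artifactual components from documented time,
#' frequency and topography features. All thresholds are exposed here;
#' defaults were chosen once for the synthetic generator's artifact classes
#' and are deliberately conservative for neural/background components.
#'
#' @param frontal_y anterior boundary: channels whose unit-sphere y exceeds
#'   this are "frontal".
#' @param blink_frontal minimum frontal fraction of squared topography
#'   weight for blink/eye-movement candidates.
#' @param blink_low minimum fraction of spectral power below 5 Hz (blink).
#' @param blink_skew minimum skewness of the source (blink transients are
#'   one-sided and positive under the sign convention).
#' @param blink_kurt minimum excess kurtosis (blinks are sparse heavy-tailed
#'   transients; keeps smooth background components out).
#' @param em_dipolar minimum lateral asymmetry of the frontal topography
#'   (eye movements project with opposite signs on the two hemispheres).
#' @param em_balance minimum left/right weight balance of the frontal
#'   topography: EOG fields load both hemispheres, single-channel
#'   artifacts do not.
#' @param em_low minimum sub-5 Hz power fraction (eye movement).
#' @param myo_high minimum fraction of spectral power above 20 Hz.
#' @param myo_lag1 maximum lag-1 autocorrelation (myogenic sources are
#'   broadband).
#' @param myo_burst minimum coefficient of variation of the 100 ms RMS
#'   envelope: muscle activity arrives in bursts, stationary sensor noise
#'   does not.
#' @param heart_period admissible median inter-peak interval, seconds.
#' @param heart_cv maximum coefficient of variation of inter-peak intervals.
#' @param cardiac_kurt excess-kurtosis split between spiky electrical
#'   (`cardiac`) and smoother pulsatile (`pulse`) periodic components.
#' @param heart_coverage minimum fraction of expected beats that must appear
#'   as detected peaks (a genuine cardiac train peaks at nearly every
#'   period; sporadic large excursions do not).
#' @param peak_z peak detection threshold in source SD units.
#' @return named list of thresholds.
#' @export
classifier_thresholds <- function(frontal_y = 0.4, blink_frontal = 0.55,
                                  blink_low = 0.60, blink_skew = 1.0,
                                  blink_kurt = 3, em_dipolar = 0.6,
                                  em_balance = 0.25, em_low = 0.65,
                                  myo_high = 0.45, myo_lag1 = 0.5,
                                  myo_burst = 0.5,
                                  heart_period = c(0.67, 1.67),
                                  heart_cv = 0.2, heart_coverage = 0.7,
                                  cardiac_kurt = 3, peak_z = 3.5) {
  as.list(environment())
}

#' Label independent components by artifact class
#'
#' Heuristic classifier over documented features: blink (frontal-dominant
#' topography, sub-5 Hz power, skewed amplitude distribution), eye movement
#' (lateral-frontal dipolar topography, slow step-like course), myogenic
#' (>20 Hz power, low lag-1 autocorrelation), cardiac/pulse (quasi-periodic
#' peak train with inter-peak intervals in the cardiac range; spiky trains
#' labeled cardiac, smooth ones pulse); everything else neural.
#'
#' @param dec an `eeg_ica` from [eeg_decompose()].
#' @param rec the recording the decomposition was computed on (positions and
#'   sampling rate are taken from the decomposition itself; `rec` is
#'   accepted for interface symmetry and checked for consistency).
#' @param thresholds a [classifier_thresholds()] list.
#' @return the decomposition with `labels` filled.
#' @export
classify_components <- function(dec, rec = NULL,
                                thresholds = classifier_thresholds()) {
  stopifnot(inherits(dec, "eeg_ica"))
  if (!is.null(rec) && !identical(rec$channel_names, dec$channel_names))
    stop("decomposition was not computed on this recording")
  if (is.null(dec$positions))
    stop("electrode positions are required for topography features")
  th <- thresholds
  pu <- unit_sphere_positions(dec$positions)
  frontal <- pu[, 2] > th$frontal_y
  labels <- character(dec$n_components)
  for (k in seq_len(dec$n_components)) {
    m <- dec$mixing[, k]
    m2 <- m^2 / sum(m^2)
    s <- dec$sources[k, ]
    f <- component_features(s, dec$srate, th)
    frontal_frac <- sum(m2[frontal])
    dipolar <- 0; balance <- 0
    if (any(frontal)) {
      mf <- m[frontal]
      xf <- pu[frontal, 1]
      dipolar <- abs(sum(mf * sign(xf))) / (sum(abs(mf)) + 1e-12)
      wl <- sum(abs(mf[xf < 0])); wr <- sum(abs(mf[xf > 0]))
      balance <- min(wl, wr) / (max(wl, wr) + 1e-12)
    }
    dur_s <- ncol(dec$sources) / dec$srate
    labels[k] <-
      if (frontal_frac > th$blink_frontal && f$low_frac > th$blink_low &&
          f$skew > th$blink_skew && f$kurt > th$blink_kurt &&
          dipolar <= th$em_dipolar) "blink"
      else if (frontal_frac > th$blink_frontal && dipolar > th$em_dipolar &&
               balance >= th$em_balance && f$low_frac > th$em_low)
        "eye_movement"
      else if (f$high_frac > th$myo_high && f$lag1 < th$myo_lag1 &&
               f$burst_cv > th$myo_burst) "myogenic"
      else if (f$periodic &&
               f$ipi_med >= th$heart_period[1] &&
               f$ipi_med <= th$heart_period[2] &&
               f$ipi_cv < th$heart_cv &&
               f$n_peaks >= th$heart_coverage * dur_s / f$ipi_med) {
        if (f$kurt > th$cardiac_kurt) "cardiac" else "pulse"
      } else "neural"
  }
  dec$labels <- labels
  dec
}

component_features <- function(s, srate, th) {
  n <- length(s)
  s <- s - mean(s)
  sdv <- stats::sd(s)
  if (sdv == 0)
    return(list(low_frac = 0, high_frac = 0, skew = 0, lag1 = 1,
                periodic = FALSE, ipi_med = NA, ipi_cv = NA, kurt = 0,
                n_peaks = 0, burst_cv = 0))
  p <- Mod(stats::fft(s)[seq_len(floor(n / 2))])^2
  fr <- (seq_along(p) - 1) * srate / n
  tot <- sum(p)
  low_frac <- sum(p[fr < 5]) / tot
  high_frac <- sum(p[fr > 20]) / tot
  z <- s / sdv
  skew <- mean(z^3)
  kurt <- mean(z^4) - 3
  # "lag-1" autocorrelation evaluated on a ~256 Hz time base: at the native
  # rate every band-limited source has near-unit lag-1 correlation
  lg <- max(1L, round(srate / 128))
  lag1 <- stats::cor(s[seq_len(n - lg)], s[(lg + 1):n])
  # peak train: local maxima of |z| above threshold, >= 250 ms apart
  pk <- which(abs(z) > th$peak_z)
  pk <- pk[abs(z[pk]) >= pmax(abs(z[pmax(pk - 1, 1)]), abs(z[pmin(pk + 1, n)]))]
  if (length(pk) > 1) {
    keep <- c(TRUE, diff(pk) > 0.25 * srate)
    grp <- cumsum(keep)
    pk <- vapply(split(pk, grp), function(ii) ii[which.max(abs(z[ii]))], 1)
  }
  periodic <- FALSE; ipi_med <- NA_real_; ipi_cv <- NA_real_
  if (length(pk) >= 5) {
    ipi <- diff(pk) / srate
    ipi_med <- stats::median(ipi)
    ipi_cv <- stats::IQR(ipi) / ipi_med
    periodic <- TRUE
  }
  # burstiness: variation of the short-time RMS envelope
  wlen <- max(8L, round(0.1 * srate))
  nwin <- n %/% wlen
  env <- sqrt(colMeans(matrix(s[seq_len(nwin * wlen)]^2, wlen)))
  burst_cv <- stats::sd(env) / mean(env)
  list(low_frac = low_frac, high_frac = high_frac, skew = skew, lag1 = lag1,
       periodic = periodic, ipi_med = ipi_med, ipi_cv = ipi_cv, kurt = kurt,
       n_peaks = length(pk), burst_cv = burst_cv)
}

#' Remove labeled components and reproject to sensor space
#'
#' Components whose label is in `drop_labels` are zeroed; the remaining
#' components are mixed back to the sensor space (plus the channel means
#' removed before decomposition). With an empty drop set this returns the
#' rank-`n_components` PCA reconstruction of the input.
#'
#' @param dec a labeled `eeg_ica`.
#' @param rec the recording the decomposition was computed on.
#' @param drop_labels component labels to remove.
#' @return the artifact-reduced recording.
#' @export
remove_and_reproject <- function(dec, rec,
                                 drop_labels = c("blink", "eye_movement",
                                                 "myogenic", "cardiac",
                                                 "pulse")) {
  stopifnot(inherits(dec, "eeg_ica"), inherits(rec, "eeg_recording"))
  if (!identical(rec$channel_names, dec$channel_names))
    stop("decomposition was not computed on this recording")
  if (all(is.na(dec$labels)) && length(drop_labels))
    stop("labels not filled; run classify_components() first")
  keep <- !(dec$labels %in% drop_labels)
  if (!any(keep)) {
    warning("all components dropped; returning a zero recording")
    return(with_data(rec, matrix(0, nrow(rec$data), ncol(rec$data))))
  }
  recon <- dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$center
  with_data(rec, recon)
}
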