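#' Configuration for the synthetic dry-EEG generator
#'
#' Defaults emulate a 64-channel dry-electrode recording sampled at 1,024 Hz:
#' a spatially smooth 1/f-plus-alpha background, frontal eye blinks, lateral
#' frontal eye-movement steps, high-frequency myogenic bursts on rim
#' channels, quasi-periodic cardiac interference, uncorrelated sensor noise,
#' and transient single-channel high-amplitude jumps occupying on average
#' 1.3% of channel-time (the share observed in dry recordings of this kind).
#'
#' @param n_channels electrode count (default 64).
#' @param srate sampling rate in Hz (default 1024).
#' @param duration recording length in seconds.
#' @param seed integer seed; all randomness flows from it through
#'   deterministically derived per-component substreams.
#' @param blink_rate eye blinks per minute.
#' @param eye_movement_rate saccade-like steps per minute.
#' @param emg_burst_rate myogenic bursts per minute.
#' @param heart_rate beats per minute.
#' @param jump_fraction target share of channel-time occupied by jump
#'   artifacts (default 0.013).
#' @param jump_amplitude_range jump step amplitude range in microvolts.
#' @param background_power broadband background power per channel, uV^2.
#' @param background_alpha_power 10 Hz alpha power per channel, uV^2.
#' @param sensor_noise_sd per-channel white sensor noise SD, microvolts.
#' @param n_runs,reps_per_task task-paradigm structure for
#'   [generate_task_events()]: runs and repetitions of each of the four
#'   tasks (L, R, T, F) per run.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_channels = 64, srate = 1024, duration = 60,
                         seed = 1, blink_rate = 12, eye_movement_rate = 6,
                         emg_burst_rate = 4, heart_rate = 70,
                         jump_fraction = 0.013,
                         jump_amplitude_range = c(200, 800),
                         background_power = 49, background_alpha_power = 9,
                         sensor_noise_sd = 8,
                         n_runs = 1, reps_per_task = 10) {
  if (n_channels <= 0 || duration <= 0)
    stop("n_channels and duration must be positive")
  rates <- c(blink_rate, eye_movement_rate, emg_burst_rate, heart_rate)
  if (any(rates < 0)) stop("event rates must be non-negative")
  if (jump_fraction < 0 || jump_fraction >= 0.5)
    stop("jump_fraction must lie in [0, 0.5)")
  if (srate <= 2 * 100)
    stop("srate must exceed twice the highest generated frequency (100 Hz)")
  stopifnot(length(jump_amplitude_range) == 2,
            all(jump_amplitude_range > 0),
            diff(jump_amplitude_range) >= 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic dry-EEG recording with ground truth
#'
#' Emits a recording plus an exact additive decomposition: the recording
#' equals `clean` plus every artifact component plus the jump matrix, summed
#' in the order blink, eye_movement, emg, cardiac, sensor_noise, jumps.
#' The background (`clean`) is synthesized from the lowest-quartile SPHARA
#' basis functions of the montage mesh modulated by AR(2)-filtered noise,
#' plus a posterior 10 Hz alpha oscillation projected into the same
#' low-spatial-frequency span — i.e. a spatially smooth signal by
#' construction, matching the separation (correlated signal, uncorrelated
#' noise) that spatial harmonic filtering assumes. Jumps are single-channel
#' step-plus-exponential-return transients (time constant 0.3 s, small
#' negative rebound) with step amplitudes drawn from
#' `jump_amplitude_range`.
#'
#' @param config a [synth_config()].
#' @param montage optional montage (list with `names`, `positions`);
#'   defaults to [dry_montage()] of `config$n_channels`.
#' @return list with `recording` (an [eeg_recording()]) and `ground_truth`
#'   (list: `clean`, `artifact_components` named list of matrices,
#'   `jumps` matrix, `jump_periods` data frame with 0-based half-open sample
#'   intervals `channel`, `start`, `end`, `amplitude`).
#' @export
generate_recording <- function(config, montage = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(montage)) montage <- dry_montage(config$n_channels)
  pos <- montage$positions
  nch <- nrow(pos)
  if (nch != config$n_channels) stop("montage size disagrees with config")
  ns <- round(config$duration * config$srate)
  tt <- (seq_len(ns) - 1) / config$srate

  with_preserved_rng({
    seed_rng(config$seed)
    sub <- derive_substreams(7)

    basis <- sphara_basis(sensor_mesh(pos, montage$names))
    clean <- synth_background(config, basis, pos, ns, sub[1])
    blink <- synth_blink(config, pos, ns, tt, sub[2])
    eyem <- synth_eye_movement(config, pos, ns, tt, sub[3])
    emg <- synth_emg(config, pos, ns, sub[4])
    card <- synth_cardiac(config, pos, ns, tt, sub[5])
    noise <- synth_sensor_noise(config, nch, ns, sub[6])
    jm <- synth_jumps(config, nch, ns, sub[7])

    data <- clean + blink + eyem + emg + card + noise + jm$jumps
    rec <- eeg_recording(data, config$srate, montage$names, pos)
    gt <- list(clean = clean,
               artifact_components = list(blink = blink, eye_movement = eyem,
                                          emg = emg, cardiac = card,
                                          sensor_noise = noise),
               jumps = jm$jumps, jump_periods = jm$periods)
    list(recording = rec, ground_truth = gt)
  })
}

# ---- component synthesizers -------------------------------------------------

synth_background <- function(config, basis, pos, ns, seed) {
  seed_rng(seed)
  n <- ncol(basis$vectors)
  nq <- max(2L, floor(n / 4))
  ks <- 2:nq                          # lowest-quartile BFs, constant excluded
  pats <- basis$vectors[, ks, drop = FALSE]
  pats <- sweep(pats, 2, sqrt(colMeans(pats^2)), "/")   # unit channel RMS
  w <- 1 / seq_along(ks)
  w <- w * sqrt(config$background_power / sum(w^2))
  bg <- matrix(0, n, ns)
  for (i in seq_along(ks)) {
    x <- ar2_lowpass(ns, config$srate)
    bg <- bg + outer(pats[, i], w[i] * x)
  }
  if (config$background_alpha_power > 0) {
    # posterior alpha bump projected into the low-spatial-frequency span
    pu <- unit_sphere_positions(pos)
    bump <- exp(-(rowSums(sweep(pu, 2, c(0, -0.85, 0.45))^2)) / (2 * 0.45^2))
    co <- crossprod(basis$vectors[, 1:nq, drop = FALSE], basis$mass %*% bump)
    pat <- basis$vectors[, 1:nq, drop = FALSE] %*% co
    pat <- pat / sqrt(mean(pat^2))
    env <- abs(ar2_lowpass(ns, config$srate, pole = 0.999))
    env <- env / sqrt(mean(env^2))
    tt <- (seq_len(ns) - 1) / config$srate
    osc <- sqrt(2 * config$background_alpha_power) *
      sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) * env
    bg <- bg + outer(as.vector(pat), osc)
  }
  bg
}

ar2_lowpass <- function(ns, srate, pole = 0.995) {
  e <- stats::rnorm(ns + 200)
  x <- stats::filter(e, c(2 * pole, -pole^2), method = "recursive")
  x <- as.numeric(x)[-(1:200)]
  x / stats::sd(x)
}

synth_blink <- function(config, pos, ns, tt, seed) {
  seed_rng(seed)
  out <- matrix(0, nrow(pos), ns)
  n_ev <- stats::rpois(1, config$blink_rate / 60 * config$duration)
  if (n_ev == 0 || config$blink_rate == 0) return(out)
  pu <- unit_sphere_positions(pos)
  w <- exp(-rowSums(sweep(pu, 2, c(0, 0.95, 0.31))^2) / (2 * 0.35^2))
  w <- w / max(w)
  srate <- config$srate
  for (i in seq_len(n_ev)) {
    on <- stats::runif(1, 0, config$duration - 0.35)
    dur <- stats::runif(1, 0.2, 0.35)
    amp <- stats::rnorm(1, 130, 25)
    idx <- which(tt >= on & tt < on + dur)
    out[, idx] <- out[, idx] + outer(w, amp * sin(pi * (tt[idx] - on) / dur)^2)
  }
  out
}

synth_eye_movement <- function(config, pos, ns, tt, seed) {
  seed_rng(seed)
  out <- matrix(0, nrow(pos), ns)
  n_ev <- stats::rpois(1, config$eye_movement_rate / 60 * config$duration)
  if (n_ev == 0 || config$eye_movement_rate == 0) return(out)
  pu <- unit_sphere_positions(pos)
  w <- pu[, 1] * exp(-2 * (1 - pu[, 2]))    # lateral-frontal dipole
  w <- w / max(abs(w))
  srate <- config$srate
  ramp_s <- 0.04
  for (i in seq_len(n_ev)) {
    on <- stats::runif(1, 0, config$duration - 1)
    dur <- stats::runif(1, 0.3, 0.9)
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 40, 90)
    rel <- tt - on
    s <- numeric(ns)
    s[rel >= 0 & rel < ramp_s] <- rel[rel >= 0 & rel < ramp_s] / ramp_s
    s[rel >= ramp_s & rel < dur - ramp_s] <- 1
    fall <- rel >= dur - ramp_s & rel < dur
    s[fall] <- (dur - rel[fall]) / ramp_s
    out <- out + outer(w, amp * s)
  }
  out
}

synth_emg <- function(config, pos, ns, seed) {
  seed_rng(seed)
  out <- matrix(0, nrow(pos), ns)
  n_ev <- stats::rpois(1, config$emg_burst_rate / 60 * config$duration)
  if (n_ev == 0 || config$emg_burst_rate == 0) return(out)
  pu <- unit_sphere_positions(pos)
  rim <- which(pu[, 3] < stats::quantile(pu[, 3], 0.35))   # temporal/peripheral
  bf <- signal::butter(4, c(20, 100) / (config$srate / 2), "pass")
  srate <- config$srate
  for (i in seq_len(n_ev)) {
    ctr <- sample(rim, 1)
    d2 <- rowSums(sweep(pu, 2, pu[ctr, ])^2)
    w <- exp(-d2 / (2 * 0.25^2))
    dur <- stats::runif(1, 0.3, 1.5)
    on <- stats::runif(1, 0, config$duration - dur)
    len <- round(dur * srate)
    raw <- as.numeric(signal::filter(bf, stats::rnorm(len + 200)))[-(1:200)]
    raw <- raw / stats::sd(raw) * stats::runif(1, 15, 35)
    raw <- raw * sin(pi * seq_len(len) / len)^2           # burst envelope
    i0 <- round(on * srate)
    idx <- (i0 + 1):min(i0 + len, ns)
    out[, idx] <- out[, idx] + outer(w, raw[seq_along(idx)])
  }
  out
}

synth_cardiac <- function(config, pos, ns, tt, seed) {
  seed_rng(seed)
  out <- matrix(0, nrow(pos), ns)
  if (config$heart_rate <= 0) return(out)
  pu <- unit_sphere_positions(pos)
  # broad, left-lateralized field typical of cardiac far-field interference
  w <- 0.6 - 0.4 * pu[, 1] + 0.2 * pu[, 2]
  w <- w / max(abs(w))
  rr <- 60 / config$heart_rate
  beats <- c()
  t0 <- stats::runif(1, 0, rr)
  while (t0 < config$duration) {
    beats <- c(beats, t0)
    t0 <- t0 + rr * (1 + stats::rnorm(1, 0, 0.03))
  }
  srate <- config$srate
  qrs_t <- seq(0, 0.08, by = 1 / srate)
  qrs <- exp(-((qrs_t - 0.02) / 0.008)^2) - 0.45 * exp(-((qrs_t - 0.045) / 0.014)^2)
  amp <- stats::runif(1, 10, 20)
  s <- numeric(ns)
  for (b in beats) {
    i0 <- round(b * srate)
    idx <- i0 + seq_along(qrs)
    ok <- idx <= ns
    s[idx[ok]] <- s[idx[ok]] + amp * qrs[ok]
  }
  out + outer(w, s)
}

synth_sensor_noise <- function(config, nch, ns, seed) {
  seed_rng(seed)
  if (config$sensor_noise_sd == 0) return(matrix(0, nch, ns))
  matrix(stats::rnorm(nch * ns, 0, config$sensor_noise_sd), nch, ns)
}

synth_jumps <- function(config, nch, ns, seed) {
  seed_rng(seed)
  jumps <- matrix(0, nch, ns)
  periods <- list()
  if (config$jump_fraction == 0)
    return(list(jumps = jumps,
                periods = data.frame(channel = integer(), start = integer(),
                                     end = integer(), amplitude = numeric())))
  mean_dur <- 0.9                      # uniform(0.3, 1.5) s
  lam <- config$jump_fraction * config$duration / mean_dur
  srate <- config$srate
  tau <- 0.3
  for (ch in seq_len(nch)) {
    n_ev <- stats::rpois(1, lam)
    if (n_ev == 0) next
    ons <- sort(stats::runif(n_ev, 0, config$duration - 0.3))
    durs <- stats::runif(n_ev, 0.3, 1.5)
    last_end <- -Inf
    for (i in seq_len(n_ev)) {
      s0 <- round(ons[i] * srate)
      s1 <- min(ns, s0 + round(durs[i] * srate))
      if (s0 < last_end || s1 <= s0) next          # keep periods disjoint
      amp <- sample(c(-1, 1), 1) *
        stats::runif(1, config$jump_amplitude_range[1],
                     config$jump_amplitude_range[2])
      rel <- (seq(s0, s1 - 1) - s0) / srate
      shape <- 1.25 * exp(-rel / tau) - 0.25 * exp(-rel / (3 * tau))
      jumps[ch, (s0 + 1):s1] <- jumps[ch, (s0 + 1):s1] + amp * shape
      periods[[length(periods) + 1L]] <-
        data.frame(channel = ch, start = s0, end = s1, amplitude = amp)
      last_end <- s1
    }
  }
  periods <- if (length(periods)) do.call(rbind, periods)
  else data.frame(channel = integer(), start = integer(),
                  end = integer(), amplitude = numeric())
  list(jumps = jumps, periods = periods)
}

#' Generate task event markers for the motor paradigm
#'
#' Emits `reps_per_task` trials of each of the four task labels (L, R, T, F)
#' per run, in randomized order, each trial 7 s long with inter-trial gaps
#' drawn uniformly from 0.5-2.5 s.
#'
#' @param config a [synth_config()] (`n_runs`, `reps_per_task`, `duration`,
#'   `seed`, `srate` are used).
#' @param trial_dur trial length in seconds (default 7).
#' @return data frame with `label` and `onset` (0-based sample index).
#' @export
generate_task_events <- function(config, trial_dur = 7) {
  stopifnot(inherits(config, "synth_config"))
  if (config$reps_per_task == 0 || config$n_runs == 0)
    return(data.frame(label = character(), onset = integer()))
  with_preserved_rng({
    seed_rng(config$seed + 104729L)   # event substream
    labels <- c()
    onsets <- c()
    t0 <- 0
    for (run in seq_len(config$n_runs)) {
      seq_lab <- sample(rep(c("L", "R", "T", "F"), config$reps_per_task))
      for (lab in seq_lab) {
        labels <- c(labels, lab)
        onsets <- c(onsets, round(t0 * config$srate))
        t0 <- t0 + trial_dur + stats::runif(1, 0.5, 2.5)
      }
    }
    if ((onsets[length(onsets)] / config$srate + trial_dur) > config$duration)
      stop("recording duration too short for the requested trials")
    data.frame(label = labels, onset = as.integer(onsets))
  })
}

# ---- RNG plumbing -----------------------------------------------------------

seed_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

derive_substreams <- function(n) sample.int(.Machine$integer.max - 1L, n)

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
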