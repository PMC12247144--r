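# Shared fixtures, all generated in code.

# single right triangle in the xy-plane; closed-form FEM element matrices
right_triangle_mesh <- function() {
  structure(list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 names = c("a", "b", "c"),
                 triangles = matrix(1:3, 1),
                 stiffness = NULL, mass = NULL),
            class = "sensor_mesh")
}

# regular planar grid of nx x ny points spanning [0,Lx] x [0,Ly]
grid_positions <- function(nx, ny, Lx = 1, Ly = 1) {
  g <- expand.grid(x = seq(0, Lx, length.out = nx),
                   y = seq(0, Ly, length.out = ny))
  cbind(g$x, g$y, 0)
}

# background-only generator config (no artifacts, no noise unless asked)
quiet_config <- function(duration = 10, seed = 1, n_channels = 64,
                         sensor_noise_sd = 0, ...) {
  synth_config(n_channels = n_channels, duration = duration, seed = seed,
               blink_rate = 0, eye_movement_rate = 0, emg_burst_rate = 0,
               heart_rate = 0, jump_fraction = 0,
               sensor_noise_sd = sensor_noise_sd, ...)
}

# inject one step-plus-decay jump into a recording; returns recording + period
inject_jump <- function(rec, channel, onset_s, dur_s = 1, amp = 400) {
  srate <- rec$srate
  s0 <- round(onset_s * srate)
  s1 <- s0 + round(dur_s * srate)
  rel <- (seq(s0, s1 - 1) - s0) / srate
  shape <- 1.25 * exp(-rel / 0.3) - 0.25 * exp(-rel / 0.9)
  rec$data[channel, (s0 + 1):s1] <- rec$data[channel, (s0 + 1):s1] + amp * shape
  list(rec = rec, channel = channel, start = s0, end = s1)
}

rms <- function(x) sqrt(mean(x^2))
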