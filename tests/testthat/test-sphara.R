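basis_of <- function(n) {
  mt <- dry_montage(n)
  sphara_basis(sensor_mesh(mt$positions, mt$names))
}

test_that("basis is mass-orthonormal with a constant zero-frequency mode", {
  m <- assemble_fem(right_triangle_mesh())
  b <- sphara_basis(m)
  # hand solution of the 3x3 generalized problem: lambda0 = 0, v0 = sqrt(2)
  expect_lt(abs(b$eigenvalues[1]), 1e-10)
  expect_lt(max(abs(b$vectors[, 1] - sqrt(2))), 1e-8)
  for (n in c(16, 64)) {
    b <- basis_of(n)
    G <- crossprod(b$vectors, b$mass %*% b$vectors)
    expect_lt(max(abs(G - diag(n))), 1e-8)
    expect_lt(abs(b$eigenvalues[1]), 1e-8 * max(b$eigenvalues))
    v0 <- b$vectors[, 1]
    expect_lt(diff(range(v0)) / max(abs(v0)), 1e-6)
    expect_true(!is.unsorted(b$eigenvalues))
  }
})

test_that("generalized eigenpairs match a brute-force symmetrized dense solve", {
  for (n in c(6, 10)) {
    mt <- dry_montage(n)
    m <- sensor_mesh(mt$positions, mt$names)
    b <- sphara_basis(m)
    # independent route: eigen-decompose M^(-1/2) S M^(-1/2) via eigen(M)
    em <- eigen(m$mass, symmetric = TRUE)
    Msqrt_inv <- em$vectors %*% diag(1 / sqrt(em$values)) %*% t(em$vectors)
    C <- Msqrt_inv %*% m$stiffness %*% Msqrt_inv
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE)
    lam <- rev(ev$values)
    expect_lt(max(abs(lam - b$eigenvalues)), 1e-8 * max(1, max(lam)))
    V <- Msqrt_inv %*% ev$vectors[, n:1]
    for (k in seq_len(n)) {
      align <- abs(sum(V[, k] * (m$mass %*% b$vectors[, k])))
      expect_lt(abs(align - 1), 1e-8)
    }
  }
})

test_that("second basis function on a planar rectangle has one nodal line on the long axis", {
  nx <- 8; ny <- 8
  pos <- grid_positions(nx, ny, Lx = 1, Ly = 0.6)
  b <- sphara_basis(sensor_mesh(pos))
  v <- matrix(b$vectors[, 2], nx, ny)   # grid filled x-fastest
  sign_changes <- function(x) sum(diff(sign(x[abs(x) > 1e-10])) != 0)
  expect_true(all(apply(v, 2, sign_changes) == 1))  # along x (long axis)
  expect_true(all(apply(v, 1, sign_changes) == 0))  # constant along y
})

test_that("analyze/synthesize is an exact, Parseval-preserving round trip", {
  b <- basis_of(32)
  set.seed(11)
  x <- matrix(rnorm(32 * 100, sd = 20), 32)
  co <- sphara_analyze(b, x)
  back <- sphara_synthesize(b, co)
  expect_lt(max(abs(back - x)), 1e-9 * max(abs(x)))
  # Parseval in the mass inner product, per sample
  p_chan <- colSums(x * (b$mass %*% x))
  p_coef <- colSums(co^2)
  expect_lt(max(abs(p_chan - p_coef)), 1e-9 * max(p_chan))
  # unit coefficient <-> basis column
  xk <- matrix(b$vectors[, 5], ncol = 1)
  ck <- sphara_analyze(b, xk)
  expect_lt(max(abs(ck - replace(numeric(32), 5, 1))), 1e-8)
  expect_identical(unname(sphara_analyze(b, x * 0)), matrix(0, 32, 100))
  # truncated coefficients stay in the span of the leading columns
  K <- 7
  xt <- sphara_synthesize(b, co[seq_len(K), , drop = FALSE])
  resid <- sphara_analyze(b, xt)[(K + 1):32, ]
  expect_lt(max(abs(resid)), 1e-9 * max(abs(co)))
})

test_that("power-subset selection follows the cumulative low-frequency rule", {
  b <- basis_of(16)
  # data spanned by the first three basis functions
  co <- matrix(0, 16, 4); co[1:3, ] <- rnorm(12)
  x <- sphara_synthesize(b, co)
  expect_identical(sphara_select_power(b, x, 0.95), 3L)
  expect_identical(sphara_select_power(b, x, 1.0), 3L)
  # constructed power profile 0.90 / 0.04 / 0.03 / 0.03: K = 3 at 95%
  p <- c(0.90, 0.04, 0.03, 0.03, numeric(12))
  x1 <- sphara_synthesize(b, matrix(sqrt(p), ncol = 1))
  expect_identical(sphara_select_power(b, x1, 0.95), 3L)
  # full-rank data with retained power 1 needs every basis function
  set.seed(2)
  xf <- matrix(rnorm(16 * 50), 16)
  expect_identical(sphara_select_power(b, xf, 1.0), 16L)
  expect_error(sphara_select_power(b, xf * 0), "zero")
})

test_that("Butterworth spatial gains hit the textbook anchor points", {
  b <- basis_of(32)
  # spatial DC passes untouched
  x0 <- matrix(b$vectors[, 1], 32, 10)
  spec <- spatial_filter_spec(cutoff_frequency = b$natural_frequencies[10])
  expect_lt(max(abs(sphara_filter(b, x0, spec) - x0)), 1e-9 * max(abs(x0)))
  # half-power at the cutoff frequency
  xk <- matrix(b$vectors[, 10], 32, 5)
  out <- sphara_filter(b, xk, spec)
  expect_lt(max(abs(out - xk / sqrt(2))), 1e-9)
  # gains non-increasing with spatial frequency
  g <- (1 + (b$natural_frequencies / b$natural_frequencies[10])^4)^(-0.5)
  expect_true(all(diff(g) <= 1e-12))
})

test_that("spatial filtering leaves temporal phase untouched and is linear/shift-invariant", {
  b <- basis_of(32)
  srate <- 256; n <- 512
  tt <- (seq_len(n) - 1) / srate
  x <- outer(b$vectors[, 6], sin(2 * pi * 12 * tt + 0.7))
  spec <- spatial_filter_spec(cutoff_frequency = b$natural_frequencies[6])
  y <- sphara_filter(b, x, spec)
  bin <- 12 * n / srate + 1
  for (ch in c(1, 15, 32)) {
    if (max(abs(y[ch, ])) < 1e-9) next
    ph_in <- Arg(fft(x[ch, ])[bin])
    ph_out <- Arg(fft(y[ch, ])[bin])
    expect_lt(abs(ph_in - ph_out), 1e-9)
  }
  # linearity
  set.seed(4)
  a <- matrix(rnorm(32 * 64), 32); c2 <- matrix(rnorm(32 * 64), 32)
  lhs <- sphara_filter(b, 2 * a - 3 * c2, spec)
  rhs <- 2 * sphara_filter(b, a, spec) - 3 * sphara_filter(b, c2, spec)
  expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(lhs)))
  # commutes with temporal shift
  sh <- cbind(a[, 11:64], a[, 1:10])
  y1 <- sphara_filter(b, sh, spec)
  y0 <- sphara_filter(b, a, spec)
  expect_lt(max(abs(y1 - cbind(y0[, 11:64], y0[, 1:10]))), 1e-9 * max(abs(y0)))
})

test_that("filtering synthetic background plus sensor noise lowers the error in every seeded run", {
  for (s in 1:10) {
    gen <- generate_recording(quiet_config(duration = 8, seed = 500 + s,
                                           sensor_noise_sd = 8))
    rec <- gen$recording
    bg <- gen$ground_truth$clean
    b <- sphara_basis(sensor_mesh(rec$positions, rec$channel_names))
    filt <- sphara_filter(b, rec$data, spatial_filter_spec())
    expect_lt(rms(filt - bg), rms(rec$data - bg))
  }
})
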