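#' Compute the SPHARA basis of a sensor mesh
#'
#' Spatial harmonic analysis (SPHARA) generalizes spatial Fourier analysis to
#' irregularly placed sensors: the basis functions (BFs) are eigenvectors of
#' the generalized problem `S v = lambda M v`, where `S` and `M` are the FEM
#' stiffness and mass matrices of the Laplace-Beltrami operator on the
#' triangulated sensor surface. Eigenpairs are sorted by ascending
#' eigenvalue, mass-orthonormalized (`V' M V = I`) and sign-fixed so each
#' column's maximum-magnitude entry is positive. The first BF is constant
#' (spatial DC, eigenvalue 0); the natural spatial frequency of BF k is
#' `sqrt(lambda_k)`.
#'
#' The solve is a dense symmetric reduction: with Cholesky `M = R'R`,
#' eigenvectors of the symmetrized `R^-T S R^-1` are back-transformed by
#' `R^-1`. At EEG scale (n <= 256 channels) this is exact and fast.
#'
#' @param mesh a `sensor_mesh` with FEM matrices assembled.
#' @return A `sphara_basis`: `vectors` (n x n, columns = BFs), `eigenvalues`
#'   (ascending, >= 0 up to round-off), `natural_frequencies`
#'   (`sqrt(eigenvalues)`), `mass` (the defining inner product), `names`.
#' @export
sphara_basis <- function(mesh) {
  stopifnot(inherits(mesh, "sensor_mesh"))
  if (is.null(mesh$stiffness)) stop("assemble FEM matrices first (assemble_fem)")
  S <- mesh$stiffness
  M <- mesh$mass
  R <- tryCatch(chol(M), error = function(e)
    stop("mass matrix is not positive definite"))
  Rinv <- backsolve(R, diag(nrow(M)))
  C <- t(Rinv) %*% S %*% Rinv
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  ord <- order(eg$values)            # ascending; eigen() returns descending
  lam <- eg$values[ord]
  V <- Rinv %*% eg$vectors[, ord, drop = FALSE]
  # sign convention: maximum-absolute entry of each BF positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- mesh$names
  structure(list(vectors = V, eigenvalues = lam,
                 natural_frequencies = sqrt(pmax(lam, 0)),
                 mass = M, names = mesh$names),
            class = "sphara_basis")
}

#' @export
print.sphara_basis <- function(x, ...) {
  cat(sprintf("<sphara_basis> %d basis functions; natural frequencies [%.4g, %.4g]\n",
              ncol(x$vectors), min(x$natural_frequencies), max(x$natural_frequencies)))
  invisible(x)
}

#' Plot SPHARA eigenvalue spectrum
#' @param x a `sphara_basis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sphara_basis <- function(x, ...) {
  graphics::plot(seq_along(x$natural_frequencies) - 1, x$natural_frequencies,
                 xlab = "basis function index", ylab = "natural spatial frequency",
                 pch = 20, ...)
  invisible(x)
}

#' Export a SPHARA basis
#'
#' Writes the eigenvalue table (index, eigenvalue, natural frequency, one
#' row per basis function) as CSV and the basis arrays as an RDS container
#' next to it.
#'
#' @param basis a `sphara_basis`.
#' @param basename output path without extension.
#' @return `basename`, invisibly.
#' @export
write_sphara_basis <- function(basis, basename) {
  utils::write.csv(data.frame(index = seq_along(basis$eigenvalues) - 1L,
                              eigenvalue = basis$eigenvalues,
                              natural_frequency = basis$natural_frequencies),
                   paste0(basename, "_eigenvalues.csv"), row.names = FALSE)
  saveRDS(basis, paste0(basename, "_basis.rds"))
  invisible(basename)
}

#' Transform sensor data to and from the spatial-frequency domain
#'
#' `sphara_analyze` computes per-sample basis coefficients
#' `c = V' M x` (the mass inner product of the data with each BF);
#' `sphara_synthesize` inverts it (`x = V c`). With the full basis the round
#' trip is exact to numerical precision, and the transform is an isometry
#' with respect to the mass inner product (Parseval).
#'
#' @param basis a `sphara_basis`.
#' @param data channels x samples matrix (microvolts), channel order matching
#'   the mesh.
#' @return `sphara_analyze`: n_basis x samples coefficient matrix.
#' @export
sphara_analyze <- function(basis, data) {
  data <- as.matrix(data)
  if (nrow(data) != nrow(basis$vectors))
    stop("data has ", nrow(data), " channels; basis expects ", nrow(basis$vectors))
  if (!is.null(rownames(data)) && !identical(rownames(data), basis$names))
    stop("data channel order does not match the mesh vertex order")
  crossprod(basis$vectors, basis$mass %*% data)
}

#' @param coefficients n_basis x samples coefficient matrix (possibly
#'   truncated to the first K rows).
#' @rdname sphara_analyze
#' @return `sphara_synthesize`: channels x samples matrix.
#' @export
sphara_synthesize <- function(basis, coefficients) {
  coefficients <- as.matrix(coefficients)
  K <- nrow(coefficients)
  if (K > ncol(basis$vectors)) stop("more coefficient rows than basis functions")
  out <- basis$vectors[, seq_len(K), drop = FALSE] %*% coefficients
  rownames(out) <- basis$names
  out
}

#' Smallest low-frequency basis subset retaining a power fraction
#'
#' Per-BF power is summed over time (`p_k = sum_t c_k(t)^2`); the result K is
#' the smallest count such that the K lowest-frequency BFs carry at least
#' `retained_power` of the total. Used to derive the spatial cutoff of
#' [sphara_filter()] per recording.
#'
#' @inheritParams sphara_analyze
#' @param retained_power fraction of total power to retain (0, 1].
#' @return integer K.
#' @export
sphara_select_power <- function(basis, data, retained_power = 0.95) {
  stopifnot(retained_power > 0, retained_power <= 1)
  co <- sphara_analyze(basis, data)
  p <- rowSums(co^2)
  total <- sum(p)
  if (total == 0) stop("cannot select a power subset of all-zero data")
  K <- which(cumsum(p) >= retained_power * total - 1e-12 * total)[1]
  as.integer(K)
}

#' Spatial filter specification
#'
#' @param order Butterworth order (>= 1); default 2.
#' @param cutoff_frequency spatial cutoff in natural-frequency units, or
#'   `NULL` to derive it from `retained_power` per recording.
#' @param retained_power power fraction used to derive the cutoff when
#'   `cutoff_frequency` is `NULL`; default 0.95. A value >= 1 disables
#'   attenuation entirely (infinite cutoff).
#' @param mode `"butterworth"` (smooth gain) or `"truncation"` (hard cutoff
#'   after the K-th BF).
#' @return A `spatial_filter_spec` list.
#' @export
spatial_filter_spec <- function(order = 2, cutoff_frequency = NULL,
                                retained_power = 0.95,
                                mode = c("butterworth", "truncation")) {
  mode <- match.arg(mode)
  stopifnot(order >= 1, retained_power > 0, retained_power <= 1)
  if (!is.null(cutoff_frequency) && cutoff_frequency <= 0)
    stop("cutoff_frequency must be positive")
  structure(list(order = order, cutoff_frequency = cutoff_frequency,
                 retained_power = retained_power, mode = mode),
            class = "spatial_filter_spec")
}

#' Apply a SPHARA spatial low-pass filter
#'
#' Each time sample is filtered identically and independently in the spatial
#' frequency domain: the coefficient of BF k is scaled by the order-`order`
#' Butterworth gain `g_k = (1 + (f_k/f_c)^(2 order))^(-1/2)` with `f_k` the
#' BF's natural frequency, then synthesized back to sensor space. The filter
#' is purely spatial, so temporal phase is untouched. When no explicit
#' cutoff is given, `f_c` is the natural frequency of the K-th BF from
#' [sphara_select_power()]; `retained_power >= 1` yields unit gain
#' everywhere.
#'
#' @inheritParams sphara_analyze
#' @param spec a [spatial_filter_spec()].
#' @return filtered channels x samples matrix; the selected cutoff and K are
#'   attached as attributes `cutoff_frequency` and `K`.
#' @export
sphara_filter <- function(basis, data, spec = spatial_filter_spec()) {
  stopifnot(inherits(spec, "spatial_filter_spec"))
  n <- ncol(basis$vectors)
  if (is.null(spec$cutoff_frequency)) {
    if (spec$retained_power >= 1) {
      K <- n
      fc <- Inf
    } else {
      K <- sphara_select_power(basis, data, spec$retained_power)
      fc <- basis$natural_frequencies[K]
      if (fc <= 0) fc <- basis$natural_frequencies[min(K + 1, n)]
    }
  } else {
    fc <- spec$cutoff_frequency
    K <- max(1L, sum(basis$natural_frequencies <= fc))
  }
  if (!is.infinite(fc) && fc <= 0) stop("spatial cutoff frequency must be positive")
  co <- sphara_analyze(basis, data)
  if (spec$mode == "truncation") {
    g <- as.numeric(seq_len(n) <= K)
  } else if (is.infinite(fc)) {
    g <- rep(1, n)
  } else {
    g <- (1 + (basis$natural_frequencies / fc)^(2 * spec$order))^(-0.5)
  }
  out <- sphara_synthesize(basis, co * g)
  attr(out, "cutoff_frequency") <- fc
  attr(out, "K") <- K
  out
}
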