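#' Standard 64-channel dry-cap electrode layout
#'
#' Deterministic hemispherical cap layout used by the synthetic generator: a
#' sunflower (golden-angle) arrangement of `n` electrodes on a unit sphere,
#' covering inclinations from the vertex down to `max_incl` degrees, which
#' approximates the coverage of a 64-channel dry cap (frontal, temporal and
#' occipital rim channels sit below the equator of the superior hemisphere).
#' +y is anterior (nasion), +x is right, +z is up.
#'
#' @param n number of electrodes.
#' @param max_incl largest inclination from the vertex, degrees.
#' @return list with `names` (character) and `positions` (n x 3 matrix,
#'   unit-sphere coordinates).
#' @export
dry_montage <- function(n = 64, max_incl = 105) {
  stopifnot(n >= 4, max_incl > 0, max_incl <= 150)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n) - 1L
  # equal-area spacing in cos(theta) over the cap
  cmin <- cos(max_incl * pi / 180)
  ct <- 1 - (k + 0.5) / n * (1 - cmin)
  theta <- acos(ct)
  phi <- k * golden
  pos <- cbind(x = sin(theta) * cos(phi),
               y = sin(theta) * sin(phi),
               z = ct)
  nm <- sprintf("E%02d", seq_len(n))
  rownames(pos) <- nm
  list(names = nm, positions = pos)
}

#' Read / write a plain-text electrode montage
#'
#' Whitespace-delimited file with one line per channel: `name x y z`.
#'
#' @param path file path.
#' @return `read_montage`: list with `names` and `positions` as in
#'   [dry_montage()].
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  rownames(pos) <- tab$name
  list(names = tab$name, positions = pos)
}

#' @param montage list with `names` and `positions`.
#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  tab <- data.frame(name = montage$names, montage$positions)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Normalize positions onto the unit sphere. Centre is the least-squares
# sphere-fit centre; falls back to the centroid for degenerate layouts.
unit_sphere_positions <- function(pos) {
  ctr <- fit_sphere_center(pos)
  p <- sweep(pos, 2, ctr)
  r <- sqrt(rowSums(p^2))
  if (any(r == 0)) stop("electrode coincides with sphere centre")
  p / r
}

fit_sphere_center <- function(pos) {
  # |p - c|^2 = r^2  ->  2 p.c - |c|^2 + r^2 = |p|^2 : linear in (c, t)
  A <- cbind(2 * pos, 1)
  b <- rowSums(pos^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) colMeans(pos) else sol[1:3]
}

# Azimuthal-equidistant projection about the +z axis (cap apex -> origin).
# Used both for mesh triangulation and for topographic export.
azimuthal_project <- function(pos_unit) {
  z <- pmin(1, pmax(-1, pos_unit[, 3]))
  theta <- acos(z)
  phi <- atan2(pos_unit[, 2], pos_unit[, 1])
  rho <- theta
  out <- cbind(x = rho * cos(phi), y = rho * sin(phi))
  out[theta < 1e-12, ] <- 0
  rownames(out) <- rownames(pos_unit)
  out
}
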