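#' Triangulate electrode positions into a sensor surface mesh
#'
#' EEG montages are open caps (disk topology), so the triangulation is a 2D
#' Delaunay triangulation computed in a projection plane and mapped back to
#' the 3D electrode positions: near-planar layouts are projected onto their
#' principal plane, cap-like layouts through an azimuthal-equidistant
#' projection about the cap apex. Triangles are oriented counter-clockwise in
#' the projection, which makes surface normals consistent (outward for caps).
#'
#' @param positions n x 3 numeric matrix of electrode positions (n >= 4).
#' @param names optional channel names (rownames of `positions` by default).
#' @return A `sensor_mesh` with `vertices` (n x 3, input order preserved) and
#'   `triangles` (m x 3 vertex indices, 1-based); FEM matrices unfilled until
#'   [assemble_fem()].
#' @seealso [sensor_mesh()] for the one-call constructor.
#' @export
triangulate_sensors <- function(positions, names = NULL) {
  positions <- as.matrix(positions)
  if (is.null(names)) names <- rownames(positions)
  if (is.null(names)) names <- sprintf("E%02d", seq_len(nrow(positions)))
  n <- nrow(positions)
  if (n < 4) stop("need at least 4 electrode positions")
  dup <- duplicated(round(positions, 10))
  if (any(dup))
    stop("duplicate electrode position(s): ", paste(names[dup], collapse = ", "))

  ctr <- colMeans(positions)
  sv <- svd(sweep(positions, 2, ctr))
  if (sv$d[2] < 1e-9 * sv$d[1])
    stop("electrode positions are collinear; cannot triangulate")
  planar <- sv$d[3] < 1e-6 * sv$d[1]
  if (planar) {
    xy <- sweep(positions, 2, ctr) %*% sv$v[, 1:2]
  } else {
    xy <- azimuthal_project(unit_sphere_positions(positions))
  }
  dxy <- round(xy, 10)
  if (anyDuplicated(dxy))
    stop("electrode positions project onto each other: ",
         paste(names[duplicated(dxy)], collapse = ", "))

  dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  tri <- t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
  # enforce counter-clockwise orientation in the projection plane
  for (t in seq_len(nrow(tri))) {
    a <- xy[tri[t, 1], ]; b <- xy[tri[t, 2], ]; c <- xy[tri[t, 3], ]
    if ((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]) < 0)
      tri[t, ] <- tri[t, c(1, 3, 2)]
  }
  isolated <- setdiff(seq_len(n), unique(as.vector(tri)))
  if (length(isolated))
    stop("vertices not part of any triangle: ",
         paste(names[isolated], collapse = ", "))
  structure(list(vertices = positions, names = names, triangles = tri,
                 stiffness = NULL, mass = NULL),
            class = "sensor_mesh")
}

#' Assemble FEM stiffness and mass matrices on a sensor mesh
#'
#' Linear-element finite-element discretization of the Laplace-Beltrami
#' operator on the triangulated sensor surface: the stiffness matrix uses
#' cotangent weights (for an edge ij shared by triangles with opposite angles
#' alpha, beta: `S_ij = -(cot alpha + cot beta)/2`, diagonal minus the row
#' sum), and the consistent mass matrix accumulates per-triangle
#' `A/12 * [[2,1,1],[1,2,1],[1,1,2]]` with A the triangle area. Natural
#' (Neumann) boundary conditions: no boundary modification, so constants span
#' the stiffness null space. Cotangents of obtuse angles are kept signed
#' unless `clamp_cot` is set.
#'
#' @param mesh a `sensor_mesh` from [triangulate_sensors()].
#' @param clamp_cot clamp negative cotangent weights to 0 (off by default;
#'   only useful for pathological montages).
#' @return The mesh with `stiffness` and `mass` filled (dense symmetric
#'   matrices, channel order preserved).
#' @export
assemble_fem <- function(mesh, clamp_cot = FALSE) {
  stopifnot(inherits(mesh, "sensor_mesh"))
  V <- mesh$vertices
  Tm <- mesh$triangles
  n <- nrow(V)
  S <- matrix(0, n, n)
  M <- matrix(0, n, n)
  for (t in seq_len(nrow(Tm))) {
    id <- Tm[t, ]
    p <- V[id, , drop = FALSE]
    e <- list(p[3, ] - p[2, ], p[1, ] - p[3, ], p[2, ] - p[1, ])  # edge opposite vertex i
    cr <- cross3(e[[3]], -e[[2]])
    area <- 0.5 * sqrt(sum(cr^2))
    if (area < 1e-14)
      stop("zero-area triangle among channels ",
           paste(mesh$names[id], collapse = ", "))
    for (i in 1:3) {
      j <- i %% 3 + 1; k <- j %% 3 + 1
      # cot of the angle at vertex i (between edges to j and to k)
      u <- p[j, ] - p[i, ]; v <- p[k, ] - p[i, ]
      cot_i <- sum(u * v) / sqrt(sum(cross3(u, v)^2))
      w <- 0.5 * cot_i
      if (clamp_cot) w <- max(w, 0)
      S[id[j], id[k]] <- S[id[j], id[k]] - w
      S[id[k], id[j]] <- S[id[k], id[j]] - w
      S[id[j], id[j]] <- S[id[j], id[j]] + w
      S[id[k], id[k]] <- S[id[k], id[k]] + w
    }
    Me <- area / 12 * (matrix(1, 3, 3) + diag(3))
    M[id, id] <- M[id, id] + Me
  }
  dimnames(S) <- dimnames(M) <- list(mesh$names, mesh$names)
  mesh$stiffness <- S
  mesh$mass <- M
  mesh
}

#' Build a fully assembled sensor mesh in one call
#'
#' @inheritParams triangulate_sensors
#' @inheritParams assemble_fem
#' @return A `sensor_mesh` with geometry and FEM matrices.
#' @export
sensor_mesh <- function(positions, names = NULL, clamp_cot = FALSE) {
  assemble_fem(triangulate_sensors(positions, names), clamp_cot = clamp_cot)
}

#' @export
print.sensor_mesh <- function(x, ...) {
  cat(sprintf("<sensor_mesh> %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$stiffness)) " (FEM matrices not assembled)"
              else sprintf(", surface area %.4g", mesh_area(x))))
  invisible(x)
}

#' Total surface area of a sensor mesh
#' @param mesh a `sensor_mesh`.
#' @return scalar area in squared position units.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices
  sum(apply(mesh$triangles, 1, function(id) {
    0.5 * sqrt(sum(cross3(V[id[2], ] - V[id[1], ], V[id[3], ] - V[id[1], ])^2))
  }))
}

#' Vertex adjacency of a sensor mesh
#' @param mesh a `sensor_mesh`.
#' @return list, per vertex, of the indices of mesh-edge neighbours.
#' @export
mesh_neighbors <- function(mesh) {
  n <- nrow(mesh$vertices)
  nb <- vector("list", n)
  for (t in seq_len(nrow(mesh$triangles))) {
    id <- mesh$triangles[t, ]
    for (i in 1:3) nb[[id[i]]] <- union(nb[[id[i]]], id[-i])
  }
  lapply(nb, sort)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Export / import mesh geometry as OFF
#'
#' Plain-text Object File Format: vertex coordinates then 0-based triangle
#' indices.
#' @param mesh a `sensor_mesh`.
#' @param path file path.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  ln <- readLines(path)
  stopifnot(ln[1] == "OFF")
  counts <- scan(text = ln[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  V <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  Fc <- matrix(as.integer(scan(text = ln[(3 + nv):(2 + nv + nf)],
                               quiet = TRUE)), nf, 4, byrow = TRUE)
  structure(list(vertices = V, names = sprintf("E%02d", seq_len(nv)),
                 triangles = Fc[, 2:4, drop = FALSE] + 1L,
                 stiffness = NULL, mass = NULL),
            class = "sensor_mesh")
}

#' Write a symmetric matrix as sparse triplet text
#' @param m matrix.
#' @param path file path.
#' @export
write_sparse_triplets <- function(m, path) {
  idx <- which(m != 0, arr.ind = TRUE)
  utils::write.table(data.frame(i = idx[, 1], j = idx[, 2], x = m[idx]),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
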