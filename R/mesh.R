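# Finite-volume tissue meshes.
#
# A tissue_mesh is a cell-centred finite-volume mesh: per-cell centroid,
# volume and region label, plus an interior-face table (cell pair, area,
# centroid distance, unit normal).  Outer boundaries are zero-flux by
# construction (no boundary faces are stored).  Units: mm, mm^2, mm^3.

#' Construct a finite-volume tissue mesh
#'
#' @param centroids n x 3 matrix of cell centroids (mm).
#' @param volume Per-cell volume (mm^3).
#' @param faces data.frame with columns `i`, `j` (1-based cell indices),
#'   `area` (mm^2), `dist` (centroid distance, mm), `nx`, `ny`, `nz`
#'   (unit normal from i to j) and optionally `label` (face tag used by
#'   conduction-block switches).
#' @param region Character vector of per-cell region labels.
#' @param dim Intrinsic dimension (1, 2 or 3).
#' @param spacing Nominal grid spacing (mm), used by diagnostics.
#' @return Object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(centroids, volume, faces, region = NULL,
                        dim = 3L, spacing = NA_real_) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) < 3)
    centroids <- cbind(centroids, matrix(0, nrow(centroids),
                                         3 - ncol(centroids)))
  n <- nrow(centroids)
  stopifnot(length(volume) == n, all(volume > 0), all(faces$area > 0),
            all(faces$dist > 0), all(faces$i >= 1), all(faces$j <= n))
  if (is.null(region)) region <- rep("tissue", n)
  if (is.null(faces$label)) faces$label <- NA_character_
  structure(list(centroids = centroids, volume = as.numeric(volume),
                 faces = faces, region = as.character(region),
                 dim = as.integer(dim), spacing = spacing, n_cells = n),
            class = "tissue_mesh")
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %dD, %d cells, %d interior faces; regions: %s\n",
              x$dim, x$n_cells, nrow(x$faces),
              paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

#' 1D cable mesh
#'
#' @param length_mm Cable length (default 20 mm).
#' @param dx Cell size (default 0.1 mm).
#' @param cross_section Cross-sectional area, mm^2 (cancels out of the
#'   monodomain equation; kept for bookkeeping).
#' @param region Region label.
#' @return A `tissue_mesh`.
#' @export
mesh_cable <- function(length_mm = 20, dx = 0.1, cross_section = 0.01,
                       region = "tissue") {
  n <- round(length_mm / dx)
  x <- (seq_len(n) - 0.5) * dx
  faces <- data.frame(i = seq_len(n - 1), j = 2:n,
                      area = cross_section, dist = dx,
                      nx = 1, ny = 0, nz = 0)
  tissue_mesh(cbind(x, 0, 0), rep(cross_section * dx, n), faces,
              region = rep(region, n), dim = 1L, spacing = dx)
}

#' 2D sheet mesh (structured quadrilaterals)
#'
#' @param lx,ly Sheet dimensions (mm).
#' @param dx Cell size (mm).
#' @param thickness Out-of-plane thickness (mm).
#' @return A `tissue_mesh`; cells ordered x-fastest.
#' @export
mesh_sheet <- function(lx = 10, ly = 10, dx = 0.2, thickness = 0.5) {
  nx <- round(lx / dx); ny <- round(ly / dx)
  ij <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cent <- cbind((ij$ix - 0.5) * dx, (ij$iy - 0.5) * dx, 0)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  fx <- expand.grid(ix = seq_len(nx - 1), iy = seq_len(ny))
  fy <- expand.grid(ix = seq_len(nx), iy = seq_len(ny - 1))
  faces <- rbind(
    data.frame(i = id(fx$ix, fx$iy), j = id(fx$ix + 1L, fx$iy),
               area = dx * thickness, dist = dx, nx = 1, ny = 0, nz = 0),
    data.frame(i = id(fy$ix, fy$iy), j = id(fy$ix, fy$iy + 1L),
               area = dx * thickness, dist = dx, nx = 0, ny = 1, nz = 0))
  tissue_mesh(cent, rep(dx * dx * thickness, nx * ny), faces,
              dim = 2L, spacing = dx)
}

#' 3D slab mesh (structured voxels)
#'
#' @param lx,ly,lz Slab dimensions (mm); `lz` is transmural.
#' @param dx Voxel size (mm).
#' @return A `tissue_mesh`; cells ordered x-fastest, then y, then z.
#' @export
mesh_slab <- function(lx = 10, ly = 10, lz = 3, dx = 0.5) {
  nx <- round(lx / dx); ny <- round(ly / dx); nz <- round(lz / dx)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  cent <- cbind((g$ix - 0.5) * dx, (g$iy - 0.5) * dx, (g$iz - 0.5) * dx)
  id <- function(ix, iy, iz) ((iz - 1L) * ny + (iy - 1L)) * nx + ix
  f <- list()
  gx <- expand.grid(ix = seq_len(nx - 1), iy = seq_len(ny), iz = seq_len(nz))
  f$x <- data.frame(i = id(gx$ix, gx$iy, gx$iz),
                    j = id(gx$ix + 1L, gx$iy, gx$iz),
                    area = dx^2, dist = dx, nx = 1, ny = 0, nz = 0)
  gy <- expand.grid(ix = seq_len(nx), iy = seq_len(ny - 1), iz = seq_len(nz))
  f$y <- data.frame(i = id(gy$ix, gy$iy, gy$iz),
                    j = id(gy$ix, gy$iy + 1L, gy$iz),
                    area = dx^2, dist = dx, nx = 0, ny = 1, nz = 0)
  gz <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz - 1))
  f$z <- data.frame(i = id(gz$ix, gz$iy, gz$iz),
                    j = id(gz$ix, gz$iy, gz$iz + 1L),
                    area = dx^2, dist = dx, nx = 0, ny = 0, nz = 1)
  tissue_mesh(cent, rep(dx^3, nx * ny * nz), do.call(rbind, f),
              dim = 3L, spacing = dx)
}

#' Per-cell orthonormal fiber triads
#'
#' @param mesh A `tissue_mesh`.
#' @param rule `"uniform"`: fiber axis constant (`angle0` in the x-y plane);
#'   `"transmural"`: in-plane fiber angle rotates linearly from `angle0` at
#'   the inner (`z = z_min`) face to `angle1` at the outer face (the
#'   classical +60 to -60 degree transmural rotation).
#' @param angle0,angle1 Degrees. Defaults +60 / -60 for `"transmural"`,
#'   0 for `"uniform"`.
#' @return Object of class `fiber_frame`: list of n x 3 matrices `e_fiber`,
#'   `e_sheet`, `e_normal` (orthonormal per cell).
#' @export
fiber_frames <- function(mesh, rule = c("uniform", "transmural"),
                         angle0 = NULL, angle1 = NULL) {
  rule <- match.arg(rule)
  n <- mesh$n_cells
  if (rule == "uniform") {
    a <- rep(if (is.null(angle0)) 0 else angle0, n) * pi / 180
  } else {
    if (is.null(angle0)) angle0 <- 60
    if (is.null(angle1)) angle1 <- -60
    z <- mesh$centroids[, 3]
    zr <- range(z)
    frac <- if (diff(zr) > 0) (z - zr[1]) / diff(zr) else rep(0.5, n)
    a <- (angle0 + frac * (angle1 - angle0)) * pi / 180
  }
  frame_from_angles(a)
}

frame_from_angles <- function(a) {
  ef <- cbind(cos(a), sin(a), 0)
  es <- cbind(-sin(a), cos(a), 0)
  en <- cbind(0 * a, 0 * a, 1 + 0 * a)
  structure(list(e_fiber = ef, e_sheet = es, e_normal = en),
            class = "fiber_frame")
}

#' Build a fiber frame from explicit axes
#'
#' @param e_fiber,e_sheet,e_normal n x 3 matrices; each row triad must be
#'   orthonormal (checked to 1e-10).
#' @return A `fiber_frame`.
#' @export
fiber_frame <- function(e_fiber, e_sheet, e_normal) {
  fr <- structure(list(e_fiber = as.matrix(e_fiber),
                       e_sheet = as.matrix(e_sheet),
                       e_normal = as.matrix(e_normal)),
                  class = "fiber_frame")
  check_orthonormal(fr)
  fr
}

check_orthonormal <- function(fr, tol = 1e-10) {
  d <- function(m) abs(rowSums(m * m) - 1)
  cr <- function(a, b) abs(rowSums(a * b))
  err <- max(d(fr$e_fiber), d(fr$e_sheet), d(fr$e_normal),
             cr(fr$e_fiber, fr$e_sheet), cr(fr$e_fiber, fr$e_normal),
             cr(fr$e_sheet, fr$e_normal))
  if (err > tol) stop(sprintf("fiber triads not orthonormal (max dev %.2e)", err))
  invisible(TRUE)
}

# --- tetrahedral meshes -----------------------------------------------------

tet_volume <- function(nodes, tets) {
  a <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  b <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  c_ <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Finite-volume mesh from a tetrahedral mesh
#'
#' Shared triangular faces become interior finite-volume faces; the face
#' normal is oriented from cell i to cell j and the transfer distance is
#' the centroid-to-centroid distance.
#'
#' @param nodes n_nodes x 3 matrix (mm).
#' @param tets n_tets x 4 integer matrix of node indices.
#' @param region Per-tet region labels.
#' @return A `tissue_mesh` with one cell per tet.
#' @export
tet_fv_mesh <- function(nodes, tets, region = NULL) {
  nodes <- as.matrix(nodes); tets <- as.matrix(tets)
  vol <- tet_volume(nodes, tets)
  if (any(vol <= 0)) {
    # re-orient inverted tets
    neg <- vol < 0
    tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    vol <- abs(vol)
  }
  cent <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
           nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  # four faces per tet, keyed by sorted node triple
  tri_idx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  ntet <- nrow(tets)
  tris <- matrix(0L, 4L * ntet, 3)
  owner <- rep(seq_len(ntet), each = 4)
  for (k in 1:4) {
    tri <- tets[, tri_idx[k, ], drop = FALSE]
    tris[seq(k, by = 4, length.out = ntet), ] <- t(apply(tri, 1, sort))
  }
  key <- paste(tris[, 1], tris[, 2], tris[, 3])
  dup <- split(seq_along(key), key)
  shared <- dup[lengths(dup) == 2L]
  m <- length(shared)
  fi <- integer(m); fj <- integer(m); farea <- numeric(m)
  fnrm <- matrix(0, m, 3); fdist <- numeric(m)
  kk <- 0L
  for (s in shared) {
    kk <- kk + 1L
    ci <- owner[s[1]]; cj <- owner[s[2]]
    tri <- tris[s[1], ]
    p1 <- nodes[tri[1], ]; p2 <- nodes[tri[2], ]; p3 <- nodes[tri[3], ]
    cr <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
            (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
            (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    a2 <- sqrt(sum(cr^2))
    d <- cent[cj, ] - cent[ci, ]
    dd <- sqrt(sum(d^2))
    fi[kk] <- ci; fj[kk] <- cj; farea[kk] <- a2 / 2
    fnrm[kk, ] <- d / dd; fdist[kk] <- dd
  }
  faces <- data.frame(i = fi, j = fj, area = farea, dist = fdist,
                      nx = fnrm[, 1], ny = fnrm[, 2], nz = fnrm[, 3])
  tissue_mesh(cent, vol, faces, region = region, dim = 3L)
}
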