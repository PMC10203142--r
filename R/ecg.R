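# Synthetic surface ECG via the infinite-medium lead-field integral:
# assuming isotropic torso conductivity, the potential at an electrode x_s
# is V_s = -K int grad(v) . grad(1/|x - x_s|) dx over the cardiac domain.
# One-point (centroid) quadrature per finite-volume cell; per-cell
# gradients from a least-squares reconstruction over face neighbours.

#' Electrode positions and gain
#'
#' @param positions Matrix (n_leads x 3) of electrode coordinates (mm) on
#'   the torso box.
#' @param K Gain constant lumping the intracellular/torso conductivity
#'   ratio; the default 1 gives arbitrary units.
#' @return Object of class `lead_set`.
#' @export
lead_set <- function(positions, K = 1) {
  positions <- matrix(positions, ncol = 3)
  structure(list(positions = positions, K = K), class = "lead_set")
}

#' Least-squares gradient reconstruction operator
#'
#' Precomputes, per cell, the weights mapping neighbour value differences
#' to a gradient estimate; returns a function `v -> n x 3` gradients.
#'
#' @param mesh A `tissue_mesh`.
#' @return Function of a per-cell field.
#' @export
gradient_operator <- function(mesh) {
  n <- mesh$n_cells
  f <- mesh$faces
  nb <- vector("list", n)
  for (k in seq_len(nrow(f))) {
    nb[[f$i[k]]] <- c(nb[[f$i[k]]], f$j[k])
    nb[[f$j[k]]] <- c(nb[[f$j[k]]], f$i[k])
  }
  trip <- list(i = integer(0), j = integer(0))
  W <- list(x = numeric(0), y = numeric(0), z = numeric(0))
  for (c_ in seq_len(n)) {
    js <- nb[[c_]]
    if (length(js) == 0) next
    D <- mesh$centroids[js, , drop = FALSE] -
      matrix(mesh$centroids[c_, ], length(js), 3, byrow = TRUE)
    keep_dim <- apply(abs(D), 2, max) > 1e-12
    A <- D[, keep_dim, drop = FALSE]
    # weights: pinv' rows -> gradient = P %*% dv
    P <- tryCatch(solve(crossprod(A), t(A)), error = function(e) NULL)
    if (is.null(P)) next
    Pfull <- matrix(0, 3, length(js))
    Pfull[keep_dim, ] <- P
    trip$i <- c(trip$i, rep(c_, length(js)))
    trip$j <- c(trip$j, js)
    W$x <- c(W$x, Pfull[1, ]); W$y <- c(W$y, Pfull[2, ])
    W$z <- c(W$z, Pfull[3, ])
  }
  mk <- function(w) {
    M <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = w, dims = c(n, n))
    Matrix::Diagonal(x = -as.numeric(M %*% rep(1, n))) + M
  }
  Gx <- mk(W$x); Gy <- mk(W$y); Gz <- mk(W$z)
  function(v) cbind(as.numeric(Gx %*% v), as.numeric(Gy %*% v),
                    as.numeric(Gz %*% v))
}

#' Surface potential at one electrode
#'
#' `V_s = -K sum_c (grad v)_c . grad(1/r)_c V_c` with `r = |x_c - x_s|`;
#' linear in `v` and exactly zero for a spatially uniform field.
#'
#' @param mesh A `tissue_mesh`.
#' @param v Per-cell transmembrane potential.
#' @param x_s Electrode position (3-vector, mm).
#' @param K Gain. Default 1.
#' @param grad_op Optional precomputed [gradient_operator] (recommended in
#'   loops).
#' @param clearance Minimum electrode distance in cell sizes. Default 5.
#' @return Potential (arbitrary units for K = 1).
#' @export
surface_potential <- function(mesh, v, x_s, K = 1, grad_op = NULL,
                              clearance = 5) {
  d <- sweep(mesh$centroids, 2, x_s)
  r <- sqrt(rowSums(d^2))
  h <- if (is.finite(mesh$spacing)) mesh$spacing else mean(mesh$faces$dist)
  if (min(r) < clearance * h)
    stop("electrode inside the clearance zone of the cardiac mesh")
  if (is.null(grad_op)) grad_op <- gradient_operator(mesh)
  gv <- grad_op(v)
  ginv_r <- -d / r^3          # gradient of 1/r w.r.t. x
  -K * sum(rowSums(gv * ginv_r) * mesh$volume)
}

#' ECG trace from recorded potential frames
#'
#' Evaluates the surface potential of every frame at each lead and the
#' first-minus-second lead difference (the sign convention makes wavefronts
#' travelling towards the apex-side lead register negative deflections).
#'
#' @param mesh A `tissue_mesh`.
#' @param frames List of per-cell v fields.
#' @param times Frame times (ms).
#' @param leads A `lead_set` (two or more electrodes).
#' @return data.frame of class `ecg_trace`: `t`, `V1`, `V2`, ..., `diff`
#'   (= V1 - V2).
#' @export
ecg_trace <- function(mesh, frames, times, leads) {
  if (!length(frames)) stop("no frames recorded")
  stopifnot(length(frames) == length(times))
  gop <- gradient_operator(mesh)
  nl <- nrow(leads$positions)
  V <- matrix(0, length(frames), nl)
  for (f in seq_along(frames))
    for (l in seq_len(nl))
      V[f, l] <- surface_potential(mesh, frames[[f]], leads$positions[l, ],
                                   K = leads$K, grad_op = gop)
  out <- data.frame(t = times)
  for (l in seq_len(nl)) out[[paste0("V", l)]] <- V[, l]
  if (nl >= 2) out$diff <- V[, 1] - V[, 2]
  class(out) <- c("ecg_trace", "data.frame")
  out
}

#' QRS-like activation-spread duration
#'
#' Activation-map definition: last minus first activation time over the
#' (ventricular) cells.  Trace definition: span where the lead-difference
#' magnitude exceeds `threshold` of its beat maximum.
#'
#' @param x An `activation_map` or `ecg_trace`.
#' @param cells Optional cell subset for the map definition.
#' @param threshold Trace threshold fraction. Default 0.05.
#' @return Duration, ms.
#' @export
measure_intervals <- function(x, cells = NULL, threshold = 0.05) {
  if (inherits(x, "activation_map")) {
    t <- x$times
    if (!is.null(cells)) t <- t[cells]
    if (anyNA(t)) stop("incomplete activation: unactivated cells present")
    return(max(t) - min(t))
  }
  if (inherits(x, "ecg_trace")) {
    a <- abs(x$diff)
    if (max(a) == 0) stop("flat trace")
    on <- which(a > threshold * max(a))
    return(x$t[max(on)] - x$t[min(on)])
  }
  stop("need an activation_map or ecg_trace")
}

#' Torso-box lead pair for a cardiac mesh
#'
#' Two electrodes on the heart's vertical axis: one beyond the base, one
#' beyond the apex, each at `skin_distance` from the bounding box (the
#' heart-to-skin distance of an average torso, 35 mm).
#'
#' @param mesh A `tissue_mesh`.
#' @param skin_distance mm. Default 35.
#' @param K Gain. Default 1.
#' @return A `lead_set` (lead 1 basal, lead 2 apical).
#' @export
torso_leads <- function(mesh, skin_distance = 35, K = 1) {
  cz <- range(mesh$centroids[, 3])
  cx <- mean(range(mesh$centroids[, 1]))
  cy <- mean(range(mesh$centroids[, 2]))
  lead_set(rbind(c(cx, cy, cz[2] + skin_distance),
                 c(cx, cy, cz[1] - skin_distance)), K = K)
}
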