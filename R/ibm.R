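# Moving-least-squares (MLS) transfer between the Eulerian grid and
# Lagrangian markers, direct immersed-boundary forcing, Windkessel volume
# forcing and hydrodynamic load evaluation on wet surfaces.

# grid-node coordinates of each staggered component
grid_points <- function(grid, comp = c("u", "v", "p")) {
  comp <- match.arg(comp)
  if (comp == "u") {
    x <- (seq_len(grid$nx) - 1) * grid$dx
    y <- (seq_len(grid$ny) - 0.5) * grid$dy
  } else if (comp == "v") {
    x <- (seq_len(grid$nx) - 0.5) * grid$dx
    y <- (seq_len(grid$nvy) - 1) * grid$dy +
      if (grid$bc_y == "periodic") 0 else 0
  } else {
    x <- (seq_len(grid$nx) - 0.5) * grid$dx
    y <- (seq_len(grid$ny) - 0.5) * grid$dy
  }
  list(x = x, y = y)
}

# MLS shape functions with a linear basis and a compact quartic-spline
# kernel over a 3-cell-wide support; reproduces constants and linears.
mls_shape_functions <- function(px, py, xq, yq, rs) {
  d <- sqrt((px - xq)^2 + (py - yq)^2) / rs
  w <- ifelse(d < 1, (1 - d^2)^4, 0)
  keep <- w > 0
  if (sum(keep) < 3) stop("degenerate MLS support (marker outside fluid?)")
  P <- cbind(1, px[keep] - xq, py[keep] - yq)
  A <- t(P * w[keep]) %*% P
  if (rcond(A) < 1e-12) stop("degenerate MLS moment matrix")
  phi_k <- as.numeric(solve(A, t(P * w[keep]))[1, ])
  phi <- numeric(length(px)); phi[keep] <- phi_k
  phi
}

# stencil of grid nodes around (xq, yq) with periodic wrapping in x (and y
# when periodic); returns index/coordinate vectors
mls_stencil <- function(grid, comp, xq, yq) {
  gp <- grid_points(grid, comp)
  h <- max(grid$dx, grid$dy)
  rs <- 1.6 * h
  nx <- length(gp$x); nyc <- length(gp$y)
  x0 <- gp$x[1]; y0 <- gp$y[1]
  ic <- round((xq - x0) / grid$dx) + 1
  jc <- round((yq - y0) / grid$dy) + 1
  ii <- (ic - 2):(ic + 2)
  jj <- (jc - 2):(jc + 2)
  iw <- ((ii - 1) %% nx) + 1
  px_off <- (ii - iw) * grid$dx            # periodic image offset
  if (grid$bc_y == "periodic") {
    jw <- ((jj - 1) %% nyc) + 1
    py_off <- (jj - jw) * grid$dy
  } else {
    keep <- jj >= 1 & jj <= nyc
    jj <- jj[keep]; jw <- jj; py_off <- rep(0, length(jj))
  }
  g <- expand.grid(a = seq_along(iw), b = seq_along(jw))
  list(idx = cbind(iw[g$a], jw[g$b]),
       px = gp$x[iw[g$a]] + px_off[g$a],
       py = gp$y[jw[g$b]] + py_off[g$b],
       rs = rs)
}

#' MLS interpolation from a grid field to markers
#'
#' Linear-basis moving-least-squares with a compact quartic kernel over a
#' 3-cell-wide support: constants and linear fields are reproduced exactly.
#'
#' @param grid A `flow_grid`.
#' @param field Matrix on the staggered component grid.
#' @param comp `"u"`, `"v"` or `"p"` (which staggered grid the field lives
#'   on).
#' @param xm,ym Marker coordinates (m).
#' @return Numeric vector of interpolated values.
#' @export
mls_interp <- function(grid, field, comp, xm, ym) {
  n <- length(xm)
  out <- numeric(n)
  for (m in seq_len(n)) {
    st <- mls_stencil(grid, comp, xm[m], ym[m])
    phi <- mls_shape_functions(st$px, st$py, xm[m], ym[m], st$rs)
    out[m] <- sum(phi * field[st$idx])
  }
  out
}

#' MLS spreading from markers to a grid field (transpose of interpolation)
#'
#' Uses the same shape functions as [mls_interp], scaled by the marker
#' measure over the cell volume, so that the discrete inner-product
#' identity `<spread(F), u> dV = <F, interp(u)> dA` holds to machine
#' precision and the integral of the transferred quantity is preserved.
#'
#' @inheritParams mls_interp
#' @param values Marker values (force per unit area when spreading IB
#'   forcing).
#' @param area Marker areas (m^2 per unit depth, i.e. segment lengths in
#'   2D).
#' @return Matrix on the component grid (value per unit volume).
#' @export
mls_spread <- function(grid, values, area, comp, xm, ym) {
  dims <- switch(comp, u = c(grid$nx, grid$ny), v = c(grid$nx, grid$nvy),
                 p = c(grid$nx, grid$ny))
  out <- matrix(0, dims[1], dims[2])
  cellv <- grid$dx * grid$dy
  for (m in seq_along(xm)) {
    st <- mls_stencil(grid, comp, xm[m], ym[m])
    phi <- mls_shape_functions(st$px, st$py, xm[m], ym[m], st$rs)
    out[st$idx] <- out[st$idx] + phi * values[m] * area[m] / cellv
  }
  out
}

#' Lagrangian wet-surface markers
#'
#' @param x,y Marker positions (m).
#' @param nx,ny Unit outward normals.
#' @param area Face measure per marker (length in 2D, per unit depth).
#' @param two_sided Logical: thin membrane loaded from both sides (TRUE)
#'   or closed one-sided surface (FALSE).
#' @return data.frame of class `lagrangian_surface`.
#' @export
lagrangian_surface <- function(x, y, nx, ny, area, two_sided = TRUE) {
  nn <- sqrt(nx^2 + ny^2)
  stopifnot(all(abs(nn - 1) < 1e-8), all(area > 0))
  structure(data.frame(x = x, y = y, nx = nx, ny = ny, area = area,
                       two_sided = two_sided),
            class = c("lagrangian_surface", "data.frame"))
}

#' Direct immersed-boundary forcing
#'
#' `f = (U_target - u_interp)/dt` at each marker, spread back to the grid
#' with the transposed MLS operator; after the subsequent flow step the
#' interpolated fluid velocity at the markers matches the targets to the
#' interpolation order.
#'
#' @param grid A `flow_grid`.
#' @param state A `flow_state`.
#' @param markers A `lagrangian_surface`.
#' @param u_target,v_target Desired (structural) marker velocities (m/s).
#' @param dt Time step (s).
#' @return List with `fu`, `fv` (N/m^3) and the marker slip velocities.
#' @export
ib_forcing <- function(grid, state, markers, u_target, v_target, dt) {
  eps_layer <- max(grid$dx, grid$dy)
  cellv <- grid$dx * grid$dy
  solve_component <- function(field, comp, target) {
    m <- nrow(markers)
    interp <- numeric(m)
    sten <- vector("list", m)
    for (k in seq_len(m)) {
      st <- mls_stencil(grid, comp, markers$x[k], markers$y[k])
      phi <- mls_shape_functions(st$px, st$py, markers$x[k], markers$y[k],
                                 st$rs)
      key <- (st$idx[, 2] - 1L) * 1e6 + st$idx[, 1]
      sten[[k]] <- list(idx = st$idx, key = key, phi = phi)
      interp[k] <- sum(phi * field[st$idx])
    }
    # marker-coupling matrix: G[k,l] = sum_i phi_ik phi_il A_l eps / dV
    G <- matrix(0, m, m)
    for (k in seq_len(m)) for (l in seq_len(m)) {
      common <- match(sten[[k]]$key, sten[[l]]$key)
      hit <- !is.na(common)
      if (any(hit))
        G[k, l] <- sum(sten[[k]]$phi[hit] * sten[[l]]$phi[common[hit]]) *
          markers$area[l] * eps_layer / cellv
    }
    slip <- target - interp
    coef <- tryCatch(solve(G, slip),
                     error = function(e)
                       solve(G + 1e-8 * mean(diag(G)) * diag(m), slip))
    force_area <- grid$rho * eps_layer / dt * coef
    list(f = mls_spread(grid, force_area, markers$area, comp,
                        markers$x, markers$y),
         slip = slip)
  }
  su <- solve_component(state$u, "u", u_target)
  sv <- solve_component(state$v, "v", v_target)
  list(fu = su$f, fv = sv$f, slip_u = su$slip, slip_v = sv$slip)
}

#' Windkessel outlet region
#'
#' A forced subdomain standing in for the truncated vasculature: the
#' forcing `-f_WK = alpha u + beta int_0^t u dtau + gamma n` over the
#' masked cells is equivalent to a three-element Windkessel.
#'
#' @param grid A `flow_grid`.
#' @param name Region name (also keys the integral accumulator).
#' @param xlim,ylim Mask bounds (m) of the (cylindrical, here rectangular
#'   2D) subdomain.
#' @param normal Outward unit 2-vector `n_Omega`.
#' @param alpha,beta,gamma Windkessel constants (kg m^-3 s^-1,
#'   kg m^-3 s^-2, kg m^-2 s^-2).
#' @return Object of class `windkessel_region`.
#' @export
windkessel_region <- function(grid, name, xlim, ylim, normal,
                              alpha, beta, gamma) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  normal <- normal / sqrt(sum(normal^2))
  gu <- grid_points(grid, "u"); gv <- grid_points(grid, "v")
  mask_u <- outer(gu$x, gu$y, function(x, y)
    x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2])
  mask_v <- outer(gv$x, gv$y, function(x, y)
    x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2])
  if (!any(mask_u) && !any(mask_v)) stop("empty Windkessel mask")
  structure(list(name = name, mask_u = mask_u, mask_v = mask_v,
                 normal = normal, alpha = alpha, beta = beta, gamma = gamma),
            class = "windkessel_region")
}

#' Windkessel volume forcing
#'
#' Evaluates `f_WK = -(alpha u + beta int u dtau + gamma n_Omega)` over the
#' masked faces; the per-face velocity-history integral is advanced with
#' the trapezoidal rule.
#'
#' @param region A `windkessel_region`.
#' @param grid A `flow_grid`.
#' @param state A `flow_state` (its `wk_int[[name]]` accumulator is used).
#' @param dt Time step (s); use `dt = 0` to evaluate without advancing the
#'   integral.
#' @return List with `fu`, `fv` (N/m^3) and the updated `integrals`.
#' @export
windkessel_forcing <- function(region, grid, state, dt) {
  acc <- state$wk_int[[region$name]]
  if (is.null(acc))
    acc <- list(iu = matrix(0, grid$nx, grid$ny),
                iv = matrix(0, grid$nx, grid$nvy),
                u_prev = matrix(0, grid$nx, grid$ny),
                v_prev = matrix(0, grid$nx, grid$nvy))
  iu <- acc$iu + dt / 2 * (acc$u_prev + state$u)
  iv <- acc$iv + dt / 2 * (acc$v_prev + state$v)
  fu <- matrix(0, grid$nx, grid$ny); fv <- matrix(0, grid$nx, grid$nvy)
  fu[region$mask_u] <- -(region$alpha * state$u[region$mask_u] +
                         region$beta * iu[region$mask_u] +
                         region$gamma * region$normal[1])
  fv[region$mask_v] <- -(region$alpha * state$v[region$mask_v] +
                         region$beta * iv[region$mask_v] +
                         region$gamma * region$normal[2])
  list(fu = fu, fv = fv,
       integrals = list(iu = iu, iv = iv, u_prev = state$u,
                        v_prev = state$v))
}

# cell-centred velocity-gradient components
velocity_gradients <- function(grid, u, v) {
  dudx <- (shx(u, 1) - u) / grid$dx                       # at centres
  vf <- if (grid$bc_y == "periodic") cbind(v, v[, 1]) else v
  dvdy <- (vf[, 2:(grid$ny + 1)] - vf[, 1:grid$ny]) / grid$dy
  # du/dy and dv/dx at centres via corner differences averaged
  up <- pad_y(u, grid$bc_y, tangential = TRUE)
  dudy_f <- (up[, 2:(grid$ny + 2)] - up[, 1:(grid$ny + 1)]) / grid$dy
  dudy_c <- (dudy_f[, 1:grid$ny] + dudy_f[, 2:(grid$ny + 1)]) / 2
  dudy <- (dudy_c + shx(dudy_c, 1)) / 2
  dvdx_f <- (shx(vf, 1) - vf) / grid$dx                   # at corners
  dvdx_c <- (dvdx_f[, 1:grid$ny] + dvdx_f[, 2:(grid$ny + 1)]) / 2
  dvdx <- (dvdx_c + shx(dvdx_c, -1)) / 2
  list(dudx = dudx, dudy = dudy, dvdx = dvdx, dvdy = dvdy)
}

#' Hydrodynamic loads on a wet surface
#'
#' Pressure and viscous stresses are sampled by MLS at probes offset by
#' `offset` grid spacings along the marker normals; two-sided markers
#' (membranes) are loaded by the jump across the surface,
#' `F = [-(p+ - p-) n + (tau+ - tau-) n] A`, one-sided (closed) surfaces
#' by `F = (-p n + tau n) A`.
#'
#' @param grid A `flow_grid`.
#' @param state A `flow_state`.
#' @param markers A `lagrangian_surface`.
#' @param offset Probe offset in grid spacings. Default 1.5.
#' @return data.frame with per-marker force components `fx`, `fy` (N per
#'   unit depth).
#' @export
hydrodynamic_loads <- function(grid, state, markers, offset = 1.5) {
  h <- max(grid$dx, grid$dy)
  gr <- velocity_gradients(grid, state$u, state$v)
  mu <- grid$mu
  # cell-centred pressure gradient, used to correct the probe value back
  # to the surface (removes the first-order offset bias on curved walls)
  dpdx <- (shx(state$p, 1) - shx(state$p, -1)) / (2 * grid$dx)
  pf <- pad_y(state$p, grid$bc_y, tangential = FALSE)
  dpdy <- (pf[, 3:(grid$ny + 2)] - pf[, 1:grid$ny]) / (2 * grid$dy)
  probe <- function(sgn) {
    xq <- markers$x + sgn * offset * h * markers$nx
    yq <- markers$y + sgn * offset * h * markers$ny
    p <- mls_interp(grid, state$p, "p", xq, yq) -
      sgn * offset * h * (markers$nx * mls_interp(grid, dpdx, "p", xq, yq) +
                          markers$ny * mls_interp(grid, dpdy, "p", xq, yq))
    t11 <- 2 * mu * mls_interp(grid, gr$dudx, "p", xq, yq)
    t22 <- 2 * mu * mls_interp(grid, gr$dvdy, "p", xq, yq)
    t12 <- mu * (mls_interp(grid, gr$dudy, "p", xq, yq) +
                 mls_interp(grid, gr$dvdx, "p", xq, yq))
    list(p = p, t11 = t11, t12 = t12, t22 = t22)
  }
  pl <- probe(+1)
  if (any(markers$two_sided)) mn <- probe(-1) else mn <- NULL
  fx <- numeric(nrow(markers)); fy <- numeric(nrow(markers))
  ts <- markers$two_sided
  if (any(ts)) {
    dp <- pl$p[ts] - mn$p[ts]
    dt11 <- pl$t11[ts] - mn$t11[ts]; dt12 <- pl$t12[ts] - mn$t12[ts]
    dt22 <- pl$t22[ts] - mn$t22[ts]
    fx[ts] <- (-dp * markers$nx[ts] + dt11 * markers$nx[ts] +
               dt12 * markers$ny[ts]) * markers$area[ts]
    fy[ts] <- (-dp * markers$ny[ts] + dt12 * markers$nx[ts] +
               dt22 * markers$ny[ts]) * markers$area[ts]
  }
  if (any(!ts)) {
    os <- !ts
    fx[os] <- (-pl$p[os] * markers$nx[os] + pl$t11[os] * markers$nx[os] +
               pl$t12[os] * markers$ny[os]) * markers$area[os]
    fy[os] <- (-pl$p[os] * markers$ny[os] + pl$t12[os] * markers$nx[os] +
               pl$t22[os] * markers$ny[os]) * markers$area[os]
  }
  data.frame(fx = fx, fy = fy)
}
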