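# Incompressible Navier-Stokes on a 2D staggered (MAC) grid.
#
# Fractional-step advancement: explicit Adams-Bashforth convection,
# implicit Crank-Nicolson viscous terms, pressure-Poisson projection to a
# discretely divergence-free field.  The domain is periodic in x; the y
# boundaries are periodic, free-slip or no-slip walls.  Moving immersed
# boundaries are handled by moving-least-squares (MLS) direct forcing;
# truncated vasculature by three-element Windkessel volume forcing.
# SI units (m, s, Pa); blood defaults rho = 1060 kg/m^3, mu = 3.5 mPa s.

#' Create a staggered-grid fluid domain
#'
#' @param nx,ny Number of cells.
#' @param lx,ly Domain size (m).
#' @param bc_y `"periodic"`, `"freeslip"` or `"noslip"` (x is periodic).
#' @param rho Density (kg/m^3). Default 1060.
#' @param mu Dynamic viscosity (Pa s). Default 3.5e-3.
#' @return Object of class `flow_grid` (operators are assembled lazily and
#'   cached per time step by [step_flow]).
#' @export
flow_grid <- function(nx, ny, lx = 1, ly = 1, bc_y = "periodic",
                      rho = 1060, mu = 3.5e-3) {
  bc_y <- match.arg(bc_y, c("periodic", "freeslip", "noslip"))
  g <- list(nx = nx, ny = ny, lx = lx, ly = ly, dx = lx / nx, dy = ly / ny,
            bc_y = bc_y, rho = rho, mu = mu, nvy = if (bc_y == "periodic")
              ny else ny + 1L)
  g$cache <- new.env(parent = emptyenv())
  structure(g, class = "flow_grid")
}

#' Initial flow state
#'
#' @param grid A `flow_grid`.
#' @param u,v Initial velocity matrices (`nx x ny` for u; `nx x nvy` for v).
#' @return Object of class `flow_state`: velocities, cell-centred pressure,
#'   time, previous convection terms and Windkessel integral accumulators.
#' @export
flow_state <- function(grid, u = NULL, v = NULL) {
  if (is.null(u)) u <- matrix(0, grid$nx, grid$ny)
  if (is.null(v)) v <- matrix(0, grid$nx, grid$nvy)
  structure(list(u = u, v = v, p = matrix(0, grid$nx, grid$ny), t = 0,
                 conv_prev = NULL, wk_int = list()),
            class = "flow_state")
}

# x-periodic shifts
shx <- function(M, s) {
  n <- nrow(M)
  M[((seq_len(n) - 1 + s) %% n) + 1, , drop = FALSE]
}

# pad one ghost column on each side in y; value per BC and field parity
pad_y <- function(M, bc, tangential = TRUE) {
  n <- ncol(M)
  if (bc == "periodic") cbind(M[, n], M, M[, 1])
  else if (bc == "freeslip" || !tangential) cbind(M[, 1], M, M[, n])
  else cbind(-M[, 1], M, -M[, n])   # no-slip tangential ghost
}

# convection terms -d(uu)/dx - d(uv)/dy on the u grid and the v analogue
convection <- function(grid, u, v) {
  dx <- grid$dx; dy <- grid$dy
  per <- grid$bc_y == "periodic"
  # --- u component ---
  up <- pad_y(u, grid$bc_y, tangential = TRUE)       # nx x (ny+2)
  # cell-centred (uu): average of faces i, i+1
  ucc <- ((up + shx(up, 1)) / 2)^2                   # at cell centres
  # corners above u(i,j): need v at (i-1,j+1),(i,j+1)
  vfull <- if (per) cbind(v, v[, 1]) else v          # nx x (ny+1)
  vc <- (shx(vfull, -1) + vfull) / 2                 # corner v at u-face x
  uc_top <- (up[, 2:(grid$ny + 1)] + up[, 3:(grid$ny + 2)]) / 2
  uc_bot <- (up[, 1:grid$ny] + up[, 2:(grid$ny + 1)]) / 2
  uv_top <- uc_top * vc[, 2:(grid$ny + 1)]
  uv_bot <- uc_bot * vc[, 1:grid$ny]
  conv_u <- -(ucc[, 2:(grid$ny + 1)] - shx(ucc, -1)[, 2:(grid$ny + 1)]) / dx -
    (uv_top - uv_bot) / dy
  # --- v component ---
  if (per) {
    vp <- cbind(v[, grid$ny], v, v[, 1])             # nx x (ny+2)
    jv <- seq_len(grid$ny)
  } else {
    vp <- cbind(0, v, 0)                             # walls: v=0 ghosts
    jv <- seq_len(grid$ny + 1)
  }
  vcc <- ((vp[, 1:(ncol(vp) - 1)] + vp[, 2:ncol(vp)]) / 2)^2
  dvv <- (vcc[, 2:ncol(vcc), drop = FALSE] -
          vcc[, 1:(ncol(vcc) - 1), drop = FALSE]) / dy  # at v faces
  # corners right of v(i,j): u at (i+1, j-1),(i+1, j)
  upad <- pad_y(u, grid$bc_y, tangential = TRUE)     # nx x (ny+2)
  uface <- shx(upad, 1)                              # u(i+1, .)
  nj <- length(jv)
  uc_r <- (uface[, jv] + uface[, jv + 1]) / 2        # at corner heights
  uc_l <- (upad[, jv] + upad[, jv + 1]) / 2
  vc_r <- (v[, jv, drop = FALSE] + shx(v[, jv, drop = FALSE], 1)) / 2
  vc_l <- (v[, jv, drop = FALSE] + shx(v[, jv, drop = FALSE], -1)) / 2
  conv_v <- matrix(0, grid$nx, grid$nvy)
  conv_v[, jv] <- -dvv[, seq_len(nj)] - (uc_r * vc_r - uc_l * vc_l) / dx
  if (!per) conv_v[, c(1, grid$nvy)] <- 0            # wall faces fixed
  list(u = conv_u, v = conv_v)
}

# sparse Laplacian over the u grid (x periodic)
lap_u <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  k <- matrix(seq_len(nx * ny), nx, ny)
  idx <- function(M, sx, sy) {
    M2 <- shx(M, sx)
    if (sy == 0) return(M2)
    if (grid$bc_y == "periodic")
      M2[, ((seq_len(ny) - 1 + sy) %% ny) + 1, drop = FALSE]
    else {
      # clamp: handled via coefficient adjustment below
      M2[, pmin(pmax(seq_len(ny) + sy, 1), ny), drop = FALSE]
    }
  }
  ax <- 1 / grid$dx^2; ay <- 1 / grid$dy^2
  i0 <- as.vector(k)
  entries <- list(
    data.frame(i = i0, j = as.vector(idx(k, 1, 0)), x = ax),
    data.frame(i = i0, j = as.vector(idx(k, -1, 0)), x = ax),
    data.frame(i = i0, j = i0, x = -2 * ax - 2 * ay))
  if (grid$bc_y == "periodic") {
    entries <- c(entries, list(
      data.frame(i = i0, j = as.vector(idx(k, 0, 1)), x = ay),
      data.frame(i = i0, j = as.vector(idx(k, 0, -1)), x = ay)))
  } else {
    # ghost rows: freeslip ghost = interior (adds +ay to diag);
    # noslip ghost = -interior (adds -ay to diag)
    gsgn <- if (grid$bc_y == "freeslip") 1 else -1
    jn <- as.vector(idx(k, 0, 1)); js <- as.vector(idx(k, 0, -1))
    north_ok <- rep(seq_len(ny) < ny, each = nx)
    south_ok <- rep(seq_len(ny) > 1, each = nx)
    entries <- c(entries, list(
      data.frame(i = i0[north_ok], j = jn[north_ok], x = ay),
      data.frame(i = i0[south_ok], j = js[south_ok], x = ay),
      data.frame(i = i0[!north_ok], j = i0[!north_ok], x = gsgn * ay),
      data.frame(i = i0[!south_ok], j = i0[!south_ok], x = gsgn * ay)))
  }
  e <- do.call(rbind, entries)
  Matrix::sparseMatrix(i = e$i, j = e$j, x = e$x, dims = c(nx * ny, nx * ny))
}

# sparse Laplacian over the v grid; wall faces get identity rows
lap_v <- function(grid) {
  nx <- grid$nx; nvy <- grid$nvy
  k <- matrix(seq_len(nx * nvy), nx, nvy)
  ax <- 1 / grid$dx^2; ay <- 1 / grid$dy^2
  i0 <- as.vector(k)
  per <- grid$bc_y == "periodic"
  interior_j <- if (per) rep(TRUE, nvy) else c(FALSE, rep(TRUE, nvy - 2), FALSE)
  int <- rep(interior_j, each = nx)
  wrap <- function(sx, sy) {
    M2 <- shx(k, sx)
    if (sy != 0) {
      jj <- if (per) ((seq_len(nvy) - 1 + sy) %% nvy) + 1
            else pmin(pmax(seq_len(nvy) + sy, 1), nvy)
      M2 <- M2[, jj, drop = FALSE]
    }
    as.vector(M2)
  }
  entries <- list(
    data.frame(i = i0[int], j = wrap(1, 0)[int], x = ax),
    data.frame(i = i0[int], j = wrap(-1, 0)[int], x = ax),
    data.frame(i = i0[int], j = wrap(0, 1)[int], x = ay),
    data.frame(i = i0[int], j = wrap(0, -1)[int], x = ay),
    data.frame(i = i0[int], j = i0[int], x = -2 * ax - 2 * ay))
  e <- do.call(rbind, entries)
  Matrix::sparseMatrix(i = e$i, j = e$j, x = e$x, dims = c(nx * nvy, nx * nvy))
}

# pressure Poisson operator (Neumann in y for walls, periodic x),
# augmented with a zero-mean gauge row
lap_p <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  k <- matrix(seq_len(nx * ny), nx, ny)
  ax <- 1 / grid$dx^2; ay <- 1 / grid$dy^2
  i0 <- as.vector(k)
  per <- grid$bc_y == "periodic"
  entries <- list(
    data.frame(i = i0, j = as.vector(shx(k, 1)), x = ax),
    data.frame(i = i0, j = as.vector(shx(k, -1)), x = ax))
  jn_ok <- rep(seq_len(ny) < ny, each = nx) | per
  js_ok <- rep(seq_len(ny) > 1, each = nx) | per
  jn <- as.vector(k[, ((seq_len(ny)) %% ny) + 1])
  js <- as.vector(k[, ((seq_len(ny) - 2) %% ny) + 1])
  entries <- c(entries, list(
    data.frame(i = i0[jn_ok], j = jn[jn_ok], x = ay),
    data.frame(i = i0[js_ok], j = js[js_ok], x = ay),
    data.frame(i = i0, j = i0,
               x = -2 * ax - ay * (jn_ok + js_ok))))
  e <- do.call(rbind, entries)
  Matrix::sparseMatrix(i = e$i, j = e$j, x = e$x, dims = c(nx * ny, nx * ny))
}

flow_ops <- function(grid, dt) {
  key <- sprintf("ops_%.12g", dt)
  cache <- grid$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  nu <- grid$mu / grid$rho
  Au <- Matrix::Diagonal(grid$nx * grid$ny) - (dt * nu / 2) * lap_u(grid)
  Av <- Matrix::Diagonal(grid$nx * grid$nvy) - (dt * nu / 2) * lap_v(grid)
  Lp <- lap_p(grid)
  one <- rep(1, grid$nx * grid$ny)
  Aug <- rbind(cbind(Lp, one), c(one, 0))
  ops <- list(
    Lu = lap_u(grid), Lv = lap_v(grid),
    fac_u = Matrix::lu(methods::as(Au, "CsparseMatrix")),
    fac_v = Matrix::lu(methods::as(Av, "CsparseMatrix")),
    fac_p = Matrix::lu(methods::as(Aug, "CsparseMatrix")))
  cache[[key]] <- ops
  ops
}

# discrete divergence at cell centres
flow_divergence <- function(grid, u, v) {
  du <- (shx(u, 1) - u) / grid$dx
  if (grid$bc_y == "periodic") {
    vf <- cbind(v, v[, 1])
  } else vf <- v
  dv <- (vf[, 2:(grid$ny + 1)] - vf[, 1:grid$ny]) / grid$dy
  du + dv
}

#' Advance the flow one fractional step
#'
#' Provisional velocity from AB2 convection + CN diffusion + forcings,
#' then a pressure-Poisson projection restoring a discretely
#' divergence-free field (residual divergence below 1e-8).
#'
#' @param grid A `flow_grid`.
#' @param state A `flow_state`.
#' @param dt Time step (s); the convective CFL must stay below 1.
#' @param forcing Optional list with `fu`, `fv` (body force per unit
#'   volume, N/m^3, on the u/v grids) — immersed-boundary plus Windkessel
#'   plus any driving force.
#' @param wk_regions Optional list of `windkessel_region`s applied
#'   automatically (their integral accumulators live in the state).
#' @param ib Optional immersed boundary: list with `markers` (a
#'   `lagrangian_surface`), `u_target`, `v_target`.  The direct forcing is
#'   evaluated on the provisional velocity so the no-slip targets are met
#'   before the projection.
#' @return Updated `flow_state` (with `ib_force` marker forces when `ib`
#'   is given).
#' @export
step_flow <- function(grid, state, dt, forcing = NULL, wk_regions = NULL,
                      ib = NULL) {
  cfl <- max(abs(state$u) / grid$dx, abs(state$v) / grid$dy) * dt
  if (cfl >= 1) warning(sprintf("convective CFL = %.2f >= 1", cfl))
  ops <- flow_ops(grid, dt)
  nu <- grid$mu / grid$rho
  conv <- convection(grid, state$u, state$v)
  cu <- conv$u; cv <- conv$v
  if (!is.null(state$conv_prev)) {
    cu <- 1.5 * conv$u - 0.5 * state$conv_prev$u
    cv <- 1.5 * conv$v - 0.5 * state$conv_prev$v
  }
  fu <- matrix(0, grid$nx, grid$ny); fv <- matrix(0, grid$nx, grid$nvy)
  if (!is.null(forcing)) {
    if (!is.null(forcing$fu)) fu <- fu + forcing$fu
    if (!is.null(forcing$fv)) fv <- fv + forcing$fv
  }
  if (!is.null(wk_regions)) {
    for (rg in wk_regions) {
      wf <- windkessel_forcing(rg, grid, state, dt)
      fu <- fu + wf$fu; fv <- fv + wf$fv
      state$wk_int[[rg$name]] <- wf$integrals
    }
  }
  # old-pressure gradient (incremental projection)
  gpx <- (state$p - shx(state$p, -1)) / grid$dx
  pf <- if (grid$bc_y == "periodic") cbind(state$p[, grid$ny], state$p)
        else cbind(state$p[, 1], state$p)   # Neumann ghost
  gpy <- (pf[, 2:(grid$ny + 1)] - pf[, 1:grid$ny]) / grid$dy  # at v faces 1..ny
  gv <- matrix(0, grid$nx, grid$nvy)
  if (grid$bc_y == "periodic") gv[, ] <- gpy
  else gv[, 2:grid$ny] <- gpy[, 2:grid$ny]  # wall faces keep zero
  ru <- state$u + dt * (cu + fu / grid$rho - gpx / grid$rho) +
    (dt * nu / 2) * matrix(ops$Lu %*% as.vector(state$u), grid$nx)
  rv <- state$v + dt * (cv + fv / grid$rho - gv / grid$rho) +
    (dt * nu / 2) * matrix(ops$Lv %*% as.vector(state$v), grid$nx)
  if (grid$bc_y != "periodic") rv[, c(1, grid$nvy)] <- 0
  us <- matrix(as.numeric(Matrix::solve(ops$fac_u, as.vector(ru))), grid$nx)
  vs <- matrix(as.numeric(Matrix::solve(ops$fac_v, as.vector(rv))), grid$nx)
  if (grid$bc_y != "periodic") vs[, c(1, grid$nvy)] <- 0
  if (!is.null(ib)) {
    prov <- state; prov$u <- us; prov$v <- vs
    ibf <- ib_forcing(grid, prov, ib$markers, ib$u_target, ib$v_target, dt)
    us <- us + dt * ibf$fu / grid$rho
    vs <- vs + dt * ibf$fv / grid$rho
    if (grid$bc_y != "periodic") vs[, c(1, grid$nvy)] <- 0
    state$ib_force <- ibf
  }
  # projection
  div <- flow_divergence(grid, us, vs)
  rhs <- c(as.vector(div) / dt, 0)
  phi <- as.numeric(Matrix::solve(ops$fac_p, rhs))[seq_len(grid$nx * grid$ny)]
  phi <- matrix(phi, grid$nx)
  gfx <- (phi - shx(phi, -1)) / grid$dx
  phf <- if (grid$bc_y == "periodic") cbind(phi[, grid$ny], phi)
         else cbind(phi[, 1], phi)
  gfy <- (phf[, 2:(grid$ny + 1)] - phf[, 1:grid$ny]) / grid$dy
  u_new <- us - dt * gfx
  v_new <- vs
  if (grid$bc_y == "periodic") v_new <- vs - dt * gfy
  else v_new[, 2:grid$ny] <- vs[, 2:grid$ny] - dt * gfy[, 2:grid$ny]
  state$p <- state$p + grid$rho * phi
  state$u <- u_new; state$v <- v_new
  state$conv_prev <- conv
  state$t <- state$t + dt
  state
}

#' Carreau-Yasuda effective viscosity
#'
#' `mu(gdot) = mu_inf + (mu_0 - mu_inf) [1 + (lambda gdot)^a]^((n-1)/a)`;
#' in Newtonian mode the blood value 3.5 mPa s is returned for any shear
#' rate.
#'
#' @param shear_rate Shear rate, 1/s (>= 0); vectorized.
#' @param params List with `mu0`, `mu_inf` (Pa s), `lambda` (s), `a`, `n`;
#'   defaults are the standard blood fit (mu0 = 0.056, mu_inf = 0.0035,
#'   lambda = 3.313, a = 2, n = 0.3568).
#' @param newtonian If TRUE (default) return 3.5 mPa s.
#' @return Viscosity, Pa s.
#' @export
effective_viscosity <- function(shear_rate, params = list(),
                                newtonian = TRUE) {
  stopifnot(all(shear_rate >= 0))
  if (newtonian) return(rep(3.5e-3, length(shear_rate)))
  p <- utils::modifyList(list(mu0 = 0.056, mu_inf = 0.0035, lambda = 3.313,
                              a = 2, n = 0.3568), params)
  if (p$a <= 0 || p$n > 1) stop("invalid Carreau-Yasuda exponents")
  p$mu_inf + (p$mu0 - p$mu_inf) *
    (1 + (p$lambda * shear_rate)^p$a)^((p$n - 1) / p$a)
}
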