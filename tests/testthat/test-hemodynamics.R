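# Staggered-grid incompressible flow, MLS/IBM, Windkessel, loads.

test_that("uniform velocity in a periodic box is an exact steady state", {
  g <- flow_grid(16, 16, 1, 1, bc_y = "periodic", rho = 1, mu = 0.01)
  st <- flow_state(g, matrix(0.7, 16, 16), matrix(-0.3, 16, 16))
  for (k in 1:5) st <- step_flow(g, st, 0.01)
  expect_equal(max(abs(st$u - 0.7)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$v + 0.3)), 0, tolerance = 1e-12)
})

test_that("Taylor-Green vortex decays at the analytic viscous rate", {
  nu <- 0.01
  tg <- taylor_green(64, nu)
  st <- tg$state
  Tend <- 1
  for (k in seq_len(Tend / 0.02)) {
    st <- step_flow(tg$grid, st, 0.02)
    expect_lt(max(abs(flow_divergence(tg$grid, st$u, st$v))), 1e-8)
  }
  ke <- sum(st$u^2) + sum(st$v^2)
  ke0 <- sum(tg$U^2) + sum(tg$V^2)
  expect_equal(ke / ke0, exp(-4 * nu * Tend), tolerance = 0.01)
})

test_that("Taylor-Green velocity error converges at second order", {
  err <- function(n) {
    nu <- 0.01
    tg <- taylor_green(n, nu)
    st <- tg$state
    for (k in 1:100) st <- step_flow(tg$grid, st, 0.002)
    dec <- exp(-2 * nu * 0.2)
    max(abs(st$u - tg$U * dec), abs(st$v - tg$V * dec))
  }
  expect_gt(log2(err(16) / err(32)), 1.9)
})

test_that("body-force-driven plane Poiseuille reaches the parabola", {
  g <- flow_grid(8, 64, 0.125, 1, bc_y = "noslip", rho = 1, mu = 0.1)
  st <- flow_state(g)
  fx <- 1
  f <- list(fu = matrix(fx, g$nx, g$ny))
  for (k in 1:4000) st <- step_flow(g, st, 0.002, forcing = f)
  umax_exact <- fx / (8 * g$mu)   # H = 1
  expect_equal(max(st$u), umax_exact, tolerance = 0.01)
  gu <- cardiosim:::grid_points(g, "u")
  uex <- fx / (2 * g$mu) * gu$y * (1 - gu$y)
  expect_lt(max(abs(sweep(st$u, 2, uex))) / umax_exact, 0.01)
})

test_that("global momentum balance holds in a forced periodic box", {
  g <- flow_grid(24, 24, 1, 1, bc_y = "periodic", rho = 2, mu = 0.003)
  set.seed(5)
  st <- flow_state(g, matrix(rnorm(24^2, sd = 0.1), 24),
                   matrix(rnorm(24^2, sd = 0.1), 24))
  st$v <- st$v - mean(st$v); st$u <- st$u - mean(st$u)
  f <- list(fu = matrix(0.4, 24, 24), fv = matrix(-0.1, 24, 24))
  mom0 <- c(sum(st$u), sum(st$v)) * g$dx * g$dy * g$rho
  dt <- 0.005; n <- 40
  for (k in 1:n) st <- step_flow(g, st, dt, forcing = f)
  mom1 <- c(sum(st$u), sum(st$v)) * g$dx * g$dy * g$rho
  expect_equal(mom1 - mom0, c(0.4, -0.1) * n * dt, tolerance = 1e-6)
})

test_that("MLS reproduces constants and linears; converges at O(h^2)", {
  set.seed(2)
  xm <- runif(25, 0.2, 0.8); ym <- runif(25, 0.2, 0.8)
  g <- flow_grid(32, 32, 1, 1, bc_y = "periodic")
  gp <- cardiosim:::grid_points(g, "p")
  expect_equal(mls_interp(g, matrix(7.3, 32, 32), "p", xm, ym),
               rep(7.3, 25), tolerance = 1e-12)
  lin <- outer(gp$x, gp$y, function(x, y) 2 + 3 * x - 4 * y)
  expect_equal(mls_interp(g, lin, "p", xm, ym), 2 + 3 * xm - 4 * ym,
               tolerance = 1e-12)
  smooth_err <- function(n) {
    gg <- flow_grid(n, n, 1, 1, bc_y = "periodic")
    gp <- cardiosim:::grid_points(gg, "p")
    fld <- outer(gp$x, gp$y, function(x, y) sin(2 * pi * x) * cos(2 * pi * y))
    max(abs(mls_interp(gg, fld, "p", xm, ym) -
              sin(2 * pi * xm) * cos(2 * pi * ym)))
  }
  expect_gt(log2(smooth_err(16) / smooth_err(32)), 1.7)
  expect_gt(log2(smooth_err(32) / smooth_err(64)), 1.7)
  # markers outside the fluid have no support
  gw <- flow_grid(16, 16, 1, 1, bc_y = "noslip")
  expect_error(mls_interp(gw, matrix(1, 16, 16), "p", 0.5, 1.8),
               "degenerate MLS")
})

test_that("MLS spreading is the adjoint of interpolation", {
  g <- flow_grid(32, 32, 1, 1, bc_y = "periodic")
  set.seed(4)
  xm <- runif(20, 0.1, 0.9); ym <- runif(20, 0.1, 0.9)
  Fm <- rnorm(20); Am <- runif(20, 0.01, 0.05)
  u_g <- matrix(rnorm(32 * 32), 32)
  sp <- mls_spread(g, Fm, Am, "p", xm, ym)
  lhs <- sum(sp * u_g) * g$dx * g$dy
  rhs <- sum(Fm * mls_interp(g, u_g, "p", xm, ym) * Am)
  expect_equal(lhs, rhs, tolerance = 1e-14)
  # integral preservation (partition of unity)
  expect_equal(sum(sp) * g$dx * g$dy, sum(Fm * Am), tolerance = 1e-12)
})

test_that("direct IB forcing: trivial zero, force bookkeeping, plate slip", {
  n <- 64
  g <- flow_grid(n, n, 1, 1, bc_y = "periodic", rho = 1, mu = 0.005)
  st <- flow_state(g, matrix(1, n, n), matrix(0, n, n))
  ys <- seq(0.25, 0.75, length.out = 33)
  mk <- lagrangian_surface(rep(0.5, 33), ys, rep(1, 33), rep(0, 33),
                           rep(0.5 / 32, 33))
  # targets equal the current interpolated velocities -> zero forcing
  ui <- mls_interp(g, st$u, "u", mk$x, mk$y)
  vi <- mls_interp(g, st$v, "v", mk$x, mk$y)
  ib0 <- ib_forcing(g, st, mk, ui, vi, 0.005)
  expect_lt(max(abs(ib0$fu)), 1e-8)
  expect_lt(max(abs(ib0$fv)), 1e-8)
  # stationary plate in a uniform stream: post-step slip < 5%
  for (k in 1:125)
    st <- step_flow(g, st, 0.004,
                    ib = list(markers = mk, u_target = rep(0, 33),
                              v_target = rep(0, 33)))
  slip <- mls_interp(g, st$u, "u", mk$x, mk$y)
  expect_lt(max(abs(slip)), 0.05)
})

test_that("Windkessel forcing follows the three-element law", {
  g <- flow_grid(16, 16, 1, 1, bc_y = "periodic")
  rg <- windkessel_region(g, "ao", c(0.2, 0.8), c(0.2, 0.8), c(1, 0),
                          alpha = 3.13e6, beta = 2.96e6, gamma = 18.43e6)
  # u == 0 for all time and gamma = 0 -> identically zero forcing
  rg0 <- windkessel_region(g, "z", c(0.2, 0.8), c(0.2, 0.8), c(1, 0),
                           alpha = 1e6, beta = 1e6, gamma = 0)
  st0 <- flow_state(g)
  w0 <- windkessel_forcing(rg0, g, st0, 0.01)
  expect_equal(max(abs(w0$fu)), 0)
  # constant plug flow U: opposing force grows affinely alpha U + beta U t
  U <- 0.3
  st <- flow_state(g, matrix(U, 16, 16), matrix(0, 16, 16))
  for (k in 1:50) {
    w <- windkessel_forcing(rg, g, st, 0.001)
    st$wk_int[["ao"]] <- w$integrals
  }
  expect_equal(w$fu[8, 8],
               -(3.13e6 * U + 2.96e6 * U * 0.001 * 49.5 + 18.43e6),
               tolerance = 1e-6)
  expect_error(windkessel_region(g, "bad", c(2, 3), c(2, 3), c(1, 0),
                                 1, 1, 1), "empty")
})

test_that("hydrodynamic loads: jumps, hydrostatic resultant, zeros", {
  g <- flow_grid(96, 96, 1, 1, bc_y = "periodic", rho = 1000)
  st <- flow_state(g)
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  R <- 0.18
  circ <- lagrangian_surface(0.5 + R * cos(th), 0.5 + R * sin(th),
                             cos(th), sin(th), rep(2 * pi * R / 120, 120),
                             two_sided = FALSE)
  # zero fields -> zero loads
  ld0 <- hydrodynamic_loads(g, st, circ)
  expect_equal(max(abs(ld0$fx), abs(ld0$fy)), 0)
  # hydrostatic p = rho g y on a closed circle: |F| = rho g A downward
  gp <- cardiosim:::grid_points(g, "p")
  st$p <- outer(gp$x, gp$y, function(x, y) 1000 * 9.81 * y)
  ld <- hydrodynamic_loads(g, st, circ)
  expect_equal(sum(ld$fy), -1000 * 9.81 * pi * R^2, tolerance = 0.02)
  expect_lt(abs(sum(ld$fx)) / abs(sum(ld$fy)), 0.01)
  # equal pressure on both sides of a membrane, no flow -> zero force
  memb <- lagrangian_surface(rep(0.5, 20), seq(0.3, 0.7, length.out = 20),
                             rep(1, 20), rep(0, 20), rep(0.02, 20),
                             two_sided = TRUE)
  st2 <- flow_state(g); st2$p <- matrix(500, 96, 96)
  ld2 <- hydrodynamic_loads(g, st2, memb)
  expect_lt(max(abs(ld2$fx), abs(ld2$fy)), 1e-10)
})

test_that("Carreau-Yasuda viscosity limits and Newtonian mode", {
  expect_equal(effective_viscosity(c(0, 1, 1e5)), rep(3.5e-3, 3))
  p <- list(mu0 = 0.056, mu_inf = 0.0035, lambda = 3.313, a = 2, n = 0.3568)
  expect_equal(effective_viscosity(0, p, newtonian = FALSE), p$mu0)
  expect_equal(effective_viscosity(1e9, p, newtonian = FALSE), p$mu_inf,
               tolerance = 1e-4)
  expect_error(effective_viscosity(1, list(a = -1), newtonian = FALSE),
               "exponents")
  expect_error(effective_viscosity(-1), "shear_rate")
})
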