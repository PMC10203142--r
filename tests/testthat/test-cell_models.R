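# Ionic membrane models and active tension.

test_that("every registered model rests at a fixed point of its kinetics", {
  for (nm in ionic_model_names()) {
    m <- ionic_model(nm)
    d <- ionic_rhs(m, m$rest_state)
    tol <- if (nm == "minimal") 1e-6 else 1e-3   # per ms for dimensional
    expect_lt(abs(d$dv), tol, label = paste(nm, "dv at rest"))
    expect_lt(max(abs(unlist(d$ds))), tol, label = paste(nm, "ds at rest"))
    # and the stepped state stays put
    st <- step_cell(m, m$rest_state, dt = 0.02)
    expect_lt(abs(st$v - m$rest_state$v), 1e-6)
  }
})

test_that("minimal model rhs matches the stated polynomial kinetics", {
  m <- ionic_model("minimal")
  expect_equal(ionic_rhs(m, cell_state(0, 0))$dv, 0)
  expect_equal(ionic_rhs(m, cell_state(0, 0))$ds[[1]], 0)
  # hand evaluation at (v, r) = (0.4, 0.1) with the default constants
  p <- m$params
  v <- 0.4; r <- 0.1
  dv_hand <- p$k * v * (v - p$a) * (1 - v) - v * r
  dr_hand <- (p$gamma + p$mu1 * r / (p$mu2 + v)) *
    (-r - p$k * v * (v - p$b - 1))
  d <- ionic_rhs(m, cell_state(v, r))
  expect_equal(d$dv, dv_hand)
  expect_equal(d$ds[[1]], dr_hand)
})

test_that("dimension mismatch and non-finite states are rejected", {
  m <- ionic_model("atrial")
  expect_error(ionic_rhs(m, cell_state(-81, c(1, 1))), "does not match")
  expect_error(ionic_rhs(m, cell_state(NaN, 1)), "finite")
})

test_that("suprathreshold stimulus depolarizes within 5 ms (RK4 oracle)", {
  for (nm in c("atrial", "ventricular", "purkinje")) {
    m <- ionic_model(nm)
    stim <- function(t) if (t >= 1 && t < 3) 3 else 0   # uA/mm^2, 2 ms
    oracle <- rk4_cell(m, t_end = 8, dt = 1e-3, stim = stim)
    t_cross_oracle <- oracle$t[which(oracle$v > 0)[1]]
    expect_lt(t_cross_oracle - 1, 5, label = paste(nm, "oracle crossing"))
    # the package integrator agrees on the crossing time
    v <- m$rest_state$v; s <- as.list(m$rest_state$s)
    tc <- NA
    for (k in 1:400) {
      t <- (k - 1) * 0.02
      st <- cardiosim:::step_cell_vec(m, v, s, 0.02, stim(t))
      if (is.na(tc) && st$v > 0) tc <- t + 0.02
      v <- st$v; s <- st$s
    }
    expect_lt(abs(tc - t_cross_oracle), 0.5, label = nm)
  }
})

test_that("step_cell is first-order self-convergent over a full AP", {
  m <- ionic_model("ventricular")
  run <- function(dt) {
    v <- m$rest_state$v; s <- as.list(m$rest_state$s)
    n <- round(400 / dt)
    keep <- round(seq(1, n, length.out = 200))
    out <- numeric(length(keep)); ki <- 1
    for (k in seq_len(n)) {
      I <- if ((k - 1) * dt < 2) 3 else 0
      st <- cardiosim:::step_cell_vec(m, v, s, dt, I)
      v <- st$v; s <- st$s
      if (ki <= length(keep) && k == keep[ki]) { out[ki] <- v; ki <- ki + 1 }
    }
    out
  }
  v1 <- run(0.02); v2 <- run(0.01); v3 <- run(0.005)
  e1 <- max(abs(v1 - v3)); e2 <- max(abs(v2 - v3))
  expect_gt(e1 / e2, 1.5)   # halving dt at least ~halves the error
  # step-halving consistency: 1000 x 0.002 agrees with 200 x 0.01
  va <- m$rest_state$v; sa <- as.list(m$rest_state$s)
  for (k in 1:1000) { st <- cardiosim:::step_cell_vec(m, va, sa, 0.002, 1)
    va <- st$v; sa <- st$s }
  vb <- m$rest_state$v; sb <- as.list(m$rest_state$s)
  for (k in 1:200) { st <- cardiosim:::step_cell_vec(m, vb, sb, 0.01, 1)
    vb <- st$v; sb <- st$s }
  expect_lt(abs(va - vb), 0.5)   # mV, integrator-error bound
})

test_that("gating variables stay in [0,1] under strong stimulation", {
  for (nm in c("atrial", "ventricular", "purkinje")) {
    m <- ionic_model(nm)
    v <- m$rest_state$v; s <- as.list(m$rest_state$s)
    hmin <- 1; hmax <- 0
    for (k in 1:20000) {
      I <- if (k %% 5000 < 100) 5 else 0
      st <- cardiosim:::step_cell_vec(m, v, s, 0.02, I)
      v <- st$v; s <- st$s
      hmin <- min(hmin, s[[1]]); hmax <- max(hmax, s[[1]])
    }
    expect_gte(hmin, 0); expect_lte(hmax, 1)
  }
})

test_that("Nash-Panfilov tension follows the switching linear ODE", {
  p <- list(eps0 = 1, eps1 = 10, v_star = 0.05, k_Ta = 47.9)
  expect_equal(active_tension_rate(0, 0, p), 0)
  expect_error(active_tension_rate(0.5, 1, list(k_Ta = -1)), "non-negative")
  # relaxation to k_Ta * v at constant v (both branches of eps)
  for (v0 in c(0.02, 0.8)) {
    Ta <- 5; dt <- 1e-4
    gaps <- numeric(2000)
    for (k in 1:2000) {
      Ta <- Ta + dt * active_tension_rate(v0, Ta, p)
      gaps[k] <- abs(Ta - p$k_Ta * v0)
    }
    expect_true(all(diff(gaps) <= 1e-12))   # monotone approach
  }
  # closed form for a step v: 0 -> 1: Ta(t) = k_Ta (1 - exp(-eps1 t))
  Ta <- 0; dt <- 1e-5; t_end <- 0.5
  for (k in seq_len(t_end / dt)) Ta <- Ta + dt * active_tension_rate(1, Ta, p)
  expect_equal(Ta, p$k_Ta * (1 - exp(-p$eps1 * t_end)), tolerance = 1e-3)
  # non-negativity for v >= 0 from non-negative start
  Ta <- 0
  for (k in 1:1000) {
    Ta <- Ta + 0.01 * active_tension_rate(runif(1), Ta, p)
    expect_gte(Ta, 0)
  }
})

test_that("APD measurement: trapezoid, error cases, and ODE oracle", {
  t <- seq(0, 400, by = 0.5)
  v <- ifelse(t >= 50 & t <= 250, 1, 0)   # 200 ms plateau, instant edges
  expect_equal(measure_apd(t, v, 0.9), 200, tolerance = 0.5)
  expect_error(measure_apd(t, rep(0, length(t))), "depolarizes")
  # minimal model (dimensional clock, 1 unit = 12.9 ms) vs dense RK4
  m <- ionic_model("minimal", params = list(t_scale = 12.9))
  stim <- function(t) if (t < 12.9) 0.3 else 0
  oracle <- rk4_cell(m, t_end = 450, dt = 0.005, stim = stim)
  apd_oracle <- measure_apd(oracle$t, oracle$v, 0.9)
  ap <- simulate_ap(m, dt = 0.1, t_end = 450, stim_start = 0,
                    stim_dur = 12.9, stim_amp = 0.3)
  expect_lt(abs(measure_apd(ap$t, ap$v, 0.9) - apd_oracle), 1)  # +- 1 ms
})
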