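# Fung spring-network structural solver.

test_that("Green strains: rest, uniaxial, random affine (explicit-F oracle)", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 0.01
  net <- spring_network(nodes, rep(1, 4), list(list(nodes = 1:4,
                                                    region = "LV")))
  expect_equal(green_strains(net, 1), c(0, 0, 0))
  pos <- nodes; pos[, 1] <- pos[, 1] * 1.1
  expect_equal(green_strains(net, 1, pos), c((1.1^2 - 1) / 2, 0, 0))
  # random affine map: strains must match E = (F'F - I)/2 built from F
  set.seed(3)
  A <- diag(3) + matrix(rnorm(9, sd = 0.08), 3)
  posA <- nodes %*% t(A)
  E <- (t(A) %*% A - diag(3)) / 2
  expect_equal(green_strains(net, 1, posA), diag(E), tolerance = 1e-12)
  # inverted element rejected
  bad <- nodes; bad[4, 3] <- -bad[4, 3]
  expect_error(green_strains(net, 1, bad), "inverted|Jacobian")
})

test_that("Fung energy density: closed form, symmetry, overflow guard", {
  lv <- fung_material(11.59, 9.97, 3.17, 3.17)
  expect_equal(fung_energy(c(0, 0, 0), lv), 0)
  expect_equal(fung_energy(c(0.1, 0, 0), lv),
               11.59 / 2 * (exp(9.97 * 0.01) - 1))
  m2 <- fung_material(5, 8, 2, 2)
  expect_equal(fung_energy(c(0.05, 0.1, 0.02), m2),
               fung_energy(c(0.05, 0.02, 0.1), m2))  # a_sheet == a_normal
  expect_error(fung_energy(c(30, 0, 0), lv), "overflow")
  expect_error(fung_energy(c(-0.6, 0, 0), lv), "bound")
  expect_error(fung_material(-1, 1), "c > 0")
})

test_that("internal forces are the exact negative energy gradient", {
  sm <- small_mixed_network()
  expect_equal(max(abs(internal_forces(sm$net, sm$mats))), 0,
               tolerance = 1e-12)                       # rest -> zero
  set.seed(1)
  pos <- sm$nodes + matrix(rnorm(15, sd = 5e-4), 5, 3)
  fa <- internal_forces(sm$net, sm$mats, pos)
  ffd <- fd_forces(sm$net, sm$mats, pos)
  expect_lt(max(abs(fa - ffd)) / max(abs(fa)), 1e-6)    # FD oracle
  expect_equal(colSums(fa), c(0, 0, 0), tolerance = 1e-15 * max(abs(fa)))
  # frame indifference: rigid translation leaves forces unchanged
  fb <- internal_forces(sm$net, sm$mats,
                        pos + matrix(c(0.3, -0.2, 0.5), 5, 3, byrow = TRUE))
  expect_equal(fb, fa, tolerance = 1e-9)
})

test_that("active forces: uniaxial tension, zero net force and torque", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * 0.01
  net <- spring_network(nodes, rep(1, 4),
                        list(list(nodes = 1:4, region = "LV")))
  expect_equal(max(abs(active_forces(net, 0))), 0)
  expect_error(active_forces(net, -1), "non-negative")
  pos <- nodes + matrix(rnorm(12, sd = 4e-4), 4, 3)
  f <- active_forces(net, 10, pos)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-18)
  tq <- colSums(t(vapply(1:4, function(i) {
    r <- pos[i, ]; fi <- f[i, ]
    c(r[2] * fi[3] - r[3] * fi[2], r[3] * fi[1] - r[1] * fi[3],
      r[1] * fi[2] - r[2] * fi[1])
  }, numeric(3))))
  expect_equal(tq, c(0, 0, 0), tolerance = 1e-18)
})

test_that("a free fiber-aligned bar shortens under uniform tension", {
  # two stacked tets forming a bar along x; damped dynamics to equilibrium
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)) * 0.01
  els <- list(list(nodes = 1:4, region = "LV"),
              list(nodes = c(2, 3, 4, 5), region = "LV"))
  net <- spring_network(nodes, rep(1e-3, 5), els)
  mats <- list(LV = fung_material(11.59, 9.97, 3.17, 3.17))
  mech <- list(x = net$nodes, v = matrix(0, 5, 3), a_prev = NULL,
               v_prev = NULL)
  Ta <- 5   # kPa
  for (k in 1:4000) {
    f <- internal_forces(net, mats, mech$x) + active_forces(net, Ta, mech$x)
    mech <- advance_structure(mech, net$mass, f, 2e-5, damping = 0.5)
  }
  expect_lt(max(abs(mech$v)), 1e-4)   # quiescent
  len0 <- nodes[2, 1] - nodes[1, 1]
  len <- mech$x[2, 1] - mech$x[1, 1]
  expect_lt(len, len0)                 # shortened along the fiber axis
  # and the equilibrium balances active vs passive fiber stress:
  # c a e exp(a e^2) = -Ta at the compressive strain reached
  e_fib <- green_strains(net, 1, mech$x)[1]
  sigma_p <- 11.59 * 9.97 * e_fib * exp(9.97 * e_fib^2)
  expect_equal(sigma_p, -Ta, tolerance = 0.15)
})

test_that("Adams-Bashforth point dynamics: drift, oscillator, energy", {
  # zero force, initial velocity -> straight line
  st <- list(x = matrix(0, 1, 3), v = matrix(c(1, 2, 0), 1, 3),
             a_prev = NULL, v_prev = NULL)
  for (k in 1:100) st <- advance_structure(st, 1, matrix(0, 1, 3), 0.01)
  expect_equal(as.numeric(st$x), c(1, 2, 0), tolerance = 1e-6)
  expect_error(advance_structure(st, 1, matrix(NaN, 1, 3), 0.01),
               "non-finite")
  # linear spring-mass: period within 1% at dt = T/1000 over 10 periods
  m <- 0.02; k_spring <- 3
  Tper <- 2 * pi * sqrt(m / k_spring)
  dt <- Tper / 1000
  st <- list(x = matrix(c(0.01, 0, 0), 1, 3), v = matrix(0, 1, 3),
             a_prev = NULL, v_prev = NULL)
  xs <- numeric(10000)
  E <- numeric(10000)
  for (k in 1:10000) {
    st <- advance_structure(st, m, -k_spring * st$x, dt)
    xs[k] <- st$x[1, 1]
    E[k] <- 0.5 * m * sum(st$v^2) + 0.5 * k_spring * sum(st$x^2)
  }
  up <- which(xs[-1] > 0 & xs[-length(xs)] <= 0)
  period <- mean(diff(up)) * dt
  expect_equal(period, Tper, tolerance = 0.01)
  expect_lt(abs(E[10000] - E[1]) / E[1], 0.01)   # conservative case
  # energy non-increasing with damping and no inputs
  st <- list(x = matrix(c(0.01, 0, 0), 1, 3), v = matrix(0, 1, 3),
             a_prev = NULL, v_prev = NULL)
  Eprev <- Inf
  for (k in 1:2000) {
    st <- advance_structure(st, m, -k_spring * st$x, dt, damping = 0.05)
    Ek <- 0.5 * m * sum(st$v^2) + 0.5 * k_spring * sum(st$x^2)
    if (k > 2) expect_lte(Ek, Eprev + 1e-12)
    Eprev <- Ek
  }
})

test_that("uniaxial response is monotone, convex, fiber-stiffer", {
  reg <- registries()$fung
  expect_equal(uniaxial_response(registry_fung("LV"), 1)$stress_kPa, 0)
  for (r in seq_len(nrow(reg))) {
    mat <- registry_fung(reg$region[r])
    rf <- uniaxial_response(mat, seq(1, 1.18, by = 0.005), axis = 1)
    rc <- uniaxial_response(mat, seq(1, 1.18, by = 0.005), axis = 3)
    expect_true(all(diff(rf$stress_kPa) > 0))           # monotone
    d2 <- diff(diff(rf$stress_kPa))
    expect_true(all(d2 > -1e-12))                       # convex
    if (reg$a_par[r] > reg$a_cross[r])
      expect_true(all(rf$stress_kPa[-1] > rc$stress_kPa[-1]))
  }
})

test_that("membrane (2D) elements run the same Fung machinery", {
  # valve-material triangle: energy uses fiber/sheet strains only
  nodes <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0))
  net <- spring_network(nodes, rep(1e-4, 3),
                        list(list(nodes = 1:3, region = "v",
                                  fiber = c(1, 0, 0))))
  mats <- list(v = registry_fung("mitral_tricuspid"))
  e <- green_strains(net, 1, nodes)
  expect_equal(e[1:2], c(0, 0)); expect_true(is.na(e[3]))
  pos <- nodes; pos[, 1] <- pos[, 1] * 1.05
  e2 <- green_strains(net, 1, pos)
  expect_equal(e2[1], (1.05^2 - 1) / 2, tolerance = 1e-12)
  f <- internal_forces(net, mats, pos)
  ffd <- fd_forces(net, mats, pos)
  expect_lt(max(abs(f - ffd)) / max(abs(f)), 1e-6)
})
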