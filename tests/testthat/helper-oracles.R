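# Shared oracles and fixtures built in code.

# fixed-step RK4 integration of a registered cell model's rhs (dense
# independent oracle for the operator-split / Rush-Larsen path)
rk4_cell <- function(model, t_end, dt, stim = function(t) 0) {
  v <- model$rest_state$v
  s <- as.numeric(model$rest_state$s)
  n <- ceiling(t_end / dt)
  out <- matrix(NA_real_, n + 1, 2 + length(s))
  out[1, ] <- c(0, v, s)
  deriv <- function(v, s, t) {
    d <- ionic_rhs(model, cell_state(v, s), t, I_stim = stim(t))
    c(d$dv, unlist(d$ds))
  }
  y <- c(v, s)
  for (k in seq_len(n)) {
    t <- (k - 1) * dt
    k1 <- deriv(y[1], y[-1], t)
    k2 <- deriv(y[1] + dt / 2 * k1[1], y[-1] + dt / 2 * k1[-1], t + dt / 2)
    k3 <- deriv(y[1] + dt / 2 * k2[1], y[-1] + dt / 2 * k2[-1], t + dt / 2)
    k4 <- deriv(y[1] + dt * k3[1], y[-1] + dt * k3[-1], t + dt)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k + 1, ] <- c(k * dt, y)
  }
  data.frame(t = out[, 1], v = out[, 2])
}

# central finite-difference gradient of the assembled Fung energy
fd_forces <- function(net, materials, pos, h = 1e-8) {
  f <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (j in 1:3) {
    pp <- pos; pm <- pos
    pp[i, j] <- pp[i, j] + h
    pm[i, j] <- pm[i, j] - h
    f[i, j] <- -(total_energy(net, materials, pp) -
                   total_energy(net, materials, pm)) / (2 * h)
  }
  f
}

# one tet + one membrane triangle + one cable segment, shared across tests
small_mixed_network <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)) * 0.01
  els <- list(list(nodes = 1:4, region = "LV"),
              list(nodes = c(2, 3, 5), region = "valve"),
              list(nodes = c(4, 5), region = "LV"))
  net <- spring_network(nodes, mass = rep(1e-3, 5), elements = els)
  mats <- list(LV = fung_material(11.59, 9.97, 3.17, 3.17),
               valve = fung_material(0.14, 98.58, 71.24))
  list(net = net, mats = mats, nodes = nodes)
}

# pure-diffusion membrane model: minimal kinetics with all reaction rates
# switched off (dv/dt = I only)
null_reaction_model <- function() {
  ionic_model("minimal", params = list(k = 0, gamma = 0, mu1 = 0))
}

# Taylor-Green initial condition on a periodic box [0, 2*pi]^2
taylor_green <- function(n, nu) {
  g <- flow_grid(n, n, 2 * pi, 2 * pi, bc_y = "periodic", rho = 1, mu = nu)
  gu <- cardiosim:::grid_points(g, "u")
  gv <- cardiosim:::grid_points(g, "v")
  U <- outer(gu$x, gu$y, function(x, y) cos(x) * sin(y))
  V <- outer(gv$x, gv$y, function(x, y) -sin(x) * cos(y))
  list(grid = g, state = flow_state(g, U, V), U = U, V = V)
}
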