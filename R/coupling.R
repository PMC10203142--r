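# Orchestration of the fluid, structure and electrophysiology solvers.
#
# Loose coupling: fluid (and EP) are solved first with the previous-step
# structural kinematics; the resulting hydrodynamic and active loads then
# advance the structure, whose updated configuration feeds the next step.
# Strong coupling: a predictor-corrector scheme (two-step Adams-Bashforth
# structural update) iterates flow + loads + structure until the maximum
# relative change of node positions AND velocities drops below the
# tolerance (default 1e-4), typically within 2-3 iterations.

#' Coupling configuration
#'
#' @param mode `"loose"` or `"strong"`.
#' @param tol Convergence threshold on the maximum relative change of
#'   structural positions and velocities. Default 1e-4.
#' @param max_iter Corrector cap. Default 25.
#' @param dt Time step (s).
#' @return Object of class `coupling_config`.
#' @export
coupling_config <- function(mode = c("loose", "strong"), tol = 1e-4,
                            max_iter = 25L, dt = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(tol > 0, max_iter >= 1, dt > 0)
  structure(list(mode = mode, tol = tol, max_iter = as.integer(max_iter),
                 dt = dt), class = "coupling_config")
}

#' Assemble a membrane fluid-structure system
#'
#' @param grid A `flow_grid`.
#' @param net A `spring_network` whose segment elements form the wet
#'   membrane.
#' @param materials Named material list for [internal_forces].
#' @param fixed_nodes Indices of anchored nodes.
#' @param gravity Optional body acceleration (2-vector, m/s^2).
#' @param body_force Optional constant fluid body force `c(fx, fy)`
#'   (N/m^3) driving the channel.
#' @return Object of class `fsi_system` with the initial bundle state.
#' @export
fsi_system <- function(grid, net, materials, fixed_nodes = integer(0),
                       gravity = c(0, 0), body_force = c(0, 0)) {
  mech <- list(x = net$nodes, v = matrix(0, net$n_nodes, 3),
               a_prev = NULL, v_prev = NULL)
  structure(list(grid = grid, net = net, materials = materials,
                 fixed_nodes = fixed_nodes, gravity = gravity,
                 body_force = body_force,
                 flow = flow_state(grid), mech = mech, t = 0),
            class = "fsi_system")
}

# markers at segment midpoints; normals perpendicular to the segment
membrane_markers <- function(net, pos, vel) {
  segs <- Filter(function(e) e$type == "seg", net$elements)
  m <- length(segs)
  x <- numeric(m); y <- numeric(m); nx <- numeric(m); ny <- numeric(m)
  ar <- numeric(m); um <- numeric(m); vm <- numeric(m)
  ends <- matrix(0L, m, 2)
  for (k in seq_len(m)) {
    id <- segs[[k]]$nodes
    p1 <- pos[id[1], ]; p2 <- pos[id[2], ]
    d <- p2 - p1; l <- sqrt(sum(d[1:2]^2))
    x[k] <- (p1[1] + p2[1]) / 2; y[k] <- (p1[2] + p2[2]) / 2
    nx[k] <- -d[2] / l; ny[k] <- d[1] / l
    ar[k] <- l
    um[k] <- (vel[id[1], 1] + vel[id[2], 1]) / 2
    vm[k] <- (vel[id[1], 2] + vel[id[2], 2]) / 2
    ends[k, ] <- id
  }
  list(surface = lagrangian_surface(x, y, nx, ny, ar, two_sided = TRUE),
       u = um, v = vm, ends = ends)
}

# nodal external forces from marker loads (half to each segment endpoint)
distribute_loads <- function(net, ends, loads) {
  f <- matrix(0, net$n_nodes, 3)
  for (k in seq_len(nrow(ends))) {
    f[ends[k, 1], 1:2] <- f[ends[k, 1], 1:2] + 0.5 * c(loads$fx[k], loads$fy[k])
    f[ends[k, 2], 1:2] <- f[ends[k, 2], 1:2] + 0.5 * c(loads$fx[k], loads$fy[k])
  }
  f
}

total_structural_force <- function(sys, pos, f_ext) {
  f <- f_ext + internal_forces(sys$net, sys$materials, pos)
  f[, 1] <- f[, 1] + sys$net$mass * sys$gravity[1]
  f[, 2] <- f[, 2] + sys$net$mass * sys$gravity[2]
  f
}

apply_constraints <- function(sys, mech) {
  if (length(sys$fixed_nodes)) {
    mech$x[sys$fixed_nodes, ] <- sys$net$nodes[sys$fixed_nodes, ]
    mech$v[sys$fixed_nodes, ] <- 0
  }
  mech$x[, 3] <- sys$net$nodes[, 3]   # planar problem
  mech$v[, 3] <- 0
  mech
}

flow_body_forcing <- function(sys) {
  list(fu = matrix(sys$body_force[1], sys$grid$nx, sys$grid$ny),
       fv = matrix(sys$body_force[2], sys$grid$nx, sys$grid$nvy))
}

#' One loose-coupling step
#'
#' Fluid solved first with the previous-step structure kinematics as
#' immersed-boundary targets; hydrodynamic loads and internal forces then
#' advance the structure.  Cheaper than strong coupling but conditionally
#' stable, so an energy blow-up detector aborts with a diagnostic.
#'
#' @param sys An `fsi_system`.
#' @param dt Time step (s).
#' @return Updated `fsi_system`.
#' @export
loose_step <- function(sys, dt) {
  mk <- membrane_markers(sys$net, sys$mech$x, sys$mech$v)
  sys$flow <- step_flow(sys$grid, sys$flow, dt,
                        forcing = flow_body_forcing(sys),
                        ib = list(markers = mk$surface, u_target = mk$u,
                                  v_target = mk$v))
  loads <- hydrodynamic_loads(sys$grid, sys$flow, mk$surface)
  f <- total_structural_force(sys, sys$mech$x, distribute_loads(sys$net, mk$ends, loads))
  ke_old <- sum(sys$net$mass * rowSums(sys$mech$v^2))
  sys$mech <- apply_constraints(sys, advance_structure(sys$mech, sys$net$mass, f, dt))
  ke_new <- sum(sys$net$mass * rowSums(sys$mech$v^2))
  uref <- max(abs(sys$flow$u), abs(sys$flow$v), 1e-12)
  if (!all(is.finite(sys$mech$x)) ||
      sqrt(ke_new / sum(sys$net$mass)) > 50 * uref)
    stop("loose coupling instability detected (structural energy blow-up); reduce dt")
  sys$t <- sys$t + dt
  sys
}

#' One strong-coupling (predictor-corrector) step
#'
#' Adams-Bashforth predictor for the structure, then corrector iterations
#' re-solving the flow against the updated structural kinematics and
#' re-advancing the structure from the saved state, until the maximum
#' relative change of node positions and velocities falls below
#' `cfg$tol`.
#'
#' @param sys An `fsi_system`.
#' @param cfg A `coupling_config` (mode `"strong"`).
#' @return Updated `fsi_system`; fields `iterations` and `residuals`
#'   record the corrector history.
#' @export
strong_step <- function(sys, cfg) {
  dt <- cfg$dt
  flow0 <- sys$flow
  mech0 <- sys$mech
  # predictor: advance with loads evaluated on the current configuration
  mk0 <- membrane_markers(sys$net, mech0$x, mech0$v)
  flow_p <- step_flow(sys$grid, flow0, dt, forcing = flow_body_forcing(sys),
                      ib = list(markers = mk0$surface, u_target = mk0$u,
                                v_target = mk0$v))
  loads <- hydrodynamic_loads(sys$grid, flow_p, mk0$surface)
  f <- total_structural_force(sys, mech0$x,
                              distribute_loads(sys$net, mk0$ends, loads))
  pred <- apply_constraints(sys, advance_structure(mech0, sys$net$mass, f, dt))
  residuals <- numeric(0)
  eps <- 1e-12
  flow_k <- flow_p
  # Aitken dynamic under-relaxation stabilizes the added-mass-dominated
  # fixed point (light membrane in dense blood)
  omega <- 1
  r_old <- NULL
  for (it in seq_len(cfg$max_iter)) {
    mk <- membrane_markers(sys$net, pred$x, pred$v)
    flow_k <- step_flow(sys$grid, flow0, dt, forcing = flow_body_forcing(sys),
                        ib = list(markers = mk$surface, u_target = mk$u,
                                  v_target = mk$v))
    loads <- hydrodynamic_loads(sys$grid, flow_k, mk$surface)
    f <- total_structural_force(sys, pred$x,
                                distribute_loads(sys$net, mk$ends, loads))
    corr <- apply_constraints(sys, advance_structure(mech0, sys$net$mass, f, dt))
    res_x <- max(sqrt(rowSums((corr$x - pred$x)^2)) /
                 (sqrt(rowSums(pred$x^2)) + eps))
    res_v <- max(sqrt(rowSums((corr$v - pred$v)^2)) /
                 (sqrt(rowSums(pred$v^2)) + eps))
    residuals <- c(residuals, max(res_x, res_v))
    r_k <- c(as.vector(corr$x - pred$x),
             dt * as.vector(corr$v - pred$v))
    if (!is.null(r_old)) {
      dr <- r_k - r_old
      if (sum(dr^2) > 0)
        omega <- max(min(-omega * sum(r_old * dr) / sum(dr^2), 1), 0.05)
    }
    pred$x <- pred$x + omega * (corr$x - pred$x)
    pred$v <- pred$v + omega * (corr$v - pred$v)
    pred$a_prev <- corr$a_prev; pred$v_prev <- corr$v_prev
    r_old <- r_k
    if (residuals[it] < cfg$tol) break
  }
  if (residuals[length(residuals)] >= cfg$tol)
    stop(sprintf("strong coupling did not converge in %d iterations (residual %.3e)",
                 cfg$max_iter, residuals[length(residuals)]))
  sys$flow <- flow_k
  sys$mech <- pred
  sys$iterations <- it
  sys$residuals <- residuals
  sys$t <- sys$t + dt
  sys
}

#' Steps per heartbeat
#'
#' @param hr_bpm Heart rate (beats per minute). Default 60.
#' @param dt Time step (s). Default 2e-6 (the stability regime of the
#'   loosely-coupled whole-heart model).
#' @return Integer step count for one beat.
#' @export
beat_steps <- function(hr_bpm = 60, dt = 2e-6) {
  stopifnot(hr_bpm > 0, dt > 0)
  as.integer(round(60 / hr_bpm / dt))
}

validate_run_config <- function(config) {
  errs <- character(0)
  if (is.null(config$type) ||
      !config$type %in% c("ep", "fsi", "electromech"))
    errs <- c(errs, "type must be one of ep/fsi/electromech")
  if (is.null(config$dt) || config$dt <= 0)
    errs <- c(errs, "dt must be > 0")
  if (is.null(config$t_end) || config$t_end < 0)
    errs <- c(errs, "t_end must be >= 0")
  if (!is.null(config$coupling) &&
      !config$coupling %in% c("loose", "strong"))
    errs <- c(errs, "coupling must be loose or strong")
  if (length(errs)) stop("invalid run config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}

#' Run a configured simulation
#'
#' Top-level driver: builds the named fixture, runs the requested solver
#' combination for `t_end` at `dt`, and (optionally) writes CSV traces,
#' VTK frames and a JSON manifest.  Deterministic for a given config and
#' seed.
#'
#' Config fields: `type` ("ep": cable electrophysiology; "fsi": membrane
#' in a channel; "electromech": mini-heart EP + active mechanics + ECG),
#' `dt` (ms for ep/electromech, s for fsi), `t_end`, `seed`, `coupling`,
#' `tol`, `frame_every`, `out_dir`, plus fixture parameters under
#' `fixture`.
#'
#' @param config Config list (or path to a JSON file).
#' @return Output bundle (traces, activation map / ECG or mechanics state,
#'   diagnostics log).
#' @export
run_heartbeat <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  seed <- config$seed %||% 1L
  set.seed(seed)
  out <- switch(config$type,
                ep = run_ep_config(config),
                fsi = run_fsi_config(config),
                electromech = run_electromech_config(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$traces))
      write_traces_csv(out$traces, file.path(config$out_dir, "traces.csv"))
    write_manifest(config, file.path(config$out_dir, "manifest.json"),
                   extra = list(outputs = list(traces = "traces.csv")))
  }
  out
}

run_ep_config <- function(config) {
  fx <- make_fixture(fixture_spec("cable",
                                  seed = config$seed %||% 1L))
  if (!is.null(config$fixture))
    fx <- make_fixture(do.call(fixture_spec,
                               c(list(kind = config$fixture$kind %||% "cable",
                                      seed = config$seed %||% 1L),
                                 config$fixture$params)))
  model <- ionic_model(fx$model_name %||% "atrial")
  sys <- ep_system(fx$mesh, model, fx$conductivity, chi_cm = fx$chi_cm,
                   dt = config$dt)
  if (config$t_end == 0) {
    st <- ep_rest_state(sys)
    return(list(state = st, traces = data.frame(t = 0, v_mean = mean(st$v)),
                activation = activation_map(rep(NA_real_, fx$mesh$n_cells),
                                            fx$mesh)))
  }
  res <- run_ep(sys, fx$protocol, t_end = config$t_end,
                trace_cells = c(1L, fx$mesh$n_cells %/% 2L, fx$mesh$n_cells),
                frame_every = config$frame_every %||% 0L)
  tr <- data.frame(t = res$times, v_first = res$traces[, 1],
                   v_mid = res$traces[, 2], v_last = res$traces[, 3])
  list(state = res$state, traces = tr, activation = res$activation,
       frames = res$frames, frame_times = res$frame_times)
}

run_fsi_config <- function(config) {
  fx <- make_fixture(do.call(fixture_spec,
                             c(list(kind = "membrane_channel",
                                    seed = config$seed %||% 1L),
                               config$fixture$params %||% list())))
  sys <- fsi_system(fx$grid, fx$net, fx$materials,
                    fixed_nodes = fx$fixed_nodes,
                    body_force = c(config$body_force %||% 20, 0))
  cfg <- coupling_config(config$coupling %||% "loose",
                         tol = config$tol %||% 1e-4, dt = config$dt)
  n <- round(config$t_end / config$dt)
  tip <- fx$net$n_nodes
  log <- data.frame(t = numeric(0), tip_x = numeric(0), tip_y = numeric(0),
                    iterations = integer(0), max_div = numeric(0))
  for (k in seq_len(n)) {
    sys <- if (cfg$mode == "strong") strong_step(sys, cfg)
           else loose_step(sys, cfg$dt)
    log <- rbind(log, data.frame(
      t = sys$t, tip_x = sys$mech$x[tip, 1], tip_y = sys$mech$x[tip, 2],
      iterations = sys$iterations %||% 1L,
      max_div = max(abs(flow_divergence(sys$grid, sys$flow$u, sys$flow$v)))))
  }
  list(system = sys, traces = log)
}

run_electromech_config <- function(config) {
  fx <- make_fixture(do.call(fixture_spec,
                             c(list(kind = "mini_heart",
                                    seed = config$seed %||% 1L),
                               config$fixture$params %||% list())))
  vent <- fx$ventricle
  model <- ionic_model(fx$model_name)
  # monodomain-equivalent tensors from the bidomain ventricular row
  # (per-axis harmonic mean of the intra/extracellular components)
  cr <- registry_lookup("conductivity", "ventricle")
  m_eq <- c(cr$m_int_par * cr$m_ext_par / (cr$m_int_par + cr$m_ext_par),
            cr$m_int_cross * cr$m_ext_cross / (cr$m_int_cross + cr$m_ext_cross))
  M <- assemble_conductivity(vent$frames,
                             conductivity_set(m_eq[1], m_eq[2], m_eq[2]))
  sys <- ep_system(vent$mesh, model, M, chi_cm = fx$chi_cm, dt = config$dt)
  state <- ep_rest_state(sys)
  # mechanics on the same tets (SI units)
  nodes_m <- vent$nodes * 1e-3
  els <- lapply(seq_len(nrow(vent$tets)), function(k)
    list(nodes = vent$tets[k, ], region = "LV",
         fiber = rbind(vent$frames$e_fiber[k, ], vent$frames$e_sheet[k, ],
                       vent$frames$e_normal[k, ])))
  vol_m <- tet_volume(nodes_m, vent$tets)
  mass <- numeric(nrow(nodes_m))
  for (k in seq_len(nrow(vent$tets)))
    mass[vent$tets[k, ]] <- mass[vent$tets[k, ]] + 1060 * abs(vol_m[k]) / 4
  net <- spring_network(nodes_m, pmax(mass, 1e-9), els)
  materials <- list(LV = registry_fung("LV"))
  base_nodes <- which(nodes_m[, 3] > max(nodes_m[, 3]) - 1e-6)
  mech <- list(x = net$nodes, v = matrix(0, net$n_nodes, 3), a_prev = NULL,
               v_prev = NULL)
  # gentler default tension kinetics than the single-cell defaults: the
  # dry (no blood pool) shell has no afterload, so full biophysical
  # tension at full rate inverts elements
  np <- config$np_params %||% list(k_Ta = 15, eps0 = 0.01, eps1 = 0.05,
                                   v_star = 0.05)
  nsteps <- ceiling(config$t_end / config$dt)
  mech_every <- config$mech_every %||% 1L
  frame_every <- config$frame_every %||% 20L
  frames <- list(); frame_times <- numeric(0)
  act <- rep(NA_real_, vent$mesh$n_cells)
  thr <- model$v_threshold
  tr <- data.frame(t = numeric(0), v_mean = numeric(0), Ta_mean = numeric(0),
                   apex_z = numeric(0))
  for (k in seq_len(nsteps)) {
    v_old <- state$v
    state <- step_ep(sys, state, fx$protocol, np_params = np)
    newly <- which(is.na(act) & v_old < thr & state$v >= thr)
    if (length(newly)) act[newly] <- state$t
    if (k %% mech_every == 0) {
      f <- internal_forces(net, materials, mech$x) +
        active_forces(net, state$Ta, mech$x)
      dmp <- config$damping %||% (net$mass / 0.01)  # ~10 ms relaxation
      mech <- advance_structure(mech, net$mass, f, config$dt * 1e-3 *
                                  mech_every, damping = dmp)
      mech$x[base_nodes, ] <- net$nodes[base_nodes, ]
      mech$v[base_nodes, ] <- 0
    }
    if (k %% frame_every == 0) {
      frames[[length(frames) + 1]] <- state$v
      frame_times <- c(frame_times, state$t)
    }
    if (k %% frame_every == 0) {
      apexn <- which.min(net$nodes[, 3])
      tr <- rbind(tr, data.frame(t = state$t, v_mean = mean(state$v),
                                 Ta_mean = mean(state$Ta),
                                 apex_z = mech$x[apexn, 3]))
    }
  }
  ecg <- if (length(frames) >= 2)
    ecg_trace(vent$mesh, frames, frame_times, fx$leads) else NULL
  list(state = state, mech = mech, traces = tr, ecg = ecg,
       activation = activation_map(act, vent$mesh), fixture = fx)
}
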