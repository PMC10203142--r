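# Finite-volume monodomain/bidomain reaction-diffusion solver.
#
# chi (Cm dv/dt + I_ion + I_s) = div(M grad v)                 [monodomain]
# chi (Cm dv/dt + I_ion + I_s) = div(M_int grad (v + v_ext)),
#   0 = div(M_int grad v + (M_int + M_ext) grad v_ext)         [bidomain]
#
# Two-point flux finite volumes: flux across a face uses the face-normal
# conductivity component n' M n of the two cells, combined harmonically.
# Outer boundaries are zero-flux; the bidomain elliptic solve is gauged to
# zero mean.  Units: mm, ms, mV, mS/mm; chi*Cm in uF/mm^3 acts as a single
# calibration scalar per tissue (the source tables do not print chi, Cm).

#' Orthotropic conductivity components
#'
#' @param m_par,m_sheet,m_normal Conductivity along the fiber, sheet and
#'   sheet-normal axes (mS/mm); all > 0.
#' @return Numeric vector of class `conductivity_set`.
#' @export
conductivity_set <- function(m_par, m_sheet = m_par, m_normal = m_sheet) {
  stopifnot(m_par > 0, m_sheet > 0, m_normal > 0)
  structure(c(par = m_par, sheet = m_sheet, normal = m_normal),
            class = "conductivity_set")
}

#' Assemble per-cell conductivity tensors from fiber frames
#'
#' `M = m_par e_f e_f' + m_sheet e_s e_s' + m_normal e_n e_n'` — symmetric
#' positive definite by construction.
#'
#' @param frames A `fiber_frame` (see [fiber_frames]); triads are checked
#'   for orthonormality.
#' @param comps A `conductivity_set` (or length-3 numeric vector).
#' @return n x 3 x 3 array of tensors.
#' @export
assemble_conductivity <- function(frames, comps) {
  check_orthonormal(frames)
  n <- nrow(frames$e_fiber)
  M <- array(0, c(n, 3, 3))
  add <- function(M, e, m) {
    for (a in 1:3) for (b in 1:3) M[, a, b] <- M[, a, b] + m * e[, a] * e[, b]
    M
  }
  M <- add(M, frames$e_fiber, comps[[1]])
  M <- add(M, frames$e_sheet, comps[[2]])
  M <- add(M, frames$e_normal, comps[[3]])
  M
}

#' Monodomain-equivalent conductivity tensor
#'
#' When the extracellular tensor is proportional to the intracellular one
#' (`M_ext = lambda M_int`) the bidomain system reduces to a monodomain
#' equation with `M = lambda M_int / (1 + lambda)`.
#'
#' @param M_int Per-cell tensor array (or a single 3x3 matrix / scalar).
#' @param lambda Proportionality constant, > 0.
#' @return Scaled tensor(s).
#' @export
monodomain_equivalent <- function(M_int, lambda) {
  if (lambda <= 0) stop("lambda must be > 0")
  lambda / (1 + lambda) * M_int
}

# per-cell tensor array from scalar vector
iso_tensors <- function(k, n = length(k)) {
  k <- rep_len(k, n)
  M <- array(0, c(n, 3, 3))
  M[, 1, 1] <- k; M[, 2, 2] <- k; M[, 3, 3] <- k
  M
}

# face-normal conductivity component per cell per face
face_normal_k <- function(M, cells, nrm) {
  k <- numeric(length(cells))
  for (a in 1:3) for (b in 1:3)
    k <- k + M[cells, a, b] * nrm[, a] * nrm[, b]
  k
}

# sparse FV "Laplacian": (L v)_i = sum_f T_f (v_j - v_i), mS*mm
ep_laplacian <- function(mesh, M, blocks = character(0)) {
  f <- mesh$faces
  nrm <- cbind(f$nx, f$ny, f$nz)
  ki <- face_normal_k(M, f$i, nrm)
  kj <- face_normal_k(M, f$j, nrm)
  T_f <- ifelse(ki + kj > 0, 2 * f$area * ki * kj / ((ki + kj) * f$dist), 0)
  if (length(blocks)) T_f[f$label %in% blocks] <- 0
  n <- mesh$n_cells
  ii <- c(f$i, f$j, f$i, f$j)
  jj <- c(f$j, f$i, f$i, f$j)
  xx <- c(T_f, T_f, -T_f, -T_f)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Stimulus/block/pacing protocol
#'
#' @param stimuli List of entries `list(cells, onset, duration, amplitude)`
#'   — timed volumetric current injections (cells: indices; onset/duration
#'   ms; amplitude uA/mm^3).  Pacemaker leads are entries whose onsets
#'   encode the per-lead activation schedule.
#' @param blocks Character vector of face labels (conduction-system segment
#'   names) whose faces are disabled — a conduction block switch.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(stimuli = list(), blocks = character(0)) {
  for (s in stimuli) {
    stopifnot(s$onset >= 0, is.finite(s$amplitude), s$duration > 0,
              length(s$cells) >= 1)
  }
  structure(list(stimuli = stimuli, blocks = blocks),
            class = "stimulus_protocol")
}

#' Evaluate a protocol at a time point
#'
#' Adds each active stimulus amplitude to the member cells for
#' `t` in `[onset, onset + duration)`; an empty protocol is a no-op.
#'
#' @param protocol A `stimulus_protocol` (or NULL).
#' @param t Time, ms.
#' @param n_cells Number of cells.
#' @return Per-cell volumetric stimulus current (uA/mm^3).
#' @export
apply_protocol <- function(protocol, t, n_cells) {
  I <- numeric(n_cells)
  if (is.null(protocol)) return(I)
  for (s in protocol$stimuli) {
    if (t >= s$onset && t < s$onset + s$duration)
      I[s$cells] <- I[s$cells] + s$amplitude
  }
  I
}

#' Assemble an electrophysiology system
#'
#' Pre-builds the finite-volume operators and their factorizations for a
#' fixed time step, so that [step_ep] is a cheap repeated operation.
#'
#' @param mesh A `tissue_mesh`.
#' @param model An `ionic_model` (one membrane model for the whole mesh).
#' @param conductivity Monodomain: per-cell tensor array (n x 3 x 3) or a
#'   per-cell/scalar isotropic value (mS/mm). Bidomain: `list(int=, ext=)`
#'   of tensor arrays.
#' @param chi_cm Product of surface-to-volume ratio and membrane
#'   capacitance (uF/mm^3); single calibration scalar or per-cell vector.
#' @param mode `"monodomain"` or `"bidomain"`.
#' @param dt Time step the operators are factorized for (ms).
#' @param blocks Face labels disabled by a conduction block (usually taken
#'   from the protocol).
#' @return Object of class `ep_system`.
#' @export
ep_system <- function(mesh, model, conductivity, chi_cm = 1,
                      mode = c("monodomain", "bidomain"), dt = 0.05,
                      blocks = character(0)) {
  mode <- match.arg(mode)
  stopifnot(dt > 0)
  n <- mesh$n_cells
  chi_cm <- rep_len(chi_cm, n)
  as_tensors <- function(x) {
    if (is.array(x) && length(dim(x)) == 3) x else iso_tensors(x, n)
  }
  if (mode == "bidomain") {
    if (!is.list(conductivity) || is.null(conductivity$int) ||
        is.null(conductivity$ext))
      stop("bidomain mode requires conductivity = list(int=, ext=)")
    Mi <- as_tensors(conductivity$int)
    Me <- as_tensors(conductivity$ext)
    L_int <- ep_laplacian(mesh, Mi, blocks)
    L_tot <- ep_laplacian(mesh, Mi + Me, blocks)
    # zero-mean gauge via Lagrange-multiplier augmentation
    one <- mesh$volume
    Aug <- rbind(cbind(L_tot, one), c(one, 0))
    ell_fac <- Matrix::lu(methods::as(Aug, "CsparseMatrix"))
    L <- L_int
  } else {
    L <- ep_laplacian(mesh, as_tensors(conductivity), blocks)
    L_int <- L; ell_fac <- NULL
  }
  D <- chi_cm * mesh$volume
  A <- Matrix::Diagonal(x = D) - dt * L_int
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                          LDL = FALSE)
  structure(list(mesh = mesh, model = model, mode = mode, dt = dt,
                 chi_cm = chi_cm, D = D, L_int = L_int, ell_fac = ell_fac,
                 fac = fac, blocks = blocks),
            class = "ep_system")
}

#' Initial tissue state at the model rest point
#'
#' @param sys An `ep_system`.
#' @return List with `v` (vector), `s` (list of state vectors), `Ta`
#'   (vector), `v_ext` (bidomain only) and `t`.
#' @export
ep_rest_state <- function(sys) {
  n <- sys$mesh$n_cells
  rs <- sys$model$rest_state
  list(v = rep(rs$v, n), s = lapply(rs$s, rep, n), Ta = numeric(n),
       v_ext = numeric(n), t = 0)
}

#' One operator-splitting step of the reaction-diffusion system
#'
#' Reaction step per cell (Rush-Larsen/forward-Euler membrane update plus
#' stimulus), then an implicit finite-volume diffusion step; in bidomain
#' mode the extracellular potential is obtained from the gauged elliptic
#' solve before the parabolic update.
#'
#' @param sys An `ep_system` (operators factorized for `sys$dt`).
#' @param state State list as from [ep_rest_state].
#' @param protocol A `stimulus_protocol` or NULL.
#' @param np_params If non-NULL, Nash-Panfilov parameters: active tension
#'   is advanced alongside (forward Euler on the normalized potential).
#' @return Updated state (with `t` advanced by `sys$dt`).
#' @export
step_ep <- function(sys, state, protocol = NULL, np_params = NULL) {
  dt <- sys$dt
  n <- sys$mesh$n_cells
  I_vol <- apply_protocol(protocol, state$t, n)
  # volumetric stimulus enters dv/dt as I_vol / (chi Cm); expressed as an
  # equivalent per-membrane-area current for the cell update
  I_area <- I_vol * sys$model$Cm / sys$chi_cm
  rs <- step_cell_vec(sys$model, state$v, state$s, dt, I_area)
  v <- rs$v
  if (sys$mode == "bidomain") {
    rhs <- c(-as.numeric(sys$L_int %*% v), 0)
    ve <- as.numeric(Matrix::solve(sys$ell_fac, rhs))[seq_len(n)]
    b <- sys$D * v + dt * as.numeric(sys$L_int %*% ve)
    state$v_ext <- ve
  } else {
    b <- sys$D * v
  }
  v_new <- as.numeric(Matrix::solve(sys$fac, b))
  if (!is.null(np_params)) {
    rng <- range_of_model(sys$model)
    u <- (state$v - rng[1]) / diff(rng)
    state$Ta <- pmax(state$Ta + dt * active_tension_rate(u, state$Ta, np_params), 0)
  }
  state$s <- rs$s
  state$v_prev <- state$v
  state$v <- v_new
  state$t <- state$t + dt
  state
}

#' Run an electrophysiology simulation
#'
#' Steps [step_ep] to `t_end`, tracking the activation map (first upward
#' crossing of the model threshold, linearly interpolated in time) and
#' optional traces/frames.
#'
#' @inheritParams step_ep
#' @param t_end End time, ms.
#' @param trace_cells Cell indices whose v is recorded every step.
#' @param frame_every Record a full v field every n steps (0 = never).
#' @param stop_when_activated Stop early once every cell has activated
#'   (plus `settle_ms` of additional integration).
#' @param settle_ms See above. Default 0.
#' @return List with `activation` (an `activation_map`), `state`, `times`,
#'   `traces` (matrix), `frames` (list of v fields), `frame_times`.
#' @export
run_ep <- function(sys, protocol = NULL, t_end, trace_cells = integer(0),
                   frame_every = 0L, np_params = NULL,
                   stop_when_activated = FALSE, settle_ms = 0) {
  state <- ep_rest_state(sys)
  n <- sys$mesh$n_cells
  act <- rep(NA_real_, n)
  thr <- sys$model$v_threshold
  nsteps <- ceiling(t_end / sys$dt)
  traces <- if (length(trace_cells))
    matrix(NA_real_, nsteps + 1, length(trace_cells)) else NULL
  times <- numeric(nsteps + 1)
  frames <- list(); frame_times <- numeric(0)
  if (length(trace_cells)) traces[1, ] <- state$v[trace_cells]
  all_act_t <- NA_real_
  for (k in seq_len(nsteps)) {
    v_old <- state$v
    state <- step_ep(sys, state, protocol, np_params)
    newly <- which(is.na(act) & v_old < thr & state$v >= thr)
    if (length(newly)) {
      frac <- (thr - v_old[newly]) / (state$v[newly] - v_old[newly])
      act[newly] <- (state$t - sys$dt) + frac * sys$dt
    }
    times[k + 1] <- state$t
    if (length(trace_cells)) traces[k + 1, ] <- state$v[trace_cells]
    if (frame_every > 0 && k %% frame_every == 0) {
      frames[[length(frames) + 1]] <- state$v
      frame_times <- c(frame_times, state$t)
    }
    if (stop_when_activated && !anyNA(act)) {
      if (is.na(all_act_t)) all_act_t <- state$t
      if (state$t - all_act_t >= settle_ms) { times <- times[seq_len(k + 1)];
        if (length(trace_cells)) traces <- traces[seq_len(k + 1), , drop = FALSE]
        break }
    }
  }
  list(activation = activation_map(act, sys$mesh), state = state,
       times = times, traces = traces, frames = frames,
       frame_times = frame_times)
}

#' Activation map
#'
#' @param times Per-cell first-crossing time (ms); NA marks unactivated
#'   cells.
#' @param mesh The mesh the map lives on.
#' @return Object of class `activation_map`.
#' @export
activation_map <- function(times, mesh) {
  structure(list(times = times, mesh = mesh), class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d cells, %d unactivated, span %.2f ms\n",
              length(x$times), sum(is.na(x$times)),
              diff(range(x$times, na.rm = TRUE))))
  invisible(x)
}

#' Conduction velocity from an activation map
#'
#' Least-squares slope of probe position (projection on `axis`) versus
#' activation time over `window`, excluding boundary-affected ends by
#' construction of the window.
#'
#' @param map An `activation_map`.
#' @param axis Direction (3-vector, normalized internally).
#' @param window `c(lo, hi)` in projected coordinates (mm); only probes
#'   inside are used.
#' @return Speed in m/s (mm/ms).
#' @export
measure_cv <- function(map, axis = c(1, 0, 0), window = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  x <- as.numeric(map$mesh$centroids %*% axis)
  t <- map$times
  keep <- !is.na(t)
  if (!is.null(window)) keep <- keep & x >= window[1] & x <= window[2]
  if (sum(keep) < 2) stop("need at least 2 activated probes in window")
  x <- x[keep]; t <- t[keep]
  if (stats::var(t) == 0) stop("all probes activated simultaneously")
  # slope of x vs t (mm/ms == m/s)
  stats::cov(x, t) / stats::var(t)
}

#' Calibrate chi*Cm against a target conduction velocity
#'
#' Bisection on `chi_cm` so that a 1D monodomain cable with conductivity
#' `m` conducts at `target_cv`; CV is measured over the central half of the
#' cable.  The monodomain CV scales as `sqrt(m / (chi Cm))`, so the map is
#' monotone and bisection on a log scale is robust.
#'
#' @param m Cable conductivity, mS/mm.
#' @param target_cv Target speed, m/s.
#' @param model An `ionic_model`; default the dimensional atrial surrogate.
#' @param length_mm,dx Cable geometry (default 20 mm at 0.1 mm).
#' @param dt Time step, ms.
#' @param bounds Initial `chi_cm` bracket.
#' @param tol Relative CV tolerance. Default 1e-4.
#' @param max_iter Bisection cap. Default 60.
#' @return List with `chi_cm`, `cv`, `iterations`.
#' @export
calibrate_chi_cm <- function(m, target_cv, model = ionic_model("atrial"),
                             length_mm = 20, dx = 0.1, dt = 0.05,
                             bounds = c(0.02, 20), tol = 1e-4,
                             max_iter = 60) {
  cv_of <- function(chi_cm) {
    # propagation failure -> speed 0; near-simultaneous activation (the
    # regression slope degenerates, possibly negative) -> effectively
    # infinite speed: both keep the bisection bracket well-ordered
    cv <- tryCatch(cable_cv(m, chi_cm, model, length_mm, dx, dt),
                   error = function(e) 0)
    if (cv < 0) Inf else cv
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- cv_of(lo); f_hi <- cv_of(hi)   # CV decreasing in chi_cm
  if (!(f_lo > target_cv && f_hi < target_cv))
    stop("target CV not bracketed by bounds")
  cv <- NA_real_; mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    cv <- cv_of(mid)
    if (abs(cv - target_cv) / target_cv < tol) break
    if (cv > target_cv) lo <- mid else hi <- mid
  }
  list(chi_cm = mid, cv = cv, iterations = it)
}

#' Conduction velocity on a stimulated 1D cable
#'
#' Builds a cable, stimulates the first 0.5 mm, and measures CV over the
#' central half.
#'
#' @inheritParams calibrate_chi_cm
#' @param chi_cm Calibration constant (uF/mm^3).
#' @return Speed, m/s.
#' @export
cable_cv <- function(m, chi_cm, model = ionic_model("atrial"),
                     length_mm = 20, dx = 0.1, dt = 0.05) {
  mesh <- mesh_cable(length_mm, dx)
  sys <- ep_system(mesh, model, conductivity = m, chi_cm = chi_cm, dt = dt)
  n <- mesh$n_cells
  stim_cells <- which(mesh$centroids[, 1] < 1)
  amp <- stim_amplitude(model, chi_cm)
  prot <- stimulus_protocol(list(list(cells = stim_cells, onset = 0,
                                      duration = 2, amplitude = amp)))
  # generous budget; early exit once the whole cable has activated
  t_max <- 4 * length_mm / max(target_floor_cv(m, chi_cm), 0.02)
  res <- run_ep(sys, prot, t_end = t_max, stop_when_activated = TRUE)
  measure_cv(res$activation, window = c(length_mm / 4, 3 * length_mm / 4))
}

# crude lower bound on the expected CV, used only to size the time budget
target_floor_cv <- function(m, chi_cm) 0.25 * sqrt(m / chi_cm)

# volumetric stimulus amplitude that raises v at ~one amplitude per ms for
# the given calibration constant (dv/dt contribution = I_vol/(chi Cm));
# strong enough to ignite against diffusive loading
stim_amplitude <- function(model, chi_cm) {
  amp_v <- diff(range_of_model(model))
  amp_v * mean(chi_cm)
}
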