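# Ionic membrane models and active-tension kinetics.
#
# The registry holds (i) the dimensionless minimal two-variable polynomial
# model and (ii) dimensional two-variable gate models ("atrial",
# "ventricular", "purkinje").  The dimensional models are SYNTHETIC
# stand-ins: phenomenological Mitchell-Schaeffer-type kinetics tuned to the
# resting potential, amplitude and action-potential duration typical of the
# atrial, ventricular and Purkinje myocyte models used in whole-heart
# electrophysiology; they are not transcriptions of those biophysical
# formulations.

#' Cell electrical/contractile state
#'
#' Bundles the transmembrane potential, the ionic state vector and the
#' active tension of a single cell (or of every cell of a tissue when the
#' fields are vectors/matrices).
#'
#' @param v Transmembrane potential, mV (dimensionless in `[0,1]` for the
#'   minimal model).
#' @param s Ionic state vector (model-specific length and units).
#' @param Ta Active tension, kPa. Default 0.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(v, s = numeric(0), Ta = 0) {
  stopifnot(is.numeric(v), all(is.finite(v)), all(is.finite(s)))
  structure(list(v = v, s = as.numeric(s), Ta = Ta), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> v = %.4g, %d ionic state(s), Ta = %.4g kPa\n",
              x$v[1], length(x$s), x$Ta[1]))
  invisible(x)
}

# internal constructor for a model spec; rhs(v, s, params) -> list(dv, ds)
new_ionic_model <- function(name, n_states, rest_v, rest_s, params, rhs,
                            gates = integer(0), gate_inf_tau = NULL,
                            Cm = 0.01, chi = 140, v_threshold = 0,
                            dt_default = 0.02, dimensionless = FALSE) {
  structure(list(
    name = name, n_states = n_states,
    rest_state = cell_state(rest_v, rest_s),
    params = params, rhs = rhs,
    gates = gates, gate_inf_tau = gate_inf_tau,
    Cm = Cm, chi = chi,
    v_threshold = v_threshold, dt_default = dt_default,
    dimensionless = dimensionless
  ), class = "ionic_model")
}

# Minimal two-variable model (Aliev-Panfilov-type polynomial kinetics),
# dimensionless.  dv/dt = k v(v-a)(1-v) - v r + I ; the recovery variable r
# follows dr/dt = (gamma + mu1 r/(mu2+v)) (-r - k v(v - b - 1)).
minimal_rhs <- function(v, s, p) {
  r <- s[[1]]
  dv <- p$k * v * (v - p$a) * (1 - v) - v * r
  dr <- (p$gamma + p$mu1 * r / (p$mu2 + v)) * (-r - p$k * v * (v - p$b - 1))
  list(dv = dv / p$t_scale, ds = list(dr / p$t_scale))
}

# Mitchell-Schaeffer-type kinetics on a normalized potential u in [0,1]:
#   du/dt = h u^2 (1-u)/tau_in - u/tau_out + I
#   dh/dt = (1-h)/tau_open  (u <  v_gate)
#         = -h/tau_close    (u >= v_gate)
# Dimensional wrapper: v = v_rest + v_amp * u, time in ms.
ms_rhs <- function(v, s, p) {
  u <- (v - p$v_rest) / p$v_amp
  h <- s[[1]]
  du <- h * u^2 * (1 - u) / p$tau_in - u / p$tau_out
  below <- u < p$v_gate
  dh <- ifelse(below, (1 - h) / p$tau_open, -h / p$tau_close)
  list(dv = p$v_amp * du, ds = list(dh))
}

ms_gate_inf_tau <- function(v, s, p) {
  u <- (v - p$v_rest) / p$v_amp
  below <- u < p$v_gate
  list(inf = list(ifelse(below, 1, 0)),
       tau = list(ifelse(below, p$tau_open, p$tau_close)))
}

ms_model <- function(name, v_rest, v_amp, tau_in, tau_out, tau_open,
                     tau_close, Cm = 0.01, chi = 140) {
  p <- list(v_rest = v_rest, v_amp = v_amp, v_gate = 0.13,
            tau_in = tau_in, tau_out = tau_out,
            tau_open = tau_open, tau_close = tau_close)
  new_ionic_model(name, 1L, rest_v = v_rest, rest_s = 1, params = p,
                  rhs = ms_rhs, gates = 1L, gate_inf_tau = ms_gate_inf_tau,
                  Cm = Cm, chi = chi, v_threshold = 0, dt_default = 0.02)
}

#' Ionic model registry
#'
#' Returns a registered membrane model by name.  Available models:
#' \describe{
#'   \item{`minimal`}{Dimensionless two-variable polynomial
#'     (Aliev-Panfilov-type) model; `v` in `[0,1]`, time in dimensionless
#'     units (set `t_scale` in ms via `params` for a dimensional clock; the
#'     conventional rescaling is 1 unit = 12.9 ms and 100 mV of amplitude
#'     above a -80 mV rest).}
#'   \item{`atrial`, `ventricular`, `purkinje`}{Dimensional two-variable
#'     gate models (Mitchell-Schaeffer-type kinetics; synthetic stand-ins
#'     for the biophysical atrial/ventricular/Purkinje formulations) with
#'     tissue-typical rest potential, amplitude and APD.}
#' }
#'
#' @param name Model name.
#' @param params Named list of parameter overrides merged over the model
#'   defaults.
#' @return An object of class `ionic_model` with fields `name`, `n_states`,
#'   `rest_state`, `params`, `Cm` (membrane capacitance, uF/mm^2), `chi`
#'   (surface-to-volume ratio, 1/mm), `v_threshold` (activation threshold)
#'   and `dt_default` (ms).
#' @export
ionic_model <- function(name, params = list()) {
  m <- switch(name,
    minimal = {
      p <- list(k = 8, a = 0.15, b = 0.15, gamma = 0.002,
                mu1 = 0.2, mu2 = 0.3, t_scale = 1)
      new_ionic_model("minimal", 1L, rest_v = 0, rest_s = 0, params = p,
                      rhs = minimal_rhs, Cm = 1, chi = 1,
                      v_threshold = 0.5, dt_default = 0.1,
                      dimensionless = TRUE)
    },
    # APDs roughly 260 / 300 / 380 ms; rests -81 / -86 / -69 mV
    atrial      = ms_model("atrial",      -81, 101, 0.3, 6, 120, 130),
    ventricular = ms_model("ventricular", -86, 121, 0.3, 6, 120, 150),
    purkinje    = ms_model("purkinje",    -69,  99, 0.3, 6, 120, 190),
    stop("unknown ionic model: ", name)
  )
  if (length(params)) m$params[names(params)] <- params
  m
}

#' Names of all registered ionic models
#' @return Character vector.
#' @export
ionic_model_names <- function() c("minimal", "atrial", "ventricular", "purkinje")

check_state_dim <- function(model, state) {
  if (length(state$s) != model$n_states)
    stop(sprintf("state vector length %d does not match model '%s' (%d states)",
                 length(state$s), model$name, model$n_states))
  if (!all(is.finite(state$v)) || !all(is.finite(unlist(state$s))))
    stop("non-finite cell state")
}

#' Time-derivatives of the membrane state
#'
#' Evaluates the model kinetics `dv/dt = -I_ion/Cm + I_stim/Cm` (for the
#' dimensionless minimal model the polynomial kinetics absorb `Cm = 1`) and
#' the ionic-state derivatives.
#'
#' @param model An `ionic_model`.
#' @param state A `cell_state` (vectorized over cells: `v` and each state a
#'   vector).
#' @param t Time, ms (unused by the autonomous registered models, kept for
#'   protocol-driven stimuli).
#' @param I_stim Stimulus current per unit membrane area, uA/mm^2 (added as
#'   `I_stim/Cm` to `dv/dt`).
#' @return List with `dv` and `ds` (list of per-state derivative vectors).
#' @export
ionic_rhs <- function(model, state, t = 0, I_stim = 0) {
  check_state_dim(model, state)
  d <- model$rhs(state$v, as.list(state$s), model$params)
  d$dv <- d$dv + I_stim / model$Cm
  d
}

# vectorized internal form: v numeric vector, s list of numeric vectors
ionic_rhs_vec <- function(model, v, s, I_stim = 0) {
  d <- model$rhs(v, s, model$params)
  d$dv <- d$dv + I_stim / model$Cm
  d
}

#' Advance a cell one time step
#'
#' Gating variables (declared by the model) are advanced with the
#' exponential Rush-Larsen rule `s <- s_inf + (s - s_inf) exp(-dt/tau)`;
#' all remaining states and the potential use forward Euler.  Gates that
#' would leave `[0,1]` are clamped with a warning.
#'
#' @inheritParams ionic_rhs
#' @param dt Time step, ms (> 0).
#' @return Updated `cell_state` (Ta carried through unchanged).
#' @export
step_cell <- function(model, state, dt, I_stim = 0) {
  stopifnot(dt > 0)
  check_state_dim(model, state)
  s <- as.list(state$s)
  out <- step_cell_vec(model, state$v, s, dt, I_stim)
  cell_state(out$v, unlist(out$s), state$Ta)
}

step_cell_vec <- function(model, v, s, dt, I_stim = 0) {
  d <- ionic_rhs_vec(model, v, s, I_stim)
  v_new <- v + dt * d$dv
  s_new <- s
  if (length(model$gates)) {
    git <- model$gate_inf_tau(v, s, model$params)
    k <- 0L
    for (g in model$gates) {
      k <- k + 1L
      sg <- git$inf[[k]] + (s[[g]] - git$inf[[k]]) * exp(-dt / git$tau[[k]])
      if (any(sg < -1e-12 | sg > 1 + 1e-12)) {
        warning("gating variable left [0,1]; clamped (dt too large?)")
        sg <- pmin(pmax(sg, 0), 1)
      }
      s_new[[g]] <- sg
    }
  }
  non_gates <- setdiff(seq_along(s), model$gates)
  for (j in non_gates) s_new[[j]] <- s[[j]] + dt * d$ds[[j]]
  list(v = v_new, s = s_new)
}

#' Nash-Panfilov active-tension rate
#'
#' `dTa/dt = eps(v) (k_Ta v - Ta)` with the two-level switching function
#' `eps(v) = eps0` below the threshold `v_star` and `eps1` above.  `v` is
#' the normalized potential in `[0,1]`.
#'
#' @param v Normalized transmembrane potential.
#' @param Ta Active tension, kPa.
#' @param params List with `eps0`, `eps1`, `v_star`, `k_Ta` (kPa).
#'   Defaults `eps0 = 1`, `eps1 = 10` (per time unit), `v_star = 0.05`,
#'   `k_Ta = 47.9`.
#' @return dTa/dt (kPa per time unit); vectorized.
#' @export
active_tension_rate <- function(v, Ta, params = list()) {
  p <- utils::modifyList(
    list(eps0 = 1, eps1 = 10, v_star = 0.05, k_Ta = 47.9), params)
  if (p$k_Ta < 0) stop("k_Ta must be non-negative")
  eps <- ifelse(v < p$v_star, p$eps0, p$eps1)
  eps * (p$k_Ta * v - Ta)
}

#' Action-potential duration from a voltage trace
#'
#' APD at a repolarization fraction `level` (e.g. 0.9 for APD90): the time
#' between the upstroke and downstroke crossings of
#' `rest + (1 - level) (peak - rest)`, with linear interpolation of the
#' crossing times.
#'
#' @param t Time vector, ms.
#' @param v Voltage vector (one action potential).
#' @param level Repolarization fraction in (0, 1). Default 0.9.
#' @return Duration, ms.
#' @export
measure_apd <- function(t, v, level = 0.9) {
  stopifnot(length(t) == length(v), level > 0, level < 1)
  rest <- v[1]
  peak <- max(v)
  if (peak - rest <= .Machine$double.eps * 100 * max(1, abs(peak)))
    stop("trace never depolarizes")
  thr <- rest + (1 - level) * (peak - rest)
  above <- v > thr
  up <- which(!above[-length(above)] & above[-1])
  dn <- which(above[-length(above)] & !above[-1])
  if (!length(up) || !length(dn)) stop("no threshold crossing found")
  cross <- function(i) {
    t[i] + (thr - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  dn <- dn[dn > up[1]]
  if (!length(dn)) stop("no repolarization crossing found")
  cross(dn[1]) - cross(up[1])
}

#' Integrate a single cell action potential
#'
#' Convenience driver: steps one cell with [step_cell] under a square
#' stimulus pulse, recording (t, v, Ta).  Active tension follows the
#' Nash-Panfilov rate on the normalized potential.
#'
#' @inheritParams step_cell
#' @param t_end End time, ms.
#' @param stim_start,stim_dur,stim_amp Stimulus onset, duration (ms) and
#'   amplitude (uA/mm^2).
#' @param np_params Nash-Panfilov parameters, see [active_tension_rate].
#' @param record_every Record every n-th step. Default 1.
#' @return data.frame(t, v, Ta).
#' @export
simulate_ap <- function(model, dt = model$dt_default, t_end,
                        stim_start = 1, stim_dur = 2, stim_amp = 0.5,
                        np_params = list(), record_every = 1L) {
  n <- ceiling(t_end / dt)
  v <- model$rest_state$v
  s <- as.list(model$rest_state$s)
  Ta <- 0
  amp <- diff(range_of_model(model))
  v0 <- range_of_model(model)[1]
  keep <- seq(0, n, by = record_every)
  out <- matrix(NA_real_, length(keep), 3)
  ki <- 1L
  for (i in 0:n) {
    if (i %in% keep) { out[ki, ] <- c(i * dt, v, Ta); ki <- ki + 1L }
    if (i == n) break
    t <- i * dt
    I <- if (t >= stim_start && t < stim_start + stim_dur) stim_amp else 0
    st <- step_cell_vec(model, v, s, dt, I)
    u <- (v - v0) / amp
    Ta <- Ta + dt * active_tension_rate(u, Ta, np_params)
    v <- st$v; s <- st$s
  }
  out <- out[!is.na(out[, 1]), , drop = FALSE]
  data.frame(t = out[, 1], v = out[, 2], Ta = out[, 3])
}

# nominal (rest, peak) span used to normalize v for the tension model
range_of_model <- function(model) {
  if (model$dimensionless) c(0, 1)
  else c(model$params$v_rest, model$params$v_rest + model$params$v_amp)
}
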