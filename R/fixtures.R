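# Synthetic geometry and protocol generators.  All fixtures are
# deterministic given their spec (and seed, where randomness is used).

#' Describe a synthetic fixture
#'
#' @param kind One of `"cable"`, `"sheet"`, `"slab"`,
#'   `"ellipsoid_ventricle"`, `"membrane_channel"`, `"torso_leads"`,
#'   `"mini_heart"`.
#' @param ... Kind-specific parameters (see [make_fixture]).
#' @param seed Integer seed recorded in the manifest. Default 1.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, ..., seed = 1L) {
  kind <- match.arg(kind, c("cable", "sheet", "slab", "ellipsoid_ventricle",
                            "membrane_channel", "torso_leads", "mini_heart"))
  structure(list(kind = kind, params = list(...), seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' Deterministic given spec + seed.  Kinds:
#' \describe{
#'   \item{cable}{20 mm x 0.1 mm 1D cable (`length_mm`, `dx`) with an
#'     end-stimulus protocol.}
#'   \item{sheet}{2D sheet with uniform fibers (`lx`, `ly`, `dx`).}
#'   \item{slab}{3D slab with the linear transmural fiber rotation from
#'     +60 to -60 degrees (`lx`, `ly`, `lz`, `dx`, `angle0`, `angle1`).}
#'   \item{ellipsoid_ventricle}{Truncated prolate-spheroid shell meshed
#'     with tetrahedra, apex/base labels, transmural fiber rotation.}
#'   \item{membrane_channel}{2D channel flow domain plus a flexible
#'     membrane (segment chain) anchored to the bottom wall.}
#'   \item{torso_leads}{Two-electrode lead set 35 mm outside a mesh.}
#'   \item{mini_heart}{Ellipsoid ventricle + outflow-tube membrane +
#'     aortic Windkessel parameters + torso leads + apex pacing protocol.}
#' }
#'
#' @param spec A `fixture_spec`.
#' @return Kind-specific list; always contains `spec`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  p <- spec$params
  out <- switch(spec$kind,
    cable = fixture_cable(p),
    sheet = fixture_sheet(p),
    slab = fixture_slab(p),
    ellipsoid_ventricle = fixture_ellipsoid(p),
    membrane_channel = fixture_membrane_channel(p),
    torso_leads = fixture_torso_leads(p),
    mini_heart = fixture_mini_heart(p))
  out$spec <- spec
  out
}

with_defaults <- function(p, defaults) utils::modifyList(defaults, p)

fixture_cable <- function(p) {
  p <- with_defaults(p, list(length_mm = 20, dx = 0.1, m = 1.29,
                             chi_cm = 1))
  mesh <- mesh_cable(p$length_mm, p$dx)
  model <- ionic_model("atrial")
  prot <- stimulus_protocol(list(list(
    cells = which(mesh$centroids[, 1] < 1), onset = 0, duration = 2,
    amplitude = stim_amplitude(model, p$chi_cm))))
  list(mesh = mesh, protocol = prot, model_name = "atrial",
       conductivity = p$m, chi_cm = p$chi_cm)
}

fixture_sheet <- function(p) {
  p <- with_defaults(p, list(lx = 10, ly = 10, dx = 0.2, angle = 0))
  mesh <- mesh_sheet(p$lx, p$ly, p$dx)
  list(mesh = mesh, frames = fiber_frames(mesh, "uniform", angle0 = p$angle))
}

fixture_slab <- function(p) {
  p <- with_defaults(p, list(lx = 10, ly = 10, lz = 3, dx = 0.5,
                             angle0 = 60, angle1 = -60))
  mesh <- mesh_slab(p$lx, p$ly, p$lz, p$dx)
  list(mesh = mesh,
       frames = fiber_frames(mesh, "transmural", angle0 = p$angle0,
                             angle1 = p$angle1))
}

# truncated prolate spheroid shell: polar angle phi measured from the apex
# (-z pole), phi in [phi_apex, phi_base]; nr transmural layers between the
# endocardial and epicardial ellipsoids.  Kuhn 6-tet subdivision of the
# structured hex shell (conforming across cells and the theta wrap).
fixture_ellipsoid <- function(p) {
  p <- with_defaults(p, list(
    a_endo = 20, c_endo = 40, wall = 8, n_phi = 10, n_theta = 16, nr = 2,
    phi_apex = 0.35, phi_base = 1.95, angle0 = 60, angle1 = -60))
  n_phi <- p$n_phi; n_theta <- p$n_theta; nr <- p$nr
  nid <- function(ip, it, ir)
    ((ir) * (n_phi + 1) + ip) * n_theta + ((it %% n_theta)) + 1L
  pos <- matrix(0, (n_phi + 1) * n_theta * (nr + 1), 3)
  for (ir in 0:nr) for (ip in 0:n_phi) for (it in 0:(n_theta - 1)) {
    rho <- ir / nr
    a <- p$a_endo + rho * p$wall
    cc <- p$c_endo + rho * p$wall
    phi <- p$phi_apex + (ip / n_phi) * (p$phi_base - p$phi_apex)
    th <- 2 * pi * it / n_theta
    pos[nid(ip, it, ir), ] <- c(a * sin(phi) * cos(th),
                                a * sin(phi) * sin(th),
                                -cc * cos(phi))
  }
  # Kuhn subdivision: 6 tets per hex via the vertex paths of the 3!
  # coordinate orders
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  tets <- list(); hexid <- list()
  kk <- 0L
  for (ir in 0:(nr - 1)) for (ip in 0:(n_phi - 1)) for (it in 0:(n_theta - 1)) {
    kk <- kk + 1L
    corner <- function(d) nid(ip + d[1], it + d[2], ir + d[3])
    for (q in 1:6) {
      d <- c(0, 0, 0)
      vs <- integer(4); vs[1] <- corner(d)
      for (s in 1:3) { d[perms[q, s]] <- 1; vs[s + 1] <- corner(d) }
      tets[[length(tets) + 1]] <- vs
      hexid[[length(hexid) + 1]] <- c(ip, it, ir, kk)
    }
  }
  tets <- do.call(rbind, tets)
  vol <- tet_volume(pos, tets)
  neg <- vol < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]   # consistent orientation
  hx <- do.call(rbind, hexid)
  region <- ifelse(hx[, 1] == n_phi - 1, "base", "LV")
  mesh <- tet_fv_mesh(pos, tets, region = region)
  # fiber triads from the surface-of-revolution tangents at each hex centre
  nc <- nrow(tets)
  ef <- matrix(0, nc, 3); es <- matrix(0, nc, 3); en <- matrix(0, nc, 3)
  for (k in seq_len(nc)) {
    rho <- (hx[k, 3] + 0.5) / nr
    phi <- p$phi_apex + ((hx[k, 1] + 0.5) / n_phi) * (p$phi_base - p$phi_apex)
    th <- 2 * pi * (hx[k, 2] + 0.5) / n_theta
    a <- p$a_endo + rho * p$wall; cc <- p$c_endo + rho * p$wall
    chat <- c(-sin(th), cos(th), 0)                       # circumferential
    lhat <- c(a * cos(phi) * cos(th), a * cos(phi) * sin(th),
              cc * sin(phi))
    lhat <- lhat / sqrt(sum(lhat^2))                      # apex-to-base
    lhat <- lhat - sum(lhat * chat) * chat
    lhat <- lhat / sqrt(sum(lhat^2))
    nhat <- c(chat[2] * lhat[3] - chat[3] * lhat[2],
              chat[3] * lhat[1] - chat[1] * lhat[3],
              chat[1] * lhat[2] - chat[2] * lhat[1])
    ang <- (p$angle0 + rho * (p$angle1 - p$angle0)) * pi / 180
    ef[k, ] <- cos(ang) * chat + sin(ang) * lhat
    es[k, ] <- -sin(ang) * chat + cos(ang) * lhat
    en[k, ] <- nhat
  }
  frames <- fiber_frame(ef, es, en)
  apex_cells <- which(mesh$centroids[, 3] < stats::quantile(mesh$centroids[, 3], 0.05))
  list(mesh = mesh, frames = frames, nodes = pos, tets = tets,
       region = region, apex_cells = apex_cells)
}

fixture_membrane_channel <- function(p) {
  p <- with_defaults(p, list(
    nx = 48, ny = 24, lx = 0.12, ly = 0.06, n_seg = 10, height = 0.024,
    x_pos = 0.03, thickness = 1e-2, rho_tissue = 1060,
    material = "mitral_tricuspid", bc_y = "noslip"))
  grid <- flow_grid(p$nx, p$ny, p$lx, p$ly, bc_y = p$bc_y)
  ns <- p$n_seg + 1
  nodes <- cbind(p$x_pos, seq(0, p$height, length.out = ns), 0)
  ds <- p$height / p$n_seg
  mass <- rep(p$rho_tissue * p$thickness * ds * 1, ns)  # per unit depth
  els <- lapply(seq_len(p$n_seg), function(i)
    list(nodes = c(i, i + 1L), region = p$material))
  net <- spring_network(nodes, mass, els, cross_section = p$thickness * 1)
  materials <- stats::setNames(list(registry_fung(p$material)), p$material)
  list(grid = grid, net = net, materials = materials,
       fixed_nodes = 1L, thickness = p$thickness)
}

fixture_torso_leads <- function(p) {
  p <- with_defaults(p, list(mesh = NULL, skin_distance = 35))
  if (is.null(p$mesh)) stop("torso_leads fixture needs a mesh")
  list(leads = torso_leads(p$mesh, p$skin_distance))
}

fixture_mini_heart <- function(p) {
  p <- with_defaults(p, list(nr = 1, n_phi = 8, n_theta = 12,
                             chi_cm = 0.64, dt_ep = 0.05))
  vent <- fixture_ellipsoid(list(nr = p$nr, n_phi = p$n_phi,
                                 n_theta = p$n_theta))
  # outflow tube: short triangulated cylinder membrane above the base
  zb <- max(vent$nodes[, 3])
  ntc <- 10; nzc <- 3; rt <- 12
  tube_nodes <- matrix(0, ntc * nzc, 3)
  for (iz in 0:(nzc - 1)) for (it in 0:(ntc - 1)) {
    th <- 2 * pi * it / ntc
    tube_nodes[iz * ntc + it + 1, ] <- c(rt * cos(th), rt * sin(th),
                                         zb + 4 * iz)
  }
  tube_tris <- list()
  for (iz in 0:(nzc - 2)) for (it in 0:(ntc - 1)) {
    a <- iz * ntc + (it %% ntc) + 1
    b <- iz * ntc + ((it + 1) %% ntc) + 1
    c_ <- (iz + 1) * ntc + (it %% ntc) + 1
    d <- (iz + 1) * ntc + ((it + 1) %% ntc) + 1
    tube_tris[[length(tube_tris) + 1]] <- list(nodes = c(a, b, d),
                                               region = "vessel")
    tube_tris[[length(tube_tris) + 1]] <- list(nodes = c(a, d, c_),
                                               region = "vessel")
  }
  tube <- spring_network(tube_nodes * 1e-3,
                         rep(1060 * 1.5e-3 * (2 * pi * rt * 1e-3 * 4e-3) /
                               ntc, ntc * nzc),
                         tube_tris, thickness = 1.5e-3)
  leads <- torso_leads(vent$mesh)
  wk <- registry_lookup("windkessel", "ao")
  model <- ionic_model("ventricular")
  prot <- stimulus_protocol(list(list(
    cells = vent$apex_cells, onset = 0, duration = 2,
    amplitude = stim_amplitude(model, p$chi_cm))))
  list(ventricle = vent, tube = tube, leads = leads, windkessel = wk,
       protocol = prot, model_name = "ventricular", chi_cm = p$chi_cm,
       dt_ep = p$dt_ep)
}
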