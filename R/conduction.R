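# Hierarchical conduction-system graph: slender 1D bundles (internodal
# pathways, AV node, His bundle, branches, Purkinje endpoints) coupled to a
# host myocardial mesh at insertion cells.  Network cells exchange flux
# with the host only at insertion faces; a block switch disables every face
# touching the named segment.

#' Describe a conduction-system network
#'
#' @param nodes data.frame with `id` (character), `x`, `y`, `z` (mm).
#' @param segments data.frame with `name`, `from`, `to` (node ids),
#'   `n_cells` (cells along the segment), `m` (monodomain conductivity,
#'   mS/mm), `area` (cross-section, mm^2).
#' @param insertions data.frame with `node` (graph node id) and `cell`
#'   (host-mesh cell index); may be empty.
#' @return Object of class `conduction_spec`.
#' @export
conduction_spec <- function(nodes, segments,
                            insertions = data.frame(node = character(0),
                                                    cell = integer(0))) {
  stopifnot(all(segments$from %in% nodes$id), all(segments$to %in% nodes$id),
            all(segments$n_cells >= 1), all(segments$m > 0),
            all(segments$area > 0))
  used <- unique(c(segments$from, segments$to))
  dangling <- setdiff(nodes$id, used)
  if (length(dangling))
    stop("dangling conduction-system node(s): ", paste(dangling, collapse = ", "))
  structure(list(nodes = nodes, segments = segments, insertions = insertions),
            class = "conduction_spec")
}

#' Default desk-scale conduction tree
#'
#' SA node -> internodal bundle -> AV node (slow) -> His bundle -> left and
#' right branches ending at left/right insertion points.  Conductivities
#' from the built-in registry (internodal bundles 1.29 mS/mm, Purkinje-type
#' fast segments 3.95 mS/mm); the AV segment conductivity is a configurable
#' slow value meant to be calibrated against a transit-delay target.
#'
#' @param m_av AV-node segment conductivity (mS/mm). Default 0.008
#'   (calibrated for a ~100 ms transit delay at the default geometry).
#' @param insert_left,insert_right Optional host-mesh cell indices for the
#'   branch endpoints; a vector distributes the junction over a patch.
#' @param insert_area Junction coupling area per insertion cell (mm^2);
#'   generous by default so the slender bundle can ignite the myocardial
#'   sink (distributed Purkinje-myocardial junction stand-in).
#' @return A `conduction_spec`.
#' @export
default_conduction_spec <- function(m_av = 0.008, insert_left = NULL,
                                    insert_right = NULL,
                                    insert_area = 1) {
  nodes <- data.frame(
    id = c("sa", "av_in", "av_out", "his", "left_end", "right_end"),
    x = c(0, 40, 48, 58, 88, 88),
    y = c(0, 0, 0, 0, 10, -10),
    z = 0)
  segments <- data.frame(
    name = c("internodal", "av", "his", "left_branch", "right_branch"),
    from = c("sa", "av_in", "av_out", "his", "his"),
    to   = c("av_in", "av_out", "his", "left_end", "right_end"),
    n_cells = c(80, 320, 20, 60, 60),
    m = c(1.29, m_av, 3.95, 3.95, 3.95),
    area = 0.1)
  ins <- data.frame(node = character(0), cell = integer(0),
                    area = numeric(0))
  if (!is.null(insert_left))
    ins <- rbind(ins, data.frame(node = "left_end", cell = insert_left,
                                 area = insert_area))
  if (!is.null(insert_right))
    ins <- rbind(ins, data.frame(node = "right_end", cell = insert_right,
                                 area = insert_area))
  conduction_spec(nodes, segments, ins)
}

#' Build a composite mesh from a conduction network (+ optional host)
#'
#' @param spec A `conduction_spec`.
#' @param host Optional host `tissue_mesh` the insertions couple into.
#' @param host_conductivity Host per-cell tensors (n x 3 x 3) or isotropic
#'   scalar/vector; required when `host` is given.
#' @return List of class `conduction_system` with `mesh` (composite
#'   `tissue_mesh`), `conductivity` (per-cell tensor array),
#'   `cells` (named list: per-segment cell indices, plus `host`),
#'   `sa_cell` (first cell of the segment leaving the first node).
#' @export
build_conduction_system <- function(spec, host = NULL,
                                    host_conductivity = NULL) {
  n_host <- if (is.null(host)) 0L else host$n_cells
  if (!is.null(host) && is.null(host_conductivity))
    stop("host mesh requires host_conductivity")
  if (nrow(spec$insertions) && is.null(host))
    stop("insertion sites given but no host mesh")
  if (nrow(spec$insertions) &&
      any(spec$insertions$cell > n_host | spec$insertions$cell < 1))
    stop("insertion site outside host mesh")
  cent <- list(); vol <- list(); kvec <- list(); faces <- list()
  seg_cells <- list()
  # endpoint cell bookkeeping per graph node: list of (cell, dx, area, seg)
  node_pts <- stats::setNames(vector("list", nrow(spec$nodes)), spec$nodes$id)
  offset <- n_host
  nd <- spec$nodes
  for (si in seq_len(nrow(spec$segments))) {
    sg <- lapply(spec$segments[si, ], unname)
    p0 <- unname(unlist(nd[nd$id == sg$from, c("x", "y", "z")]))
    p1 <- unname(unlist(nd[nd$id == sg$to, c("x", "y", "z")]))
    len <- sqrt(sum((p1 - p0)^2))
    nc <- sg$n_cells
    dx <- len / nc
    tt <- (seq_len(nc) - 0.5) / nc
    cent[[si]] <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                        p0[2] + tt * (p1[2] - p0[2]),
                        p0[3] + tt * (p1[3] - p0[3]))
    vol[[si]] <- rep(sg$area * dx, nc)
    kvec[[si]] <- rep(sg$m, nc)
    ids <- offset + seq_len(nc)
    seg_cells[[sg$name]] <- ids
    dirv <- (p1 - p0) / len
    if (nc > 1)
      faces[[length(faces) + 1]] <- data.frame(
        i = ids[-nc], j = ids[-1], area = sg$area, dist = dx,
        nx = dirv[1], ny = dirv[2], nz = dirv[3], label = sg$name)
    node_pts[[sg$from]] <- c(node_pts[[sg$from]],
                             list(list(cell = ids[1], dx = dx,
                                       area = sg$area, seg = sg$name)))
    node_pts[[sg$to]] <- c(node_pts[[sg$to]],
                           list(list(cell = ids[nc], dx = dx,
                                     area = sg$area, seg = sg$name)))
    offset <- offset + nc
  }
  # junction faces: clique over endpoints meeting at each graph node
  for (pts in node_pts) {
    if (length(pts) < 2) next
    for (a in seq_len(length(pts) - 1)) for (b in (a + 1):length(pts)) {
      pa <- pts[[a]]; pb <- pts[[b]]
      faces[[length(faces) + 1]] <- data.frame(
        i = pa$cell, j = pb$cell, area = min(pa$area, pb$area),
        dist = (pa$dx + pb$dx) / 2, nx = 1, ny = 0, nz = 0,
        label = pb$seg)
    }
  }
  # insertion faces into the host myocardium
  if (nrow(spec$insertions)) {
    hs <- if (is.finite(host$spacing)) host$spacing else
      mean(host$faces$dist)
    for (r in seq_len(nrow(spec$insertions))) {
      tgt <- spec$insertions$cell[r]
      ar <- if (!is.null(spec$insertions$area))
        spec$insertions$area[r] else NA
      for (pt in node_pts[[spec$insertions$node[r]]]) {
        faces[[length(faces) + 1]] <- data.frame(
          i = pt$cell, j = tgt, area = if (is.na(ar)) pt$area else ar,
          dist = (pt$dx + hs) / 2, nx = 1, ny = 0, nz = 0,
          label = pt$seg)
      }
    }
  }
  net_cent <- do.call(rbind, cent)
  net_vol <- unlist(vol)
  net_k <- unlist(kvec)
  n_net <- length(net_vol)
  if (is.null(host)) {
    all_cent <- net_cent; all_vol <- net_vol
    region <- rep("network", n_net)
    M <- iso_tensors(net_k)
  } else {
    all_cent <- rbind(host$centroids, net_cent)
    all_vol <- c(host$volume, net_vol)
    region <- c(host$region, rep("network", n_net))
    Mh <- if (is.array(host_conductivity) && length(dim(host_conductivity)) == 3)
      host_conductivity else iso_tensors(host_conductivity, n_host)
    M <- array(0, c(n_host + n_net, 3, 3))
    M[seq_len(n_host), , ] <- Mh
    M[n_host + seq_len(n_net), , ] <- iso_tensors(net_k)
  }
  # network faces use the cells' isotropic conductivity regardless of the
  # nominal normal direction stored above
  fc <- do.call(rbind, faces)
  if (!is.null(host)) fc <- rbind(transform(host$faces,
                                            label = host$faces$label), fc)
  mesh <- tissue_mesh(all_cent, all_vol, fc, region = region,
                      dim = max(1L, if (is.null(host)) 1L else host$dim))
  first_seg <- spec$segments$name[1]
  structure(list(mesh = mesh, conductivity = M,
                 cells = c(seg_cells, list(host = seq_len(n_host))),
                 sa_cell = seg_cells[[first_seg]][1]),
            class = "conduction_system")
}

#' Calibrate the AV-node conductivity for a target transit delay
#'
#' Bisects the conductivity of the segment named `"av"` until the
#' activation-time difference between the cells immediately upstream and
#' downstream of the AV segment matches `target_ms`.
#'
#' @param target_ms Target AV transit delay (ms). Default 100.
#' @param model Ionic model used on the network.
#' @param chi_cm Calibration constant (uF/mm^3).
#' @param dt Time step (ms).
#' @param bounds Conductivity bracket (mS/mm).
#' @param tol Relative delay tolerance. Default 0.02.
#' @param max_iter Bisection cap.
#' @return List with `m_av`, `delay`, `iterations`.
#' @export
calibrate_av_delay <- function(target_ms = 100, model = ionic_model("atrial"),
                               chi_cm = 0.64, dt = 0.05,
                               bounds = c(0.005, 0.1), tol = 0.02,
                               max_iter = 40) {
  delay_of <- function(m_av) {
    cs <- build_conduction_system(default_conduction_spec(m_av = m_av))
    sys <- ep_system(cs$mesh, model, cs$conductivity, chi_cm = chi_cm, dt = dt)
    stim <- stimulus_protocol(list(list(
      cells = cs$cells$internodal[1:5], onset = 0, duration = 2,
      amplitude = stim_amplitude(model, chi_cm))))
    res <- run_ep(sys, stim, t_end = 60 + 6 * target_ms,
                  stop_when_activated = TRUE)
    a <- res$activation$times
    pre <- a[utils::tail(cs$cells$internodal, 1)]
    post <- a[cs$cells$his[1]]
    if (is.na(pre) || is.na(post)) return(NA_real_)
    post - pre
  }
  lo <- bounds[1]; hi <- bounds[2]
  d_lo <- delay_of(lo); d_hi <- delay_of(hi)
  if (is.na(d_lo)) d_lo <- Inf   # conduction block: infinite delay
  if (!(d_lo > target_ms && d_hi < target_ms))
    stop("target delay not bracketed by bounds")
  dly <- NA_real_; mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    dly <- delay_of(mid)
    if (is.na(dly)) { lo <- mid; next }
    if (abs(dly - target_ms) / target_ms < tol) break
    if (dly > target_ms) lo <- mid else hi <- mid
  }
  list(m_av = mid, delay = dly, iterations = it)
}

#' Intact / LBBB / CRT activation study on a two-ventricle sheet
#'
#' Desk-scale analogue of bundle-branch block and resynchronization: a 2D
#' myocardial sheet (left half labelled LV, right half RV) is activated
#' through the conduction tree.  Three runs share one geometry: intact
#' conduction; left-branch block (LBBB); LBBB plus a left-ventricular
#' pacing lead that fires when the right insertion activates (CRT, only
#' the LV lead issues triggering signals).  The activation-spread duration
#' (last minus first myocardial activation) orders as
#' intact < CRT < LBBB.
#'
#' @param lx,ly,dx Sheet geometry (mm). Defaults 24 x 16 at 0.8 mm.
#' @param m_myo Isotropic myocardial conductivity (mS/mm); default the
#'   per-axis harmonic mean of the ventricular longitudinal bidomain row.
#' @param chi_cm Calibration constant. Default 0.64.
#' @param dt Time step (ms). Default 0.1.
#' @param model Ionic model. Default atrial surrogate (one model spans the
#'   composite mesh).
#' @param crt_delay_ms LV-lead delay after the right insertion activates.
#'   Default 5.
#' @return List with `duration` (named: intact, lbbb, crt), activation
#'   maps, and the insertion cells.
#' @export
lbbb_crt_study <- function(lx = 24, ly = 16, dx = 0.8,
                           m_myo = 0.17 * 0.62 / (0.17 + 0.62),
                           chi_cm = 0.64, dt = 0.1,
                           model = ionic_model("atrial"),
                           crt_delay_ms = 5) {
  host <- mesh_sheet(lx, ly, dx)
  host$region <- ifelse(host$centroids[, 1] < lx / 2, "LV", "RV")
  pick <- function(x, y)
    order((host$centroids[, 1] - x)^2 + (host$centroids[, 2] - y)^2)[1:5]
  ins_l <- pick(lx / 4, ly / 2)
  ins_r <- pick(3 * lx / 4, ly / 2)
  spec <- default_conduction_spec(insert_left = ins_l, insert_right = ins_r)
  cs <- build_conduction_system(spec, host = host,
                                host_conductivity = m_myo)
  myo <- cs$cells$host
  sa_stim <- list(cells = cs$cells$internodal[1:5], onset = 0, duration = 2,
                  amplitude = stim_amplitude(model, chi_cm))
  run_one <- function(blocks, extra_stim = list(), t_end = 600) {
    sys <- ep_system(cs$mesh, model, cs$conductivity, chi_cm = chi_cm,
                     dt = dt, blocks = blocks)
    prot <- stimulus_protocol(c(list(sa_stim), extra_stim))
    res <- run_ep(sys, prot, t_end = t_end, stop_when_activated = TRUE)
    res$activation
  }
  act_intact <- run_one(character(0))
  act_lbbb <- run_one("left_branch")
  t_right <- min(act_lbbb$times[ins_r])
  lv_lead <- list(cells = ins_l, onset = t_right + crt_delay_ms,
                  duration = 2, amplitude = stim_amplitude(model, chi_cm))
  if (is.na(t_right)) stop("right insertion failed to activate under LBBB")
  act_crt <- run_one("left_branch", list(lv_lead))
  dur <- c(intact = measure_intervals(act_intact, cells = myo),
           lbbb = measure_intervals(act_lbbb, cells = myo),
           crt = measure_intervals(act_crt, cells = myo))
  list(duration = dur, activation = list(intact = act_intact,
                                         lbbb = act_lbbb, crt = act_crt),
       insertions = c(left = ins_l, right = ins_r))
}
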