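# Spring-network structural solver with Fung orthotropic strain energy.
#
# Elements are linear segments (2 nodes), triangles (3 nodes, membranes)
# or tetrahedra (4 nodes, myocardium).  Each element stores its rest
# metric; internal forces are the exact negative gradient of the assembled
# Fung energy, so the discrete model is energetically consistent with the
# constitutive law.  Units: positions m, masses kg, forces N; Fung c is
# given in kPa and converted to Pa internally.

#' Fung orthotropic material
#'
#' Strain energy density `W = c/2 (exp(Q) - 1)` with
#' `Q = a_par e_par^2 + a_sheet e_sheet^2 + a_normal e_normal^2` in the
#' Green strains along the fiber/sheet/sheet-normal axes.
#'
#' @param c Stress scale, kPa (> 0).
#' @param a_par,a_sheet,a_normal Dimensionless exponents (>= 0).
#' @return Object of class `fung_material`.
#' @export
fung_material <- function(c, a_par, a_sheet = a_par, a_normal = a_sheet) {
  stopifnot(c > 0, a_par >= 0, a_sheet >= 0, a_normal >= 0)
  structure(list(c = c, a = c(a_par, a_sheet, a_normal)),
            class = "fung_material")
}

#' Fung strain-energy density
#'
#' @param strains Green strain components `c(e_par, e_sheet, e_normal)`
#'   (2D membranes: the third component is ignored when `NA`).  Each must
#'   be >= -0.5 (the physical lower bound of a Green strain).
#' @param mat A `fung_material`.
#' @return Energy density, kPa; zero iff all strains are zero.
#' @export
fung_energy <- function(strains, mat) {
  e <- strains
  use <- !is.na(e)
  if (any(e[use] < -0.5)) stop("Green strain below physical bound -0.5")
  Q <- sum(mat$a[use] * e[use]^2)
  if (Q > 700) stop("Fung exponent overflow: nonphysical strain state")
  mat$c / 2 * (exp(Q) - 1)
}

#' Build a spring network
#'
#' @param nodes n x 3 matrix of positions (m).
#' @param mass Per-node lumped mass (kg), > 0.
#' @param elements List of elements, each
#'   `list(nodes = <2/3/4 indices>, region = <material key>, fiber = ...)`:
#'   for tetrahedra `fiber` is a 3x3 matrix whose rows are the fiber,
#'   sheet and sheet-normal axes in the rest configuration (defaults to
#'   the identity triad); for triangles a 3-vector in-plane fiber axis
#'   (default: first rest edge); segments need none.
#' @param thickness Membrane thickness (m) used by triangle elements.
#' @param cross_section Cross-section (m^2) used by segment elements.
#' @param wet_nodes Optional indices of wet-surface nodes.
#' @return Object of class `spring_network` with precomputed rest metrics.
#' @export
spring_network <- function(nodes, mass, elements, thickness = 1e-3,
                           cross_section = 1e-6, wet_nodes = integer(0)) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3, all(mass > 0), length(mass) == nrow(nodes))
  els <- lapply(elements, function(el) {
    idx <- el$nodes
    x <- nodes[idx, , drop = FALSE]
    el$region <- if (is.null(el$region)) "tissue" else el$region
    if (length(idx) == 4) {
      Dm <- t(x[2:4, ]) - x[1, ]
      vol <- det(Dm) / 6
      if (vol <= 0) stop("degenerate or inverted rest tetrahedron")
      el$Binv <- solve(Dm)
      el$measure <- vol
      if (is.null(el$fiber)) el$fiber <- diag(3)
      el$type <- "tet"
    } else if (length(idx) == 3) {
      e1 <- x[2, ] - x[1, ]; e2 <- x[3, ] - x[1, ]
      nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
               e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1])
      a2 <- sqrt(sum(nrm^2))
      if (a2 <= 0) stop("degenerate rest triangle")
      t1 <- e1 / sqrt(sum(e1^2))
      nn <- nrm / a2
      t2 <- c(nn[2] * t1[3] - nn[3] * t1[2],
              nn[3] * t1[1] - nn[1] * t1[3],
              nn[1] * t1[2] - nn[2] * t1[1])
      Dm <- cbind(c(sum(e1 * t1), sum(e1 * t2)), c(sum(e2 * t1), sum(e2 * t2)))
      el$Binv <- solve(Dm)
      el$measure <- a2 / 2
      f3 <- if (is.null(el$fiber)) e1 else el$fiber
      f2d <- c(sum(f3 * t1), sum(f3 * t2))
      f2d <- f2d / sqrt(sum(f2d^2))
      el$fiber2d <- f2d
      el$sheet2d <- c(-f2d[2], f2d[1])
      el$type <- "tri"
    } else if (length(idx) == 2) {
      L0 <- sqrt(sum((x[2, ] - x[1, ])^2))
      if (L0 <= 0) stop("degenerate rest segment")
      el$L0 <- L0
      el$measure <- L0
      el$type <- "seg"
    } else stop("elements must have 2, 3 or 4 nodes")
    el
  })
  net <- structure(list(nodes = nodes, mass = as.numeric(mass),
                        elements = els, thickness = thickness,
                        cross_section = cross_section,
                        wet_nodes = wet_nodes, n_nodes = nrow(nodes)),
                   class = "spring_network")
  net$tet_batch <- build_tet_batch(els)
  net
}

# stacked arrays for vectorized tetrahedral force assembly; matrices are
# stored column-major as n x 9
build_tet_batch <- function(els) {
  keep <- vapply(els, function(e) e$type == "tet", TRUE)
  if (!any(keep)) return(NULL)
  tl <- els[keep]
  ne <- length(tl)
  idx <- t(vapply(tl, function(e) as.integer(e$nodes), integer(4)))
  Binv <- t(vapply(tl, function(e) as.numeric(e$Binv), numeric(9)))
  vol <- vapply(tl, function(e) e$measure, 0)
  dirs <- t(vapply(tl, function(e) as.numeric(t(e$fiber)), numeric(9)))
  # dirs[, j + 3*(d-1)] = component j of material direction d
  list(which = which(keep), idx = idx, Binv = Binv, vol = vol, dirs = dirs,
       region = vapply(tl, function(e) e$region, ""))
}

# batch kinematics for all tets: deformation gradient (n x 9), pushed
# material directions Fa (list of n x 3), strains (n x 3), det(F)
tet_kinematics_batch <- function(tb, pos) {
  ne <- nrow(tb$idx)
  Ds <- matrix(0, ne, 9)
  for (k in 1:3) for (i in 1:3)
    Ds[, i + 3 * (k - 1)] <- pos[tb$idx[, k + 1], i] - pos[tb$idx[, 1], i]
  F <- matrix(0, ne, 9)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3)
      acc <- acc + Ds[, i + 3 * (k - 1)] * tb$Binv[, k + 3 * (j - 1)]
    F[, i + 3 * (j - 1)] <- acc
  }
  detF <- F[, 1] * (F[, 5] * F[, 9] - F[, 8] * F[, 6]) -
          F[, 4] * (F[, 2] * F[, 9] - F[, 8] * F[, 3]) +
          F[, 7] * (F[, 2] * F[, 6] - F[, 5] * F[, 3])
  Fa <- vector("list", 3)
  strains <- matrix(0, ne, 3)
  for (d in 1:3) {
    M <- matrix(0, ne, 3)
    for (i in 1:3) {
      acc <- 0
      for (j in 1:3)
        acc <- acc + F[, i + 3 * (j - 1)] * tb$dirs[, j + 3 * (d - 1)]
      M[, i] <- acc
    }
    Fa[[d]] <- M
    strains[, d] <- (rowSums(M^2) - 1) / 2
  }
  list(F = F, detF = detF, Fa = Fa, strains = strains)
}

# per-element material constants (c in Pa, exponents n x 3)
tet_material_constants <- function(tb, materials) {
  regs <- unique(tb$region)
  cPa <- numeric(length(tb$region))
  a <- matrix(0, length(tb$region), 3)
  for (r in regs) {
    mat <- materials[[r]]
    if (is.null(mat)) stop("no material for region ", r)
    sel <- tb$region == r
    cPa[sel] <- 1e3 * mat$c
    a[sel, ] <- matrix(mat$a, sum(sel), 3, byrow = TRUE)
  }
  list(cPa = cPa, a = a)
}

# scatter per-element nodal force blocks G (list by node slot) to nodes
tet_scatter <- function(tb, G_slots, n_nodes) {
  contrib <- do.call(rbind, G_slots)
  group <- as.vector(tb$idx)
  out <- rowsum(contrib, group)
  f <- matrix(0, n_nodes, 3)
  f[as.integer(rownames(out)), ] <- out
  f
}

# vectorized tet forces; Ta = NULL for passive-only, or per-element kPa
tet_forces_batch <- function(net, materials, pos, Ta = NULL,
                             passive = TRUE) {
  tb <- net$tet_batch
  kin <- tet_kinematics_batch(tb, pos)
  if (any(kin$detF <= 0)) stop("inverted element (negative Jacobian)")
  ne <- nrow(tb$idx)
  P <- matrix(0, ne, 9)
  if (passive) {
    mc <- tet_material_constants(tb, materials)
    Q <- rowSums(mc$a * kin$strains^2)
    if (any(Q > 700)) stop("Fung exponent overflow: nonphysical strain state")
    expQ <- exp(Q)
    for (d in 1:3) {
      coef <- mc$cPa * expQ * mc$a[, d] * kin$strains[, d]
      for (i in 1:3) for (j in 1:3)
        P[, i + 3 * (j - 1)] <- P[, i + 3 * (j - 1)] +
          coef * kin$Fa[[d]][, i] * tb$dirs[, j + 3 * (d - 1)]
    }
  }
  if (!is.null(Ta)) {
    TaPa <- 1e3 * Ta
    nrmFa <- sqrt(rowSums(kin$Fa[[1]]^2))
    coef <- TaPa / nrmFa
    for (i in 1:3) for (j in 1:3)
      P[, i + 3 * (j - 1)] <- P[, i + 3 * (j - 1)] +
        coef * kin$Fa[[1]][, i] * tb$dirs[, j]
  }
  # G = vol * P %*% t(Binv); node j+1 force = -G[, j], node 1 = +sum
  G <- vector("list", 3)
  for (j in 1:3) {
    Gj <- matrix(0, ne, 3)
    for (i in 1:3) {
      acc <- 0
      for (k in 1:3)
        acc <- acc + P[, i + 3 * (k - 1)] * tb$Binv[, j + 3 * (k - 1)]
      Gj[, i] <- tb$vol * acc
    }
    G[[j]] <- Gj
  }
  slots <- list(G[[1]] + G[[2]] + G[[3]], -G[[1]], -G[[2]], -G[[3]])
  tet_scatter(tb, slots, net$n_nodes)
}

#' @export
print.spring_network <- function(x, ...) {
  ty <- table(vapply(x$elements, `[[`, "", "type"))
  cat(sprintf("<spring_network> %d nodes, elements: %s\n", x$n_nodes,
              paste(names(ty), ty, sep = "=", collapse = ", ")))
  invisible(x)
}

# deformation gradient and fiber-frame Green strains for one element
element_kinematics <- function(net, el, pos) {
  x <- pos[el$nodes, , drop = FALSE]
  if (el$type == "tet") {
    Ds <- t(x[2:4, ]) - x[1, ]
    F <- Ds %*% el$Binv
    if (det(F) <= 0) stop("inverted element (negative Jacobian)")
    a <- el$fiber
    e <- c(sum((F %*% a[1, ])^2), sum((F %*% a[2, ])^2),
           sum((F %*% a[3, ])^2)) / 2 - 0.5
    list(F = F, strains = e, dirs = a)
  } else if (el$type == "tri") {
    Ds <- cbind(x[2, ] - x[1, ], x[3, ] - x[1, ])
    F <- Ds %*% el$Binv             # 3 x 2
    a <- rbind(el$fiber2d, el$sheet2d)
    e <- c(sum((F %*% a[1, ])^2), sum((F %*% a[2, ])^2)) / 2 - 0.5
    list(F = F, strains = c(e, NA), dirs = a)
  } else {
    d <- x[2, ] - x[1, ]
    l <- sqrt(sum(d^2))
    lam <- l / el$L0
    list(F = lam, strains = c((lam^2 - 1) / 2, NA, NA), dir3 = d / l, l = l)
  }
}

#' Green strains of one element in its fiber frame
#'
#' `E = (F'F - I)/2` from the element deformation gradient; returned
#' components are `e_i' E e_i` along the material fiber/sheet/normal axes
#' (membranes: normal component `NA`; segments: only the fiber component).
#'
#' @param net A `spring_network`.
#' @param element Element index.
#' @param positions Current node positions (defaults to rest).
#' @return Numeric triple `c(par, sheet, normal)`.
#' @export
green_strains <- function(net, element, positions = net$nodes) {
  element_kinematics(net, net$elements[[element]], as.matrix(positions))$strains
}

element_volume_scale <- function(net, el) {
  switch(el$type,
         tet = el$measure,
         tri = el$measure * net$thickness,
         seg = el$measure * net$cross_section)
}

#' Total Fung strain energy of the network
#'
#' @param net A `spring_network`.
#' @param materials Named list mapping element regions to `fung_material`s.
#' @param positions Current node positions.
#' @return Energy, J.
#' @export
total_energy <- function(net, materials, positions = net$nodes) {
  W <- 0
  for (el in net$elements) {
    kin <- element_kinematics(net, el, as.matrix(positions))
    mat <- materials[[el$region]]
    if (is.null(mat)) stop("no material for region ", el$region)
    W <- W + 1e3 * fung_energy(kin$strains, mat) * element_volume_scale(net, el)
  }
  W
}

#' Internal passive forces
#'
#' Exact negative gradient of the assembled Fung energy with respect to the
#' node positions: `F_int = -d(sum_el W_e V_rest)/dx`.
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces (N).
#' @export
internal_forces <- function(net, materials, positions = net$nodes) {
  pos <- as.matrix(positions)
  f <- matrix(0, net$n_nodes, 3)
  if (!is.null(net$tet_batch))
    f <- f + tet_forces_batch(net, materials, pos)
  for (el in net$elements) {
    if (el$type == "tet") next   # handled by the vectorized batch
    mat <- materials[[el$region]]
    if (is.null(mat)) stop("no material for region ", el$region)
    kin <- element_kinematics(net, el, pos)
    scale <- element_volume_scale(net, el)
    cPa <- 1e3 * mat$c
    if (el$type == "seg") {
      e <- kin$strains[1]
      dWde <- cPa * mat$a[1] * e * exp(mat$a[1] * e^2)
      # dE/dl = l / L0^2 ; force pair along current axis
      fmag <- scale * dWde * kin$l / el$L0^2
      f[el$nodes[1], ] <- f[el$nodes[1], ] + fmag * kin$dir3
      f[el$nodes[2], ] <- f[el$nodes[2], ] - fmag * kin$dir3
      next
    }
    e <- kin$strains[!is.na(kin$strains)]
    nk <- length(e)
    Q <- sum(mat$a[1:nk] * e^2)
    if (Q > 700) stop("Fung exponent overflow: nonphysical strain state")
    expQ <- exp(Q)
    # P = dW/dF = c e^Q sum_i a_i e_i (F a_i) a_i'
    P <- 0
    for (i in seq_len(nk)) {
      Fa <- kin$F %*% kin$dirs[i, ]
      P <- P + cPa * expQ * mat$a[i] * e[i] * (Fa %*% t(kin$dirs[i, ]))
    }
    G <- scale * P %*% t(el$Binv)     # d(energy)/d(Ds)
    idx <- el$nodes
    f[idx[1], ] <- f[idx[1], ] + colSums(t(G))
    for (j in seq_len(ncol(G)))
      f[idx[j + 1], ] <- f[idx[j + 1], ] - G[, j]
  }
  f
}

#' Active contractile forces
#'
#' Each element contributes the nodal forces of a uniaxial tension `Ta`
#' along its current fiber direction (first Piola stress
#' `Ta (F a)(a)'/|F a|`, i.e. a Cauchy tension along the deformed fiber),
#' using the rest-configuration cross-section convention.  Net force and
#' net torque vanish per element by construction.
#'
#' @param net A `spring_network`.
#' @param Ta Per-element active tension, kPa (>= 0).
#' @param positions Current node positions.
#' @return n x 3 matrix of forces (N).
#' @export
active_forces <- function(net, Ta, positions = net$nodes) {
  Ta <- rep_len(Ta, length(net$elements))
  if (any(Ta < 0)) stop("active tension must be non-negative")
  pos <- as.matrix(positions)
  f <- matrix(0, net$n_nodes, 3)
  if (!is.null(net$tet_batch))
    f <- f + tet_forces_batch(net, NULL, pos,
                              Ta = Ta[net$tet_batch$which],
                              passive = FALSE)
  for (k in seq_along(net$elements)) {
    if (Ta[k] == 0 || net$elements[[k]]$type == "tet") next
    el <- net$elements[[k]]
    kin <- element_kinematics(net, el, pos)
    scale <- element_volume_scale(net, el)
    TaPa <- 1e3 * Ta[k]
    if (el$type == "seg") {
      fmag <- TaPa * net$cross_section
      f[el$nodes[1], ] <- f[el$nodes[1], ] + fmag * kin$dir3
      f[el$nodes[2], ] <- f[el$nodes[2], ] - fmag * kin$dir3
      next
    }
    a1 <- kin$dirs[1, ]
    Fa <- kin$F %*% a1
    P <- TaPa / sqrt(sum(Fa^2)) * (Fa %*% t(a1))
    G <- scale * P %*% t(el$Binv)
    idx <- el$nodes
    f[idx[1], ] <- f[idx[1], ] + colSums(t(G))
    for (j in seq_len(ncol(G)))
      f[idx[j + 1], ] <- f[idx[j + 1], ] - G[, j]
  }
  f
}

#' Advance the structural dynamics one step
#'
#' Per-node Newton equation `m_n d2x/dt2 = F_ext + F_int + F_act` advanced
#' with a two-step Adams-Bashforth update of velocity then position
#' (forward Euler on the first step), with optional linear velocity
#' damping.
#'
#' @param state List with `x` (positions), `v` (velocities), and
#'   optionally `a_prev`, `v_prev` from the previous step.
#' @param mass Per-node mass (kg).
#' @param force Total nodal force, n x 3 (N).
#' @param dt Time step (s).
#' @param damping Linear damping coefficient (kg/s). Default 0.
#' @return Updated state.
#' @export
advance_structure <- function(state, mass, force, dt, damping = 0) {
  stopifnot(dt > 0)
  if (!all(is.finite(force))) stop("non-finite force input")
  a <- force / mass - (damping / mass) * state$v
  if (is.null(state$a_prev)) {
    v_new <- state$v + dt * a
    x_new <- state$x + dt * state$v
  } else {
    v_new <- state$v + dt * (1.5 * a - 0.5 * state$a_prev)
    x_new <- state$x + dt * (1.5 * state$v - 0.5 * state$v_prev)
  }
  list(x = x_new, v = v_new, a_prev = a, v_prev = state$v)
}

#' Quasi-static uniaxial stress-strain response
#'
#' Stress `dW/de` along one material axis with the other strains free
#' (for the quadratic-exponent Fung law the free lateral strains relax to
#' zero, so `sigma = c a e exp(a e^2)`).
#'
#' @param mat A `fung_material`.
#' @param stretch Vector of stretch ratios (>= 1).
#' @param axis 1 = fiber, 2 = sheet, 3 = sheet-normal.
#' @return data.frame(stretch, strain, stress_kPa).
#' @export
uniaxial_response <- function(mat, stretch = seq(1, 1.2, by = 0.01),
                              axis = 1) {
  stopifnot(all(stretch >= 1))
  e <- (stretch^2 - 1) / 2
  a <- mat$a[axis]
  data.frame(stretch = stretch, strain = e,
             stress_kPa = mat$c * a * e * exp(a * e^2))
}
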