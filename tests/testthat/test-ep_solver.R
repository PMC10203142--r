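# Finite-volume monodomain/bidomain solver.

test_that("conductivity tensors assemble from fiber triads", {
  mesh <- mesh_cable(2, 0.5)
  fr <- fiber_frames(mesh, "uniform")
  M <- assemble_conductivity(fr, conductivity_set(1, 1, 1))
  expect_equal(M[1, , ], diag(3))
  # ventricular intracellular row, axis-aligned frame
  Mi <- assemble_conductivity(fr, conductivity_set(0.17, 0.019, 0.019))
  expect_equal(Mi[2, , ], diag(c(0.17, 0.019, 0.019)))
  # rotated frame: same eigenvalues (eigendecomposition oracle)
  a <- 0.73
  frr <- fiber_frame(matrix(c(cos(a), sin(a), 0), 4, 3, byrow = TRUE),
                     matrix(c(-sin(a), cos(a), 0), 4, 3, byrow = TRUE),
                     matrix(c(0, 0, 1), 4, 3, byrow = TRUE))
  Mr <- assemble_conductivity(frr, conductivity_set(0.17, 0.019, 0.019))
  expect_equal(sort(eigen(Mr[1, , ])$values), sort(c(0.17, 0.019, 0.019)),
               tolerance = 1e-12)
  expect_equal(Mr[1, , ], t(Mr[1, , ]))   # symmetric
  bad <- fr; bad$e_fiber[1, ] <- c(2, 0, 0)
  expect_error(assemble_conductivity(bad, conductivity_set(1)),
               "orthonormal")
})

test_that("monodomain reduction scales the intracellular tensor", {
  M <- diag(c(0.17, 0.019, 0.019))
  expect_equal(monodomain_equivalent(M, 1), diag(c(0.085, 0.0095, 0.0095)))
  expect_equal(monodomain_equivalent(M, 1e9), M, tolerance = 1e-8)
  expect_error(monodomain_equivalent(M, 0), "lambda")
  # Purkinje row ships the already-reduced scalar: pass-through
  expect_equal(registry_lookup("conductivity", "purkinje")$m_mono, 3.95)
})

test_that("uniform field evolves exactly like the single-cell ODE", {
  mesh <- mesh_cable(5, 0.25)
  model <- ionic_model("ventricular")
  sys <- ep_system(mesh, model, conductivity = 0.5, chi_cm = 1, dt = 0.02)
  st <- ep_rest_state(sys)
  st$v <- rep(-30, mesh$n_cells)   # uniform, off-rest
  v1 <- st$v[1]; s1 <- lapply(st$s, `[`, 1)
  for (k in 1:50) {
    st <- step_ep(sys, st)
    cell <- cardiosim:::step_cell_vec(model, v1, s1, 0.02, 0)
    v1 <- cell$v; s1 <- cell$s
  }
  expect_equal(max(abs(st$v - v1)), 0, tolerance = 1e-10)
  expect_lt(diff(range(st$v)), 1e-12)   # stays spatially uniform
})

test_that("diffusion conserves the total charge with zero reaction", {
  mesh <- mesh_sheet(4, 4, 0.5)
  sys <- ep_system(mesh, null_reaction_model(), conductivity = 0.3,
                   chi_cm = 2, dt = 0.1)
  st <- ep_rest_state(sys)
  set.seed(7)
  st$v <- runif(mesh$n_cells)
  q0 <- sum(2 * mesh$volume * st$v)
  for (k in 1:50) {
    st <- step_ep(sys, st)
    q <- sum(2 * mesh$volume * st$v)
    expect_lt(abs(q - q0) / abs(q0), 1e-10)
  }
})

test_that("Gaussian variance grows as 2 (m / chi Cm) t (heat kernel)", {
  mesh <- mesh_cable(20, 0.1)
  m <- 0.1414; chi_cm <- 1
  sys <- ep_system(mesh, null_reaction_model(), conductivity = m,
                   chi_cm = chi_cm, dt = 0.05)
  st <- ep_rest_state(sys)
  x <- mesh$centroids[, 1]
  st$v <- exp(-(x - 10)^2 / (2 * 1^2))
  varx <- function(v) {
    w <- v / sum(v); mu <- sum(w * x); sum(w * (x - mu)^2)
  }
  v0 <- varx(st$v)
  Tend <- 10
  for (k in seq_len(Tend / 0.05)) st <- step_ep(sys, st)
  growth <- varx(st$v) - v0
  expect_equal(growth, 2 * (m / chi_cm) * Tend, tolerance = 0.02)
})

test_that("conduction velocity scales as sqrt(m)", {
  model <- ionic_model("atrial")
  cv1 <- cable_cv(0.14, chi_cm = 0.64, model = model)
  cv2 <- cable_cv(0.14 / 4, chi_cm = 0.64, model = model)
  expect_equal(cv2 / cv1, 0.5, tolerance = 0.03)
  # fit exponent over a decade
  ms <- 0.14 * c(1, 2.15, 4.64, 10)
  cvs <- vapply(ms, function(m) cable_cv(m, chi_cm = 0.64, model = model), 0)
  expo <- stats::coef(stats::lm(log(cvs) ~ log(ms)))[2]
  expect_equal(unname(expo), 0.5, tolerance = 0.02)
})

test_that("bidomain reduces to monodomain for proportional tensors", {
  mesh <- mesh_cable(20, 0.1)
  model <- ionic_model("atrial")
  lam <- 2; m_i <- 0.3; chi_cm <- 0.64
  fr <- fiber_frames(mesh, "uniform")
  Mi <- assemble_conductivity(fr, conductivity_set(m_i, m_i, m_i))
  stim_cells <- which(mesh$centroids[, 1] < 1)
  prot <- stimulus_protocol(list(list(
    cells = stim_cells, onset = 0, duration = 2,
    amplitude = cardiosim:::stim_amplitude(model, chi_cm))))
  cv_of <- function(sys) {
    res <- run_ep(sys, prot, t_end = 120, stop_when_activated = TRUE)
    measure_cv(res$activation, window = c(5, 15))
  }
  cv_bi <- cv_of(ep_system(mesh, model, list(int = Mi, ext = lam * Mi),
                           chi_cm = chi_cm, mode = "bidomain", dt = 0.05))
  cv_mono <- cv_of(ep_system(mesh, model, monodomain_equivalent(Mi, lam),
                             chi_cm = chi_cm, dt = 0.05))
  expect_equal(cv_bi, cv_mono, tolerance = 0.01)
})

test_that("1D bidomain CV equals harmonic-mean monodomain CV", {
  mesh <- mesh_cable(20, 0.1)
  model <- ionic_model("atrial")
  chi_cm <- 0.64
  fr <- fiber_frames(mesh, "uniform")
  # atrial longitudinal components: NOT proportional across axes
  Mi <- assemble_conductivity(fr, conductivity_set(0.18, 0.02, 0.02))
  Me <- assemble_conductivity(fr, conductivity_set(0.66, 0.25, 0.25))
  prot <- stimulus_protocol(list(list(
    cells = which(mesh$centroids[, 1] < 1), onset = 0, duration = 2,
    amplitude = cardiosim:::stim_amplitude(model, chi_cm))))
  res_bi <- run_ep(ep_system(mesh, model, list(int = Mi, ext = Me),
                             chi_cm = chi_cm, mode = "bidomain", dt = 0.05),
                   prot, t_end = 120, stop_when_activated = TRUE)
  m_harm <- 0.18 * 0.66 / (0.18 + 0.66)
  res_mono <- run_ep(ep_system(mesh, model, m_harm, chi_cm = chi_cm,
                               dt = 0.05),
                     prot, t_end = 120, stop_when_activated = TRUE)
  cv_bi <- measure_cv(res_bi$activation, window = c(5, 15))
  cv_mono <- measure_cv(res_mono$activation, window = c(5, 15))
  expect_equal(cv_bi, cv_mono, tolerance = 0.01)
})

test_that("measure_cv: plane wave, degenerate cases", {
  mesh <- mesh_cable(10, 0.5)
  map <- activation_map(mesh$centroids[, 1], mesh)   # t = x -> 1 mm/ms
  expect_equal(measure_cv(map), 1)
  expect_error(measure_cv(activation_map(rep(3, mesh$n_cells), mesh)),
               "simultaneously")
  expect_error(measure_cv(activation_map(rep(NA_real_, mesh$n_cells), mesh)),
               "activated")
})

test_that("protocol evaluation honours windows, emptiness, lead delays", {
  expect_equal(apply_protocol(NULL, 5, 10), rep(0, 10))
  expect_equal(apply_protocol(stimulus_protocol(), 5, 10), rep(0, 10))
  p <- stimulus_protocol(list(list(cells = 2:3, onset = 0, duration = 2,
                                   amplitude = 4)))
  expect_equal(apply_protocol(p, -1, 4), rep(0, 4))
  expect_equal(apply_protocol(p, 1.9, 4), c(0, 4, 4, 0))
  expect_equal(apply_protocol(p, 2, 4), rep(0, 4))
  expect_error(stimulus_protocol(list(list(cells = 1, onset = -1,
                                           duration = 1, amplitude = 1))))
  # two pacing leads, 0 and 50 ms: activation onsets differ by 50 +- dt
  mesh <- mesh_cable(20, 0.1)
  model <- ionic_model("atrial")
  amp <- cardiosim:::stim_amplitude(model, 0.64)
  left <- which(mesh$centroids[, 1] < 1)
  right <- which(mesh$centroids[, 1] > 19)
  prot <- stimulus_protocol(list(
    list(cells = left, onset = 0, duration = 2, amplitude = amp),
    list(cells = right, onset = 50, duration = 2, amplitude = amp)))
  # slow tissue so the left wave cannot reach the right site first
  sys <- ep_system(mesh, model, 0.04, chi_cm = 0.64, dt = 0.05)
  res <- run_ep(sys, prot, t_end = 80, stop_when_activated = TRUE)
  a <- res$activation$times
  expect_equal(min(a[right]) - min(a[left]), 50, tolerance = 0.1)
})

test_that("activation maps are invariant under mesh relabelling", {
  mesh <- mesh_cable(10, 0.2)
  n <- mesh$n_cells
  set.seed(42)
  perm <- sample(n)                       # new id of old cell i = perm[i]
  inv <- order(perm)
  mesh2 <- tissue_mesh(mesh$centroids[inv, , drop = FALSE],
                       mesh$volume[inv],
                       transform(mesh$faces, i = perm[mesh$faces$i],
                                 j = perm[mesh$faces$j]),
                       region = mesh$region[inv], dim = 1L,
                       spacing = mesh$spacing)
  model <- ionic_model("atrial")
  amp <- cardiosim:::stim_amplitude(model, 0.64)
  stim1 <- which(mesh$centroids[, 1] < 1)
  prot1 <- stimulus_protocol(list(list(cells = stim1, onset = 0,
                                       duration = 2, amplitude = amp)))
  prot2 <- stimulus_protocol(list(list(cells = perm[stim1], onset = 0,
                                       duration = 2, amplitude = amp)))
  a1 <- run_ep(ep_system(mesh, model, 0.5, chi_cm = 0.64, dt = 0.05),
               prot1, t_end = 60, stop_when_activated = TRUE)$activation
  a2 <- run_ep(ep_system(mesh2, model, 0.5, chi_cm = 0.64, dt = 0.05),
               prot2, t_end = 60, stop_when_activated = TRUE)$activation
  expect_equal(a2$times[perm], a1$times, tolerance = 1e-10)
})

test_that("conduction-system blocks stop propagation at the named segment", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 10, 20), y = 0, z = 0)
  segs <- data.frame(name = c("s1", "s2"), from = c("a", "b"),
                     to = c("b", "c"), n_cells = 40, m = 1.29, area = 0.1)
  cs <- build_conduction_system(conduction_spec(nodes, segs))
  model <- ionic_model("atrial")
  amp <- cardiosim:::stim_amplitude(model, 0.64)
  prot <- stimulus_protocol(list(list(cells = cs$cells$s1[1:4], onset = 0,
                                      duration = 2, amplitude = amp)),
                            blocks = "s2")
  sys <- ep_system(cs$mesh, model, cs$conductivity, chi_cm = 0.64,
                   dt = 0.05, blocks = prot$blocks)
  res <- run_ep(sys, prot, t_end = 100)
  a <- res$activation$times
  expect_true(all(!is.na(a[cs$cells$s1])))
  expect_true(all(is.na(a[cs$cells$s2])))
  # dangling node and out-of-mesh insertions are rejected
  expect_error(conduction_spec(rbind(nodes, data.frame(id = "zz", x = 1,
                                                       y = 1, z = 1)), segs),
               "dangling")
  expect_error(build_conduction_system(
    conduction_spec(nodes, segs,
                    data.frame(node = "c", cell = 5, area = 1))),
    "no host mesh")
})

test_that("AV-node conductivity calibrates to a ~100 ms transit delay", {
  cal <- calibrate_av_delay(100, chi_cm = 0.64, tol = 0.02)
  expect_equal(cal$delay, 100, tolerance = 0.025)
  expect_gt(cal$m_av, 0)
})
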