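test_that("default strike reproduces the printed force and timing", {
  mesh <- orb_default_mesh()
  sys <- orb_default_system()
  case <- default_strike_load(mesh)

  expect_length(case$load_nodes, 6)
  expect_equal(case$peak_force_per_node, 2400)
  # total force along the strike direction over time
  total <- function(t) sum(load_vector(case, t, sys))
  expect_equal(total(1.3e-3), 14400)
  expect_identical(total(0), 0)
  expect_identical(total(3e-3), 0)
  expect_equal(total(0.65e-3), 7200) # linear ramp midpoint
  expect_identical(total(2.6e-3), 0)

  # nonzero only on translational dofs of the strike nodes
  f <- load_vector(case, 1e-3, sys)
  nz <- which(f != 0)
  allowed <- as.vector(vapply(
    case$load_nodes, function(n) 6L * (n - 1L) + 1:3, integer(3)
  ))
  expect_true(all(nz %in% allowed))

  # profile is continuous at every knot
  for (tk in case$profile_knots[, 1]) {
    eps <- 1e-9
    expect_equal(load_profile(case, tk - eps), load_profile(case, tk),
      tolerance = 1e-5
    )
    expect_equal(load_profile(case, tk + eps), load_profile(case, tk),
      tolerance = 1e-5
    )
  }
})

test_that("malformed load profiles are rejected", {
  expect_error(
    load_case(1, c(1, 0, 0), 10, cbind(c(0, 1e-3, 2e-3), c(0.1, 1, 0))),
    "start and end"
  )
  expect_error(
    load_case(1, c(1, 0, 0), 10, cbind(c(0, 1e-3, 2e-3), c(0, 0.5, 0))),
    "fraction 1"
  )
  expect_error(
    load_case(1, c(1, 0, 0), 10, cbind(c(0, 2e-3, 1e-3), c(0, 1, 0))),
    "increase"
  )
})

test_that("stable_dt recovers the closed-form oscillator limit", {
  # k = 1 N/mm, m = 1 tonne: omega = 1 rad/s, dt = 2 s
  expect_equal(stable_dt(sdof_system(1, 1)), 2, tolerance = 1e-3)
  expect_equal(stable_dt(sdof_system(4, 1)), 1, tolerance = 1e-3)
})

test_that("stable_dt matches a dense generalized eigensolve", {
  mesh <- orb_small_mesh()
  sys <- assemble(mesh, material())
  dt <- stable_dt(sys)
  free <- sys$free_dofs
  s <- 1 / sqrt(sys$M[free])
  A <- t(s * t(s * as.matrix(sys$K[free, free])))
  lam_max <- max(eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(dt, 2 / sqrt(lam_max), tolerance = 0.05)
})

test_that("mesh refinement reduces the stable time step", {
  mk <- function(n) {
    mesh <- plate_mesh(20, 20, n, n, 1)
    mesh$fixed_nodes <- orbishock:::plate_boundary_nodes(mesh, 20, 20)
    assemble(mesh, material())
  }
  expect_lt(stable_dt(mk(8)), stable_dt(mk(4)))
})

test_that("oscillator period matches the harmonic closed form", {
  sdof <- sdof_system(1, 1)
  dt <- stable_dt(sdof) / 20
  hist <- integrate_transient(
    sdof, orbishock:::zero_load_case(),
    time_config(dt = dt, t_end = 6 * pi, snapshot_interval = dt),
    initial = list(u = c(1, rep(0, 17)))
  )
  expect_equal(trace_period(hist$times, hist$U[1, ]), 2 * pi,
    tolerance = 0.005
  )
  # Newmark agrees on the same problem
  hist_nm <- integrate_transient(
    sdof, orbishock:::zero_load_case(),
    time_config("newmark_average_acceleration",
      dt = dt, t_end = 6 * pi, snapshot_interval = dt
    ),
    initial = list(u = c(1, rep(0, 17)))
  )
  expect_equal(trace_period(hist_nm$times, hist_nm$U[1, ]), 2 * pi,
    tolerance = 0.005
  )
})

test_that("zero load leaves the system at rest", {
  mesh <- orb_small_mesh()
  sys <- assemble(mesh, material())
  case <- default_strike_load(mesh)
  case$peak_force_per_node <- 0
  hist <- integrate_transient(sys, case, time_config())
  expect_identical(max(abs(hist$U)), 0)
  expect_identical(max(abs(hist$V)), 0)
})

test_that("the response is linear in the load amplitude", {
  mesh <- orb_small_mesh()
  sys <- assemble(mesh, material())
  case <- default_strike_load(mesh)
  cfg <- time_config(t_end = 3e-3)
  h1 <- integrate_transient(sys, case, cfg)
  case3 <- case
  case3$peak_force_per_node <- 3 * case$peak_force_per_node
  h3 <- integrate_transient(sys, case3, cfg)
  expect_equal(h3$U, 3 * h1$U, tolerance = 1e-8)
})

test_that("snapshots cover the full window and respect constraints", {
  hist <- orb_default_run()
  expect_length(hist$times, 11)
  expect_equal(hist$times, seq(0, 1e-2, by = 1e-3), tolerance = 1e-12)
  fixed_dofs <- as.vector(vapply(
    orb_default_mesh()$fixed_nodes, function(n) 6L * (n - 1L) + 1:6, integer(6)
  ))
  expect_identical(max(abs(hist$U[fixed_dofs, ])), 0)
})

test_that("free vibration conserves energy within one percent", {
  mesh <- orb_small_mesh()
  sys <- assemble(mesh, material())
  case <- default_strike_load(mesh)
  case$peak_force_per_node <- 0
  # smooth initial velocity: the static strike deformation shape at a
  # 100 mm/s peak (a coherent low-mode field, as after a real impulse)
  strike <- default_strike_load(mesh)
  u_static <- static_solve(sys, load_vector(strike, 1.3e-3, sys))
  v0 <- u_static / max(abs(u_static)) * 100
  hist <- integrate_transient(sys, case, time_config(),
    initial = list(v = v0)
  )
  etot <- hist$energy$kinetic + hist$energy$strain
  expect_lt(max(abs(etot - etot[1])) / etot[1], 0.01)
})

test_that("explicit steps beyond the stability limit are refused", {
  mesh <- orb_small_mesh()
  sys <- assemble(mesh, material())
  case <- default_strike_load(mesh)
  big_dt <- 10 * stable_dt(sys)
  expect_error(
    integrate_transient(sys, case, time_config(dt = big_dt, t_end = 1e-3)),
    "stable_dt"
  )
})
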