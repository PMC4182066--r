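mat_bone <- material()

test_that("element stiffness is symmetric and annihilates rigid motions", {
  set.seed(3)
  for (rep in 1:4) {
    coords <- matrix(rnorm(9), 3, 3) * 10
    K <- element_stiffness(coords, 0.8, mat_bone)
    expect_equal(K, t(K), tolerance = 1e-12)
    nK <- norm(K, "2")
    # translations
    for (ax in 1:3) {
      u <- numeric(18)
      u[seq(ax, 18, by = 6)] <- 1
      expect_lt(max(abs(K %*% u)), 1e-8 * nK * sqrt(sum(u^2)))
    }
    # rotations about the three axes through the origin
    for (ax in 1:3) {
      th <- numeric(3)
      th[ax] <- 1
      u <- numeric(18)
      for (i in 1:3) {
        r <- coords[i, ]
        u[(6 * (i - 1) + 1):(6 * (i - 1) + 3)] <- c(
          th[2] * r[3] - th[3] * r[2],
          th[3] * r[1] - th[1] * r[3],
          th[1] * r[2] - th[2] * r[1]
        )
        u[(6 * (i - 1) + 4):(6 * (i - 1) + 6)] <- th
      }
      expect_lt(max(abs(K %*% u)), 1e-8 * nK * sqrt(sum(u^2)))
    }
  }
})

test_that("membrane block matches the hand-derived CST stiffness", {
  # unit right triangle, t = 1, E = 1, nu = 0; plane-stress B assembled
  # by hand from the nodal coordinate differences
  B <- rbind(
    c(-1, 0, 1, 0, 0, 0),
    c(0, -1, 0, 0, 0, 1),
    c(-1, -1, 0, 1, 1, 0)
  )
  D <- diag(c(1, 1, 0.5))
  K_hand <- 0.5 * t(B) %*% D %*% B

  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m1 <- material(1e6, 0, 1000) # E_mpa = 1
  K <- element_stiffness(coords, 1, m1, drilling_factor = 0)
  mem <- as.vector(vapply(0:2, function(i) 6L * i + c(1L, 2L), integer(2)))
  expect_equal(unname(K[mem, mem]), unname(K_hand), tolerance = 1e-12)
})

test_that("membrane scales with t and bending with t^3", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(0.4, 1.7, 0))
  mem <- as.vector(vapply(0:2, function(i) 6L * i + c(1L, 2L), integer(2)))
  bnd <- as.vector(vapply(0:2, function(i) 6L * i + c(3L, 4L, 5L), integer(3)))
  K1 <- element_stiffness(coords, 1, mat_bone, drilling_factor = 0)
  K2 <- element_stiffness(coords, 2, mat_bone, drilling_factor = 0)
  expect_equal(K2[mem, mem], 2 * K1[mem, mem], tolerance = 1e-12)
  expect_equal(K2[bnd, bnd], 8 * K1[bnd, bnd], tolerance = 1e-12)
})

test_that("degenerate triangles are rejected with the element id", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(element_stiffness(coords, 1, mat_bone), "degenerate")
  mesh <- plate_mesh(1, 1, 1, 1, 1)
  mesh$nodes[4, ] <- 2 * mesh$nodes[2, ] # collinear with nodes 1 and 2
  expect_error(assemble(mesh, mat_bone), "element [0-9]+")
})

test_that("unconstrained assembly has exactly the six rigid modes", {
  mesh <- plate_mesh(1, 1, 1, 1, 0.5)
  sys <- assemble(mesh, mat_bone)
  ev <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-6 * max(ev)), 6L)
  expect_true(all(ev > -1e-9 * max(ev)))

  # constraining a node removes all six of its dofs
  mesh$fixed_nodes <- 1L
  sys2 <- assemble(mesh, mat_bone)
  expect_identical(sys2$constrained_dofs, 1:6)
})

test_that("cantilever tip deflection matches Euler-Bernoulli theory", {
  L <- 100
  w <- 10
  t <- 2
  P <- 10
  m0 <- material(1.2e9, 0, 1900) # nu = 0 to match beam theory
  mesh <- plate_mesh(L, w, 16, 2, t)
  mesh$fixed_nodes <- which(mesh$nodes[, 1] < 1e-9)
  sys <- assemble(mesh, m0)
  tip <- which(mesh$nodes[, 1] > L - 1e-9)
  f <- numeric(sys$ndof)
  f[6 * (tip - 1) + 3] <- P / length(tip)
  u <- static_solve(sys, f)
  w_tip <- mean(u[6 * (tip - 1) + 3])
  w_ref <- P * L^3 / (3 * m0$E_mpa * (w * t^3 / 12))
  expect_equal(w_tip, w_ref, tolerance = 0.05)
})

test_that("static solutions are frame-indifferent and linear", {
  L <- 50
  mesh <- plate_mesh(L, 10, 8, 2, 1.5)
  mesh$fixed_nodes <- which(mesh$nodes[, 1] < 1e-9)
  sys <- assemble(mesh, mat_bone)
  tip <- which(mesh$nodes[, 1] > L - 1e-9)
  f <- numeric(sys$ndof)
  f[6 * (tip - 1) + 3] <- 5
  u <- static_solve(sys, f)

  # linearity
  u2 <- static_solve(sys, 2 * f)
  expect_equal(u2, 2 * u, tolerance = 1e-12)
  expect_identical(static_solve(sys, numeric(sys$ndof)), numeric(sys$ndof))

  # equivariance under a random rotation of mesh and load
  R <- fixed_rotation()
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(R)
  sys_r <- assemble(mesh_r, mat_bone)
  f_r <- numeric(sys$ndof)
  for (nd in tip) f_r[6 * (nd - 1) + 1:3] <- R %*% c(0, 0, 5)
  u_r <- static_solve(sys_r, f_r)
  u_rot <- u
  for (nd in seq_len(nrow(mesh$nodes))) {
    u_rot[6 * (nd - 1) + 1:3] <- R %*% u[6 * (nd - 1) + 1:3]
    u_rot[6 * (nd - 1) + 4:6] <- R %*% u[6 * (nd - 1) + 4:6]
  }
  expect_lt(max(abs(u_rot - u_r)), 1e-8 * max(abs(u)))
})

test_that("insufficiently constrained systems raise a diagnostic", {
  mesh <- plate_mesh(10, 10, 2, 2, 1) # no fixed nodes at all
  sys <- assemble(mesh, mat_bone)
  f <- numeric(sys$ndof)
  f[3] <- 1
  expect_error(static_solve(sys, f), "rigid")
})

test_that("lumped mass conserves the analytic surface mass", {
  # single triangle of area 1 mm^2, t = 1 mm, rho = 1000 kg/m^3:
  # total mass 1e-9 tonne (= 1e-6 kg) on each translational axis
  tri <- shell_mesh(
    nodes = rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0)),
    triangles = matrix(1:3, 1), thickness = 1
  )
  m1000 <- material(1.2e9, 0.3, 1000)
  M <- lumped_mass(tri, m1000)
  for (ax in 1:3) {
    expect_equal(sum(M[seq(ax, 18, by = 6)]), 1e-9, tolerance = 1e-12)
  }
  expect_true(all(M > 0))

  # orbit mesh vs independent area-sum oracle (direct cross products)
  mesh <- orb_default_mesh()
  M <- lumped_mass(mesh, mat_bone)
  p1 <- mesh$nodes[mesh$triangles[, 1], ]
  p2 <- mesh$nodes[mesh$triangles[, 2], ]
  p3 <- mesh$nodes[mesh$triangles[, 3], ]
  cr <- cbind(
    (p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
      (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
    (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
      (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
    (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  )
  mass_ref <- sum(mat_bone$rho * sqrt(rowSums(cr^2)) / 2 * mesh$thickness)
  expect_equal(sum(M[seq(1, length(M), by = 6)]), mass_ref,
    tolerance = 1e-10
  )

  # refinement leaves the total translational mass unchanged
  mc <- plate_mesh(10, 10, 4, 4, 1.3)
  mf <- plate_mesh(10, 10, 8, 8, 1.3)
  expect_equal(
    sum(lumped_mass(mc, mat_bone)[seq(1, 6 * nrow(mc$nodes), by = 6)]),
    sum(lumped_mass(mf, mat_bone)[seq(1, 6 * nrow(mf$nodes), by = 6)]),
    tolerance = 1e-10
  )
})

test_that("membrane patch test reproduces constant strain", {
  expect_lt(membrane_patch_test(), 1e-8)
})

test_that("plate bending converges monotonically to the Navier series", {
  a <- 100
  t <- 1
  q <- 0.01
  D <- mat_bone$E_mpa * t^3 / (12 * (1 - 0.3^2))
  w_ref <- navier_plate_center_deflection(q, a, a, D)
  errs <- vapply(c(8, 16, 32), function(n) {
    mesh <- plate_mesh(a, a, n, n, t)
    sys <- orbishock:::ss_plate_system(mesh, a, a, mat_bone)
    u <- static_solve(sys, orbishock:::plate_pressure_load(mesh, q))
    ic <- which.min((mesh$nodes[, 1] - a / 2)^2 + (mesh$nodes[, 2] - a / 2)^2)
    abs(u[6 * (ic - 1) + 3] / w_ref - 1)
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("solutions are consistent across unit systems", {
  # same cantilever posed in mm-N-tonne-s and in m-N-kg-s
  L <- 100
  w <- 10
  t <- 2
  P <- 7
  mesh_mm <- plate_mesh(L, w, 8, 2, t)
  mesh_mm$fixed_nodes <- which(mesh_mm$nodes[, 1] < 1e-9)
  sys_mm <- assemble(mesh_mm, material(1.2e9, 0.3, 1900))
  mesh_m <- mesh_mm
  mesh_m$nodes <- mesh_mm$nodes / 1000
  mesh_m$thickness <- mesh_mm$thickness / 1000
  mat_si <- material(1.2e9, 0.3, 1900)
  mat_si$E_mpa <- 1.2e9 # N/m^2 when lengths are metres
  mat_si$rho <- 1900    # kg/m^3
  sys_m <- assemble(mesh_m, mat_si)
  tip <- which(mesh_mm$nodes[, 1] > L - 1e-9)
  f <- numeric(sys_mm$ndof)
  f[6 * (tip - 1) + 3] <- P / length(tip)
  u_mm <- static_solve(sys_mm, f)
  u_m <- static_solve(sys_m, f)
  tr <- as.vector(vapply(
    seq_len(nrow(mesh_mm$nodes)), function(n) 6L * (n - 1L) + 1:3, integer(3)
  ))
  expect_equal(u_m[tr] * 1000, u_mm[tr], tolerance = 1e-9)
})
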