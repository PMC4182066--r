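# build a minimal displacement_history carrying a prescribed nodal
# translation field (rotations zero)
fake_history <- function(mesh, times, fields) {
  nnode <- nrow(mesh$nodes)
  U <- matrix(0, 6 * nnode, length(times))
  for (k in seq_along(times)) {
    tr <- fields[[k]] # nnode x 3
    for (c in 1:3) U[seq(c, by = 6, length.out = nnode), k] <- tr[, c]
  }
  structure(
    list(times = times, U = U, V = U * 0, dt = NA, method = "synthetic"),
    class = "displacement_history"
  )
}

test_that("signed displacement follows the inward-positive convention", {
  mesh <- orb_small_mesh()
  nnode <- nrow(mesh$nodes)
  # uniform rigid translation downward (toward the maxillary sinus)
  down <- matrix(rep(c(0, 0, -1), each = nnode), ncol = 3)
  hist <- fake_history(mesh, c(0, 1e-3), list(down * 0, down))
  field <- signed_wall_displacement(hist, mesh)
  fl <- field$node_region %in% c("floor_anterior", "floor_posterior")
  expect_true(all(field$s[fl, 2] < 0))
  # zero history gives the zero field
  expect_identical(max(abs(field$s[, 1])), 0)
})

test_that("orbital-axis projection equals x-displacement signed by side", {
  mesh <- orb_small_mesh()
  nnode <- nrow(mesh$nodes)
  set.seed(5)
  tr <- matrix(rnorm(3 * nnode), ncol = 3)
  hist <- fake_history(mesh, c(0, 1e-3), list(tr * 0, tr))
  field <- signed_wall_displacement(hist, mesh, "orbital_axis")
  # oracle: recompute node normals directly from winding cross products
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
  nx <- numeric(nnode)
  for (k in 1:3) {
    for (e in seq_len(nrow(mesh$triangles))) {
      nd <- mesh$triangles[e, k]
      nx[nd] <- nx[nd] + cr[e, 1] / 2
    }
  }
  expect_equal(field$s[, 2], sign(nx) * tr[, 1], tolerance = 1e-12)
})

test_that("flipping the mesh orientation flips the signed field", {
  mesh <- orb_small_mesh()
  nnode <- nrow(mesh$nodes)
  set.seed(6)
  tr <- matrix(rnorm(3 * nnode), ncol = 3)
  hist <- fake_history(mesh, c(0, 1e-3), list(tr * 0, tr))
  f1 <- signed_wall_displacement(hist, mesh)
  flipped <- mesh
  flipped$triangles <- mesh$triangles[, c(1, 3, 2)]
  f2 <- signed_wall_displacement(hist, flipped)
  expect_equal(f2$s, -f1$s, tolerance = 1e-12)
})

# hand-built signed field over the 11-snapshot grid
synthetic_field <- function(traces, regions, times = seq(0, 1e-2, 1e-3)) {
  structure(
    list(
      times = times, s = traces, axis_mode = "wall_normal",
      node_region = regions, fixed_nodes = integer(), probe_A = 1L
    ),
    class = "signed_displacement_field"
  )
}

test_that("retrograde detection agrees with an exhaustive scan oracle", {
  times <- seq(0, 1e-2, 1e-3)
  traces <- rbind(
    -sin(2 * pi * 100 * times),            # reverses
    -abs(sin(2 * pi * 100 * times)),       # outward only
    0.05 * sin(2 * pi * 100 * times),      # below threshold
    sin(2 * pi * 150 * times)              # goes inward first
  )
  regions <- rep("floor_anterior", 4)
  field <- synthetic_field(traces, regions)
  eps <- 0.1
  # oracle: brute-force scan over nodes and snapshots
  oracle_onset <- Inf
  for (i in seq_len(nrow(traces))) {
    out_seen <- FALSE
    for (k in seq_along(times)) {
      if (traces[i, k] < -eps) out_seen <- TRUE
      if (out_seen && traces[i, k] > eps) {
        oracle_onset <- min(oracle_onset, times[k])
        break
      }
    }
  }
  got <- detect_retrograde(field, eps)
  expect_equal(got$onset, oracle_onset)

  # property: detection equals the oracle on random fields
  set.seed(9)
  for (rep in 1:20) {
    tr <- matrix(rnorm(5 * 11, sd = 0.5), nrow = 5)
    tr[, 1] <- 0
    fld <- synthetic_field(tr, rep("medial", 5))
    oo <- Inf
    for (i in 1:5) {
      out_seen <- FALSE
      for (k in 1:11) {
        if (tr[i, k] < -eps) out_seen <- TRUE
        if (out_seen && tr[i, k] > eps) {
          oo <- min(oo, times[k])
          break
        }
      }
    }
    got <- detect_retrograde(fld, eps)
    if (is.finite(oo)) {
      expect_equal(got$onset, oo)
    } else {
      expect_true(is.na(got$onset))
    }
  }
})

test_that("no reversal is reported for outward-only or quiet fields", {
  field <- synthetic_field(
    matrix(-seq(0, 5, length.out = 11), 1), "floor_anterior"
  )
  expect_true(is.na(detect_retrograde(field, 0.1)$onset))
  field2 <- synthetic_field(
    matrix(0.01 * sin(seq(0, 6 * pi, length.out = 11)), 1), "medial"
  )
  expect_true(is.na(detect_retrograde(field2, 0.1)$onset))
  # epsilon larger than the field never fires
  field3 <- synthetic_field(
    matrix(-sin(2 * pi * 100 * seq(0, 1e-2, 1e-3)), 1), "medial"
  )
  expect_true(is.na(detect_retrograde(field3, 2)$onset))
})

test_that("probe metrics reproduce the arithmetic identity", {
  tr <- matrix(c(0, -4.37, -2, 1.55, 0), 1)
  field <- synthetic_field(tr, "floor_anterior",
    times = seq(0, 4e-3, 1e-3)
  )
  pm <- probe_metrics(field, 1L)
  expect_equal(pm$outward, 4.37)
  expect_equal(pm$inward, 1.55)
  expect_equal(pm$peak_to_peak, 5.92)

  zero <- synthetic_field(matrix(0, 1, 5), "medial", seq(0, 4e-3, 1e-3))
  pmz <- probe_metrics(zero, 1L)
  expect_identical(c(pmz$outward, pmz$inward, pmz$peak_to_peak), c(0, 0, 0))

  flat <- synthetic_field(matrix(-3, 1, 5), "medial", seq(0, 4e-3, 1e-3))
  pmf <- probe_metrics(flat, 1L)
  expect_equal(pmf$outward, 3)
  expect_identical(pmf$inward, 0)

  fixed <- synthetic_field(tr, "floor_anterior", seq(0, 4e-3, 1e-3))
  fixed$fixed_nodes <- 1L
  expect_error(probe_metrics(fixed, 1L), "fixed")
})

test_that("stress recovery matches plane-stress closed forms", {
  expect_equal(von_mises_2d(50, 0, 0), 50)
  expect_equal(von_mises_2d(0, 0, 20), sqrt(3) * 20)

  # uniform uniaxial stretch of a flat plate: vm = E * strain on both fibers
  m0 <- material(1.2e9, 0, 1900)
  mesh <- plate_mesh(10, 5, 2, 1, 1)
  eps <- 1e-3
  nnode <- nrow(mesh$nodes)
  tr <- cbind(eps * mesh$nodes[, 1], 0, 0)
  hist <- fake_history(mesh, c(0, 1), list(tr * 0, tr))
  st <- recover_stress(hist, mesh, m0)
  expect_equal(
    st$von_mises_top[, 2], rep(m0$E_mpa * eps, nrow(mesh$triangles)),
    tolerance = 1e-9
  )
  expect_equal(st$von_mises_top[, 2], st$von_mises_bottom[, 2],
    tolerance = 1e-12
  )
  expect_identical(max(st$von_mises_top[, 1]), 0)

  # pure in-plane shear: vm = sqrt(3) * G * gamma
  gam <- 2e-3
  tr2 <- cbind(gam * mesh$nodes[, 2], 0, 0)
  hist2 <- fake_history(mesh, c(0, 1), list(tr2 * 0, tr2))
  st2 <- recover_stress(hist2, mesh, m0)
  tau <- m0$E_mpa / 2 * gam
  expect_equal(
    st2$von_mises_top[, 2], rep(sqrt(3) * tau, nrow(mesh$triangles)),
    tolerance = 1e-9
  )
})

test_that("cantilever root bending stress matches beam theory", {
  L <- 100
  w <- 10
  t <- 2
  P <- 10
  m0 <- material(1.2e9, 0, 1900)
  mesh <- plate_mesh(L, w, 16, 2, t)
  mesh$fixed_nodes <- which(mesh$nodes[, 1] < 1e-9)
  sys <- assemble(mesh, m0)
  tip <- which(mesh$nodes[, 1] > L - 1e-9)
  f <- numeric(sys$ndof)
  f[6 * (tip - 1) + 3] <- P / length(tip)
  u <- static_solve(sys, f)
  hist <- structure(
    list(times = c(0), U = matrix(u), V = matrix(0, length(u), 1)),
    class = "displacement_history"
  )
  st <- recover_stress(hist, mesh, m0)
  ge <- orbishock:::mesh_element_geometry(mesh)
  Ii <- w * t^3 / 12
  sig <- pmax(st$von_mises_top[, 1], st$von_mises_bottom[, 1])
  # compare every element in the inner half of the strip at its centroid
  inner <- which(ge$centroid[, 1] > 0.1 * L & ge$centroid[, 1] < 0.6 * L)
  sig_ref <- P * (L - ge$centroid[inner, 1]) * (t / 2) / Ii
  expect_lt(max(abs(sig[inner] / sig_ref - 1)), 0.1)
})

test_that("first exceedance agrees with an exhaustive scan", {
  mesh <- orb_small_mesh()
  ntri <- nrow(mesh$triangles)
  times <- seq(0, 1e-2, 1e-3)
  set.seed(12)
  vt <- matrix(runif(ntri * 11, 0, 50), ntri)
  vb <- matrix(runif(ntri * 11, 0, 50), ntri)
  # plant a known exceedance in a floor element at snapshot 7
  fl <- which(mesh$region %in% c("floor_anterior", "floor_posterior"))
  e_star <- fl[3]
  vt[e_star, 7] <- 120
  stress <- structure(
    list(
      times = times, von_mises_top = vt, von_mises_bottom = vb,
      sigma_top = NULL, sigma_bottom = NULL
    ),
    class = "stress_field"
  )
  got <- first_exceedance(stress, 100, mesh)
  expect_equal(got$time, times[7])
  expect_identical(got$element, e_star)
  expect_identical(got$region, mesh$region[e_star])

  expect_true(is.na(first_exceedance(stress, Inf, mesh)$time))
  low <- first_exceedance(stress, 1e-12, mesh)
  expect_equal(low$time, times[1])
})

test_that("the default run shows the outward-then-retrograde sequence", {
  mesh <- orb_default_mesh()
  hist <- orb_default_run()
  rep <- wave_report(hist, mesh, material())

  # identity and ordering invariants
  expect_equal(
    rep$probe_A_peak_to_peak,
    rep$probe_A_outward + rep$probe_A_inward
  )
  expect_false(is.na(rep$reversal_onset))
  expect_gte(rep$reversal_onset, rep$peak_outward$time)
  expect_lte(rep$reversal_onset, rep$peak_inward$time)
  expect_true(all(rep$per_region$peak_outward_mm >= 0))
  expect_true(all(rep$per_region$peak_inward_mm >= 0))
})
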