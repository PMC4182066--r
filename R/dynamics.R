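#' Impulsive load case
#'
#' A set of load nodes sharing one force direction and a piecewise-linear
#' force-fraction time profile.  The profile starts and ends at fraction 0
#' and attains fraction 1 at exactly one knot.
#'
#' @param load_nodes ordered node indices receiving the force.
#' @param direction global force direction (normalized internally).
#' @param peak_force_per_node peak force per node (N).
#' @param profile_knots two-column matrix or data.frame (time s, fraction).
#' @return object of class \code{load_case}.
#' @export
load_case <- function(load_nodes, direction, peak_force_per_node,
                      profile_knots) {
  profile_knots <- as.matrix(profile_knots)
  stopifnot(
    length(load_nodes) >= 1L,
    length(direction) == 3L, any(direction != 0),
    peak_force_per_node >= 0,
    ncol(profile_knots) == 2L, nrow(profile_knots) >= 3L
  )
  tt <- profile_knots[, 1L]
  ff <- profile_knots[, 2L]
  if (any(diff(tt) <= 0)) stop("knot times must increase", call. = FALSE)
  if (ff[1L] != 0 || ff[length(ff)] != 0) {
    stop("profile must start and end at fraction 0", call. = FALSE)
  }
  if (any(ff < 0 | ff > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (sum(ff == 1) != 1L) {
    stop("profile must attain fraction 1 at exactly one knot", call. = FALSE)
  }
  structure(
    list(
      load_nodes = as.integer(load_nodes),
      direction = direction / sqrt(sum(direction^2)),
      peak_force_per_node = peak_force_per_node,
      profile_knots = cbind(time = tt, fraction = ff)
    ),
    class = "load_case"
  )
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf(
    "Load case: %d nodes x %g N peak (total %g N), direction (%.2f, %.2f, %.2f)\n",
    length(x$load_nodes), x$peak_force_per_node,
    x$peak_force_per_node * length(x$load_nodes),
    x$direction[1L], x$direction[2L], x$direction[3L]
  ))
  cat(
    "  profile knots (s, fraction):",
    paste(sprintf(
      "(%g, %g)", x$profile_knots[, 1L], x$profile_knots[, 2L]
    ), collapse = " "), "\n"
  )
  invisible(x)
}

#' Default orbital-rim strike
#'
#' The reference impulse: 6 nodes on the free inferior rim each loaded with
#' 2400 N (14400 N total) along the posterior orbital axis (+x), ramping
#' linearly from zero at t = 0 to the peak at 1.3 ms and back to zero at
#' 2.6 ms.
#'
#' @param mesh a \code{\link{shell_mesh}} whose \code{load_nodes} are set
#'   (at least 6).
#' @param peak_force_per_node peak per-node force (N).
#' @param direction strike direction in the global frame.
#' @return a \code{\link{load_case}}.
#' @export
default_strike_load <- function(mesh, peak_force_per_node = 2400,
                                direction = c(1, 0, 0)) {
  if (length(mesh$load_nodes) < 6L) {
    stop("mesh must carry at least 6 load nodes", call. = FALSE)
  }
  load_case(
    load_nodes = mesh$load_nodes[1:6],
    direction = direction,
    peak_force_per_node = peak_force_per_node,
    profile_knots = cbind(c(0, 1.3e-3, 2.6e-3), c(0, 1, 0))
  )
}

#' Force fraction of a load case at time t
#'
#' Piecewise-linear interpolation of the profile knots; zero outside the
#' knot range.
#'
#' @param case a \code{\link{load_case}}.
#' @param t time (s), vectorized.
#' @return force fraction(s) in [0, 1].
#' @export
load_profile <- function(case, t) {
  stats::approx(
    case$profile_knots[, 1L], case$profile_knots[, 2L],
    xout = t, yleft = 0, yright = 0, rule = 2
  )$y
}

#' Global nodal force vector at time t
#'
#' @param case a \code{\link{load_case}}.
#' @param t time (s).
#' @param system a \code{global_system} (defines the dof layout).
#' @return numeric vector of length \code{system$ndof} (N on translations).
#' @export
load_vector <- function(case, t, system) {
  f <- numeric(system$ndof)
  amp <- case$peak_force_per_node * load_profile(case, t)
  if (amp != 0) {
    for (nd in case$load_nodes) {
      f[6L * (nd - 1L) + 1:3] <- f[6L * (nd - 1L) + 1:3] + amp * case$direction
    }
  }
  f
}

#' Stable time step of the explicit central-difference integrator
#'
#' Returns 2/omega_max where omega_max^2 is the largest eigenvalue of the
#' constrained generalized problem K u = omega^2 M u, estimated by power
#' iteration on the mass-normalized stiffness.
#'
#' @param system a \code{global_system}.
#' @param tol relative tolerance on omega_max^2.
#' @param maxit iteration cap.
#' @return stable time step (s).
#' @export
stable_dt <- function(system, tol = 1e-3, maxit = 5000L) {
  free <- system$free_dofs
  Kff <- system$K[free, free]
  s <- 1 / sqrt(system$M[free])
  set.seed(0L)
  x <- rnorm(length(free))
  x <- x / sqrt(sum(x^2))
  lam <- 0
  for (it in seq_len(maxit)) {
    y <- s * as.numeric(Kff %*% (s * x))
    lam_new <- sum(x * y)
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop("zero stiffness operator", call. = FALSE)
    x <- y / ny
    if (it > 5L && abs(lam_new - lam) <= tol * abs(lam_new)) {
      return(2 / sqrt(lam_new))
    }
    lam <- lam_new
  }
  stop(sprintf(
    "power iteration did not converge in %d iterations (last omega_max^2 = %.6g, rel change %.3g)",
    maxit, lam, abs(lam_new - lam) / abs(lam_new)
  ), call. = FALSE)
}

#' Time-integration configuration
#'
#' @param method \code{"central_difference"} (explicit, default) or
#'   \code{"newmark_average_acceleration"} (implicit, unconditionally
#'   stable).
#' @param dt solver step (s) or \code{"auto"}: \code{cfl_safety *
#'   stable_dt} for central difference, 1e-5 s for Newmark.
#' @param t_end simulated horizon (s); default 10 ms.
#' @param snapshot_interval cadence of recorded states (s); default 1 ms.
#' @param cfl_safety fraction of the stable step used when \code{dt} is
#'   "auto".
#' @return object of class \code{time_config}.
#' @export
time_config <- function(method = c(
                          "central_difference",
                          "newmark_average_acceleration"
                        ),
                        dt = "auto", t_end = 1e-2,
                        snapshot_interval = 1e-3, cfl_safety = 0.8) {
  method <- match.arg(method)
  stopifnot(
    t_end > 0, snapshot_interval > 0, snapshot_interval <= t_end,
    cfl_safety > 0, cfl_safety <= 1
  )
  if (!identical(dt, "auto")) {
    stopifnot(is.numeric(dt), dt > 0, snapshot_interval >= dt)
  }
  structure(
    list(
      method = method, dt = dt, t_end = t_end,
      snapshot_interval = snapshot_interval, cfl_safety = cfl_safety
    ),
    class = "time_config"
  )
}

resolve_dt <- function(system, config) {
  dt <- config$dt
  if (identical(dt, "auto")) {
    dt <- if (config$method == "central_difference") {
      config$cfl_safety * stable_dt(system)
    } else {
      1e-5
    }
  } else if (config$method == "central_difference") {
    lim <- config$cfl_safety * stable_dt(system)
    if (dt > lim) {
      stop(sprintf(
        "dt = %.3g s exceeds cfl_safety * stable_dt = %.3g s", dt, lim
      ), call. = FALSE)
    }
  }
  # land snapshots exactly on solver steps
  nsub <- max(1L, as.integer(ceiling(config$snapshot_interval / dt - 1e-12)))
  config$snapshot_interval / nsub
}

#' Transient integration of the shell system
#'
#' Integrates M u'' + C u' + K u = f(t) from rest with C the Rayleigh
#' damping of the material.  Central difference uses a half-step velocity
#' damping term and one stiffness matvec per step; Newmark (average
#' acceleration) factorizes the effective stiffness once.  States and the
#' energy balance (external work, kinetic, strain, dissipated; N mm) are
#' recorded every \code{snapshot_interval}.
#'
#' @param system a \code{global_system}.
#' @param case a \code{\link{load_case}}.
#' @param config a \code{\link{time_config}}.
#' @param initial optional list with \code{u} and/or \code{v} (full-length
#'   dof vectors) replacing the rest start.
#' @return object of class \code{displacement_history}: list with
#'   \code{times} (s), \code{U} and \code{V} (ndof x n_snapshots matrices;
#'   mm and mm/s on translations), \code{energy} (data.frame), \code{dt},
#'   \code{method}.
#' @export
integrate_transient <- function(system, case, config = time_config(),
                                initial = NULL) {
  stopifnot(
    inherits(system, "global_system"),
    inherits(case, "load_case"),
    inherits(config, "time_config")
  )
  dt <- resolve_dt(system, config)
  nsnap <- as.integer(round(config$t_end / config$snapshot_interval)) + 1L
  nsub <- as.integer(round(config$snapshot_interval / dt))
  nstep <- nsub * (nsnap - 1L)
  free <- system$free_dofs
  Kff <- system$K[free, free]
  m <- system$M[free]
  alpha <- system$material$rayleigh_alpha
  beta <- system$material$rayleigh_beta
  diam <- max(apply(system$mesh$nodes, 2L, function(v) diff(range(v))))
  blow <- 1e3 * diam

  fvec <- function(t) load_vector(case, t, system)[free]

  u <- numeric(length(free))
  v <- numeric(length(free))
  if (!is.null(initial)) {
    if (!is.null(initial$u)) u <- initial$u[free]
    if (!is.null(initial$v)) v <- initial$v[free]
  }

  U <- matrix(0, system$ndof, nsnap)
  V <- matrix(0, system$ndof, nsnap)
  times <- config$snapshot_interval * (seq_len(nsnap) - 1L)
  work <- kin <- str <- dis <- numeric(nsnap)

  record <- function(k, u, v, W, Dis) {
    U[free, k] <<- u
    V[free, k] <<- v
    work[k] <<- W
    kin[k] <<- 0.5 * sum(m * v^2)
    str[k] <<- 0.5 * sum(u * as.numeric(Kff %*% u))
    dis[k] <<- Dis
  }

  if (config$method == "central_difference") {
    f_cur <- fvec(0)
    Ku <- as.numeric(Kff %*% u)
    a0 <- (f_cur - Ku - alpha * m * v - beta * as.numeric(Kff %*% v)) / m
    u_prev <- u - dt * v + dt^2 / 2 * a0
    Ku_prev <- as.numeric(Kff %*% u_prev)
    W <- 0
    Dis <- 0
    record(1L, u, v, W, Dis)
    snap_next <- 2L
    u_hist_prev <- u_prev # for central velocity at snapshots
    for (n in seq_len(nstep)) {
      tn <- (n - 1L) * dt
      vel_half <- (u - u_prev) / dt
      damp <- alpha * m * vel_half + beta * (Ku - Ku_prev) / dt
      acc <- (f_cur - Ku - damp) / m
      u_next <- 2 * u - u_prev + dt^2 * acc
      f_next <- fvec(tn + dt)
      W <- W + 0.5 * sum((f_cur + f_next) * (u_next - u))
      Dis <- Dis + sum(damp * (u_next - u))
      if (max(abs(u_next)) > blow) {
        stop(sprintf(
          "instability detected at step %d (t = %.3g s): displacement norm exceeded 1000 x mesh diameter; reduce dt",
          n, tn + dt
        ), call. = FALSE)
      }
      u_prev <- u
      Ku_prev <- Ku
      u <- u_next
      Ku <- as.numeric(Kff %*% u)
      f_cur <- f_next
      if (n %% nsub == 0L && snap_next <= nsnap) {
        # state at snapshot = u (step n); velocity via one lookahead step
        vel_half2 <- (u - u_prev) / dt
        damp2 <- alpha * m * vel_half2 + beta * (Ku - Ku_prev) / dt
        acc2 <- (f_cur - Ku - damp2) / m
        u_ahead <- 2 * u - u_prev + dt^2 * acc2
        vsnap <- (u_ahead - u_prev) / (2 * dt)
        record(snap_next, u, vsnap, W, Dis)
        snap_next <- snap_next + 1L
      }
    }
  } else {
    bN <- 0.25
    gN <- 0.5
    Keff <- Kff * (1 + gN / (bN * dt) * beta) +
      Matrix::Diagonal(x = m * (1 / (bN * dt^2) + alpha * gN / (bN * dt)))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Keff), LDL = FALSE)
    Cv <- function(vv) alpha * m * vv + beta * as.numeric(Kff %*% vv)
    f_cur <- fvec(0)
    a <- (f_cur - as.numeric(Kff %*% u) - Cv(v)) / m
    W <- 0
    Dis <- 0
    record(1L, u, v, W, Dis)
    snap_next <- 2L
    for (n in seq_len(nstep)) {
      tn1 <- n * dt
      f_next <- fvec(tn1)
      rhs_m <- m * (u / (bN * dt^2) + v / (bN * dt) + (1 / (2 * bN) - 1) * a)
      cu <- gN / (bN * dt) * u + (gN / bN - 1) * v +
        dt * (gN / (2 * bN) - 1) * a
      rhs_c <- alpha * m * cu + beta * as.numeric(Kff %*% cu)
      u_next <- as.numeric(Matrix::solve(ch, f_next + rhs_m + rhs_c))
      a_next <- (u_next - u - dt * v) / (bN * dt^2) - (1 / (2 * bN) - 1) * a
      v_next <- v + dt * ((1 - gN) * a + gN * a_next)
      W <- W + 0.5 * sum((f_cur + f_next) * (u_next - u))
      Dis <- Dis + 0.5 * sum((Cv(v) + Cv(v_next)) * (u_next - u))
      u <- u_next
      v <- v_next
      a <- a_next
      f_cur <- f_next
      if (n %% nsub == 0L && snap_next <= nsnap) {
        record(snap_next, u, v, W, Dis)
        snap_next <- snap_next + 1L
      }
    }
  }

  structure(
    list(
      times = times, U = U, V = V,
      energy = data.frame(
        time = times, external_work = work, kinetic = kin,
        strain = str, dissipated = dis
      ),
      dt = dt, method = config$method
    ),
    class = "displacement_history"
  )
}

#' @export
print.displacement_history <- function(x, ...) {
  cat(sprintf(
    "Displacement history: %d snapshots over %g s (%s, dt = %.3g s)\n",
    length(x$times), max(x$times), x$method, x$dt
  ))
  invisible(x)
}
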