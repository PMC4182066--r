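# lazily computed shared fixtures: the default orbit run is expensive, so
# every test file draws on one cached instance
.orb_cache <- new.env(parent = emptyenv())

orb_default_mesh <- function() {
  if (is.null(.orb_cache$mesh)) {
    .orb_cache$mesh <- generate_orbit(orbit_params())
  }
  .orb_cache$mesh
}

orb_default_system <- function() {
  if (is.null(.orb_cache$system)) {
    .orb_cache$system <- assemble(orb_default_mesh(), material())
  }
  .orb_cache$system
}

orb_default_run <- function() {
  if (is.null(.orb_cache$run)) {
    .orb_cache$run <- integrate_transient(
      orb_default_system(),
      default_strike_load(orb_default_mesh()),
      time_config()
    )
  }
  .orb_cache$run
}

orb_small_mesh <- function() {
  if (is.null(.orb_cache$small)) {
    .orb_cache$small <- generate_orbit(orbit_params(target_elements = 180))
  }
  .orb_cache$small
}

# random rotation matrix with a fixed seed
fixed_rotation <- function(seed = 42L) {
  set.seed(seed)
  th <- rnorm(3)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}
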