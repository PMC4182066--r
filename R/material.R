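#' Linear elastic shell material
#'
#' Isotropic linear elasticity with mass density and optional Rayleigh
#' damping (C = alpha*M + beta*K).  Inputs are SI; the object also carries
#' the values converted to the internal mm-N-tonne-s system (stresses in
#' MPa) used by the assembly and solvers.
#'
#' The default Young's modulus of 1.2 GPa is the mean extensometer value
#' measured on cadaveric orbital-wall bone samples; Poisson's ratio and
#' density are not part of that measurement and default to typical
#' cortical-bone values (0.3 and 1900 kg/m^3).
#'
#' @param youngs_modulus Young's modulus in Pa.
#' @param poisson_ratio dimensionless, in [0, 0.5).
#' @param density mass density in kg/m^3.
#' @param rayleigh_alpha mass-proportional damping coefficient (1/s).
#' @param rayleigh_beta stiffness-proportional damping coefficient (s).
#' @return object of class \code{material}.
#' @examples
#' material()             # orbital bone defaults
#' material(2.1e11, 0.3, 7850)  # steel, for benchmarks
#' @export
material <- function(youngs_modulus = 1.2e9, poisson_ratio = 0.3,
                     density = 1900, rayleigh_alpha = 0, rayleigh_beta = 0) {
  stopifnot(
    youngs_modulus > 0,
    poisson_ratio >= 0, poisson_ratio < 0.5,
    density > 0,
    rayleigh_alpha >= 0, rayleigh_beta >= 0
  )
  structure(
    list(
      youngs_modulus = youngs_modulus,
      poisson_ratio = poisson_ratio,
      density = density,
      rayleigh_alpha = rayleigh_alpha,
      rayleigh_beta = rayleigh_beta,
      # internal mm-N-tonne-s values
      E_mpa = youngs_modulus / 1e6,
      poisson = poisson_ratio,
      rho = density * 1e-12
    ),
    class = "material"
  )
}

# default-material accessor usable where the argument shadows the
# constructor's name
orbital_bone_material <- function() material()

#' @export
print.material <- function(x, ...) {
  cat("Shell material\n")
  cat(sprintf("  E   = %.4g Pa (%.4g MPa)\n", x$youngs_modulus, x$E_mpa))
  cat(sprintf("  nu  = %.3g\n", x$poisson_ratio))
  cat(sprintf("  rho = %.4g kg/m^3\n", x$density))
  if (x$rayleigh_alpha > 0 || x$rayleigh_beta > 0) {
    cat(sprintf(
      "  Rayleigh damping: alpha = %.3g 1/s, beta = %.3g s\n",
      x$rayleigh_alpha, x$rayleigh_beta
    ))
  }
  invisible(x)
}
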