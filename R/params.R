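#' SALR interaction parameters
#'
#' Container for the square-well-linear (SWL) pair potential constants.
#' Lengths are measured in particle diameters \eqn{\sigma} and energies in
#' well depths \eqn{\epsilon}; both are 1 in reduced units and kept as
#' explicit fields only so that the unit convention is visible in code.
#'
#' @param zeta repulsion strength \eqn{\zeta} (dimensionless, >= 0).
#' @param lam attractive well range \eqn{\lambda} in units of sigma;
#'   must satisfy 1 < lam < kappa.
#' @param kappa repulsion range \eqn{\kappa} in units of sigma.
#' @param sigma particle hard-core diameter (unit of length; default 1).
#' @param epsilon attractive well depth (unit of energy; default 1; 0 gives
#'   the pure hard-sphere limit).
#'
#' @return An object of class `salr_params`.
#' @examples
#' p <- salr_params()            # the default SALR parameterization
#' pair_potential(c(0.9, 1.2, 2, 5), p)
#' @export
salr_params <- function(zeta = 0.05, lam = 1.5, kappa = 4.0,
                        sigma = 1, epsilon = 1) {
  stopifnot(sigma > 0, epsilon >= 0, zeta >= 0)
  if (!(lam > 1 && lam < kappa))
    stop("require 1 < lam < kappa (attractive range inside repulsive range)")
  structure(list(zeta = zeta, lam = lam, kappa = kappa,
                 sigma = sigma, epsilon = epsilon),
            class = "salr_params")
}

#' @export
print.salr_params <- function(x, ...) {
  cat("SALR square-well-linear potential (reduced units)\n")
  cat(sprintf("  zeta = %g, lambda = %g, kappa = %g (sigma = %g, epsilon = %g)\n",
              x$zeta, x$lam, x$kappa, x$sigma, x$epsilon))
  invisible(x)
}

#' Spherical-shell confinement geometry
#'
#' Two concentric hard spherical walls; particle centers are allowed on the
#' closed interval `[R_inn, R_out]` of radial coordinates.
#'
#' @param R_inn inner radius (sigma units, >= 0).
#' @param R_out outer radius (sigma units, > R_inn).
#' @return An object of class `shell_geometry` with fields `R_inn`, `R_out`,
#'   `W` (width) and `R_c` (mid-shell radius).
#' @examples
#' shell_geometry(6, 11)
#' @export
shell_geometry <- function(R_inn, R_out) {
  stopifnot(is.numeric(R_inn), is.numeric(R_out), length(R_inn) == 1,
            length(R_out) == 1, R_inn >= 0, R_out > R_inn)
  if (R_inn < 1.5 && R_inn > 0)
    warning("R_inn < 1.5 sigma: particles across the inner sphere feel the ",
            "long-range repulsion; ordered structures are not expected")
  structure(list(R_inn = R_inn, R_out = R_out,
                 W = R_out - R_inn, R_c = (R_inn + R_out) / 2),
            class = "shell_geometry")
}

#' @export
print.shell_geometry <- function(x, ...) {
  cat(sprintf("Spherical shell: R_inn = %g, R_out = %g (W = %g, R_c = %g) sigma\n",
              x$R_inn, x$R_out, x$W, x$R_c))
  invisible(x)
}

#' Thermodynamic state for grand-canonical simulation
#'
#' @param T_star reduced temperature k_B T / epsilon (> 0).
#' @param mu_star reduced chemical potential mu / epsilon.
#' @return An object of class `thermo_state` with derived fields `beta`
#'   (1/T_star) and `z`, the activity exp(mu*/T*)/sigma^3 under the
#'   convention that the de Broglie wavelength equals sigma.
#' @export
thermo_state <- function(T_star = 0.35, mu_star = -2.17) {
  stopifnot(is.numeric(T_star), length(T_star) == 1)
  if (T_star <= 0) stop("T_star must be > 0")
  structure(list(T_star = T_star, mu_star = mu_star,
                 beta = 1 / T_star, z = exp(mu_star / T_star)),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("Thermodynamic state: T* = %g, mu* = %g (activity z = %.6g / sigma^3)\n",
              x$T_star, x$mu_star, x$z))
  invisible(x)
}

#' Particle configuration
#'
#' A set of particle positions (sigma units, origin at the shell center)
#' with optional attached geometry.
#'
#' @param positions numeric matrix with 3 columns (x, y, z), one row per
#'   particle; a numeric vector of length 3 is accepted for one particle.
#' @param shell optional [shell_geometry()] the configuration lives in.
#' @param validate check shell containment and hard-core overlap.
#' @return A `configuration`: the position matrix with attributes.
#' @export
configuration <- function(positions, shell = NULL, validate = FALSE) {
  if (is.null(positions) || length(positions) == 0)
    positions <- matrix(numeric(0), ncol = 3)
  if (is.vector(positions)) positions <- matrix(positions, ncol = 3, byrow = TRUE)
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  obj <- structure(positions, shell = shell, class = c("configuration", "matrix", "array"))
  if (validate) validate_configuration(obj, shell)
  obj
}

#' Validate a configuration against hard constraints
#'
#' Checks that all particles lie inside the shell (walls inclusive) and
#' that no pair of centers is closer than the hard-core diameter.
#'
#' @param config a [configuration()] (or plain position matrix).
#' @param shell a [shell_geometry()]; defaults to the one attached to `config`.
#' @param sigma hard-core diameter.
#' @param tol numerical slack on both checks.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_configuration <- function(config, shell = NULL, sigma = 1, tol = 1e-9) {
  pos <- as_positions(config)
  if (is.null(shell)) shell <- attr(config, "shell")
  n <- nrow(pos)
  if (!is.null(shell) && n > 0) {
    r <- sqrt(rowSums(pos^2))
    bad <- which(r < shell$R_inn - tol | r > shell$R_out + tol)
    if (length(bad))
      stop(sprintf("particle %d outside shell (|r| = %.6f)", bad[1], r[bad[1]]))
  }
  if (n > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin < sigma - tol)
      stop(sprintf("hard-core overlap: minimum pair distance %.6f < %g", dmin, sigma))
  }
  invisible(TRUE)
}

# strip configuration class/attributes down to a plain double matrix
as_positions <- function(config) {
  if (is.null(config) || length(config) == 0) return(matrix(numeric(0), ncol = 3))
  m <- unclass(config)
  attr(m, "shell") <- NULL
  if (is.vector(m)) m <- matrix(m, ncol = 3, byrow = TRUE)
  storage.mode(m) <- "double"
  m
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("Particle configuration: N = %d\n", nrow(x)))
  sh <- attr(x, "shell")
  if (!is.null(sh)) print(sh)
  invisible(x)
}
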