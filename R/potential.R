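#' Square-well-linear SALR pair potential
#'
#' The competing-interaction pair potential: a hard core of diameter sigma,
#' an attractive square well of depth epsilon out to lambda*sigma, and a
#' linear repulsive ramp that decays to zero at kappa*sigma:
#' \deqn{u(r) = \infty \ (r < \sigma);\quad -\epsilon \ (\sigma \le r < \lambda\sigma);
#'   \quad \epsilon\,\zeta(\kappa - r/\sigma) \ (\lambda\sigma \le r < \kappa\sigma);
#'   \quad 0 \ (r \ge \kappa\sigma).}
#' The ramp is linear with slope \eqn{-\zeta\epsilon/\sigma} and continuous at
#' kappa*sigma; the well/ramp step at lambda*sigma has height
#' \eqn{\zeta(\kappa-\lambda)\epsilon} (0.125 epsilon at the default parameters).
#'
#' @param r center-to-center distance(s), sigma units; must be > 0.
#' @param params a [salr_params()].
#' @return Energy in epsilon units, vectorized over `r` (`Inf` inside the core).
#' @examples
#' pair_potential(c(1.2, 1.5, 2.0, 4.0), salr_params())
#' @export
pair_potential <- function(r, params = salr_params()) {
  if (any(r <= 0)) stop("pair_potential: distance must be positive")
  rr <- r / params$sigma
  u <- numeric(length(rr))
  u[rr < 1] <- Inf
  u[rr >= 1 & rr < params$lam] <- -params$epsilon
  ramp <- rr >= params$lam & rr < params$kappa
  u[ramp] <- params$epsilon * params$zeta * (params$kappa - rr[ramp])
  u
}

#' Hard-wall shell confinement potential
#'
#' Zero for particle centers inside the closed shell
#' `R_inn <= |r| <= R_out` (centers may sit exactly on either wall),
#' infinite outside.
#'
#' @param position a 3-vector or 3-column matrix of positions (sigma units,
#'   origin at the shell center).
#' @param shell a [shell_geometry()].
#' @return Energy in epsilon (0 or `Inf`), one value per position.
#' @export
external_potential <- function(position, shell) {
  pos <- as_positions(position)
  r <- sqrt(rowSums(pos^2))
  ifelse(r >= shell$R_inn & r <= shell$R_out, 0, Inf)
}

#' Total configurational energy
#'
#' Sum of the SALR pair potential over all unordered pairs plus the hard-wall
#' term for every particle.  This is the plain O(N^2) reference evaluation;
#' the Monte Carlo engine keeps the same quantity incrementally and is tested
#' against this function.
#'
#' @param config a [configuration()] or position matrix.
#' @param params a [salr_params()].
#' @param shell a [shell_geometry()] (or `NULL` to skip the wall term).
#' @return Total energy in epsilon; `Inf` for overlapping or escaped particles.
#' @export
total_energy <- function(config, params = salr_params(), shell = NULL) {
  pos <- as_positions(config)
  if (is.null(shell)) shell <- attr(config, "shell")
  n <- nrow(pos)
  if (n == 0) return(0)
  if (!is.null(shell) && any(is.infinite(external_potential(pos, shell))))
    return(Inf)
  if (n == 1) return(0)
  d <- stats::dist(pos)
  if (any(d < params$sigma)) return(Inf)
  sum(pair_potential(as.numeric(d), params))
}

#' Interaction energy of one particle (or trial position)
#'
#' Energy of a single particle with all other particles in the configuration
#' plus its own wall term.  Used for incremental Metropolis energy changes;
#' for finite-energy configurations `total_energy` equals half the sum of the
#' pair parts of `particle_energy` over all particles (the wall terms are
#' all zero there).
#'
#' @param config a [configuration()] or position matrix.
#' @param i either an integer particle index into `config`, or a numeric
#'   3-vector trial position (interacting with all of `config`).
#' @param params a [salr_params()].
#' @param shell a [shell_geometry()] (or `NULL` to skip the wall term).
#' @return Energy in epsilon (possibly `Inf`).
#' @export
particle_energy <- function(config, i, params = salr_params(), shell = NULL) {
  pos <- as_positions(config)
  if (is.null(shell)) shell <- attr(config, "shell")
  if (length(i) == 1 && is.numeric(i) && i == round(i) && i >= 1 && i <= nrow(pos)) {
    p <- pos[i, ]
    others <- pos[-i, , drop = FALSE]
  } else if (length(i) == 3) {
    p <- as.numeric(i)
    others <- pos
  } else stop("i must be a particle index or a 3-vector trial position")
  u <- if (is.null(shell)) 0 else external_potential(p, shell)
  if (is.infinite(u)) return(Inf)
  if (nrow(others) == 0) return(u)
  d <- sqrt(rowSums(sweep(others, 2, p)^2))
  if (any(d < params$sigma)) return(Inf)
  u + sum(pair_potential(d, params))
}

#' Accessible volume of a shell (density-reporting convention)
#'
#' The volume used to report number densities: since particle centers can sit
#' exactly on both walls, half a hard core protrudes past each, so sigma/2 is
#' subtracted from the inner and added to the outer radius:
#' \deqn{V = \frac{4\pi}{3}\left[(R_{out}+\tfrac12)^3 - (R_{inn}-\tfrac12)^3\right].}
#' Note this is a reporting convention only; the grand-canonical acceptance
#' rules use the geometric shell volume between the walls (see
#' [shell_volume()]).
#'
#' @param shell a [shell_geometry()] with `R_inn >= 0.5`.
#' @return Volume in sigma^3.
#' @examples
#' accessible_volume(shell_geometry(6, 11))   # ~ 5673.7
#' @export
accessible_volume <- function(shell) {
  if (shell$R_inn < 0.5)
    stop("accessible_volume requires R_inn >= 0.5 sigma")
  (4 * pi / 3) * ((shell$R_out + 0.5)^3 - (shell$R_inn - 0.5)^3)
}

#' Geometric shell volume between the hard walls
#'
#' @param shell a [shell_geometry()].
#' @return `(4 pi / 3) (R_out^3 - R_inn^3)` in sigma^3.
#' @export
shell_volume <- function(shell) {
  (4 * pi / 3) * (shell$R_out^3 - shell$R_inn^3)
}

#' Reduced number density
#'
#' `rho* = N sigma^3 / V` with V the [accessible_volume()] of the shell.
#'
#' @param N particle count (>= 0).
#' @param shell a [shell_geometry()].
#' @return Dimensionless number density.
#' @export
number_density <- function(N, shell) {
  stopifnot(all(N >= 0))
  N / accessible_volume(shell)
}
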