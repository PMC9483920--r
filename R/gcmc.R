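#' Monte Carlo move mix
#'
#' @param p_displacement probability that a trial move is a single-particle
#'   displacement; the remainder is split evenly between insertion and
#'   deletion attempts. Default 0.95 / 0.05.
#' @return A `move_mix` object.
#' @export
move_mix <- function(p_displacement = 0.95) {
  stopifnot(p_displacement >= 0, p_displacement <= 1)
  structure(list(p_displacement = p_displacement,
                 p_exchange = 1 - p_displacement),
            class = "move_mix")
}

#' Run schedule for a GCMC simulation
#'
#' One Monte Carlo step is one trial move (displacement, insertion, or
#' deletion). Production observables are sampled every `sample_interval`
#' steps; configurations are stored every `traj_interval` steps (0 disables
#' trajectory storage).
#'
#' @param n_equilibration,n_production step counts (>= 0).
#' @param sample_interval steps between observable records.
#' @param traj_interval steps between stored configurations (0 = none).
#' @param seed RNG seed making the whole run deterministic.
#' @return A `run_schedule` object.
#' @export
run_schedule <- function(n_equilibration = 1e6, n_production = 1e6,
                         sample_interval = 1e3, traj_interval = 0,
                         seed = 1L) {
  stopifnot(n_equilibration >= 0, n_production >= 0, sample_interval >= 1)
  structure(list(n_equilibration = n_equilibration,
                 n_production = n_production,
                 sample_interval = sample_interval,
                 traj_interval = traj_interval,
                 seed = as.integer(seed)),
            class = "run_schedule")
}

# shared driver behind run_gcmc(); geometry is "shell" or "box"
gcmc_chunk <- function(pos, params, thermo, mix, n_steps, sample_interval,
                       traj_interval, geometry, shell, box_L, delta,
                       ideal_gas) {
  gcmc_run_cpp(pos, params$epsilon, params$zeta, params$lam, params$kappa,
               thermo$T_star, thermo$mu_star,
               if (geometry == "shell") 0L else 1L,
               if (geometry == "shell") shell$R_inn else 0,
               if (geometry == "shell") shell$R_out else 0,
               box_L, mix$p_displacement, delta,
               n_steps, sample_interval, traj_interval, ideal_gas)
}

#' Grand-canonical Monte Carlo simulation
#'
#' Metropolis GCMC in the (mu, V, T) ensemble for the SALR fluid, either
#' confined in a hard-wall spherical shell (`geometry = "shell"`) or in a
#' periodic cubic box (`geometry = "box"`, used for bulk reference runs).
#' Trial moves are single-particle displacements (uniform in a cube of
#' half-width `delta`) and insertions/deletions with the standard
#' grand-canonical acceptance rules; the activity is
#' \eqn{z = \exp(\mu^*/T^*)/\sigma^3} (de Broglie wavelength taken equal to
#' sigma) and pairs with the geometric volume of the insertion region.
#'
#' @param params a [salr_params()].
#' @param thermo a [thermo_state()].
#' @param shell a [shell_geometry()] (shell geometry).
#' @param box_L box edge in sigma (box geometry).
#' @param geometry `"shell"` or `"box"`.
#' @param mix a [move_mix()].
#' @param schedule a [run_schedule()].
#' @param init initial [configuration()] (default: empty system).
#' @param delta maximum displacement half-width in sigma, fixed for the whole
#'   run (default 0.5; no mid-run tuning, preserving detailed balance). Set
#'   `tune_delta = TRUE` to adapt delta toward 30--50% displacement
#'   acceptance during equilibration only, freezing it for production.
#' @param ideal_gas disable all pair interactions (walls only); the particle
#'   number is then Poisson with mean z * V.
#' @param tune_delta see `delta`.
#' @return A `gcmc` object: list with `observables` (data.frame of step, N,
#'   U, u_star, rho_star over production), `final` configuration,
#'   `trajectory` (list of configurations), `acceptance` counters, `delta`,
#'   energy bookkeeping fields `U` and `U_recomputed`, and the inputs.
#' @examples
#' sh <- shell_geometry(6, 11)
#' run <- run_gcmc(shell = sh, thermo = thermo_state(0.35, -2.17),
#'                 schedule = run_schedule(2e4, 2e4, 1e3, seed = 7))
#' summary(run)
#' @export
run_gcmc <- function(params = salr_params(), thermo = thermo_state(),
                     shell = NULL, box_L = NULL,
                     geometry = c("shell", "box"),
                     mix = move_mix(), schedule = run_schedule(),
                     init = NULL, delta = 0.5, ideal_gas = FALSE,
                     tune_delta = FALSE) {
  geometry <- match.arg(geometry)
  if (thermo$T_star <= 0) stop("T_star must be positive")
  if (geometry == "shell") {
    if (is.null(shell)) stop("shell geometry requires a shell_geometry()")
    box_L <- 0
  } else {
    if (is.null(box_L) || box_L <= 0) stop("box geometry requires box_L > 0")
    if (box_L < 2 * params$kappa)
      warning("box_L < 2*kappa: minimum image truncates the repulsive tail")
  }
  pos <- if (is.null(init)) matrix(numeric(0), ncol = 3) else as_positions(init)

  set.seed(schedule$seed)
  steps_done <- 0

  # equilibration (optionally with delta adaptation in short frozen stages)
  n_eq <- schedule$n_equilibration
  if (n_eq > 0) {
    if (tune_delta) {
      n_stage <- max(1, ceiling(n_eq / 10))
      remaining <- n_eq
      while (remaining > 0) {
        n_now <- min(n_stage, remaining)
        res <- gcmc_chunk(pos, params, thermo, mix, n_now, 0, 0,
                          geometry, shell, box_L, delta, ideal_gas)
        pos <- res$positions
        rate <- res$acc[["disp_acc"]] / max(1, res$acc[["disp_try"]])
        if (rate < 0.3) delta <- max(0.05, delta * 0.8)
        else if (rate > 0.5) delta <- min(2.0, delta * 1.25)
        remaining <- remaining - n_now
      }
    } else {
      res <- gcmc_chunk(pos, params, thermo, mix, n_eq, 0, 0,
                        geometry, shell, box_L, delta, ideal_gas)
      pos <- res$positions
    }
    steps_done <- n_eq
  }

  res <- gcmc_chunk(pos, params, thermo, mix, schedule$n_production,
                    schedule$sample_interval, schedule$traj_interval,
                    geometry, shell, box_L, delta, ideal_gas)

  N <- res$log_N
  U <- res$log_U
  rho <- if (geometry == "shell") number_density(N, shell) else N / box_L^3
  obs <- data.frame(step = res$log_step, N = N, U = U,
                    u_star = ifelse(N > 0, U / N, 0), rho_star = rho)

  traj <- lapply(res$trajectory, configuration,
                 shell = if (geometry == "shell") shell else NULL)
  structure(list(
    observables = obs,
    final = configuration(res$positions,
                          shell = if (geometry == "shell") shell else NULL),
    trajectory = traj,
    U = res$U, U_recomputed = res$U_recomputed,
    acceptance = res$acc, delta = delta,
    params = params, thermo = thermo, shell = shell, box_L = box_L,
    geometry = geometry, mix = mix, schedule = schedule,
    ideal_gas = ideal_gas
  ), class = "gcmc")
}

#' @export
print.gcmc <- function(x, ...) {
  cat(sprintf("GCMC run (%s geometry): %g equilibration + %g production steps\n",
              x$geometry, x$schedule$n_equilibration, x$schedule$n_production))
  cat(sprintf("  T* = %g, mu* = %g, final N = %d, final U = %.4f eps\n",
              x$thermo$T_star, x$thermo$mu_star, nrow(x$final), x$U))
  invisible(x)
}

#' @export
summary.gcmc <- function(object, ...) {
  obs <- object$observables
  out <- list(
    geometry = object$geometry,
    T_star = object$thermo$T_star, mu_star = object$thermo$mu_star,
    n_samples = nrow(obs),
    mean_N = mean(obs$N), sd_N = stats::sd(obs$N),
    mean_rho = mean(obs$rho_star),
    mean_u = mean(obs$u_star),
    energy_drift = abs(object$U - object$U_recomputed),
    acceptance = object$acceptance, delta = object$delta
  )
  class(out) <- "summary.gcmc"
  out
}

#' @export
print.summary.gcmc <- function(x, ...) {
  cat(sprintf("GCMC summary (%s): T* = %g, mu* = %g\n",
              x$geometry, x$T_star, x$mu_star))
  cat(sprintf("  <N> = %.2f (sd %.2f), <rho*> = %.4f, <u*> = %.4f over %d samples\n",
              x$mean_N, x$sd_N, x$mean_rho, x$mean_u, x$n_samples))
  cat(sprintf("  |U_incremental - U_recomputed| = %.3g eps\n", x$energy_drift))
  a <- x$acceptance
  cat(sprintf("  acceptance: disp %.1f%%, ins %.1f%%, del %.1f%% (delta = %.2f)\n",
              100 * a[["disp_acc"]] / max(1, a[["disp_try"]]),
              100 * a[["ins_acc"]] / max(1, a[["ins_try"]]),
              100 * a[["del_acc"]] / max(1, a[["del_try"]]), x$delta))
  invisible(x)
}

#' @export
plot.gcmc <- function(x, which = c("N", "u_star"), ...) {
  which <- match.arg(which)
  obs <- x$observables
  graphics::plot(obs$step, obs[[which]], type = "l",
                 xlab = "MC step", ylab = which, ...)
  invisible(x)
}

#' Run GCMC until the particle number plateaus
#'
#' Repeats production chunks from an empty start until the chunk-averaged
#' particle number changes by less than `tol` (relative) between consecutive
#' chunks, then returns the run over the final chunk. Used to locate the
#' equilibrium filling of a shell without fixing the equilibration length in
#' advance.
#'
#' @param params,thermo,shell,mix as in [run_gcmc()].
#' @param chunk_steps steps per chunk (the plateau window).
#' @param max_chunks hard cap on the number of chunks.
#' @param min_chunks minimum chunks before testing for the plateau.
#' @param tol relative change in chunk-mean N that counts as flat.
#' @param sample_interval observable sampling interval within chunks.
#' @param seed RNG seed.
#' @return List with `mean_N` (plateau chunk average), `history` (per-chunk
#'   mean N), `n_steps_total`, `converged`, and `final` configuration.
#' @export
gcmc_plateau <- function(params = salr_params(), thermo = thermo_state(),
                         shell, mix = move_mix(), chunk_steps = 1e6,
                         max_chunks = 40, min_chunks = 3, tol = 0.01,
                         sample_interval = 1e3, seed = 1L) {
  set.seed(seed)
  pos <- matrix(numeric(0), ncol = 3)
  means <- numeric(0)
  converged <- FALSE
  final <- NULL
  for (ch in seq_len(max_chunks)) {
    res <- gcmc_chunk(pos, params, thermo, mix, chunk_steps, sample_interval,
                      0, "shell", shell, 0, 0.5, FALSE)
    pos <- res$positions
    means <- c(means, mean(res$log_N))
    final <- res
    if (ch >= min_chunks) {
      rel <- abs(means[ch] - means[ch - 1]) / max(1, means[ch])
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  list(mean_N = means[length(means)], history = means,
       n_steps_total = length(means) * chunk_steps, converged = converged,
       final = configuration(pos, shell = shell))
}
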