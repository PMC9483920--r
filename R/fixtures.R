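# Ideal decorated configurations of packing-model structures: geometric
# stand-ins for equilibrated cluster microstates, used to test the density
# and topology analysis without simulation.

# minimum distance from each point (rows of P) to a polyline (rows of L)
dist_to_polyline <- function(P, L) {
  if (nrow(L) == 1) {
    return(sqrt(rowSums(sweep(P, 2, L[1, ])^2)))
  }
  dmin <- rep(Inf, nrow(P))
  for (s in seq_len(nrow(L) - 1)) {
    a <- L[s, ]; b <- L[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    Pa <- sweep(P, 2, a)
    t <- if (len2 < 1e-300) rep(0, nrow(P)) else pmin(1, pmax(0, (Pa %*% ab) / len2))
    proj <- outer(as.numeric(t), ab)
    d <- sqrt(rowSums((Pa - proj)^2))
    dmin <- pmin(dmin, d)
  }
  dmin
}

# random sequential addition inside a tube: uniform proposals in the
# bounding box, kept when inside the tube and >= 1 sigma from all accepted
rsa_fill <- function(L, rad, density, lo, hi) {
  span <- hi - lo
  # tube volume by Monte Carlo over the bounding box
  probe <- matrix(stats::runif(3 * 4000), ncol = 3)
  probe <- sweep(sweep(probe, 2, span, "*"), 2, lo, "+")
  vfrac <- mean(dist_to_polyline(probe, L) <= rad)
  target <- round(density * vfrac * prod(span))
  if (target == 0) return(matrix(numeric(0), ncol = 3))
  acc <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(acc) < target && tries < 400 * target) {
    m <- min(2000, 400 * target - tries)
    cand <- matrix(stats::runif(3 * m), ncol = 3)
    cand <- sweep(sweep(cand, 2, span, "*"), 2, lo, "+")
    tries <- tries + m
    cand <- cand[dist_to_polyline(cand, L) <= rad, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      if (nrow(acc) >= target) break
      p <- cand[r, ]
      if (nrow(acc) == 0 || min(rowSums(sweep(acc, 2, p)^2)) >= 1)
        acc <- rbind(acc, p)
    }
  }
  if (nrow(acc) < target)
    warning("rsa fill saturated below the target density")
  unname(acc)
}

# face-centered-cubic lattice sites filling a bounding box at a given
# number density (4 sites per cubic cell of edge a = (4/rho)^(1/3))
fcc_sites <- function(lo, hi, density) {
  a <- (4 / density)^(1 / 3)
  ii <- seq(floor(lo[1] / a) - 1, ceiling(hi[1] / a) + 1)
  jj <- seq(floor(lo[2] / a) - 1, ceiling(hi[2] / a) + 1)
  kk <- seq(floor(lo[3] / a) - 1, ceiling(hi[3] / a) + 1)
  base <- as.matrix(expand.grid(x = ii * a, y = jj * a, z = kk * a))
  offs <- rbind(c(0, 0, 0), c(0.5, 0.5, 0) * a, c(0.5, 0, 0.5) * a,
                c(0, 0.5, 0.5) * a)
  do.call(rbind, lapply(seq_len(4), function(o) sweep(base, 2, offs[o, ], "+")))
}

#' Decorate center-line curves with particles
#'
#' Fills the tube volume around each center-line (and the ball around each
#' sphere point) with particles at the target number density: an FCC
#' lattice restricted to the tube interior, with positional jitter, subject
#' to the hard-core constraint (no pair closer than 1 sigma) and clipped to
#' the shell. Deterministic given the seed.
#'
#' @param curves list of components as produced by [generate_centerline()],
#'   or any list of elements with fields `points` (polyline matrix) and
#'   `type` (`"sphere"` elements are filled as balls of `sphere_radius`).
#' @param shell optional [shell_geometry()] used for clipping.
#' @param tube_radius tube radius in sigma (default 1.5, the equilibrium
#'   cylindrical cluster radius r0).
#' @param sphere_radius radius of spherical-cluster balls (default
#'   `tube_radius`).
#' @param target_density particles per sigma^3 inside the tubes (default
#'   0.9; must stay below close packing sqrt(2)).
#' @param jitter maximum radial displacement applied to each lattice site.
#' @param method `"fcc"` (default; lattice fill, reaches dense packings) or
#'   `"rsa"` (random sequential addition: statistically uniform tube
#'   filling, limited to moderate densities ~<= 0.6 per sigma^3).
#' @param seed RNG seed.
#' @return A [configuration()]; the per-curve component index is attached
#'   as attribute `"curve_id"`.
#' @export
decorate_curves <- function(curves, shell = NULL, tube_radius = 1.5,
                            sphere_radius = tube_radius,
                            target_density = 0.9, jitter = 0.1,
                            method = c("fcc", "rsa"), seed = 1L) {
  method <- match.arg(method)
  if (target_density < 0) stop("target_density must be >= 0")
  if (target_density > sqrt(2))
    stop("target_density exceeds close packing for unit hard spheres")
  if (jitter > 0.3 * tube_radius)
    stop("jitter must stay below 0.3 * tube_radius")
  set.seed(seed)
  if (target_density == 0)
    return(configuration(NULL, shell = shell))
  pts <- list(); ids <- integer(0)
  for (ci in seq_along(curves)) {
    cv <- curves[[ci]]
    rad <- if (identical(cv$type, "sphere")) sphere_radius else tube_radius
    L <- cv$points
    lo <- apply(L, 2, min) - rad - 0.5
    hi <- apply(L, 2, max) + rad + 0.5
    if (method == "fcc") {
      sites <- fcc_sites(lo, hi, target_density)
      keep <- dist_to_polyline(sites, L) <= rad
      sites <- sites[keep, , drop = FALSE]
    } else {
      sites <- rsa_fill(L, rad, target_density, lo, hi)
    }
    if (nrow(sites)) {
      pts[[length(pts) + 1]] <- sites
      ids <- c(ids, rep(ci, nrow(sites)))
    }
  }
  if (!length(pts)) return(configuration(NULL, shell = shell))
  pos <- do.call(rbind, pts)

  # jitter (uniform in a ball of radius `jitter`), with hard-core repair:
  # re-draw the jitter of offending particles, then drop unresolved ones
  if (jitter > 0 && nrow(pos) > 0) {
    jit <- function(n) {
      v <- matrix(stats::rnorm(3 * n), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      v * jitter * stats::runif(n)^(1 / 3)
    }
    jpos <- pos + jit(nrow(pos))
    for (pass in 1:5) {
      d <- as.matrix(stats::dist(jpos))
      diag(d) <- Inf
      bad <- which(apply(d, 1, min) < 1)
      if (!length(bad)) break
      jpos[bad, ] <- pos[bad, , drop = FALSE] + jit(length(bad))
    }
    d <- as.matrix(stats::dist(jpos))
    diag(d) <- Inf
    drop <- integer(0)
    repeat {
      mins <- apply(d, 1, min)
      if (all(mins >= 1)) break
      w <- which.min(mins)
      drop <- c(drop, w)
      d[w, ] <- Inf; d[, w] <- Inf
    }
    if (length(drop)) { jpos <- jpos[-drop, , drop = FALSE]; ids <- ids[-drop] }
    pos <- jpos
  }

  if (!is.null(shell) && nrow(pos) > 0) {
    r <- sqrt(rowSums(pos^2))
    keep <- r >= shell$R_inn & r <= shell$R_out
    pos <- pos[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  cfg <- configuration(pos, shell = shell)
  attr(cfg, "curve_id") <- ids
  cfg
}

#' Decorate a derived structure
#'
#' Convenience wrapper: builds the center-lines of a derived structure in a
#' shell and decorates them with particles.
#'
#' @param structure a [derived_connectivity()] result.
#' @param shell a [shell_geometry()].
#' @param ... passed to [decorate_curves()].
#' @return A [configuration()].
#' @examples
#' ds <- derived_connectivity(9, 1, 1, 0)
#' cfg <- decorate(ds, shell_geometry(6, 11), seed = 2)
#' @export
decorate <- function(structure, shell, ...) {
  cl <- generate_centerline(structure, shell)
  decorate_curves(cl, shell = shell, ...)
}

#' Worked-example fixture suite
#'
#' One decorated fixture per structure of the four studied shells, with the
#' expected cluster summary (component count, class multiset, open-end
#' count) from the packing model. Used as the cross-module consistency
#' suite: cluster analysis of each decorated configuration must recover the
#' expectation exactly.
#'
#' @param seed base RNG seed (each entry offsets it deterministically).
#' @return Named list of entries: `name`, `shell`, `structure`,
#'   `expected` (list with `n_clusters`, `classes` sorted class vector,
#'   `n_open_ends`), and `spec` (decoration arguments).
#' @export
worked_example_suite <- function(seed = 100L) {
  shells <- list(s3_8 = shell_geometry(3, 8), s5_10 = shell_geometry(5, 10),
                 s6_11 = shell_geometry(6, 11), s7.5_12.5 = shell_geometry(7.5, 12.5))
  entries <- list(
    # small shell, n = 6 (theta = pi/3): tori-only, tori+2 spheres, hybrid
    list(name = "n6_all_tori", shell = "s3_8", n = 6, l_A = 0, l_B = 0, m = 0),
    list(name = "n6_two_tori_two_spheres", shell = "s3_8", n = 6, l_A = 2, l_B = 2, m = 0),
    list(name = "n6_theta_loop", shell = "s3_8", n = 6, l_A = 0, l_B = 0, m = 2),
    list(name = "n6_hybrid_half", shell = "s3_8", n = 6, l_A = 2, l_B = 0, m = 1),
    # n = 8 shell (theta = pi/4)
    list(name = "n8_all_tori", shell = "s5_10", n = 8, l_A = 0, l_B = 0, m = 0),
    list(name = "n8_three_tori_two_spheres", shell = "s5_10", n = 8, l_A = 2, l_B = 2, m = 0),
    list(name = "n8_hybrid_half", shell = "s5_10", n = 8, l_A = 2, l_B = 0, m = 1),
    # n = 9 shell: generating structure and all pure rotations
    list(name = "n9_m0", shell = "s6_11", n = 9, l_A = 1, l_B = 1, m = 0),
    list(name = "n9_m1", shell = "s6_11", n = 9, l_A = 1, l_B = 1, m = 2),
    list(name = "n9_m2", shell = "s6_11", n = 9, l_A = 1, l_B = 1, m = 4),
    list(name = "n9_m3", shell = "s6_11", n = 9, l_A = 1, l_B = 1, m = 6),
    list(name = "n9_m4", shell = "s6_11", n = 9, l_A = 1, l_B = 1, m = 8),
    # n = 11 shell: generating structure and all pure rotations
    list(name = "n11_m0", shell = "s7.5_12.5", n = 11, l_A = 1, l_B = 1, m = 0),
    list(name = "n11_m1", shell = "s7.5_12.5", n = 11, l_A = 1, l_B = 1, m = 2),
    list(name = "n11_m2", shell = "s7.5_12.5", n = 11, l_A = 1, l_B = 1, m = 4),
    list(name = "n11_m3", shell = "s7.5_12.5", n = 11, l_A = 1, l_B = 1, m = 6),
    list(name = "n11_m4", shell = "s7.5_12.5", n = 11, l_A = 1, l_B = 1, m = 8),
    list(name = "n11_m5", shell = "s7.5_12.5", n = 11, l_A = 1, l_B = 1, m = 10)
  )
  out <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    ds <- derived_connectivity(e$n, e$l_A, e$l_B, e$m)
    classes <- sort(vapply(ds$components, function(cc)
      switch(cc$type, sphere = "spherical", closed = "closed-tube",
             open = "open-tube"), ""))
    out[[e$name]] <- list(
      name = e$name, shell = shells[[e$shell]], structure = ds,
      expected = list(n_clusters = ds$n_components, classes = classes,
                      n_open_ends = ds$n_open_ends),
      spec = list(tube_radius = 1.5, target_density = 0.9, jitter = 0.1,
                  seed = seed + i))
  }
  out
}
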