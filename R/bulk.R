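# Analysis helpers for bulk (periodic-box) configurations of the
# cylindrical-cluster hexagonal phase: inter-cluster spacing from the
# intermediate-range peak of the pair distance distribution, and the
# cylinder radius from unwrapped per-cluster local-axis offsets.

#' Inter-cluster spacing of a bulk configuration
#'
#' Estimates the characteristic distance between neighboring cylindrical
#' cluster axes (the hexagonal lattice constant l0) as the location of the
#' intermediate-range peak of g(r): pair counts are binned, divided by the
#' r^2 shell weight, and the maximum in the search window is refined by
#' quadratic interpolation.
#'
#' @param config position matrix (periodic box coordinates).
#' @param box_L box edge in sigma.
#' @param window search window for the inter-cluster peak, beyond the
#'   intra-cluster range and below half the box edge.
#' @param bin histogram bin width.
#' @return Peak position in sigma.
#' @export
bulk_spacing <- function(config, box_L, window = c(4, 8), bin = 0.15) {
  pos <- as_positions(config)
  hi <- min(window[2], box_L / 2 - 1e-6)
  d <- pair_distances_cpp(pos, hi, 1L, box_L)
  d <- d[d >= window[1]]
  if (length(d) < 50) stop("too few pairs in the search window")
  br <- seq(window[1], hi + bin, by = bin)
  h <- graphics::hist(d, breaks = br, plot = FALSE)
  gr <- h$counts / h$mids^2
  i <- which.max(gr)
  # quadratic refinement on the log-counts around the peak
  if (i > 1 && i < length(gr) && all(gr[c(i - 1, i + 1)] > 0)) {
    y <- log(gr[(i - 1):(i + 1)])
    denom <- y[1] - 2 * y[2] + y[3]
    off <- if (abs(denom) > 1e-12) 0.5 * (y[1] - y[3]) / denom else 0
    h$mids[i] + off * bin
  } else h$mids[i]
}

#' Cylinder radius of bulk clusters
#'
#' Unwraps each periodic cluster and pools the per-particle perpendicular
#' offsets from the local skeleton axis; reports the uniform-disk
#' calibrated radius (see [tube_radius()]).
#'
#' @param config position matrix (periodic box coordinates).
#' @param box_L box edge.
#' @param r_bond bond cutoff.
#' @param min_size ignore clusters smaller than this.
#' @return List with `radius` (calibrated), `sd`, and `n_clusters` used.
#' @export
bulk_tube_radius <- function(config, box_L, r_bond = 1.5, min_size = 15) {
  cs <- build_clusters(config, r_bond = r_bond, box_L = box_L)
  perp <- numeric(0)
  used <- 0L
  for (k in seq_len(cs$n_clusters)) {
    members <- which(cs$labels == k)
    if (length(members) < min_size) next
    P <- unwrap_cluster(cs$positions, cs$graph, members, box_L)
    perp <- c(perp, local_axis_offsets(P)$perp)
    used <- used + 1L
  }
  if (!used) stop("no cluster of the requested minimum size")
  list(radius = 1.5 * mean(perp), sd = 1.5 * stats::sd(perp),
       n_clusters = used)
}
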