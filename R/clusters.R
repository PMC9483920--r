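#' Identify bonded clusters in a configuration
#'
#' Particles are vertices of a bond graph with edges between pairs closer
#' than `r_bond`; clusters are its connected components. The default cutoff
#' is the attractive-well range lambda*sigma = 1.5: particles inside each
#' other's square well count as bonded.
#'
#' @param config a [configuration()] or position matrix.
#' @param r_bond bond distance in sigma (> 1).
#' @param box_L optional periodic box edge; distances then use the minimum
#'   image convention (bulk configurations).
#' @return A `cluster_set`: list with `labels` (per-particle cluster id),
#'   `n_clusters`, `sizes`, `positions`, `graph` (igraph bond graph),
#'   `r_bond`, `shell`, `box_L`.
#' @export
build_clusters <- function(config, r_bond = 1.5, box_L = NULL) {
  stopifnot(r_bond > 1)
  pos <- as_positions(config)
  n <- nrow(pos)
  shell <- attr(config, "shell")
  if (n == 0) {
    return(structure(list(labels = integer(0), n_clusters = 0L,
                          sizes = integer(0), positions = pos,
                          graph = igraph::make_empty_graph(0, directed = FALSE),
                          r_bond = r_bond, shell = shell, box_L = box_L),
                     class = "cluster_set"))
  }
  if (is.null(box_L)) {
    d <- as.matrix(stats::dist(pos))
  } else {
    d <- minimum_image_dist(pos, box_L)
  }
  adj <- d <= r_bond
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = NULL)
  # keep distances as weights for geodesic computations
  ed <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ed)) igraph::E(g)$weight <- d[cbind(ed[, 1], ed[, 2])]
  comp <- igraph::components(g)
  structure(list(labels = as.integer(comp$membership),
                 n_clusters = as.integer(comp$no),
                 sizes = as.integer(comp$csize),
                 positions = pos, graph = g,
                 r_bond = r_bond, shell = shell, box_L = box_L),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d particles in %d cluster(s) (r_bond = %g)\n",
              nrow(x$positions), x$n_clusters, x$r_bond))
  if (x$n_clusters > 0)
    cat("  sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = ", "), "\n")
  invisible(x)
}

# all minimum-image pair distances as a dense matrix (bulk analysis)
minimum_image_dist <- function(pos, box_L) {
  n <- nrow(pos)
  d2 <- matrix(0, n, n)
  for (a in 1:3) {
    da <- outer(pos[, a], pos[, a], "-")
    da <- da - box_L * round(da / box_L)
    d2 <- d2 + da^2
  }
  sqrt(d2)
}

# unwrap a periodic cluster: BFS from the first member, placing each newly
# reached particle at its parent's position plus the minimum-image step
unwrap_cluster <- function(pos, g, members, box_L) {
  sub <- igraph::induced_subgraph(g, members)
  bb <- igraph::bfs(sub, root = 1, father = TRUE)
  order_ <- as.integer(bb$order)
  parent <- as.integer(bb$father)
  up <- pos[members, , drop = FALSE]
  for (v in order_) {
    p <- parent[v]
    if (is.na(p)) next
    step <- up[v, ] - up[p, ]
    step <- step - box_L * round(step / box_L)
    up[v, ] <- up[p, ] + step
  }
  up
}

# local tube radius by neighborhood PCA.  Two passes per particle: a rough
# axis from the spherical neighborhood, then an axial slab (all cluster
# particles within nb_radius of the particle ALONG the rough axis,
# regardless of perpendicular offset) whose centroid is unbiased across the
# cross-section; the particle's perpendicular distance to the slab axis is
# recorded.  Returns per-particle perpendicular distances and axis foot
# points.
local_axis_offsets <- function(P, nb_radius = 2.5) {
  n <- nrow(P)
  d <- as.matrix(stats::dist(P))
  perp <- numeric(n)
  foot <- matrix(0, n, 3)
  fit_axis <- function(Q) {
    ctr <- colMeans(Q)
    ax <- svd(sweep(Q, 2, ctr), nu = 0, nv = 1)$v[, 1]
    list(ctr = ctr, ax = ax)
  }
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= nb_radius)
    Q <- P[nb, , drop = FALSE]
    if (length(nb) < 4) {
      ctr <- colMeans(Q)
      perp[i] <- sqrt(sum((P[i, ] - ctr)^2))
      foot[i, ] <- ctr
      next
    }
    f1 <- fit_axis(Q)
    # slab pass: symmetric across the cross-section, so the refit centroid
    # sits on the tube axis instead of being dragged toward particle i
    tall <- sweep(P, 2, f1$ctr) %*% f1$ax
    ti <- tall[i]
    slab <- which(abs(tall - ti) <= nb_radius & d[i, ] <= 2 * nb_radius)
    if (length(slab) >= 4) f1 <- fit_axis(P[slab, , drop = FALSE])
    rel <- P[i, ] - f1$ctr
    t <- sum(rel * f1$ax)
    foot[i, ] <- f1$ctr + t * f1$ax
    perp[i] <- sqrt(sum((rel - t * f1$ax)^2))
  }
  list(perp = perp, foot = foot)
}

#' Tube radius of a cluster
#'
#' Mean perpendicular distance of member particles from the local skeleton
#' axis (estimated by neighborhood PCA). With `calibration = "uniform"`
#' (default) the raw mean is multiplied by 3/2, the uniform-disk moment
#' correction (a uniformly filled tube of radius R has mean perpendicular
#' distance 2R/3, so the calibrated estimate reads R); `"none"` reports the
#' raw mean (a thin hollow tube of radius R then reads R). For spherical
#' clusters the distance from the centroid is used instead (uniform-ball
#' correction 4/3).
#'
#' @param positions position matrix of one cluster's particles.
#' @param class cluster classification (`"spherical"` switches to centroid
#'   distances).
#' @param calibration `"uniform"` or `"none"`.
#' @param nb_radius neighborhood radius for the local axis fit.
#' @return List with `radius` and `sd` (same calibration applied).
#' @export
tube_radius <- function(positions, class = "tube",
                        calibration = c("uniform", "none"), nb_radius = 2.5) {
  calibration <- match.arg(calibration)
  P <- as_positions(positions)
  if (identical(class, "spherical")) {
    ctr <- colMeans(P)
    r <- sqrt(rowSums(sweep(P, 2, ctr)^2))
    fac <- if (calibration == "uniform") 4 / 3 else 1
  } else {
    r <- local_axis_offsets(P, nb_radius)$perp
    fac <- if (calibration == "uniform") 3 / 2 else 1
  }
  list(radius = fac * mean(r), sd = fac * stats::sd(r))
}

#' Classify the shape of one cluster
#'
#' Coarse topology of a particle cluster: `"spherical"` (compact blob),
#' `"closed-tube"` (loop), `"open-tube"` (two free ends), or `"irregular"`
#' (branching; never silently misclassified). Small clusters (< 5
#' particles) are spherical by default. A cluster is spherical when its
#' geodesic extent (longest graph geodesic through the bond network) does
#' not exceed 1.5 times its tube diameter; tubes are closed when removing
#' one interior cross-section leaves them connected, open when it splits
#' them in two.
#'
#' @param positions position matrix of the cluster's particles (unwrapped
#'   if periodic).
#' @param r_bond bond cutoff used for the intra-cluster graph.
#' @return List with `class`, `n_ends`, `ends` (2 x 3 matrix of end
#'   centroids for open tubes, else NULL), `extent` (geodesic), `radius`
#'   (calibrated tube radius estimate).
#' @export
classify_cluster <- function(positions, r_bond = 1.5) {
  P <- as_positions(positions)
  n <- nrow(P)
  rad <- tube_radius(P, class = "tube")$radius
  if (n < 5)
    return(list(class = "spherical", n_ends = 0L, ends = NULL,
                extent = if (n > 1) max(stats::dist(P)) else 0,
                radius = tube_radius(P, class = "spherical")$radius))
  d <- as.matrix(stats::dist(P))
  adj <- d <= r_bond
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ed <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- d[cbind(ed[, 1], ed[, 2])]
  # double sweep for the longest geodesic
  d0 <- igraph::distances(g, v = 1)[1, ]
  p1 <- which.max(d0)
  d1 <- igraph::distances(g, v = p1)[1, ]
  p2 <- which.max(d1)
  L <- d1[p2]

  if (L <= 1.5 * 2 * rad) {
    return(list(class = "spherical", n_ends = 0L, ends = NULL, extent = L,
                radius = tube_radius(P, class = "spherical")$radius))
  }
  # cut one interior cross-section: particles at mid arc distance from the
  # sweep endpoint form one cross-sectional slab on a path but two opposite
  # slabs on a loop, so only the connected band piece containing the first
  # band particle is removed -- a path then splits in two, a loop stays whole
  band <- which(abs(d1 - L / 2) <= 1.0)
  bsub <- igraph::components(igraph::induced_subgraph(g, band))$membership
  piece <- band[bsub == bsub[1]]
  rest <- setdiff(seq_len(n), piece)
  ncomp <- if (length(rest) == 0) 0L
           else igraph::components(igraph::induced_subgraph(g, rest))$no
  if (ncomp == 1) {
    cls <- "closed-tube"; n_ends <- 0L; ends <- NULL
  } else if (ncomp == 2) {
    cls <- "open-tube"; n_ends <- 2L
    e1 <- colMeans(P[d1 <= 1.5, , drop = FALSE])
    e2 <- colMeans(P[sqrt(rowSums(sweep(P, 2, P[p2, ])^2)) <= 1.5, , drop = FALSE])
    ends <- rbind(e1, e2)
  } else {
    cls <- "irregular"; n_ends <- NA_integer_; ends <- NULL
  }
  list(class = cls, n_ends = n_ends, ends = ends, extent = L, radius = rad)
}

#' Full cluster analysis of a configuration
#'
#' Combines [build_clusters()] and [classify_cluster()]: identifies bonded
#' clusters, classifies each, and summarizes sizes, classes, free ends,
#' centroids and radii.
#'
#' @param config a [configuration()] or position matrix.
#' @param r_bond bond cutoff (sigma).
#' @param box_L optional periodic box edge (clusters are unwrapped before
#'   classification).
#' @return A `cluster_topology` object: the `cluster_set` plus a
#'   data.frame `summary` (cluster, size, class, n_ends, radius) and
#'   per-cluster details in `details`.
#' @examples
#' cfg <- decorate(derived_connectivity(9, 1, 1, 0), shell_geometry(6, 11),
#'                 seed = 5)
#' cluster_topology(cfg)$summary
#' @export
cluster_topology <- function(config, r_bond = 1.5, box_L = NULL) {
  cs <- build_clusters(config, r_bond = r_bond, box_L = box_L)
  details <- vector("list", cs$n_clusters)
  rows <- list()
  for (k in seq_len(cs$n_clusters)) {
    members <- which(cs$labels == k)
    P <- if (is.null(box_L)) cs$positions[members, , drop = FALSE]
         else unwrap_cluster(cs$positions, cs$graph, members, box_L)
    cl <- classify_cluster(P, r_bond = r_bond)
    cl$members <- members
    cl$centroid <- colMeans(P)
    details[[k]] <- cl
    rows[[k]] <- data.frame(cluster = k, size = length(members),
                            class = cl$class, n_ends = cl$n_ends,
                            radius = cl$radius, extent = cl$extent)
  }
  structure(list(clusters = cs,
                 summary = if (length(rows)) do.call(rbind, rows)
                           else data.frame(cluster = integer(0), size = integer(0),
                                           class = character(0), n_ends = integer(0),
                                           radius = numeric(0), extent = numeric(0)),
                 details = details),
            class = "cluster_topology")
}

#' @export
print.cluster_topology <- function(x, ...) {
  cat(sprintf("Cluster topology: %d cluster(s)\n", x$clusters$n_clusters))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Mean spacing between neighboring tube axes
#'
#' For each skeleton (local-axis) point of every cluster, the distance to
#' the nearest skeleton point of a different cluster -- or of a different
#' fold of the same coiled cluster (a point much farther along the tube
#' than its straight-line distance) -- averaged over all points.
#'
#' @param topo a [cluster_topology()] result (non-periodic).
#' @param fold_factor a same-cluster point counts as a different fold when
#'   its graph geodesic distance exceeds `fold_factor` times its Euclidean
#'   distance.
#' @param max_points skeleton subsample cap per cluster.
#' @return Mean nearest-neighbor axis spacing in sigma.
#' @export
cluster_spacing <- function(topo, fold_factor = 2.5, max_points = 300) {
  cs <- topo$clusters
  K <- cs$n_clusters
  single_tube <- K == 1 && topo$summary$class[1] %in% c("open-tube", "closed-tube")
  if (K < 2 && !single_tube)
    stop("cluster_spacing needs >= 2 clusters or a single coiled tube")
  # quasi-2-D skeleton: with a shell, project particles onto the mid-shell
  # sphere before the local-axis fit and reproject the feet, removing the
  # radial component of the scatter
  R_c <- if (!is.null(cs$shell)) cs$shell$R_c else NULL
  skel <- list(); lab <- list(); idx <- list()
  for (k in seq_len(K)) {
    members <- topo$details[[k]]$members
    P <- cs$positions[members, , drop = FALSE]
    if (topo$summary$class[k] == "spherical") {
      fp <- matrix(colMeans(P), ncol = 3)
      id <- NA_integer_
    } else {
      if (!is.null(R_c)) {
        S <- R_c * P / sqrt(rowSums(P^2))
        fp <- local_axis_offsets(S, nb_radius = 2.0)$foot
        fp <- R_c * fp / sqrt(rowSums(fp^2))
      } else {
        fp <- local_axis_offsets(P)$foot
      }
      id <- members
    }
    if (nrow(fp) > max_points) {
      keep <- seq(1, nrow(fp), length.out = max_points)
      fp <- fp[round(keep), , drop = FALSE]
      if (!all(is.na(id))) id <- id[round(keep)]
    }
    skel[[k]] <- fp
    lab[[k]] <- rep(k, nrow(fp))
    idx[[k]] <- if (all(is.na(id))) rep(NA_integer_, nrow(fp)) else id
  }
  S <- do.call(rbind, skel)
  SL <- unlist(lab)
  SI <- unlist(idx)
  dS <- as.matrix(stats::dist(S))
  # geodesic separations within clusters, for fold detection
  geo <- matrix(Inf, nrow(S), nrow(S))
  for (k in seq_len(K)) {
    w <- which(SL == k)
    if (all(is.na(SI[w]))) next
    gd <- igraph::distances(cs$graph, v = SI[w], to = SI[w])
    geo[w, w] <- gd
  }
  vals <- numeric(0)
  for (i in seq_len(nrow(S))) {
    other <- SL != SL[i] |
      (is.finite(geo[i, ]) & geo[i, ] > fold_factor * pmax(dS[i, ], 1e-9) &
         dS[i, ] > 2)
    other[i] <- FALSE
    if (any(other)) vals <- c(vals, min(dS[i, other]))
  }
  if (!length(vals))
    stop("no neighboring fold or cluster found (single compact cluster?)")
  mean(vals)
}
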