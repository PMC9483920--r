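#' Three-dimensional local-density accumulation grid
#'
#' A cubic grid of cells of edge ~sigma/2 covering the bounding cube of the
#' shell, `[-(R_out+0.5), +(R_out+0.5)]^3`; particle counts are accumulated
#' per cell over sampled configurations and averaged into a local density.
#'
#' @param shell a [shell_geometry()] (sets the covered cube), or pass
#'   `half_extent` directly.
#' @param cell_edge cell edge in sigma (default exactly 0.5).
#' @param half_extent half-edge of the covered cube (default R_out + 0.5).
#' @return A `density_field`: list with `origin`, `cell_edge`, `dims`,
#'   `counts` (3-D array), `n_samples`.
#' @export
density_field <- function(shell = NULL, cell_edge = 0.5, half_extent = NULL) {
  stopifnot(cell_edge > 0)
  if (is.null(half_extent)) {
    if (is.null(shell)) stop("provide a shell or half_extent")
    half_extent <- shell$R_out + 0.5
  }
  ncell <- ceiling(2 * half_extent / cell_edge)
  origin <- -ncell * cell_edge / 2   # symmetric cover, rounded up
  structure(list(origin = rep(origin, 3), cell_edge = cell_edge,
                 dims = rep(ncell, 3),
                 counts = array(0, dim = rep(ncell, 3)), n_samples = 0L),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("Density field: %d^3 cells of edge %g sigma, %d sample(s)\n",
              x$dims[1], x$cell_edge, x$n_samples))
  invisible(x)
}

#' Accumulate a configuration into a density field
#'
#' Each particle increments exactly one cell; the sample counter increases
#' by one (also for empty configurations).
#'
#' @param field a [density_field()].
#' @param config a [configuration()] or position matrix.
#' @return The updated field.
#' @export
accumulate_density <- function(field, config) {
  pos <- as_positions(config)
  field$n_samples <- field$n_samples + 1L
  if (nrow(pos) == 0) return(field)
  ijk <- floor(sweep(pos, 2, field$origin) / field$cell_edge) + 1
  if (any(ijk < 1) || any(ijk > matrix(field$dims, nrow(ijk), 3, byrow = TRUE)))
    stop("particle outside the density grid")
  lin <- (ijk[, 3] - 1) * field$dims[1] * field$dims[2] +
    (ijk[, 2] - 1) * field$dims[1] + ijk[, 1]
  tab <- tabulate(lin, nbins = prod(field$dims))
  field$counts <- field$counts + array(tab, dim = field$dims)
  field
}

#' Mean local density
#'
#' Per-cell density rho(cell) = counts / (n_samples * cell_volume); its
#' integral over the grid equals the sample-mean particle number exactly.
#'
#' @param field an accumulated [density_field()].
#' @return 3-D array of densities in sigma^-3.
#' @export
mean_density <- function(field) {
  if (field$n_samples < 1) stop("no samples accumulated")
  field$counts / (field$n_samples * field$cell_edge^3)
}

#' Smooth a density grid with a separable box filter
#'
#' One or more passes of a 3-cell moving average along each axis. Useful
#' before iso-surface extraction of sharply binarized fields, whose
#' staircase level sets otherwise overestimate surface areas; averaged
#' simulation densities are already smooth and normally need none.
#'
#' @param vals 3-D array (or [density_field()], smoothed in place).
#' @param passes number of box-filter passes.
#' @return Object of the same type with smoothed values.
#' @export
smooth_density <- function(vals, passes = 1) {
  fld <- NULL
  if (inherits(vals, "density_field")) { fld <- vals; vals <- fld$counts }
  box1 <- function(a, dim_) {
    idx <- seq_len(dim(a)[dim_])
    lo <- pmax(idx - 1, 1); hi <- pmin(idx + 1, dim(a)[dim_])
    pick <- function(w) switch(dim_, a[w, , , drop = FALSE],
                               a[, w, , drop = FALSE], a[, , w, drop = FALSE])
    (pick(lo) + pick(idx) + pick(hi)) / 3
  }
  for (p in seq_len(passes)) for (d in 1:3) vals <- box1(vals, d)
  if (!is.null(fld)) { fld$counts <- vals; fld } else vals
}

#' Extract an iso-density surface
#'
#' Triangulates the level set `rho = rho_iso` of the averaged density by
#' marching tetrahedra on the cell-center samples, with welded vertices
#' (watertight for level sets fully inside the grid). Vertices are in sigma
#' units in the shell frame.
#'
#' @param field an accumulated [density_field()], or a plain 3-D array with
#'   `origin` and `cell_edge` given.
#' @param rho_iso iso level in sigma^-3 (default 0.4).
#' @param origin,cell_edge grid geometry when `field` is a plain array.
#' @return An `iso_mesh`: list with `vertices` (n x 3) and `triangles`
#'   (m x 3, 1-based). Empty (with a warning) when the level is outside the
#'   data range.
#' @export
extract_isosurface <- function(field, rho_iso = 0.4, origin = NULL,
                               cell_edge = NULL) {
  if (inherits(field, "density_field")) {
    vals <- mean_density(field)
    origin <- field$origin
    cell_edge <- field$cell_edge
  } else {
    vals <- field
    if (is.null(origin) || is.null(cell_edge))
      stop("plain-array input needs origin and cell_edge")
    if (length(origin) == 1) origin <- rep(origin, 3)
  }
  if (rho_iso >= max(vals) || rho_iso <= min(vals)) {
    warning("iso level outside the data range; empty mesh")
    return(structure(list(vertices = matrix(numeric(0), ncol = 3),
                          triangles = matrix(integer(0), ncol = 3)),
                     class = "iso_mesh"))
  }
  res <- marching_tetrahedra_cpp(as.numeric(vals), dim(vals), rho_iso,
                                 as.numeric(origin + cell_edge / 2), cell_edge)
  structure(list(vertices = res$vertices, triangles = res$triangles),
            class = "iso_mesh")
}

#' @export
print.iso_mesh <- function(x, ...) {
  cat(sprintf("Iso-surface mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Total surface area of a triangle mesh
#' @param mesh an `iso_mesh`.
#' @return Area in sigma^2.
#' @export
mesh_area <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(0)
  v <- mesh$vertices
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Euler characteristic of a triangle mesh
#'
#' V - E + F on the welded mesh; a closed orientable surface of genus g has
#' Euler characteristic 2 - 2g (2 for a sphere, 0 for a torus).
#'
#' @param mesh an `iso_mesh`.
#' @return Integer Euler characteristic (sum over connected surface pieces).
#' @export
mesh_euler_characteristic <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(0L)
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(1, 3)])
  ed <- t(apply(ed, 1, sort))
  E <- nrow(unique(ed))
  V <- length(unique(as.integer(tr)))
  as.integer(V - E + nrow(tr))
}

#' Write a mesh as Wavefront OBJ
#' @param mesh an `iso_mesh`.
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# iso-density surface (sigma units)", con)
  if (nrow(mesh$vertices))
    writeLines(sprintf("v %.8f %.8f %.8f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$triangles))
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

#' Write a mesh as legacy ASCII VTK PolyData
#' @param mesh an `iso_mesh`.
#' @param path output file.
#' @export
write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               "iso-density surface (sigma units)", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nv)), con)
  if (nv) writeLines(sprintf("%.8f %.8f %.8f", mesh$vertices[, 1],
                             mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  if (nt) writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1,
                             mesh$triangles[, 2] - 1, mesh$triangles[, 3] - 1), con)
  invisible(path)
}

#' Save / load a density field (flat binary array + JSON sidecar)
#'
#' @param field a [density_field()].
#' @param path base path; writes `<path>.bin` and `<path>.json`.
#' @export
write_density <- function(field, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(field$counts), con, size = 8)
  close(con)
  meta <- list(dims = field$dims, origin = field$origin,
               cell_edge = field$cell_edge, n_samples = field$n_samples)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  vals <- readBin(con, "numeric", n = prod(meta$dims), size = 8)
  close(con)
  structure(list(origin = meta$origin, cell_edge = meta$cell_edge,
                 dims = meta$dims, counts = array(vals, dim = meta$dims),
                 n_samples = as.integer(meta$n_samples)),
            class = "density_field")
}
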