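#' Rotation quantum of a tori-and-spheres packing
#'
#' A generating structure of k tori and l polar spheres crosses a meridian
#' plane at n = 2k + l equally spaced positions; cutting the shell on that
#' plane and rotating one hemisphere by multiples of
#' \eqn{\theta = 2\pi/(2k+l)} reconnects the tube ends smoothly.
#'
#' @param k number of tori (>= 1).
#' @param l number of polar spheres, 0, 1 or 2.
#' @return theta in radians.
#' @examples
#' rotation_angle(4, 1)   # 2*pi/9
#' rotation_angle(2, 2)   # pi/3
#' @export
rotation_angle <- function(k, l) {
  if (!all(l %in% c(0, 1, 2))) stop("l must be 0, 1 or 2")
  stopifnot(all(k >= 1), all(k == round(k)))
  2 * pi / (2 * k + l)
}

#' Shell inner radius admitting an optimal n-fold packing
#'
#' For n = 2k + l close-packed tori and spheres of diameter D in a shell of
#' width W, the tube centers sit on the mid-shell meridian circle of radius
#' R_c = R_inn + W/2 and adjacent centers touch, so the meridian chord
#' equals D:
#' \deqn{R_{inn} = \frac{D}{2\sin(\pi/n)} - \frac{W}{2}.}
#' With D = W this is the pure hard-packing model; with D set to the bulk
#' cluster lattice constant it matches the simulated shells.
#'
#' @param n total meridian crossing count 2k + l (>= 3).
#' @param W shell width in sigma.
#' @param D tube/sphere diameter in sigma (default W).
#' @return R_inn in sigma.
#' @examples
#' shell_inner_radius(6, 5)        # 2.5
#' shell_inner_radius(9, 5, D = 6) # ~ 6.27
#' @export
shell_inner_radius <- function(n, W, D = W) {
  stopifnot(n >= 3, n == round(n), W > 0, D > 0)
  R_inn <- D / (2 * sin(pi / n)) - W / 2
  if (R_inn <= 0)
    stop(sprintf("no valid shell: D/(2 sin(pi/%d)) <= W/2", as.integer(n)))
  R_inn
}

# one (k, l) decomposition of an n-fold packing for a given shell
packing_solution <- function(k, l, shell) {
  n <- 2 * k + l
  structure(list(k = k, l = l, n = n, theta = 2 * pi / n,
                 R_c = shell$R_c,
                 spacing = 2 * shell$R_c * sin(pi / n),
                 shell = shell),
            class = "packing_solution")
}

#' @export
print.packing_solution <- function(x, ...) {
  cat(sprintf("Packing: %d tori + %d sphere(s) (n = %d, theta = 2*pi/%d = %.4f rad)\n",
              x$k, x$l, x$n, x$n, x$theta))
  cat(sprintf("  R_c = %g sigma, meridian spacing = %.4f sigma\n",
              x$R_c, x$spacing))
  invisible(x)
}

#' Select the optimal packing for a shell
#'
#' Chooses the meridian crossing count n that brings the chord spacing
#' `2 R_c sin(pi/n)` closest to the preferred inter-cluster distance
#' `d_star`, and returns the parity-consistent (k, l) decompositions:
#' odd n has a unique decomposition (k = (n-1)/2, l = 1); even n admits both
#' (n/2, 0) and (n/2 - 1, 2), which fill shells of the same size.
#'
#' The default `d_star = 5.6` sigma sits between the bulk hexagonal lattice
#' constant (l0 ~ 6 sigma) and the hard-packing value and reproduces the
#' observed structures for all four simulated shells (n = 6, 8, 9, 11).
#'
#' @param shell a [shell_geometry()].
#' @param d_star preferred spacing between neighboring cluster axes (sigma).
#' @param n_max largest n considered.
#' @return A `packing_selection`: list with `n`, `theta`, `spacing`, `R_c`,
#'   `solutions` (list of `packing_solution`), and `tie` (TRUE when two n
#'   values fit equally well; both are then included in `alternatives`).
#' @examples
#' select_packing(shell_geometry(6, 11))     # n = 9: 4 tori + 1 sphere
#' @export
select_packing <- function(shell, d_star = 5.6, n_max = 100) {
  stopifnot(d_star > 0)
  ns <- 3:n_max
  err <- abs(2 * shell$R_c * sin(pi / ns) - d_star)
  best <- which.min(err)
  tie <- sum(err <= err[best] + 1e-9) > 1
  n <- ns[best]
  sols <- if (n %% 2 == 1) {
    list(packing_solution((n - 1) / 2, 1, shell))
  } else {
    list(packing_solution(n / 2, 0, shell),
         packing_solution(n / 2 - 1, 2, shell))
  }
  alt <- if (tie) {
    lapply(ns[err <= err[best] + 1e-9], function(nn) {
      if (nn %% 2 == 1) list(packing_solution((nn - 1) / 2, 1, shell))
      else list(packing_solution(nn / 2, 0, shell),
                packing_solution(nn / 2 - 1, 2, shell))
    })
  } else NULL
  structure(list(n = n, theta = 2 * pi / n,
                 spacing = 2 * shell$R_c * sin(pi / n), R_c = shell$R_c,
                 solutions = sols, tie = tie, alternatives = alt,
                 d_star = d_star, shell = shell),
            class = "packing_selection")
}

#' @export
print.packing_selection <- function(x, ...) {
  cat(sprintf("Optimal packing for shell (R_inn = %g, R_out = %g), d* = %g sigma:\n",
              x$shell$R_inn, x$shell$R_out, x$d_star))
  cat(sprintf("  n = %d meridian crossings (theta = 2*pi/%d), spacing %.3f sigma%s\n",
              x$n, x$n, x$spacing, if (x$tie) " [TIE]" else ""))
  for (s in x$solutions)
    cat(sprintf("  - %d tori + %d sphere(s)\n", s$k, s$l))
  invisible(x)
}

# --- derived-structure connectivity ---------------------------------------
#
# Meridian positions 0..n-1 sit on the great circle in the cut plane at
# angles alpha_i = pi/2 + (off_H + i) * theta, where off_H = 0 when the
# hemisphere's packing has polar spheres (l >= 1; caps at the poles) and
# off_H = 1/2 for the all-tori packing (l = 0; no polar position).  On its
# own grid a hemisphere matches position i with c_H - i (mod n), with
# c_H = 0 (l >= 1) or -1 (l = 0); the fixed points of that involution are
# exactly the cap positions.  Rotating hemisphere B by m half-quanta
# (angle m*theta/2) shifts its grid by s = (off_B - off_A) + m/2 positions,
# which is an integer precisely for the admissible (pure m even / hybrid m
# odd) combinations; B then matches p with (c_B + 2 s) - p on A's grid.

hemi_offset <- function(l) if (l == 0) 0.5 else 0
hemi_c <- function(l) if (l == 0) -1 else 0
hemi_caps <- function(n, l) {
  if (l == 0) integer(0) else if (l == 1) 0L else c(0L, n %/% 2L)
}

check_parity <- function(n, l) {
  if (n %% 2 == 1 && l != 1) stop("odd n requires l = 1")
  if (n %% 2 == 0 && !(l %in% c(0, 2))) stop("even n requires l = 0 or 2")
}

#' Connectivity of a derived (rotated or hybrid) structure
#'
#' Cuts the generating structure on a meridian plane and rotates hemisphere
#' B by `m` half-quanta (total angle m*theta/2, theta = 2*pi/n).  Even `m`
#' are pure rotations of a single packing (`l_A = l_B`); odd `m` join the
#' two different even-n packings (hybrids, `l_A != l_B`).  Each hemisphere
#' contributes a perfect matching of its non-cap meridian positions (every
#' half-torus joins mirror positions about the polar axis) plus caps where
#' its polar spheres are cut; the connected components of the union of the
#' two matchings are the tubular clusters of the derived structure:
#' alternating cycles are closed tubes, alternating paths are open tubes
#' whose ends sit at the cap positions.
#'
#' @param n meridian crossing count (2k + l of the generating packing).
#' @param l_A,l_B polar sphere counts of the two hemispheres.
#' @param m rotation in units of theta/2 (may be negative: opposite
#'   handedness).
#' @return A `derived_structure`: list with `n`, `l_A`, `l_B`, `m`,
#'   `theta`, `components` (each with `type` "closed"/"open"/"sphere",
#'   `positions` traversed in order, `edges` with the hemisphere carrying
#'   each arc, and for open components the two cap ends), `n_components`,
#'   `n_open_ends`, and `position_angle` (angles of positions 0..n-1 in the
#'   cut plane).
#' @examples
#' derived_connectivity(9, 1, 1, 6)  # rotation 3*theta: 1 open + 1 closed
#' @export
derived_connectivity <- function(n, l_A, l_B, m) {
  stopifnot(n >= 3, n == round(n), m == round(m))
  check_parity(n, l_A); check_parity(n, l_B)
  hybrid <- l_A != l_B
  if (hybrid && n %% 2 == 1) stop("hybrids require even n")
  if (hybrid && m %% 2 == 0)
    stop("hybrid structures occur only at odd multiples of theta/2")
  if (!hybrid && m %% 2 == 1)
    stop("pure rotations are even multiples of theta/2")
  s_shift <- (hemi_offset(l_B) - hemi_offset(l_A)) + m / 2
  stopifnot(abs(s_shift - round(s_shift)) < 1e-12)
  s_shift <- round(s_shift)

  cA <- hemi_c(l_A); cB <- hemi_c(l_B)
  mside <- function(i, side) if (side == "A") (cA - i) %% n else (cB + 2 * s_shift - i) %% n
  caps_A <- hemi_caps(n, l_A)
  caps_B <- (hemi_caps(n, l_B) + s_shift) %% n
  is_cap <- function(p, side) if (side == "A") p %in% caps_A else p %in% caps_B
  other <- function(side) if (side == "A") "B" else "A"

  visited <- rep(FALSE, n)
  comps <- list()
  # open components start at a cap and leave through the opposite hemisphere,
  # then alternate A/B arcs until the next cap; a position capped on both
  # sides is an isolated sphere
  for (sc in list(list(cp = caps_A, first = "B"), list(cp = caps_B, first = "A"))) {
    for (p0 in sc$cp) {
      if (visited[p0 + 1]) next
      p <- p0; side <- sc$first
      pos_seq <- p0; edge_sides <- character(0)
      visited[p0 + 1] <- TRUE
      while (!is_cap(p, side)) {
        q <- mside(p, side)
        edge_sides <- c(edge_sides, side)
        pos_seq <- c(pos_seq, q)
        visited[q + 1] <- TRUE
        p <- q; side <- other(side)
      }
      type <- if (length(pos_seq) == 1) "sphere" else "open"
      comps[[length(comps) + 1]] <- list(
        type = type, positions = pos_seq, edges = edge_sides,
        ends = if (type == "open") c(pos_seq[1], pos_seq[length(pos_seq)]) else NULL)
    }
  }
  # remaining positions lie on alternating cycles (closed tubes)
  for (p0 in 0:(n - 1)) {
    if (visited[p0 + 1]) next
    p <- p0; side <- "A"
    pos_seq <- integer(0); edge_sides <- character(0)
    repeat {
      pos_seq <- c(pos_seq, p)
      visited[p + 1] <- TRUE
      q <- mside(p, side)
      edge_sides <- c(edge_sides, side)
      p <- q
      side <- other(side)
      if (p == p0 && side == "A") break
    }
    comps[[length(comps) + 1]] <- list(type = "closed", positions = pos_seq,
                                       edges = edge_sides, ends = NULL)
  }

  theta <- 2 * pi / n
  structure(list(
    n = n, l_A = l_A, l_B = l_B, m = m, theta = theta,
    hybrid = hybrid, handedness = sign(m),
    components = comps,
    n_components = length(comps),
    n_open_ends = 2L * sum(vapply(comps, function(cc) cc$type == "open", TRUE)),
    position_angle = pi / 2 + (hemi_offset(l_A) + 0:(n - 1)) * theta
  ), class = "derived_structure")
}

#' @export
print.derived_structure <- function(x, ...) {
  lab <- if (x$hybrid) sprintf("hybrid (l = %d | %d)", x$l_A, x$l_B)
         else sprintf("pure (l = %d)", x$l_A)
  cat(sprintf("Derived structure: n = %d, rotation %g * theta/2, %s\n",
              x$n, x$m, lab))
  for (cc in x$components) {
    cat(sprintf("  - %s: positions {%s}%s\n", cc$type,
                paste(cc$positions, collapse = ","),
                if (cc$type == "open")
                  sprintf(" (ends at %d, %d)", cc$ends[1], cc$ends[2]) else ""))
  }
  invisible(x)
}

# multiset signature of component types/sizes, for menu deduplication
structure_signature <- function(ds) {
  paste(sort(vapply(ds$components, function(cc)
    sprintf("%s%d", cc$type, length(cc$positions)), "")), collapse = "|")
}

#' Enumerate the menu of derived structures for a shell
#'
#' All distinct derived (and, for even n, hybrid) structures of the optimal
#' packing for a shell, deduplicated by component signature and restricted
#' to one handedness.
#'
#' @param shell a [shell_geometry()].
#' @param d_star preferred cluster spacing passed to [select_packing()].
#' @return List with the `packing_selection` and a list `structures` of
#'   `derived_structure` objects.
#' @export
structure_menu <- function(shell, d_star = 5.6) {
  sel <- select_packing(shell, d_star)
  n <- sel$n
  out <- list()
  seen <- character(0)
  combos <- if (n %% 2 == 1) list(c(1, 1)) else list(c(0, 0), c(2, 2), c(0, 2), c(2, 0))
  for (ll in combos) {
    ms <- if (ll[1] == ll[2]) seq(0, n, by = 2) else seq(1, 2 * n - 1, by = 2)
    for (m in ms) {
      ds <- derived_connectivity(n, ll[1], ll[2], m)
      sig <- paste(ll[1], ll[2], structure_signature(ds))
      if (!(sig %in% seen)) { seen <- c(seen, sig); out[[length(out) + 1]] <- ds }
    }
  }
  list(selection = sel, structures = out)
}
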