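# Independent oracles used across tests.

# Orbit-decomposition oracle for derived-structure connectivity: the two
# hemisphere matchings are encoded as involutions on the meridian positions
# (caps are fixed points); the clusters are the orbits of the group the two
# involutions generate.  Types follow from the fixed points inside an
# orbit: size-1 orbits are spheres, orbits containing fixed points are open
# tubes, the rest closed tubes.  This shares no code with the alternating
# path/cycle trace in derived_connectivity().
connectivity_oracle <- function(n, l_A, l_B, m) {
  off <- function(l) if (l == 0) 0.5 else 0
  cc <- function(l) if (l == 0) -1 else 0
  caps_own <- function(l) if (l == 0) integer(0) else if (l == 1) 0L else c(0L, n %/% 2L)
  s <- (off(l_B) - off(l_A)) + m / 2
  stopifnot(abs(s - round(s)) < 1e-12)
  s <- round(s)
  a <- ((cc(l_A) - 0:(n - 1)) %% n) + 1          # involution A, 1-based
  b <- ((cc(l_B) + 2 * s - 0:(n - 1)) %% n) + 1  # involution B
  fixed_a <- (caps_own(l_A) %% n) + 1
  fixed_b <- ((caps_own(l_B) + s) %% n) + 1
  stopifnot(all(a[fixed_a] == fixed_a), all(b[fixed_b] == fixed_b))
  seen <- rep(FALSE, n)
  comps <- list()
  for (v in 1:n) {
    if (seen[v]) next
    orbit <- v
    frontier <- v
    seen[v] <- TRUE
    while (length(frontier)) {
      nxt <- unique(c(a[frontier], b[frontier]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      orbit <- c(orbit, nxt)
      frontier <- nxt
    }
    ends <- sum(orbit %in% fixed_a) + sum(orbit %in% fixed_b)
    type <- if (length(orbit) == 1) "sphere" else if (ends > 0) "open" else "closed"
    comps[[length(comps) + 1]] <- list(type = type, size = length(orbit),
                                       ends = if (type == "open") ends else 0L)
  }
  comps
}

# multiset signature (type+size) of components, either representation
comp_signature <- function(comps, from_oracle = FALSE) {
  sort(vapply(comps, function(cmp) {
    size <- if (from_oracle) cmp$size else length(cmp$positions)
    sprintf("%s:%d", cmp$type, size)
  }, ""))
}

# all admissible (l_A, l_B, m) combinations for a given n (one period)
connectivity_cases <- function(n) {
  if (n %% 2 == 1) {
    data.frame(l_A = 1, l_B = 1, m = seq(0, 2 * n - 2, by = 2))
  } else {
    rbind(
      expand.grid(l_A = c(0, 2), l_B = c(0, 2), m = seq(0, 2 * n - 2, by = 2)),
      expand.grid(l_A = c(0, 2), l_B = c(0, 2), m = seq(1, 2 * n - 1, by = 2))
    ) |> subset((l_A == l_B) == (m %% 2 == 0))
  }
}

# a uniformly random 3-D rotation matrix
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
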