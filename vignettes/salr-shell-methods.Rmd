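---
title: "Methods: SALR colloids in narrow spherical shells"
author: "salrshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SALR colloids in narrow spherical shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salrshell)
```

## The physical system and the model

`salrshell` simulates and analyses a colloidal fluid whose particles
interact through competing interactions: a short-range attraction and a
long-range repulsion (SALR). The pair potential is the square-well-linear
form in reduced units (lengths in particle diameters $\sigma$, energies in
well depths $\epsilon$):

$$
u(r) =
\begin{cases}
\infty & r < \sigma\\
-\epsilon & \sigma \le r < \lambda\sigma\\
\epsilon\,\zeta\,(\kappa - r/\sigma) & \lambda\sigma \le r < \kappa\sigma\\
0 & r \ge \kappa\sigma
\end{cases}
$$

with defaults $\zeta = 0.05$, $\lambda = 1.5$, $\kappa = 4$. The ramp is
continuous at $\kappa\sigma$ and steps down by $\zeta(\kappa-\lambda)\epsilon
= 0.125\,\epsilon$ at $\lambda\sigma$. At reduced temperature $T^* = 0.35$
and chemical potentials around $\mu^* \approx -2.2$ this fluid microphase
separates: in bulk it forms the hexagonal phase of parallel cylindrical
clusters with lattice constant $l_0 \approx 6\sigma$ and cluster radius
$r_0 \approx 1.5\sigma$.

The fluid is confined between two concentric hard spherical walls
(`shell_geometry`), with particle centers allowed on the closed interval
$R_{inn} \le |\mathbf r| \le R_{out}$. All studied shells have width
$W = R_{out} - R_{inn} = 5\sigma$, which accommodates exactly one layer of
cylindrical clusters, making the system quasi-two-dimensional. Below
$R_{inn} \approx 1.5\sigma$ particles on opposite sides of the inner sphere
enter each other's repulsive range, which destabilizes ordered structures;
the constructor warns in that regime.

Two volume conventions coexist on purpose. Densities are *reported* as
$\rho^* = N\sigma^3/V$ with the accessible volume
$V = \tfrac{4\pi}{3}\big[(R_{out}+\tfrac12)^3 - (R_{inn}-\tfrac12)^3\big]$,
acknowledging the half hard-core that protrudes past each wall. The
grand-canonical acceptance rules instead pair the activity with the
geometric wall-to-wall volume $\tfrac{4\pi}{3}(R_{out}^3 - R_{inn}^3)$,
because that is the region the insertion proposal density covers; mixing
the two would bias the ensemble. The ideal-gas test
($\langle N\rangle = zV$) validates this pairing.

## Grand-canonical Monte Carlo

`run_gcmc` performs Metropolis sampling in the $(\mu, V, T)$ ensemble. One
step is one trial move: displacement with probability 0.95 (uniform in a
cube of half-width $\delta = 0.5\sigma$), otherwise insertion or deletion
with equal probability. Insertions propose positions uniformly in the
shell via the inverse-CDF in $r^3$ times an isotropic direction; the
acceptance factors are the standard $\min\!\big(1, zV/(N{+}1)\,
e^{-\beta\Delta U}\big)$ and $\min\!\big(1, N/(zV)\, e^{-\beta\Delta
U}\big)$ with activity $z = e^{\mu^*/T^*}\sigma^{-3}$. Setting the thermal
wavelength to $\sigma$ makes printed $\mu^*$ values directly usable; any
other convention only shifts $\mu^*$ by a constant.

$\delta$ stays fixed during production (tuning move sizes on the fly
breaks detailed balance); an optional equilibration-phase tuner targets a
30--50% displacement acceptance and then freezes $\delta$. Energies are
tracked incrementally through a cell list (cell edge $\ge \kappa/2$,
neighbor scan over two shells) and checked against a brute-force $O(N^2)$
recomputation at the end of every run; the bookkeeping test requires
agreement to $10^{-8} N\,\epsilon$. All randomness flows through R's RNG,
so a seed makes runs bit-reproducible. A periodic cubic box mode
(`geometry = "box"`) supports bulk reference runs; its minimum-image
convention requires $L \ge 2\kappa\sigma$.

Desk-scale defaults are deliberate: production runs of $10^6$--$4\times
10^7$ steps and systems of up to $\sim 2000$ particles equilibrate the
small and mid-size shells and the $12\sigma$ bulk box in minutes. The
package reports a filling plateau (`gcmc_plateau`) by chunked means of $N$
with a 1% flatness criterion rather than fixing an equilibration length in
advance. Full-scale campaigns ($10^{10}$ steps) are outside the intended
scope of the test suite and are simply longer schedules.

## Density fields and iso-surfaces

`density_field` accumulates per-cell particle counts on a cubic grid of
cell edge exactly $0.5\sigma$ covering the bounding cube of the shell
(grid dimensions rounded up). The mean local density satisfies the exact
identity $\sum_{cells}\rho\,v_{cell} = \overline N$, which is asserted in
the tests. The grid is a full cube; cells outside the shell simply stay
empty.

Level sets at $\rho_{iso} = 0.4\sigma^{-3}$ are triangulated by marching
tetrahedra on a Kuhn (6-tetrahedron) subdivision of each grid cube, with
vertices welded per grid edge. The welded mesh is watertight for level
sets inside the grid, so Euler characteristics (and hence genus: 2 for a
blob, 0 for a torus) are meaningful; this is how cluster shapes are
classified from densities without visual inspection. Sharp indicator
fields produce staircase level sets whose area overestimates the true
surface; `smooth_density` (a separable 3-cell box filter) is provided for
such synthetic inputs. Averaged simulation densities are already smooth.
Meshes export as OBJ and legacy VTK.

## Cluster identification and topology

Particles closer than $r_{bond}$ are bonded; clusters are connected
components of the bond graph (`build_clusters`). The default
$r_{bond} = \lambda\sigma = 1.5$ declares particles bonded exactly when
they sit in each other's attractive well, the standard convention for SALR
cluster phases.

`classify_cluster` distinguishes compact blobs, closed tubes and open
tubes. A cluster is *spherical* when its longest weighted graph geodesic
does not exceed 1.5 times its tube diameter. For tubes, the closed/open
decision removes one interior cross-section: particles at half the maximal
arc distance from a sweep endpoint form one cross-sectional slab on a path
but two opposite slabs on a loop, so removing a single connected band
piece splits an open tube in two and leaves a loop whole. Anything else
(three or more remnants, i.e. branching) is labelled *irregular* rather
than silently misclassified. Open-tube ends are reported as centroids of
the particles near the two geodesic extremes.

Tube radii are mean perpendicular distances from a local skeleton axis fit
by two-pass neighborhood PCA: a rough axis from the spherical
neighborhood, then a refit on an axial slab, whose centroid is unbiased
across the cross-section. A uniformly filled tube of radius $R$ has mean
perpendicular distance $2R/3$, so the default calibration multiplies by
$3/2$; `calibration = "none"` reports the raw mean, under which a thin
hollow tube of radius $R$ reads $R$ (both behaviours are exercised in the
tests, since either can be the quantity of interest). Spherical clusters
use distances from the centroid with the uniform-ball factor $4/3$.

Inter-cluster spacing (`cluster_spacing`) averages, over skeleton points,
the distance to the nearest skeleton point of a different cluster or of a
different fold of the same coil (a point whose along-tube arc distance far
exceeds its straight-line distance). In shells the skeleton is built from
particles projected onto the mid-shell sphere of radius $R_c$, exploiting
the quasi-2-D geometry to remove radial scatter. For bulk boxes,
`bulk_spacing` instead reads the intermediate-range peak of $g(r)$ between
4 and $8\sigma$, and `bulk_tube_radius` pools local-axis offsets of
unwrapped periodic clusters.

## The packing model

The geometric model explains which structures can appear in a shell of
width $W$. A *generating structure* packs $k$ tori and $l \in \{0,1,2\}$
polar spheres of diameter $W$ into the shell; the tube centers cross a
meridian plane at $n = 2k + l$ points equally spaced on the mid-shell
circle of radius $R_c$, so the touching condition fixes
$R_{inn} = D/(2\sin(\pi/n)) - W/2$ for tube diameter $D$. Cutting the
shell along a meridian plane and rotating one hemisphere about the axis
perpendicular to that plane by multiples of $\theta = 2\pi/n$ reconnects
all tube ends smoothly (*derived structures*); for even $n$ the two
degenerate packings ($k$ tori vs $k{-}1$ tori + 2 spheres) can be mixed at
odd multiples of $\theta/2$ (*hybrid structures*). Both rotation signs are
admissible and give mirror-image, opposite-handed structures
(`centerline_handedness`).

Connectivity is computed combinatorially (`derived_connectivity`): each
hemisphere contributes a perfect matching of its non-cap meridian
positions (every half-torus joins mirror positions about the polar axis)
plus fixed points at its cut polar spheres; components of the union of the
two matchings are the clusters. An independent orbit-decomposition oracle
reproduces the same components in the test suite, exhaustively for
$n \le 31$. Position indexing puts caps at the poles when $l \ge 1$ and
offsets the grid by $\theta/2$ when $l = 0$ so no position is polar —
without this choice the mirror matching would not be an involution on the
grid.

Real clusters are soft and repel each other, so the effective tube
diameter that selects $n$ for a *given* shell is not $W$ but an
inter-cluster spacing $d^*$. `select_packing` chooses $n \ge 3$ minimizing
$|2R_c\sin(\pi/n) - d^*|$. The default $d^* = 5.6\sigma$ sits between the
bulk lattice constant ($\approx 6\sigma$) and the hard-packing limit; a
test re-verifies by brute force over $d^* \in [5, 6]$ that this value
(and a window around it) reproduces the observed $n = 6, 8, 9, 11$ for
the four studied shells. Exact ties between two $n$ are flagged and both
candidates returned.

## Fixtures: decorated ideal structures

`decorate` turns a derived structure's center-lines (half-circle arcs on
the mid-shell sphere, rotated in one hemisphere) into particle
configurations: an FCC lattice at 0.9 particles/$\sigma^3$ restricted to
tubes of radius $1.5\sigma$ (the equilibrium cluster radius), jittered by
$0.1\sigma$ and repaired to respect the hard core. The density sits above
$\rho_{iso} = 0.4$ (iso-surfaces are well formed) and below close packing;
the jitter suppresses lattice artifacts in density grids. An alternative
`"rsa"` fill gives statistically uniform tubes for estimator-calibration
tests but saturates near 0.6 particles/$\sigma^3$. Fixtures are geometric
stand-ins, not thermodynamic microstates: they validate the analysis
chain (clustering, classification, spacing, radii, iso-surface topology)
with known ground truth, which is precisely what they are used for in the
worked-example suite; passing them says nothing about simulation
equilibration, which the stochastic checks cover separately.

## Numerical choices and edge cases

* Boundary conventions: hard core rejects $r < \sigma$ (contact allowed);
  both shell walls are inclusive.
* Cell lists fall back to a single cell (plain loop) when the box is
  smaller than the interaction range.
* `derived_connectivity` rejects inconsistent parity combinations
  ($n$ odd with $l \ne 1$, hybrids at even multiples of $\theta/2$, pure
  rotations at odd ones) as errors rather than guessing.
* Degenerate inputs: empty configurations are valid everywhere (zero
  energy, empty cluster sets, empty density samples still count);
  iso-levels outside the data range return an empty mesh with a warning;
  `cluster_spacing` on a single compact cluster is an error by design.
* The plateau detector compares successive $10^6$-step chunk means of $N$
  at 1% relative tolerance, a scale at which the studied shells' filling
  curves flatten while cluster rearrangements continue.

## Known limitations

* The classifier assumes tubes are quasi-1-D and non-touching at
  $r_{bond}$; genuinely branched percolating structures are reported as
  `irregular`, not resolved.
* Fold counting for coiled open clusters (meridian crossings between the
  two ends) depends on an arc-direction convention; the reported count
  uses the shorter arc and is flagged as a convention in the
  documentation.
* Desk-scale schedules equilibrate small shells reliably but sample
  structure *formation*, not the full structure menu per state point;
  different seeds can and do settle into different menu members, which is
  itself the model's central prediction.
* The bulk $12\sigma$ box is commensurate with the cylinder spacing only
  approximately; spacing estimates there carry a few-percent finite-size
  bias.
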