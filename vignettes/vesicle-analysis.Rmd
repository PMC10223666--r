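---
title: "Analysing self-assembled fatty-acid vesicle trajectories"
author: "vesitraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing self-assembled fatty-acid vesicle trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesitraj)
```

# Scope

`vesitraj` characterises molecular-simulation trajectories of vesicles
self-assembled from single-chain, ten-carbon fatty acids (decanoic acid,
DA), optionally with an embedded hydrophobic helix. The package covers the
structural and dynamic observables that describe such a protocell-like
compartment: vesicle radius and bilayer thickness from per-leaflet headgroup
radii of gyration, leaflet assignment and flip-flop counting, diffusion
coefficients from mean squared displacement with anomalous-regime flagging,
Shrake–Rupley solvent-accessible surface area (SASA), chain order parameters
corrected for membrane curvature, two-dimensional headgroup density maps,
peptide–amphiphile radial distribution functions, and the tilt of a helix
against the local bilayer normal.

It deliberately does not run or steer molecular dynamics, parameterise force
fields, or model self-assembly kinetics. The companion synthetic generator
produces an already-assembled vesicle: a stand-in for the *endpoint* of
aggregation, not its pathway.

# The measurement model

## Geometry from headgroup shells

A two-leaflet spherical vesicle puts its headgroups on two concentric
shells. For each leaflet we compute the radius of gyration of the headgroup
oxygens (O1 and O2) about the vesicle center,

$$r_g = \sqrt{\frac{1}{N}\sum_i \lVert x_i - c \rVert^2},$$

where the center $c$ is the mass-weighted centroid of *all* amphiphile
atoms, not headgroups only — using the full monomer mass distribution
reduces the bias a 21/79 leaflet imbalance would otherwise introduce. The
bilayer thickness is $r_{g,\mathrm{outer}} - r_{g,\mathrm{inner}}$ and the
reported radius is, by default, the outer-leaflet $r_g$. A vesicle of ~7 nm
diameter with 1.5 nm thickness is consistent only with the outer-radius
convention, which is why it is the default; `radius_convention` also accepts
`"inner"` and `"midplane"`.

Leaflets are assigned from monomer *orientation*: the vector from the O1/O2
midpoint to the terminal tail carbon, compared with the outward radial
direction. Inner-leaflet monomers point their tails outward (toward the
midplane), outer-leaflet monomers inward. Monomers whose orientation cosine
is within the dead zone (default $|\cos| < 0.2$) stay unassigned.
Orientation-based assignment remains correct *during* a flip-flop transit
and on rippled patches, where radial-distance bimodality mislabels;
the radial variant is retained as `assign_leaflets_radial()` for
cross-checking.

## Diffusion

The mean squared displacement
$M(\tau) = \langle \lVert r(t+\tau) - r(t) \rVert^2 \rangle$ is averaged
over all time origins and all selected molecule centroids, computed with the
standard FFT autocorrelation identity ($O(F \log F)$ per particle) and
verified in the tests against an explicit all-origins double loop. The
Einstein relation $D = M(\tau) / (2E\tau)$ is fitted by least squares over a
window of lags; $E$ is the dimensionality (3 by default). The default
window, 10%–50% of the maximum lag, excludes the short-time regime and
the poorly-averaged tail; it is configuration-exposed because no universal
choice exists.

The anomalous exponent $\hat\alpha$ is the log–log slope over the same
window. When $|\hat\alpha - 1| > 0.2$ the motion is flagged anomalous and
$D$ is reported as absent, because a constant-$D$ Einstein reading is not
meaningful for $M(\tau) \propto \tau^\alpha$ with $\alpha \ne 1$. The 0.2
threshold is a package choice: tight enough that genuine sub-diffusion at
$\alpha = 0.5$ is always caught, loose enough that fit noise on Brownian
fixtures (a few percent on $\hat\alpha$) never trips it. Diffusion is
reported in nm²/ns; multiply by 10 for $10^{-5}\,\mathrm{cm^2/s}$.

## Flip-flops

A flip-flop event is a leaflet-label change that *persists*: the new label
must hold for `min_dwell` consecutive frames (default 20). Excursions
through the unassigned dead zone, or flickers shorter than the dwell
window, do not count. This hysteresis is the reason assignment keeps an
explicit unassigned state rather than forcing a binary label.

## SASA

Shrake–Rupley with a deterministic golden-spiral point set (default 960
points per atom), probe radius 1.4 Å (water), and Bondi-style van der Waals
radii. An isolated atom gets exactly $4\pi(r + r_\mathrm{probe})^2$. The
atom selection is explicit (`selection`), so whether a reported SASA covers
amphiphiles only or the whole system is always a visible choice. Rotation
invariance of the point-set discretisation is at the 0.1% level for
moderately overlapped clusters at 960 points; deeply buried cores show
somewhat larger discretisation sensitivity, as any fixed-point-set method
does.

## Order parameters on a curved membrane

$S = \langle 3\cos^2\theta - 1 \rangle / 2$, where $\theta$ is measured
against each monomer's *local* normal — the outward radial direction at its
headgroup. Using a per-monomer reference frame is equivalent to reorienting
every molecule so its local normal maps onto the z axis, and removes the
curvature artefact a single global normal would cause. For heavy-atom
(hydrogen-free) input the CH direction at carbon $C_i$ is reconstructed as
the bisector of the two C–C bonds, projected perpendicular to the
$C_{i-1}\!\to\!C_{i+1}$ segment — a standard proxy. Anchors: all-trans
chains aligned with the normal give $S = -0.5$ exactly (the segment vectors
are axial by zigzag geometry), isotropic orientations give 0, and the magic
angle (54.74°) gives 0.

## Density maps and RDF

Headgroup density maps bin $(\cos\theta, \phi)$ about the vesicle center —
an equal-area grid, so a uniformly covered shell is flat. The RDF between
two atom groups is the shell-volume-normalised pair-distance histogram,
scaled by the mean number density of the reference group estimated over its
bounding sphere (overridable). For strongly inhomogeneous systems such as a
vesicle this makes the large-$r$ limit approximate, which is documented
rather than hidden.

## Peptide tilt

The peptide axis is the unit vector from the first to the last C$\alpha$.
The local bilayer normal is built from the DA monomers near the peptide:
any monomer with a heavy atom within 8 Å of any peptide atom qualifies, and
the normal is the normalised average of the qualifying monomers' outward
radial directions. By default each monomer's contribution is tapered
linearly with its distance to the peptide (`weighting = "linear"`). The
taper exists because the plain average has an irreducible sampling error of
order $1/(r\sqrt{\rho})$ — monomers entering and leaving at the hard cutoff
edge carry the largest transverse components — and the taper suppresses
exactly those edge terms; `weighting = "uniform"` restores the plain
average. The tilt is $\arccos$ of the axis–normal dot product, classified
into windows 0–30° (inserted, C→N), 60–120° (surface), 150–180° (inserted,
N→C), else intermediate. The windows are reporting conventions anchored at
the three physically meaningful geometries; they are configuration-exposed.

Whether the tilt should use a per-frame local normal or a smoothed one is
genuinely open; per-frame is implemented, and a windowed average can be
formed from the `tilt_series()` tibble with ordinary dplyr verbs.

# The synthetic generator

Every analyzer is validated by parameter recovery against fixtures with
known ground truth, because reference all-atom trajectories for these
systems are not publicly deposited. The generator emulates:

* **Composition and geometry** — the `"DA-25"` preset builds 1000 monomers
  with 21% in the inner leaflet (210/790) on shells of 2.0/3.5 nm: a 7 nm
  vesicle with 1.5 nm bilayer thickness and a water-filled interior.
  Headgroups sit on golden-spiral lattices with Gaussian jitter (default
  0.05 nm), rejected below a 0.45 nm minimum spacing (the headgroup
  diameter scale).
* **Chain states** — gel tails are all-trans (every C–C–C–C dihedral 180°);
  fluid tails draw dihedrals uniformly from {±60°, 180°}. These give
  analytically distinct order-parameter regimes ($S = -0.5$ exactly vs
  partially disordered).
* **Motion** — monomers are rigid bodies whose centers diffuse. Brownian
  motion uses iid Gaussian steps with per-axis variance $2 D \Delta t$.
  Anomalous motion ($\alpha \ne 1$) is generated as exact fractional
  Gaussian noise via a Cholesky factor of the increment covariance
  ($H = \alpha/2$). Correlated increments matter here: a process with
  independent but rescaled steps satisfies the target power law only from
  the initial time origin, while the MSD estimator averages over *all*
  origins — with stationary fGn increments the time-averaged MSD follows
  $6 D \tau^\alpha$ as intended, and planted sub-diffusion is actually
  detectable.
* **Flip-flops** — listed monomers migrate radially to the opposite shell
  across a configurable transit window (default 10 frames), reversing
  orientation at the midpoint; everything else stays leaflet-stable.
* **Peptide** — an ideal α-helix C$\alpha$ trace (rise 1.5 Å, 100° per
  residue, default 16 residues) rotated so its end-to-end vector makes
  *exactly* the planted angle with the outward radial at its midpoint.
  The end-to-end vector, not the helical axis, is planted, because the
  analyzer measures the end-to-end vector; for a non-integer number of
  turns the two differ by several degrees.

The same seed always reproduces a fixture bit for bit, and
`write_ground_truth()` emits a YAML sidecar so recovery tests compare
against recorded truth rather than constants.

What the generator does **not** emulate: thermal conformational noise
within monomers, membrane undulations, solvent structure, electrostatics,
protonation state, or any force-field energetics. Passing recovery tests
therefore demonstrates estimator correctness — that each analyzer measures
what it claims on data whose answer is known — not that the estimators are
robust to every artefact of real all-atom trajectories.

# Numerical and design choices

* **Units** — coordinates are Angstrom internally (the PDB native unit);
  all report-facing geometry converts to nm. Time is ns; the default
  sampling interval is 0.01 ns per frame.
* **Periodic boundaries** — minimum-image unwrapping
  (`unwrap_trajectory()`) is applied only when a box is present; synthetic
  fixtures are box-free to sidestep wrapping ambiguity in tests.
* **Clustering** — aggregate detection is single-linkage on heavy-atom
  contacts (default 6 Å) with a monomer-centroid prefilter; cluster ids are
  deterministic (ordered by lowest member molecule id) and the partition is
  verified against a brute-force transitive closure.
* **Degenerate inputs** — zero-length orientation vectors are unassigned
  with a warning; empty leaflets make geometry an error rather than a NaN;
  non-positive MSD values inside the fit window are a fit error; missing
  element radii name the offending elements.
* **Tie-breaks** — density-map bins are half-open with clamping at the
  poles; flip events record the first frame of the persistent new label.
* **Fixture sizes** — recovery studies use deliberately modest problems:
  geometry on the 1000-monomer composition; diffusion on 100 monomers ×
  2000 frames × 5 seeds; flip-flop counting on 250 monomers × 300 frames;
  SASA direction on a dense 460-monomer vesicle; tilt recovery on a
  9300-monomer vesicle (8.5/10 nm shells), where the local-normal
  estimator's $1/(r\sqrt{\rho})$ sampling error drops below the 2°
  tolerance. The tilt study is the one place fixture size is driven by
  estimator convergence rather than economy: on a 3.5 nm vesicle the
  8 Å neighbourhood simply contains too few discrete monomers for a
  sub-2° local normal.
* **SASA phase direction** — fluid-tail vesicles exceed gel-tail vesicles
  in total SASA only at realistic (dense) headgroup packing: kinked chains
  bury more of *themselves*, ordered chains bury more of their
  *neighbours*, and the second effect dominates once chains actually touch.
  The direction test therefore runs at the preset's surface density.

# Known limitations

* The RDF's large-$r$ normalisation is approximate for shell-like reference
  groups; compare curves, not absolute plateaus, across systems.
* The local-normal estimator degrades on very small or very sparse
  vesicles (few monomers within 8 Å); `tilt_series()` reports the support
  count and flags missing frames so this is visible in output.
* Anomalous-motion generation reproduces the fGn covariance exactly but is
  Gaussian by construction; heavy-tailed or aging dynamics are out of
  scope.
* Monomer rigidity means intramolecular observables (order parameters) are
  exactly their planted values; they validate the measurement geometry, not
  conformational sampling.

# A typical session

```{r example, eval = FALSE}
sys <- make_vesicle(vesicle_preset("DA-25", seed = 1))
sys <- make_dynamic_trajectory(sys, motion_spec(
  d_true = 0.5, n_frames = 500, timestep = 0.01, seed = 2))

lab <- assign_leaflets(sys$trajectory$frames[[1]]$coords, sys$map)
vesicle_geometry(sys$trajectory$frames[[1]]$coords, sys$map, lab)

curve <- msd(sys$trajectory, sys$map, max_lag = 2.5)
glance(diffusion_coefficient(curve))
autoplot(curve)

summary_row <- run_pipeline(list(
  label = "DA-25", seed = 1, output_dir = "da25-out"
), system = sys)
```
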