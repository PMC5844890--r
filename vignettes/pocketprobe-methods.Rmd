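---
title: "pocketprobe: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketprobe: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketprobe)
```

`pocketprobe` supports three recurring tasks in structure-guided ligand
design at protein pockets: mapping where a pocket rewards particular chemical
groups, quantifying how tightly candidate ligands bind, and comparing
liganded structures. This vignette documents the models behind each module,
the parameter choices, and the numerical methods, so results can be
interpreted and reproduced without reading the source.

## 1. Probe affinity maps

### Energy model

A map assigns to each point $p$ of a regular grid the interaction energy of a
small chemical probe placed at $p$ with a rigid receptor:

$$E(p) \;=\; \sum_{i}\Big[ E^{\mathrm{LJ}}_i(r_{ip}) + E^{\mathrm{el}}_i(r_{ip}) \Big] \;+\; \sum_{\mathrm{H\,sites}} E^{\mathrm{hb}}(d, \theta),$$

truncated above at `emax_cap` (default $+5$ kcal/mol) so that clashes do not
dominate the dynamic range of visualisations and region extraction.

**Lennard-Jones (12-6).** For receptor atom $i$ at distance $r$,

$$E^{\mathrm{LJ}} = \varepsilon_{ij}\left[\left(\tfrac{r_{\min}}{r}\right)^{12} - 2\left(\tfrac{r_{\min}}{r}\right)^{6}\right],$$

with combination rules $r_{\min} = R_i + r_{\min,\mathrm{probe}}$ (sum of the
atom radius — taken from the PQR file when present, otherwise from a built-in
per-element table — and the probe's optimum half-distance) and
$\varepsilon_{ij} = \sqrt{\varepsilon_i\,\varepsilon_{\mathrm{probe}}}$ with
per-element well depths C 0.15, N 0.16, O 0.20, H 0.02, S 0.25, P 0.20
kcal/mol. This parameterisation is in the tradition of empirical
interaction-field programs: deliberately coarse, transferable, and cheap.

**Electrostatics.** A Coulomb term
$E^{\mathrm{el}} = 332.0636\, q_1 q_2 / (\epsilon(r)\, r)$ (kcal/mol with
charges in elementary units and distances in Å). The default dielectric is
distance-dependent, $\epsilon(r) = 4r$, a standard implicit-screening choice
for continuum-free pocket mapping: it damps long-range monopole interactions
roughly as bulk water does while leaving short-range contacts strong, and it
costs nothing. A constant-$\epsilon$ model is available via
`dielectric_constant()` for sensitivity checks. Charged probes require PQR
input (`read_pqr()`); maps with neutral, non-H-bonding probes also work from
plain PDB files.

**Hydrogen bonds.** Rather than folding H-bonding into the 12-6 term, an
explicit 6-4 radial profile with an angular weight is used:

$$E^{\mathrm{hb}}(d, \theta) = \left[\frac{C}{d^{6}} - \frac{D}{d^{4}}\right]\cos^{m}(180^\circ - \theta), \qquad \theta \ge 90^\circ,$$

with $C = 2 E_{\min} d_0^{6}$ and $D = 3 E_{\min} d_0^{4}$ so the radial
minimum is exactly $-E_{\min}$ at $d = d_0$ (defaults $E_{\min} = 4$
kcal/mol, $d_0 = 2.8$ Å, $m = 2$). The 6-4 form is softer than 12-10
alternatives, reflecting the partly electrostatic nature of the interaction,
and the $\cos^m$ weight with a hard 90° cutoff encodes the strong
directionality of H-bonds that an isotropic term cannot capture. Receptor
donors are N/O atoms with an explicit hydrogen within 1.2 Å (the angle
$\theta$ is then measured at that hydrogen); acceptors are all oxygens plus
unprotonated nitrogens, with directionality measured at the acceptor against
its nearest bonded heavy atom (≤ 1.8 Å; $\theta = 180^\circ$ if the atom has
no such neighbour). Because donors need explicit hydrogens, protonated input
(PQR from a preparation pipeline) gives the most faithful maps.

### Probes

`default_probes()` returns five probes spanning the interaction types a
pocket can reward:

| probe | $\varepsilon$ | $r_{\min}$ (Å) | charge | donor | acceptor |
|---|---|---|---|---|---|
| `CH3` | 0.15 | 2.00 | 0 | no | no |
| `O_ACC` | 0.20 | 1.70 | 0 | no | yes |
| `NH4` | 0.17 | 1.85 | +1 | yes | no |
| `OH` | 0.21 | 1.75 | 0 | yes | yes |
| `HYDROPHOBIC` | 0.15 | 2.00 | 0 | no | no |

`HYDROPHOBIC` is `CH3` with the electrostatic term disabled entirely — a
pragmatic stand-in for "pure shape/dispersion complementarity" maps.

### Grid, regions, decomposition

The default grid is $50 \times 50 \times 50$ points at 0.5 Å spacing
(125,000 points, a 24.5 Å cube), centred on a user-supplied point — enough to
cover a drug-sized pocket plus margin at a resolution finer than the energy
model's own accuracy. Favourable regions are extracted by thresholding the
map and taking 26-connected components of sub-threshold grid points
(`find_regions()`); 26-connectivity (face, edge and corner neighbours) avoids
splitting a single basin that happens to thread diagonally through the
lattice. Each region reports its volume, centroid, minimum energy and
location. `residue_decomposition()` splits a receptor-ligand interaction
energy (LJ + Coulomb over all atom pairs) into per-residue contributions that
sum exactly to the total, for ranking which residues drive binding.

```{r map-example}
pocket <- toy_pocket(features = data.frame(element = "O", name = "OD1",
  x = 0, y = 0, z = 0, charge = -0.5, radius = 1.52))
g <- grid_spec(center = centroid(pocket), npoints = 21, spacing = 0.5)
m <- compute_map(pocket, default_probes()$NH4, g)
regs <- find_regions(m, threshold = -2.5)
length(regs)
regs[[1]]$min_energy
```

Maps round-trip through OpenDX scalar files (`write_dx()` / `read_dx()`),
the lingua franca of molecular visualisation tools.

## 2. Binding equilibria

### Exact solvers

For a single 1:1 equilibrium with total receptor $T_t$, total ligand $L_t$
and association constant $K_b$, `solve_single()` evaluates the bound
concentration via the numerically stable form of the quadratic root,

$$C_b = \frac{2\,T_t L_t}{S + \sqrt{S^2 - 4\,T_t L_t}}, \qquad S = T_t + L_t + 1/K_b,$$

which avoids the catastrophic cancellation of the textbook
$(S - \sqrt{\cdot})/2$ form when $T_t L_t \ll S^2$. For two ligands competing
for one site, `solve_competition()` solves the scalar equation

$$T_f\left(1 + \frac{K_A A_t}{1 + K_A T_f} + \frac{K_B B_t}{1 + K_B T_f}\right) = T_t$$

for free receptor $T_f$ by bracketed root finding on $[0, T_t]$ followed by
Newton polishing to $\sim 10^{-14}$ relative residual; all species then
follow algebraically. Mass balance holds to better than $10^{-12}$ relative
across eight decades of inputs (see the acceptance suite).

### Estimators

Three estimators mirror three experiment styles:

* `fit_direct()` — direct titrations where a measured signal is linear in
  free and bound ligand, $y = \alpha C_f + \beta C_b + \gamma$. For each
  trial $K_b$ on a $\log_{10}$ grid the linear coefficients are profiled out
  by least squares, and the grid optimum is refined with `optimize()`. If the
  profile is flat (spectrally identical species), the fit aborts with an
  "uninformative" error rather than returning an arbitrary number. An
  optional residual bootstrap supplies a standard error.
* `fit_displacement()` — competitor titration series against a reporter
  ligand of known $K_b$. The reporter's bound fraction at each competitor
  concentration comes from the exact competition solver; the competitor's
  $K_b$ is profiled the same way. When the optimum sits against the upper
  search bound, or raising $K_b$ two decades barely changes the fit, the
  result is flagged `saturated`: the reporter is fully displaced at the first
  titration points and the data support only a lower bound. This is the
  quantitative failure mode of displacement assays for ligands vastly
  stronger than the reporter, and the flag is the package's guard against
  over-reading such fits.
* `estimate_kb_centrifugation()` — competition experiments that directly
  measure free and bound concentrations of both ligands (e.g. by pelleting
  the receptor). Each experiment yields a point estimate
  $K_{b,X} = K_{b,\mathrm{ref}} \cdot (C_{b,X} C_{f,\mathrm{ref}}) / (C_{b,\mathrm{ref}} C_{f,X})$,
  and replicates are pooled as mean ± SD. Non-positive measurements are
  excluded with a warning.

```{r kb-example}
st <- solve_competition(10e-6, 15e-6, 15e-6, 9.1e7, 2.87e8)
st$ligands
```

## 3. Synthetic data

Real assay data are noisy and scarce; the generators provide controlled
stand-ins whose ground truth is known exactly, which is what the test suite
and acceptance criteria are built on.

* `toy_pocket()` — a ring of carbon atoms (a crude pocket wall) plus
  user-placed feature atoms with charges and radii. Simple enough that map
  features can be predicted analytically, which is the point.
* `simulate_displacement()` — a competitor dilution series (default 0–70 µM,
  ten points) against a fixed receptor/reporter pair, with a linear
  fluorescence model and multiplicative log-normal noise
  ($y \cdot e^{\sigma Z}$). Multiplicative noise reflects how plate-reader
  error scales with signal; it is a simplification (no additive dark-count
  floor, no pipetting error on the x-axis).
* `simulate_centrifugation()` — replicated competition experiments in both
  mixing orders, with independent log-normal noise on each of the four
  measured concentrations. Order invariance of the estimates is a built-in
  consistency check on equilibrium (the model is order-free by construction;
  real kinetically trapped systems would not be).

All generators are pure functions of their design object and seed, so every
simulated dataset is exactly reproducible.

## 4. Structure comparison

`match_ca()` pairs Cα atoms across two structures using an explicit chain
correspondence plus residue number and name (mismatched or missing residues
are dropped and counted; insertion codes are ignored). `superpose()` is the
closed-form Kabsch solution: SVD of the cross-covariance of centred
coordinates, with the sign of the smallest singular vector corrected so the
rotation is proper ($\det R = +1$), and no outlier rejection — the reported
RMSD is over all matched pairs. Collinear point sets are rejected as
degenerate rather than silently returning one of the infinitely many optima.
`contacts()` inventories receptor residues near a ligand (heavy-atom cutoff,
default 4 Å) and classifies them as hydrogen-bonding (donor-acceptor
distance ≤ 3.5 Å and D-H···A angle ≥ 120° when the hydrogen is present)
or hydrophobic.

## 5. Numerical choices and problem sizes

* Grid energies are computed vectorised over all grid points per receptor
  atom; a default 125,000-point map over a few hundred atoms takes seconds on
  one CPU. The per-point cost is linear in receptor size; maps of full
  proteins (~10⁴ atoms) remain tractable (minutes).
* The 1-D $K_b$ profiles use a 60-point $\log_{10}$ grid over a wide default
  range ($10^2$–$10^{12}$ M⁻¹ direct, $10^2$–$10^{14}$ displacement)
  followed by golden-section refinement; binding constants are only ever
  meaningful on a log scale, and the grid stage makes the search robust to
  the multimodal profiles noisy data can produce.
* Root finding for the competition equilibrium is bracketed (guaranteed
  convergence) with Newton polish (fast tail convergence); tolerances are
  relative to $T_t$ so the solver behaves identically from picomolar to
  millimolar totals.
* Connected components use `igraph` on the thresholded lattice; region
  extraction on a default grid is sub-second.

These sizes (toy receptors of tens of atoms, grids up to the default 50³,
1000-case property sweeps, 200-replicate noise studies) are the package's own
validation choices: large enough to exercise every code path and expose
estimator failure modes, small enough that the entire suite runs in a couple
of minutes on a single CPU.
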