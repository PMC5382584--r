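---
title: "Population analysis of chaperone-bound transmembrane helices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of chaperone-bound transmembrane helices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovescope)
```

## Scope and model

`groovescope` analyzes molecular-dynamics trajectories of a recurring
structural motif: a Get3/TRC40/ArsA-family ATPase dimer (the *carrier*)
holding a single tail-anchored transmembrane helix (the *ligand*) in a
hydrophobic groove, in a box of water. The package does not run dynamics;
it consumes multi-model PDB trajectories (one MODEL per frame) and a
plain-text per-atom parameter table, and computes the observables by which
such simulations are usually summarized: superposition RMSD, a
helix-rotation angle, terminal hydration-shell counts, probe-to-pocket
contacts, 2-D population maps with cluster/dwell analysis, per-cluster
average structures, and a pairwise interaction-enthalpy surrogate. A
second, independent arm analyzes NADH-coupled ATPase assay traces.

## The helical-rotation metric

The central observable is the rotation of the carrier about the ligand
helix axis. Per frame:

1. the frame is superposed onto frame 0 using the ligand backbone
   (mass-weighted Kabsch fit, reflection-corrected);
2. the helix axis $a$ is the top eigenvector of the coordinate covariance
   of the ligand backbone **at frame 0**, oriented from the first selected
   residue toward the last (N→C). A per-frame axis would conflate helix
   flexing with carrier motion, which is why the axis is fixed after
   alignment;
3. $v_f = \mathrm{COM}(\text{carrier}) - \mathrm{COM}(\text{ligand
   backbone})$ is projected off the axis, $p_f = v_f - (v_f\cdot a)a$;
4. $\theta_f = \mathrm{atan2}(\lVert p_0 \times p_f\rVert,\; p_0\cdot
   p_f)$, reported in degrees.

$\theta$ is unsigned in $[0, 180]$ — rotation plots for these systems stay
below ~60° and no handedness convention is established for them — with a
signed variant (about $+a$, range $(-180, 180]$) behind the `signed` flag.
$\theta(0) = 0$ by construction, and the metric is invariant under any
global rigid transform of a frame (the ligand-backbone superposition
removes it; a property test asserts invariance to $10^{-6}$ degrees). The
ligand center of mass uses the backbone atoms only, for consistency with
the alignment selection. If the projected carrier offset $\lVert p_f
\rVert$ falls below 0.5 Å the angle is ill-conditioned and the frame is
reported as an error rather than a number.

Both the carrier selection entering the center of mass (whole carrier by
default) and the ligand backbone selection are configurable, since
reasonable analyses might restrict the carrier to its groove helices.

## Hydration shells, contacts, periodic boundaries

The terminal hydration count is the number of distinct water *oxygens*
(residues HOH/WAT/SOL; oxygen names O/OW/OH2) whose minimum-image distance
to **any heavy atom** of the first and last two ligand residues is ≤ 5 Å.
Each water counts once even if it touches both termini. The heavy-atom
and oxygen-only conventions are the standard water-shell semantics; the
boundary is inclusive (a water at exactly the cutoff counts), a choice one
must simply fix and test. Contacts use the same machinery: the minimum
heavy-atom distance between a probe residue's side chain and a pocket
selection, with an inclusive 4.5 Å default cutoff.

Minimum-image wrapping applies only when the trajectory carries an
orthorhombic box; without one, raw distances are used (stripped or
synthetic trajectories may legitimately be unboxed). Distances are
computed by a vectorized all-pairs evaluation — at the system sizes this
package targets (hundreds of atoms in the distance-relevant selections) a
cell list would add complexity without measurable benefit, and the
all-pairs path is what the brute-force oracle tests certify.

## Population maps, clusters, dwell intervals

Two per-frame series are binned on a 2-D grid with half-open bins
$[e, e+w)$ whose edges are multiples of the bin width. Defaults: 2° for
rotation, 1 for hydration counts, 0.25 Å for distances — matching the
visual granularity of published heat maps of these observables. Bins with
at least 10 % of the maximal bin count (configurable) are *significant*;
clusters are 8-connected components of significant bins (4-connectivity
needlessly fragments diagonal ridges). Clusters are indexed
chronologically — cluster 1 contains the earliest assigned frame — which
matches the convention of numbering the initial state first.

Frames map to the cluster owning their bin; frames in non-significant bins
stay unassigned rather than being forced into a nearest cluster, so
cluster occupancies need not sum to 100 %. Dwell intervals are maximal
runs of consecutive assigned frames, reported as (first, last) times; a
revisited cluster has several intervals. This accommodates trajectories
that alternate between two states, whose cluster time windows then
interleave.

Average structures superpose all member frames onto the first member via
the alignment selection (ligand backbone by default) and take the
unweighted coordinate mean.

## Interaction-enthalpy surrogate

Per-cluster binding enthalpies are estimated with a fixed-radius pairwise
generalized-Born model plus Lennard-Jones, summed over carrier–ligand atom
pairs:

$$E_{elec} = \sum_{ij} k_e q_i q_j \left[\frac{1}{\varepsilon_p r} -
\left(\frac{1}{\varepsilon_p} - \frac{1}{\varepsilon_w}\right)
\frac{1}{f_{GB}}\right], \quad
f_{GB} = \sqrt{r^2 + R_iR_j e^{-r^2/4R_iR_j}}$$

with $k_e = 332.0636$ kcal·Å/(mol·e²), $\varepsilon_p = 1$,
$\varepsilon_w = 78.5$, and Lorentz–Berthelot combining for the LJ term.
$f_{GB} \to r$ when either Born radius is zero, recovering the fully
screened $1/\varepsilon_w$ Coulomb limit. This is deliberately **not** a
full MM-GBSA: there is no surface-area (nonpolar) term and Born radii are
fixed inputs, not recomputed per snapshot. Absolute values are therefore
not comparable to force-field MM-GBSA numbers; the surrogate preserves the
*comparative* per-cluster analysis (which cluster binds tighter) while
being exactly testable against closed forms and a brute-force pair-sum
oracle. Favorable energies are negative; reports also carry $|E|$ since
enthalpy magnitudes are often quoted unsigned. Pairs closer than 0.1 Å
are treated as clashes and reported as errors naming the pair.

## ATPase assay kinetics

In the coupled assay, ATP turnover regenerates via pyruvate kinase and
lactate dehydrogenase oxidizes NADH 1:1, so the A340 slope converts
directly to a rate. The initial rate is an ordinary least-squares line
over a window (whole trace by default; an automatic option picks the
longest prefix with $r^2 \ge 0.99$), and

$$\text{activity} = \frac{|slope|}{\varepsilon \ell}\; V \cdot 60 \cdot
10^9 / m \quad [\text{nmol·min}^{-1}\text{mg}^{-1}]$$

with $\varepsilon = 6220\ \mathrm{M^{-1}cm^{-1}}$ for NADH at 340 nm, a
0.55 cm default path (a 200 µL fill in a 96-well plate; assay protocols
sometimes print "200 ml" for this volume, which we read as the standard
200 µL), both configurable. Relative Vmax divides each oxyanion
condition by the same enzyme's basal Vmax (the basal ratio is exactly 1),
with ratio uncertainties propagated as
$r\sqrt{(\sigma_a/a)^2 + (\sigma_b/b)^2}$; rounding happens only at
report time, at the table's printed precision.

## The synthetic generator

Because trajectories of real systems are rarely redistributable, the
generator builds a stylized complex with exactly known ground truth:

- a fixed 20-residue ideal α-helix backbone (chain L, 100°/1.5 Å per
  residue) along $z$ — the ligand;
- two rigid carrier arcs on a 9.7 Å cylinder (chain A spanning 120°,
  chain B 20°), deliberately asymmetric so the combined center of mass
  sits several Å off the axis and the rotation metric has a long lever
  arm;
- oxygen-only waters: per frame, exactly the scheduled number placed
  3.0–4.9 Å from terminal backbone atoms, the rest parked in a bulk shell
  > 7 Å away;
- a probe side-chain pseudo-atom on the last ligand residue, placed inside
  (≤ 4 Å) or far from (> 8 Å) a three-atom pocket on chain A according to
  a contact schedule;
- an 80 Å cubic box by default, exercising the minimum-image code.

Each frame the carrier is rigidly rotated about the ligand backbone's
principal axis through its mass-weighted center of mass — exactly the
axis and origin the analysis measures against — by the scheduled angle,
then Gaussian jitter of the configured σ is added to the carrier atoms.
The ligand is held fixed: it defines the analysis frame, and jittering it
would inject ligand-superposition noise into every observable, turning a
controlled recovery experiment into a joint test of two error sources.
Shell waters and the probe atom are placed exactly (after the jitter), so
hydration counts and contact flags are recovered exactly at any noise
level while rotation recovery degrades smoothly with σ (max error ≈ 0.25°
at σ = 0.1 Å over 120 frames). Dwell-state schedules come from
`make_cluster_schedule`: segments of constant (rotation, hydration,
contact) state with small within-state rotation jitter (0.4° s.d.
default), linear interpolation across gaps, and recorded frame ranges.

What the generator does **not** emulate: force-field dynamics, thermal
ensembles, helix flexing, water exchange kinetics, or any physical
realism in the parameters. Passing recovery tests therefore demonstrates
the *analysis* is correct, not that real simulations would show these
behaviors.

Assay traces follow $A_{340}(t) = \varepsilon\ell\,[\mathrm{NADH}]_0 -
\varepsilon\ell\,\text{rate}\cdot t + \mathcal N(0, \sigma)$ with
$[\mathrm{NADH}]_0 = 0.3$ mM, and refuse specifications that would
exhaust NADH before the trace ends.

## Numerical choices and degenerate inputs

- Kabsch superposition uses SVD with determinant sign correction; fewer
  than 3 atoms is an error.
- The principal axis requires a relative eigenvalue gap ≥ $10^{-6}$;
  planar/spherical selections raise an ambiguity error instead of
  returning an arbitrary direction.
- Convergence detection: the plateau is the mean of the final 20 % of the
  series; the convergence time is the earliest time from which every
  forward-looking window mean (5 ns window, 0.3-unit tolerance by
  default) stays within tolerance of the plateau. This is our
  construction — published convergence times are typically stated without
  a criterion — so the defaults are explicit and configurable.
- Histogram edges are width-aligned (`floor(min/width) * width`), making
  bin boundaries reproducible across runs with different data ranges.
- Ions are grouped with solvent by default; whether published enthalpy
  analyses included ions is typically unstated, and keeping them out of
  the carrier/ligand groups makes the pairwise sums unambiguous.
- All randomness flows through explicit seeds; a fixed seed gives
  bit-identical generator output and byte-identical pipeline files.

## Problem sizes

The bundled demos and validation runs use desk-scale versions of the
study conditions: 160 ns schedules at 0.4 ns/frame for the demos
(~400 frames), and 1600 snapshots at 0.1 ns/frame for the four-state
recovery run — the same snapshot count as the densest published analysis
this package's observables are modeled on. These sizes keep a full
validation run in the tens of seconds while leaving every algorithmic
path (binning, connectivity, dwell splitting, energetics) fully
exercised; nothing in the implementation is specific to these sizes.

## Limitations

- The enthalpy surrogate's absolute scale is not MM-GBSA-comparable (no
  nonpolar term, fixed radii); only within-system comparisons are
  meaningful.
- In a rigid-rotation synthetic system the carrier–ligand pair distances
  barely change between rotational states, so per-cluster enthalpy
  *contrasts* are small there by construction; contrast tests use
  explicitly separated geometries instead.
- The selection grammar covers chains, residue ranges, residue/atom names,
  backbone and water shorthands with boolean combinators — not the full
  expressiveness of MD analysis suites (no distance-based or within-style
  selections).
- Dwell-interval semantics (maximal consecutive assigned runs) are one
  defensible reading of cluster time windows; analyses built on smoothed
  state assignments (e.g. hidden-Markov smoothing) are out of scope.
- PDBx/mmCIF and binary trajectory formats are not read; the interchange
  format is multi-model PDB.
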