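---
title: "Methods: automated SEC-SAXS analysis of membrane-protein-detergent complexes"
author: "memsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated SEC-SAXS analysis of membrane-protein-detergent complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memsaxs)
```

## The problem

Membrane proteins are measured by small-angle X-ray scattering (SAXS) as
protein–detergent complexes (PDCs): the protein's transmembrane belt is
wrapped by a toroidal corona of detergent, hydrophobic tails against the
protein and hydrophilic heads facing the solvent. Inline size-exclusion
chromatography (SEC-SAXS) yields thousands of short-exposure 1D frames
spanning buffer and elution peaks. `memsaxs` automates the whole chain:
chromatogram processing with a quantitative quality score, model-free
invariants, and three low-resolution modeling routes chosen from whatever a
priori information is available.

## Chromatogram processing and the K figure of merit

The elution profile is the per-frame mean intensity over the common $s$
grid ($s = 4\pi \sin\theta/\lambda$, stored in Å$^{-1}$). Buffer frames are
found as the flattest low stretch: a sliding window of width
$\max(10, m/40)$ frames minimizing *mean + 2·|slope|·width + 2·sd*; among
windows scoring within one window-sd of the optimum the earliest is taken,
matching the usual pre-peak buffer. Peaks are contiguous stretches above
baseline + 5·noise, cut at half prominence; a stretch whose half-prominence
boundary does not exist on both sides (a drifting baseline, a truncated
elution) is not a peak. Sample and buffer frames are averaged with
inverse-variance weights and subtracted with uncertainties propagated in
quadrature.

Data quality is summarized by

$$K = 100\% \cdot c_v^{aver} \cdot \langle\chi^2\rangle,$$

where $c_v^{aver} = \sigma_{R_g}/R_g$ is the coefficient of variation of
the Guinier radius of the subtracted curve (a single fit; its worked
arithmetic $100\cdot(0.2/5.65)\cdot 2.46 = 8.7$ is reproduced by
`k_figure_of_merit()`), and $\langle\chi^2\rangle$ is the mean weighted
squared deviation of the peak frames from the frame of maximal integral
intensity,

$$\langle\chi^2\rangle = \frac{1}{m}\sum_l \frac{1}{n-1}\sum_k
\frac{(I_p - c_l I_l)^2}{\sigma_p^2 + c_l^2\sigma_l^2}.$$

$K < 10\%$ is reliable, $K \ge 30\%$ flags low quality. Two choices the
formula leaves open: (i) the frame set includes the reference frame (its
term is zero; for $m \ge 10$ the $\pm 1/m$ difference is negligible);
(ii) the exact minimizer of the summand over $c_l$ has no closed form, so
$c_l$ is the closed-form weighted least-squares scale with weights
$1/\sigma_p^2$ followed by one re-weighting iteration with the combined
variance — deterministic and, on replicate noise at the recorded
$\sigma$, calibrated so $\langle\chi^2\rangle$ tends to one (checked over
20 seeded repetitions in the tests).

## Model-free invariants

* **Guinier**: iterative window search restricted to $0.5 \le sR_g \le
  1.3$, with a sign-runs test on residuals (5% level) shrinking the window
  from the high-$s$ end while curvature is detected. $R_g = \sqrt{-3\,
  \mathrm{slope}}$, $\sigma_{R_g} = 3\sigma_{slope}/(2R_g)$.
* **P(r)**: regularized indirect transform on a 50-shell histogram basis
  with zero end points, second-derivative smoothness penalty, and the
  regularization weight at the L-curve corner. Without a $D_{max}$ hint, a
  geometric scan over $[2R_g, 5R_g]$ takes the smallest value whose
  solution stays above $-1\%$ of the maximum, ends gently (last shell below
  5% of the maximum — a large last-shell value means real pair distances
  are being truncated) and has a stable $R_g$. Intensities are normalized
  to unit scale internally so the estimator is scale invariant up to the
  conditioning of the solve.
* **Porod**: background $B$ from regressing $I$ on $s^{-4}$ over the
  high-$s$ quarter (clamped to $[0, \min I_{tail}]$), Porod constant from
  the tail mean of $s^4(I-B)$ (robust to compact-particle oscillations),
  invariant $Q$ assembled from a Guinier extension below $s_{min}$, the
  trapezoid over the data and a $K_p/s_{max}$ tail; $V = 2\pi^2 I_0/Q$.
  MW uses the common empirical 1.6 Å$^3$/Da divisor and is reported as
  *apparent*: the detergent biases it for PDCs.
* **Automatic $s_{max}$**: first local minimum of Savitzky–Golay smoothed
  (local quadratic, 11 points) log-intensity, requiring a dip of at least
  3% against the following maximum, capped at 0.10 Å$^{-1}$ by default.

## Detergent geometry

Tail length from the Tanford formula $l_c = 1.5 + 1.265\,n_c$ Å; the head
layer length defaults to the tail length. Tail volume uses the companion
volume formula $27.4 + 26.9\,n_c$ Å$^3$; head volumes come from a small
built-in table keyed by head formula (maltoside, glucoside, LDAO,
phosphocholine), with a 1.9 Å$^3$/electron fallback that is flagged.
Electron densities divide electron counts by these volumes; the protein
density comes from residue electron counts over standard residue volumes
(0.42 e$^-$/Å$^3$ fallback), buffer defaults to water (0.334 e$^-$/Å$^3$),
and user-supplied densities always win. Contrasts are densities minus
buffer.

The hybrid path starts the corona at $a = b = t = l_c$, ellipticity 1 and
rotation 0; the transmembrane thickness $a + t$ is capped at 45 Å. The
three-phase grid derives the protein cylinder from
$D_{memb} = D_{max} - 2\,l_{head} - 2\,l_{tail}$ with $D_{max}$ measured
orthogonal to the membrane normal.

Closed forms used as modeling restraints: a torus of central radius $R$
and cross-section radius $r$ has $V = 2\pi^2 R r^2$ and
$R_g^2 = R^2 + r^2$ (ellipticity $e$ scales in-plane second moments by
$(e^2 + e^{-2})/2$); both, and the hemi-torus variant, are validated
against Monte-Carlo point sampling in the tests. The *confined* corona
regions of the search grid (the solid of revolution between the cylinder
surface and the tail/head surfaces, split at the mid-plane into the two
hemi-tori) get their volumes in closed form and their $R_g$ by
deterministic 2D quadrature.

## Scattering engine

Intensities come from the Debye sum over pseudo-atoms or beads,
$I(s) = \Phi^2(s r_0)\sum_{ij} g_i g_j\,\mathrm{sinc}(s d_{ij})$ with
$g_i$ the contrast-times-volume and $\Phi$ the sphere form-factor
amplitude. For cost control pair distances are histogrammed; each bin is
evaluated at its weighted mean distance with a half-variance curvature
correction, leaving a third-order binning error (the default bin width
$\min(\pi/(32\,s_{max}),\ \mathrm{spacing}/2)$ keeps binned and exact sums
within 0.5% even through deep form-factor minima; the wider
$\min(\pi/(8\,s_{max}), r_{bead})$ suffices inside the annealers, where
binning error is far below the fit tolerance). $I(0) = (\sum g_i)^2$ is
computed exactly. Corona bodies around an atomic model are filled on a
3 Å lattice (tails in the torus, heads in the surrounding shell of
thickness $t$), excluding points within 1.7 Å + spacing/2 of any atom;
protein atoms carry per-element displaced-solvent volumes at the uniform
protein contrast. Atomic models are aligned by principal axes, longest
axis to $z$.

## The three modeling paths

**Path selection** is a deterministic truth table: atomic model + both
detergent formulae → hybrid corona fitting; both formulae + (sequence or a
direct protein density) → three-phase ab initio; anything less →
single-phase ab initio. Detergent chemistry is mandatory for the first
two, so a sequence-only record falls through to the third.

**Hybrid**: exhaustive grid search of $(a, b, t)$ over start
$\pm l_c/3$ (7 nodes per axis by default, i.e. a step of $l_c/6$ — the
range is prescribed, the step is this package's choice), ellipticity and
rotation held fixed, each node scored by weighted least squares with a
free scale and optional constant. Fits with $\chi^2 > 2$ carry a warning.

**Three-phase ab initio**: simulated annealing of per-bead phase labels
(solvent, protein, tails, heads) on a hexagonal close-packed grid filling
the $D_{max}$ sphere (40 beads per diameter by default), confined by
region masks: a fixed protein core at the origin (radius
$\max(3\ \mathrm{bead\ diameters},\ r_{50\%V}$ from the sequence MW at
1.21 Å$^3$/Da)), a free protein/solvent cylinder, tails and heads locked
to their hemi-torus regions, and one-bead-diameter boundary layers where
either adjacent phase is allowed. The energy adds to $\chi^2$: a
discontinuity penalty (fraction of non-solvent beads with fewer than 3
like-phase contacts of the 12 HCP neighbours), a looseness penalty
($1 -$ largest connected component fraction per phase), and squared
relative deviations of per-phase volumes and $R_g$ from the geometric
expectations (weights 20 and 10; discontinuity and looseness weight 1).
The start temperature is auto-calibrated to ~50% initial acceptance
(median $|\Delta E|/\ln 2$ over sampled moves), cooling 0.97 per sweep,
stopping after 12 improvement-free sweeps. $\chi^2$, contacts, moments
and the pair histogram are updated incrementally and exactly per move;
exact per-flip connectivity is prohibitive at $10^4$ beads, so the
looseness term is refreshed on a lagged schedule (every 500 accepted
moves and at every temperature step; exact evaluation is available and
used on small grids). Greedy descent ($T = 0$) is provably non-increasing
when the lagged term is disabled, which is how that property is tested.

**Single-phase ab initio**: the same engine with one particle phase in
the $D_{max}$ sphere, fit to $s \le s_{max}$ from the first-minimum rule.
$P_n$ symmetry uses an asymmetric-wedge scheme — wedge beads are
replicated by rotation about $z$ and symmetry mates flip as one orbit, so
outputs are exactly $n$-fold symmetric. Ten independent runs (the
protocol default) are compared by normalized spatial discrepancy (NSD,
the Kozin–Svergun symmetrized nearest-neighbour measure); the published
criterion names the "lowest variance" model while the conventional choice
is the lowest mean pairwise NSD — the mean is implemented and both are
recorded. The ensemble is aligned to that reference (principal axes, all
eight sign combinations including the improper ones, lowest NSD wins —
the enantiomer check), the occupancy map is thresholded at half the runs
into an averaged volume, and one refinement run is seeded from it with
beads outside locked to solvent. A hollow result (central occupancy below
30% of the shell) adds an informational empty-micelle note; modeling also
proceeds (with a warning) when $K \ge 30\%$, since a hard stop is easy to
configure but a hint is more useful.

## The synthetic generator

`phantom_spec()`/`make_phantom_pdc()` build a ground-truth PDC from the
same geometry family the search grid uses — protein cylinder, tails
between the cylinder surface and the tail torus surface, head shell of
the head-layer thickness — with maltoside-like contrasts
(+0.086/−0.057/+0.181 e$^-$/Å$^3$ for protein/tails/heads against water)
and the head thickness equal to the tail length, mirroring the modeling
assumption (real maltoside heads are thinner; that discrepancy is a known
limitation, not emulated). The oracle curve is the exact unbinned Debye
sum over a ≤2 Å fill. `simulate_frame_series()` adds a smooth power-law
buffer, a Gaussian elution peak (truncated below $10^{-6}$ of its
amplitude so distant frames are exactly buffer) and Gaussian noise
$\sigma(s) = \alpha\sqrt{I+\beta}$ with the true $\sigma$ recorded —
Gaussian rather than Poisson keeps the $\chi^2$ expectations exact at
typical SAXS count levels. Every output embeds its seed and spec;
regeneration is bit-identical. What passing tests show is therefore
recovery under matched geometry and honest noise; they do not probe
radiation damage, inter-particle interference, capillary fouling or
detector artefacts in real data.

## Problem sizes and numerical choices

The test-suite and acceptance computations use deliberately compact study
sizes chosen as this package's reference conditions: 600–1600 frame
simulated runs, a phantom of ~10$^4$ lattice points, three-phase grids of
24 beads per diameter (~10$^4$ beads; the production default stays at the
protocol's 40), single-phase grids of 12–24 beads per diameter with 5–10
consensus runs, and 343-node corona searches. Annealing runs are
bit-reproducible for a given seed. Degenerate inputs fail loudly with
named errors (too few points, non-monotone grids, all-zero frames,
vanishing Porod invariant, insufficient fit range, impossible corona
geometry), and alignment falls back to the identity with a warning when
the inertia tensor is degenerate.

## Known limitations

Ellipticity and corona rotation are held fixed (circular, horizontal
torus); nanodiscs, amphipols and bicelles are out of scope;
membrane-associated (surface-bound) proteins would need the fixed protein
core shifted to the disc edge — a documented extension, not implemented;
the apparent MW ignores detergent contributions by construction; and the
frame bundle is a plain gzip tar archive of per-frame profiles plus a
JSON manifest.
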