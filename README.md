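# memsaxs

Automated analysis and low-resolution modeling of SEC-SAXS data from
membrane proteins solubilized in detergent.

Membrane proteins are measured in solution as protein–detergent complexes
(PDCs): the transmembrane belt is wrapped by a toroidal detergent corona,
hydrophobic tails inward, hydrophilic heads outward. With inline
size-exclusion chromatography (SEC-SAXS) one run produces thousands of 1D
frames I(s) vs s = 4π sin θ/λ spanning buffer and elution peaks. This
package takes a run from raw frames to a structural model and a
machine-readable summary, for beamline pipelines and for anyone
re-analyzing SEC-SAXS series offline.

## What it computes

**Chromatogram processing.** Elution profile (per-frame mean intensity),
automatic buffer/sample region detection (all peaks), inverse-variance
frame averaging and subtraction, and the data-quality figure of merit

    K = 100% · c_v^aver · <χ²>,

the Guinier-R_g coefficient of variation of the subtracted curve times the
mean weighted squared deviation of the peak frames from the peak-maximum
frame. K < 10% is reliable, K ≥ 30% flags low quality (e.g.
`k_figure_of_merit(0.2/5.65, 2.46)` gives K = 8.7%, reliable).

**Model-free invariants.** Guinier fit with automatic range selection
(0.5 ≤ sR_g ≤ 1.3 plus a residual-curvature screen), P(r) by regularized
indirect transform with automatic D_max, Porod volume and apparent MW, and
the automatic s_max from the curve's first local minimum.

**Three modeling paths**, selected from the available a priori record:

1. *Hybrid corona fit* (atomic model + detergent formulae): grid search of
   the torus parameters (a, b, t) in start ± Tanford/3 around
   a = b = t = l_c = 1.5 + 1.265·n_c Å, Debye scattering of
   protein + tails + heads, χ² > 2 flagged.
2. *Three-phase ab initio* (formulae + sequence or densities): simulated
   annealing of solvent/protein/tails/heads bead labels on a close-packed
   grid confined to a cylinder (diameter D_memb = D_max − 2·l_head −
   2·l_tail) plus two hemi-tori, with connectivity penalties and per-phase
   volume/R_g restraints from closed-form torus geometry.
3. *Single-phase ab initio* (anything less): particle/solvent annealing
   against s ≤ s_max with Pn symmetry, 10 independent runs, NSD-based
   reference selection, ensemble averaging and a final refinement.

Results are written as subtracted curves, bead-model PDB files, a
chromatogram table, a frame bundle (gzip tar of per-frame profiles) and an
XML + JSON summary with machine-readable warning codes.

## Worked example

The synthetic generator builds a ground-truth PDC phantom and a full frame
series around it, so the pipeline can be exercised with no external data:

```r
library(memsaxs)

spec <- phantom_spec(protein_radius = 8, protein_height = 36, n_c = 8,
                     spacing = 3, s_grid = seq(0.008, 0.25, length.out = 100),
                     frames = 600, peak_frame = 300, peak_width = 25, seed = 11)
phantom <- make_phantom_pdc(spec)
sim <- simulate_frame_series(phantom$oracle, spec)

# a priori record: atomic model + detergent chemistry -> hybrid path
toy <- make_toy_protein(3, 24)
apriori <- apriori_info(atoms = toy, head_formula = "C6H11O6",
                        tail_formula = "C8H17")

report <- run_pipeline(sim$series, apriori,
                       ampp_config(seed = 4, corona_steps = 5,
                                   corona_spacing = 4),
                       out_dir = "ampp_out")
report
#> SEC-SAXS summary: 1 peak(s)
#>  peak 1: frames [270, 329), K = 1.4% (reliable), path = hybrid, model chi2 = 0.59

round(unlist(report$peaks[[1]]$overall), 2)
#>      Rg           I0      Rg_real         Dmax      V_porod       MW_kda  s_max
#>   26.10 150872342.13        25.20        67.01     73440.88        45.90   0.10
```

The sample region (frames 270–328) sits on the injected peak at frame 300;
K = 1.4% says the peak frames are mutually consistent and the Guinier fit
is tight, so the subtracted curve is trustworthy. The Guinier and
real-space R_g agree (26.1 vs 25.2 Å), D_max ≈ 67 Å matches the phantom
(62 Å plus the transform's resolution), and the corona fit reaches
χ² = 0.59 — no warnings fire. The apparent MW (45.9 kDa) includes the
detergent corona by construction, which is why it is labelled apparent.

A thin command-line front end covers the same workflow from a shell
(`run`, `chromatogram`, `invariants`, `simulate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ampp.R",package="memsaxs"))')" \
    run --frames frames_dir --apriori apriori.json --out out --seed 1
```

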