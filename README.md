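# memdrug

Trajectory analysis for small-molecule binding at phospholipid bilayer
membranes.

When a drug molecule sits at a lipid membrane interface, the questions a
simulation study asks are always the same: *where* does it bind (pair
structure), *how strongly* (free-energy barriers), *for how long*
(hydrogen-bond kinetics), and *does the membrane itself stay healthy*
(area per lipid, thickness). `memdrug` implements that analysis battery
for systems like a benzothiadiazine-class drug at a
DOPC/DOPS/cholesterol bilayer, plus a synthetic trajectory generator with
known ground truth so every estimator is testable without running
molecular dynamics.

## What it computes

* **Radial distribution functions.** For site selections A and B,

  g_AB(r) = V ⟨n_B(r)⟩ / (4 N_B π r² Δr),

  with minimum-image distances in orthorhombic boxes, half-open bins, and
  normalisation such that g → 1 at long range in a uniform system.
  Equivalent sites (e.g. the phosphoryl oxygens O13/O14) pool into one
  population at the selection level.

* **Potentials of mean force and barriers.** The reversible-work
  transform W(r) = −k_BT ln g(r), with W undefined (not capped) where
  g = 0; a barrier is ΔW = W(first local maximum) − W(preceding first
  local minimum) inside a search window, reported in k_BT and converted
  to kcal/mol with an explicit factor (default 0.596 kcal/mol per k_BT).

* **Membrane metrics.** Area per lipid A = LxLy / (lipids + cholesterol
  per leaflet) and bilayer thickness Δz = difference of per-leaflet mean
  phosphorus z, per frame and averaged.

* **Hydrogen-bond kinetics.** Distance-criterion bond timelines
  (cutoff 2.5 Å by default), mean continuous lifetimes τ with transient
  breaks below a tolerance (default 2 ns) merged away, and detection of
  bridging frames where two drug sites hold two distinct membrane
  molecules simultaneously.

* **Synthetic trajectories.** A two-leaflet pseudo-bilayer
  (56:14:30 DOPC:DOPS:cholesterol per leaflet, one drug molecule) whose
  donor sites bind partner oxygens as a seeded two-state process with
  prescribed bond-length distribution and on/off kinetics — the ground
  truth behind the whole test suite.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `05_hbonds.R`, shared settings in `00_config.R`); each
step regenerates the 200 ns synthetic trajectory deterministically from
the seed and writes its tables under `results/`. The same calls, directly:

```r
library(memdrug)

cfg <- synthetic_config(seed = 20260922L, n_frames = 2000L, dt = 0.1)
run <- generate_synthetic(cfg)

membrane_series(run$trajectory)
#> <membrane_series> 2000 frames: A = 60.94 +/- 3.09 A^2 (5.1%), dz = 42.99 +/- 0.04 A (0.1%)

h2  <- select_sites(run$system, "DBD3", "H2")
rdf <- pooled_rdf(run$trajectory, h2, "DOPC", c("O13", "O14"))
rdf
#> <rdf_curve> 240 bins, dr = 0.05 A, N_A = 1, N_B = 224, peak g = 211.187 at r = 1.675 A

extract_barrier(rdf_to_pmf(rdf))
#> <barrier_result> min W = -5.353 kBT at r = 1.675 A; max W = 1.518 kBT at r = 3.075 A; dW = 6.871 kBT (4.1 kcal/mol)
```

Reading: the bilayer stays intact (thickness pinned at 43 Å with 0.1%
fluctuation; the 5% area fluctuation is the configured box breathing);
the drug's H2 donor shows a sharp first shell at 1.675 ± 0.05 Å against
the pooled DOPC head oxygens — the generator's 1.7 Å hydrogen bond — and
unbinding it costs 6.9 k_BT (4.1 kcal/mol) on this record, the free-energy
barrier between the bound minimum and the first maximum of W(r).

The lifetime table from step 5 of the workflow, same trajectory:

```
          pair_label mean_distance_bound   tau n_intervals bound_fraction
1   H2 / O13-14 DOPC                1.70 18.29           8          0.732
2 H4 / O Cholesterol                2.06  5.73          12          0.321
```

H2 holds the DOPC head oxygens in long bound episodes (mean 18 ns on this
200 ns record, configured mean dwell 30 ns — edge truncation biases short
records downward); H4's cholesterol bond is an order faster, and 23% of
frames show both donors bridging two different membrane molecules.

A config-driven end-to-end run (`run_config()` / `run_all()`) produces
the same tables plus a provenance manifest from a single YAML file, and
reruns with the same seed are byte-identical.

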