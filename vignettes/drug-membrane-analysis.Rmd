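---
title: "Methods: drug–membrane interaction analysis from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug–membrane interaction analysis from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdrug)
```

## Scope

`memdrug` analyses molecular-dynamics trajectories of a small drug molecule
at a phospholipid bilayer (DOPC/DOPS/cholesterol in the default
vocabulary): site–site radial distribution functions (RDFs), potentials of
mean force (PMFs) and their free-energy barriers, area-per-lipid and
bilayer-thickness series, and hydrogen-bond lifetime and bridging
statistics. It does not run dynamics: no forces, no integrator, no
electrostatics. Trajectories come either from files (PDB/GRO single
frames, a plain-text multi-frame format, a JSON site map) or from the
package's own synthetic generator, which exists so that every estimator
can be validated against known ground truth.

## Radial distribution functions

For tagged site populations A and B the package computes

$$g_{AB}(r) = \frac{V\,\langle n_B(r)\rangle}{4 N_B \pi r^2 \Delta r},$$

where $n_B(r)$ counts B sites in the spherical shell $[r, r+\Delta r)$
around an A site (minimum-image convention, orthorhombic boxes only),
the average runs over frames and A sites, $N_B$ is the B population size
and $V$ the box volume. The normalisation makes $g \to 1$ at large $r$ in
a uniform fluid, which is tested directly on an ideal gas.

Numerical conventions, each covered by a test:

* **Volume.** $V$ is the trajectory-averaged box volume. Constant-pressure
  boxes fluctuate and a single convention is needed; the per-frame
  alternative differs only at the fluctuation level and the choice is
  recorded in the curve's metadata.
* **Binning.** Half-open bins $[r, r+\Delta r)$; distances at or beyond
  `r_max` are discarded; `r_max` may not exceed half the smallest box edge
  (minimum-image validity).
* **Shell area.** The denominator uses the bin-centre $r^2$ (first centre
  $\Delta r/2$), not the exact shell volume; at the default
  $\Delta r = 0.05$ Å the difference is below 1% and the brute-force
  equivalence test uses the same convention, so pair counts are compared
  bit for bit.
* **Defaults.** $\Delta r = 0.05$ Å and `r_max` = 12 Å resolve the
  1.6–2.1 Å hydrogen-bond band while keeping well inside the default box.

Equivalent sites (e.g. the two phosphoryl oxygens O13/O14, which share a
negative charge) are pooled **at the selection level**: the pooled
population becomes B with $N_B$ the pooled count. Averaging two separate
RDFs would give the same answer only with matched per-site counts, so a
single convention is enforced and the additivity of raw counts is tested.

## Potentials of mean force and barriers

The reversible-work relation $W_{AB}(r) = -k_BT \ln g_{AB}(r)$ converts an
RDF into a free-energy profile along the pair distance. $W$ is kept in
$k_BT$ units; bins with $g = 0$ are **undefined** (`NA`), not zero and not
capped — at finite sampling a vanishing $g$ carries no information.

A barrier is the difference between the **first local maximum** and the
preceding **first local minimum** of $W(r)$ inside a search window
(default 1–6 Å, spanning the hydrogen-bond first shell and the second
shells around 4–5 Å). Details that matter in practice:

* Extrema are located on the $r$-ordered sequence of *defined* bins, so
  sparsely sampled stretches where $g$ drops to zero between the first
  shell and the background do not mask the barrier.
* Sampling noise creates spurious extrema. A prominence threshold (default
  0.05 $k_BT$) discards minimum/maximum pairs whose rise is smaller; an
  optional centred moving average (odd window) is available but off by
  default — barrier heights are read off whatever curve the extrema were
  found on.
* Ties resolve toward smaller $r$; a window with no minimum-then-maximum
  pattern yields a distinct "no barrier" result, not $\Delta W = 0$.
* The quartic double-well oracle pins the numerics: recovered extrema sit
  within one bin width of the analytic ones and $\Delta W$ matches the
  grid-evaluated value to $10^{-9}$.

Barriers are reported in $k_BT$ and converted to kcal/mol with an
**explicit factor defaulting to 0.596**. That printed convention
corresponds to roughly 300 K, while the simulated temperature of 310.15 K
would give $k_BT \approx 0.616$ kcal/mol; the package follows the printed
convention by default, never recomputes the factor from temperature
silently, and leaves the choice to the caller as a visible argument.

## Membrane metrics

Area per lipid is $A = L_x L_y / N_\text{leaflet}$ with
$N_\text{leaflet}$ the number of lipid **plus cholesterol** molecules in
one leaflet (cholesterol is part of the definition here; a flag exposes
the lipid-only convention for comparison with other tools). Bilayer
thickness $\Delta z$ is the difference between per-leaflet mean
phosphorus $z$-coordinates — robust, translation invariant, and a single
scalar per frame. Series summaries use the population standard deviation
(the series is the full record, not a sample), verified against a
two-pass oracle at $10^{-12}$.

Leaflet labels are taken from the site map when present; otherwise they
are assigned from a reference frame by the sign of the phosphorus $z$
relative to the median phosphorus $z$ (cholesterol uses its hydroxyl
oxygen). This presumes an intact, roughly planar bilayer — it will
mislabel heavily undulating membranes.

## Hydrogen-bond kinetics

Bond detection is **distance-only**: bound iff the minimum-image
donor–acceptor distance is $\le$ cutoff, boundary inclusive. The default
cutoff of 2.5 Å encloses the observed 1.6–2.1 Å band with margin; no
angular criterion is imposed because none is needed to reproduce the
distance signature, and the geometry of a coarse site map may not support
one. For pooled partners (O13-14 style) the per-frame bond partner is the
nearest pooled site, so a swap between equivalent oxygens of one molecule
is not a break.

The lifetime $\tau$ is the mean duration of continuous bound intervals
after merging unbound gaps no longer than a **tolerance** (default 2 ns —
transient breaking and reformation is measurement noise at the timescales
of interest, and every output header logs the value used). A merged
interval spans its internal gaps, so two 10 ns runs across a 0.2 ns break
count as one 20.2 ns interval. $\tau$ is non-decreasing in the tolerance
(tested on random timelines). Intervals truncated by the trajectory ends
are included by default, which biases $\tau$ downward when lifetimes are
comparable to the record length; `include_edges = FALSE` trades that bias
for discarded data. Never-bound pairs report `tau = NA` with zero
intervals — deliberately distinct from $\tau = 0$.

A **bridge** is a frame in which at least two drug sites are
simultaneously bound to sites of two *distinct* membrane molecules (two
bonds to one molecule is a chelate, not a bridge). Detection is verified
against a brute-force triple loop.

## The synthetic generator

The generator emulates the statistical shapes the estimators consume,
not the physics that produces them:

* **Geometry.** Two leaflets of 100 pseudo-molecules each (56 DOPC,
  14 DOPS, 30 cholesterol — largest-remainder rounding for other sizes) on
  jittered square lattices at $z = \pm 21.5$ Å in a
  78.1 × 78.1 × 95.7 Å box; phospholipids carry P, O13/O14 (head),
  O11/O12, O22/O32 (toward the bilayer centre), cholesterol carries its
  hydroxyl O/H, and a single drug molecule (H2, H4, O11, O12) sits at the
  upper interface.
* **Kinetics.** Each donor follows an alternating renewal process:
  exponential unbound dwell at rate $\sum_j k_\mathrm{on}^{(j)}$, partner
  $j$ chosen with probability $\propto k_\mathrm{on}^{(j)}$, exponential
  bound dwell at that partner's $k_\mathrm{off}$. With one partner per
  donor — the default — this is exactly the independent two-state chain.
  The competing-risks form was chosen over fully independent per-pair
  chains so a donor is never geometrically bound to two partners at once
  and coordinates stay consistent with the ground-truth timelines.
* **Distances.** While bound the donor–partner distance is
  $|N(\mu, \sigma)|$ ($\mu$ = 1.7 Å for H2, 2.05 Å for H4, $\sigma$ =
  0.1 Å); the Gaussian form is this package's assumption — nothing in the
  emulated setting prescribes a distribution, only the band. While
  unbound the donor random-walks in the interfacial slab with reflecting
  walls, excluded from coming within 4 Å of any partner-pool oxygen so
  that first shells stay attributable and ground truth is never
  contradicted by geometry.
* **Clocks.** The two-state process lives on a continuous clock
  (returned as ground truth) and is *sampled* on the frame grid, exactly
  as a real trajectory analysis would sample it — so the estimator's
  discretisation bias is measurable: sub-`dt` excursions can be missed,
  and the tests quantify the residual bias against the $1/k_\mathrm{off}$
  closed form.
* **Fluctuations.** The lateral box area breathes with a configurable
  relative jitter (default 5%, matching the fluctuation level the
  analyses are expected to tolerate), lipid atoms get 0.25 Å thermal
  jitter, leaflet placement jitters by 0.5 Å in $z$.
* **Defaults for rates.** $k_\mathrm{on} = 0.1$ ns$^{-1}$ for both
  donors; $k_\mathrm{off} = 1/30$ ns$^{-1}$ (H2 at the DOPC head
  oxygens) and $1/4$ ns$^{-1}$ (H4 at the cholesterol hydroxyl), placing
  mean lifetimes at 30 and 4 ns — inside the 1–70 ns regime the analyses
  target, with the head-group bond much longer-lived than the
  cholesterol bond.

What passing tests on this generator **do** show: the estimators recover
known dwell times, bond lengths, leaflet geometry and fluctuation levels,
with the correct normalisations and conventions. What they **do not**
show: anything about force-field realism — the generator has no water, no
ions, no lipid conformational dynamics, no correlated motions, no
drug translocation across leaflets; RDF backgrounds beyond the first
shell are shaped by the walker's slab, not by liquid structure. Claims
about real membranes require real trajectories.

## Reproducibility and problem sizes

Everything stochastic is seeded; identical `(seed, config)` reproduce
bit-identical trajectories and byte-identical pipeline CSVs (the manifest
carries the only timestamp). The generator keeps its RNG stream isolated
so callers' `set.seed` state is untouched.

The analysis scripts use a 2000-frame, 0.1 ns-per-frame record (200 ns)
of the 1104-atom default system — enough for tens of binding events of
the slow pair and hundreds of the fast one; lifetime-estimator
calibration uses a coordinate-free distance timeline of $2.4 \times 10^6$
frames ($\ge 2000$ bound intervals), and the uniform-limit RDF check uses
a 4000-point ideal gas over 200 frames. These sizes were chosen so each
statistical assertion has at least ~3-standard-error headroom.

## Known limitations

* Orthorhombic boxes only; triclinic input is rejected at the readers.
* The PMF route is the reversible-work transform of an equilibrium RDF;
  it is not umbrella sampling or constrained-force averaging and inherits
  every sampling defect of the RDF, especially near $g \to 0$.
* $\tau$ from mean continuous intervals is not an autocorrelation-based
  lifetime; intermittent/continuous correlation-function formalisms are
  deliberately out of scope.
* The distance-only bond criterion cannot distinguish a hydrogen bond
  from an incidental close contact of the donor with a heavy atom; with
  coarse site maps this is the only workable criterion, and the cutoff is
  logged in every output.
* DCD/XTC binary trajectories are not read; the canonical format is
  plain text, with PDB/GRO for single frames.
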