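---
title: "Coarse-grained modelling of intermediate filament subunit plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of intermediate filament subunit plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(ifplast)
```

## The scientific problem

Intermediate filaments (IFs) such as vimentin, desmin and the keratins
assemble from a soluble pool of subunits: coiled-coil dimers about 50 nm
long, and tetramers — two antiparallel, half-staggered dimers — that appear
as roughly 75 nm rods. Textbook cartoons draw these subunits as straight
sticks, but imaging of dried subunits on mica shows everything from extended
curly threads to compact dots 17–26 nm across, with divalent ions or
chemical fixation shifting the population towards the dots. Two structural
elements explain the flexibility: each coiled-coil segment is only about as
long as its own persistence length (~25 nm), so its ends decorrelate by
roughly 70 degrees; and the short L12 linker between the two coil segments
acts as a nearly free hinge.

`ifplast` packages a desk-scale computational counterpart of that study:

* bead–chain models of the dimer and tetramer (`build_dimer()`,
  `build_tetramer()`);
* an adhesive substrate modelled as a hexagonal lattice of Lennard-Jones
  beads, calibrated against a stated adhesion energy density
  (`build_substrate()`, `calibrate_bead_well_depth()`);
* overdamped Langevin sampling in solution and during deposition
  (`run_simulation()`), with conformational observables (`end_to_end_length()`,
  `projection_area()`, `cg_sasa()`, `kabsch_rmsd()`,
  `estimate_persistence_length()`);
* a synthetic AFM scene generator and a height-map morphometry pipeline
  (`generate_scene()`, `measure_afm_image()`) so that the image-analysis
  side is testable end-to-end without instrument data.

## The chain model

One bead represents 1 nm of dimer contour (radius 1 nm, matching the ~2 nm
dimer width). A dimer is a 51-bead path: coil 1 (22 nm), the L12 linker
(3 nm), coil 2 (25 nm) — the split respects the constraint that each coil is
20–25 nm long and the total is 50 nm. Both strands of the coiled coil run
through the same beads, so a bead carries ~18 residues
(2 x ~466 residues / 51 beads).

The energy is a sum of standard coarse-grained terms
(`forcefield_params()`):

| term | form | default | why |
|---|---|---|---|
| bonds | harmonic, ½k(r−b)² | k = 50 kcal/mol/nm² | stiff but integrable at the chosen step |
| bending (coil) | ½k θ², θ = deviation from straight | 14.90 kcal/mol/rad² | `Lp kBT / b` with Lp = 25 nm at 300 K |
| bending (hinge) | same | 0.60 (Lp ≈ 1 nm) | the L12 linker is nearly free |
| excluded volume | WCA at bead diameter | ε = 1, σ = 2 nm | pure repulsion, no spurious cohesion |
| electrostatics | Yukawa between coil beads | −1 e/bead, λD = 0.8 nm, ε_r = 78.5 | coil segments repel at assembly pH; λD for the NaCl condition (~3 nm would model low salt) |
| crosslinks | harmonic | k = 5 kcal/mol/nm², rest 2 nm | soft stand-in for A11-overlap cohesion |

The tetramer is two antiparallel dimer copies, staggered by 25 nm and offset
laterally by 2 nm, with crosslinks between facing overlap beads. The 2 nm
gap is inferred from the dimer width — no inter-dimer potential is given in
the source literature, so this is a package choice.

## Substrate adhesion and its calibration

The substrate is a rigid triangular lattice of beads at z = 0 with 0.98 nm
spacing. Chain and lattice beads interact through
`ε[(σ/r)¹² − 2(σ/r)⁶]`, written so that σ is the distance of zero force and
the well depth is −ε. The calibration chain is:

1. a per-residue adhesion well of 1.48 kcal/mol, consistent with an adhesion
   energy density of 50–60 mJ/m² over a 0.28 nm² residue footprint
   (`gamma_to_per_residue_energy(50, 0.28)` = 2.01 kcal/mol brackets it from
   above);
2. a per-bead target of 18 x 1.48 = 26.64 kcal/mol;
3. `calibrate_bead_well_depth()` finds the per-pair ε whose lattice-summed
   single-bead well equals that target. The sum is linear in ε, so one
   unit-depth z-scan gives the answer exactly; tests confirm the round trip
   against a brute-force scan.

Two numerical choices matter here. First, the per-pair σ: the all-atom
combining rule behind the original substrate cannot be recovered, so σ is a
single configurable number. We use 0.7 nm — the smallest value at which the
lattice plane is impenetrable. Below ~0.63 nm the three-fold hollows (nearest
bead only 0.57 nm away laterally) become attractive channels and the energy
minimum sits *inside* the plane; at 0.7 nm a bead adsorbs at z ≈ 0.41 nm,
and deposited chains sit at a mean height of ~0.42 nm, squarely in the
physically expected 0.3–1.0 nm range. Second, the nonbonded cutoff is
2.5 nm, below the 3 nm starting height, so a freshly placed subunit starts
outside interaction range.

The adsorbed surface is strongly corrugated: the well above a hollow site
(−26.6 kcal/mol) is over twice as deep as above a lattice bead
(−12 kcal/mol), so lateral hopping costs many kBT and an adsorbed chain is
effectively pinned — the model's expression of the observation that the
surface traps subunits in the conformation they arrive with.

## Dynamics

`run_simulation()` integrates overdamped Langevin dynamics: position update
`dx = (F/γ) dt + sqrt(2 kBT dt/γ) ξ`, with γ = 1 per bead. A Nose-Hoover
thermostat on inertial dynamics would add nothing at this resolution;
temperature enters only through fluctuation–dissipation. Units are nm and
kcal/mol, so one reduced time unit is the time a free bead needs to diffuse
~1 nm (D = kBT/γ = 0.596 nm²/τ at 300 K).

* Timestep: 1e-3 τ in solution (bond forces limit stability), 1e-4 τ over
  the substrate (the adhesion well is the stiffest curvature, ~600
  kcal/mol/nm²). A force-overflow guard aborts with the offending step if an
  unstable step is requested.
* The substrate force inside the integrator is trilinearly interpolated
  from a table built at run start by exact lattice summation on a 0.02 nm
  grid over the periodic cell; this is ~10x faster than direct summation
  and agrees with the exact gradient to ~1%. All *exported* energies use
  the exact pairwise sum.
* The deposition protocol applies a constant downward force
  (0.0012 kcal/mol/Å per residue, x18 per bead) to beads more than 5 nm
  above the plane; a subunit placed at the standard 3 nm never feels it,
  but it guards against escape during long runs.
* Randomness: one dedicated xoshiro256+ stream per run, seeded from the
  run config; repeated runs are bit-identical.
* Environment modes: `substrate+calcium` switches on a Gaussian attraction
  (depth 1.5 kcal/mol, range 1.5 nm, both configurable) between nonbonded
  coil beads, a stand-in for divalent bridging; `substrate+glutaraldehyde`
  freezes every nonbonded pair currently within 1.5 nm into a permanent
  harmonic crosslink, once, at invocation.

Equilibration is convergence-driven rather than wall-clock-driven:
`check_convergence()` requires the trailing RMSD-to-reference series to show
bounded drift and fluctuation.

### Problem sizes

The package's standard experiments are sized for a desk: persistence
recovery uses 4e6 steps of a 26-bead coil per seed (about 400 equilibrated
frames over three seeds); deposition runs use 1.2–1.5e6 steps (capture
happens within the first ~10 τ, the rest is plateau); solution reference
runs use 2–2.5e6 steps at the coarser solution timestep, enough for clear
compaction though not for the fully collapsed hairpin equilibrium, which
needs roughly another order of magnitude of sampling.

## What the model reproduces, and one thing it cannot

With these ingredients the package reproduces, from scratch:

* the conversion 50–60 mJ/m² x 0.28 nm² → 2.01–2.42 kcal/mol;
* the ~70° mean tangent angle of a coil segment one persistence length long;
* recovery of the 25 nm persistence length (±10%) from simulated tangent
  correlations, closing the loop `Lp → bend_k → simulation → fitted Lp`;
* the deposited dimer length: a straight-started dimer lands nearly
  extended, mean end-to-end ≈ 49 nm against the measured 47.9 ± 0.1 nm;
* the solution/substrate contrast: with matched seeds, solution runs are
  always more compact than deposition runs, for dimer and tetramer alike.

The deposited *tetramer*, however, stays a ~73 nm rod in this model, well
above the measured 58.5 ± 0.3 nm. The reason is instructive: lumping 18
residues into one bead turns a per-residue well of ~2.5 kBT (reversible,
residue-by-residue) into a per-bead well of ~45 kBT (irreversible). A
straight-started rod reaches the surface long before the slow rotation of
its protruding dimer arms about the L12 hinges (10³–10⁴ τ) can fold it, and
is then pinned as-is. An atomistic subunit keeps re-equilibrating while
adsorbed and arrives from an already-equilibrated solution structure, so it
lands partially folded. The dimer is insensitive to this artifact — its
trapped conformation is nearly straight anyway — but honest CG tetramer
deposition from an extended start cannot land at 58 nm without either
per-residue adhesion resolution or an equilibrated starting conformation.
We report the discrepancy rather than re-tuning the calibrated adhesion or
the prescribed protocol.

## Conformational observables

* `end_to_end_length()`: terminal-bead distance; for the tetramer, the
  maximum over the terminal beads of the two paths (an "end-to-end length"
  is otherwise undefined for a two-chain object).
* `kabsch_rmsd()`: SVD superposition, proper rotations only, equal weights.
* `projection_area()`: the union of bead disks rasterised in a
  principal-axis frame. The convention "project along the first principal
  axis" taken literally gives the minimal cross-section of a rod; because
  the observable is meant to track spreading on the surface, the default
  projects onto the plane of the first two axes (normal = third axis), and
  `plane = "first_axis"` switches to the literal convention. Degenerate
  (collinear) frames fall back to a fixed lexicographic axis order.
* `cg_sasa()`: Shrake–Rupley point sampling on a deterministic Fibonacci
  sphere (362 points/bead by default).
* `estimate_persistence_length()`: log-linear fit of pooled bond-tangent
  correlations over lags 1–10; a chain with no measurable decay returns
  `Inf` flagged `"ge_contour"`.
* `equivalent_disk_diameter()`: `2 sqrt(A/pi)`. Note that applying it to
  footprint areas of 587 and 246 nm² gives 27.3 and 17.7 nm, slightly above
  the 26 and 17 nm quoted alongside those areas in the experimental
  literature; the formula is exact, so we keep it and note the mismatch.

## The synthetic AFM generator

`generate_scene()` renders what a dried-subunit field looks like to an AFM:

* dots: spherical caps whose true footprint areas are exponential with the
  preset mean — the measured area distributions decrease exponentially, and
  the exponential is the maximum-entropy choice given only a mean;
* curly threads: discrete 2D worm-like centrelines (step 2 nm, planar
  persistence length 50 nm, width 6 nm — invented but visually and
  statistically plausible) with a cap cross-profile;
* per-object peak heights: normal with the preset mean/sd, truncated at 0,
  and each rendered object is rescaled so its maximum equals its drawn
  height exactly;
* optional filaments: straight tapes (height 2.5 ± 0.8 nm) crossing the
  image;
* tip dilation (`render_tip_dilation()`): grayscale morphological dilation
  by a spherical cap, the standard first-order tip-convolution model;
* noise (`add_noise()`): white Gaussian height noise, default 0.03 nm.

Objects are placed by rejection sampling with a 3-px separation margin. The
whole population is drawn *before* placement and placed largest-first;
re-drawing an object on rejection would systematically thin the large-area
tail. Every object's class, drawn area, drawn height and footprint mask are
recorded as ground truth.

Defaults the experimental record does not fix: image 2 x 2 µm, pixel 1 nm.
The pixel size matters: at 2 nm the 6 nm thread crest is sampled by barely
three pixels and no local denoising can both suppress the noise-driven
positive bias of per-object maxima and leave crest heights unbiased; at 1 nm
both biases sit at the percent level.

What the generator does **not** emulate: feedback artifacts, line noise and
drift, tip wear and double-tip images, the molecular substructure of
subunits, or any correlation between a subunit's height and its area.
Passing round-trip tests therefore demonstrates that the measurement
pipeline is unbiased for idealised AFM fields with known statistics — not
that it would be artifact-proof on instrument data.

## The morphometry pipeline

`measure_afm_image()` chains the steps: `flatten_background()` (exact
least-squares plane removal plus median recentring — a plane is removed
exactly, thin sparse objects bias it negligibly), `segment_objects()`,
`exclude_filament_contacts()`, then `summarize_objects()` /
`area_probability_distribution()`.

Segmentation thresholds at `k_sigma = 3` robust noise sd (MAD of the whole
flattened image), labels 8-connected components, drops objects under
8 pixels (a false-positive floor: a blank noise image yields zero objects)
and flags border-touching objects. A 3x3 mean denoise precedes the
threshold. Heights use a robust peak statistic: the median of *unsmoothed*
heights over the object pixels within one smoothed-noise sd of the smoothed
maximum. A plain maximum is biased upward by the noise's extreme-value
statistics over the near-flat top of wide thin objects (~+15% at 0.03 nm
noise on 0.31 nm objects); a smoothed maximum erodes few-pixel peaks of
the smallest objects (~-20%); the near-peak median has neither problem and
reduces to the exact maximum on clean images.

Class labels: `filament` when the footprint exceeds 5000 nm² *or* the
object is taller than 1.5 nm. An elongation-based filament rule would
misclassify legitimate long threads (a 570 nm² thread at 6 nm width has
aspect ratio ~16), whereas height separates the populations cleanly —
filament tapes are 4–8x taller than dried subunits. Subunits are `thread`
above elongation 2.5, else `dot`. All thresholds are arguments.

Filament contacts: subunits whose footprint comes within 3 px of a filament
footprint are flagged and excluded from statistics. The radius cannot
meaningfully be 1 px: 8-connected labelling already merges anything that
close into the filament component itself.

Expected recovery accuracy at the default settings, n = 500 objects: mean
peak height within ~2%, mean footprint area within ~5% for dot-dominated
scenes and ~12% for tall thread-rich ones (threshold clipping of the cap
skirt pulls areas down a few percent; tip dilation pushes tall thread
footprints up — and the exponential area law, with sd equal to its mean,
makes areas the noisier statistic in any case).

## Known limitations

* Adhesion is irreversible at bead resolution (the tetramer discussion
  above); kinetic competition between adsorption and folding is therefore
  not quantitative.
* Electrostatics between the chain and the substrate are off: the substrate
  beads are formally neutral in the calibrated model, although the original
  energy decomposition mentions a substrate electrostatic contribution —
  the two statements cannot both hold, and we follow the zero-charge
  parameterisation.
* No hydrodynamic interactions; friction is per-bead.
* The 2D worm-like thread model and the filament tape are caricatures
  adequate for statistics, not for morphology.
* Assembly kinetics (unit-length filaments, end-to-end annealing) are out
  of scope.
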