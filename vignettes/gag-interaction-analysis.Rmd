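---
title: "Characterizing protein-glycosaminoglycan binding from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing protein-glycosaminoglycan binding from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gaginter)
```

## The problem

Synovial fluid owes much of its lubricating ability to interactions among
its macromolecular components. Two of them are human serum albumin (HSA),
a 585-residue transport protein organized into domains I-III, each split
into subdomains A and B, and chondroitin sulfate (CS), a highly negatively
charged glycosaminoglycan of alternating N-acetylgalactosamine (GalNAc)
and glucuronic acid (GlcA) units. CS occurs in two isomeric forms that
differ only in the sulfation position on GalNAc - C4 (CS-4) versus C6
(CS-6) - and their relative abundance changes with joint disease. Whether,
where, and how strongly CS binds albumin, and how dissolved Na+, Ca2+ or
Mg2+ ions modulate that binding, is therefore of direct interest for
understanding cartilage lubrication.

`gaginter` implements the trajectory-analysis side of this question: given
multi-frame structural snapshots of a receptor-ligand-solvent-ion system,
it detects and counts the interactions that hold such complexes together,
quantifies conformational stability, and performs the binding-energy
accounting used to rank complexes. Because no public trajectories exist
for this system, the package ships a synthetic-trajectory generator that
plants interactions with known ground truth, so that every detector is
validated end to end before it is pointed at real data.

## Interaction model

**Hydrogen bonds (HBo).** A candidate is any donor-H...acceptor triple in
which donor and acceptor are N or O atoms (donors carry a bonded
hydrogen) on opposite sides of the partition pair being scanned. The bond
energy is

E = E_opt x f(d_HA) x g(theta_donor) x g(theta_acceptor),

with optimum `E_opt = 25` kJ/mol, a distance factor `f` equal to 1 up to
2.1 Angstrom and falling linearly to 0 at 2.6 Angstrom, and angular
factors `g` rising linearly from 0 at 100 degrees to 1 at 180 degrees
(donor angle at the hydrogen; acceptor angle against the acceptor's first
bonded heavy neighbor, taken as ideal when the acceptor has none). A bond
is *counted* when E reaches 25% of the optimum, 6.25 kJ/mol. The ramp
boundaries and the angular gate are parameters of
`analysis_params()`; the published account of this system states the
optimum and the 25% counting rule but not the functional form, so the
piecewise-linear form here is the package's own documented choice, chosen
to be exactly reproducible and monotone where the model requires it.

**Hydrophobic contacts (HP).** An atom is flagged hydrophobic when it is
carbon or sulfur and all of its bonded heavy neighbors are carbon or
sulfur (vacuously true for isolated pseudo-atoms). A contact is a
receptor-ligand pair of flagged atoms within `hp_cutoff`, default 4.5
Angstrom between centers. No distance criterion for HP contacts is stated
in the source account; 4.5 Angstrom follows common contact-analysis
practice and is configuration-exposed.

**Ionic contacts.** Formal charge groups are built by rule: Arg
guanidinium and Lys ammonium (+1), Asp/Glu carboxylate (-1), the ligand
sulfate (-1, representative atom S) and carboxylate (-1, representative
C), and monatomic ions (Na +1, Ca/Mg +2, Cl -1). A contact is a pair of
opposite-sign groups on opposite solutes whose geometric centers (mean of
member heavy atoms) lie within `ionic_cutoff`, default 5.0 Angstrom -
again a documented package choice, not a recovered parameter.

**Bridges.** A water bridge exists when one water molecule forms counted
hydrogen bonds to a receptor atom and to a ligand atom in the same frame;
an ionic bridge exists when one cation lies within `ionic_cutoff` of the
centers of a negative receptor group and a negative ligand group
simultaneously (anions never mediate). Bridge records carry a class label
joining the element of each side's representative heavy atom through the
mediator species, e.g. `C-Ca-C` for a Glu carboxylate bridged by calcium
to a sugar carboxylate; carboxylates are represented by their carbon and
sulfates by their sulfur, which is what makes the reported `C-Ca-C` and
carbon-sulfur classes come out as element pairs rather than oxygens.
Bridges are counted per frame with no minimum lifetime - they are known
to be short-lived, and the census counts states, not episodes. Single
ring/hydroxyl oxygens as cation-coordination endpoints (giving classes
like `C-Ca-O`) are supported but opt-in via `coordination_classes`,
because they are not formal charge groups.

**Windowing.** All reported statistics are means with doubled population
standard deviations over the analysis window, by default the portion of
the trajectory after the 40 ns equilibration point up to 140 ns. "From 40
ns" is boundary-ambiguous, so the package fixes one convention: a frame is
included when its time is *strictly greater* than `equilibration_time` and
at most `window_end`. On the canonical 100 ps save schedule (1400 frames
over 140 ns) this yields exactly 1000 analysis frames.
`equilibration_onset()` offers an automatic plateau finder (rolling-mean
slope below a tolerance) as an alternative to the fixed default.

## Binding-energy accounting

The energy needed to disassemble the complex into separated, solvated
parts is

Ebind = Epr + Epl + Esr + Esl - Epc - Esc,

where `Ep*` are potential energies of receptor, ligand and complex and
`Es*` the corresponding solvation energies. The energy of binding is
`EoB = -Ebind`, negative for favorable binding; lower EoB means stronger
binding. Solvation terms are priced through the solvent-accessible
surface area at 0.65 kJ/mol per Angstrom^2 of exposed area; because this
cost carries a receptor-dependent constant, EoB is meaningful only
comparatively, and every report tags the cost parameter used. The
potential-energy components are ingested from per-frame TSV tables
(`read_energy_table()`) - they come from whatever engine produced the
trajectory, and recomputing them is explicitly not this package's job. A
minimal Coulomb+Lennard-Jones evaluator (`pairwise_energy()`) exists only
so fixtures can be made self-consistent in tests.

SASA is computed with the Shrake-Rupley method on a deterministic golden-
spiral point set (default 960 points/atom, probe 1.4 Angstrom) over a
fixed element radius table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, Na
2.27, Mg 1.73, Ca 2.31, Cl 1.75 Angstrom), all overridable. With 960
points the two-sphere case agrees with the exact spherical-cap formula to
well under 2%.

`rank_complexes()` averages each complex's windowed EoB means across its
salt solutions, sorts ascending (ties keep input order) and attaches
docking ranks; `isomer_contrast()` compares the grand means of two rank
tables as `100 x (|m_CS4| - |m_CS6|) / |m_CS4|`. The grand mean is taken
over the ten per-complex averaged values (one per docked complex), not
over the thirty per-solution values; that normalization is what
reproduces the published ~15% advantage of CS-4 over CS-6 from the
published per-complex table, which ships with the package
(`reference_eob()`).

```{r}
ref <- reference_eob()
r4 <- rank_complexes(data.frame(complex = 1:10, eob = ref$eob[ref$isomer == "CS4"]))
r6 <- rank_complexes(data.frame(complex = 1:10, eob = ref$eob[ref$isomer == "CS6"]))
c(cs4 = mean(r4$mean_eob), cs6 = mean(r6$mean_eob),
  contrast_pct = isomer_contrast(r4, r6))
```

## Stability analysis

`superpose()` computes the least-squares rigid fit (Kabsch, via SVD, with
the determinant correction that guarantees a proper rotation);
`rmsd_series()` reports the minimized deviation of every frame against a
reference frame (the first stored frame by default) over a fit selection
defaulting to the protein backbone (N/CA/C/O) plus the sugar ring atoms.
`rmsf()` superposes the windowed frames onto the receptor backbone first -
removing global tumbling, on which the source account is silent - and then
takes each atom's root-mean-square deviation from its time-mean position.
Fluctuation totals are aggregated with `rmsf_group_sums()` by receptor
subdomain (IA 5-107, IB 108-197, IIA 198-296, IIB 297-382, IIIA 383-494,
IIIB 495-569; residues 1-4 and 570-585 are reported as "unassigned"
rather than folded into a neighboring domain, and still participate in
interaction detection) and by ligand mer triplets (24 mers in eight groups
of three). Averaging over independent realizations is a separate
aggregation step - a list of profiles - rather than something hidden
inside `rmsf()`.

## The synthetic-data generator

The generator is kinematic, not physical: no force field, no integrator.
Its purpose is planting interactions whose identity, location and timing
are known exactly, so detector output can be scored as precision/recall
against a ledger.

* **Receptor.** A reduced model: per residue the backbone N/H/CA/C/O plus
  a one-to-three-atom side-chain pseudo-group carrying the residue's
  donor/acceptor/hydrophobic/charge identity, laid out on a serpentine
  grid (13 residues per row). A repeating 13-residue motif mixes Lys,
  Ser, Glu, Leu, Arg, Gln, Asp, Ala, Tyr and Gly so every interaction
  type has receptor-side partners. The first row's side chains point
  outward and act as the exposed binding surface; protein termini charge
  groups are not modeled in this reduced representation.
* **Ligand.** An idealized extended chain of alternating GalNAc/GlcA
  hexagon rings 5.2 Angstrom apart, one sulfate per GalNAc (ester oxygen
  at C4 or C6 by isomer - the only structural difference between the
  CS-4 and CS-6 fixtures), one carboxylate per GlcA, and labeled
  hydroxyl/ring oxygens (`O`, `O3`, `O13`, `O14`). Downstream maps are
  keyed by these class labels, not by sugar stereochemistry, which is
  deliberately not reproduced.
* **Solvent and ions.** Waters (rigid O-H-H triplets) and ions are
  rejection-sampled uniformly in the 120 x 110 x 110 Angstrom box, kept
  away from the solutes, from each other, and from the planting zone.
  This is what makes noiseless fixtures *exactly* ledger-clean: a
  detector finding anything unplanted is a bug, not noise.
* **Events.** Each planted event claims a free surface residue of a
  compatible type, a free ligand mer, and (for bridges) a mediator water
  or cation, for its frame range; the involved ligand atoms are placed in
  ideal detection geometry with at least a 10% margin against the
  relevant cutoff during the event and return to the (distant) ligand
  body outside it. Every planted configuration is re-checked with the
  real detectors at generation time and generation aborts if the margin
  is not met. Per-atom Gaussian jitter is added after planting, so
  detection recall degrades smoothly with the jitter scale while the
  ledger stays fixed.
* **Scales.** The desk-scale default (60 receptor residues, 12-mer
  ligand, 500 waters, 20 cations, 40 anions, 200 frames) keeps a full
  generate-detect-validate cycle in seconds on one CPU; the full-scale
  geometry (585 residues, 24 mers, 1400 frames at 100 ps spacing) is a
  parameter choice away and is exercised for the frame-schedule and
  domain-partition checks. The "24 unit chains" of the source system are
  read as 24 monosaccharide mers (12 disaccharides); this is
  configurable.

What passing tests on these fixtures shows is that the detectors,
censuses, maps and accounting are *correct implementations of their
definitions*; it does not show that the definitions capture everything in
real explicit-solvent dynamics (polarization, bifurcated bonds, sugar
ring puckering, ion desolvation kinetics are all outside the fixtures'
vocabulary).

```{r}
spec <- fixture_spec(n_waters = 60, n_cations = 8, n_anions = 10,
                     n_frames = 40, planted_events = default_event_schedule(40),
                     rng_seed = 1)
fix <- generate_trajectory(spec)
fix
validate_ledger(fix$traj, fix$ledger)$per_type
```

## Numerical choices and degenerate inputs

* Superposition requires three non-collinear fit atoms; degenerate
  selections raise an error rather than returning an arbitrary frame.
* Population (not sample) standard deviations everywhere, doubled in
  summaries to match the error-bar convention of the censuses.
* Ranking ties keep input order; tied strongest binding sites are all
  flagged, with a warning.
* Empty analysis windows, malformed energy tables, unknown residue names
  without a fallback partition, odd mer counts, and boxes too small to
  place solvent all fail fast with specific errors.
* Atom identity is the 1-based row index of the atom table; all records,
  ledgers and maps use the same indexing.
* Bond perception is distance-based (covalent radii + 0.45 Angstrom) and
  intended for the clean geometries this package reads and writes, not as
  a general perception algorithm.

## Limitations

The package analyzes trajectories; it does not produce them. Docking,
force-field dynamics, protonation-state prediction and secondary-structure
analysis are out of scope. The HP/ionic cutoffs and the hydrogen-bond
functional form are documented conventions: when comparing against
numbers produced by other tooling, expect agreement in trends and in
everything the thresholds do not touch, and calibrate the cutoffs if
exact census parity with another engine is needed.
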