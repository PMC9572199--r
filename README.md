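# gaginter

Trajectory analysis of protein–glycosaminoglycan binding: how chondroitin
sulfate (CS), in its 4- and 6-sulfated isomeric forms, binds human serum
albumin (HSA) in salt solution, and how to quantify that binding from
multi-frame structural snapshots.

The package is aimed at structural bioinformaticians who have (or want to
simulate having) explicit-solvent trajectories of a
receptor–ligand–water–ion system and need the standard census machinery
around them:

* **Direct interactions** — per-frame detection of hydrogen bonds under an
  energy model (25 kJ/mol optimum; a bond is counted when its energy
  exceeds 25% of the optimum, 6.25 kJ/mol), hydrophobic contacts between
  apolar atoms, and ionic contacts between opposite formal-charge groups.
* **Mediated interactions** — water bridges (one water hydrogen-bonded to
  both solutes at once) and ionic bridges (one cation coordinating a
  negative group on each solute), with element-class labels such as
  `C-Ca-C` or `S-Ca-C`.
* **Stability** — Kabsch-superposed RMSD time series, per-atom RMSF, and
  fluctuation sums by HSA subdomain (IA 5–107 … IIIB 495–569) and by
  ligand mer triplet (24 mers → 8 groups).
* **Energetics** — the six-term disassembly accounting
  `Ebind = Epr + Epl + Esr + Esl − Epc − Esc`, with solvation terms priced
  at 0.65 kJ/(mol·Å²) of solvent-accessible surface (Shrake–Rupley),
  `EoB = −Ebind` windowed means ± doubled SD, per-complex ranking and the
  CS-4 vs CS-6 grand-mean contrast.
* **Reporting** — contact maps of ligand oxygen classes (SO4−, COO−, O,
  O3, O13, O14) against the 20 amino-acid types, binding-site strings per
  subdomain, and a deterministic `run_pipeline()` orchestrator.
* **Synthetic ground truth** — a kinematic trajectory generator that
  plants all five interaction types at known frames with a machine-readable
  ledger, so every detector is testable at precision = recall = 1 on
  noiseless fixtures and degrades gracefully under Gaussian jitter.

All statistics follow one windowing convention: frames with time strictly
greater than the 40 ns equilibration point and at most 140 ns, which on
the canonical 100 ps save schedule (1400 frames) selects exactly 1000
frames.

## Worked example

Generate a desk-scale fixture with planted interactions, run the censuses,
and check the detectors against the ledger:

```r
library(gaginter)

spec <- fixture_spec(n_waters = 120, n_cations = 10, n_anions = 12,
                     n_frames = 60, planted_events = default_event_schedule(60),
                     rng_seed = 1)
fix <- generate_trajectory(spec)
#> synthetic fixture: 981 atoms, 60 frames, 15 planted events (192 frame-events)

p  <- analysis_params(equilibration_time = 1000, window_end = 6000)
census(fix$traj, params = p)$summary
#>    type mean       sd2 n_frames
#> 1   HBo 0.62 0.9707729       50
#> 2    HP 0.68 0.9329523       50
#> 3 ionic 0.62 0.9707729       50

bridge_census(fix$traj, params = p)$class_summary
#>    kind class_label mean       sd2 n_frames
#> 1 ionic      C-Ca-S 0.68 0.9329523       50
#> 2 water       O-W-O 0.68 0.9329523       50

validate_ledger(fix$traj, fix$ledger)$per_type
#>           type n_true n_detected n_matched precision recall
#> 1          HBo     39         39        39         1      1
#> 2           HP     39         39        39         1      1
#> 3        ionic     39         39        39         1      1
#> 4 water_bridge     39         39        39         1      1
#> 5 ionic_bridge     36         36        36         1      1
```

The means are counts per frame over the analysis window (the planted
events cover part of it, hence the fractional values), and `sd2` is the
doubled population standard deviation used as the error bar throughout.
Precision = recall = 1 says the detectors found exactly the planted
interactions and nothing else.

Ranking the published per-complex binding energies of the ten docked
HSA:CS complexes (shipped with the package) reproduces the isomer
contrast:

```r
ref <- reference_eob()
r4 <- rank_complexes(data.frame(complex = 1:10, eob = ref$eob[ref$isomer == "CS4"]))
r6 <- rank_complexes(data.frame(complex = 1:10, eob = ref$eob[ref$isomer == "CS6"]))
mean(r4$mean_eob); mean(r6$mean_eob); isomer_contrast(r4, r6)
#> [1] -1954.2
#> [1] -1655.5
#> [1] 15.28503
```

i.e. the CS-4 complexes are bound about 15% more strongly than the CS-6
complexes under the grand-mean normalization. See the vignette
(`vignettes/gag-interaction-analysis.Rmd`) for the models, parameter
defaults and design choices.

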