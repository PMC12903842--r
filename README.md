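# anomertraj

Trajectory analysis of anomer selectivity in sugar transporters.

Glucose in solution is a mixture of two slowly interconverting anomers —
α-glucose (axial C1 hydroxyl) and β-glucose (equatorial) — and
membrane transporters of the GLUT family can discriminate between them.
Flooding molecular-dynamics simulations (many free ligand copies of each
anomer around a membrane-embedded transporter) make that discrimination
measurable residue by residue. `anomertraj` is the analysis layer for such
simulations, for computational structural biologists who have trajectories
(or want synthetic ones with known ground truth) and need the statistics:

* **Hydrogen-bond detection** between ligand species and protein residues,
  on a declared geometric convention (donor–acceptor ≤ 3.5 Å,
  D–H···A angle ≥ 150°, both configurable), with an exhaustive
  brute-force oracle for testing.
* **Anomer preference ratios** per residue,
  `ratio(r) = N_alpha(r) / N_beta(r)`, classified with inclusive thresholds:
  ratio ≥ 1.4 → α-preferring, ratio ≤ 0.7 → β-preferring, between → none,
  fewer than 10 total bonds → insufficient. Region summaries tally the
  classes over the extracellular vestibule, pore and intracellular
  vestibule (geometric membrane-slab partition).
* **Mixed-vs-single-anomer proportion shifts**: how a residue's share of a
  species' total bond count changes when both anomers are present together,
  flagging candidate cooperative interactions.
* **Sliding-window RMSF** matrices over contiguous windows (a 250 ns
  trajectory tiles into exactly ten 25 ns windows), Kabsch superposition,
  between-condition difference maps with the `RMSF_A − RMSF_B` sign
  convention, and minimum-distance salt-bridge monitors.
* **Ligand pathway tracks** along the membrane normal (z origin at the
  membrane centre) and residency events with gap merging, filtered by the
  strict "longer than 4 ns" inclusion rule, plus pore
  entry/exit/permeation counts.
* A **synthetic toy-transporter generator** whose programmed contact
  propensities, regions, fluctuations and permeation paths are recovered
  exactly by the pipeline — the test oracle for everything above.

## Worked example

A synthetic mixed-anomer flooding run: four residues get programmed contact
propensities `(p_alpha, p_beta)` — residue 2 favours α 4:1, residue 5
favours β 1:4, residues 8 and 20 are even — and the pipeline must read the
preferences back off the trajectory.

```r
library(anomertraj)

cfg <- list(
  synthetic = list(
    n_frames = 5000, dt_ns = 0.1,
    propensities = data.frame(resno   = c(2L, 5L, 8L, 20L),
                              p_alpha = c(0.40, 0.10, 0.20, 0.30),
                              p_beta  = c(0.10, 0.40, 0.20, 0.30))),
  species_map = list(GLC = "alpha", BGC = "beta"),
  rmsf = list(window_len_ns = 25, fit = TRUE, condition = "mixed"),
  outdir = "demo_run", seed = 42)

res <- run_pipeline(cfg)
res$preference
#>   residue resno n_alpha n_beta     ratio classification        region
#> 1     A:2     2    1948    511 3.8121331          alpha intracellular
#> 2     A:5     5     471   2006 0.2347956           beta intracellular
#> 3     A:8     8     940   1005 0.9353234           none          pore
#> 4    A:20    20    1485   1564 0.9494885           none extracellular
res$region_summary
#>          region n_alpha_pref n_beta_pref n_none n_insufficient
#> 1 extracellular            0           0      1              0
#> 2          pore            0           0      1              0
#> 3 intracellular            1           1      0              0
#> 4         other            0           0      0              0
```

Residue 2's empirical ratio 3.81 recovers the programmed 4:1 bias (≥ 1.4 →
`alpha`), residue 5's 0.23 recovers 1:4 (≤ 0.7 → `beta`), and the even
residues land between the thresholds (`none`). The counts are bond-frames
over 5,000 frames: residue 2 bound α-glucose in 1,948 of them, close to the
programmed per-frame probability 0.40. Regions come from each residue's Cα
position relative to the membrane slab. `demo_run/` now holds the CSV/JSON
artifacts (events, contact table, preference table, region summary, RMSF
matrix, ligand tracks, residency events, transit summary) and a manifest
with MD5 checksums; rerunning with the same config and seed reproduces every
file byte for byte.

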