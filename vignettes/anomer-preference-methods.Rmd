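---
title: "Methods: anomer-preference trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anomer-preference trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Glucose in solution is a mixture of two anomers, alpha and beta, which
interconvert slowly (mutarotation) relative to the timescale of a binding
event. Facilitated-diffusion transporters of the GLUT family may therefore
encounter, and discriminate between, both forms. Flooding molecular-dynamics
simulations — many free ligand copies around a membrane-embedded transporter —
let one measure that discrimination residue by residue: which residues
hydrogen-bond more often to alpha- than to beta-glucose, where those residues
sit along the permeation pathway, whether the presence of one anomer changes
the other's interaction pattern, and whether the anomers leave different
fluctuation signatures on the protein.

`anomertraj` implements the analysis layer of that workflow. It does not run
molecular dynamics; it consumes trajectories (or generates synthetic ones with
known ground truth) and computes the statistics below.

## The preference statistic

For each protein residue $r$, count hydrogen bonds to each species over the
frames of a mixed-anomer trajectory, and form

$$\mathrm{ratio}(r) = \frac{N_\alpha(r)}{N_\beta(r)}.$$

Classification uses inclusive thresholds: `ratio >= 1.4` is alpha-preferring,
`ratio <= 0.7` beta-preferring, anything between is "none". Two deliberate
edge rules:

* **Zero denominator.** $N_\beta = 0$ with sufficient total bonds gives
  `ratio = Inf`, classified alpha: the statistic is a proportion of observed
  bonds, and an all-alpha residue is maximally alpha-preferring. CSV output
  prints `inf`.
* **Count floor.** Residues with fewer than `min_total_bonds = 10` total
  bonds are reported `insufficient`, never `none`: deep-pore visits are rare
  events and a handful of bonds cannot support either a preference claim or a
  no-preference claim.

A subtlety worth knowing: the published cutoffs are not reciprocal
($1/1.4 \approx 0.714 \neq 0.7$), so relabelling the species maps every ratio
to its reciprocal but does *not* perfectly mirror the classification for
ratios inside $[1.4, 1/0.7)$ and $(0.7, 1/1.4]$. The package treats the
printed cutoffs as authoritative; the test suite asserts the mirror symmetry
everywhere outside those narrow bands (and exactly, under reciprocal
thresholds).

Whether published counts of this kind are bond-frames (two simultaneous bonds
in one frame count twice) or bonded-frames (presence) is usually unstated.
Both are computed; bond-frames is the default and the `count` argument of
`build_preference_table()` switches to presence counting.

## Hydrogen-bond convention

No single geometric definition of a hydrogen bond is universal, so the
criteria here are an explicit, configurable convention, echoed into every
output: donor–acceptor heavy-atom distance $\le 3.5$ Å and
donor–hydrogen–acceptor angle (measured at the hydrogen) $\ge 150^\circ$.
Donors are N/O atoms bearing at least one covalent hydrogen (from PSF
connectivity when available, otherwise by attaching each hydrogen to the
nearest heavy atom within 1.2 Å, a standard covalent-bond bound); acceptors
are all N/O. Only ligand–protein bonds are reported, in both donor
directions. `detect_hbonds()` is contractually equal to the brute-force
triple enumeration `oracle_detect_hbonds()`; the fast path is vectorised but
implements the identical predicate, and the equivalence is asserted on random
frames in the tests.

## Regions and the membrane frame

All z values are reported relative to a single membrane centre (fixed from
the first frame by default, matching the convention of plotting pathways
against one z origin). Regions are a geometric stand-in for an anatomical
classification: extracellular above the slab ($z > +h$), intracellular below
($z < -h$), pore inside the slab within a cylinder around the pore axis,
"other" elsewhere. Defaults $h = 15$ Å and pore radius $10$ Å approximate a
DPPC hemislab around a GLUT-sized transporter; both are configurable, and
residue region identity is computed once from first-frame C$\alpha$ positions
(treated as static, as in published residue maps).

## Mixed-vs-single proportion shifts

For one species, a residue's *share* is its bond count divided by the species
total within a condition. `proportion_shift()` reports
`share_mixed - share_single` per residue; residues whose share moves by at
least `min_share_delta` (default 0.02, i.e. two percentage points of the
species' bond budget) are flagged as candidates for cooperative effects —
interactions that occur at higher or lower proportion when both anomers are
present together. Shares within a condition sum to one by construction, so
shifts are zero-sum across residues.

## Windowed RMSF and difference maps

RMSF is the per-atom standard deviation about the within-window mean
position:
$\mathrm{RMSF}_i = \sqrt{\langle |\mathbf{r}_i - \langle\mathbf{r}_i\rangle|^2 \rangle}$.
Windows are contiguous and non-overlapping from $t = 0$; the window count is
$\lfloor \mathrm{span} / \mathrm{length} \rfloor$ with the trajectory span
defined as `n_frames * dt` (each frame stands for one sampling interval), so
a 250 ns trajectory tiles into exactly ten 25 ns windows. Within each window,
frames are by default superposed onto the window's first frame over the
C$\alpha$ selection (Kabsch least-squares fit, proper rotation enforced), so
rigid-body drift does not masquerade as fluctuation; the fit flag is recorded
in outputs because published RMSF protocols often leave it unstated. The
per-window mean (not a global mean) is the reference, which is what lets
short windows localise transient events.

Difference maps are first-argument-minus-second: positive cells mean the
first condition fluctuates more (rendered red by convention, e.g.
$\mathrm{RMSF}_\alpha - \mathrm{RMSF}_\beta > 0$). Salt bridges are monitored
as plain minimum distances between two atom selections, with 4 Å as the
conventional "formed" annotation — no dielectric model is implied.

Useful closed form: under isotropic Gaussian jitter of s.d. $\sigma$ per
axis, RMSF converges to $\sigma\sqrt{3}$; with $\sigma = 0.5$ Å that is
0.866 Å, which the tests verify at 20,000 frames within 2%.

## Residency events and the 4 ns filter

A ligand's track is its heavy-atom centre of geometry per frame (hydrogens
are noisy and add nothing). Pore events are maximal runs of frames inside
the pore cylinder; extramembranous-contact events are maximal runs with at
least one hydrogen bond to an extracellular or intracellular residue. Runs
separated by at most `gap_tolerance_ns` (default 0.5 ns) are merged, since
contacts flicker at thermal timescales and published durations imply some
continuity notion; 0 disables merging. Event duration is
`span_frames * dt`, closed on both endpoint frames, so frames 10–29 at
dt = 0.1 ns last exactly 2.0 ns.

The inclusion filter keeps events *strictly longer* than 4 ns (a flag makes
the boundary inclusive), and reports the excluded fraction plus, separately,
the fraction of excluded events shorter than 2 ns. The filter applies to
contiguous events; cumulative residence per ligand/location is reported as an
extra column for anyone who prefers that reading. Pore transit bookkeeping
assigns the approach side from the z sign at the nearest out-of-pore frame
before the event (positive = extracellular), symmetric on exit; a full
permeation is an event whose flanking signs differ.

## The synthetic generator

The generator is the package's acceptance oracle, not a simulator: no force
field, lipids or water. Its defaults define the study conditions used
throughout the tests:

* a pseudo-transporter of 4 rings × 6 serine-like residues (CA + hydroxyl
  O–H; the oxygen is both donor and acceptor) at z = ±20 and ±7.5 Å around a
  vertical pore axis of radius 8 Å — so rings sit in the extracellular,
  pore and intracellular regions of a ±15 Å slab;
* 10 + 10 ligand copies (hydroxyl probes named GLC/BGC, the wwPDB codes for
  the two glucopyranose anomers), emulating flooding compositions of tens of
  copies per species at toy scale;
* residue jitter $\sigma_{res} = 0.3$ Å/axis, ligand walk step 1 Å/frame,
  5,000–20,000 frames at dt = 0.1 ns — minutes on one CPU.

Bond placement is geometric by construction: with probability $p(r, s)$ per
frame, the ligand copy assigned to residue $r$ is snapped into ideal
geometry (O···O 2.9 Å, angle 180°), and free ligands are kept at a 5 Å
clearance from all protein N/O, so ground-truth propensities translate
*exactly* into detection probabilities, decoupling generator physics from
detector correctness. The residue's own hydroxyl hydrogen points
tangentially so the reverse bond direction never also scores, and
simultaneous alpha/beta bonds to one residue approach from directions 20°
apart. One RNG stream is seeded once and consumed in a fixed order per frame
— residue jitter block, walker steps in ligand order (programmed-path
ligands consume none), bond draws by ascending residue number with alpha
before beta — so a fixed spec and seed reproduce output files byte for byte.

What the generator does *not* emulate: real binding-site geometry,
correlated protein motions, ligand–ligand competition, water, and
finite-lifetime bound states (a bond lasts exactly one frame draw).
Passing tests therefore demonstrate the correctness of the statistics and
plumbing, not the biology of glucose transport; on real trajectories the
hydrogen-bond convention and the region geometry remain declared choices
whose influence should be checked by varying them.

## Problem sizes and numerical choices

The test suite and the acceptance script run the parameter-recovery study at
10 residues × ratios {0.25, 0.5, 1, 2, 4}, 10 + 10 ligands, 10,000 frames and
20 seeds, a size chosen to give every biased residue an expected bond count
two orders of magnitude above the classification floor while completing in a
few minutes on one CPU. Expected recovery: classification matches the sign of
$\log \rho$ for $\rho \le 0.5$ or $\ge 2$, and $\rho = 1$ residues read
"none", in at least 95% of (residue, seed) cases.

Other numerics: coordinates are treated as already whole-molecule (no
periodic re-imaging — a documented precondition for external data); frame
times come from the configured `dt_ns`, never from file metadata (DCD time
fields are unreliable across writers); PDB round trips are exact to the
0.001 Å fixed-column precision and DCD to single-precision float; the
Kabsch fit enforces a proper rotation via the SVD sign correction and
refuses fewer than three non-collinear points; windows drop (and log) a
trailing remainder rather than emitting a short window.

## Interfaces

Everything is driven either by the exported functions or by
`run_pipeline(config)`, where `config` is a named list or YAML file (species
name map, dt, membrane geometry, hydrogen-bond criteria, thresholds, window
lengths, residency parameters, output directory, seed). The pipeline writes
CSV tables (events, contact counts, preference table, region summary, RMSF
matrices, tracks, residency events), JSON summaries, and a manifest listing
every output with its MD5 checksum; `compare_conditions()` produces the
between-condition difference maps and proportion shifts. This package is a
library, not a shell tool, so those two functions are the orchestration
surface.
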