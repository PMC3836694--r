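---
title: "Detecting nucleotide-sensitive hinge residues in the Hsp70/DnaK NBD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nucleotide-sensitive hinge residues in the Hsp70/DnaK NBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingescan)
```

## The scientific problem

The nucleotide-binding domain (NBD) of the bacterial Hsp70 chaperone DnaK is
built from four subdomains (I-A, I-B, II-A, II-B) arranged around a
nucleotide cleft. ATP binding, hydrolysis and release drive the domain
between "open" and "closed" conformations, and that motion is relayed to the
substrate-binding domain as the allosteric signal that regulates client
binding. The motion is largely rigid-body: subdomain II-B swings relative to
the I-A/I-B/II-A core. Rigid-body motion of this kind must be articulated
somewhere, and the articulation points are *hinge residues* — positions
whose backbone (phi, psi) angles occupy two or more distinct conformations,
letting the flanking blocks move while everything else stays locally rigid.

`hingescan` implements the trajectory-analysis procedure for locating such
residues and deciding which of them respond to the bound nucleotide:

1. **Openness** — the distance between the unweighted Ca center of mass of
   subdomain II-B and that of the pooled remaining subdomains, per frame
   (`openness_series()`), with an open/closed call at a configurable
   threshold (`classify_openness()`).
2. **Essential dynamics** — eigen-analysis of the Ca covariance over runs
   pooled and iteratively superposed onto their mean (`combine_runs()`,
   `compute_ed()`); the low-index modes describe the collective
   inter-subdomain motions, and helix-axis utilities (`helix_axis()`,
   `interhelical_angle()`, `helix_bend_angle()`) characterize the shear
   geometry at the subdomain interface.
3. **Torsion analysis** — per-residue (phi, psi) series
   (`compute_dihedrals()`), periodic Ramachandran densities and
   density-level clustering on the torus (`cluster_torus()`), multimodality
   calls (`multimodal_residues()`) and nucleotide-state shift calls
   (`compare_states()`).
4. **Correlation to the nucleotide** — dynamic cross-correlation of Ca
   displacements with ligand pseudo-sites (`dcc_matrix()`), ranking by
   absolute correlation (`rank_by_ligand()`), and a cross-run tally
   (`tally_runs()`): a residue is *significant* when it reaches the top-k
   list in at least `min_runs` of the independent runs.
5. **Conservation** — per-column identity and conservative-substitution
   percentages by taxon group from a user-supplied alignment
   (`conservation_profile()`, `flag_conserved()`).
6. **Calling** — `build_report()` combines the evidence into tiers
   (A: multimodal + state-shifted + tally-significant; B: multimodal plus
   one of the two; C: multimodal only), and `select_candidates()` applies
   the conservation filter.

`run_pipeline()` executes the stages end to end from one declarative
config; every stage writes CSV/JSON with its parameters echoed, and reruns
with the same config are byte-identical.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `k` | 60 | residues | top-correlation list length per run (published analysis choice) |
| `min_runs` | 4 | runs | tally significance out of 10 nucleotide-bound runs (published) |
| `near_cutoff` | 8 | Angstrom | "near the nucleotide" flag, strict `<` (published) |
| `openness_threshold` | 29.5 | Angstrom | open/closed boundary; midpoint of the reported apo (31.9) and ATP (27.3) means |
| `min_occupancy` | 0.05 | fraction | a torus cluster must hold 5% of frames to count as a conformation |
| `bin`, `sigma_bins` | 10, 1 | degrees, bins | Ramachandran grid cell and smoothing width |
| `mass` | 0.8 | fraction | probability mass the density superlevel set must cover |
| `merge_radius` | 40 | degrees | superlevel fragments closer than this are one conformation |
| `match_radius` | 40 | degrees | cluster-center matching radius between states |
| `delta_occ` | 0.3 | fraction | occupancy change that counts as a state shift |
| `identity_min` | 90 | percent | conservation threshold, non-strict |
| `bend_threshold` | 30 | degrees | helix "bent" flag |

The first three are the values used in the original analysis of this
system. The clustering parameters are this package's own: the published
work judged multimodality from density maps by eye, so the reproducible
rule — smallest density superlevel covering 80% of mass, periodic
8-connected components, fragments merged below the mode-width scale
(40 degrees, the same scale as the state-matching radius; two
conformations closer than that could not be scored as distinct anyway), a
5% occupancy floor — is stated here and echoed in every report.
`flag_conserved()` applies its threshold non-strictly, because published
conservation tables highlight rows printed *at* 90%.

Two conservation modes are first-class: identity-only and combined
(identity + conservative substitutions, where "conservative" means a
positive BLOSUM62 score against the reference letter, the closest
reconstructable analogue of BLASTP positives). The published mutant panel
is only arithmetically consistent with the combined reading (one mutated
residue has 31%/5% identity but 95%/95% combined), so reports carry both
rather than silently choosing.

## The synthetic generator

No trajectories were deposited for this system, so validation uses
`plant_spec()` / `generate_trajectory()`: ensembles with planted,
recoverable ground truth that emulate the statistical structure the
analysis assumes.

Per frame the generator (1) samples every residue's (phi, psi) from a von
Mises pair — hinge residues first choose mode 1 or mode 2 by a Bernoulli
draw on the state's mode-2 occupancy; (2) rebuilds the backbone from the
sampled torsions; (3) rigidly translates the II-B block along the line
joining the group centers so the openness follows
Normal(`openness_mean`, `openness_sd`) with state defaults 31.9 / 27.3 /
26.1 Angstrom (apo / ATP / ADP+Pi, the reported per-state means); (4) forms
the ligand pseudo-particle as the weighted sum of the coupled residues' Ca
displacements plus isotropic noise; and (5) adds 0.1-Angstrom Cartesian
jitter. The openness targets are drawn by stratified inversion (a random
Latin hypercube on the normal quantiles): each frame is still marginally
Normal, but the realized ensemble mean converges at O(1/F), so a 500-frame
run recovers the planted mean to about 0.01 Angstrom.

Two design points deserve emphasis, because they are what makes the
generator behave like a folded protein rather than a polymer:

* **Scaffold tether.** A chain rebuilt from independently sampled torsions
  is a floppy polymer — orientation noise random-walks down the chain and
  the Cartesian fluctuations reach hundreds of Angstrom, burying every
  collective observable. Real folds are restrained by tertiary contacts.
  The rebuild therefore tethers the chain to a reference scaffold: each
  atom placement honours the sampled phi/psi *exactly* (a dihedral depends
  only on the rotation about the step axis) while the bond angle flexes
  within +/-60 degrees of ideal (bounded away from collinearity) and the
  omega step tracks the scaffold step direction with a weak, capped pull
  toward the reference position. The result is a stationary ~1-2 Angstrom
  Ca RMSF — folded-protein scale — with machine-precision torsion round
  trips. Hinge flips appear as local Cartesian pulses that heal within a
  few residues, as they do across a real hinge.
* **Latent coupling mode.** Nucleotide-correlated residues in a real pocket
  share a collective breathing motion with the ligand. The generator plants
  exactly that: a per-frame Gaussian amplitude (sd `coupling_amp`, default
  0.8 Angstrom) along a fixed direction, carried by every coupled residue
  scaled by its weight and spread over a tapered +/-3-residue window so
  bonded neighbours are never torn apart (relative displacements above
  ~0.3 Angstrom would corrupt junction dihedrals). The ground truth records
  the effective per-residue weights; recovery statistics treat the w >= 0.7
  core as planted positives and residues with zero planted weight as the
  false-positive universe.

The background torsional concentration (kappa = 800, about 2 degrees of
dispersion) is chosen so that the *chain-propagated* Cartesian wiggle lands
at realistic RMSF; the marginal torsional width of real backbones is larger,
but under independent per-residue draws it is propagation, not the marginal
width, that sets the Cartesian scale. Hinge residues default to kappa = 20
(about 13 degrees per mode) with modes (-57, -47) and (-120, 130) — well
separated on the torus.

Default study conditions used by the validation suite and the acceptance
script, stated once: hinge recovery runs 120-residue chains (subdomain map
rescaled from the DnaK boundaries), three hinges at residues 28/60/88 — two
switching mode-2 occupancy 0.2 to 0.8 between the ATP and ADP+Pi states,
one state-invariant at 0.5 — with 3 states x 5 runs x 300 frames per seed;
coupling recovery runs full-length 383-residue chains whose coupled core is
the 30 residues reported nucleotide-correlated for this system, 10
nucleotide-bound runs x 250 frames per replicate (the original runs
collected 5000 snapshots each; 250 balances statistical power against
suite runtime). The mode-1-concentration property of the essential
dynamics is demonstrated on a hinge-free ensemble with `openness_sd = 2`:
the stated signal-to-jitter ratio condition does not account for the
chain-wiggle noise channel, which the II-B motion must also dominate.

What the generator does *not* emulate: side chains, real Ramachandran basin
shapes (modes are isotropic von Mises pairs with no phi-psi covariance),
solvent or force-field physics, correlated torsional compensation, and the
rotational component of the II-B motion (the planted displacement is a pure
translation; rotation is left to the essential-dynamics stage as a
qualitative observation). Passing the recovery suite therefore shows the
*analysis* is correct and well-calibrated against data satisfying its
assumptions — not that real trajectories satisfy them.

## Numerical choices and degenerate inputs

* Superposition is closed-form Kabsch (SVD); fewer than three or collinear
  fit atoms are errors. The iterative fit to the ensemble mean runs at
  least two passes and stops when the mean shifts by under 1e-4 Angstrom.
* Eigenvector signs are fixed (largest-magnitude component positive) for
  reproducibility; tiny negative eigenvalues are clamped to zero; a
  motionless trajectory is flagged rather than an error.
* Dihedrals follow the IUPAC sign convention in [-180, 180); collinear
  quadruples give NA with a warning; chain-terminal and gap-adjacent
  residues carry NA.
* Correlation scores reduce over ligand sites by the maximum absolute
  value; top-k ties break by ascending residue number; a zero-variance
  site's row is zeroed and flagged.
* The rigid II-B translation severs the chain at the two subdomain
  junctions; junction dihedrals are stabilized by the long lever arms, but
  the two or three junction residues can show state-dependent smearing —
  they are the known residual false-positive channel of the state-shift
  caller and stay well inside its 5% budget.
* MSA columns where the reference has a gap carry no residue number; gaps
  and X in other rows count in the denominator as plain mismatches.

## Known limitations

* The crossed-helix check runs on an idealized synthetic Ca model built at
  the crystal-structure crossing geometry (`crossed_helices()`), not on
  deposited coordinates; it validates the axis machinery, not the database
  entry.
* The published multimodal-residue and correlation tables shipped in
  `inst/extdata` are inputs from the literature for filter arithmetic;
  they cannot be regenerated here because the original trajectories are
  unavailable.
* Density-level clustering needs on the order of 50+ defined frames per
  residue; occupancies near the 5% floor are detected unreliably by design
  (that is what the floor is for).
* `run_pipeline()` tallies correlation over the nucleotide-bound states
  only (5 ATP + 5 ADP+Pi runs for the default configuration), matching the
  4-of-10 significance rule; an apo-only configuration reports no tally.

## A minimal run

```{r, eval = FALSE}
cfg <- list(simulate = list(n_residues = 120, seed = 1, coupled = "default"),
            n_runs = 5, n_frames = 300, out_dir = "hingescan_out")
report <- run_pipeline(cfg)
subset(report$table, tier != "none")
```
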