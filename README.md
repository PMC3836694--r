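# hingescan

Detection of nucleotide-sensitive backbone hinge residues in the
Hsp70/DnaK nucleotide-binding domain (NBD) from molecular-dynamics
trajectories — for structural bioinformaticians studying chaperone
allostery, and more generally for anyone who needs a reproducible,
tested implementation of hinge detection by phi/psi multimodality.

The NBD's four subdomains (I-A, I-B, II-A, II-B) form a nucleotide cleft
whose opening and closing transmits the ATP/ADP state to the rest of the
chaperone. The package quantifies that motion and traces it to individual
residues through five coordinated analyses:

* **Openness** `d(t) = | COM_Ca(II-B) - COM_Ca(I-A + I-B + II-A) |`, the
  per-frame distance between subdomain centers of mass, with an
  open/closed call (`open` iff the run mean exceeds 29.5 Å, the midpoint
  of the reported apo and ATP-state means of 31.9 Å and 27.3 Å).
* **Essential dynamics**: eigen-decomposition of the Ca covariance matrix
  `C = <dx dx^T>` over runs pooled and iteratively superposed onto their
  mean; cumulative eigenvalue fractions, mode projections, per-residue
  loadings, and helix-axis geometry (inter-helical crossing and bend
  angles).
* **Torus clustering of (phi, psi)**: per-residue Ramachandran densities on
  the doubly periodic torus, density-level clustering, multimodality calls
  (a hinge residue occupies >= 2 clusters), and state-shift calls between
  nucleotide states (a new/lost cluster within a 40 degree matching radius,
  or an occupancy change >= 0.3).
* **Dynamic cross-correlation to the nucleotide**:
  `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with ligand
  pseudo-sites appended; residues ranked by max |C| over ligand sites
  (anti-correlation counts equally), the top 60 tallied across runs, and
  residues reaching the list in >= 4 of 10 nucleotide-bound runs called
  significant; hypergeometric enrichment against the proline-switch set
  (K70, R71, P143, A144, Y145, F146, R151, E171).
* **Conservation**: per-column identity and conservative-substitution
  percentages (BLOSUM62 score > 0 vs the reference letter) by taxon group,
  with identity-only and combined filters at a non-strict 90% threshold.

A hinge report combines the evidence into tiers (A: multimodal +
state-shifted + tally-significant, B: two of the three kinds, C: multimodal
only) and applies the conservation filter to nominate mutation candidates.

Because no trajectories were deposited for this system, the package ships a
first-class synthetic generator (`plant_spec()`, `generate_trajectory()`,
`generate_msa()`) that plants recoverable ground truth — per-state openness,
bimodal hinge torsions with state-dependent occupancies, a ligand
pseudo-particle riding a latent coupling mode, and alignments with target
column conservation — so every stage is validated end to end. The methods
vignette (`vignettes/hinge-detection-methods.Rmd`) documents the model,
every tunable parameter, and the generator's design and limitations.

## Worked example

Simulate three nucleotide states (apo, ATP, ADP+Pi) with three planted
hinges on a 120-residue chain and run the whole pipeline:

```r
library(hingescan)

cfg <- list(simulate = list(n_residues = 120, seed = 5, coupled = "default"),
            n_runs = 3, n_frames = 150, out_dir = "hingescan_out")
rep <- run_pipeline(cfg)
rep
#> hinge report: 120 residues; tiers A/B/C: 2/1/0; conservation rule: not evaluated

subset(rep$table, tier != "none")[, c("residue", "multimodal",
      "state_shifted", "tally", "tally_significant", "tier")]
#>  residue multimodal state_shifted tally tally_significant tier
#>       28       TRUE          TRUE     4              TRUE    A
#>       60       TRUE         FALSE     6              TRUE    B
#>       88       TRUE          TRUE     6              TRUE    A
```

The generator planted hinges at residues 28, 60 and 88; residues 28 and 88
switch their mode-2 occupancy between the ATP and ADP+Pi states and ride
the nucleotide coupling mode, so they are recovered as tier A (multimodal,
state-shifted, and correlation-significant in >= 4 of the 6 nucleotide-bound
runs), while the state-invariant hinge 60 lands in tier B. The output
directory holds per-stage CSVs (openness, eigenvalues, clusters, state
shifts, tally, report) plus `report.json`, `truth.json` and a parameter log.

The openness of a single simulated apo ensemble:

```r
sp <- plant_spec(n_residues = 120, state = "apo", seed = 1)
g  <- generate_trajectory(sp, 500)
openness_series(g$trajectory, sp$subdomain_map)
#> openness 'apo_run': 31.9 +/- 1.0 A over 500 frames -> open
```

The conservation filter applied to the published hinge-region table and
multimodal-residue list shipped with the package:

```r
tab <- dnak_conservation_table()
flag_conserved(tab, 90, c("bacteria", "animals"), "identity")
#> [1] 203 223 227 228 229
intersect(flag_conserved(tab, 90, c("bacteria", "animals"), "combined"),
          dnak_multimodal_residues()$residue)
#> [1] 202 203 223 227 228 229
```

These are the residue sets behind the published alanine-mutant panel
(S203, G223, L227, G228 — and I202, which only the combined
identity+conservative reading admits).

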