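# Shared fixtures, all built in code.

## flat xyz of a structure3d
flat_xyz <- function(s) as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))

## circular difference helper mirroring the package-internal convention
cdiff <- function(a, b) ((a - b + 180) %% 360) - 180

## pool an ensemble's runs into one trajectory (no fitting; torsions are
## rigid-invariant)
pool_runs <- function(ens) {
  xyz <- do.call(rbind, lapply(ens$runs, function(r) r$trajectory$xyz))
  trajectory(ens$runs[[1]]$trajectory$topology, xyz, label = "pooled")
}

## per-state pooled residue clusterings for one seed of the default
## 120-residue hinge plant
hinge_clusterings <- function(seed, states = c("apo", "ATP", "ADP_Pi"),
                              n_runs = 5, n_frames = 300) {
  out <- lapply(states, function(st) {
    sp <- plant_spec(n_residues = 120, state = st, seed = seed)
    ens <- generate_ensemble(sp, n_runs, n_frames)
    list(clust = cluster_residues(compute_dihedrals(pool_runs(ens))),
         truth = ens$truth)
  })
  names(out) <- states
  out
}

## random rigid transform applied to a flat xyz vector
random_rigid <- function(v, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  m <- matrix(v, ncol = 3, byrow = TRUE) %*% t(R)
  m <- sweep(m, 2, runif(3, -20, 20), "+")
  as.vector(t(m))
}
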