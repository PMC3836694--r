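# Essential dynamics: covariance eigen-analysis of Ca fluctuations over
# combined runs, after iterative superposition onto the ensemble mean.

## iteratively superpose all frames of an xyz matrix onto the running mean.
## Returns list(xyz, transforms) so callers (DCC) can co-transform ligand
## pseudo-sites. tol is the max mean-coordinate shift in Angstrom.
iterative_fit <- function(xyz, fit_sel, tol = 1e-4, max_pass = 30) {
  transforms <- vector("list", nrow(xyz))
  mu <- colMeans(xyz)
  for (pass in seq_len(max_pass)) {
    for (f in seq_len(nrow(xyz))) {
      tr <- superpose(xyz[f, ], mu, fit_sel)
      xyz[f, ] <- apply_transform(xyz[f, ], tr)
      transforms[[f]] <- if (is.null(transforms[[f]])) tr else
        compose_transforms(transforms[[f]], tr)
    }
    mu2 <- colMeans(xyz)
    shift <- max(abs(mu2 - mu))
    mu <- mu2
    if (pass >= 2 && shift < tol) break
  }
  list(xyz = xyz, mean = mu, transforms = transforms)
}

## compose two row-vector rigid transforms: first t1, then t2
compose_transforms <- function(t1, t2) {
  ## x -> ((x - c1) R1 + d1 - c2) R2 + d2  ==  (x - c1) R1R2 + shift
  list(R = t1$R %*% t2$R,
       center_mobile = t1$center_mobile,
       center_reference = as.vector(
         (t1$center_reference - t2$center_mobile) %*% t2$R) + t2$center_reference,
       rmsd = t2$rmsd)
}

#' Concatenate runs and superpose every frame onto the ensemble mean
#'
#' Frames of all runs are pooled in run order and iteratively fitted to the
#' running mean structure (at least two passes; stops when the mean shifts
#' by less than `tol` Angstrom).
#'
#' @param trajs list of [trajectory()] objects sharing one topology.
#' @param fit_sel atom indices used for fitting (default: all Ca).
#' @param tol convergence tolerance on the mean, Angstrom.
#' @return A [trajectory()] of the pooled, fitted frames.
#' @export
combine_runs <- function(trajs, fit_sel = NULL, tol = 1e-4) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  topo <- trajs[[1]]$topology
  for (t in trajs) {
    if (natoms(t$topology) != natoms(topo) ||
        !identical(t$topology$atoms$resno, topo$atoms$resno) ||
        !identical(t$topology$atoms$elety, topo$atoms$elety))
      stopf("runs have mismatching topologies")
  }
  fit_sel <- fit_sel %||% ca_indices(topo)
  if (length(fit_sel) == 0) fit_sel <- seq_len(natoms(topo))
  xyz <- do.call(rbind, lapply(trajs, function(t) t$xyz))
  fit <- iterative_fit(xyz, fit_sel, tol = tol)
  trajectory(topo, fit$xyz,
             label = paste0("combined(", length(trajs), " runs)"))
}

#' Essential dynamics of a (combined) trajectory
#'
#' Covariance matrix of Ca coordinate deviations from the ensemble mean,
#' followed by a symmetric eigendecomposition. Modes are sorted by
#' eigenvalue (descending); each eigenvector's sign is fixed so its
#' largest-magnitude component is positive.
#'
#' @param traj a fitted [trajectory()], e.g. from [combine_runs()].
#' @param sel atom indices entering the covariance (default: all Ca).
#' @return An `ed_result`: list with `mean` (3N vector), `cov` (3N x 3N,
#'   Angstrom^2), `values`, `vectors`, `cumfrac`, `sel` and a `zero_motion`
#'   flag when the input has no variance.
#' @export
compute_ed <- function(traj, sel = NULL) {
  sel <- sel %||% ca_indices(traj$topology)
  if (length(sel) == 0) sel <- seq_len(natoms(traj$topology))
  if (length(sel) < 2) stopf("need at least 2 atoms")
  if (nframes(traj) < 2) stopf("need more than one frame")
  X <- traj$xyz[, xyz_idx(sel), drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  tot <- sum(vals)
  zero <- tot < 1e-12
  cumfrac <- if (zero) rep(0, length(vals)) else cumsum(vals) / tot
  structure(list(mean = mu, cov = C, values = vals, vectors = vecs,
                 cumfrac = cumfrac, sel = sel, zero_motion = zero),
            class = "ed_result")
}

#' @export
print.ed_result <- function(x, ...) {
  k <- min(5, length(x$values))
  cat(sprintf("essential dynamics: %d modes; top-%d eigenvalues (A^2): %s\n",
              length(x$values), k,
              paste(signif(x$values[1:k], 3), collapse = ", ")))
  if (x$zero_motion) cat("  (flagged: no motion in input)\n")
  invisible(x)
}

#' Cumulative variance captured by the first k modes
#'
#' @param ed an `ed_result`.
#' @param k number of leading modes.
#' @return Fraction in `[0, 1]`.
#' @export
cumulative_variance <- function(ed, k) {
  if (k < 1 || k > length(ed$values)) stopf("k out of range 1..%d", length(ed$values))
  if (ed$zero_motion) return(0)
  sum(ed$values[1:k]) / sum(ed$values)
}

#' Project frames onto essential-dynamics modes
#'
#' Dot product of each frame's deviation from the ED mean with the selected
#' eigenvectors; over the fitting ensemble each projection series has mean
#' ~0 and variance equal to the mode eigenvalue.
#'
#' @param traj a [trajectory()] (same topology/fitting as the ED input).
#' @param ed an `ed_result`.
#' @param modes mode indices.
#' @return `F x length(modes)` matrix of projections (Angstrom).
#' @export
project_modes <- function(traj, ed, modes = 1) {
  if (any(modes < 1 | modes > length(ed$values)))
    stopf("mode index out of range 1..%d", length(ed$values))
  X <- traj$xyz[, xyz_idx(ed$sel), drop = FALSE]
  sweep(X, 2, ed$mean) %*% ed$vectors[, modes, drop = FALSE]
}

#' Squared eigenvector loading per residue
#'
#' Sums the squared x/y/z components of a mode over each selected atom,
#' giving the fraction of the mode's (unit) norm carried by each residue.
#'
#' @param ed an `ed_result`.
#' @param traj the trajectory the ED came from (for residue numbers).
#' @param mode mode index.
#' @return data.frame with `resno` and `loading2`.
#' @export
mode_loadings <- function(ed, traj, mode = 1) {
  v <- ed$vectors[, mode]
  l2 <- rowSums(matrix(v, ncol = 3, byrow = TRUE)^2)
  data.frame(resno = traj$topology$atoms$resno[ed$sel], loading2 = l2)
}
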