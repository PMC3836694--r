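# phi/psi extraction, periodic Ramachandran densities, torus clustering,
# multimodality and nucleotide-state shift calls.

## signed dihedral (IUPAC convention) for four F x 3 point matrices, degrees
## in [-180, 180)
dihedral_frames <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  x <- row_dot(n1, n2)
  y <- row_dot(row_cross(n1, n2), row_unit(b2))
  ang <- atan2(y, x) * 180 / pi
  ang[row_norm(n1) < 1e-10 | row_norm(n2) < 1e-10] <- NA_real_  # collinear
  wrap_deg(ang)
}

#' Backbone phi/psi time series of a trajectory
#'
#' phi(i) = dihedral(C'(i-1), N(i), Ca(i), C'(i)); psi(i) = dihedral(N(i),
#' Ca(i), C'(i), N(i+1)), signed IUPAC convention, degrees in `[-180, 180)`.
#' The first residue carries no phi and the last no psi (stored `NA`);
#' residues missing a backbone atom, or with a numbering gap to their
#' neighbour, get `NA` with a warning.
#'
#' @param x a [trajectory()] or [structure3d()] (treated as one frame).
#' @return A `torsion_series`: list with `phi` and `psi` (`F x N` matrices,
#'   columns named by residue number) and `resno`.
#' @export
compute_dihedrals <- function(x) {
  if (inherits(x, "structure3d"))
    x <- trajectory(x, matrix(as_flat_xyz(x), nrow = 1))
  topo <- x$topology$atoms
  prot <- which(topo$type == "ATOM")
  resno <- sort(unique(topo$resno[prot]))
  n <- length(resno)
  F <- nframes(x)
  atom_of <- function(r, name) {
    i <- which(topo$resno == r & topo$elety == name & topo$type == "ATOM")
    if (length(i)) i[1] else NA_integer_
  }
  Ni <- vapply(resno, atom_of, integer(1), name = "N")
  CAi <- vapply(resno, atom_of, integer(1), name = "CA")
  Ci <- vapply(resno, atom_of, integer(1), name = "C")
  incomplete <- is.na(Ni) | is.na(CAi) | is.na(Ci)
  if (any(incomplete))
    warnf("%d residue(s) missing backbone atoms; torsions set NA",
          sum(incomplete))
  coords <- function(ai) {
    out <- matrix(NA_real_, F, 3 * n)
    ok <- !is.na(ai)
    out[, xyz_idx(which(ok))] <- x$xyz[, xyz_idx(ai[ok]), drop = FALSE]
    out
  }
  Nc <- coords(Ni); CAc <- coords(CAi); Cc <- coords(Ci)
  at <- function(M, i) M[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  phi <- matrix(NA_real_, F, n); psi <- matrix(NA_real_, F, n)
  for (i in seq_len(n)) {
    if (i > 1 && resno[i] - resno[i - 1] == 1 &&
        !incomplete[i] && !is.na(Ci[i - 1]))
      phi[, i] <- dihedral_frames(at(Cc, i - 1), at(Nc, i), at(CAc, i), at(Cc, i))
    if (i < n && resno[i + 1] - resno[i] == 1 &&
        !incomplete[i] && !is.na(Ni[i + 1]))
      psi[, i] <- dihedral_frames(at(Nc, i), at(CAc, i), at(Cc, i), at(Nc, i + 1))
  }
  colnames(phi) <- colnames(psi) <- resno
  structure(list(phi = phi, psi = psi, resno = resno), class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  cat(sprintf("torsion series: %d frames x %d residues\n",
              nrow(x$phi), length(x$resno)))
  invisible(x)
}

## periodic bin index 1..nbin for angles in degrees
bin_of <- function(a, nbin) {
  i <- floor((a + 180) / (360 / nbin)) + 1L
  pmin(pmax(i, 1L), nbin)
}

#' Periodic Ramachandran density grid for one residue
#'
#' 2-D histogram of (phi, psi) on a `nbin x nbin` grid of `bin`-degree
#' cells, smoothed with a wrapped Gaussian kernel so that density is
#' continuous across the +/-180 seam, and normalized to sum 1.
#'
#' @param phi,psi angle series, degrees (NA frames dropped).
#' @param bin cell width, degrees (default 10 -> 36 x 36 grid).
#' @param sigma_bins Gaussian smoothing width in bins (0 = none).
#' @param min_frames minimum number of defined frames.
#' @return `nbin x nbin` matrix (rows = phi bins); attribute `"centers"`
#'   holds the bin-center angles.
#' @export
rama_density <- function(phi, psi, bin = 10, sigma_bins = 1, min_frames = 50) {
  ok <- is.finite(phi) & is.finite(psi)
  if (sum(ok) < min_frames)
    stopf("only %d defined frames (need >= %d)", sum(ok), min_frames)
  nbin <- as.integer(round(360 / bin))
  flat <- (bin_of(psi[ok], nbin) - 1L) * nbin + bin_of(phi[ok], nbin)
  h <- matrix(as.numeric(tabulate(flat, nbins = nbin * nbin)), nbin, nbin)
  if (sigma_bins > 0) {
    K <- ceiling(4 * sigma_bins)
    off <- -K:K
    kern <- exp(-off^2 / (2 * sigma_bins^2))
    kern <- kern / sum(kern)
    wrap <- function(i) ((i - 1) %% nbin) + 1L
    ## separable circular convolution
    tmp <- matrix(0, nbin, nbin)
    for (k in seq_along(off)) tmp <- tmp + kern[k] * h[wrap(seq_len(nbin) + off[k]), ]
    h2 <- matrix(0, nbin, nbin)
    for (k in seq_along(off)) h2 <- h2 + kern[k] * tmp[, wrap(seq_len(nbin) + off[k])]
    h <- h2
  }
  h <- h / sum(h)
  attr(h, "centers") <- seq(-180 + bin / 2, 180 - bin / 2, by = bin)
  h
}

## periodic 8-connected components of a logical grid; returns integer labels
torus_components <- function(sel) {
  nbin <- nrow(sel)
  lab <- matrix(0L, nbin, nbin)
  cur <- 0L
  wrap <- function(i) ((i - 1L) %% nbin) + 1L
  for (i0 in seq_len(nbin)) for (j0 in seq_len(nbin)) {
    if (!sel[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i0, j0), 1)
    lab[i0, j0] <- cur
    while (nrow(stack)) {
      p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- wrap(p[1] + di); jj <- wrap(p[2] + dj)
        if (sel[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack <- rbind(stack, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Cluster one residue's phi/psi series on the torus
#'
#' Density-threshold clustering: grid cells are ranked by smoothed density
#' and the lowest level covering at least `mass` of the probability is kept;
#' the retained cells are grouped by periodic 8-connectivity; every frame is
#' assigned to the nearest cluster center by toroidal geodesic distance;
#' clusters holding fewer than `min_occupancy` of the frames are discarded
#' (their frames stay unassigned). Cluster centers are refined as circular
#' means of their member frames.
#'
#' @inheritParams rama_density
#' @param mass probability mass the density superlevel set must cover.
#' @param min_occupancy occupancy floor below which a cluster is dropped.
#' @param merge_radius superlevel fragments with centers closer than this
#'   (degrees) are merged before frame assignment.
#' @return A `torus_clustering`: list with `clusters` (data.frame: id,
#'   phi, psi, occupancy, n), `n_modes`, `n_frames`, `assignment` (integer
#'   per defined frame, NA = unassigned) and the parameters used.
#' @export
cluster_torus <- function(phi, psi, bin = 10, sigma_bins = 1, mass = 0.8,
                          min_occupancy = 0.05, merge_radius = 40,
                          min_frames = 50) {
  ok <- is.finite(phi) & is.finite(psi)
  dens <- rama_density(phi, psi, bin, sigma_bins, min_frames)
  ctr <- attr(dens, "centers")
  o <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[o])
  level <- dens[o][which(cum >= mass)[1]]
  sel <- dens >= level
  lab <- torus_components(sel)
  ncomp <- max(lab)
  cphi <- numeric(ncomp); cpsi <- numeric(ncomp); cw <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    cells <- which(lab == k, arr.ind = TRUE)
    w <- dens[lab == k]
    cphi[k] <- circ_mean(ctr[cells[, 1]], w)
    cpsi[k] <- circ_mean(ctr[cells[, 2]], w)
    cw[k] <- sum(w)
  }
  ## merge superlevel fragments closer than the mode-width scale: a torus
  ## cluster narrower than one mode cannot be a distinct conformation
  while (ncomp > 1) {
    d <- outer(seq_len(ncomp), seq_len(ncomp), function(i, j)
      torus_dist(cphi[i], cpsi[i], cphi[j], cpsi[j]))
    diag(d) <- Inf
    if (min(d) >= merge_radius) break
    k <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(k); j <- max(k)
    wij <- c(cw[i], cw[j])
    cphi[i] <- circ_mean(c(cphi[i], cphi[j]), wij)
    cpsi[i] <- circ_mean(c(cpsi[i], cpsi[j]), wij)
    cw[i] <- sum(wij)
    cphi <- cphi[-j]; cpsi <- cpsi[-j]; cw <- cw[-j]
    ncomp <- ncomp - 1L
  }
  ## assign defined frames to nearest center (toroidal geodesic)
  pf <- phi[ok]; ps <- psi[ok]
  dmat <- vapply(seq_len(ncomp),
                 function(k) torus_dist(pf, ps, cphi[k], cpsi[k]),
                 numeric(length(pf)))
  assign <- if (ncomp == 1) rep(1L, length(pf)) else max.col(-dmat)
  nfrm <- length(pf)
  cl <- data.frame(id = seq_len(ncomp), phi = cphi, psi = cpsi,
                   n = as.vector(table(factor(assign, levels = seq_len(ncomp)))))
  cl$occupancy <- cl$n / nfrm
  keep <- cl$occupancy >= min_occupancy
  assign[!(assign %in% cl$id[keep])] <- NA_integer_
  cl <- cl[keep, , drop = FALSE]
  ## refine centers from member frames
  for (r in seq_len(nrow(cl))) {
    mem <- which(!is.na(assign) & assign == cl$id[r])
    if (length(mem)) {
      cl$phi[r] <- circ_mean(pf[mem])
      cl$psi[r] <- circ_mean(ps[mem])
    }
  }
  cl <- cl[order(-cl$occupancy), , drop = FALSE]
  assign <- match(assign, cl$id)          # renumber to occupancy order
  cl$id <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  structure(list(clusters = cl[, c("id", "phi", "psi", "occupancy", "n")],
                 n_modes = nrow(cl), n_frames = nfrm, assignment = assign,
                 params = list(bin = bin, sigma_bins = sigma_bins, mass = mass,
                               min_occupancy = min_occupancy)),
            class = "torus_clustering")
}

#' @export
print.torus_clustering <- function(x, ...) {
  cat(sprintf("torus clustering: %d mode(s) over %d frames\n",
              x$n_modes, x$n_frames))
  print(x$clusters, digits = 3)
  invisible(x)
}

#' Cluster every residue of a torsion series
#'
#' @param ts a `torsion_series` from [compute_dihedrals()].
#' @param ... passed to [cluster_torus()].
#' @return Named list (by residue number) of `torus_clustering` objects;
#'   residues with too few defined frames are skipped.
#' @export
cluster_residues <- function(ts, ...) {
  out <- list()
  for (i in seq_along(ts$resno)) {
    r <- as.character(ts$resno[i])
    cl <- tryCatch(cluster_torus(ts$phi[, i], ts$psi[, i], ...),
                   error = function(e) NULL)
    if (!is.null(cl)) out[[r]] <- cl
  }
  out
}

#' Residues with two or more phi/psi modes
#'
#' @param clusterings named list of `torus_clustering` (see
#'   [cluster_residues()]).
#' @return Sorted integer residue numbers with `n_modes >= 2`.
#' @export
multimodal_residues <- function(clusterings) {
  n <- vapply(clusterings, function(x) x$n_modes, integer(1))
  sort(as.integer(names(clusterings)[n >= 2]))
}

#' Compare per-residue clusterings between two nucleotide states
#'
#' Clusters of the two states are matched greedily by toroidal geodesic
#' distance between centers. A residue is called shifted when a qualifying
#' cluster in either state has no partner within `match_radius`, or when a
#' matched pair's occupancies differ by at least `delta_occ`.
#'
#' @param clustA,clustB named lists of `torus_clustering` for states A and B.
#' @param match_radius maximal center distance (degrees) for a match.
#' @param delta_occ occupancy-difference threshold.
#' @return data.frame with one row per residue present in both states:
#'   `residue`, `shifted`, `criterion` ("unmatched", "occupancy", or ""),
#'   `n_unmatched`, `max_docc`.
#' @export
compare_states <- function(clustA, clustB, match_radius = 40, delta_occ = 0.3) {
  res <- intersect(names(clustA), names(clustB))
  out <- lapply(res, function(r) {
    a <- clustA[[r]]$clusters
    b <- clustB[[r]]$clusters
    na <- nrow(a); nb <- nrow(b)
    d <- outer(seq_len(na), seq_len(nb), function(i, j)
      torus_dist(a$phi[i], a$psi[i], b$phi[j], b$psi[j]))
    matched <- NULL
    freeA <- seq_len(na); freeB <- seq_len(nb)
    while (length(freeA) && length(freeB)) {
      sub <- d[freeA, freeB, drop = FALSE]
      k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      if (sub[k[1], k[2]] > match_radius) break
      matched <- rbind(matched, c(freeA[k[1]], freeB[k[2]]))
      freeA <- freeA[-k[1]]; freeB <- freeB[-k[2]]
    }
    n_un <- length(freeA) + length(freeB)
    docc <- if (is.null(matched)) numeric(0) else
      abs(a$occupancy[matched[, 1]] - b$occupancy[matched[, 2]])
    crit <- if (n_un > 0) "unmatched" else
      if (length(docc) && max(docc) >= delta_occ) "occupancy" else ""
    data.frame(residue = as.integer(r), shifted = crit != "",
               criterion = crit, n_unmatched = n_un,
               max_docc = if (length(docc)) max(docc) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$residue), , drop = FALSE]
}
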