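# Dynamic cross-correlation (DCC) of residue motions with nucleotide
# pseudo-sites, top-k ranking by absolute correlation, cross-run tallying,
# partner queries and set enrichment.

#' Dynamic cross-correlation matrix with ligand pseudo-sites
#'
#' Frames are iteratively superposed onto the run mean over the Ca
#' selection (the same rigid transform is applied to the ligand series so
#' protein and ligand deviations live in one frame). The correlation is the
#' standard 3-D displacement normalization
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, with `dr` the
#' deviation of a site from its mean position. Ligand sites are appended as
#' extra rows/columns.
#'
#' @param traj a [trajectory()] with at least 10 frames.
#' @param sel Ca atom indices (default: all Ca).
#' @param ligand `NULL`, an `F x 3` matrix, or a named list of such
#'   matrices (one per pseudo-site, e.g. ADP and Pi).
#' @param fit superpose frames before taking deviations (default TRUE).
#' @return A `cor_matrix`: correlation matrix with site labels (residue
#'   numbers, then ligand names); attribute `"sites"` is a data.frame with
#'   `label`, `type` ("residue"/"ligand"), `resno`. Zero-variance sites get
#'   zero off-diagonal rows and are recorded in attribute `"flat_sites"`.
#' @export
dcc_matrix <- function(traj, sel = NULL, ligand = NULL, fit = TRUE) {
  if (nframes(traj) < 10) stopf("need at least 10 frames, got %d", nframes(traj))
  sel <- sel %||% ca_indices(traj$topology)
  if (length(sel) == 0) stopf("empty Ca selection")
  if (!is.null(ligand) && !is.list(ligand)) ligand <- list(ligand = ligand)
  F <- nframes(traj)
  xyz <- traj$xyz
  if (fit) {
    ft <- iterative_fit(xyz, sel)
    xyz <- ft$xyz
    if (!is.null(ligand))
      ligand <- lapply(ligand, function(L) {
        t(vapply(seq_len(F), function(f)
          frame_mat(apply_transform(as.vector(t(L[f, , drop = FALSE])),
                                    ft$transforms[[f]]))[1, ],
          numeric(3)))
      })
  }
  resno <- traj$topology$atoms$resno[sel]
  X <- xyz[, xyz_idx(sel), drop = FALSE]
  if (!is.null(ligand)) {
    for (nm in names(ligand)) {
      L <- ligand[[nm]]
      if (nrow(L) != F) stopf("ligand series '%s' has %d frames, trajectory %d",
                              nm, nrow(L), F)
      X <- cbind(X, L)
    }
  }
  nsite <- ncol(X) / 3
  Xc <- sweep(X, 2, colMeans(X))
  G <- crossprod(Xc)
  ix <- seq(1, 3 * nsite, 3)
  num <- G[ix, ix] + G[ix + 1, ix + 1] + G[ix + 2, ix + 2]
  v <- diag(num)
  flat <- v < 1e-12
  vs <- v; vs[flat] <- 1
  C <- num / sqrt(outer(vs, vs))
  C[flat, ] <- 0; C[, flat] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  nlig <- length(ligand %||% list())
  labels <- c(as.character(resno), names(ligand %||% list()))
  dimnames(C) <- list(labels, labels)
  sites <- data.frame(
    label = labels,
    type = c(rep("residue", length(resno)), rep("ligand", nlig)),
    resno = c(resno, rep(NA_integer_, nlig)),
    stringsAsFactors = FALSE)
  if (any(flat)) warnf("%d site(s) with zero variance; rows zeroed", sum(flat))
  structure(C, sites = sites, flat_sites = labels[flat], class = "cor_matrix")
}

cor_sites <- function(C) attr(C, "sites")

#' Rank residues by absolute correlation to the nucleotide
#'
#' Per residue the score is the maximum `|C|` over all ligand pseudo-sites
#' (+1 and -1 are treated alike). Residues are ordered by descending score
#' with ties broken by ascending residue number; the first `k` are
#' returned.
#'
#' @param C a `cor_matrix` with at least one ligand site.
#' @param k list length (default 60).
#' @return data.frame `residue`, `score`, in rank order.
#' @export
rank_by_ligand <- function(C, k = 60) {
  s <- cor_sites(C)
  lig <- which(s$type == "ligand")
  if (length(lig) == 0) stopf("correlation matrix has no ligand site")
  res <- which(s$type == "residue")
  sc <- apply(abs(C[res, lig, drop = FALSE]), 1, max)
  o <- order(-sc, s$resno[res])
  top <- head(o, min(k, length(o)))
  data.frame(residue = s$resno[res][top], score = unname(sc[top]))
}

#' Tally top-k membership across runs
#'
#' Counts, per residue, in how many runs it appears among the top-k
#' nucleotide-correlated residues; residues reaching `min_runs` are flagged
#' significant.
#'
#' @param run_lists named list of integer vectors (top-k residues per run);
#'   duplicate run labels are an error.
#' @param min_runs significance threshold (default 4).
#' @param universe residue numbers to report (default: union of the lists).
#' @return A `nucleotide_tally` data.frame: `residue`, `count`,
#'   `significant`; attributes `n_runs`, `min_runs`.
#' @export
tally_runs <- function(run_lists, min_runs = 4, universe = NULL) {
  if (length(run_lists) < 1) stopf("no run lists supplied")
  if (!is.null(names(run_lists)) && anyDuplicated(names(run_lists)))
    stopf("duplicate run labels")
  lists <- lapply(run_lists, function(x) {
    if (is.data.frame(x)) x$residue else as.integer(x)
  })
  universe <- universe %||% sort(unique(unlist(lists)))
  cnt <- rowSums(vapply(lists, function(l) universe %in% l,
                        logical(length(universe))))
  out <- data.frame(residue = universe, count = as.integer(cnt),
                    significant = cnt >= min_runs)
  attr(out, "n_runs") <- length(lists)
  attr(out, "min_runs") <- min_runs
  class(out) <- c("nucleotide_tally", "data.frame")
  out
}

#' Top correlated partners of one residue
#'
#' @param C a `cor_matrix`.
#' @param residue query residue number.
#' @param k number of partners.
#' @return data.frame `residue`, `C` (signed), ordered by `|C|` descending;
#'   the query itself and ligand sites are excluded.
#' @export
partner_query <- function(C, residue, k = 60) {
  s <- cor_sites(C)
  qi <- which(s$type == "residue" & s$resno == residue)
  if (length(qi) != 1) stopf("residue %s not present", residue)
  res <- which(s$type == "residue")
  res <- setdiff(res, qi)
  cc <- C[res, qi]
  o <- order(-abs(cc), s$resno[res])
  top <- head(o, min(k, length(o)))
  data.frame(residue = s$resno[res][top], C = unname(cc[top]))
}

#' Hypergeometric enrichment of a reference residue set in a partner list
#'
#' One-sided tail probability of observing at least the overlap between a
#' top-k list and a reference set, drawing `k` residues from a universe of
#' `universe_n` without replacement.
#'
#' @param partners integer residues (or a data.frame with a `residue`
#'   column), e.g. from [partner_query()].
#' @param reference reference residue set (non-empty).
#' @param universe_n universe size (e.g. 383 for the DnaK NBD).
#' @return List `overlap`, `p_value`, `k`, `m`.
#' @export
set_enrichment <- function(partners, reference, universe_n) {
  if (is.data.frame(partners)) partners <- partners$residue
  if (length(reference) == 0) stopf("empty reference set")
  k <- length(unique(partners))
  m <- length(unique(reference))
  if (m > universe_n) stopf("reference set larger than universe")
  ov <- length(intersect(partners, reference))
  p <- stats::phyper(ov - 1, m, universe_n - m, k, lower.tail = FALSE)
  list(overlap = ov, p_value = p, k = k, m = m)
}

#' The proline-switch residue set of DnaK
#'
#' The allosteric residue network K70, R71, P143, A144, Y145, F146, R151,
#' E171, used as the default enrichment reference for hinge partners.
#' @return Integer residue numbers.
#' @export
proline_switch_residues <- function() {
  c(70L, 71L, 143L, 144L, 145L, 146L, 151L, 171L)
}

#' Per-residue minimum distance to ligand atoms
#'
#' @param structure a [structure3d()] containing the ligand atoms.
#' @param ligand_resid residue name(s) of the ligand (HETATM), e.g. "ATP";
#'   alternatively pass explicit `ligand_idx` atom indices.
#' @param ligand_idx optional explicit atom indices of the ligand.
#' @param near_cutoff "near" flag distance, Angstrom (strictly less than).
#' @return data.frame `resno`, `distance`, `near`.
#' @export
distance_to_ligand <- function(structure, ligand_resid = NULL,
                               ligand_idx = NULL, near_cutoff = 8) {
  a <- structure$atoms
  if (is.null(ligand_idx)) {
    if (is.null(ligand_resid)) stopf("give ligand_resid or ligand_idx")
    ligand_idx <- which(a$resid %in% ligand_resid)
  }
  if (length(ligand_idx) == 0) stopf("ligand selection resolves to no atoms")
  L <- as.matrix(a[ligand_idx, c("x", "y", "z")])
  prot <- setdiff(which(a$type == "ATOM"), ligand_idx)
  out <- lapply(split(prot, a$resno[prot]), function(idx) {
    P <- as.matrix(a[idx, c("x", "y", "z")])
    d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
    min(sqrt(pmax(d2, 0)))
  })
  resno <- as.integer(names(out))
  d <- unlist(out, use.names = FALSE)
  o <- order(resno)
  data.frame(resno = resno[o], distance = d[o], near = d[o] < near_cutoff)
}
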