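# Frame superposition, RMSD series, subdomain center-of-mass openness and
# helix-axis geometry.

## coerce a frame argument (flat xyz vector, A x 3 matrix, structure3d, or
## trajectory + frame index) to a flat xyz vector
as_flat_xyz <- function(x, frame = 1) {
  if (inherits(x, "trajectory")) return(x$xyz[frame, ])
  if (inherits(x, "structure3d"))
    return(as.vector(t(as.matrix(x$atoms[, c("x", "y", "z")]))))
  if (is.matrix(x) && ncol(x) == 3) return(as.vector(t(x)))
  as.numeric(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` over the fit selection. Coordinates transform as
#' row vectors: `fitted = (x - center_mobile) %*% R + center_reference`.
#'
#' @param mobile,reference flat xyz vectors (or `A x 3` matrices) of equal
#'   length.
#' @param fit_sel atom indices used for the fit (default: all atoms).
#' @return List with `R` (3x3 proper rotation), `center_mobile`,
#'   `center_reference`, and `rmsd` (Angstrom, over the fit selection).
#' @export
superpose <- function(mobile, reference, fit_sel = NULL) {
  mv <- as_flat_xyz(mobile); rv <- as_flat_xyz(reference)
  if (length(mv) != length(rv)) stopf("coordinate lengths differ")
  na <- length(mv) / 3
  fit_sel <- fit_sel %||% seq_len(na)
  if (length(fit_sel) < 3) stopf("need at least 3 fit atoms")
  P <- frame_mat(mv[xyz_idx(fit_sel)])
  Q <- frame_mat(rv[xyz_idx(fit_sel)])
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stopf("fit atoms are (nearly) collinear; superposition is degenerate")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, center_mobile = cp, center_reference = cq, rmsd = rmsd)
}

## apply a superpose() transform to a flat xyz vector (all atoms)
apply_transform <- function(v, tr) {
  m <- frame_mat(v)
  m <- sweep(m, 2, tr$center_mobile) %*% tr$R
  as.vector(t(sweep(m, 2, tr$center_reference, "+")))
}

## RMSD between two flat xyz vectors over a selection, without fitting
raw_rmsd <- function(a, b, sel) {
  ia <- xyz_idx(sel)
  sqrt(mean(rowSums((frame_mat(a[ia]) - frame_mat(b[ia]))^2)))
}

#' Per-frame Ca RMSD series
#'
#' Each frame is superposed onto the reference over `fit_sel`, then the RMSD
#' is reported over `report_sel` (default: the fit selection).
#'
#' @param traj a [trajectory()].
#' @param reference flat xyz vector or [structure3d()] (default: frame 1).
#' @param fit_sel,report_sel atom indices.
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, fit_sel = NULL,
                        report_sel = NULL) {
  ref <- if (is.null(reference)) traj$xyz[1, ] else as_flat_xyz(reference)
  na <- natoms(traj$topology)
  fit_sel <- fit_sel %||% seq_len(na)
  report_sel <- report_sel %||% fit_sel
  if (length(report_sel) == 0 || length(fit_sel) == 0)
    stopf("empty selection")
  vapply(seq_len(nframes(traj)), function(f) {
    tr <- superpose(traj$xyz[f, ], ref, fit_sel)
    raw_rmsd(apply_transform(traj$xyz[f, ], tr), ref, report_sel)
  }, numeric(1))
}

#' Subdomain center-of-mass openness series
#'
#' Per frame, the Euclidean distance between the unweighted Ca center of
#' mass of `group` (subdomain II-B by default) and that of the pooled
#' `others` (I-A, I-B and II-A). No fitting is needed: the distance between
#' group centers is invariant to rigid motion of the frame.
#'
#' @param traj a [trajectory()].
#' @param map a [make_subdomain_map()] result.
#' @param group mobile group name.
#' @param others groups pooled into the fixed block (those present in the
#'   map are used).
#' @param threshold open/closed boundary passed to [classify_openness()].
#' @return An `openness_series`: list with per-frame `distance` (Angstrom),
#'   `mean`, `sd`, `classification` and `label`.
#' @export
openness_series <- function(traj, map, group = "II-B",
                            others = c("I-A", "I-B", "II-A"),
                            threshold = 29.5) {
  others <- intersect(others, names(map))
  if (!group %in% names(map)) stopf("map has no group '%s'", group)
  if (length(others) == 0) stopf("map has none of the reference groups")
  ia <- ca_indices(traj$topology, subdomain_residues(map, group))
  ib <- ca_indices(traj$topology, subdomain_residues(map, others))
  if (length(ia) == 0 || length(ib) == 0)
    stopf("empty Ca selection for a subdomain group")
  com <- function(idx) {
    cols <- xyz_idx(idx)
    x <- traj$xyz[, cols, drop = FALSE]
    k <- length(idx)
    cbind(rowMeans(x[, seq(1, 3 * k, 3), drop = FALSE]),
          rowMeans(x[, seq(2, 3 * k, 3), drop = FALSE]),
          rowMeans(x[, seq(3, 3 * k, 3), drop = FALSE]))
  }
  d <- unname(row_norm(com(ia) - com(ib)))
  structure(list(distance = d, mean = mean(d), sd = stats::sd(d),
                 classification = classify_openness(mean(d), threshold),
                 threshold = threshold, label = traj$label),
            class = "openness_series")
}

#' @export
print.openness_series <- function(x, ...) {
  cat(sprintf("openness '%s': %.1f +/- %.1f A over %d frames -> %s\n",
              x$label, x$mean, x$sd, length(x$distance), x$classification))
  invisible(x)
}

#' Open/closed call from a mean inter-subdomain distance
#'
#' "open" iff the mean exceeds the threshold (default 29.5 Angstrom, the
#' midpoint of the reported apo and ATP-state means); the boundary itself is
#' called "closed".
#'
#' @param mean_distance mean II-B to I-A/B+II-A center-of-mass distance, Angstrom.
#' @param threshold boundary, Angstrom.
#' @return `"open"` or `"closed"`.
#' @export
classify_openness <- function(mean_distance, threshold = 29.5) {
  if (any(mean_distance <= 0)) stopf("mean distance must be positive")
  ifelse(mean_distance > threshold, "open", "closed")
}

## Ca coordinates (k x 3) of a residue range from a structure/trajectory frame
range_ca_coords <- function(x, range, frame = 1) {
  topo <- if (inherits(x, "trajectory")) x$topology else x
  idx <- ca_indices(topo, seq.int(range[1], range[2]))
  v <- as_flat_xyz(x, frame)
  frame_mat(v[xyz_idx(idx)])
}

#' Helix axis, inter-helical angle and helix bend
#'
#' `helix_axis()` returns the first principal axis of the centered Ca
#' coordinates of a residue range, with its sign fixed to point from the
#' N- to the C-terminal end. `interhelical_angle()` is the acute angle
#' between two such axes. `helix_bend_angle()` splits a helix at a pivot
#' residue and reports the angle between the proximal and distal
#' sub-segment axes (both oriented N to C), flagging the helix as bent when
#' the angle exceeds `bend_threshold`.
#'
#' @param x [structure3d()] or [trajectory()].
#' @param range `c(first, last)` residue numbers (>= 4 Ca needed).
#' @param frame frame index for trajectories.
#' @return `helix_axis`: unit 3-vector.
#' @export
helix_axis <- function(x, range, frame = 1) {
  ca <- range_ca_coords(x, range, frame)
  if (nrow(ca) < 4) stopf("need >= 4 Ca atoms in range %d-%d", range[1], range[2])
  cc <- sweep(ca, 2, colMeans(ca))
  if (max(abs(cc)) < 1e-9) stopf("degenerate helix: all atoms coincide")
  ax <- stats::prcomp(ca, center = TRUE)$rotation[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' @rdname helix_axis
#' @param rangeA,rangeB residue ranges of the two helices.
#' @return `interhelical_angle`: degrees in `[0, 90]`.
#' @export
interhelical_angle <- function(x, rangeA, rangeB, frame = 1) {
  a <- helix_axis(x, rangeA, frame)
  b <- helix_axis(x, rangeB, frame)
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}

#' @rdname helix_axis
#' @param pivot pivot residue number (>= 4 Ca needed on each side).
#' @param bend_threshold degrees above which the helix is flagged bent.
#' @return `helix_bend_angle`: list with `angle` (degrees, `[0, 180]`) and
#'   logical `bent`.
#' @export
helix_bend_angle <- function(x, range, pivot, frame = 1, bend_threshold = 30) {
  if (pivot - range[1] + 1 < 4 || range[2] - pivot + 1 < 4)
    stopf("pivot %d too close to the range ends %d-%d", pivot, range[1], range[2])
  a <- helix_axis(x, c(range[1], pivot), frame)
  b <- helix_axis(x, c(pivot, range[2]), frame)
  ang <- acos(pmax(-1, pmin(1, sum(a * b)))) * 180 / pi
  list(angle = ang, bent = ang > bend_threshold, pivot = pivot,
       threshold = bend_threshold)
}
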