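# Internal helpers. Rows of an F x 3 matrix are treated as 3-vectors so the
# same code serves one frame or a whole trajectory.

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_dot <- function(a, b) rowSums(a * b)

row_norm <- function(a) sqrt(rowSums(a * a))

row_unit <- function(a) a / row_norm(a)

as_row3 <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1, ncol = 3)
}

## wrap angles (degrees) into [-180, 180)
wrap_deg <- function(x) ((x + 180) %% 360) - 180

## shortest signed angular difference a - b on the circle, degrees
circ_diff <- function(a, b) wrap_deg(a - b)

## geodesic distance on the (phi, psi) torus, degrees
torus_dist <- function(phi1, psi1, phi2, psi2) {
  sqrt(circ_diff(phi1, phi2)^2 + circ_diff(psi1, psi2)^2)
}

## circular mean of angles in degrees (optionally weighted)
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  r <- x * pi / 180
  wrap_deg(atan2(sum(w * sin(r)), sum(w * cos(r))) * 180 / pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## xyz vector indices of atom i (bio3d convention: flat x1,y1,z1,x2,...)
xyz_idx <- function(i) {
  as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))
}

## reshape one flat xyz frame (length 3A) into an A x 3 matrix
frame_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
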