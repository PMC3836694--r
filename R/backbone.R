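# Backbone construction from internal coordinates (NeRF chain extension).
# Ideal geometry; omega fixed at 180 deg. Placement is vectorized across
# frames: each step operates on F x 3 matrices, so rebuilding a whole
# ensemble costs one pass over the chain, not one per frame.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
ANG_N_CA_C <- 111.2   # at Ca, between N-Ca and Ca-C
ANG_CA_C_N <- 116.2   # at C,  between Ca-C and C-N
ANG_C_N_CA <- 121.7   # at N,  between C-N and N-Ca

## Place atom D given the three preceding atoms (F x 3 matrices), the D-C
## bond length, the B-C-D angle (deg, scalar) and the A-B-C-D dihedral
## (deg, scalar or length-F). Sign convention matches dihedral_frames().
##
## When a reference position and a steer bound are given, the bond angle is
## flexed within +/- steer degrees to bring D as close as possible to the
## reference -- a tertiary-contact-like tether that keeps the chain near its
## scaffold. The dihedral is honoured exactly either way (it depends only on
## the rotation about the B->C axis, which steering never touches).
nerf_place <- function(A, B, C, bond, theta, chi, ref = NULL,
                       ref_prev = NULL, steer = 0, chi_steer = 0,
                       gain = 0.3) {
  ch <- rep(chi * pi / 180, length.out = nrow(C))
  bc <- row_unit(C - B)
  n  <- row_unit(row_cross(B - A, bc))
  m  <- row_cross(n, bc)
  th <- rep(theta * pi / 180, length.out = nrow(C))
  if (!is.null(ref) && (steer > 0 || chi_steer > 0)) {
    ## track the reference step direction, with a weak pull back to the
    ## reference position (small gain avoids clamp-saturation oscillation)
    g <- if (is.null(ref_prev)) ref - C
         else {
           pull <- gain * (ref_prev - C)
           pn <- row_norm(pull)
           over <- pn > 1           # cap the pull at 1 A to keep the turn
           pull[over, ] <- pull[over, , drop = FALSE] / pn[over]
           (ref - ref_prev) + pull
         }
    if (chi_steer > 0) {
      ## dihedral may flex too (used for omega only): aim fully at ref
      ch_opt <- atan2(row_dot(g, n), row_dot(g, m))
      clim <- chi_steer * pi / 180
      dd <- ((ch_opt - ch + pi) %% (2 * pi)) - pi
      ch <- ch + pmin(pmax(dd, -clim), clim)
    }
    v0 <- m * cos(ch) + n * sin(ch)
    th_opt <- atan2(row_dot(g, v0), -row_dot(g, bc))
    if (steer > 0) {
      lim <- steer * pi / 180
      ## clamp to +/- steer around ideal, and keep the triad well away from
      ## collinearity (degenerate dihedrals downstream)
      th <- pmin(pmax(th_opt, th - lim), th + lim)
      th <- pmin(pmax(th, 65 * pi / 180), 160 * pi / 180)
    }
  }
  v <- m * cos(ch) + n * sin(ch)
  C - bond * cos(th) * bc + bond * sin(th) * v
}

## phi, psi: F x n matrices (degrees). Returns F x (9n) xyz matrix with
## atom order N1 CA1 C1 N2 CA2 C2 ...  phi[,1] and psi[,n] are unused.
## ref (flat length-9n xyz) + steer > 0 tether the chain to a scaffold via
## bond-angle flexing (see nerf_place); sampled dihedrals stay exact.
build_backbone_frames <- function(phi, psi, omega = 180, ref = NULL,
                                  steer = 0) {
  n <- ncol(phi)
  if (!identical(dim(phi), dim(psi))) stopf("phi and psi dimensions differ")
  if (n < 3) stopf("need at least 3 residues to build a backbone")
  F <- nrow(phi)
  xyz <- matrix(NA_real_, F, 9 * n)
  cols <- function(atom, i) (9 * (i - 1) + 3 * (atom - 1)) + 1:3  # atom: 1=N,2=CA,3=C
  one <- function(v) matrix(v, F, 3, byrow = TRUE)
  refm <- function(atom, i) {
    if (is.null(ref)) NULL else one(ref[cols(atom, i)])
  }
  ## first residue in the xy-plane
  N1  <- one(c(0, 0, 0))
  CA1 <- one(c(BOND_N_CA, 0, 0))
  ## C1 in the xy-plane so that angle N-CA-C = 111.2 deg
  a1  <- pi - ANG_N_CA_C * pi / 180
  C1  <- CA1 + one(BOND_CA_C * c(cos(a1), sin(a1), 0))
  xyz[, cols(1, 1)] <- N1; xyz[, cols(2, 1)] <- CA1; xyz[, cols(3, 1)] <- C1
  Np <- N1; CAp <- CA1; Cp <- C1
  for (i in 2:n) {
    Ni  <- nerf_place(Np, CAp, Cp, BOND_C_N, ANG_CA_C_N, psi[, i - 1],
                      refm(1, i), refm(3, i - 1), steer)
    CAi <- nerf_place(CAp, Cp, Ni, BOND_N_CA, ANG_C_N_CA, omega,
                      refm(2, i), refm(1, i), steer, chi_steer = 3 * steer)
    Ci  <- nerf_place(Cp, Ni, CAi, BOND_CA_C, ANG_N_CA_C, phi[, i],
                      refm(3, i), refm(2, i), steer)
    xyz[, cols(1, i)] <- Ni; xyz[, cols(2, i)] <- CAi; xyz[, cols(3, i)] <- Ci
    Np <- Ni; CAp <- CAi; Cp <- Ci
  }
  xyz
}

backbone_topology <- function(n_residues, chain = "A", resid = "ALA") {
  data.frame(
    elety = rep(c("N", "CA", "C"), n_residues),
    element = rep(c("N", "C", "C"), n_residues),
    resno = rep(seq_len(n_residues), each = 3),
    resid = resid, chain = chain, x = 0, y = 0, z = 0, type = "ATOM",
    stringsAsFactors = FALSE)
}

#' Build an ideal backbone from phi/psi angles
#'
#' Places N, Ca and C atoms for every residue using ideal bond lengths
#' (N-Ca 1.458, Ca-C 1.525, C-N 1.329 Angstrom), ideal bond angles and a
#' fixed omega of 180 degrees, so that torsions recomputed from the built
#' coordinates reproduce the inputs to well under half a degree.
#'
#' @param n_residues number of residues (>= 3).
#' @param phi_psi numeric `n x 2` matrix of (phi, psi) in degrees, or a
#'   length-2 vector applied to every residue. `phi[1]` and `psi[n]` are
#'   undefined for a chain and are ignored.
#' @return A [structure3d()] with 3 backbone atoms per residue.
#' @export
generate_backbone <- function(n_residues, phi_psi = c(-57, -47)) {
  if (n_residues < 3) stopf("need at least 3 residues, got %d", n_residues)
  if (is.null(dim(phi_psi))) phi_psi <- matrix(phi_psi, n_residues, 2, byrow = TRUE)
  if (nrow(phi_psi) != n_residues) stopf("phi_psi must have one row per residue")
  xyz <- build_backbone_frames(matrix(phi_psi[, 1], 1), matrix(phi_psi[, 2], 1))
  atoms <- backbone_topology(n_residues)
  m <- frame_mat(xyz[1, ])
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  structure3d(atoms, metadata = list(generator = "generate_backbone"))
}

## parametric alpha-helix Ca trace: rise 1.5 A, 100 deg/res; radius 2.3 A
## (standard); short non-integer-turn segments tilt the principal axis by a
## few degrees at full radius, so callers needing an accurate planted axis
## can thin the radius
ideal_helix_ca <- function(n, radius = 2.3) {
  t <- seq_len(n) - 1
  cbind(radius * cos(t * 100 * pi / 180), radius * sin(t * 100 * pi / 180),
        1.5 * t)
}

#' Synthetic crossed-helix Ca model
#'
#' Constructs an idealized Ca-only model of the two crossed alpha-helices at
#' the subdomain I-A/II-A interface of the Hsp70 NBD (residue numbering
#' 171-179 and 367-377), crossing at a prescribed angle. This is a synthetic
#' stand-in built from ideal helix geometry, not deposited coordinates; it
#' exercises the helix-axis machinery at the crossing geometry reported for
#' the NBD crystal structure (roughly 75 degrees).
#'
#' @param angle_deg planted inter-helical (acute) angle, degrees.
#' @return A [structure3d()] with Ca atoms numbered 171-179 and 367-377;
#'   `metadata$synthetic` is `TRUE`.
#' @export
crossed_helices <- function(angle_deg = 75) {
  h1 <- ideal_helix_ca(9, radius = 0.8)        # axis ~ +z
  th <- angle_deg * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  h2 <- ideal_helix_ca(11, radius = 0.8) %*% t(R)
  h2 <- sweep(h2, 2, c(8, 4, 0), "+")          # offset so the helices pack
  ca <- rbind(h1, h2)
  atoms <- data.frame(
    elety = "CA", element = "C",
    resno = c(171:179, 367:377),
    resid = "ALA", chain = "A",
    x = ca[, 1], y = ca[, 2], z = ca[, 3], type = "ATOM",
    stringsAsFactors = FALSE)
  structure3d(atoms, metadata = list(synthetic = TRUE,
                                     planted_angle_deg = angle_deg))
}
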