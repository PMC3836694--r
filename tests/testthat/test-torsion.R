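test_that("dihedrals are rigid-invariant, scale-invariant, mirror-antisymmetric", {
  set.seed(1)
  pp <- cbind(rvonmises(15, -90, 3), rvonmises(15, 60, 3))
  s <- generate_backbone(15, pp)
  base <- compute_dihedrals(s)
  v <- flat_xyz(s)
  ## rigid transform
  s_r <- s
  m <- matrix(random_rigid(v, 3), ncol = 3, byrow = TRUE)
  s_r$atoms$x <- m[, 1]; s_r$atoms$y <- m[, 2]; s_r$atoms$z <- m[, 3]
  td_r <- compute_dihedrals(s_r)
  expect_lt(max(abs(cdiff(td_r$phi[, -1], base$phi[, -1]))), 1e-6)
  ## uniform scaling
  s_s <- s
  s_s$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] * 3.7
  td_s <- compute_dihedrals(s_s)
  expect_lt(max(abs(cdiff(td_s$psi[, -15], base$psi[, -15]))), 1e-6)
  ## mirror flips every sign
  s_m <- s; s_m$atoms$x <- -s$atoms$x
  td_m <- compute_dihedrals(s_m)
  expect_lt(max(abs(cdiff(td_m$phi[, -1], -base$phi[, -1]))), 1e-6)
  ## terminal angles undefined
  expect_true(is.na(base$phi[1, 1]))
  expect_true(is.na(base$psi[1, 15]))
})

test_that("missing backbone atoms yield NA with a warning", {
  s <- generate_backbone(8)
  s$atoms <- s$atoms[-which(s$atoms$resno == 4 & s$atoms$elety == "C"), ]
  expect_warning(td <- compute_dihedrals(s), "missing backbone")
  expect_true(is.na(td$phi[1, 4]))
  expect_true(is.na(td$psi[1, 4]))
  expect_false(is.na(td$phi[1, 6]))
})

test_that("rama density is normalized, periodic across the wrap, near-uniform for uniform input", {
  set.seed(2)
  phi <- rvonmises(5000, 179, 30)
  psi <- rvonmises(5000, -179, 30)
  d <- rama_density(phi, psi)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  ## mode straddling the seam: density continuous (max cell at a corner,
  ## neighbours across the wrap are comparable, no cliff)
  mx <- which(d == max(d), arr.ind = TRUE)[1, ]
  wrap_nb <- d[(mx[1] %% 36) + 1, (mx[2] %% 36) + 1]
  expect_gt(wrap_nb, max(d) * 0.2)
  ## uniform draws: max/min cell ratio < 2 at large n
  set.seed(3)
  u <- rama_density(runif(1e5, -180, 180), runif(1e5, -180, 180))
  expect_lt(max(u) / min(u), 2)
  expect_error(rama_density(phi[1:10], psi[1:10]), "defined frames")
  ## a single repeated angle occupies a single cell before smoothing
  one <- rama_density(rep(-57, 100), rep(-47, 100), sigma_bins = 0)
  expect_equal(sum(one > 0), 1)
})

test_that("torus clustering counts planted modes and respects the wrap", {
  set.seed(4)
  one <- cluster_torus(rvonmises(5000, -60, 20), rvonmises(5000, -45, 20))
  expect_equal(one$n_modes, 1)
  z <- rbinom(5000, 1, 0.5) == 1
  phi <- ifelse(z, rvonmises(5000, -60, 20), rvonmises(5000, -150, 20))
  psi <- ifelse(z, rvonmises(5000, -45, 20), rvonmises(5000, 160, 20))
  two <- cluster_torus(phi, psi)
  expect_equal(two$n_modes, 2)
  expect_true(all(two$clusters$occupancy > 0.4 & two$clusters$occupancy < 0.6))
  ## mode straddling the wrap is not split
  wrapd <- cluster_torus(rvonmises(5000, 175, 20), rvonmises(5000, 0, 20))
  expect_equal(wrapd$n_modes, 1)
  expect_lt(abs(cdiff(wrapd$clusters$phi[1], 175)), 5)
})

test_that("cluster_torus is equivariant under a global angle rotation", {
  set.seed(5)
  z <- rbinom(4000, 1, 0.3) == 1
  phi <- ifelse(z, rvonmises(4000, -120, 20), rvonmises(4000, -57, 20))
  psi <- ifelse(z, rvonmises(4000, 130, 20), rvonmises(4000, -47, 20))
  a <- cluster_torus(phi, psi)
  b <- cluster_torus(cdiff(phi + 90, 0), cdiff(psi + 90, 0))
  expect_equal(a$n_modes, b$n_modes)
  oa <- order(-a$clusters$occupancy); ob <- order(-b$clusters$occupancy)
  expect_equal(a$clusters$occupancy[oa], b$clusters$occupancy[ob],
               tolerance = 0.02)
  expect_lt(max(abs(cdiff(b$clusters$phi[ob], a$clusters$phi[oa] + 90))), 8)
})

test_that("multimodal calls ignore frame order", {
  set.seed(6)
  sp <- plant_spec(n_residues = 50, seed = 6)
  g <- generate_trajectory(sp, 200)
  td <- compute_dihedrals(g$trajectory)
  cl1 <- cluster_residues(td)
  perm <- sample(200)
  td2 <- td; td2$phi <- td$phi[perm, ]; td2$psi <- td$psi[perm, ]
  cl2 <- cluster_residues(td2)
  expect_identical(multimodal_residues(cl1), multimodal_residues(cl2))
})

test_that("state comparison flags occupancy swaps and extra modes, not identity", {
  mk <- function(occ2, seed, extra = FALSE) {
    set.seed(seed)
    n <- 2000
    z <- rbinom(n, 1, occ2) == 1
    phi <- ifelse(z, rvonmises(n, -120, 20), rvonmises(n, -57, 20))
    psi <- ifelse(z, rvonmises(n, 130, 20), rvonmises(n, -47, 20))
    if (extra) {
      w <- rbinom(n, 1, 0.5) == 1
      phi[w] <- rvonmises(sum(w), 60, 20)
      psi[w] <- rvonmises(sum(w), 40, 20)
    }
    list(cluster_torus(phi, psi))
  }
  wrap1 <- function(x) { names(x) <- "7"; x }
  ## identical ensembles: nothing shifts
  same <- compare_states(wrap1(mk(0.3, 1)), wrap1(mk(0.3, 2)))
  expect_false(any(same$shifted))
  ## occupancy swap 0.9 -> 0.1 with fixed centers: flagged via the
  ## occupancy delta (or, if the 10% mode dips under the density level in
  ## one state, via the unmatched-cluster rule -- still a shift call)
  swap <- compare_states(wrap1(mk(0.9, 3)), wrap1(mk(0.1, 4)))
  expect_true(swap$shifted[1])
  expect_true(swap$criterion[1] %in% c("occupancy", "unmatched"))
  swap2 <- compare_states(wrap1(mk(0.8, 3)), wrap1(mk(0.2, 4)))
  expect_equal(swap2$criterion[1], "occupancy")
  ## extra mode in state B only
  extra <- compare_states(wrap1(mk(0.0, 5)), wrap1(mk(0.0, 6, extra = TRUE)))
  expect_true(extra$shifted[1])
  expect_equal(extra$criterion[1], "unmatched")
})
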