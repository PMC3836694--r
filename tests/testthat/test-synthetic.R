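test_that("backbone rebuilt from phi/psi returns those angles within 0.5 deg", {
  set.seed(7)
  pp <- cbind(rvonmises(30, -100, 4), rvonmises(30, 80, 4))
  s <- generate_backbone(30, pp)
  td <- compute_dihedrals(s)
  expect_lt(max(abs(cdiff(td$phi[1, 2:30], pp[2:30, 1]))), 0.5)
  expect_lt(max(abs(cdiff(td$psi[1, 1:29], pp[1:29, 2]))), 0.5)
  expect_error(generate_backbone(2), "at least 3")
})

test_that("ideal-geometry chains have correct Ca-Ca spacing", {
  s <- generate_backbone(20, c(-120, 120))
  ca <- as.matrix(s$atoms[s$atoms$elety == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
})

test_that("tethered rebuild keeps dihedrals exact while staying compact", {
  n <- 80
  ref <- generate_backbone(n)
  set.seed(3)
  sp <- plant_spec(n_residues = n, hinges = NULL, seed = 3)
  g <- generate_trajectory(sp, 30)
  ## compactness: every residue stays within a few Angstrom of its mean
  X <- g$trajectory$xyz
  drift <- vapply(seq_len(n), function(r) {
    cols <- c(3 * (3 * (r - 1) + 2) - 2:0)
    sqrt(mean(sweep(X[, cols, drop = FALSE], 2,
                    colMeans(X[, cols, drop = FALSE]))^2))
  }, numeric(1))
  expect_lt(max(drift), 5)
})

test_that("von Mises sampler has the right circular moments", {
  set.seed(11)
  x <- rvonmises(4e4, 30, 20)
  expect_lt(abs(cdiff(atan2(mean(sin(x * pi / 180)),
                            mean(cos(x * pi / 180))) * 180 / pi, 30)), 1)
  ## circular sd ~ 1/sqrt(kappa) for large kappa
  expect_lt(abs(sd(cdiff(x, 30)) - 180 / pi / sqrt(20)), 0.5)
  u <- rvonmises(2e4, 0, 0)
  expect_gt(ks.test(u, "punif", -180, 180)$p.value, 1e-4)
})

test_that("same spec and seed give identical trajectories; runs differ", {
  sp <- plant_spec(n_residues = 50, seed = 9)
  a <- generate_trajectory(sp, 15)
  b <- generate_trajectory(sp, 15)
  expect_identical(a$trajectory$xyz, b$trajectory$xyz)
  expect_identical(a$ligand, b$ligand)
  ens <- generate_ensemble(sp, 2, 15)
  expect_false(identical(ens$runs[[1]]$trajectory$xyz,
                         ens$runs[[2]]$trajectory$xyz))
})

test_that("plant_spec validates its inputs", {
  expect_error(plant_spec(hinges = data.frame(
    residue = c(5, 5), phi1 = -57, psi1 = -47, phi2 = -120, psi2 = 130,
    kappa = 20, occ2_apo = .5, occ2_ATP = .5, occ2_ADP_Pi = .5)),
    "duplicate")
  expect_error(plant_spec(hinges = data.frame(
    residue = 1, phi1 = -57, psi1 = -47, phi2 = -120, psi2 = 130,
    kappa = 20, occ2_apo = .5, occ2_ATP = .5, occ2_ADP_Pi = .5)),
    "hinge residues")
  expect_error(plant_spec(coupled = data.frame(residue = 5, weight = 1.5)),
    "weights")
  expect_error(generate_trajectory(plant_spec(), 5), "at least 10")
})

test_that("zero-hinge ensembles stay unimodal downstream", {
  ## per-residue false-positive bound: at most 5% of residues may throw a
  ## spurious second mode
  sp <- plant_spec(n_residues = 60, hinges = NULL, seed = 13)
  g <- generate_trajectory(sp, 500)
  cl <- cluster_residues(compute_dihedrals(g$trajectory))
  expect_lte(length(multimodal_residues(cl)) / 60, 0.05)
})

test_that("a planted ATP/ADP occupancy swap is recovered as a state shift", {
  h <- data.frame(residue = 30, phi1 = -57, psi1 = -47, phi2 = -120,
                  psi2 = 130, kappa = 20, occ2_apo = .5, occ2_ATP = .05,
                  occ2_ADP_Pi = .9)
  cl <- lapply(c("ATP", "ADP_Pi"), function(st) {
    sp <- plant_spec(n_residues = 60, state = st, hinges = h, seed = 17)
    cluster_residues(compute_dihedrals(generate_trajectory(sp, 400)$trajectory))
  })
  sh <- compare_states(cl[[1]], cl[[2]])
  expect_true(sh$shifted[sh$residue == 30])
  expect_lt(mean(sh$shifted[sh$residue != 30]), 0.06)
})

test_that("generated MSAs hit their identity targets and conservative letters score > 0", {
  gm <- generate_msa(500, identity_pct = 90, conservative_pct = 9,
                     reference = "SERINE", seed = 5)
  prof <- conservation_profile(gm$msa)
  expect_true(all(abs(prof$identity_pct - 90) <= 2))
  ## conservative letters at the Ser column really score > 0 vs S
  col1 <- gm$msa$seqs[-1, 1]
  alt <- setdiff(unique(col1), c("S", "-"))
  data(BLOSUM62, package = "Biostrings", envir = environment())
  nonid <- col1[col1 != "S" & col1 != "-"]
  cons <- nonid[BLOSUM62["S", nonid] > 0]
  expect_equal(mean(col1 %in% cons) * 100,
               prof$conservative_pct[prof$column == 1], tolerance = 1e-9)
  ## column forced to 100% identity
  gm2 <- generate_msa(50, identity_pct = 100, conservative_pct = 0,
                      reference = "AC", seed = 1)
  expect_true(all(gm2$msa$seqs[, 1] == "A"))
  expect_error(generate_msa(50, identity_pct = 95, conservative_pct = 10),
               "exceeds 100")
})

test_that("MSA round trip through FASTA keeps groups and letters", {
  gm <- generate_msa(40, identity_pct = 85, conservative_pct = 10,
                     n_columns = 30,
                     groups = c(bacteria = 20, animals = 19), seed = 8)
  fa <- tempfile(fileext = ".fasta"); gr <- tempfile(fileext = ".tsv")
  write_msa(gm$msa, fa, gr)
  back <- read_alignment(fa, utils::read.delim(gr))
  expect_identical(back$seqs, gm$msa$seqs)
  expect_identical(back$groups, gm$msa$groups)
})
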