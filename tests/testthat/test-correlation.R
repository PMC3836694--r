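test_that("DCC matches a brute-force double-loop oracle", {
  set.seed(1)
  topo <- generate_backbone(6)
  xyz <- matrix(rnorm(200 * 54), 200, 54)
  tr <- trajectory(topo, xyz)
  lig <- matrix(rnorm(600), 200, 3)
  C <- dcc_matrix(tr, ligand = lig, fit = FALSE)
  ## oracle: explicit double loop over site pairs
  sites <- cbind(xyz[, as.vector(rbind(3 * (3 * (1:6 - 1) + 2) - 2,
                                       3 * (3 * (1:6 - 1) + 2) - 1,
                                       3 * (3 * (1:6 - 1) + 2)))], lig)
  n <- 7
  O <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    di <- scale(sites[, (3 * i - 2):(3 * i)], scale = FALSE)
    dj <- scale(sites[, (3 * j - 2):(3 * j)], scale = FALSE)
    O[i, j] <- mean(rowSums(di * dj)) /
      sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
  }
  expect_lt(max(abs(unclass(C) - O)), 1e-10)
  expect_true(all(diag(C) == 1))
  expect_true(all(abs(C) <= 1))
  expect_equal(unclass(C), t(unclass(C)))
})

test_that("identical and negated motions give +1 / -1; zero variance is flagged", {
  topo <- generate_backbone(3)
  v <- flat_xyz(topo)
  set.seed(2)
  base <- matrix(rnorm(50 * 9, sd = 0.5), 50, 9)
  base[, 4:6] <- base[, 1:3]        # Ca2 ... wait columns are atoms
  xyz <- matrix(rep(v, each = 50), 50)
  ca <- select_atoms(topo, elety = "CA")
  d1 <- matrix(rnorm(150, sd = 1), 50, 3)
  xyz[, 3 * ca[1] - 2:0] <- xyz[, 3 * ca[1] - 2:0] + d1
  xyz[, 3 * ca[2] - 2:0] <- xyz[, 3 * ca[2] - 2:0] + d1
  xyz[, 3 * ca[3] - 2:0] <- xyz[, 3 * ca[3] - 2:0] - d1
  tr <- trajectory(topo, xyz)
  C <- dcc_matrix(tr, fit = FALSE)
  expect_equal(C["1", "2"], 1, tolerance = 1e-12)
  expect_equal(C["1", "3"], -1, tolerance = 1e-12)
  ## a frozen site gets a zeroed row and a warning
  xyz2 <- xyz; xyz2[, 3 * ca[3] - 2:0] <- 0
  expect_warning(C2 <- dcc_matrix(trajectory(topo, xyz2), fit = FALSE),
                 "zero variance")
  expect_equal(unname(C2["3", "1"]), 0)
  expect_equal(unname(C2["3", "3"]), 1)
})

test_that("DCC is invariant to permuting frames", {
  set.seed(3)
  topo <- generate_backbone(5)
  xyz <- matrix(rnorm(60 * 45), 60, 45)
  C1 <- dcc_matrix(trajectory(topo, xyz), fit = FALSE)
  C2 <- dcc_matrix(trajectory(topo, xyz[sample(60), ]), fit = FALSE)
  expect_equal(unclass(C1), unclass(C2), tolerance = 1e-12)
})

test_that("ranking uses absolute correlation with deterministic tie-breaks", {
  labels <- c(as.character(1:4), "ATP")
  C <- diag(5)
  C[1, 5] <- C[5, 1] <- -0.9
  C[2, 5] <- C[5, 2] <- 0.8
  C[3, 5] <- C[5, 3] <- 0.8
  C[4, 5] <- C[5, 4] <- 0.1
  dimnames(C) <- list(labels, labels)
  attr(C, "sites") <- data.frame(label = labels,
                                 type = c(rep("residue", 4), "ligand"),
                                 resno = c(1:4, NA))
  class(C) <- "cor_matrix"
  r <- rank_by_ligand(C, k = 3)
  expect_equal(r$residue, c(1, 2, 3))   # |-0.9| first; tie 2 vs 3 by resno
  expect_equal(rank_by_ligand(C, k = 99)$residue, 1:4)
})

test_that("tallying counts run membership and applies the 4-run rule", {
  lists <- c(lapply(1:3, function(i) c(10, 20)), lapply(1:7, function(i) c(20, 30)))
  names(lists) <- paste0("run", 1:10)
  t1 <- tally_runs(lists, min_runs = 4)
  expect_equal(t1$count[t1$residue == 10], 3)
  expect_false(t1$significant[t1$residue == 10])  # 3 of 10: below threshold
  expect_equal(t1$count[t1$residue == 20], 10)
  expect_true(t1$significant[t1$residue == 20])
  names(lists)[2] <- "run1"
  expect_error(tally_runs(lists), "duplicate")
  ## degenerate parameters mark everything significant
  full <- lapply(1:3, function(i) 1:50)
  t2 <- tally_runs(full, min_runs = 1, universe = 1:50)
  expect_true(all(t2$significant))
})

test_that("partner queries exclude the query and mirror constructed motion", {
  topo <- generate_backbone(3)
  v <- flat_xyz(topo)
  set.seed(4)
  xyz <- matrix(rep(v, each = 40), 40)
  ca <- select_atoms(topo, elety = "CA")
  d1 <- matrix(rnorm(120), 40, 3)
  xyz[, 3 * ca[1] - 2:0] <- xyz[, 3 * ca[1] - 2:0] + d1
  xyz[, 3 * ca[2] - 2:0] <- xyz[, 3 * ca[2] - 2:0] + d1
  xyz[, 3 * ca[3] - 2:0] <- xyz[, 3 * ca[3] - 2:0] +
    matrix(rnorm(120), 40, 3)
  C <- dcc_matrix(trajectory(topo, xyz), fit = FALSE)
  p <- partner_query(C, 1, k = 2)
  expect_false(1 %in% p$residue)
  expect_equal(p$residue[1], 2)
  expect_equal(p$C[1], 1, tolerance = 1e-10)
  expect_error(partner_query(C, 99), "not present")
})

test_that("hypergeometric enrichment equals the closed form", {
  ## reference set fully inside a top-60 list, universe 383
  p <- set_enrichment(1:60, c(5, 12, 23, 31, 44, 50, 55, 60), 383)
  expect_equal(p$overlap, 8)
  closed <- prod((60:53) / (383:376))   # C(60,8)/C(383,8)
  expect_equal(p$p_value, closed, tolerance = 1e-12)
  ## disjoint list and set: tail probability of >= 0 overlap is 1
  p0 <- set_enrichment(1:60, 100:107, 383)
  expect_equal(p0$overlap, 0)
  expect_equal(p0$p_value, 1)
  expect_error(set_enrichment(1:60, integer(0), 383), "empty")
  expect_identical(proline_switch_residues(),
                   c(70L, 71L, 143L, 144L, 145L, 146L, 151L, 171L))
})

test_that("distance to ligand uses strict 8 A nearness and exact minima", {
  s <- generate_backbone(10)
  lig <- data.frame(elety = c("PA", "PB"), element = "P", resno = c(900, 900),
                    resid = "ATP", chain = "A",
                    x = c(3, 100), y = c(0, 100), z = c(0, 100),
                    type = "HETATM")
  s$atoms <- rbind(s$atoms, lig)
  d <- distance_to_ligand(s, "ATP")
  ## brute-force oracle
  prot <- s$atoms[s$atoms$type == "ATOM", ]
  for (r in c(1, 5, 10)) {
    P <- as.matrix(prot[prot$resno == r, c("x", "y", "z")])
    L <- as.matrix(lig[, c("x", "y", "z")])
    mind <- min(sqrt(outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)))
    expect_equal(d$distance[d$resno == r], mind, tolerance = 1e-6)
  }
  ## strict inequality at exactly 8 A
  s2 <- generate_backbone(3)
  ca1 <- s2$atoms[s2$atoms$resno == 1 & s2$atoms$elety == "CA", c("x", "y", "z")]
  far <- s2$atoms
  ## place single-atom ligand exactly 8 A from the closest atom of residue 3
  a3 <- as.matrix(s2$atoms[s2$atoms$resno == 3, c("x", "y", "z")])
  probe <- a3[1, ] + c(8, 0, 0) * 1
  ## ensure probe is >= 8 from every atom: push along +x from the max-x atom
  mx <- which.max(a3[, 1])
  probe <- a3[mx, ] + c(8, 0, 0)
  s2$atoms <- rbind(s2$atoms, data.frame(elety = "X1", element = "X",
    resno = 901, resid = "PRB", chain = "A", x = probe[1], y = probe[2],
    z = probe[3], type = "HETATM"))
  d2 <- distance_to_ligand(s2, "PRB")
  expect_equal(min(d2$distance), 8, tolerance = 1e-9)
  expect_false(d2$near[which.min(d2$distance)])
  expect_error(distance_to_ligand(s2, "ZZZ"), "no atoms")
})
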