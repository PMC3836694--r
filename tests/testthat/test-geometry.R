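test_that("superposition recovers constructed rigid transforms", {
  set.seed(2)
  A <- matrix(rnorm(90), 30, 3)
  self <- superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$R, diag(3), tolerance = 1e-8)
  th <- pi / 2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- sweep(A %*% t(Rz), 2, c(5, 0, 0), "+")
  tr <- superpose(B, A)
  expect_lt(tr$rmsd, 1e-10)
  expect_equal(det(tr$R), 1, tolerance = 1e-10)
  ## applying the transform really maps B onto A
  fitted <- matrix(apply_transform <- hingescan:::apply_transform(
    as.vector(t(B)), tr), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(fitted - A)), 1e-9)
  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  L <- cbind(1:10, 2 * (1:10), -1 * (1:10))  # collinear
  expect_error(superpose(L, L), "collinear")
})

test_that("Kabsch fit matches bio3d and beats a quaternion-grid oracle", {
  set.seed(4)
  ref <- matrix(rnorm(383 * 3, sd = 8), 383, 3)
  mob <- ref + matrix(rnorm(383 * 3, 0, 0.1), 383, 3)
  mob <- sweep(mob %*% t(diag(3)), 2, c(1, -2, 0.5), "+")
  tr <- superpose(mob, ref)
  ## bio3d oracle
  fitted <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob)),
                           fixed.inds = 1:1149, mobile.inds = 1:1149)
  rmsd_bio3d <- sqrt(mean((fitted - as.vector(t(ref)))^2) * 3)
  expect_equal(tr$rmsd, rmsd_bio3d, tolerance = 1e-6)
  ## random-rotation grid search never beats the closed-form optimum by >10%
  cm <- colMeans(mob); cr <- colMeans(ref)
  Mc <- sweep(mob, 2, cm); Rc <- sweep(ref, 2, cr)
  set.seed(5)
  best <- Inf
  for (i in 1:400) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- rbind(
      c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
        2 * (q[2] * q[4] + q[3] * q[1])),
      c(2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
        2 * (q[3] * q[4] - q[2] * q[1])),
      c(2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
        1 - 2 * (q[2]^2 + q[3]^2)))
    best <- min(best, sqrt(mean(rowSums((Mc %*% R - Rc)^2))))
  }
  expect_lte(tr$rmsd, best * 1.0000001)
  expect_gt(best, tr$rmsd * 0.9)  # grid gets within 10% only from above
})

test_that("rmsd_series: zeros on identical frames, exact on a planted shift", {
  s <- generate_backbone(40)
  v <- flat_xyz(s)
  tr <- trajectory(s, rbind(v, v, v))
  expect_equal(rmsd_series(tr), rep(0, 3), tolerance = 1e-10)
  ## displace atoms of residues 31..40 by exactly 1 A in +x, fit on 1..20
  v2 <- v
  idx <- select_atoms(s, resno = 31:40)
  v2[3 * idx - 2] <- v2[3 * idx - 2] + 1
  tr2 <- trajectory(s, matrix(v2, nrow = 1))
  fit_sel <- select_atoms(s, resno = 1:20)
  out <- rmsd_series(tr2, v, fit_sel = fit_sel, report_sel = idx)
  expect_equal(out, 1.0, tolerance = 1e-9)
})

test_that("openness series is exact on constructions and invariant to rigid motion", {
  s <- generate_backbone(120)
  map <- scaled_subdomain_map(120)
  v <- flat_xyz(s)
  ## move II-B so the COM distance is exactly 27.3
  iib <- subdomain_residues(map, "II-B")
  rest <- subdomain_residues(map, c("I-A", "I-B", "II-A"))
  com <- function(vv, res) {
    idx <- select_atoms(s, resno = res, elety = "CA")
    colMeans(matrix(vv[as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))],
                    ncol = 3, byrow = TRUE))
  }
  d <- com(v, iib) - com(v, rest)
  u <- d / sqrt(sum(d^2))
  shift <- (27.3 - sqrt(sum(d^2))) * u
  idx <- select_atoms(s, resno = iib)
  v[3 * idx - 2] <- v[3 * idx - 2] + shift[1]
  v[3 * idx - 1] <- v[3 * idx - 1] + shift[2]
  v[3 * idx] <- v[3 * idx] + shift[3]
  tr <- trajectory(s, rbind(v, random_rigid(v, 1), random_rigid(v, 2)))
  o <- openness_series(tr, map)
  expect_equal(o$distance, rep(27.3, 3), tolerance = 1e-6)
  expect_equal(o$classification, "closed")
  ## same residues in both groups -> zero distance
  map0 <- make_subdomain_map(list("II-B" = list(c(10, 20))))
  expect_error(openness_series(tr, map0), "none of the reference groups")
})

test_that("openness classification reproduces the published state labels", {
  expect_equal(classify_openness(31.9), "open")
  expect_equal(classify_openness(27.3), "closed")
  expect_equal(classify_openness(26.1), "closed")
  expect_equal(classify_openness(29.5), "closed")   # boundary is closed
  expect_equal(classify_openness(29.5 + 1e-9), "open")
  ## monotone in its input
  x <- seq(20, 40, by = 0.5)
  lab <- classify_openness(x)
  expect_true(all(diff(lab == "open") >= 0))
  expect_error(classify_openness(-1), "positive")
})

test_that("helix axis: direction, equivariance, and inter-helical symmetry", {
  h <- hingescan:::ideal_helix_ca(19)   # 5 full turns: axis is clean
  s <- structure3d(data.frame(elety = "CA", element = "C", resno = 1:19,
                              resid = "ALA", chain = "A", x = h[, 1],
                              y = h[, 2], z = h[, 3]))
  ax <- helix_axis(s, c(1, 19))
  expect_lt(acos(abs(sum(ax * c(0, 0, 1)))) * 180 / pi, 2)
  expect_gt(ax[3], 0)                      # points N -> C
  expect_error(helix_axis(s, c(1, 3)), ">= 4")
  ## equivariance under a known rotation
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  h2 <- h %*% t(R)
  s2 <- s; s2$atoms$x <- h2[, 1]; s2$atoms$y <- h2[, 2]; s2$atoms$z <- h2[, 3]
  ax2 <- helix_axis(s2, c(1, 19))
  expect_lt(acos(pmin(1, abs(sum(ax2 * (R %*% ax))))) * 180 / pi, 1e-4)
  ## crossed-helix model: angle in the published 70-80 deg window, symmetric
  ch <- crossed_helices(75)
  ang <- interhelical_angle(ch, c(171, 179), c(367, 377))
  expect_gt(ang, 70); expect_lt(ang, 80)
  expect_equal(ang, interhelical_angle(ch, c(367, 377), c(171, 179)))
  expect_lte(ang, 90)
  expect_equal(interhelical_angle(ch, c(171, 179), c(171, 179)), 0,
               tolerance = 1e-9)
})

test_that("helix bend angle detects a constructed kink", {
  h <- hingescan:::ideal_helix_ca(37)   # halves of 5 full turns each
  s <- structure3d(data.frame(elety = "CA", element = "C", resno = 1:37,
                              resid = "ALA", chain = "A", x = h[, 1],
                              y = h[, 2], z = h[, 3]))
  straight <- helix_bend_angle(s, c(1, 37), 19)
  expect_lt(straight$angle, 5)
  expect_false(straight$bent)
  ## rotate the distal half by 40 deg about an axis through the pivot Ca,
  ## perpendicular to the helix axis (z)
  th <- 40 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  pivot <- h[19, ]
  h[20:37, ] <- sweep(sweep(h[20:37, ], 2, pivot) %*% t(R), 2, pivot, "+")
  s$atoms$x <- h[, 1]; s$atoms$y <- h[, 2]; s$atoms$z <- h[, 3]
  bent <- helix_bend_angle(s, c(1, 37), 19)
  expect_equal(bent$angle, 40, tolerance = 4)
  expect_true(bent$bent)
  expect_error(helix_bend_angle(s, c(1, 37), 3), "too close")
})
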