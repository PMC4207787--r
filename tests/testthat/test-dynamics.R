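# Kabsch superposition, RMSD, average structure, RMSF, B-factor conversion

test_that("superposition recovers rigid motions and rejects degenerate input", {
  set.seed(11)
  P <- matrix(rnorm(30, sd = 4), ncol = 3)
  # identity
  expect_lt(kabsch_superpose(P, P)$rmsd, 1e-12)
  # a named rigid motion: 37 degrees about z plus a translation
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- apply_rigid(P, Rz, c(5, -3, 2))
  sup <- kabsch_superpose(Q, P)
  expect_lte(sup$rmsd, 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
  # degenerate geometry
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "fewer than 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposed RMSD matches brute-force minimization over rotations", {
  # 4-point asymmetric sets; oracle: optimize Euler angles directly
  set.seed(21)
  for (trial in 1:5) {
    A <- matrix(rnorm(12, sd = 3), ncol = 3)
    B <- matrix(rnorm(12, sd = 3), ncol = 3)
    fit <- kabsch_superpose(B, A)$rmsd
    Ac <- sweep(A, 2, colMeans(A))
    Bc <- sweep(B, 2, colMeans(B))
    obj <- function(ang) {
      cx <- cos(ang[1]); sx <- sin(ang[1])
      cy <- cos(ang[2]); sy <- sin(ang[2])
      cz <- cos(ang[3]); sz <- sin(ang[3])
      Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
      Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
      Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
      sqrt(mean(rowSums((Bc %*% (Rx %*% Ry %*% Rz) - Ac)^2)))
    }
    starts <- rbind(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                    c(0, 0, pi / 2), c(pi, pi / 3, -pi / 3),
                    c(-pi / 2, pi, pi / 2))
    oracle <- min(apply(starts, 1, function(s0) {
      stats::optim(s0, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))$value
    }))
    expect_equal(fit, oracle, tolerance = 1e-6)
  }
})

test_that("rmsd follows the closed form and is a pseudometric", {
  # 8 fixed atoms, two displaced by 2 A: sqrt(2 * 4 / 10)
  A <- matrix(rnorm(30), ncol = 3)
  B <- A
  B[1, 1] <- A[1, 1] + 2
  B[2, 2] <- A[2, 2] + 2
  expect_equal(rmsd(A, B), sqrt(2 * 4 / 10), tolerance = 1e-12)
  expect_equal(rmsd(A, B), rmsd(B, A))
  expect_equal(rmsd(A, A), 0)
  expect_error(rmsd(A, B[1:5, ]), "atom count")
  # pseudometric on superposed frames: random triples obey the triangle
  # inequality
  set.seed(5)
  for (trial in 1:200) {
    X <- matrix(rnorm(24), ncol = 3)
    Y <- X + matrix(rnorm(24, sd = 0.5), ncol = 3)
    Z <- X + matrix(rnorm(24, sd = 0.5), ncol = 3)
    dxy <- rmsd(X, Y, superpose = TRUE)
    dyz <- rmsd(Y, Z, superpose = TRUE)
    dxz <- rmsd(X, Z, superpose = TRUE)
    expect_gte(dxy, 0)
    expect_lte(dxz, dxy + dyz + 1e-9)
    expect_equal(rmsd(X, Y, superpose = TRUE),
                 rmsd(Y, X, superpose = TRUE), tolerance = 1e-9)
  }
})

test_that("average structure handles symmetric, identical and noisy ensembles", {
  s <- toy_dimer(10)
  base <- get_coords(s)
  # two frames symmetric about a midpoint -> the midpoint
  set.seed(30)
  delta <- matrix(rnorm(length(base), sd = 0.05), ncol = 3)
  e <- new_ensemble(s, rbind(c(t(base + delta)), c(t(base - delta))))
  # the iterative mean sits at the midpoint up to the (small) rigid
  # component of the perturbation that the superposition redistributes
  mid_dev <- max(abs(get_coords(average_structure(e)) - base))
  expect_lt(mid_dev, 0.35 * max(abs(delta)))
  # identical frames -> that frame
  e2 <- new_ensemble(s, rbind(c(t(base)), c(t(base)), c(t(base))))
  avg2 <- average_structure(e2)
  expect_equal(get_coords(avg2), base, tolerance = 1e-9)
  expect_equal(avg2$label, "ave")
  # small perturbations: iterative mean close to the one-pass
  # fixed-reference mean
  set.seed(31)
  xyz <- t(vapply(1:5, function(i) {
    c(t(base + matrix(rnorm(length(base), sd = 0.1), ncol = 3)))
  }, numeric(length(base))))
  e3 <- new_ensemble(s, xyz)
  avg3 <- get_coords(average_structure(e3))
  ref <- get_coords(e3, 1)
  onepass <- Reduce(`+`, lapply(1:5, function(f) {
    fc <- get_coords(e3, f)
    apply_superposition(fc, kabsch_superpose(fc, ref))
  })) / 5
  expect_lt(max(abs(avg3 - onepass)), 0.05)
  expect_error(average_structure(new_ensemble(s, matrix(c(t(base)), 1))),
               "at least 2 frames")
})

test_that("rmsf recovers a planted oscillation and ignores global rotations", {
  s <- toy_dimer(12)  # 96 atoms hold the frame; atom 1 oscillates
  base <- get_coords(s)
  frames <- lapply(1:10, function(f) {
    fc <- base
    fc[1, 1] <- fc[1, 1] + ifelse(f %% 2 == 0, 1, -1)
    fc
  })
  e <- new_ensemble(s, t(vapply(frames, function(x) c(t(x)),
                                numeric(length(base)))))
  all_sel <- seq_len(nrow(base))
  prof <- rmsf(e, sel = all_sel, superpose_sel = all_sel)
  expect_equal(prof$rmsf[1], 1, tolerance = 0.05)
  expect_lt(max(prof$rmsf[-1]), 0.1)
  # a global rigid rotation of every frame changes nothing
  set.seed(41)
  R <- random_rotation()
  e_rot <- new_ensemble(s, t(vapply(frames, function(x) {
    c(t(apply_rigid(x, R, c(3, -2, 7))))
  }, numeric(length(base)))))
  prof_rot <- rmsf(e_rot, sel = all_sel, superpose_sel = all_sel)
  expect_equal(prof_rot$rmsf, prof$rmsf, tolerance = 1e-8)
  # rigid ensemble -> all-zero profile; single frame -> error
  e_rigid <- new_ensemble(s, rbind(c(t(base)), c(t(base))))
  expect_lt(max(rmsf(e_rigid, sel = all_sel)$rmsf), 1e-9)
  expect_error(rmsf(new_ensemble(s, matrix(c(t(base)), 1))), "single frame")
})

test_that("the B-factor conversion matches its closed form", {
  expect_equal(rmsf_to_bfactor(0), 0)
  expect_equal(rmsf_to_bfactor(1), 8 * pi^2 / 3)
  expect_equal(rmsf_to_bfactor(1), 26.3189, tolerance = 1e-4)
  expect_equal(rmsf_to_bfactor(0.5), 6.5797, tolerance = 1e-4)
  expect_error(rmsf_to_bfactor(-0.1), "nonnegative")
})

test_that("superposition agrees with the independent bio3d implementation", {
  skip_if_not_installed("bio3d")
  set.seed(51)
  A <- matrix(rnorm(45, sd = 3), ncol = 3)
  B <- A + matrix(rnorm(45, sd = 0.3), ncol = 3)
  ours <- kabsch_superpose(B, A)$rmsd
  theirs <- bio3d::rmsd(c(t(A)), c(t(B)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})
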