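# Toy potential, rigid/relaxed binding-energy protocols, candidate selection

test_that("the toy potential matches closed-form pair terms", {
  # two neutral atoms at the LJ minimum separation: energy is -epsilon
  r_min <- 2^(1 / 6) * 3.4
  e <- toy_energy(rbind(c(0, 0, 0), c(r_min, 0, 0)),
                  epsilon = 0.2, sigma = 3.4, charge = 0)
  expect_equal(e, -0.2, tolerance = 1e-12)
  # energy vanishes at large separation
  far <- toy_energy(rbind(c(0, 0, 0), c(5000, 0, 0)),
                    epsilon = 0.2, sigma = 3.4, charge = 0.5)
  expect_lt(abs(far), 1e-5)
  # three atoms against a hand-summed pairwise oracle
  coords <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(1.4, 2.9, 0))
  eps <- c(0.1, 0.2, 0.15); sig <- c(3.2, 3.4, 3.0); q <- c(0.3, -0.4, 0.1)
  pair_term <- function(i, j) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    e_ij <- sqrt(eps[i] * eps[j]); s_ij <- (sig[i] + sig[j]) / 2
    4 * e_ij * ((s_ij / r)^12 - (s_ij / r)^6) +
      332.06 * q[i] * q[j] / (4 * r^2)
  }
  expect_equal(toy_energy(coords, eps, sig, q),
               pair_term(1, 2) + pair_term(1, 3) + pair_term(2, 3),
               tolerance = 1e-10)
  expect_error(toy_energy(rbind(c(0, 0, 0), c(0, 0, 0)), 0.1, 3, 0),
               "singularity")
  # shipped parameter table is well-formed
  params <- toy_potential_params()
  expect_true(all(c("atom_class", "epsilon", "sigma", "charge") %in%
                    names(params)))
  expect_true(all(params$epsilon > 0))
})

test_that("the rigid protocol averages the last-window interaction energy", {
  mk <- function(e, role, source) energy_trajectory(e, role, source)
  n <- 25
  er <- -1000 + sin(1:n)
  el <- -50 + cos(1:n)
  # non-interacting: complex = receptor + ligand at every snapshot
  expect_equal(ddg_rigid(mk(er + el, "complex", "extracted-from-complex"),
                         mk(er, "receptor", "extracted-from-complex"),
                         mk(el, "ligand", "extracted-from-complex")), 0)
  # constant interaction of -25
  expect_equal(ddg_rigid(mk(er + el - 25, "complex", "extracted-from-complex"),
                         mk(er, "receptor", "extracted-from-complex"),
                         mk(el, "ligand", "extracted-from-complex")), -25)
  # varying interaction: equals the spreadsheet-style mean of the last 20
  set.seed(121)
  inter <- rnorm(n, -10)
  got <- ddg_rigid(mk(er + el + inter, "complex", "extracted-from-complex"),
                   mk(er, "receptor", "extracted-from-complex"),
                   mk(el, "ligand", "extracted-from-complex"))
  expect_equal(got, mean(inter[(n - 19):n]), tolerance = 1e-10)
  # guard rails: window, alignment, source tags
  short <- mk(rnorm(10), "complex", "extracted-from-complex")
  expect_error(ddg_rigid(short,
                         mk(rnorm(10), "receptor", "extracted-from-complex"),
                         mk(rnorm(10), "ligand", "extracted-from-complex")),
               "at least 20")
  expect_error(ddg_rigid(mk(er + el, "complex", "extracted-from-complex"),
                         mk(er[1:24], "receptor", "extracted-from-complex"),
                         mk(el, "ligand", "extracted-from-complex")),
               "aligned")
  expect_error(ddg_rigid(mk(er + el, "complex", "extracted-from-complex"),
                         mk(er, "receptor", "independent-run"),
                         mk(el, "ligand", "extracted-from-complex")),
               "source")
  # a shared constant added to complex and receptor streams cancels
  c0 <- 123.4
  expect_equal(
    ddg_rigid(mk(er + el - 25 + c0, "complex", "extracted-from-complex"),
              mk(er + c0, "receptor", "extracted-from-complex"),
              mk(el, "ligand", "extracted-from-complex")),
    -25, tolerance = 1e-9)
})

test_that("the relaxed protocol shifts by exactly the component relaxation", {
  mk <- function(e, role, source) energy_trajectory(e, role, source)
  n <- 30
  set.seed(131)
  er <- -900 + rnorm(n); el <- -40 + rnorm(n)
  ec <- er + el - 25 + rnorm(n, sd = 0.5)
  rigid <- ddg_rigid(mk(ec, "complex", "extracted-from-complex"),
                     mk(er, "receptor", "extracted-from-complex"),
                     mk(el, "ligand", "extracted-from-complex"))
  # independent runs numerically identical to the extracted ones
  same <- ddg_relaxed(mk(ec, "complex", "extracted-from-complex"),
                      mk(er, "receptor", "independent-run"),
                      mk(el, "ligand", "independent-run"))
  expect_equal(same, rigid, tolerance = 1e-10)
  # receptor relaxing by 5 makes the relaxed estimate 5 higher
  relaxed <- ddg_relaxed(mk(ec, "complex", "extracted-from-complex"),
                         mk(er - 5, "receptor", "independent-run"),
                         mk(el, "ligand", "independent-run"))
  expect_equal(relaxed - rigid, 5, tolerance = 1e-10)
})

test_that("noisy planted binding energies are recovered within sampling error", {
  spec <- synth_spec(seed = 17, ddg_noise = 2)
  tr <- make_energy_traj(spec, "CPDX", ddg_true = -25)
  est <- ddg_rigid(tr$complex, tr$receptor_ext, tr$ligand_ext)
  expect_lt(abs(est - (-25)), 3 * 2 / sqrt(20))
})

test_that("threshold selection uses OR semantics and matches a scan oracle", {
  res <- data.frame(id = c("a", "b", "c", "d"),
                    ddg_rigid = c(-25, -10, -21, -19.9),
                    ddg_relaxed = c(-10, -10, -30, -20))
  sel <- select_candidates(res, threshold = -20)
  expect_true("a" %in% sel$id)        # rigid qualifies alone
  expect_false("b" %in% sel$id)       # neither protocol qualifies
  expect_equal(sel$id[1], "c")        # sorted by the better energy
  expect_true("d" %in% sel$id)        # boundary counts as "better than"
  set.seed(141)
  res2 <- data.frame(id = sprintf("m%03d", 1:200),
                     ddg_rigid = runif(200, -40, 0),
                     ddg_relaxed = runif(200, -40, 0))
  got <- select_candidates(res2, threshold = -20)
  brute <- res2$id[res2$ddg_rigid <= -20 | res2$ddg_relaxed <= -20]
  expect_setequal(got$id, brute)
  expect_false(is.unsorted(got$ddg_best))
  # monotone: improving one compound's energy never removes it
  res3 <- res2
  res3$ddg_rigid[5] <- res3$ddg_rigid[5] - 30
  got3 <- select_candidates(res3, threshold = -20)
  expect_true(all(setdiff(got$id, got3$id) == res2$id[5]) ||
                all(got$id %in% got3$id))
  expect_true(res3$id[5] %in% got3$id)
  # truncation cap
  expect_lte(nrow(select_candidates(res2, threshold = -20, max_n = 5)), 5)
})
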