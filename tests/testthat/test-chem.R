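# Descriptors, drug-likeness filter, fingerprints, similarity clustering,
# liability flags

test_that("descriptors of reference molecules match hand-derived values", {
  d <- compute_descriptors(c("CCO", "c1ccccc1", "CCCCCCCC", "CC(=O)NCC"))
  # ethanol: 2C + 6H + O summed from standard atomic masses; one O-H donor
  expect_equal(d$mw[1], 46.07, tolerance = 0.01)
  expect_equal(d$hbd[1], 1)
  # ethanol tPSA is the single hydroxyl fragment contribution
  expect_equal(d$tpsa[1], 20.23, tolerance = 0.01)
  # benzene: no heteroatoms, rigid ring
  expect_equal(d$hbd[2], 0)
  expect_equal(d$hba[2], 0)
  expect_equal(d$rotb[2], 0)
  expect_equal(d$tpsa[2], 0)
  # octane: 5 internal acyclic single bonds
  expect_equal(d$rotb[3], 5)
  # N-ethyl acetamide: the amide C-N bond and terminal bonds are excluded,
  # leaving only N-CH2
  expect_equal(d$rotb[4], 1)
  expect_error(compute_descriptors("not-a-smiles((("), "unparseable")
})

test_that("descriptor computation is deterministic", {
  a <- compute_descriptors(c("CCO", "CC(=O)NCC", "c1ccncc1"))
  b <- compute_descriptors(c("CCO", "CC(=O)NCC", "c1ccncc1"))
  expect_identical(a, b)
})

test_that("the PPI filter applies strict open intervals and lists violations", {
  mid <- data.frame(id = "ok", mw = 350, tpsa = 80, logp = 2, hbd = 2,
                    hba = 5, rotb = 6)
  expect_true(ppi_druglike_filter(mid)$pass)
  heavy <- mid; heavy$mw <- 750
  r <- ppi_druglike_filter(heavy)
  expect_false(r$pass)
  expect_equal(r$violations, "mw")
  greasy <- mid; greasy$logp <- -5
  expect_false(ppi_druglike_filter(greasy)$pass)
  # bounds are exclusive exactly as stated
  edge <- mid; edge$mw <- 100
  expect_false(ppi_druglike_filter(edge)$pass)
  edge$mw <- 100.01
  expect_true(ppi_druglike_filter(edge)$pass)
  # a record with no donors fails the strict 0 < HBD bound
  nodonor <- mid; nodonor$hbd <- 0
  expect_false(ppi_druglike_filter(nodonor)$pass)
  expect_error(ppi_druglike_filter(mid[, -2]), "lack descriptor")
  multi <- mid; multi$mw <- 900; multi$rotb <- 20
  expect_equal(ppi_druglike_filter(multi)$violations, "mw,rotb")
})

test_that("filtering is idempotent", {
  spec <- synth_spec(seed = 9, library_size = 300)
  lib <- make_library(spec)
  once <- ppi_druglike_filter(lib)
  kept <- once[once$pass, setdiff(names(once), c("pass", "violations"))]
  twice <- ppi_druglike_filter(kept)
  expect_true(all(twice$pass))
  expect_identical(twice$id, kept$id)
})

test_that("fingerprints are deterministic and atom-order invariant", {
  f1 <- fingerprint(c("CCO", "c1ccccc1"), id = c("a", "b"))
  f2 <- fingerprint(c("CCO", "c1ccccc1"), id = c("a", "b"))
  expect_identical(f1, f2)
  # alternate spellings / kekulizations of the same molecules
  pairs <- list(c("CCO", "OCC"),
                c("c1ccccc1", "C1=CC=CC=C1"),
                c("CC(C)O", "OC(C)C"),
                c("CC(=O)NC1CCCCC1", "C1CCCCC1NC(C)=O"))
  for (p in pairs) {
    fp <- fingerprint(p, id = c("x", "y"))
    expect_identical(fp$x, fp$y)
  }
  # different molecules get different bitsets
  fp2 <- fingerprint(c("C", "CCCCCCCCCC"), id = c("methane", "decane"))
  expect_false(identical(fp2$methane, fp2$decane))
})

test_that("tanimoto matches brute-force bit arithmetic and its edge cases", {
  set.seed(61)
  nbits <- 128
  for (trial in 1:200) {
    a <- sort(sample.int(nbits, sample(0:40, 1)))
    b <- sort(sample.int(nbits, sample(0:40, 1)))
    va <- logical(nbits); va[a] <- TRUE
    vb <- logical(nbits); vb[b] <- TRUE
    expected <- if (!any(va) && !any(vb)) 1 else sum(va & vb) / sum(va | vb)
    expect_equal(tanimoto(a, b), expected)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
  }
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  x <- c(1L, 5L); attr(x, "nbits") <- 64
  y <- c(1L, 5L); attr(y, "nbits") <- 128
  expect_error(tanimoto(x, y), "lengths differ")
  # equal nonempty bitsets are exactly similarity 1, unequal are below
  expect_equal(tanimoto(c(2L, 9L), c(2L, 9L)), 1)
  expect_lt(tanimoto(c(2L, 9L), c(2L, 9L, 17L)), 1)
  expect_equal(tanimoto(1:5, 6:10), 0)
})

test_that("diversity clustering matches a quadratic reference implementation", {
  fps <- random_fps(100, seed = 71)
  got <- diversity_cluster(fps, max_distance = 0.3)
  # reference: same leader scheme, written independently and quadratically
  ids <- sort(names(fps), decreasing = TRUE)
  reps <- character(0)
  for (id in ids) {
    ok <- FALSE
    for (r in reps) {
      if (1 - tanimoto(fps[[id]], fps[[r]]) <= 0.3) { ok <- TRUE; break }
    }
    if (!ok) reps <- c(reps, id)
  }
  expect_setequal(got$representatives, reps)
  # representatives are pairwise farther than the threshold
  for (i in seq_along(got$representatives)) {
    for (j in seq_len(i - 1)) {
      d <- 1 - tanimoto(fps[[got$representatives[i]]],
                        fps[[got$representatives[j]]])
      expect_gt(d, 0.3)
    }
  }
  # every member sits within the sphere of its representative
  ok <- mapply(function(id, rep) {
    1 - tanimoto(fps[[id]], fps[[rep]]) <= 0.3
  }, got$assignment$id, got$assignment$representative)
  expect_true(all(ok))
  # degenerate cases
  same <- fps[c(1, 1, 1)]
  names(same) <- c("A1", "A2", "A3")
  expect_equal(length(diversity_cluster(same)$representatives), 1)
  expect_error(diversity_cluster(list()), "empty")
})

test_that("scaffold clustering equals brute-force connected components", {
  fps <- random_fps(40, nbits = 64, density = 0.25, seed = 81)
  got <- scaffold_cluster(fps, min_similarity = 0.6)
  # oracle: boolean transitive closure of the similarity graph
  n <- length(fps)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && tanimoto(fps[[i]], fps[[j]]) >= 0.6) adj[i, j] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- match(apply(adj, 1, function(r) paste(which(r), collapse = ",")),
                unique(apply(adj, 1, function(r)
                  paste(which(r), collapse = ","))))
  expect_equal(adjusted_rand(got$cluster, comp), 1)
  # chain linkage: a~b, b~c joined even when a and c are dissimilar
  chain <- list(a = c(1:10), b = c(3:12), c = c(5:14), d = c(50:60))
  for (i in seq_along(chain)) attr(chain[[i]], "nbits") <- 128
  attr(chain, "nbits") <- 128
  expect_gte(tanimoto(chain$a, chain$b), 0.6)
  expect_gte(tanimoto(chain$b, chain$c), 0.6)
  expect_lt(tanimoto(chain$a, chain$d), 0.6)
  cl <- scaffold_cluster(chain, min_similarity = 0.6)
  expect_equal(cl$cluster[1:3], rep(cl$cluster[1], 3))
  expect_false(cl$cluster[4] == cl$cluster[1])
})

test_that("every shipped liability rule flags its exemplar molecule", {
  exemplars <- c(acyl_halide = "CC(=O)Cl", aldehyde = "CC=O",
                 isocyanate = "CN=C=O", epoxide = "C1CO1",
                 michael_acceptor = "CC(=O)C=C", alkyl_bromide = "CCBr",
                 quinone = "O=C1C=CC(=O)C=C1",
                 catechol = "c1ccc(O)c(O)c1")
  rules <- liability_smarts()
  expect_setequal(rules$name, names(exemplars))
  flags <- liability_flags(unname(exemplars), id = names(exemplars))
  for (nm in names(exemplars)) {
    expect_true(grepl(nm, flags$flags[flags$id == nm]),
                label = paste("rule", nm, "matches its exemplar"))
  }
  clean <- liability_flags(c("CCO", "CCCC(N)C(=O)O"))
  expect_true(clean$clean[1])
})
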