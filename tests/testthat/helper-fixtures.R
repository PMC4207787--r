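# Shared fixtures: all built in code at test time.

# small helical dimer via the generator (deterministic geometry)
toy_dimer <- function(n_residues = 10) {
  make_toy_dimer(synth_spec(seed = 1, n_residues = n_residues))
}

# plain atom table -> Structure, filling bookkeeping columns
quick_structure <- function(x, y, z, element = "C", chain = "A",
                            name = NULL, resno = NULL, label = "fixture") {
  n <- length(x)
  if (is.null(name)) name <- sprintf("X%d", seq_len(n))
  if (is.null(resno)) resno <- seq_len(n)
  new_structure(data.frame(
    serial = seq_len(n), name = name, altloc = "", resname = "UNK",
    chain = chain, resno = resno, x = x, y = y, z = z,
    occ = 1, b = 0, element = rep_len(element, n), het = FALSE,
    stringsAsFactors = FALSE), label = label)
}

# hollow wall box enclosing an analytic cubic void of the given volume:
# single-layer atom walls with vdW surfaces at -0.25 and (side - 0.25) on
# every axis, so the void boundary falls mid-cell on both the 1.0 A and
# 0.5 A detection lattices
box_structure <- function(side = 10, element = "C", shift = c(0, 0, 0),
                          lateral = 0.85, radius = 1.7) {
  a <- -0.25 - radius          # atom plane below each low face
  b <- side - 0.25 + radius    # atom plane above each high face
  g <- seq(a, b, by = lateral)
  face <- expand.grid(u = g, v = g)
  pts <- rbind(
    cbind(a, face$u, face$v), cbind(b, face$u, face$v),
    cbind(face$u, a, face$v), cbind(face$u, b, face$v),
    cbind(face$u, face$v, a), cbind(face$u, face$v, b))
  pts <- unique(pts)
  pts <- sweep(pts, 2, shift, "+")
  quick_structure(pts[, 1], pts[, 2], pts[, 3], element = element,
                  label = "box")
}

# random sparse fingerprints (sorted on-bit sets) for similarity tests
random_fps <- function(n, nbits = 256, density = 0.12, ids = NULL,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fps <- lapply(seq_len(n), function(i) {
    sort(sample.int(nbits, max(1, rbinom(1, nbits, density))))
  })
  names(fps) <- if (is.null(ids)) sprintf("F%04d", seq_len(n)) else ids
  attr(fps, "nbits") <- nbits
  for (i in seq_along(fps)) attr(fps[[i]], "nbits") <- nbits
  fps
}

# adjusted Rand index from the contingency table (closed form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# independent Ward agglomerator: recomputes the Ward objective from the base
# distance matrix at every merge (no Lance-Williams update), heights on the
# ward.D2 scale
ward_oracle <- function(D) {
  n <- nrow(D)
  D2 <- D^2
  cl <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  idmap <- -seq_len(n)                 # hclust convention
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  wdist <- function(A, B) {
    nA <- length(A); nB <- length(B)
    ab <- mean(D2[A, B, drop = FALSE])
    aa <- if (nA > 1) sum(D2[A, A]) / (2 * nA^2) else 0
    bb <- if (nB > 1) sum(D2[B, B]) / (2 * nB^2) else 0
    sqrt(2 * nA * nB / (nA + nB) * (ab - aa - bb))
  }
  for (s in seq_len(n - 1)) {
    act <- which(active)
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(act)) for (jj in seq_len(ii - 1)) {
      i <- act[ii]; j <- act[jj]
      h <- wdist(cl[[i]], cl[[j]])
      if (h < bh) { bh <- h; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    merges[s, ] <- sort(c(idmap[i], idmap[j]))
    heights[s] <- bh
    cl[[i]] <- c(cl[[i]], cl[[j]])
    active[j] <- FALSE
    idmap[i] <- s
  }
  list(merge = merges, height = heights)
}

random_distance_matrix <- function(n, lo = 0.5, hi = 5) {
  M <- matrix(runif(n * n, lo, hi), n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

# rigid motion helpers
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(coords, R, t) sweep(coords %*% R, 2, t, "+")
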