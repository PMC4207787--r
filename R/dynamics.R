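# Superposition, RMSD/RMSF and B-factor conversion used to validate an
# ensemble before pocket analysis.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected mobile atoms onto the selected reference atoms (SVD solution,
#' with the determinant sign corrected so no reflection is introduced).
#' Row-vector convention: `x_new = x %*% rotation + translation`.
#'
#' @param mobile `Structure` or n x 3 coordinate matrix to move.
#' @param reference `Structure` or n x 3 coordinate matrix to match.
#' @param sel `AtomSelection` or index vector; NULL = all atoms. The same
#'   selection is applied to both inputs, which must have equal atom counts.
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom, over the selection after the
#'   transform).
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  M <- get_coords(mobile)
  R0 <- get_coords(reference)
  if (nrow(M) != nrow(R0))
    stop("mobile and reference atom counts differ (", nrow(M), " vs ",
         nrow(R0), ")")
  idx <- .sel_indices(sel, nrow(M))
  P <- M[idx, , drop = FALSE]
  Q <- R0[idx, , drop = FALSE]
  if (nrow(P) < 3) stop("degenerate geometry: fewer than 3 selected atoms")
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP)
  Qc <- sweep(Q, 2, cQ)
  sv_check <- svd(Pc, nu = 0, nv = 0)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1))
    stop("degenerate geometry: selected atoms are collinear")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  rot <- s$u %*% D %*% t(s$v)
  trans <- cQ - drop(cP %*% rot)
  moved <- Pc %*% rot
  rmsd_val <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd_val),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param coords `Structure` or n x 3 matrix.
#' @param sup result of [kabsch_superpose()].
#' @return transformed n x 3 matrix (or `Structure` if one was given).
#' @export
apply_superposition <- function(coords, sup) {
  stopifnot(inherits(sup, "superposition"))
  if (inherits(coords, "Structure"))
    return(set_coords(coords, apply_superposition(get_coords(coords), sup)))
  sweep(coords %*% sup$rotation, 2, sup$translation, "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b `Structure`s or n x 3 matrices with matched atom ordering.
#' @param sel selection over which the deviation is measured.
#' @param superpose if TRUE, `b` is first superposed onto `a` over `sel`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, sel = NULL, superpose = FALSE) {
  A <- get_coords(a)
  B <- get_coords(b)
  if (nrow(A) != nrow(B))
    stop("coordinate sets differ in atom count (", nrow(A), " vs ",
         nrow(B), ")")
  idx <- .sel_indices(sel, nrow(A))
  if (superpose) {
    sup <- kabsch_superpose(B, A, sel = idx)
    return(sup$rmsd)
  }
  sqrt(mean(rowSums((A[idx, , drop = FALSE] - B[idx, , drop = FALSE])^2)))
}

#' Iteratively superposed average structure of an ensemble
#'
#' Every frame is superposed onto a running reference (initially the first
#' frame) over `sel`, the per-atom mean is taken, and the procedure repeats
#' with the mean as the new reference until the mean moves by at most `tol`
#' or `max_iter` iterations are reached. No energy minimization is applied
#' to the mean; it is a plain geometric average.
#'
#' @param e an `Ensemble` with at least 2 frames.
#' @param sel superposition selection (NULL = all atoms).
#' @param tol convergence tolerance on the maximum coordinate change (A).
#' @param max_iter iteration cap.
#' @return a `Structure` labelled `"ave"`.
#' @export
average_structure <- function(e, sel = NULL, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(e, "Ensemble"))
  nf <- n_frames(e)
  if (nf < 2) stop("average structure needs at least 2 frames")
  idx <- .sel_indices(sel, n_atoms(e))
  ref <- get_coords(e, 1)
  for (iter in seq_len(max_iter)) {
    acc <- matrix(0, nrow(ref), 3)
    for (f in seq_len(nf)) {
      fc <- get_coords(e, f)
      sup <- kabsch_superpose(fc, ref, sel = idx)
      acc <- acc + apply_superposition(fc, sup)
    }
    mean_coords <- acc / nf
    delta <- max(abs(mean_coords - ref))
    ref <- mean_coords
    if (delta <= tol) break
  }
  out <- set_coords(e$topology, ref)
  out$label <- "ave"
  out
}

#' Per-atom root-mean-square fluctuation of an ensemble
#'
#' Frames are superposed onto the iteratively averaged structure over
#' `superpose_sel`; the fluctuation of each selected atom is the square root
#' of its time-mean squared deviation from its time-mean position. Because
#' every frame is superposed first, a global rigid motion applied to all
#' frames leaves the profile unchanged.
#'
#' @param e an `Ensemble` with at least 2 frames.
#' @param sel atoms to profile; default: the C-alpha trace.
#' @param superpose_sel superposition selection; default: same as `sel`.
#' @return a `FluctuationProfile` data.frame with columns `index`, `chain`,
#'   `resno`, `name`, `rmsf` (A) and `bfactor` (A^2, `8*pi^2/3 * rmsf^2`).
#' @export
rmsf <- function(e, sel = NULL, superpose_sel = NULL) {
  stopifnot(inherits(e, "Ensemble"))
  if (n_frames(e) < 2)
    stop("fluctuations are undefined for a single frame")
  if (is.null(sel)) sel <- select_atoms(e$topology, atoms = "CA")
  idx <- .sel_indices(sel, n_atoms(e))
  sup_idx <- if (is.null(superpose_sel)) idx
  else .sel_indices(superpose_sel, n_atoms(e))
  avg <- get_coords(average_structure(e, sel = sup_idx))
  nf <- n_frames(e)
  stack <- array(0, dim = c(length(idx), 3, nf))
  for (f in seq_len(nf)) {
    fc <- get_coords(e, f)
    sup <- kabsch_superpose(fc, avg, sel = sup_idx)
    stack[, , f] <- apply_superposition(fc, sup)[idx, , drop = FALSE]
  }
  mean_pos <- apply(stack, c(1, 2), mean)
  sqdev <- vapply(seq_len(nf), function(f) {
    rowSums((stack[, , f] - mean_pos)^2)
  }, numeric(length(idx)))
  vals <- sqrt(rowMeans(matrix(sqdev, nrow = length(idx))))
  a <- e$topology$atoms[idx, ]
  out <- data.frame(index = idx, chain = a$chain, resno = a$resno,
                    name = a$name, rmsf = vals,
                    bfactor = rmsf_to_bfactor(vals))
  class(out) <- c("FluctuationProfile", "data.frame")
  out
}

#' Convert an RMSF to a crystallographic pseudo B-factor
#'
#' Uses the isotropic harmonic relation `B = (8 * pi^2 / 3) * rmsf^2`,
#' mapping Angstrom fluctuations to Angstrom^2 temperature factors.
#'
#' @param rmsf nonnegative fluctuation(s), Angstrom.
#' @return B-factor(s), Angstrom^2.
#' @export
rmsf_to_bfactor <- function(rmsf) {
  if (any(rmsf < 0)) stop("rmsf must be nonnegative")
  (8 * pi^2 / 3) * rmsf^2
}
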