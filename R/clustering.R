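# Binding-site conformation clustering: all-atom pocket RMSD matrix over the
# snapshots, Ward agglomeration, medoid extraction, population density.

#' Pairwise superposed-RMSD matrix over an ensemble
#'
#' Entry (i, j) is the RMSD of the measurement selection after superposing
#' frame j onto frame i over the superposition selection (upper triangle
#' computed, mirrored to keep the matrix exactly symmetric). By default both
#' selections are the binding-site selection itself; pass a global backbone
#' selection as `superpose_sel` for a frame alignment that is independent of
#' the pocket atoms.
#'
#' @param e an `Ensemble` with at least 2 frames.
#' @param sel `AtomSelection` measured by the RMSD (e.g. all atoms of the
#'   binding-site residues).
#' @param superpose_sel selection used for the Kabsch fit; default `sel`.
#' @return symmetric n x n matrix of distances in Angstrom, zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(e, sel, superpose_sel = sel) {
  stopifnot(inherits(e, "Ensemble"))
  nf <- n_frames(e)
  if (nf < 2) stop("pairwise matrix needs at least 2 frames")
  idx <- .sel_indices(sel, n_atoms(e))
  sup_idx <- .sel_indices(superpose_sel, n_atoms(e))
  if (length(sup_idx) < 3)
    stop("superposition selection needs at least 3 atoms")
  sup <- array(0, dim = c(length(sup_idx), 3, nf))
  mea <- array(0, dim = c(length(idx), 3, nf))
  for (f in seq_len(nf)) {
    fc <- get_coords(e, f)
    sup[, , f] <- fc[sup_idx, , drop = FALSE]
    mea[, , f] <- fc[idx, , drop = FALSE]
  }
  m <- pairwise_rmsd_cpp(sup, mea)
  dimnames(m) <- NULL
  m
}

.validate_dmatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (!all(is.finite(m))) stop("distance matrix has non-finite entries")
  if (any(m < 0)) stop("distance matrix has negative entries")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-8)) stop("distance matrix diagonal is not zero")
  invisible(m)
}

#' Ward hierarchical agglomeration of a distance matrix
#'
#' Agglomerative (bottom-up) clustering with the Ward criterion in its
#' `ward.D2` form: the Lance-Williams recurrence is applied to squared
#' distances and merge heights are reported back on the distance scale
#' (Angstrom for an RMSD matrix). Clusters are the connected groups below
#' the cut height; the number of clusters is emergent, not fixed, unless
#' `k` is given. Heights are checked for monotonicity; inversions (possible
#' on non-metric input) are reported as a warning.
#'
#' @param m symmetric distance matrix (e.g. from [pairwise_rmsd_matrix()]).
#' @param cut_height dendrogram cut, same units as `m` (default 1.3 A).
#' @param k optional fixed cluster count overriding the height cut.
#' @param method `"ward.D2"` (default, textbook Ward objective) or
#'   `"ward.D"`.
#' @return object of class `Clustering`: `labels` (per-frame cluster id,
#'   numbered by decreasing cluster size), `merge_tree` (data.frame `i`,
#'   `j`, `height` in hclust convention), `medoids` (named per-cluster frame
#'   index), `sizes`, and the underlying `hclust` object.
#' @export
ward_hac <- function(m, cut_height = 1.3, k = NULL,
                     method = c("ward.D2", "ward.D")) {
  .validate_dmatrix(m)
  method <- match.arg(method)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 frames to cluster")
  if (is.null(k) && cut_height <= 0) stop("cut_height must be positive")
  hc <- stats::hclust(stats::as.dist(m), method = method)
  if (any(diff(hc$height) < -1e-8))
    warning("non-monotone merge heights (inversion): input is not metric")
  raw <- if (is.null(k)) stats::cutree(hc, h = cut_height)
  else stats::cutree(hc, k = k)
  # relabel clusters by decreasing size (ties: first appearance)
  tab <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(tab), names(tab))
  labels <- as.integer(remap[as.character(raw)])
  medoids <- vapply(seq_along(tab), function(cl) {
    members <- which(labels == cl)
    .medoid_of(m, members)
  }, integer(1))
  out <- list(labels = labels,
              merge_tree = data.frame(i = hc$merge[, 1], j = hc$merge[, 2],
                                      height = hc$height),
              medoids = medoids,
              sizes = as.integer(tab),
              cut_height = if (is.null(k)) cut_height else NA_real_,
              method = method,
              hclust = hc)
  class(out) <- "Clustering"
  out
}

#' @export
print.Clustering <- function(x, ...) {
  cat("<Clustering>", length(x$sizes), "clusters over", length(x$labels),
      "frames (", x$method,
      if (!is.na(x$cut_height)) paste0(", cut ", x$cut_height, " A"), ")\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  medoid frames:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

.medoid_of <- function(m, members) {
  if (length(members) == 1) return(members)
  sub <- m[members, members, drop = FALSE]
  means <- rowMeans(sub)
  members[which.min(means)]  # which.min takes the first (lowest index) on ties
}

#' Medoid (centroid structure) of a cluster
#'
#' The cluster member minimizing the mean distance to all other members: an
#' actual ensemble frame, directly usable for docking, rather than an
#' averaged geometry. Ties resolve to the lowest frame index.
#'
#' @param clustering a `Clustering` from [ward_hac()].
#' @param m the distance matrix the clustering was built from.
#' @param cluster_id cluster label.
#' @return frame index of the medoid.
#' @export
medoid <- function(clustering, m, cluster_id) {
  stopifnot(inherits(clustering, "Clustering"))
  members <- which(clustering$labels == cluster_id)
  if (length(members) == 0) stop("unknown cluster id: ", cluster_id)
  .medoid_of(m, members)
}

#' Population density around a frame
#'
#' Number of frames (excluding the center itself) within `radius` of the
#' given frame, per the distance matrix. Used to report how representative a
#' selected conformation is of the whole ensemble.
#'
#' @param m distance matrix.
#' @param center frame index.
#' @param radius inclusion radius, same units as `m` (default 1.5 A);
#'   radius 0 counts exact duplicates only.
#' @return integer count.
#' @export
population_density <- function(m, center, radius = 1.5) {
  .validate_dmatrix(m)
  if (center < 1 || center > nrow(m)) stop("invalid center frame index")
  if (radius < 0) stop("radius must be nonnegative")
  sum(m[center, -center] <= radius)
}
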