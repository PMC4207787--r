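# Grid-probe cavity detection and druggability descriptors. A transparent
# geometric score stands in for SVM-based webserver scores: same [0,1] range
# and triage role, but no numerical equivalence is claimed.

.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

.vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# mark cells whose center lies within radii[i] of centers[i, ]
.mark_spheres <- function(mask, dims, origin, spacing, centers, radii) {
  nx <- dims[1]; ny <- dims[2]
  for (a in seq_len(nrow(centers))) {
    r <- radii[a]; cc <- centers[a, ]
    lo <- pmax(1, floor((cc - r - origin) / spacing) + 1)
    hi <- pmin(dims, ceiling((cc + r - origin) / spacing) + 1)
    if (any(lo > hi)) next
    ax <- lo[1]:hi[1]; ay <- lo[2]:hi[2]; az <- lo[3]:hi[3]
    dx2 <- (origin[1] + (ax - 1) * spacing - cc[1])^2
    dy2 <- (origin[2] + (ay - 1) * spacing - cc[2])^2
    dz2 <- (origin[3] + (az - 1) * spacing - cc[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sel <- which(d2 <= r^2)
    if (length(sel) == 0) next
    lin <- rep(ax, times = length(ay) * length(az)) +
      nx * (rep(rep(ay - 1L, each = length(ax)), times = length(az)) +
              ny * rep(az - 1L, each = length(ax) * length(ay)))
    mask[lin[sel]] <- TRUE
  }
  mask
}

.cell_centers <- function(lin, dims, origin, spacing) {
  nx <- dims[1]; ny <- dims[2]
  ix <- (lin - 1L) %% nx
  iy <- ((lin - 1L) %/% nx) %% ny
  iz <- (lin - 1L) %/% (nx * ny)
  cbind(origin[1] + ix * spacing,
        origin[2] + iy * spacing,
        origin[3] + iz * spacing)
}

# min distance from each of a small set of points to a (possibly large) set
# of reference points, chunked to bound memory
.min_dist_to <- function(points, refs, chunk = 512L) {
  out <- rep(Inf, nrow(points))
  for (start in seq(1, nrow(points), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(points))
    p <- points[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(refs^2), "+") - 2 * p %*% t(refs)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Detect candidate cavities on a structure with a grid probe
#'
#' The structure is embedded in a cubic lattice. Cells inside the van der
#' Waals volume of any heavy atom are protein; remaining cells within
#' `max_surface_dist` of the vdW surface are cavity candidates. A candidate
#' is buried when at least `burial_threshold` of 26 lattice scan directions
#' hit a protein cell. Buried cells are grouped into pockets by face
#' adjacency; components smaller than `min_volume` are discarded and the
#' rest are returned sorted by volume (descending). The grid origin is
#' snapped to the lattice so translating a structure by a multiple of the
#' spacing reproduces the same pockets exactly.
#'
#' @param s a `Structure`.
#' @param spacing grid spacing in Angstrom, within `[0.5, 1.5]`.
#' @param burial_threshold minimum number of blocked directions (of 26) for
#'   a cell to count as buried.
#' @param probe_radius solvent probe radius (A), used for the grid margin.
#' @param max_surface_dist maximum distance (A) from a cavity cell center to
#'   the vdW surface; bounds how far from the protein a pocket may extend.
#' @param min_volume smallest reported pocket volume, Angstrom^3.
#' @param include_het include HETATM atoms in the protein volume.
#' @param descriptors compute surface/lipophilicity/lining/druggability for
#'   each pocket (see [pocket_descriptors()]).
#' @return list of `Pocket` objects, largest first.
#' @export
detect_pockets <- function(s, spacing = 1.0, burial_threshold = 18,
                           probe_radius = 1.4, max_surface_dist = 4.5,
                           min_volume = 30, include_het = FALSE,
                           descriptors = TRUE) {
  stopifnot(inherits(s, "Structure"))
  if (spacing < 0.5 || spacing > 1.5)
    stop("spacing must lie in [0.5, 1.5] Angstrom")
  a <- s$atoms
  keep <- a$element != "H"
  if (!include_het) keep <- keep & !a$het
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure: no heavy atoms")
  centers <- as.matrix(a[, c("x", "y", "z")])
  radii <- .vdw_radius(a$element)
  margin <- max_surface_dist + 2 * probe_radius + 2 * spacing
  lo <- apply(centers, 2, min) - margin
  hi <- apply(centers, 2, max) + margin
  origin <- floor(lo / spacing) * spacing
  dims <- as.integer(ceiling((hi - origin) / spacing) + 1)
  ncell <- prod(dims)
  protein <- logical(ncell)
  protein <- .mark_spheres(protein, dims, origin, spacing, centers, radii)
  near <- logical(ncell)
  near <- .mark_spheres(near, dims, origin, spacing, centers,
                        radii + max_surface_dist)
  counts <- burial_count_cpp(protein, dims)
  cavity <- which(near & !protein & counts >= burial_threshold)
  grid <- list(origin = origin, dims = dims, spacing = spacing,
               protein = protein, counts = counts,
               burial_threshold = burial_threshold,
               atoms = a, atom_centers = centers)
  if (length(cavity) == 0) return(list())
  comp <- .grid_components(cavity, dims)
  pockets <- lapply(split(cavity, comp), function(cells) {
    structure(list(cells = cells,
                   cell_centers = .cell_centers(cells, dims, origin, spacing),
                   spacing = spacing,
                   volume = length(cells) * spacing^3,
                   grid = grid),
              class = "Pocket")
  })
  vols <- vapply(pockets, function(p) p$volume, numeric(1))
  pockets <- pockets[vols >= min_volume]
  pockets <- pockets[order(-vapply(pockets, function(p) p$volume,
                                   numeric(1)))]
  names(pockets) <- sprintf("P%d", seq_along(pockets) - 1L)
  if (descriptors)
    pockets <- lapply(pockets, pocket_descriptors, s = s)
  pockets
}

# face-adjacency connected components over linear cell indices
.grid_components <- function(cells, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ix <- (cells - 1L) %% nx
  iy <- ((cells - 1L) %/% nx) %% ny
  iz <- (cells - 1L) %/% (nx * ny)
  edges <- NULL
  for (d in list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))) {
    ok <- (ix + d[1] < nx) & (iy + d[2] < ny) & (iz + d[3] < nz)
    nb <- cells + d[1] + nx * (d[2] + ny * d[3])
    pos <- match(nb, cells)
    good <- ok & !is.na(pos)
    if (any(good))
      edges <- rbind(edges, cbind(which(good), pos[good]))
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' Compute descriptors of a detected pocket
#'
#' Surface is the total area of cavity-cell faces not shared with another
#' cell of the same pocket; the lipophilic part is the area of faces whose
#' nearest protein atom is an apolar carbon or sulfur (no N/O within the
#' 1.9 A bond-inference distance). Lining residues are those with any atom
#' within 4.0 A of a cavity cell center. Depth is the largest grid-path
#' distance from a pocket cell to unburied (bulk) space, capped at 10 A
#' (fully enclosed voids take the cap). Finally a druggability score is
#' attached via [druggability_score()].
#'
#' @param p a `Pocket` produced by [detect_pockets()].
#' @param s the `Structure` the pocket was detected on.
#' @param lining_dist lining-residue distance cutoff, A.
#' @param bond_dist distance below which two heavy atoms count as bonded, A.
#' @param depth_cap depth saturation, A.
#' @return the `Pocket`, updated with `surface`, `lipo_surface`,
#'   `lining_residues`, `depth` and `druggability`.
#' @export
pocket_descriptors <- function(p, s, lining_dist = 4.0, bond_dist = 1.9,
                               depth_cap = 10) {
  stopifnot(inherits(p, "Pocket"))
  grid <- p$grid
  if (is.null(grid))
    stop("pocket lacks grid context; produce it with detect_pockets()")
  dims <- grid$dims; nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  spacing <- p$spacing
  cells <- p$cells
  ix <- (cells - 1L) %% nx
  iy <- ((cells - 1L) %/% nx) %% ny
  iz <- (cells - 1L) %/% (nx * ny)
  in_pocket <- logical(prod(dims)); in_pocket[cells] <- TRUE
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  face_centers <- NULL
  for (d in seq_len(6)) {
    dd <- dirs[d, ]
    jx <- ix + dd[1]; jy <- iy + dd[2]; jz <- iz + dd[3]
    inside <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
    nb <- cells + dd[1] + nx * (dd[2] + ny * dd[3])
    exposed <- !inside | !in_pocket[pmax(nb, 1L)]
    if (any(exposed)) {
      fc <- p$cell_centers[exposed, , drop = FALSE]
      fc <- sweep(fc, 2, dd * spacing / 2, "+")
      face_centers <- rbind(face_centers, fc)
    }
  }
  n_faces <- nrow(face_centers)
  p$surface <- n_faces * spacing^2
  # apolar atoms: C or S with no N/O neighbour within bond distance
  atoms <- grid$atoms
  ac <- grid$atom_centers
  is_no <- atoms$element %in% c("N", "O")
  apolar <- atoms$element %in% c("C", "S")
  if (any(apolar) && any(is_no)) {
    no_dist <- .min_dist_to(ac[apolar, , drop = FALSE],
                            ac[is_no, , drop = FALSE])
    apolar[apolar] <- no_dist > bond_dist
  }
  # nearest protein atom per exposed face
  if (n_faces > 0) {
    nearest <- integer(n_faces)
    for (start in seq(1, n_faces, by = 512L)) {
      idx <- start:min(start + 511L, n_faces)
      f <- face_centers[idx, , drop = FALSE]
      d2 <- outer(rowSums(f^2), rowSums(ac^2), "+") - 2 * f %*% t(ac)
      nearest[idx] <- apply(d2, 1, which.min)
    }
    p$lipo_surface <- sum(apolar[nearest]) * spacing^2
  } else {
    p$lipo_surface <- 0
  }
  # lining residues
  atom_min <- .min_dist_to(ac, p$cell_centers)
  lining <- atoms[atom_min <= lining_dist, c("chain", "resno")]
  p$lining_residues <- unique(lining)
  rownames(p$lining_residues) <- NULL
  # depth: BFS steps from bulk (unburied, non-protein) space
  open <- !grid$protein & grid$counts < grid$burial_threshold
  steps <- grid_depth_cpp(grid$protein, open, dims)
  d <- steps[cells] * spacing
  d[steps[cells] < 0] <- depth_cap  # enclosed void: unreachable from bulk
  p$depth <- min(max(d), depth_cap)
  p$druggability <- druggability_score(p)
  p
}

#' Geometric druggability score of a pocket
#'
#' A transparent logistic combination of normalized descriptors:
#' `plogis(w0 + w1 * min(volume, 1500)/1500 + w2 * lipo_surface/surface +
#' w3 * depth/10)`. The score is monotone increasing in each descriptor and
#' always lies in (0, 1). Default weights place a large, deep, lipophilic
#' pocket above 0.8 and a small shallow surface dimple below 0.3; the
#' weights are a package default, not a reproduction of any trained model.
#'
#' @param p a `Pocket` with descriptors computed.
#' @param weights numeric length 4: intercept, volume, lipophilicity and
#'   depth weights.
#' @return druggability score in (0, 1).
#' @export
druggability_score <- function(p, weights = c(-6, 4, 3, 4)) {
  stopifnot(inherits(p, "Pocket"), length(weights) == 4)
  if (is.null(p$surface) || is.null(p$depth))
    stop("descriptors not computed; call pocket_descriptors() first")
  if (p$surface <= 0) stop("pocket has zero surface")
  x <- weights[1] +
    weights[2] * min(p$volume, 1500) / 1500 +
    weights[3] * p$lipo_surface / p$surface +
    weights[4] * p$depth / 10
  stats::plogis(x)
}

#' Filter pockets by proximity to a target residue
#'
#' Keeps pockets whose minimum cavity-cell distance to any atom of the
#' given residue is at most `max_dist`, annotating each with that distance
#' (`site_distance`), and optionally applies a druggability floor. This is
#' the triage step that keeps pockets close to the destabilizing mutation
#' site.
#'
#' @param pockets list of `Pocket` objects.
#' @param s the `Structure` they were detected on.
#' @param chain,res_seq residue identity (native numbering).
#' @param max_dist maximum pocket-to-residue distance, A.
#' @param min_score optional druggability floor (e.g. 0.80).
#' @return filtered, annotated list of `Pocket`s.
#' @export
pockets_near_residue <- function(pockets, s, chain, res_seq, max_dist = 10,
                                 min_score = NULL) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  ratoms <- a[a$chain == chain & a$resno == res_seq & a$element != "H", ,
              drop = FALSE]
  if (nrow(ratoms) == 0)
    stop("residue ", chain, ":", res_seq, " not present in structure")
  rc <- as.matrix(ratoms[, c("x", "y", "z")])
  out <- list()
  for (nm in names(pockets)) {
    p <- pockets[[nm]]
    d <- min(.min_dist_to(rc, p$cell_centers))
    if (d <= max_dist &&
        (is.null(min_score) || (!is.null(p$druggability) &&
                                p$druggability > min_score))) {
      p$site_distance <- d
      out[[nm]] <- p
    }
  }
  out
}

#' Tabulate pocket descriptors
#' @param pockets list of `Pocket`s.
#' @return data.frame with one row per pocket: volume (A^3), surface (A^2),
#'   lipophilic surface (A^2), depth (A), druggability, lining residue count.
#' @export
pocket_table <- function(pockets) {
  if (length(pockets) == 0)
    return(data.frame(pocket = character(), volume = numeric(),
                      surface = numeric(), lipo_surface = numeric(),
                      depth = numeric(), druggability = numeric(),
                      n_lining = integer()))
  data.frame(
    pocket = names(pockets),
    volume = vapply(pockets, function(p) p$volume, numeric(1)),
    surface = vapply(pockets, function(p) p$surface %||% NA_real_,
                     numeric(1)),
    lipo_surface = vapply(pockets, function(p) p$lipo_surface %||% NA_real_,
                          numeric(1)),
    depth = vapply(pockets, function(p) p$depth %||% NA_real_, numeric(1)),
    druggability = vapply(pockets, function(p) p$druggability %||% NA_real_,
                          numeric(1)),
    n_lining = vapply(pockets, function(p) {
      if (is.null(p$lining_residues)) NA_integer_
      else nrow(p$lining_residues)
    }, integer(1)),
    row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.Pocket <- function(x, ...) {
  cat(sprintf("<Pocket> volume %.1f A^3", x$volume))
  if (!is.null(x$surface))
    cat(sprintf(", surface %.1f A^2 (lipophilic %.1f), depth %.1f A, score %.2f",
                x$surface, x$lipo_surface, x$depth, x$druggability))
  cat("\n")
  invisible(x)
}
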