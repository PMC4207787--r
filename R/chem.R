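# Physicochemical descriptors, PPI-adapted drug-likeness filtering, circular
# fingerprints, Tanimoto similarity, diversity/scaffold clustering and
# substructure liability flags.
#
# Descriptor values (MW, Crippen-type logP, Ertl-type tPSA, donor/acceptor
# counts) come from the OpenBabel backend behind ChemmineR; the rotatable
# bond count and the fingerprint are computed in-package on the bond graph.

.smiles_to_sdf <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("mol%03d", seq_along(smiles))
  # a bondless (single heavy atom) molecule does not survive the SDF round
  # trip; give it one explicit hydrogen, which .mol_graph() strips again
  bare <- grepl("^\\[?[A-Za-z][a-z]?[0-9+-]*\\]?$", trimws(smiles))
  smiles <- ifelse(bare, paste0(trimws(smiles), "[H]"), smiles)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
    error = function(e) {
      # locate the offender for a useful message
      for (i in seq_along(smiles)) {
        ok <- tryCatch({
          suppressWarnings(ChemmineR::smiles2sdf(
            stats::setNames(smiles[i], ids[i])))
          TRUE
        }, error = function(e2) FALSE)
        if (!ok)
          stop("unparseable SMILES: '", smiles[i], "' (entry ", i, ")",
               call. = FALSE)
      }
      stop("SMILES parsing failed: ", conditionMessage(e), call. = FALSE)
    })
  sizes <- vapply(ChemmineR::cid(sdf), function(i) {
    nrow(ChemmineR::atomblock(sdf[[i]]))
  }, integer(1))
  if (any(sizes == 0))
    stop("unparseable SMILES: '", smiles[which(sizes == 0)[1]], "' (entry ",
         which(sizes == 0)[1], ")")
  sdf
}

# heavy-atom bond graph of one molecule: elements + bonds (a1, a2, order);
# explicit hydrogens are stripped (implicit counts are derived from valence)
.mol_graph <- function(sdfmol) {
  ab <- ChemmineR::atomblock(sdfmol)
  bb <- ChemmineR::bondblock(sdfmol)
  element <- toupper(gsub("_.*$", "", rownames(ab)))
  bonds <- if (length(bb) > 0 && nrow(bb) > 0 && ncol(bb) >= 3)
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  else data.frame(a1 = integer(), a2 = integer(), order = integer())
  heavy <- element != "H"
  if (!all(heavy)) {
    remap <- cumsum(heavy)
    keep <- heavy[bonds$a1] & heavy[bonds$a2]
    bonds <- bonds[keep, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]
    bonds$a2 <- remap[bonds$a2]
    element <- element[heavy]
  }
  rownames(bonds) <- NULL
  list(element = element, bonds = bonds, n = length(element))
}

.graph_degree <- function(g) {
  deg <- integer(g$n)
  if (nrow(g$bonds) > 0) {
    t1 <- tabulate(g$bonds$a1, g$n)
    t2 <- tabulate(g$bonds$a2, g$n)
    deg <- t1 + t2
  }
  deg
}

# ring bonds = edges that are not bridges
.ring_bonds <- function(g) {
  if (nrow(g$bonds) == 0) return(logical(0))
  ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a1", "a2")]),
                                    directed = FALSE)
  if (igraph::vcount(ig) < g$n)
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  br <- igraph::bridges(ig)
  ring <- rep(TRUE, nrow(g$bonds))
  ring[as.integer(br)] <- FALSE
  ring
}

.STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1, BR = 1,
                  I = 1, B = 3, SI = 4)

.implicit_h <- function(g) {
  bsum <- numeric(g$n)
  for (k in seq_len(nrow(g$bonds))) {
    o <- g$bonds$order[k]
    bsum[g$bonds$a1[k]] <- bsum[g$bonds$a1[k]] + o
    bsum[g$bonds$a2[k]] <- bsum[g$bonds$a2[k]] + o
  }
  val <- .STD_VALENCE[g$element]
  val[is.na(val)] <- 0
  pmax(0, round(val - bsum))
}

#' Compute physicochemical descriptors for SMILES
#'
#' Molecular weight, Crippen-type atomic-contribution logP, Ertl-type
#' fragment-contribution tPSA, hydrogen-bond donor and (acceptor-typed)
#' acceptor counts are computed through the OpenBabel backend. The rotatable
#' bond count follows the usual convention: acyclic single bonds between two
#' non-terminal heavy atoms, excluding amide C-N bonds.
#'
#' @param smiles character vector of SMILES strings.
#' @param id optional compound identifiers (defaults to `mol001`, ...).
#' @return data.frame with columns `id`, `smiles`, `mw` (g/mol), `logp`,
#'   `tpsa` (A^2), `hbd`, `hba`, `rotb`.
#' @export
compute_descriptors <- function(smiles, id = NULL) {
  if (length(smiles) == 0) stop("no SMILES given")
  if (is.null(id)) id <- sprintf("mol%03d", seq_along(smiles))
  sdf <- .smiles_to_sdf(smiles, id)
  props <- ChemmineR::propOB(sdf)
  rotb <- vapply(seq_along(smiles), function(i) {
    .count_rotatable(.mol_graph(sdf[[i]]))
  }, integer(1))
  data.frame(id = id, smiles = smiles,
             mw = props$MW, logp = props$logP, tpsa = props$TPSA,
             hbd = as.integer(props$HBD), hba = as.integer(props$HBA1),
             rotb = rotb, stringsAsFactors = FALSE)
}

.count_rotatable <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  deg <- .graph_degree(g)
  ring <- .ring_bonds(g)
  # carbons carrying a double-bonded oxygen (for the amide exclusion)
  carbonyl_c <- rep(FALSE, g$n)
  dbl_o <- g$bonds$order == 2 &
    (g$element[g$bonds$a1] == "O" | g$element[g$bonds$a2] == "O")
  for (k in which(dbl_o)) {
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    cc <- if (g$element[a1] == "C") a1 else if (g$element[a2] == "C") a2
    else next
    carbonyl_c[cc] <- TRUE
  }
  n_rot <- 0L
  for (k in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[k] != 1 || ring[k]) next
    a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
    if (deg[a1] < 2 || deg[a2] < 2) next
    amide <- (carbonyl_c[a1] && g$element[a2] == "N") ||
      (carbonyl_c[a2] && g$element[a1] == "N")
    if (amide) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

# ---- PPI-adapted drug-likeness filter ---------------------------------------

#' Default PPI-adapted drug-likeness filter rules
#'
#' Open intervals, strict on both sides, widened relative to classical oral
#' drug-likeness because protein-protein interface modulators tend to be
#' larger and more lipophilic: 100 < MW < 700, 0 < tPSA < 160,
#' -4 < logP < 6, 0 < HBD < 5, 0 < HBA < 10, 0 < RotBonds < 15.
#'
#' @return data.frame with columns `descriptor`, `lo`, `hi`.
#' @export
ppi_filter_rules <- function() {
  data.frame(descriptor = c("mw", "tpsa", "logp", "hbd", "hba", "rotb"),
             lo = c(100, 0, -4, 0, 0, 0),
             hi = c(700, 160, 6, 5, 10, 15),
             stringsAsFactors = FALSE)
}

#' Apply the PPI-adapted drug-likeness filter
#'
#' A record passes iff every descriptor lies strictly inside its open
#' interval; all violated rules are listed. Filtering is idempotent: running
#' the filter on an already-filtered table flags nothing new.
#'
#' @param records data.frame with one column per rule descriptor (as from
#'   [compute_descriptors()] or the synthetic library generator).
#' @param rules filter rules; see [ppi_filter_rules()].
#' @return `records` with added columns `pass` (logical) and `violations`
#'   (comma-separated descriptor names, `""` when none).
#' @export
ppi_druglike_filter <- function(records, rules = ppi_filter_rules()) {
  stopifnot(is.data.frame(records), is.data.frame(rules))
  if (any(rules$lo >= rules$hi)) stop("malformed rule: lo >= hi")
  missing <- setdiff(rules$descriptor, names(records))
  if (length(missing) > 0)
    stop("records lack descriptor(s): ", paste(missing, collapse = ", "))
  viol <- matrix(FALSE, nrow(records), nrow(rules))
  for (r in seq_len(nrow(rules))) {
    x <- records[[rules$descriptor[r]]]
    if (anyNA(x))
      stop("missing values in descriptor '", rules$descriptor[r], "'")
    viol[, r] <- !(x > rules$lo[r] & x < rules$hi[r])
  }
  records$pass <- rowSums(viol) == 0
  records$violations <- apply(viol, 1, function(v) {
    paste(rules$descriptor[v], collapse = ",")
  })
  records
}

# ---- circular fingerprints and Tanimoto -------------------------------------

.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 33 + (x %% 2147483647)) %% 2147483647
  h
}

.PHARMACOPHORE <- c(none = 0L, donor = 1L, acceptor = 2L, halogen = 3L,
                    acidic = 4L, basic = 5L)

.atom_pharmacophore <- function(g, himpl, ring) {
  deg <- .graph_degree(g)
  cls <- rep(0L, g$n)
  is_no <- g$element %in% c("N", "O")
  cls[is_no] <- .PHARMACOPHORE[["acceptor"]]
  cls[is_no & himpl >= 1] <- .PHARMACOPHORE[["donor"]]
  cls[g$element %in% c("F", "CL", "BR", "I")] <- .PHARMACOPHORE[["halogen"]]
  # acidic: O-H on a carbon that also carries =O (carboxylic-type)
  if (nrow(g$bonds) > 0) {
    carbonyl_c <- rep(FALSE, g$n)
    for (k in which(g$bonds$order == 2)) {
      a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
      if (g$element[a1] == "C" && g$element[a2] == "O") carbonyl_c[a1] <- TRUE
      if (g$element[a2] == "C" && g$element[a1] == "O") carbonyl_c[a2] <- TRUE
    }
    for (k in which(g$bonds$order == 1)) {
      a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
      if (g$element[a1] == "O" && himpl[a1] >= 1 && carbonyl_c[a2])
        cls[a1] <- .PHARMACOPHORE[["acidic"]]
      if (g$element[a2] == "O" && himpl[a2] >= 1 && carbonyl_c[a1])
        cls[a2] <- .PHARMACOPHORE[["acidic"]]
    }
    # basic: sp3-like N with only single bonds and no adjacent carbonyl
    for (i in which(g$element == "N")) {
      kk <- which(g$bonds$a1 == i | g$bonds$a2 == i)
      if (length(kk) > 0 && all(g$bonds$order[kk] == 1)) {
        nb <- ifelse(g$bonds$a1[kk] == i, g$bonds$a2[kk], g$bonds$a1[kk])
        if (!any(carbonyl_c[nb])) cls[i] <- .PHARMACOPHORE[["basic"]]
      }
    }
  }
  cls
}

.circular_fp_one <- function(g, radius, nbits) {
  deg <- .graph_degree(g)
  himpl <- .implicit_h(g)
  ringb <- .ring_bonds(g)
  in_ring <- rep(FALSE, g$n)
  if (nrow(g$bonds) > 0) {
    in_ring[g$bonds$a1[ringb]] <- TRUE
    in_ring[g$bonds$a2[ringb]] <- TRUE
  }
  pharm <- .atom_pharmacophore(g, himpl, ringb)
  elem_id <- match(g$element, names(.STD_VALENCE))
  elem_id[is.na(elem_id)] <- 99L
  codes <- vapply(seq_len(g$n), function(i) {
    .hash_ints(c(elem_id[i], deg[i], himpl[i], as.integer(in_ring[i]),
                 pharm[i]))
  }, numeric(1))
  all_codes <- codes
  if (nrow(g$bonds) > 0) {
    nbrs <- lapply(seq_len(g$n), function(i) {
      kk <- which(g$bonds$a1 == i | g$bonds$a2 == i)
      cbind(ifelse(g$bonds$a1[kk] == i, g$bonds$a2[kk], g$bonds$a1[kk]),
            g$bonds$order[kk])
    })
    for (r in seq_len(radius)) {
      new_codes <- vapply(seq_len(g$n), function(i) {
        nb <- nbrs[[i]]
        if (nrow(nb) == 0) return(.hash_ints(c(r, codes[i])))
        pairs <- cbind(nb[, 2], codes[nb[, 1]])
        ord <- order(pairs[, 2], pairs[, 1])
        .hash_ints(c(r, codes[i], t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      codes <- new_codes
      all_codes <- c(all_codes, codes)
    }
  }
  sort(unique(as.integer(unique(all_codes) %% nbits) + 1L))
}

#' Circular substructure fingerprints with pharmacophoric atom typing
#'
#' Each atom receives an initial code from its element, heavy degree,
#' implicit hydrogen count, ring membership and pharmacophore class (donor,
#' acceptor, halogen, acidic, basic); codes are iteratively rehashed with
#' sorted neighbour (bond order, code) pairs out to the given radius
#' (radius 2 = diameter 4), and every intermediate code is folded into
#' `nbits` bits. SMILES are canonicalized first, so two spellings of the
#' same molecule give identical bitsets and repeated runs are deterministic.
#'
#' @param smiles character vector of SMILES.
#' @param id optional identifiers used to name the result.
#' @param radius neighbourhood radius (default 2).
#' @param nbits folded fingerprint length (default 2048).
#' @return named list of sorted on-bit positions (1-based), with attribute
#'   `nbits`.
#' @export
fingerprint <- function(smiles, id = NULL, radius = 2, nbits = 2048) {
  if (is.null(id)) id <- sprintf("mol%03d", seq_along(smiles))
  sdf0 <- .smiles_to_sdf(smiles, id)
  cansmi <- ChemmineR::propOB(sdf0)$cansmiNS
  sdf <- .smiles_to_sdf(cansmi, id)
  out <- lapply(seq_along(smiles), function(i) {
    .circular_fp_one(.mol_graph(sdf[[i]]), radius, nbits)
  })
  names(out) <- id
  attr(out, "nbits") <- nbits
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over the on-bit sets. Two empty bitsets are
#' defined to have similarity 1 (identical, if trivially so).
#'
#' @param a,b fingerprints: sorted on-bit vectors from [fingerprint()], with
#'   matching `nbits`.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  na <- attr(a, "nbits"); nb <- attr(b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb)
    stop("fingerprint lengths differ (", na, " vs ", nb, ")")
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

.tanimoto_matrix <- function(fps) {
  n <- length(fps)
  m <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]])
  }
  m
}

#' Sphere-exclusion (leader) diversity clustering
#'
#' Compounds are processed in descending identifier order; each compound
#' joins the first existing representative within Tanimoto distance
#' `max_distance`, else it founds a new cluster. Representatives are
#' therefore pairwise more distant than `max_distance`, and the processing
#' order makes the result deterministic.
#'
#' @param fps named list of fingerprints (names are compound ids).
#' @param max_distance maximum Tanimoto distance (1 - similarity) inside a
#'   cluster (default 0.3).
#' @return list with `representatives` (character ids) and `assignment`
#'   (data.frame `id`, `representative`, `distance`).
#' @export
diversity_cluster <- function(fps, max_distance = 0.3) {
  if (length(fps) == 0) stop("empty library")
  ids <- names(fps)
  if (is.null(ids)) stop("fingerprints must be named by compound id")
  ord <- order(ids, decreasing = TRUE)
  reps <- character(0)
  assign_rep <- character(length(fps))
  assign_dist <- numeric(length(fps))
  names(assign_rep) <- names(assign_dist) <- ids
  for (i in ord) {
    d_to_reps <- vapply(reps, function(r) 1 - tanimoto(fps[[i]], fps[[r]]),
                        numeric(1))
    hit <- which(d_to_reps <= max_distance)
    if (length(hit) > 0) {
      assign_rep[i] <- reps[hit[1]]
      assign_dist[i] <- d_to_reps[hit[1]]
    } else {
      reps <- c(reps, ids[i])
      assign_rep[i] <- ids[i]
      assign_dist[i] <- 0
    }
  }
  list(representatives = reps,
       assignment = data.frame(id = ids, representative = unname(assign_rep),
                               distance = unname(assign_dist),
                               stringsAsFactors = FALSE))
}

#' Single-linkage scaffold clustering of bioactives
#'
#' Connected components of the graph joining every pair of compounds with
#' Tanimoto similarity at least `min_similarity`.
#'
#' @param fps named list of fingerprints.
#' @param min_similarity edge threshold (default 0.6).
#' @return data.frame `id`, `cluster` (components numbered by decreasing
#'   size, ties by first member).
#' @export
scaffold_cluster <- function(fps, min_similarity = 0.6) {
  if (length(fps) == 0) stop("empty set of actives")
  n <- length(fps)
  sim <- .tanimoto_matrix(fps)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  edges <- which(upper.tri(sim) & sim >= min_similarity, arr.ind = TRUE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  mem <- igraph::components(g)$membership
  tab <- sort(table(mem), decreasing = TRUE)
  remap <- stats::setNames(seq_along(tab), names(tab))
  data.frame(id = names(fps), cluster = as.integer(remap[as.character(mem)]),
             stringsAsFactors = FALSE)
}

# ---- liability flags --------------------------------------------------------

#' Minimal substructure liability rules
#'
#' A small, documented subset of reactive-group and assay-interference
#' (PAINS-type) SMARTS patterns; deliberately not a full curated liability
#' catalogue.
#'
#' @return data.frame `name`, `smarts`, `class`.
#' @export
liability_smarts <- function() {
  data.frame(
    name = c("acyl_halide", "aldehyde", "isocyanate", "epoxide",
             "michael_acceptor", "alkyl_bromide", "quinone", "catechol"),
    smarts = c("[CX3](=O)[F,Cl,Br,I]",
               "[CX3H1](=O)[#6]",
               "[NX2]=C=[OX1]",
               "[OX2r3]1[#6r3][#6r3]1",
               "[CX3]=[CX3][CX3]=[OX1]",
               "[CX4][Br]",
               "O=C1C=CC(=O)C=C1",
               "c1ccc(O)c(O)c1"),
    class = c("reactive", "reactive", "reactive", "reactive", "reactive",
              "reactive", "pains", "pains"),
    stringsAsFactors = FALSE)
}

#' Flag compounds carrying liability substructures
#'
#' @param smiles character vector of SMILES.
#' @param id optional identifiers.
#' @param rules SMARTS rule table; see [liability_smarts()].
#' @return data.frame `id`, `smiles`, `flags` (comma-separated rule names),
#'   `clean` (logical).
#' @export
liability_flags <- function(smiles, id = NULL, rules = liability_smarts()) {
  if (is.null(id)) id <- sprintf("mol%03d", seq_along(smiles))
  sdf <- .smiles_to_sdf(smiles, id)
  hits <- matrix(FALSE, length(smiles), nrow(rules))
  for (r in seq_len(nrow(rules))) {
    counts <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, rules$smarts[r], uniqueMatches = FALSE),
      error = function(e) stop("malformed SMARTS in rule '", rules$name[r],
                               "': ", conditionMessage(e)))
    hits[, r] <- counts > 0
  }
  flags <- apply(hits, 1, function(h) paste(rules$name[h], collapse = ","))
  data.frame(id = id, smiles = smiles, flags = flags,
             clean = !nzchar(flags), stringsAsFactors = FALSE)
}
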