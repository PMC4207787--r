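#' @useDynLib dimerstab, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qnorm pnorm sd setNames plogis
#' @importFrom utils head tail read.csv write.csv
NULL

# ---- domain types -----------------------------------------------------------

#' Construct a Structure from an atom table
#'
#' A `Structure` is an ordered atom table with Cartesian coordinates in
#' Angstrom. Atom identity is the triple (chain, residue number, atom name),
#' which must be unique within one structure. Residue numbering is kept
#' verbatim from the input; no renumbering is ever applied, and reports always
#' print `chain:resno` so a second chain keeps its native numbers.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `occ`, `b`, `element`, `het`.
#' @param label free-text label (for example a snapshot name).
#' @return an object of class `Structure`.
#' @export
new_structure <- function(atoms, label = "") {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "resname", "chain", "resno",
                "x", "y", "z", "element")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element)))
    stop("atoms with empty element symbol")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, name) atom identity: ",
         key[duplicated(key)][1])
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat("<Structure", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ">\n")
  cat("  atoms:", nrow(a), " (", sum(a$het), "HETATM )\n")
  cat("  chains:", paste(unique(a$chain), collapse = ", "), "\n")
  cat("  residues:", length(unique(paste(a$chain, a$resno))), "\n")
  invisible(x)
}

#' Number of atoms in a Structure or Ensemble topology
#' @param x a `Structure` or `Ensemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Ensemble")) x <- x$topology
  nrow(x$atoms)
}

#' Extract coordinates as an n x 3 matrix
#' @param x a `Structure`, or an `Ensemble` together with `frame`.
#' @param frame frame index when `x` is an `Ensemble`.
#' @return numeric matrix with one row per atom, columns x, y, z.
#' @export
get_coords <- function(x, frame = NULL) {
  if (inherits(x, "Ensemble")) {
    if (is.null(frame)) stop("frame index required for an Ensemble")
    return(matrix(x$xyz[frame, ], ncol = 3, byrow = TRUE))
  }
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a Structure
#' @param s a `Structure`.
#' @param coords n x 3 matrix.
#' @return the modified `Structure`.
#' @export
set_coords <- function(s, coords) {
  stopifnot(inherits(s, "Structure"), nrow(coords) == nrow(s$atoms))
  s$atoms$x <- coords[, 1]
  s$atoms$y <- coords[, 2]
  s$atoms$z <- coords[, 3]
  s
}

#' Construct a multi-snapshot Ensemble
#'
#' All frames share one topology (the reference `Structure`); each frame is a
#' flat coordinate row `(x1, y1, z1, x2, ...)`. Frames are separated by a
#' constant timestep.
#'
#' @param topology `Structure` giving the shared atom ordering.
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param timestep_ps positive timestep between frames, picoseconds.
#' @return object of class `Ensemble`.
#' @export
new_ensemble <- function(topology, xyz, timestep_ps = 1) {
  stopifnot(inherits(topology, "Structure"))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topology$atoms))
    stop("frame width ", ncol(xyz), " does not match topology atom count ",
         nrow(topology$atoms))
  if (nrow(xyz) == 0) stop("ensemble with zero frames")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  stopifnot(timestep_ps > 0)
  structure(list(topology = topology, xyz = xyz, timestep_ps = timestep_ps),
            class = "Ensemble")
}

#' Number of frames in an Ensemble
#' @param e an `Ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(e) {
  stopifnot(inherits(e, "Ensemble"))
  nrow(e$xyz)
}

#' Materialize one frame of an Ensemble as a Structure
#' @param e an `Ensemble`.
#' @param frame frame index.
#' @param label label for the extracted structure.
#' @return a `Structure`.
#' @export
frame_structure <- function(e, frame, label = NULL) {
  stopifnot(inherits(e, "Ensemble"), frame >= 1, frame <= n_frames(e))
  s <- set_coords(e$topology, get_coords(e, frame))
  s$label <- if (is.null(label)) sprintf("frame_%d", frame) else label
  s
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("<Ensemble>", n_frames(x), "frames x", n_atoms(x), "atoms,",
      x$timestep_ps, "ps/frame\n")
  invisible(x)
}

# ---- PDB parsing ------------------------------------------------------------

.parse_num <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- which(is.na(v))
  if (length(bad) > 0)
    stop(sprintf("malformed ATOM record at line %d: bad %s field '%s'",
                 lineno[bad[1]], what, trimws(txt[bad[1]])))
  v
}

.element_from_name <- function(name) {
  # PDB atom names lead with the element once digits/spaces are stripped;
  # two-letter elements occupy the first column pair
  stripped <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(stripped, 1, 2))
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")
  ifelse(two %in% known2, two, toupper(substr(stripped, 1, 1)))
}

.parse_atom_lines <- function(lines, linenos) {
  rec <- substr(lines, 1, 6)
  serial <- .parse_num(substr(lines, 7, 11), linenos, "serial")
  name <- trimws(substr(lines, 13, 16))
  altloc <- trimws(substr(lines, 17, 17))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resno <- .parse_num(substr(lines, 23, 26), linenos, "residue number")
  x <- .parse_num(substr(lines, 31, 38), linenos, "x")
  y <- .parse_num(substr(lines, 39, 46), linenos, "y")
  z <- .parse_num(substr(lines, 47, 54), linenos, "z")
  occ_txt <- trimws(substr(lines, 55, 60))
  occ <- suppressWarnings(as.numeric(occ_txt))
  occ[is.na(occ)] <- 1
  b_txt <- trimws(substr(lines, 61, 66))
  b <- suppressWarnings(as.numeric(b_txt))
  b[is.na(b)] <- 0
  element <- toupper(trimws(substr(lines, 77, 78)))
  element <- ifelse(nzchar(element), element, .element_from_name(name))
  data.frame(serial = as.integer(serial), name = name, altloc = altloc,
             resname = resname, chain = chain, resno = as.integer(resno),
             x = x, y = y, z = z, occ = occ, b = b, element = element,
             het = rec == "HETATM", stringsAsFactors = FALSE)
}

# keep the highest-occupancy alternate location; first wins on ties
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    idx[which.max(atoms$occ[idx])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a PDB file into a Structure or Ensemble
#'
#' Fixed-column ATOM/HETATM records are parsed; a file without MODEL records
#' yields a `Structure`, a multi-model file yields an `Ensemble` with one
#' frame per MODEL. Alternate locations are resolved to the
#' highest-occupancy copy (first wins on ties). HETATM records are kept and
#' flagged via the `het` column; selections exclude them by default.
#'
#' @param path path to a PDB file.
#' @param label label for the result; defaults to the file name.
#' @param timestep_ps frame spacing assigned to multi-model files.
#' @return a `Structure` or an `Ensemble`.
#' @export
read_pdb <- function(path, label = NULL, timestep_ps = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- basename(path)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    idx <- which(is_atom)
    if (length(idx) == 0) stop("no ATOM/HETATM records in ", path)
    atoms <- .resolve_altloc(.parse_atom_lines(lines[idx], idx))
    return(new_structure(atoms, label = label))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  frames <- vector("list", length(model_starts))
  topology <- NULL
  for (m in seq_along(model_starts)) {
    idx <- which(is_atom & seq_along(lines) > model_starts[m] &
                   seq_along(lines) < model_ends[m])
    if (length(idx) == 0) stop("MODEL ", m, " contains no atoms")
    atoms <- .resolve_altloc(.parse_atom_lines(lines[idx], idx))
    if (m == 1) {
      topology <- new_structure(atoms, label = label)
    } else if (nrow(atoms) != nrow(topology$atoms)) {
      stop("MODEL ", m, " has ", nrow(atoms), " atoms; MODEL 1 has ",
           nrow(topology$atoms))
    }
    frames[[m]] <- c(t(as.matrix(atoms[, c("x", "y", "z")])))
  }
  new_ensemble(topology, do.call(rbind, frames), timestep_ps = timestep_ps)
}

# ---- PDB writing ------------------------------------------------------------

.format_atom_name <- function(name, element) {
  # one-letter elements with short names start in column 14
  ifelse(nchar(name) >= 4 | nchar(element) >= 2,
         formatC(name, width = -4),
         paste0(" ", formatC(name, width = -3)))
}

.format_atom_lines <- function(atoms) {
  rec <- ifelse(atoms$het, "HETATM", "ATOM  ")
  sprintf("%s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec,
          atoms$serial %% 100000L,       # serial wraps at the 5-column width
          .format_atom_name(atoms$name, atoms$element),
          substr(atoms$altloc, 1, 1),
          atoms$resname, atoms$chain,
          atoms$resno %% 10000L,
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
          formatC(substr(atoms$element, 1, 2), width = 2))
}

#' Write a Structure or Ensemble to a PDB file
#'
#' Coordinates are written at the fixed-column PDB precision of 3 decimals,
#' so a read/write round trip reproduces them to 5e-4 Angstrom. Atom serials
#' wider than the 5-column field are written modulo 100000 (residue numbers
#' modulo 10000), matching the classic PDB dialect.
#'
#' @param x a `Structure` or `Ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  out <- file(path, "w")
  on.exit(close(out))
  if (inherits(x, "Structure")) {
    writeLines(.format_atom_lines(x$atoms), out)
  } else if (inherits(x, "Ensemble")) {
    for (m in seq_len(n_frames(x))) {
      s <- set_coords(x$topology, get_coords(x, m))
      writeLines(sprintf("MODEL %8d", m), out)
      writeLines(.format_atom_lines(s$atoms), out)
      writeLines("ENDMDL", out)
    }
  } else {
    stop("x must be a Structure or Ensemble")
  }
  writeLines("END", out)
  invisible(path)
}

# ---- atom selections --------------------------------------------------------

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

.parse_selection_spec <- function(spec) {
  out <- list(chains = NULL, resno = NULL, atoms = "all")
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  for (p in parts) {
    kv <- strsplit(trimws(p), "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed selection term: '", p, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "chain") {
      out$chains <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key == "res") {
      ranges <- strsplit(val, ",", fixed = TRUE)[[1]]
      out$resno <- unlist(lapply(ranges, function(r) {
        ab <- as.integer(strsplit(trimws(r), "-", fixed = TRUE)[[1]])
        if (anyNA(ab)) stop("malformed residue range: '", r, "'")
        if (length(ab) == 1) ab else seq(ab[1], ab[2])
      }))
    } else if (key == "atoms") {
      out$atoms <- val
    } else {
      stop("unknown selection key: '", key, "'")
    }
  }
  out
}

#' Select atoms of a Structure
#'
#' Builds an `AtomSelection`: strictly increasing atom indices plus the
#' human-readable spec that produced them. The atom class is one of `"all"`
#' (every heavy atom of the listed residues), `"backbone"` (N, CA, C, O) or
#' `"CA"`. HETATM records and hydrogens are excluded unless requested.
#'
#' @param s a `Structure` (or `Ensemble`, whose topology is used).
#' @param spec optional selection string, e.g.
#'   `"chain=C,D;res=1-120;atoms=backbone"`; overrides the other arguments.
#' @param chains chain identifiers to keep (NULL = all chains).
#' @param resno residue numbers to keep (NULL = all residues).
#' @param atoms atom class: `"all"`, `"backbone"` or `"CA"`.
#' @param include_het keep HETATM records.
#' @param include_hydrogens keep hydrogen atoms in `"all"` selections.
#' @return object of class `AtomSelection` with fields `indices` and `spec`.
#' @export
select_atoms <- function(s, spec = NULL, chains = NULL, resno = NULL,
                         atoms = c("all", "backbone", "CA"),
                         include_het = FALSE, include_hydrogens = FALSE) {
  if (inherits(s, "Ensemble")) s <- s$topology
  stopifnot(inherits(s, "Structure"))
  if (!is.null(spec)) {
    parsed <- .parse_selection_spec(spec)
    chains <- parsed$chains
    resno <- parsed$resno
    atoms <- parsed$atoms
  }
  atoms <- match.arg(atoms, c("all", "backbone", "CA"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) {
    absent <- setdiff(chains, unique(a$chain))
    if (length(absent) > 0)
      stop("selection matched no atoms: chain '", absent[1],
           "' not present in structure")
    keep <- keep & a$chain %in% chains
  }
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!include_het) keep <- keep & !a$het
  if (atoms == "backbone") {
    keep <- keep & a$name %in% .BACKBONE_NAMES
  } else if (atoms == "CA") {
    keep <- keep & a$name == "CA"
  } else if (!include_hydrogens) {
    keep <- keep & a$element != "H"
  }
  idx <- which(keep)
  if (length(idx) == 0)
    stop("selection matched no atoms (chains=",
         paste(chains, collapse = ","), " res=",
         if (is.null(resno)) "all" else paste(range(resno), collapse = "-"),
         " atoms=", atoms, ")")
  described <- if (is.null(spec)) {
    sprintf("chain=%s;res=%s;atoms=%s",
            if (is.null(chains)) "*" else paste(chains, collapse = ","),
            if (is.null(resno)) "*" else paste(range(resno), collapse = "-"),
            atoms)
  } else spec
  structure(list(indices = idx, spec = described), class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat("<AtomSelection>", length(x$indices), "atoms [", x$spec, "]\n")
  invisible(x)
}

.sel_indices <- function(sel, n = NULL) {
  idx <- if (inherits(sel, "AtomSelection")) sel$indices
  else if (is.null(sel)) seq_len(n)
  else as.integer(sel)
  if (is.null(idx) || length(idx) == 0) stop("empty atom selection")
  idx
}
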