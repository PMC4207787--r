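# Rigid and relaxed binding free-energy protocols over per-snapshot energy
# trajectories, with last-window averaging and threshold selection, plus a
# fully specified toy pair potential so the protocols can be exercised
# without a molecular dynamics engine.

#' Construct a per-snapshot energy trajectory
#'
#' @param energies finite per-snapshot potential energies, kcal/mol.
#' @param role one of `"complex"`, `"receptor"`, `"ligand"`.
#' @param source `"extracted-from-complex"` (component energies evaluated on
#'   the complex snapshots) or `"independent-run"` (component simulated
#'   alone, so relaxation and entropic effects are implicitly included).
#' @param timestep_ps snapshot spacing, picoseconds.
#' @return object of class `EnergyTrajectory`.
#' @export
energy_trajectory <- function(energies,
                              role = c("complex", "receptor", "ligand"),
                              source = c("extracted-from-complex",
                                         "independent-run"),
                              timestep_ps = 1) {
  role <- match.arg(role)
  source <- match.arg(source)
  if (length(energies) == 0) stop("empty energy trajectory")
  if (any(!is.finite(energies))) stop("non-finite energies in trajectory")
  stopifnot(timestep_ps > 0)
  structure(list(role = role, source = source,
                 energies = as.numeric(energies), timestep_ps = timestep_ps),
            class = "EnergyTrajectory")
}

#' @export
print.EnergyTrajectory <- function(x, ...) {
  cat("<EnergyTrajectory>", x$role, "(", x$source, "),",
      length(x$energies), "snapshots, mean",
      format(mean(x$energies), digits = 6), "kcal/mol\n")
  invisible(x)
}

.check_traj <- function(t, role, source, window, label) {
  if (!inherits(t, "EnergyTrajectory")) stop(label, " is not an EnergyTrajectory")
  if (t$role != role) stop(label, " has role '", t$role, "', expected '",
                           role, "'")
  if (t$source != source)
    stop(label, " has source '", t$source, "', expected '", source, "'")
  if (length(t$energies) < window)
    stop(label, " has ", length(t$energies), " snapshots; need at least ",
         window)
  invisible(t)
}

.window_mean <- function(x, window) mean(utils::tail(x, window))

#' Rigid (single-trajectory) binding free energy
#'
#' `ddG = <E_complex - E_receptor - E_ligand>` averaged over the last
#' `window` snapshots, with the receptor and ligand energies evaluated on
#' the same complex snapshots (single-trajectory protocol). All three
#' trajectories must be snapshot-aligned.
#'
#' @param complex_t,receptor_t,ligand_t `EnergyTrajectory` objects; the
#'   receptor and ligand must carry source `"extracted-from-complex"`.
#' @param window number of trailing snapshots averaged (default 20,
#'   matching 20 ps at a 1 ps snapshot spacing).
#' @return binding energy, kcal/mol (negative = favourable).
#' @export
ddg_rigid <- function(complex_t, receptor_t, ligand_t, window = 20) {
  .check_traj(complex_t, "complex", "extracted-from-complex", window,
              "complex_t")
  .check_traj(receptor_t, "receptor", "extracted-from-complex", window,
              "receptor_t")
  .check_traj(ligand_t, "ligand", "extracted-from-complex", window,
              "ligand_t")
  n <- length(complex_t$energies)
  if (length(receptor_t$energies) != n || length(ligand_t$energies) != n)
    stop("trajectories are not snapshot-aligned (",
         n, ", ", length(receptor_t$energies), ", ",
         length(ligand_t$energies), " snapshots)")
  .window_mean(complex_t$energies - receptor_t$energies - ligand_t$energies,
               window)
}

#' Relaxed (separate-trajectory) binding free energy
#'
#' `ddG = <E_complex> - <E_receptor,indep> - <E_ligand,indep>`, each mean
#' over the last `window` snapshots of its own run. The receptor and ligand
#' trajectories come from independent simulations of the components alone,
#' so component relaxation (and, implicitly, entropic effects) enter the
#' estimate.
#'
#' @inheritParams ddg_rigid
#' @export
ddg_relaxed <- function(complex_t, receptor_t, ligand_t, window = 20) {
  .check_traj(complex_t, "complex", "extracted-from-complex", window,
              "complex_t")
  .check_traj(receptor_t, "receptor", "independent-run", window,
              "receptor_t")
  .check_traj(ligand_t, "ligand", "independent-run", window, "ligand_t")
  .window_mean(complex_t$energies, window) -
    .window_mean(receptor_t$energies, window) -
    .window_mean(ligand_t$energies, window)
}

#' Select candidates by binding-energy threshold
#'
#' A compound is kept when its rigid OR relaxed binding energy is at least
#' as favourable as the threshold (more negative or equal). Selected
#' compounds are sorted by their better (lower) energy, ties broken by id,
#' and optionally truncated to the first `max_n`.
#'
#' @param results data.frame with columns `id`, `ddg_rigid`, `ddg_relaxed`
#'   (kcal/mol).
#' @param threshold selection threshold, kcal/mol (default -20).
#' @param max_n optional cap on the returned list length.
#' @return the selected rows, ordered, with an added `ddg_best` column.
#' @export
select_candidates <- function(results, threshold = -20, max_n = Inf) {
  stopifnot(is.data.frame(results),
            all(c("id", "ddg_rigid", "ddg_relaxed") %in% names(results)))
  if (nrow(results) == 0) stop("empty results table")
  best <- pmin(results$ddg_rigid, results$ddg_relaxed)
  keep <- best <= threshold
  out <- results[keep, , drop = FALSE]
  out$ddg_best <- best[keep]
  out <- out[order(out$ddg_best, out$id), , drop = FALSE]
  if (is.finite(max_n) && nrow(out) > max_n)
    out <- out[seq_len(max_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- toy potential ----------------------------------------------------------

#' Load the shipped toy potential parameter table
#'
#' Lennard-Jones well depths/diameters and partial charges per atom class.
#' The parameter set is a self-contained toy; it makes no claim of
#' force-field equivalence and exists so the binding-energy protocols can
#' be exercised on explicit coordinates.
#'
#' @return data.frame `atom_class`, `epsilon` (kcal/mol), `sigma` (A),
#'   `charge` (e).
#' @export
toy_potential_params <- function() {
  path <- system.file("extdata", "toy_potential.csv", package = "dimerstab")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Toy pairwise potential energy
#'
#' Sum over atom pairs of a Lennard-Jones term plus a screened Coulomb term
#' with distance-dependent dielectric `eps(r) = 4r`:
#' `4*eps_ij*((sig_ij/r)^12 - (sig_ij/r)^6) + 332.06*qi*qj/(4*r^2)`.
#' Lorentz-Berthelot combination (arithmetic sigma, geometric epsilon); no
#' cutoff. Coincident atoms are a singularity error.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param epsilon,sigma,charge per-atom parameters (length n or 1).
#' @return potential energy, kcal/mol.
#' @export
toy_energy <- function(coords, epsilon, sigma, charge) {
  coords <- get_coords(coords)
  n <- nrow(coords)
  if (n < 2) return(0)
  epsilon <- rep_len(epsilon, n)
  sigma <- rep_len(sigma, n)
  charge <- rep_len(charge, n)
  d <- as.matrix(stats::dist(coords))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  r <- d[pair]
  if (any(r < 1e-9)) stop("singularity: coincident atoms at pair (",
                          pair[which(r < 1e-9)[1], 1], ", ",
                          pair[which(r < 1e-9)[1], 2], ")")
  i <- pair[, 1]; j <- pair[, 2]
  eij <- sqrt(epsilon[i] * epsilon[j])
  sij <- (sigma[i] + sigma[j]) / 2
  sr6 <- (sij / r)^6
  lj <- 4 * eij * (sr6^2 - sr6)
  coul <- 332.06 * charge[i] * charge[j] / (4 * r^2)
  sum(lj + coul)
}
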