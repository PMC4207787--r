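# Deterministic synthetic inputs with planted ground truth: a toy two-chain
# dimer, a conformational ensemble with discrete binding-site states, a
# compound library straddling the drug-likeness filter, correlated docking
# score tables with planted binders, and energy trajectories with planted
# binding energies. One integer seed reproduces every generated byte; the
# planted truths are carried alongside the data and are never consumed by
# the pipeline stages under test.

#' Synthetic study specification
#'
#' Bundles every knob of the generator. Defaults emulate the study
#' conditions the pipeline was designed around: a 1500-snapshot ensemble at
#' 1 ps spacing with 8 discrete binding-site states, a library of 5000
#' compounds of which 10 are planted binders with a true binding energy of
#' -25 kcal/mol against -5 for non-binders, and Gaussian snapshot noise of
#' 2 kcal/mol on the energy streams. The state amplitude (3 A) and thermal
#' noise (0.15 A) are chosen so that inter-state binding-site RMSD exceeds
#' 3 A while intra-state RMSD stays below 0.5 A (separation about 10x the
#' thermal noise), which is what a well-resolved conformational selection
#' scenario looks like.
#'
#' @param seed integer master seed; derives every substream.
#' @param n_residues residues per chain of the toy dimer.
#' @param k_states planted binding-site conformational states.
#' @param state_amplitude displacement amplitude per state, A.
#' @param thermal_sigma per-coordinate Gaussian noise, A.
#' @param n_snapshots ensemble frames.
#' @param timestep_ps frame spacing, ps.
#' @param library_size compounds in the synthetic library.
#' @param n_binders planted true binders.
#' @param violation_fraction fraction of library records planted outside at
#'   least one filter interval.
#' @param score_noise docking-score noise, score units.
#' @param ddg_true_binder,ddg_true_nonbinder planted binding energies,
#'   kcal/mol.
#' @param ddg_noise Gaussian snapshot noise on the complex energy, kcal/mol.
#' @param relax_offset planted component-relaxation offset, kcal/mol
#'   (relaxed minus rigid).
#' @param n_energy_snapshots snapshots per energy trajectory.
#' @return object of class `SynthSpec`.
#' @export
synth_spec <- function(seed = 1, n_residues = 60, k_states = 8,
                       state_amplitude = 3, thermal_sigma = 0.15,
                       n_snapshots = 1500, timestep_ps = 1,
                       library_size = 5000, n_binders = 10,
                       violation_fraction = 0.3, score_noise = 0.5,
                       ddg_true_binder = -25, ddg_true_nonbinder = -5,
                       ddg_noise = 2, relax_offset = 5,
                       n_energy_snapshots = 40) {
  stopifnot(k_states >= 1, state_amplitude > 0, thermal_sigma >= 0,
            n_snapshots >= 1, n_residues >= 10, library_size >= 1,
            n_binders <= library_size, violation_fraction >= 0,
            violation_fraction < 1, n_energy_snapshots >= 20)
  spec <- list(seed = as.integer(seed), n_residues = n_residues,
               k_states = k_states, state_amplitude = state_amplitude,
               thermal_sigma = thermal_sigma, n_snapshots = n_snapshots,
               timestep_ps = timestep_ps, library_size = library_size,
               n_binders = n_binders,
               violation_fraction = violation_fraction,
               score_noise = score_noise,
               ddg_true_binder = ddg_true_binder,
               ddg_true_nonbinder = ddg_true_nonbinder,
               ddg_noise = ddg_noise, relax_offset = relax_offset,
               n_energy_snapshots = n_energy_snapshots)
  class(spec) <- "SynthSpec"
  spec
}

# named substream: every generated artifact draws from its own seed derived
# from (master seed, substream name), keeping artifacts independently
# reproducible
.substream_seed <- function(seed, name) {
  h <- seed %% 2147483646
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483646
  as.integer(h + 1)
}

.with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substream_seed(seed, name))
  force(code)
}

# ---- toy dimer --------------------------------------------------------------

#' Build the deterministic toy two-chain dimer
#'
#' Two parallel helical chains (C and D) of backbone atoms (N, CA, C, O),
#' facing each other across an interface groove about 9 A wide. The
#' geometry is a pure function of the residue count: no randomness enters,
#' so the structure is bitwise reproducible. The residue facing the middle
#' of the groove on chain C is recorded as the `mutation_site` attribute
#' (the toy counterpart of a destabilizing interface mutation).
#'
#' @param spec a `SynthSpec`.
#' @return a `Structure` with chains C and D.
#' @export
make_toy_dimer <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  n <- spec$n_residues
  resnames <- rep(c("ALA", "LEU", "GLY", "SER", "VAL"), length.out = n)
  helix <- function(chain, mirror) {
    t <- seq_len(n)
    theta <- t * 100 * pi / 180
    r <- 2.3
    ca <- cbind(r * cos(theta), r * sin(theta), 1.5 * t)
    if (mirror) ca[, 1] <- 9 - ca[, 1]
    rows <- lapply(t, function(i) {
      axis <- c(0, 0, 1)
      nvec <- ca[i, ] + c(-0.5, 1.2, -0.9)
      cvec <- ca[i, ] + c(0.6, -1.1, 0.9)
      ovec <- cvec + c(0.7, -0.8, 0.2)
      data.frame(name = c("N", "CA", "C", "O"),
                 element = c("N", "C", "C", "O"),
                 resname = resnames[i], chain = chain, resno = i,
                 x = c(nvec[1], ca[i, 1], cvec[1], ovec[1]),
                 y = c(nvec[2], ca[i, 2], cvec[2], ovec[2]),
                 z = c(nvec[3], ca[i, 3], cvec[3], ovec[3]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  atoms <- rbind(helix("C", FALSE), helix("D", TRUE))
  atoms$serial <- seq_len(nrow(atoms))
  atoms$altloc <- ""
  atoms$occ <- 1
  atoms$b <- 0
  atoms$het <- FALSE
  s <- new_structure(atoms, label = "toy_dimer")
  attr(s, "mutation_site") <- list(chain = "C", resno = n %/% 2)
  s
}

#' Interface / binding-site selection of the toy dimer
#'
#' Residues with any atom within `cutoff` of the other chain; the returned
#' selection covers all atoms of those residues on both chains, the toy
#' counterpart of an all-atom binding-site selection.
#'
#' @param s the dimer `Structure`.
#' @param cutoff inter-chain contact distance, A.
#' @return an `AtomSelection`.
#' @export
interface_selection <- function(s, cutoff = 6) {
  a <- s$atoms
  cc <- as.matrix(a[a$chain == "C", c("x", "y", "z")])
  dd <- as.matrix(a[a$chain == "D", c("x", "y", "z")])
  dmin_c <- .min_dist_to(cc, dd)
  dmin_d <- .min_dist_to(dd, cc)
  res_c <- unique(a$resno[a$chain == "C"][dmin_c <= cutoff])
  res_d <- unique(a$resno[a$chain == "D"][dmin_d <= cutoff])
  keep <- (a$chain == "C" & a$resno %in% res_c) |
    (a$chain == "D" & a$resno %in% res_d)
  if (!any(keep)) stop("no interface residues within ", cutoff, " A")
  structure(list(indices = which(keep),
                 spec = sprintf("interface residues (contact <= %g A)",
                                cutoff)),
            class = "AtomSelection")
}

#' Generate a synthetic ensemble with planted conformational states
#'
#' Each snapshot is the base structure plus a per-state displacement of the
#' binding-site atoms plus isotropic Gaussian thermal noise on every atom.
#' The per-state displacement assigns each binding-site atom a fixed random
#' unit direction scaled by the state amplitude; the patterns are
#' deliberately non-rigid so the planted separation survives the Kabsch
#' superposition that the downstream distance matrix applies over the same
#' selection (a rigid sub-motion of exactly the fitted atoms would be
#' invisible to it).
#'
#' @param s the dimer `Structure` from [make_toy_dimer()].
#' @param spec a `SynthSpec`.
#' @return list: `ensemble` (an `Ensemble`), `labels` (planted per-frame
#'   state), `references` (list of k noise-free state coordinate matrices),
#'   `binding_site` (the `AtomSelection` that was displaced).
#' @export
make_ensemble <- function(s, spec) {
  stopifnot(inherits(s, "Structure"), inherits(spec, "SynthSpec"))
  sel <- interface_selection(s)
  idx <- sel$indices
  base <- get_coords(s)
  natom <- nrow(base)
  k <- spec$k_states
  nf <- spec$n_snapshots
  .with_substream(spec$seed, "ensemble", {
    patterns <- lapply(seq_len(k), function(st) {
      v <- matrix(rnorm(length(idx) * 3), ncol = 3)
      v / sqrt(rowSums(v^2))
    })
    labels <- c(rep(seq_len(k), length.out = min(2L * k, nf)),
                if (nf > 2L * k) sample(seq_len(k), nf - 2L * k,
                                        replace = TRUE))
    labels <- labels[seq_len(nf)]
    references <- lapply(seq_len(k), function(st) {
      ref <- base
      ref[idx, ] <- ref[idx, ] + spec$state_amplitude * patterns[[st]]
      ref
    })
    xyz <- matrix(0, nf, 3 * natom)
    for (f in seq_len(nf)) {
      fc <- references[[labels[f]]] +
        matrix(rnorm(natom * 3, sd = spec$thermal_sigma), ncol = 3)
      xyz[f, ] <- c(t(fc))
    }
    list(ensemble = new_ensemble(s, xyz, timestep_ps = spec$timestep_ps),
         labels = labels, references = references, binding_site = sel)
  })
}

# ---- compound library -------------------------------------------------------

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Generate a synthetic compound library with planted filter violations
#'
#' Descriptors of passing records are drawn from truncated normals strictly
#' inside the PPI-adapted filter intervals; a planted fraction of records
#' receives one or more descriptors outside their interval. The
#' ground-truth pass flag (`true_pass`) and the planted violations
#' (`true_violations`) are emitted alongside the data for evaluation and
#' must never feed the filter under test. SMILES strings are simple valid
#' heteroatom chains; their chemistry is not meant to be realistic and the
#' planted descriptors, not recomputed ones, define each record.
#'
#' @param spec a `SynthSpec`.
#' @return data.frame: `id`, `smiles`, descriptor columns (`mw`, `tpsa`,
#'   `logp`, `hbd`, `hba`, `rotb`), `true_pass`, `true_violations`.
#' @export
make_library <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  n <- spec$library_size
  rules <- ppi_filter_rules()
  .with_substream(spec$seed, "library", {
    ids <- sprintf("CPD%06d", seq_len(n))
    smiles <- vapply(seq_len(n), function(i) {
      len <- sample(4:12, 1)
      paste(sample(c("C", "C", "C", "C", "N", "O"), len, replace = TRUE),
            collapse = "")
    }, character(1))
    desc <- data.frame(
      mw = .rtrunc_norm(n, 400, 120, 101, 699),
      tpsa = .rtrunc_norm(n, 80, 30, 1, 159),
      logp = .rtrunc_norm(n, 2, 1.5, -3.9, 5.9),
      hbd = sample(1:4, n, replace = TRUE),
      hba = sample(1:9, n, replace = TRUE),
      rotb = sample(1:14, n, replace = TRUE))
    violate <- runif(n) < spec$violation_fraction
    true_viol <- character(n)
    lows <- list(mw = c(20, 100), tpsa = c(-20, 0), logp = c(-8, -4),
                 hbd = 0, hba = 0, rotb = 0)
    highs <- list(mw = c(700, 950), tpsa = c(160, 240), logp = c(6, 9),
                  hbd = 5:8, hba = 10:14, rotb = 15:22)
    for (i in which(violate)) {
      n_rules <- 1 + stats::rbinom(1, 1, 0.2)
      which_rules <- sample(rules$descriptor, n_rules)
      for (d in which_rules) {
        side <- sample(c("lo", "hi"), 1)
        pool <- if (side == "lo") lows[[d]] else highs[[d]]
        desc[[d]][i] <- if (length(pool) == 2 && d %in% c("mw", "tpsa", "logp"))
          runif(1, pool[1], pool[2]) else sample(pool, 1)
      }
      true_viol[i] <- paste(sort(which_rules), collapse = ",")
    }
    # recompute the planted truth from the final descriptor values (a draw
    # meant to violate one rule must not silently pass another)
    viol_mat <- vapply(seq_len(nrow(rules)), function(r) {
      x <- desc[[rules$descriptor[r]]]
      !(x > rules$lo[r] & x < rules$hi[r])
    }, logical(n))
    true_pass <- rowSums(viol_mat) == 0
    true_viol <- apply(viol_mat, 1, function(v) {
      paste(sort(rules$descriptor[v]), collapse = ",")
    })
    out <- cbind(data.frame(id = ids, smiles = smiles,
                            stringsAsFactors = FALSE),
                 desc,
                 data.frame(true_pass = true_pass,
                            true_violations = true_viol,
                            stringsAsFactors = FALSE))
    out
  })
}

# ---- docking score tables ---------------------------------------------------

#' Generate correlated docking score tables with planted binders
#'
#' Two engines score the same compound universe for each receptor
#' conformation: engine A on a positive higher-is-better scale (around
#' 4-9), engine B on a negative lower-is-better scale (around -9 to -4).
#' Both derive from a shared latent affinity (hence positively correlated
#' ranks); planted binders draw their latent affinity above every
#' non-binder, so at zero score noise they occupy the exact top ranks of
#' both engines.
#'
#' @param spec a `SynthSpec`.
#' @param ids compound universe to score (e.g. the filtered library ids).
#' @param conformations conformation labels (one pair of tables each).
#' @return list: `tables` (per conformation, a list with `A` and `B`
#'   `ScoreTable`s), `binders` (planted binder ids).
#' @export
make_score_tables <- function(spec, ids,
                              conformations = c("conf1", "conf2", "conf3")) {
  stopifnot(inherits(spec, "SynthSpec"))
  ids <- as.character(ids)
  n <- length(ids)
  if (spec$n_binders > n)
    stop("more planted binders than compounds to score")
  .with_substream(spec$seed, "scores", {
    binders <- sort(sample(ids, spec$n_binders))
    latent <- .rtrunc_norm(n, 0, 1, -Inf, 2)
    latent[ids %in% binders] <- runif(spec$n_binders, 3, 4)
    conf_shift <- stats::setNames(
      seq(-0.2, 0.2, length.out = length(conformations)), conformations)
    tables <- lapply(conformations, function(cf) {
      sA <- 6.5 + 0.5 * latent + conf_shift[[cf]] +
        rnorm(n, sd = spec$score_noise)
      sB <- -6.5 - 0.5 * latent - conf_shift[[cf]] +
        rnorm(n, sd = spec$score_noise)
      list(A = score_table(ids, sA, engine = "engineA", conformation = cf,
                           direction = "higher"),
           B = score_table(ids, sB, engine = "engineB", conformation = cf,
                           direction = "lower"))
    })
    names(tables) <- conformations
    list(tables = tables, binders = binders)
  })
}

# ---- energy trajectories ----------------------------------------------------

#' Generate energy trajectories with a planted binding energy
#'
#' Builds the five per-snapshot energy streams one compound needs: the
#' complex, the receptor and ligand extracted from the complex snapshots,
#' and independent receptor and ligand runs. The complex energy is the sum
#' of the extracted component energies plus the planted binding energy plus
#' Gaussian snapshot noise; the independent runs equal the extracted
#' streams lowered by a planted relaxation offset (split 60/40 between
#' receptor and ligand), so relaxed-minus-rigid recovers the offset
#' exactly.
#'
#' @param spec a `SynthSpec`.
#' @param compound_id identifier (also names the RNG substream).
#' @param ddg_true planted binding energy, kcal/mol; defaults to the
#'   spec's non-binder value.
#' @return list of `EnergyTrajectory`: `complex`, `receptor_ext`,
#'   `ligand_ext`, `receptor_ind`, `ligand_ind`; attributes `ddg_true` and
#'   `relax_offset` carry the planted truth.
#' @export
make_energy_traj <- function(spec, compound_id,
                             ddg_true = spec$ddg_true_nonbinder) {
  stopifnot(inherits(spec, "SynthSpec"))
  n <- spec$n_energy_snapshots
  .with_substream(spec$seed, paste0("energy:", compound_id), {
    e_rec <- -12000 + rnorm(n, sd = 8)
    e_lig <- -150 + rnorm(n, sd = 3)
    eps <- rnorm(n, sd = spec$ddg_noise)
    e_cplx <- e_rec + e_lig + ddg_true + eps
    r_rec <- 0.6 * spec$relax_offset
    r_lig <- 0.4 * spec$relax_offset
    out <- list(
      complex = energy_trajectory(e_cplx, "complex",
                                  "extracted-from-complex",
                                  spec$timestep_ps),
      receptor_ext = energy_trajectory(e_rec, "receptor",
                                       "extracted-from-complex",
                                       spec$timestep_ps),
      ligand_ext = energy_trajectory(e_lig, "ligand",
                                     "extracted-from-complex",
                                     spec$timestep_ps),
      receptor_ind = energy_trajectory(e_rec - r_rec, "receptor",
                                       "independent-run", spec$timestep_ps),
      ligand_ind = energy_trajectory(e_lig - r_lig, "ligand",
                                     "independent-run", spec$timestep_ps))
    attr(out, "ddg_true") <- ddg_true
    attr(out, "relax_offset") <- spec$relax_offset
    out
  })
}

#' Write every synthetic artifact to a directory
#'
#' Emits the toy ensemble as a multi-model PDB, the library and score
#' tables as CSV, energy streams for the planted binders as CSV, and the
#' planted truths as separate side-car files (suffix `_truth`), which the
#' pipeline never reads.
#'
#' @param spec a `SynthSpec`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_synthetic_data <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dimer <- make_toy_dimer(spec)
  ens <- make_ensemble(dimer, spec)
  write_pdb(ens$ensemble, file.path(dir, "ensemble.pdb"))
  utils::write.csv(data.frame(frame = seq_along(ens$labels),
                              state = ens$labels),
                   file.path(dir, "ensemble_truth.csv"), row.names = FALSE)
  lib <- make_library(spec)
  utils::write.csv(lib[, setdiff(names(lib),
                                 c("true_pass", "true_violations"))],
                   file.path(dir, "library.csv"), row.names = FALSE)
  utils::write.csv(lib[, c("id", "true_pass", "true_violations")],
                   file.path(dir, "library_truth.csv"), row.names = FALSE)
  st <- make_score_tables(spec, lib$id)
  for (cf in names(st$tables)) {
    for (eng in c("A", "B")) {
      tab <- st$tables[[cf]][[eng]]
      utils::write.csv(
        data.frame(compound_id = tab$entries$id, score = tab$entries$score),
        file.path(dir, sprintf("scores_%s_engine%s.csv", cf, eng)),
        row.names = FALSE)
    }
  }
  writeLines(st$binders, file.path(dir, "binders_truth.txt"))
  for (b in utils::head(st$binders, 3)) {
    tr <- make_energy_traj(spec, b, ddg_true = spec$ddg_true_binder)
    df <- do.call(rbind, lapply(names(tr), function(nm) {
      t <- tr[[nm]]
      data.frame(compound_id = b, stream = nm, role = t$role,
                 source = t$source,
                 snapshot_ps = seq_along(t$energies) * t$timestep_ps,
                 energy_kcal_mol = t$energies)
    }))
    utils::write.csv(df, file.path(dir, sprintf("energies_%s.csv", b)),
                     row.names = FALSE)
  }
  invisible(dir)
}
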