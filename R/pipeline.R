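# End-to-end orchestration of the screening protocol on synthetic data:
# ensemble -> binding-site clustering -> pockets -> drug-likeness filter ->
# consensus docking -> binding-energy rescoring -> candidate selection.

#' Pipeline configuration
#'
#' All stage thresholds in one validated object. Unknown arguments are an
#' error (fail-fast: a silently ignored typo would corrupt a screen).
#'
#' @param seed master seed; also seeds the synthetic generator.
#' @param synth a `SynthSpec`; defaults to `synth_spec(seed)`.
#' @param cut_height Ward dendrogram cut for binding-site states, A.
#' @param population_radius radius for the population-density report, A.
#' @param druggability_floor pocket triage score floor.
#' @param n_conformations medoid conformations carried into docking.
#' @param top_n per-engine top-list size for the consensus.
#' @param ddg_window trailing snapshots averaged by the energy protocols.
#' @param ddg_threshold selection threshold, kcal/mol.
#' @param final_n cap on the final candidate list.
#' @param pocket_spacing grid spacing for pocket detection, A.
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1, synth = synth_spec(seed),
                            cut_height = 1.3, population_radius = 1.5,
                            druggability_floor = 0.80, n_conformations = 3,
                            top_n = 2000, ddg_window = 20,
                            ddg_threshold = -20, final_n = 51,
                            pocket_spacing = 1.0) {
  stopifnot(inherits(synth, "SynthSpec"), cut_height > 0,
            population_radius > 0, druggability_floor >= 0,
            druggability_floor <= 1, n_conformations >= 1, top_n >= 1,
            ddg_window >= 1, final_n >= 1)
  cfg <- list(seed = as.integer(seed), synth = synth,
              cut_height = cut_height,
              population_radius = population_radius,
              druggability_floor = druggability_floor,
              n_conformations = n_conformations, top_n = top_n,
              ddg_window = ddg_window, ddg_threshold = ddg_threshold,
              final_n = final_n, pocket_spacing = pocket_spacing)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a flat key=value file
#'
#' Lines of the form `key = value` (comments with `#`); keys must be
#' formals of [pipeline_config()], unknown keys are an error.
#'
#' @param path configuration file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")),
                 character(1))
  allowed <- setdiff(names(formals(pipeline_config)), "synth")
  bad <- setdiff(keys, allowed)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  args <- lapply(vals, function(v) as.numeric(v))
  names(args) <- keys
  do.call(pipeline_config, args)
}

.log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}

.run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the screening pipeline end-to-end on synthetic data
#'
#' Executes ensemble generation, trajectory validation (RMSD against the
#' average structure, C-alpha RMSF), binding-site Ward clustering with
#' medoid extraction and population density, pocket detection and
#' druggability triage near the planted mutation site, PPI-adapted
#' drug-likeness filtering, per-conformation two-engine consensus
#' intersection, rigid/relaxed binding-energy rescoring, and threshold
#' selection of the final candidates. Planted truths are used only to
#' report recovery statistics, never inside a stage's decision.
#'
#' @param config a `PipelineConfig`.
#' @param verbose log one line per stage.
#' @return object of class `RunReport`: per-stage `counts`, stage outputs
#'   (`clustering`, `pockets`, `consensus`, `candidates`, ...),
#'   `parameters`, `seed` and `timestamp`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  spec <- config$synth
  t0 <- Sys.time()

  dimer <- .run_stage("synthesize", make_toy_dimer(spec))
  ens <- .run_stage("synthesize", make_ensemble(dimer, spec))
  e <- ens$ensemble
  .log_stage(verbose, "synthesize", n_frames(e), " frames x ", n_atoms(e),
             " atoms, ", spec$k_states, " planted states")

  backbone <- select_atoms(dimer, atoms = "backbone")
  dyn <- .run_stage("dynamics", {
    avg <- average_structure(e, sel = backbone)
    frame_rmsd <- vapply(seq_len(n_frames(e)), function(f) {
      rmsd(get_coords(avg), get_coords(e, f), sel = backbone,
           superpose = TRUE)
    }, numeric(1))
    prof <- rmsf(e, sel = select_atoms(dimer, atoms = "CA"),
                 superpose_sel = backbone)
    list(mean_rmsd = mean(frame_rmsd), max_rmsd = max(frame_rmsd),
         mean_rmsf = mean(prof$rmsf), profile = prof)
  })
  .log_stage(verbose, "dynamics",
             sprintf("mean backbone RMSD vs average %.2f A, mean CA RMSF %.2f A",
                     dyn$mean_rmsd, dyn$mean_rmsf))

  cluster_out <- .run_stage("cluster", {
    m <- pairwise_rmsd_matrix(e, sel = ens$binding_site)
    cl <- ward_hac(m, cut_height = config$cut_height)
    n_conf <- min(config$n_conformations, length(cl$sizes))
    medoid_frames <- cl$medoids[seq_len(n_conf)]
    pop <- population_density(m, medoid_frames[1],
                              radius = config$population_radius)
    list(matrix = m, clustering = cl, medoid_frames = medoid_frames,
         population = pop)
  })
  .log_stage(verbose, "cluster", length(cluster_out$clustering$sizes),
             " clusters at cut ", config$cut_height, " A; ",
             cluster_out$population, " frames within ",
             config$population_radius,
             " A of the top medoid")

  site <- attr(dimer, "mutation_site")
  pocket_out <- .run_stage("pockets", {
    best <- frame_structure(e, cluster_out$medoid_frames[1])
    pockets <- detect_pockets(best, spacing = config$pocket_spacing)
    near <- pockets_near_residue(pockets, best, site$chain, site$resno,
                                 max_dist = 10)
    scores <- vapply(near, function(p) p$druggability, numeric(1))
    n_floor <- sum(scores > config$druggability_floor)
    selected <- if (n_floor > 0) {
      names(near)[scores > config$druggability_floor][
        which.max(vapply(near[scores > config$druggability_floor],
                         function(p) p$volume, numeric(1)))]
    } else if (length(near) > 0) names(near)[which.max(scores)]
    else NA_character_
    list(pockets = pockets, near = near, n_floor = n_floor,
         selected = selected)
  })
  .log_stage(verbose, "pockets", length(pocket_out$pockets), " pockets, ",
             length(pocket_out$near), " near ", site$chain, ":",
             site$resno, ", ", pocket_out$n_floor, " above score ",
             config$druggability_floor,
             if (pocket_out$n_floor == 0 && length(pocket_out$near) > 0)
               " (floor not met; best-scoring site pocket carried forward)"
             else "")

  lib <- .run_stage("filter", make_library(spec))
  filt <- .run_stage("filter", {
    open_cols <- setdiff(names(lib), c("true_pass", "true_violations"))
    ppi_druglike_filter(lib[, open_cols])
  })
  filtered_ids <- filt$id[filt$pass]
  .log_stage(verbose, "filter", length(filtered_ids), " of ", nrow(lib),
             " compounds pass the PPI drug-likeness filter")

  screen <- .run_stage("screen", {
    conf_labels <- sprintf("medoid_%d", cluster_out$medoid_frames)
    st <- make_score_tables(spec, filtered_ids,
                            conformations = conf_labels)
    per_conf <- lapply(st$tables, function(tt) {
      consensus_pair(tt$A, tt$B, n = config$top_n)
    })
    pooled <- pool_conformations(per_conf)
    list(tables = st, pooled = pooled)
  })
  .log_stage(verbose, "screen", "consensus per conformation: ",
             paste(screen$pooled$per_conformation, collapse = "/"),
             " (sum ", screen$pooled$sum_of_counts, ", union ",
             screen$pooled$union_size, ")")

  energy <- .run_stage("energy", {
    pooled_ids <- screen$pooled$pooled$id
    binders <- screen$tables$binders
    res <- do.call(rbind, lapply(pooled_ids, function(id) {
      truth <- if (id %in% binders) spec$ddg_true_binder
      else spec$ddg_true_nonbinder
      tr <- make_energy_traj(spec, id, ddg_true = truth)
      data.frame(id = id,
                 ddg_rigid = ddg_rigid(tr$complex, tr$receptor_ext,
                                       tr$ligand_ext,
                                       window = config$ddg_window),
                 ddg_relaxed = ddg_relaxed(tr$complex, tr$receptor_ind,
                                           tr$ligand_ind,
                                           window = config$ddg_window),
                 stringsAsFactors = FALSE)
    }))
    selected <- select_candidates(res, threshold = config$ddg_threshold,
                                  max_n = config$final_n)
    list(results = res, selected = selected)
  })
  .log_stage(verbose, "energy", nrow(energy$selected), " candidates at ",
             config$ddg_threshold, " kcal/mol (window ", config$ddg_window,
             ")")

  binders <- screen$tables$binders
  recovered <- sum(energy$selected$id %in% binders)
  counts <- list(
    frames = n_frames(e),
    clusters = length(cluster_out$clustering$sizes),
    population_within_radius = cluster_out$population,
    pockets = length(pocket_out$pockets),
    pockets_near_site = length(pocket_out$near),
    pockets_above_floor = pocket_out$n_floor,
    library = nrow(lib),
    filtered = length(filtered_ids),
    consensus_per_conformation = unname(screen$pooled$per_conformation),
    consensus_sum = screen$pooled$sum_of_counts,
    consensus_union = screen$pooled$union_size,
    ddg_selected = nrow(energy$selected),
    final = min(nrow(energy$selected), config$final_n),
    planted_binders = length(binders),
    binders_recovered = recovered)
  funnel <- c(counts$library, counts$filtered, counts$consensus_union,
              counts$ddg_selected, counts$final)
  if (any(diff(funnel) > 0))
    warning("funnel counts are not monotone nonincreasing: ",
            paste(funnel, collapse = " >= "))
  report <- list(counts = counts,
                 dynamics = dyn[c("mean_rmsd", "max_rmsd", "mean_rmsf")],
                 clustering = cluster_out$clustering,
                 pocket_table = pocket_table(pocket_out$pockets),
                 selected_pocket = pocket_out$selected,
                 consensus = screen$pooled,
                 ddg = energy$results,
                 candidates = energy$selected,
                 planted_binders = binders,
                 parameters = config[setdiff(names(config), "synth")],
                 synth_parameters = unclass(spec),
                 seed = config$seed,
                 timestamp = format(t0, "%Y-%m-%d %H:%M:%S"))
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  c <- x$counts
  cat("<RunReport> seed", x$seed, "\n")
  cat(sprintf("  ensemble: %d frames -> %d binding-site clusters (top medoid: %d frames within radius)\n",
              c$frames, c$clusters, c$population_within_radius))
  cat(sprintf("  pockets: %d detected, %d near site, %d above druggability floor\n",
              c$pockets, c$pockets_near_site, c$pockets_above_floor))
  cat(sprintf("  funnel: %d library -> %d filtered -> %d consensus union -> %d selected (final %d)\n",
              c$library, c$filtered, c$consensus_union, c$ddg_selected,
              c$final))
  cat(sprintf("  planted binders recovered: %d / %d\n",
              c$binders_recovered, c$planted_binders))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the machine-readable portion of a `RunReport` (counts, scalar
#' dynamics summaries, parameters, seed) as JSON. The wall-clock timestamp
#' is excluded so reports from identical seeds are byte-identical.
#'
#' @param report a `RunReport`.
#' @param path output file.
#' @param include_timestamp include the wall-clock stamp.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, include_timestamp = FALSE) {
  stopifnot(inherits(report, "RunReport"))
  out <- list(seed = report$seed, counts = report$counts,
              dynamics = report$dynamics,
              selected_pocket = report$selected_pocket,
              candidates = report$candidates,
              parameters = report$parameters,
              synth_parameters = report$synth_parameters)
  if (include_timestamp) out$timestamp <- report$timestamp
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
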