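#' Configuration for the docking pipeline
#'
#' Defaults follow the protocol: interface-pLDDT gate at 85, mobile-residue
#' threshold at 80, three temperature rungs at kT = 1.5/3/5 kcal/mol with
#' eight trajectories, 4 Angstrom / 8 degree rigid moves for the global
#' search, 1 Angstrom / 3 degree moves with 3:1 backbone:rigid weighting for
#' local refinement, energy-based clustering to five representatives, and
#' five final models ranked by interface score.
#'
#' @param gate_threshold interface-pLDDT gate (0-100).
#' @param mobile_threshold per-residue pLDDT below which residues are
#'   mobile.
#' @param min_run minimum mobile segment length.
#' @param ladder a [replica_ladder()].
#' @param global_moves,local_moves [move_schedule()]s for the two stages.
#' @param global_steps,local_steps Monte Carlo steps per trajectory.
#' @param swap_every,snapshot_every replica-exchange bookkeeping intervals.
#' @param energy_keep_fraction,cluster_rmsd,n_clusters clustering controls.
#' @param n_final_models number of ranked models to return.
#' @param score score model, function `pose -> energy`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gate_threshold = 85, mobile_threshold = 80,
                            min_run = 3, ladder = replica_ladder(),
                            global_moves = global_schedule(),
                            local_moves = local_schedule(),
                            global_steps = 5000, local_steps = 1000,
                            swap_every = 50, snapshot_every = 50,
                            energy_keep_fraction = 0.2, cluster_rmsd = 5,
                            n_clusters = 5, n_final_models = 5,
                            score = default_score) {
  stopifnot(gate_threshold >= 0, gate_threshold <= 100,
            mobile_threshold >= 0, mobile_threshold <= 100,
            global_steps > 0, local_steps > 0)
  structure(list(gate_threshold = gate_threshold,
                 mobile_threshold = mobile_threshold, min_run = min_run,
                 ladder = ladder, global_moves = global_moves,
                 local_moves = local_moves, global_steps = global_steps,
                 local_steps = local_steps, swap_every = swap_every,
                 snapshot_every = snapshot_every,
                 energy_keep_fraction = energy_keep_fraction,
                 cluster_rmsd = cluster_rmsd, n_clusters = n_clusters,
                 n_final_models = n_final_models, score = score),
            class = "pipeline_config")
}

#' Rank docking decoys by interface score
#'
#' Ascending interface score; ties broken by total energy, then by
#' provenance (input) order.
#'
#' @param decoys list of decoy records, each with `interface_score` and
#'   `energy`.
#' @param n number of models to keep.
#' @return The `n` best decoys, best first.
#' @export
rank_models <- function(decoys, n = length(decoys)) {
  if (length(decoys) == 0L) stop("no decoys to rank")
  iscore <- vapply(decoys, `[[`, numeric(1), "interface_score")
  energy <- vapply(decoys, `[[`, numeric(1), "energy")
  ord <- order(iscore, energy, seq_along(decoys))
  decoys[head(ord, n)]
}

#' Run the confidence-gated docking pipeline
#'
#' Implements the full flow: the interface-pLDDT gate decides between a
#' global rigid-body replica-exchange search (randomized start, 4 Angstrom /
#' 8 degree moves) followed by energy-based clustering to at most five
#' representatives and flexible local refinement of each, or direct local
#' refinement of the input pose (1 Angstrom / 3 degree moves, backbone moves
#' weighted 3:1 on mobile residues with pLDDT < 80). Final models are the
#' best `n_final_models` local decoys by interface score. Fully reproducible
#' from `seed`.
#'
#' @param model predicted complex as a `struct3d`.
#' @param partners partner spec string or parsed list.
#' @param confidence named pLDDT vector; defaults to the B-factor column.
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @return List of class `pipeline_report`: `gate` (interface report),
#'   `stages` run, `mobile` selection, decoy counts, `cluster_reps`,
#'   `final` ranked models (each with `pose`, `structure`,
#'   `interface_score`, `energy` and provenance), `seed` and `config`.
#' @export
run_docking_pipeline <- function(model, partners,
                                 confidence = confidence_from_bfactor(model),
                                 config = pipeline_config(), seed = 1) {
  sp <- split_partners(model, partners)
  gate_report <- interface_report(model, partners, profile = confidence,
                                  gate_threshold = config$gate_threshold)
  mobile <- select_mobile_residues(confidence, config$mobile_threshold,
                                   config$min_run)
  lig_chains <- chain_labels(sp$ligand)
  usable_mobile <- sum(mobile$segments$chain %in% lig_chains)
  if (usable_mobile == 0L) {
    warning("no mobile segments on the ligand partner: ",
            "local stage is rigid-body only")
  }
  start_pose <- new_pose(sp$receptor, sp$ligand)
  set.seed(seed %% .Machine$integer.max)
  stage_seeds <- sample.int(.Machine$integer.max - 1L,
                            2L + config$n_clusters)
  stages <- "gate"
  n_global <- 0L
  cluster_reps <- list()
  if (gate_report$gate == "GLOBAL") {
    global_res <- run_replica_exchange(
      start_pose, config$ladder, config$global_moves, config$score,
      n_steps = config$global_steps, swap_every = config$swap_every,
      snapshot_every = config$snapshot_every, mode = "global",
      seed = stage_seeds[1], randomize_start = TRUE)
    n_global <- length(global_res$decoys)
    cluster_reps <- cluster_decoys(global_res,
                                   config$energy_keep_fraction,
                                   config$cluster_rmsd, config$n_clusters)
    starts <- lapply(cluster_reps, decoy_to_pose, template = start_pose)
    stages <- c(stages, "global", "cluster")
    global_result <- global_res
  } else {
    starts <- list(start_pose)
    global_result <- NULL
  }
  local_decoys <- list()
  for (i in seq_along(starts)) {
    res <- run_replica_exchange(
      starts[[i]], config$ladder, config$local_moves, config$score,
      n_steps = config$local_steps, swap_every = config$swap_every,
      snapshot_every = config$snapshot_every, mobile = mobile,
      mode = "local", seed = stage_seeds[1L + i])
    for (d in res$decoys) {
      d$start_index <- i
      d$interface_score <- interface_score(
        decoy_to_pose(d, start_pose), config$score)
      local_decoys[[length(local_decoys) + 1L]] <- d
    }
  }
  stages <- c(stages, "local", "rank")
  ranked <- rank_models(local_decoys, config$n_final_models)
  final <- lapply(ranked, function(d) {
    pose <- decoy_to_pose(d, start_pose)
    list(pose = pose, structure = pose_complex(pose),
         interface_score = d$interface_score, energy = d$energy,
         trajectory = d$trajectory, replica = d$replica, step = d$step,
         start_index = d$start_index, seed = d$seed)
  })
  out <- list(gate = gate_report, stages = stages, mobile = mobile,
              n_global_decoys = n_global,
              n_local_decoys = length(local_decoys),
              cluster_reps = cluster_reps,
              global_result = global_result,
              local_decoys = local_decoys,
              final = final, seed = seed, config = config)
  class(out) <- "pipeline_report"
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_report> gate %s; stages: %s; %d global / ",
                     "%d local decoys; %d final models (best interface ",
                     "score %.2f)\n"),
              x$gate$gate, paste(x$stages, collapse = " -> "),
              x$n_global_decoys, x$n_local_decoys, length(x$final),
              if (length(x$final)) x$final[[1]]$interface_score else NA))
  invisible(x)
}

#' Write the ranked models of a pipeline report to PDB files
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths (`model_1.pdb`, ...).
#' @export
write_pipeline_models <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(report$final)) {
    p <- file.path(dir, sprintf("model_%d.pdb", i))
    write_structure(report$final[[i]]$structure, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
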