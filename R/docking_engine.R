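#' Coarse-grained cross-partner contact score
#'
#' The default pluggable score model: over all receptor-ligand Cbeta pairs
#' (Calpha for glycine), pairs closer than `d_clash` pay a harmonic clash
#' penalty `k_rep * (d_clash - d)^2`, pairs between `d_clash` and
#' `d_contact` gain a constant contact reward `-eps`, and distant pairs
#' contribute nothing. Lower is better; the score is invariant under any
#' global rigid transform of the whole complex.
#'
#' @param pose a `dock_pose`.
#' @param d_clash clash distance (Angstrom).
#' @param d_contact contact distance (Angstrom).
#' @param k_rep clash force constant (score units per square Angstrom).
#' @param eps per-contact reward (score units).
#' @return Energy in score units.
#' @export
default_score <- function(pose, d_clash = 4, d_contact = 8, k_rep = 5,
                          eps = 1) {
  lig <- realize_ligand(pose)
  cpp_pair_potential(pose$rec_cb, lig[pose$lig_cb_rows, , drop = FALSE],
                     d_clash, d_contact, k_rep, eps)
}

#' Interface score of a pose
#'
#' Binding score relative to the separated partners: energy of the complex
#' minus the energy with the ligand displaced 500 Angstrom along the
#' receptor-to-ligand center-of-mass axis. For strictly short-ranged score
#' models this equals the complex energy; for arbitrary score models it
#' removes any internal offset.
#'
#' @param pose a `dock_pose`.
#' @param score score model, a function `pose -> energy`.
#' @return Interface energy in score units.
#' @export
interface_score <- function(pose, score = default_score) {
  e_bound <- score(pose)
  axis <- ligand_centroid(pose) - colMeans(pose$rec_heavy)
  nrm <- sqrt(sum(axis * axis))
  axis <- if (nrm < 1e-9) c(1, 0, 0) else axis / nrm
  far <- pose
  far$transform <- compose_translation(pose$transform, axis * 500)
  e_bound - score(far)
}

#' Metropolis acceptance test
#'
#' Accepts an energy change `delta_e` at temperature `kT` with probability
#' `min(1, exp(-delta_e / kT))`, consuming one uniform variate from the
#' current R random stream only when the move is uphill.
#'
#' @param delta_e proposed energy change (score units).
#' @param kT temperature in the same units.
#' @return Logical: accept the move.
#' @export
metropolis_accept <- function(delta_e, kT) {
  if (kT <= 0) stop("kT must be positive")
  if (delta_e <= 0) return(TRUE)
  runif(1) < exp(-delta_e / kT)
}

#' Temperature ladder for replica exchange
#'
#' @param kT_values strictly increasing temperatures, default
#'   c(1.5, 3, 5) kcal/mol.
#' @param n_trajectories number of independent trajectories, default 8.
#' @return List of class `replica_ladder`.
#' @export
replica_ladder <- function(kT_values = c(1.5, 3, 5), n_trajectories = 8) {
  if (length(kT_values) < 2L) stop("ladder needs at least two rungs")
  if (any(diff(kT_values) <= 0)) stop("kT values must be strictly increasing")
  if (any(kT_values <= 0)) stop("kT values must be positive")
  structure(list(kT_values = as.numeric(kT_values),
                 n_trajectories = as.integer(n_trajectories)),
            class = "replica_ladder")
}

#' Replica-exchange swap test between adjacent rungs
#'
#' Exchange of configurations between adjacent temperature rungs is
#' accepted with probability `min(1, exp((beta_i - beta_j) (E_i - E_j)))`,
#' `beta = 1/kT` — the standard parallel-tempering criterion, symmetric
#' under relabeling of the two states.
#'
#' @param state_i,state_j lists with elements `energy`, `kT` and `rung`
#'   (integer ladder index); the rungs must be adjacent.
#' @return Logical: exchange the configurations.
#' @export
attempt_swap <- function(state_i, state_j) {
  if (abs(state_i$rung - state_j$rung) != 1L) {
    stop("swaps are only attempted between adjacent rungs")
  }
  arg <- (1 / state_i$kT - 1 / state_j$kT) *
    (state_i$energy - state_j$energy)
  if (arg >= 0) return(TRUE)
  runif(1) < exp(arg)
}

#' Run temperature replica-exchange Monte Carlo docking
#'
#' Runs `ladder$n_trajectories` independent trajectories, each holding one
#' configuration per temperature rung. At every step each rung proposes one
#' move (rigid-body only in `"global"` mode; in `"local"` mode a categorical
#' draw between backbone and rigid moves with the schedule weights) and
#' applies the Metropolis test at its own temperature. Every `swap_every`
#' steps configuration exchanges are attempted between adjacent rungs,
#' alternating even/odd pairs. Snapshots of the coldest rung are recorded
#' every `snapshot_every` steps. The run is fully reproducible from `seed`:
#' a master stream spawns one sub-seed per trajectory.
#'
#' @param start starting `dock_pose`.
#' @param ladder a [replica_ladder()].
#' @param schedule a [move_schedule()].
#' @param score score model, function `pose -> energy` (lower is better).
#' @param n_steps Monte Carlo steps per trajectory.
#' @param swap_every steps between swap attempts.
#' @param snapshot_every steps between coldest-rung snapshots.
#' @param mobile optional [select_mobile_residues()] selection (local mode).
#' @param mode `"global"` (rigid only) or `"local"`.
#' @param seed integer master seed.
#' @param randomize_start randomize the ligand orientation independently at
#'   the start of each trajectory (used by the global stage).
#' @return List of class `docking_result` with `decoys` (each holding the
#'   ligand conformation, transform, energy and provenance), `acceptance`
#'   and `swap_acceptance` summaries, and the run settings.
#' @export
run_replica_exchange <- function(start, ladder, schedule, score = default_score,
                                 n_steps = 5000, swap_every = 50,
                                 snapshot_every = 50, mobile = NULL,
                                 mode = c("global", "local"), seed = 1,
                                 randomize_start = FALSE) {
  mode <- match.arg(mode)
  stopifnot(n_steps > 0)
  n_rungs <- length(ladder$kT_values)
  kT <- ladder$kT_values
  use_backbone <- mode == "local" && !is.null(mobile) &&
    length(mobile$residues) > 0L
  p_backbone <- if (use_backbone) {
    schedule$backbone_weight /
      (schedule$backbone_weight + schedule$rigid_weight)
  } else 0
  set.seed(seed %% .Machine$integer.max)
  traj_seeds <- sample.int(.Machine$integer.max - 1L, ladder$n_trajectories)

  decoys <- list()
  acc <- matrix(0, ladder$n_trajectories, n_rungs)
  swap_att <- swap_acc <- 0L
  for (traj in seq_len(ladder$n_trajectories)) {
    set.seed(traj_seeds[traj])
    p0 <- if (randomize_start) randomize_orientation(start) else start
    configs <- rep(list(p0), n_rungs)
    e0 <- score(p0)
    if (!is.finite(e0)) stop("non-finite starting energy in trajectory ", traj)
    energies <- rep(e0, n_rungs)
    n_acc <- integer(n_rungs)
    for (step in seq_len(n_steps)) {
      for (r in seq_len(n_rungs)) {
        prop <- if (use_backbone && runif(1) < p_backbone) {
          perturb_backbone(configs[[r]], mobile, schedule)
        } else {
          perturb_rigid(configs[[r]], schedule)
        }
        e_new <- score(prop)
        if (!is.finite(e_new)) {
          stop("non-finite energy at trajectory ", traj, ", step ", step,
               ", rung ", r)
        }
        if (metropolis_accept(e_new - energies[r], kT[r])) {
          configs[[r]] <- prop
          energies[r] <- e_new
          n_acc[r] <- n_acc[r] + 1L
        }
      }
      if (step %% swap_every == 0L) {
        first <- if ((step %/% swap_every) %% 2L == 1L) 1L else 2L
        for (i in if (first > n_rungs - 1L) integer(0)
                  else seq(first, n_rungs - 1L, by = 2L)) {
          swap_att <- swap_att + 1L
          ok <- attempt_swap(list(energy = energies[i], kT = kT[i], rung = i),
                             list(energy = energies[i + 1L], kT = kT[i + 1L],
                                  rung = i + 1L))
          if (ok) {
            swap_acc <- swap_acc + 1L
            tmp <- configs[[i]]
            configs[[i]] <- configs[[i + 1L]]
            configs[[i + 1L]] <- tmp
            energies[c(i, i + 1L)] <- energies[c(i + 1L, i)]
          }
        }
      }
      if (step %% snapshot_every == 0L) {
        cold <- configs[[1L]]
        decoys[[length(decoys) + 1L]] <- list(
          transform = cold$transform,
          lig_local = cold$lig_local,
          torsion_state = cold$torsion_state,
          energy = energies[1L],
          trajectory = traj, replica = 1L, step = step,
          seed = traj_seeds[traj])
      }
    }
    acc[traj, ] <- n_acc / n_steps
  }
  structure(list(decoys = decoys,
                 acceptance = acc,
                 swap_acceptance = if (swap_att > 0) swap_acc / swap_att
                                   else NA_real_,
                 ladder = ladder, schedule = schedule, mode = mode,
                 n_steps = n_steps, seed = seed,
                 template = start),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf(paste0("<docking_result> %s mode: %d decoys from %d ",
                     "trajectories x %d steps, best energy %.2f\n"),
              x$mode, length(x$decoys), x$ladder$n_trajectories, x$n_steps,
              if (length(x$decoys)) min(decoy_energies(x$decoys)) else NA))
  invisible(x)
}

#' @rdname cluster_decoys
#' @export
decoy_energies <- function(decoys) {
  vapply(decoys, `[[`, numeric(1), "energy")
}

#' Rebuild a full pose from a decoy record
#'
#' @param decoy one decoy entry from a `docking_result`.
#' @param template the pose the run started from (receptor caches reused).
#' @return A `dock_pose`.
#' @export
decoy_to_pose <- function(decoy, template) {
  template$transform <- decoy$transform
  template$lig_local <- decoy$lig_local
  template$lig_centroid_local <- colMeans(decoy$lig_local)
  template$torsion_state <- decoy$torsion_state
  template
}

decoy_ligand_ca <- function(decoy, template) {
  apply_rigid(decoy$lig_local[template$lig_ca_rows, , drop = FALSE],
              decoy$transform)
}

#' Energy-based greedy clustering of docking decoys
#'
#' Keeps the lowest-energy `energy_keep_fraction` of the decoys, then
#' clusters greedily: the best-energy remaining decoy seeds a cluster and
#' removes every decoy within `rmsd_threshold` ligand-Calpha RMSD of it
#' (the receptor is common to all decoys, so no superposition is needed);
#' repeated up to `n_clusters` times. Representatives are returned
#' best-energy first. Fewer than `n_clusters` clusters may result.
#'
#' @param result a `docking_result`, or a list of decoys (then `template`
#'   is required).
#' @param energy_keep_fraction fraction of lowest-energy decoys to keep.
#' @param rmsd_threshold cluster radius in Angstrom (ligand RMSD).
#' @param n_clusters maximum number of cluster representatives.
#' @param template pose template (defaults to `result$template`).
#' @return List of decoy records (the representatives).
#' @export
cluster_decoys <- function(result, energy_keep_fraction = 0.2,
                           rmsd_threshold = 5, n_clusters = 5,
                           template = NULL) {
  if (inherits(result, "docking_result")) {
    decoys <- result$decoys
    if (is.null(template)) template <- result$template
  } else {
    decoys <- result
    if (is.null(template)) stop("template pose required for raw decoy lists")
  }
  if (length(decoys) == 0L) stop("no decoys to cluster")
  e <- decoy_energies(decoys)
  keep_n <- max(1L, ceiling(length(decoys) * energy_keep_fraction))
  keep <- order(e)[seq_len(keep_n)]
  pool <- decoys[keep]
  cas <- lapply(pool, decoy_ligand_ca, template = template)
  reps <- list()
  remaining <- seq_along(pool)
  while (length(remaining) > 0L && length(reps) < n_clusters) {
    # pool is energy-sorted, so the first remaining decoy is the best
    seed_i <- remaining[1L]
    reps[[length(reps) + 1L]] <- pool[[seed_i]]
    ref_ca <- cas[[seed_i]]
    dists <- vapply(remaining, function(i) {
      sqrt(mean(rowSums((cas[[i]] - ref_ca)^2)))
    }, numeric(1))
    remaining <- remaining[dists > rmsd_threshold]
  }
  reps
}
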