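test_that("contact score matches brute force and handles limiting cases", {
  toy <- make_toy_complex(seed = 31)
  # far-apart partners score zero
  set.seed(1)
  far <- make_decoy(toy$native, 80)
  expect_equal(default_score(far), 0)
  # random poses equal the brute-force all-pairs evaluation
  for (k in 1:5) {
    set.seed(k)
    d <- make_decoy(toy$native, runif(1, 2, 15))
    lig_cb <- realize_ligand(d)[d$lig_cb_rows, , drop = FALSE]
    expect_equal(default_score(d),
                 brute_pair_potential(d$rec_cb, lig_cb), tolerance = 1e-12)
  }
  # single Cbeta pair at 6 A scores exactly -eps
  a <- ca_structure(matrix(c(0, 0, 0), 1), "A")
  b <- ca_structure(matrix(c(6, 0, 0), 1), "B")
  pose <- new_pose(a, b)
  expect_equal(default_score(pose), -1)
})

test_that("interface score is the bound-minus-separated energy", {
  toy <- make_toy_complex(seed = 32)
  set.seed(2)
  far <- make_decoy(toy$native, 80)
  expect_equal(interface_score(far), 0)
  # bound clash-free toy: -n_contacts * eps
  sp <- split_partners(toy$complex, "A_B")
  n_pairs <- brute_cb_contacts_range(sp$receptor, sp$ligand, 4, 8)
  expect_equal(interface_score(toy$native), -n_pairs)
  expect_true(is.finite(interface_score(toy$native, funnel_score_factory(toy$native))))
})

test_that("randomized orientations are uniform, in contact, reproducible", {
  toy <- make_toy_complex(seed = 33)
  set.seed(10)
  p1 <- randomize_orientation(toy$native)
  set.seed(10)
  p2 <- randomize_orientation(toy$native)
  expect_identical(realize_ligand(p1), realize_ligand(p2))
  # slide contract: contact within 5.5 A
  set.seed(11)
  for (k in 1:20) {
    p <- randomize_orientation(toy$native)
    d <- redock:::cpp_min_cross_dist(p$rec_heavy, realize_ligand(p))
    expect_lte(d, 5.5)
  }
  # rotation angles follow the uniform-rotation density
  set.seed(12)
  angles <- replicate(10000, quat_rotation_angle(random_unit_quat()))
  cdf <- function(x) (x - sin(x)) / pi
  ks <- suppressWarnings(stats::ks.test(angles, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("rigid perturbations have the calibrated magnitudes", {
  toy <- make_toy_complex(seed = 34)
  sched <- global_schedule() # 4 A, 8 degrees
  # rotations act about the centroid, so centroid displacement = translation
  set.seed(20)
  c0 <- colMeans(realize_ligand(toy$native))
  trans <- replicate(10000, {
    p <- perturb_rigid(toy$native, sched)
    sqrt(sum((colMeans(realize_ligand(p)) - c0)^2))
  })
  expect_equal(mean(trans), 4, tolerance = 0.05)
  # quaternion norm preserved
  set.seed(21)
  p <- perturb_rigid(toy$native, sched)
  expect_equal(sum(p$transform$q^2), 1, tolerance = 1e-9)
  # zero-magnitude schedule is the identity
  zs <- move_schedule(trans_mag = 0, rot_mag = 0)
  expect_identical(realize_ligand(perturb_rigid(toy$native, zs)),
                   realize_ligand(toy$native))
})

test_that("backbone moves touch only downstream ligand atoms", {
  toy <- make_toy_complex(seed = 35)
  conf <- make_confidence(toy$complex, baseline = 90,
                          segments = data.frame(start = 26, end = 30, value = 60))
  mobile <- select_mobile_residues(conf) # residues B:6..B:10 (26..30 overall)
  expect_equal(nrow(mobile$segments), 1L)
  expect_equal(mobile$segments$chain, "B")
  sched <- local_schedule()
  set.seed(30)
  p <- perturb_backbone(toy$native, mobile, sched)
  moved <- which(rowSums(abs(p$lig_local - toy$native$lig_local)) > 1e-12)
  lig_ids <- toy$native$lig_atom_ids
  first_seg_row <- min(which(lig_ids == mobile$segments$start))
  expect_true(all(moved >= first_seg_row))
  expect_gt(length(moved), 0)
  # zero torsion magnitude leaves coordinates untouched
  zs <- move_schedule(1, 3, backbone_weight = 3, torsion_mag = 0)
  pz <- perturb_backbone(toy$native, mobile, zs)
  expect_lt(max(abs(pz$lig_local - toy$native$lig_local)), 1e-9)
  # empty selection is a no-op
  empty <- select_mobile_residues(make_confidence(toy$complex, baseline = 95))
  expect_identical(perturb_backbone(toy$native, empty, sched)$lig_local,
                   toy$native$lig_local)
})

test_that("Metropolis criterion is exact in the limits and in frequency", {
  expect_true(metropolis_accept(-1, 1.5))
  expect_true(metropolis_accept(0, 1.5))
  expect_error(metropolis_accept(1, 0), "positive")
  set.seed(40)
  acc <- mean(replicate(20000, metropolis_accept(1.5, 1.5)))
  expect_equal(acc, exp(-1), tolerance = 0.02)
})

test_that("swap criterion accepts equal energies and validates adjacency", {
  s1 <- list(energy = -5, kT = 1.5, rung = 1L)
  s2 <- list(energy = -5, kT = 3, rung = 2L)
  expect_true(attempt_swap(s1, s2))
  expect_true(attempt_swap(s2, s1)) # symmetric under relabeling
  s3 <- list(energy = -5, kT = 5, rung = 3L)
  expect_error(attempt_swap(s1, s3), "adjacent")
  # downhill-in-the-exchange always accepted: colder rung holds higher energy
  hot_low <- list(energy = -10, kT = 3, rung = 2L)
  cold_high <- list(energy = 2, kT = 1.5, rung = 1L)
  expect_true(attempt_swap(cold_high, hot_low))
})

test_that("replica exchange is reproducible and conserves rigid geometry", {
  toy <- make_toy_complex(seed = 36)
  fs <- funnel_score_factory(toy$native)
  ladder <- replica_ladder(n_trajectories = 2)
  r1 <- run_replica_exchange(toy$native, ladder, global_schedule(), fs,
                             n_steps = 300, seed = 99, randomize_start = TRUE)
  r2 <- run_replica_exchange(toy$native, ladder, global_schedule(), fs,
                             n_steps = 300, seed = 99, randomize_start = TRUE)
  expect_identical(lapply(r1$decoys, `[[`, "transform"),
                   lapply(r2$decoys, `[[`, "transform"))
  expect_identical(decoy_energies(r1$decoys), decoy_energies(r2$decoys))
  # recorded energies equal re-scored snapshots (no drift)
  for (d in r1$decoys[c(1, 5, 10)]) {
    expect_equal(fs(decoy_to_pose(d, toy$native)), d$energy, tolerance = 1e-9)
  }
  # rigid global moves never alter intra-ligand distances
  d0 <- stats::dist(realize_ligand(toy$native))
  for (d in r1$decoys[c(2, 8, 12)]) {
    di <- stats::dist(realize_ligand(decoy_to_pose(d, toy$native)))
    expect_lt(max(abs(di - d0)), 1e-9)
  }
})

test_that("a flat landscape accepts every move", {
  toy <- make_toy_complex(seed = 37)
  flat <- function(pose) 0
  res <- run_replica_exchange(toy$native, replica_ladder(n_trajectories = 2),
                              global_schedule(), flat, n_steps = 100, seed = 5)
  expect_true(all(res$acceptance == 1))
  expect_equal(res$swap_acceptance, 1)
})

test_that("greedy energy clustering separates distinct pose groups", {
  toy <- make_toy_complex(seed = 38)
  mk <- function(pose, energy, step) {
    list(transform = pose$transform, lig_local = pose$lig_local,
         torsion_state = pose$torsion_state, energy = energy,
         trajectory = 1L, replica = 1L, step = step, seed = 1L)
  }
  # two tight groups ~20 A apart
  set.seed(50)
  g1 <- make_decoy(toy$native, 1)
  g2 <- make_decoy(toy$native, 22)
  jitter_pose <- function(p) {
    q <- p
    q$transform <- redock:::compose_translation(p$transform, rnorm(3, 0, 0.2))
    q
  }
  decoys <- c(lapply(1:5, function(i) mk(jitter_pose(g1), -10 + i * 0.1, i)),
              lapply(1:5, function(i) mk(jitter_pose(g2), -8 + i * 0.1, 5 + i)))
  reps <- cluster_decoys(decoys, energy_keep_fraction = 1, rmsd_threshold = 5,
                         n_clusters = 5, template = toy$native)
  expect_length(reps, 2L)
  expect_equal(reps[[1]]$energy, -9.9) # best energy seeds the first cluster
  # single decoy returns itself; identical poses collapse to one
  expect_length(cluster_decoys(decoys[1], template = toy$native,
                               energy_keep_fraction = 1), 1L)
  same <- lapply(1:6, function(i) mk(g1, -5, i))
  expect_length(cluster_decoys(same, energy_keep_fraction = 1,
                               template = toy$native), 1L)
})
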