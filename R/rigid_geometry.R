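## Quaternion and rigid-transform primitives. Quaternions are length-4
## numeric vectors c(w, x, y, z), kept unit-normalized.

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         nrow = 3, byrow = TRUE)
}

quat_from_axis_angle <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis * axis))
  s <- sin(angle_rad / 2)
  quat_normalize(c(cos(angle_rad / 2), axis * s))
}

#' Uniform random rotation
#'
#' Samples a unit quaternion uniformly on the 3-sphere (normalized 4-vector
#' of independent standard normals), giving a rotation uniform over SO(3).
#' Uses the current R random number stream.
#'
#' @return Unit quaternion c(w, x, y, z).
#' @export
random_unit_quat <- function() {
  q <- rnorm(4)
  while (sum(q * q) < 1e-12) q <- rnorm(4)
  quat_normalize(q)
}

#' Rotation angle of a quaternion, in radians
#' @param q unit quaternion.
#' @return Angle in \[0, pi\].
#' @export
quat_rotation_angle <- function(q) 2 * acos(min(1, abs(q[1])))

random_unit_vector <- function() {
  v <- rnorm(3)
  while (sum(v * v) < 1e-12) v <- rnorm(3)
  v / sqrt(sum(v * v))
}

#' Rigid transform (rotation then translation)
#'
#' Represents x' = R(q) x + t with a unit quaternion `q` and translation `t`.
#'
#' @param q unit quaternion, default identity.
#' @param t translation 3-vector in Angstrom.
#' @return List of class `rigid_transform`.
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  structure(list(q = quat_normalize(q), t = as.numeric(t)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param tr a [rigid_transform()].
#' @return Transformed n x 3 matrix.
#' @export
apply_rigid <- function(coords, tr) {
  out <- coords %*% t(quat_to_matrix(tr$q))
  out[, 1L] <- out[, 1L] + tr$t[1L]
  out[, 2L] <- out[, 2L] + tr$t[2L]
  out[, 3L] <- out[, 3L] + tr$t[3L]
  out
}

## lean internal constructor: same fields as rigid_transform(), no checks
new_tr <- function(q, t) {
  tr <- list(q = q, t = t)
  class(tr) <- "rigid_transform"
  tr
}

## compose: rotate by q2 about point p, applied after tr
compose_rotation_about <- function(tr, q2, p) {
  r2 <- quat_to_matrix(q2)
  new_tr(q = quat_normalize(quat_multiply(q2, tr$q)),
         t = as.numeric(r2 %*% (tr$t - p)) + p)
}

compose_translation <- function(tr, dt) {
  new_tr(q = tr$q, t = tr$t + dt)
}

## Rodrigues rotation of selected points about an axis through `origin`.
rotate_about_axis <- function(coords, origin, axis, angle_rad) {
  axis <- axis / sqrt(sum(axis * axis))
  centered <- sweep(coords, 2, origin)
  k <- axis
  cosa <- cos(angle_rad)
  sina <- sin(angle_rad)
  cross <- cbind(k[2] * centered[, 3] - k[3] * centered[, 2],
                 k[3] * centered[, 1] - k[1] * centered[, 3],
                 k[1] * centered[, 2] - k[2] * centered[, 1])
  dotk <- as.numeric(centered %*% k)
  rot <- centered * cosa + cross * sina + outer(dotk * (1 - cosa), k)
  sweep(rot, 2, origin, `+`)
}

## NeRF atom placement: position of atom d given three predecessors with
## bond |c-d|, angle b-c-d (deg) and dihedral a-b-c-d (deg).
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n * n))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Docking pose: fixed receptor plus transformed ligand
#'
#' A pose holds the receptor rigidly fixed and realizes the ligand as its
#' internal (local-frame) coordinates under a rigid transform. Backbone
#' (torsion) perturbations modify the local-frame coordinates of the ligand;
#' rigid moves modify the transform. Coordinate views needed by scoring are
#' pre-cached.
#'
#' @param receptor,ligand `struct3d` partners (ligand in its starting
#'   placement; the initial transform is the identity).
#' @return List of class `dock_pose`.
#' @export
new_pose <- function(receptor, ligand) {
  rec_heavy <- get_coords(receptor, "heavy")
  rec_cb <- get_coords(receptor, "cb")
  lig_all <- atom_coords(ligand)
  la <- ligand$atoms
  lig_ids <- atom_residue_ids(la)
  lig_res <- unique(lig_ids)
  cb_rows <- vapply(lig_res, function(u) {
    idx <- which(lig_ids == u)
    cb <- idx[la$elety[idx] == "CB"]
    if (length(cb) == 0L) cb <- idx[la$elety[idx] == "CA"]
    if (length(cb) == 0L) NA_integer_ else cb[1L]
  }, integer(1))
  ca_rows <- vapply(lig_res, function(u) {
    idx <- which(lig_ids == u & la$elety == "CA")
    if (length(idx) == 0L) NA_integer_ else idx[1L]
  }, integer(1))
  bb_rows <- which(la$elety %in% c("N", "CA", "C", "O"))
  structure(list(
    receptor = receptor,
    ligand_base = ligand,
    rec_heavy = rec_heavy$coords,
    rec_cb = rec_cb$coords,
    rec_bb = get_coords(receptor, "backbone")$coords,
    lig_local = lig_all,
    lig_centroid_local = colMeans(lig_all),
    lig_atom_ids = lig_ids,
    lig_res_ids = lig_res,
    lig_cb_rows = cb_rows[!is.na(cb_rows)],
    lig_ca_rows = ca_rows[!is.na(ca_rows)],
    lig_bb_rows = bb_rows,
    transform = rigid_transform(),
    torsion_state = list(phi = numeric(0), psi = numeric(0))
  ), class = "dock_pose")
}

#' @export
print.dock_pose <- function(x, ...) {
  cat(sprintf("<dock_pose> receptor %d res, ligand %d res, |t| = %.2f A\n",
              n_residues(x$receptor), length(x$lig_res_ids),
              sqrt(sum(x$transform$t^2))))
  invisible(x)
}

#' Realized ligand coordinates of a pose
#' @param pose a `dock_pose`.
#' @return n_atoms x 3 matrix of ligand coordinates in the receptor frame.
#' @export
realize_ligand <- function(pose) apply_rigid(pose$lig_local, pose$transform)

#' Realized complex structure of a pose
#'
#' @param pose a `dock_pose`.
#' @return `struct3d` of receptor plus realized ligand, receptor first.
#' @export
pose_complex <- function(pose) {
  lig <- set_coords(pose$ligand_base, realize_ligand(pose))
  new_structure(rbind(pose$receptor$atoms, lig$atoms),
                model_id = pose$receptor$model_id)
}

ligand_centroid <- function(pose) {
  c0 <- pose$lig_centroid_local
  if (is.null(c0)) c0 <- colMeans(pose$lig_local)
  as.numeric(quat_to_matrix(pose$transform$q) %*% c0) + pose$transform$t
}

#' Randomize the spatial orientation of the ligand partner
#'
#' Gives the ligand a rotation drawn uniformly over SO(3), places it along a
#' uniformly random direction from the receptor center well outside contact,
#' then slides it back toward the receptor in `step` Angstrom increments
#' until the closest cross-partner heavy-atom distance reaches
#' `contact_dist`. Used to start unbiased global docking trajectories.
#'
#' @param pose a `dock_pose`.
#' @param contact_dist slide-in stop distance (Angstrom).
#' @param step slide step (Angstrom).
#' @return The randomized `dock_pose`.
#' @export
randomize_orientation <- function(pose, contact_dist = 5, step = 0.5) {
  q <- random_unit_quat()
  u <- random_unit_vector()
  rec_center <- colMeans(pose$rec_heavy)
  lig_c0 <- colMeans(pose$lig_local)
  rec_span <- max(sqrt(rowSums(sweep(pose$rec_heavy, 2, rec_center)^2)))
  lig_span <- max(sqrt(rowSums(sweep(pose$lig_local, 2, lig_c0)^2)))
  start_dist <- rec_span + lig_span + 20
  # rotation about ligand centroid, centroid placed along u
  r <- quat_to_matrix(q)
  target <- rec_center + u * start_dist
  tr <- rigid_transform(q = q, t = target - as.numeric(r %*% lig_c0))
  pose$transform <- tr
  for (iter in seq_len(100000L)) {
    d <- cpp_min_cross_dist(pose$rec_heavy, realize_ligand(pose))
    if (d <= contact_dist) break
    pose$transform <- compose_translation(pose$transform, -u * step)
  }
  pose$torsion_state <- list(phi = numeric(0), psi = numeric(0))
  pose
}

#' Move schedule for Monte Carlo perturbations
#'
#' Magnitudes of the rigid-body and backbone moves and the relative weights
#' with which move types are drawn. The global search uses 4 Angstrom / 8
#' degree rigid moves and no backbone moves; local refinement uses 1
#' Angstrom / 3 degree rigid moves with backbone moves weighted 3:1 over
#' rigid-body moves and 3 degree torsion perturbations.
#'
#' @param trans_mag expected translation magnitude (Angstrom).
#' @param rot_mag rotation-angle standard deviation (degrees).
#' @param backbone_weight,rigid_weight relative draw weights.
#' @param torsion_mag phi/psi offset standard deviation (degrees).
#' @return List of class `move_schedule`.
#' @export
move_schedule <- function(trans_mag, rot_mag, backbone_weight = 0,
                          rigid_weight = 1, torsion_mag = 3) {
  stopifnot(trans_mag >= 0, rot_mag >= 0, torsion_mag >= 0,
            backbone_weight >= 0, rigid_weight >= 0,
            backbone_weight + rigid_weight > 0)
  structure(list(trans_mag = trans_mag, rot_mag = rot_mag,
                 backbone_weight = backbone_weight,
                 rigid_weight = rigid_weight, torsion_mag = torsion_mag),
            class = "move_schedule")
}

#' @rdname move_schedule
#' @export
global_schedule <- function(trans_mag = 4, rot_mag = 8) {
  move_schedule(trans_mag, rot_mag, backbone_weight = 0, rigid_weight = 1)
}

#' @rdname move_schedule
#' @export
local_schedule <- function(trans_mag = 1, rot_mag = 3, torsion_mag = 3) {
  move_schedule(trans_mag, rot_mag, backbone_weight = 3, rigid_weight = 1,
                torsion_mag = torsion_mag)
}

## E|N(0, sigma I3)| = sigma * 2 * sqrt(2/pi); scale so the expected
## translation magnitude equals trans_mag.
CHI3_MEAN <- 2 * sqrt(2 / pi)

#' Rigid-body Monte Carlo perturbation
#'
#' Adds a Gaussian translation (isotropic, expected magnitude
#' `schedule$trans_mag`) and a rotation about a uniformly random axis
#' through the current ligand centroid with Gaussian angle (sd
#' `schedule$rot_mag` degrees).
#'
#' @param pose a `dock_pose`.
#' @param schedule a [move_schedule()].
#' @return The perturbed `dock_pose`.
#' @export
perturb_rigid <- function(pose, schedule) {
  if (schedule$rot_mag > 0) {
    axis <- random_unit_vector()
    angle <- rnorm(1, 0, schedule$rot_mag) * pi / 180
    q <- quat_from_axis_angle(axis, angle)
    pose$transform <- compose_rotation_about(pose$transform, q,
                                             ligand_centroid(pose))
  }
  if (schedule$trans_mag > 0) {
    dt <- rnorm(3, 0, schedule$trans_mag / CHI3_MEAN)
    pose$transform <- compose_translation(pose$transform, dt)
  }
  pose
}

#' Backbone perturbation of a mobile segment
#'
#' Simplified directed backbone move: one mobile segment on the ligand is
#' chosen at random and every residue in it receives Gaussian phi/psi
#' offsets (sd `schedule$torsion_mag` degrees). Each torsion rotation
#' propagates to all downstream atoms of that chain (no loop closure).
#' Mobile segments on receptor chains are ignored (the receptor is the
#' fixed partner of the pose). With an empty usable selection the pose is
#' returned unchanged.
#'
#' @param pose a `dock_pose`.
#' @param mobile a [select_mobile_residues()] result.
#' @param schedule a [move_schedule()].
#' @return The perturbed `dock_pose`.
#' @export
perturb_backbone <- function(pose, mobile, schedule) {
  segs <- mobile$segments
  lig_chains <- unique(pose$ligand_base$atoms$chain)
  segs <- segs[segs$chain %in% lig_chains, , drop = FALSE]
  if (nrow(segs) == 0L) return(pose)
  k <- if (nrow(segs) == 1L) 1L else sample.int(nrow(segs), 1L)
  seg_ids <- seq_res_ids(pose, segs$start[k], segs$end[k])
  for (id in seg_ids) {
    dphi <- rnorm(1, 0, schedule$torsion_mag) * pi / 180
    dpsi <- rnorm(1, 0, schedule$torsion_mag) * pi / 180
    pose <- apply_torsion(pose, id, dphi, dpsi)
    pose$torsion_state$phi[id] <- (pose$torsion_state$phi[id] %||% 0) + dphi
    pose$torsion_state$psi[id] <- (pose$torsion_state$psi[id] %||% 0) + dpsi
  }
  pose
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

seq_res_ids <- function(pose, start_id, end_id) {
  ids <- pose$lig_res_ids
  i <- match(start_id, ids)
  j <- match(end_id, ids)
  if (is.na(i) || is.na(j)) stop("mobile segment residues not in ligand")
  ids[i:j]
}

## Rotate downstream atoms about the phi (N-CA) and psi (CA-C) axes of one
## ligand residue, in the ligand local frame.
apply_torsion <- function(pose, res_id, dphi, dpsi) {
  la <- pose$ligand_base$atoms
  ids <- pose$lig_atom_ids
  ridx <- which(ids == res_id)
  chain <- la$chain[ridx[1]]
  chain_rows <- which(la$chain == chain)
  after_rows <- chain_rows[chain_rows > max(ridx)]
  n_row <- ridx[la$elety[ridx] == "N"][1]
  ca_row <- ridx[la$elety[ridx] == "CA"][1]
  c_row <- ridx[la$elety[ridx] == "C"][1]
  o_row <- ridx[la$elety[ridx] == "O"]
  if (is.na(n_row) || is.na(ca_row) || is.na(c_row)) {
    stop("residue ", res_id, " lacks backbone atoms for torsion move")
  }
  x <- pose$lig_local
  if (dphi != 0) {
    # phi rotation moves everything bonded past CA: sidechain + C, O, and
    # all downstream residues of the chain
    move <- c(setdiff(ridx, c(n_row, ca_row)), after_rows)
    x[move, ] <- rotate_about_axis(x[move, , drop = FALSE], x[n_row, ],
                                   x[ca_row, ] - x[n_row, ], dphi)
  }
  if (dpsi != 0) {
    move <- c(o_row, after_rows)
    x[move, ] <- rotate_about_axis(x[move, , drop = FALSE], x[ca_row, ],
                                   x[c_row, ] - x[ca_row, ], dpsi)
  }
  pose$lig_local <- x
  pose$lig_centroid_local <- colMeans(x)
  pose
}
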