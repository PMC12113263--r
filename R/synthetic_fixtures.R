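## Synthetic toy complexes with planted native poses. Backbones are built at
## ideal geometry (N-CA 1.46, CA-C 1.52, C-N 1.33 Angstrom, standard angles)
## by internal-coordinate chain extension; enough realism for geometric and
## sampling tests, with explicit Cbeta atoms so contact metrics never hit the
## glycine fallback unless asked for.

build_chain <- function(n_res, phi, psi, chain = "A", resname = "ALA",
                        bfactor = 90) {
  if (length(phi) == 1L) phi <- rep(phi, n_res)
  if (length(psi) == 1L) psi <- rep(psi, n_res)
  stopifnot(n_res >= 2L, length(phi) == n_res, length(psi) == n_res)
  has_cb <- resname != "GLY"
  # seed atoms of residue 1
  n1 <- c(0, 0, 0)
  ca1 <- c(1.46, 0, 0)
  c1 <- place_atom(c(-1, 1, 0), n1, ca1, 1.52, 111.2, phi[1])
  coords <- list(N = n1, CA = ca1, C = c1)
  rows <- list()
  add <- function(resno, elety, xyz, elesy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, ins = "", resid = resname,
      elety = elety, elesy = elesy, x = xyz[1], y = xyz[2], z = xyz[3],
      b = bfactor, stringsAsFactors = FALSE)
  }
  prev <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      n_i <- place_atom(prev$N, prev$CA, prev$C, 1.33, 114.0, psi[i - 1L])
      ca_i <- place_atom(prev$CA, prev$C, n_i, 1.46, 123.0, 180)
      c_i <- place_atom(prev$C, n_i, ca_i, 1.52, 111.2, phi[i])
      # carbonyl O of the previous residue, trans to the new N
      o_prev <- place_atom(n_i, prev$CA, prev$C, 1.23, 121.0, 180)
      add(i - 1L, "O", o_prev, "O")
      prev <- list(N = n_i, CA = ca_i, C = c_i)
    }
    add(i, "N", prev$N, "N")
    add(i, "CA", prev$CA, "C")
    add(i, "C", prev$C, "C")
    if (has_cb) {
      cb <- place_atom(prev$N, prev$C, prev$CA, 1.53, 110.5, 122.5)
      add(i, "CB", cb, "C")
    }
  }
  # O of the last residue from its own psi
  o_last <- place_atom(prev$N, prev$CA, prev$C, 1.23, 121.0, psi[n_res] + 180)
  add(n_res, "O", o_last, "O")
  at <- do.call(rbind, rows)
  # restore canonical atom order N, CA, C, O, CB within each residue
  order_key <- match(at$elety, c("N", "CA", "C", "O", "CB"))
  at <- at[order(at$resno, order_key), ]
  rownames(at) <- NULL
  new_structure(at)
}

## rigid-align a structure: center on origin, principal axis along z
align_principal <- function(s) {
  xyz <- atom_coords(s)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  v <- svd(xc)$v
  if (det(v) < 0) v[, 3] <- -v[, 3]
  # first principal direction -> z
  rot <- cbind(v[, 2], v[, 3], v[, 1])
  set_coords(s, xc %*% rot)
}

geometry_angles <- function(geometry, n_res) {
  switch(geometry,
         ideal_helix = list(phi = rep(-57, n_res), psi = rep(-47, n_res)),
         extended = list(phi = rep(-139, n_res), psi = rep(135, n_res)),
         random_walk = list(phi = runif(n_res, -180, -30),
                            psi = runif(n_res, -90, 180)),
         stop("unknown geometry: ", geometry))
}

#' Generate a toy two-partner complex with a planted native pose
#'
#' Builds two ideal-geometry peptide partners (chain A = receptor, chain B =
#' ligand), placed side by side so that the native pose is clash-free (no
#' cross-partner heavy-atom pair under 2.5 Angstrom) with at least five
#' cross-partner Cbeta pairs within 8 Angstrom. Deterministic for a given
#' seed.
#'
#' @param n_receptor,n_ligand residues per partner (at least 8).
#' @param geometry `"ideal_helix"`, `"extended"` or `"random_walk"`.
#' @param native_gap closest cross-partner heavy-atom distance of the
#'   planted pose (Angstrom).
#' @param resname 3-letter residue type for all residues (`"GLY"` gives a
#'   Cbeta-free fixture).
#' @param bfactor B-factor (pLDDT) written on every atom.
#' @param seed integer seed (used by `"random_walk"` geometry).
#' @return List with `complex` (`struct3d`, chains A then B), `native`
#'   (a `dock_pose` at the planted pose), `partners` (spec string `"A_B"`).
#' @export
make_toy_complex <- function(n_receptor = 20, n_ligand = 16,
                             geometry = c("ideal_helix", "extended",
                                          "random_walk"),
                             native_gap = 4.5, resname = "ALA",
                             bfactor = 90, seed = 1) {
  geometry <- match.arg(geometry)
  if (n_receptor < 8L || n_ligand < 8L) {
    stop("need at least 8 residues per partner")
  }
  if (native_gap <= 2.5) stop("native_gap must exceed the 2.5 A clash limit")
  set.seed(seed)
  ga <- geometry_angles(geometry, n_receptor)
  gb <- geometry_angles(geometry, n_ligand)
  a <- align_principal(build_chain(n_receptor, ga$phi, ga$psi, chain = "A",
                                   resname = resname, bfactor = bfactor))
  b <- align_principal(build_chain(n_ligand, gb$phi, gb$psi, chain = "B",
                                   resname = resname, bfactor = bfactor))
  # antiparallel: flip ligand about the x axis
  xb <- atom_coords(b)
  xb[, 2] <- -xb[, 2]
  xb[, 3] <- -xb[, 3]
  b <- set_coords(b, xb)
  # slide ligand in along +x until the planted gap is reached
  xa <- atom_coords(a)
  span <- max(xa[, 1]) - min(atom_coords(b)[, 1]) + native_gap + 10
  offset <- span
  repeat {
    bt <- sweep(atom_coords(b), 2, c(offset, 0, 0), `+`)
    d <- cpp_min_cross_dist(xa, bt)
    if (d <= native_gap || offset <= 0) break
    offset <- offset - 0.1
  }
  b <- set_coords(b, sweep(atom_coords(b), 2, c(offset, 0, 0), `+`))
  cmplx <- new_structure(rbind(a$atoms, b$atoms))
  sp <- split_partners(cmplx, "A_B")
  # generation contract
  dmin <- cpp_min_cross_dist(atom_coords(sp$receptor),
                             atom_coords(sp$ligand))
  ncont <- count_interface_contacts(sp$receptor, sp$ligand, 8)
  if (dmin < 2.5) stop("generated native pose has clashes (min ",
                       round(dmin, 2), " A)")
  if (ncont < 5L) stop("generated native pose has only ", ncont,
                       " Cbeta pairs within 8 A")
  list(complex = cmplx, native = new_pose(sp$receptor, sp$ligand),
       partners = "A_B")
}

#' Ligand RMSD of a pose relative to the planted native pose
#'
#' Backbone RMSD of the realized ligand against the native ligand. The
#' receptor is common and fixed, so no superposition is involved.
#'
#' @param pose,native `dock_pose` objects sharing the same partners.
#' @return RMSD in Angstrom.
#' @export
pose_lrms <- function(pose, native) {
  x <- realize_ligand(pose)[pose$lig_bb_rows, , drop = FALSE]
  y <- realize_ligand(native)[native$lig_bb_rows, , drop = FALSE]
  sqrt(mean(rowSums((x - y)^2)))
}

#' Generate a rigid decoy at a controlled ligand-RMSD from the native pose
#'
#' Perturbs the ligand rigidly (random translation plus rotation) and
#' rescales the perturbation until the measured ligand RMSD falls within
#' 10% of `lrms_target`. A target of 0 returns the native pose.
#'
#' @param native a `dock_pose` (planted native).
#' @param lrms_target target ligand RMSD (Angstrom).
#' @param max_attempts attempts before giving up.
#' @return A `dock_pose` decoy.
#' @export
make_decoy <- function(native, lrms_target, max_attempts = 1000) {
  stopifnot(lrms_target >= 0)
  if (lrms_target == 0) return(native)
  tol <- 0.1 * lrms_target
  for (attempt in seq_len(max_attempts)) {
    u <- random_unit_vector()
    axis <- random_unit_vector()
    angle0 <- runif(1, 0, 20) * pi / 180
    s <- 1
    prev <- native
    for (iter in 1:40) {
      cand <- native
      q <- quat_from_axis_angle(axis, angle0 * s)
      cand$transform <- compose_rotation_about(cand$transform, q,
                                               ligand_centroid(cand))
      cand$transform <- compose_translation(cand$transform,
                                            u * lrms_target * s)
      l <- pose_lrms(cand, native)
      if (abs(l - lrms_target) <= tol) return(cand)
      if (l > 0) s <- s * lrms_target / l
      prev <- cand
    }
  }
  stop("could not reach target ligand RMSD of ", lrms_target, " A")
}

#' Synthetic per-residue confidence profile
#'
#' Baseline pLDDT everywhere, overridden on planted low-confidence segments,
#' with optional Gaussian noise; values are clipped to \[0, 100\].
#'
#' @param structure the `struct3d` the profile describes.
#' @param baseline baseline pLDDT value.
#' @param segments optional data.frame with columns `start`, `end`
#'   (1-based residue positions) and `value`.
#' @param noise_sd Gaussian noise standard deviation.
#' @return Named pLDDT vector in structure residue order.
#' @export
make_confidence <- function(structure, baseline = 90, segments = NULL,
                            noise_sd = 0) {
  ids <- residue_ids(structure)
  v <- rep(baseline, length(ids))
  if (!is.null(segments)) {
    for (k in seq_len(nrow(segments))) {
      s <- segments$start[k]
      e <- segments$end[k]
      if (s < 1L || e > length(ids) || s > e) {
        stop("segment [", s, ",", e, "] out of range")
      }
      v[s:e] <- segments$value[k]
    }
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  setNames(pmin(100, pmax(0, v)), ids)
}

#' Score model with a planted funnel at the native pose
#'
#' Returns a score model equal to [default_score()] plus a Gaussian basin
#' centered on the planted native pose:
#' `score(pose) = default_score(pose) - depth * exp(-Lrms^2 / (2 width^2))`
#' where Lrms is the ligand backbone RMSD to the native. The default depth
#' (150 score units) is far larger than both the hottest ladder temperature
#' and the spread of the contact term, so the planted basin is the global
#' minimum of the landscape; the default width (6 Angstrom) makes the basin
#' wide enough to capture trajectories diffusing over the partner surface
#' while keeping the minimum sharply at the native pose. This provides a
#' known answer for validating the replica-exchange sampler.
#'
#' @param native a `dock_pose` (planted native).
#' @param width basin width (Angstrom).
#' @param depth basin depth (score units).
#' @return Function `pose -> energy`.
#' @export
funnel_score_factory <- function(native, width = 6, depth = 150) {
  stopifnot(width > 0, depth > 0)
  nat_bb <- realize_ligand(native)[native$lig_bb_rows, , drop = FALSE]
  bb_rows <- native$lig_bb_rows
  force(width); force(depth)
  function(pose) {
    x <- realize_ligand(pose)
    l2 <- mean(rowSums((x[bb_rows, , drop = FALSE] - nat_bb)^2))
    cpp_pair_potential(pose$rec_cb, x[pose$lig_cb_rows, , drop = FALSE],
                       4, 8, 5, 1) - depth * exp(-l2 / (2 * width^2))
  }
}

#' Write a toy fixture to disk (PDB + confidence JSON)
#'
#' Emits the complex PDB, the native-pose PDB and a ColabFold-style scores
#' JSON for a synthetic confidence profile; used by the command-line
#' `make-fixture` entry point and handy for demos.
#'
#' @param dir output directory (created if needed).
#' @param profile optional confidence profile; default from B-factors.
#' @param ... passed to [make_toy_complex()].
#' @return Invisibly, the list of written paths.
#' @export
write_toy_fixture <- function(dir, profile = NULL, ...) {
  toy <- make_toy_complex(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(profile)) profile <- confidence_from_bfactor(toy$complex)
  paths <- list(
    complex = file.path(dir, "complex.pdb"),
    native = file.path(dir, "native.pdb"),
    scores = file.path(dir, "scores.json"))
  write_structure(toy$complex, paths$complex)
  write_structure(pose_complex(toy$native), paths$native)
  jsonlite::write_json(list(plddt = as.numeric(profile)), paths$scores,
                       auto_unbox = FALSE, digits = NA)
  invisible(paths)
}
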