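test_that("native contact detection matches brute force", {
  set.seed(61)
  for (k in 1:10) {
    r <- rand_structure(12, chain = "A", box = 14)
    l <- rand_structure(12, chain = "B", box = 14)
    got <- native_contacts(r, l, 5)
    expect_setequal(paste(got$receptor, got$ligand, sep = "|"),
                    brute_contact_pairs(r, l, 5))
  }
  a <- ca_structure(matrix(c(0, 0, 0), 1), "A")
  b <- ca_structure(matrix(c(4.9, 0, 0), 1), "B")
  expect_equal(nrow(native_contacts(a, b, 5)), 1L)
  expect_equal(nrow(native_contacts(a, set_coords(b, atom_coords(b) + 100), 5)), 0L)
})

test_that("fnat spans the identity, disjoint and half-overlap cases", {
  toy <- make_toy_complex(seed = 62)
  expect_equal(fnat(toy$complex, toy$complex, "A_B"), 1.0)
  set.seed(3)
  far <- pose_complex(make_decoy(toy$native, 60))
  expect_equal(fnat(far, toy$complex, "A_B"), 0.0)
  # constructed half overlap: 2 of 4 native contacts preserved
  rec <- ca_structure(matrix(c(0, 0, 0, 10, 0, 0, 20, 0, 0, 30, 0, 0),
                             4, byrow = TRUE), "A")
  lig_ref <- ca_structure(matrix(c(0, 4, 0, 10, 4, 0, 20, 4, 0, 30, 4, 0),
                                 4, byrow = TRUE), "B")
  lig_mod <- ca_structure(matrix(c(0, 4, 0, 10, 4, 0, 20, 40, 0, 30, 40, 0),
                                 4, byrow = TRUE), "B")
  ref <- new_structure(rbind(rec$atoms, lig_ref$atoms))
  mod <- new_structure(rbind(rec$atoms, lig_mod$atoms))
  expect_equal(fnat(mod, ref, "A_B"), 0.5)
  # a reference without contacts is rejected
  apart <- new_structure(rbind(rec$atoms,
                               set_coords(lig_ref, atom_coords(lig_ref) + 500)$atoms))
  expect_error(fnat(mod, apart, "A_B"), "native contacts")
})

test_that("interface RMSD vanishes for identity and rigid copies", {
  toy <- make_toy_complex(seed = 63)
  expect_lt(interface_rmsd(toy$complex, toy$complex, "A_B"), 1e-12)
  set.seed(4)
  moved <- random_rigid_copy(toy$complex)
  expect_lt(interface_rmsd(moved, toy$complex, "A_B"), 1e-9)
  # displaced ligand: equals an independently coded Kabsch fit (bio3d)
  d <- make_decoy(toy$native, 3)
  model <- pose_complex(d)
  got <- interface_rmsd(model, toy$complex, "A_B")
  expect_gt(got, 0.3)
  # oracle: bio3d::rot.lsq over the same backbone interface atoms
  sp_r <- split_partners(toy$complex, "A_B")
  iface <- find_interface_residues(sp_r$receptor, sp_r$ligand, 10)
  bb_ref <- get_coords(toy$complex, "backbone")
  keep <- bb_ref$residue %in% iface
  xr <- bb_ref$coords[keep, ]
  xm <- get_coords(model, "backbone")$coords[keep, ]
  fitted <- matrix(bio3d::rot.lsq(xx = t(xm), yy = t(xr)), ncol = 3,
                   byrow = TRUE)
  oracle <- sqrt(mean(rowSums((fitted - xr)^2)))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("ligand RMSD reflects pure translations exactly", {
  toy <- make_toy_complex(seed = 64)
  expect_lt(ligand_rmsd(toy$complex, toy$complex, "A_B"), 1e-12)
  # translate the ligand by exactly 5 A, receptor untouched
  shifted <- toy$native
  shifted$transform <- rigid_transform(t = c(0, 0, 5))
  expect_equal(ligand_rmsd(pose_complex(shifted), toy$complex, "A_B"), 5,
               tolerance = 1e-9)
  # random decoy: equals the two-step oracle (receptor fit, ligand RMSD)
  set.seed(6)
  d <- make_decoy(toy$native, 7)
  model <- pose_complex(d)
  got <- ligand_rmsd(model, toy$complex, "A_B")
  bb_ref <- get_coords(toy$complex, "backbone")
  bb_mod <- get_coords(model, "backbone")
  is_rec <- grepl("^A:", bb_ref$residue)
  fit <- kabsch_superpose(bb_mod$coords[is_rec, ], bb_ref$coords[is_rec, ])
  lig_fit <- apply_superposition(bb_mod$coords[!is_rec, ], fit)
  oracle <- sqrt(mean(rowSums((lig_fit - bb_ref$coords[!is_rec, ])^2)))
  expect_equal(got, oracle, tolerance = 1e-9)
  # receptor fixed here, so this also equals the planted pose_lrms
  expect_equal(got, pose_lrms(d, toy$native), tolerance = 1e-9)
})

test_that("DockQ closed forms, monotonicity and CAPRI bins are exact", {
  expect_equal(dockq(1, 0, 0), 1.0)
  expect_equal(dockq(0, 1.5, 8.5), 1 / 3)
  expect_lt(dockq(0, 1e6, 1e6), 1e-6)
  # monotone in each component
  expect_gt(dockq(0.8, 1, 2), dockq(0.5, 1, 2))
  expect_gt(dockq(0.5, 1, 2), dockq(0.5, 3, 2))
  expect_gt(dockq(0.5, 1, 2), dockq(0.5, 1, 6))
  # CAPRI classes at and around the printed bin edges
  expect_equal(capri_class(0.22), "incorrect")
  expect_equal(capri_class(0.23), "incorrect")
  expect_equal(capri_class(0.24), "acceptable")
  expect_equal(capri_class(0.49), "acceptable")
  expect_equal(capri_class(0.5), "medium")
  expect_equal(capri_class(0.79), "medium")
  expect_equal(capri_class(0.8), "high")
})

test_that("joint identity and rigid invariance hold for all quality metrics", {
  for (geom in c("ideal_helix", "extended")) {
    toy <- make_toy_complex(geometry = geom, seed = 65)
    qm <- quality_metrics(toy$complex, toy$complex, "A_B")
    expect_equal(qm$fnat, 1)
    expect_lt(qm$irms, 1e-9)
    expect_lt(qm$lrms, 1e-9)
    expect_equal(qm$dockq, 1, tolerance = 1e-9)
    expect_equal(qm$capri_class, "high")
    expect_true(qm$success)
  }
  # metrics are invariant under a global rigid transform of the model
  toy <- make_toy_complex(seed = 66)
  set.seed(8)
  d <- make_decoy(toy$native, 4)
  model <- pose_complex(d)
  qm1 <- quality_metrics(model, toy$complex, "A_B")
  set.seed(9)
  qm2 <- quality_metrics(random_rigid_copy(model), toy$complex, "A_B")
  expect_equal(qm1$fnat, qm2$fnat)
  expect_equal(qm1$irms, qm2$irms, tolerance = 1e-6)
  expect_equal(qm1$lrms, qm2$lrms, tolerance = 1e-6)
  expect_equal(qm1$dockq, qm2$dockq, tolerance = 1e-6)
})
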