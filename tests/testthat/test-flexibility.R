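test_that("residue mapping handles identity, truncation and substitutions", {
  toy <- make_toy_complex(seed = 21)
  s <- toy$complex
  m <- map_residues(s, s)
  expect_equal(m$pairs$id_a, m$pairs$id_b)
  expect_equal(unname(m$coverage), c(1, 1))

  # two N-terminal residues removed from chain A
  at <- s$atoms
  drop <- at$chain == "A" & at$resno <= 2
  trunc <- new_structure(at[!drop, , drop = FALSE])
  m2 <- map_residues(s, trunc)
  expect_equal(nrow(m2$pairs), n_residues(s) - 2L)

  # an internal point substitution stays mapped
  at2 <- s$atoms
  at2$resid[at2$chain == "A" & at2$resno == 10] <- "VAL"
  sub <- new_structure(at2)
  m3 <- map_residues(s, sub)
  expect_true("A:10" %in% m3$pairs$id_a)
  expect_equal(nrow(m3$pairs), n_residues(s))

  # grossly different sequences are refused
  at3 <- s$atoms
  at3$resid <- "LEU"
  expect_error(map_residues(s, new_structure(at3)), "identity")
})

test_that("Kabsch superposition recovers exact fits and is optimal", {
  set.seed(42)
  a <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_lt(kabsch_superpose(a, a)$rmsd, 1e-12)
  # exact recovery of a planted rigid motion, proper rotation
  tr <- rigid_transform(q = random_unit_quat(), t = rnorm(3, 0, 8))
  b <- apply_rigid(a, tr)
  fit <- kabsch_superpose(a, b)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(a[1:2, ], b[1:2, ]), "3 points")
  expect_error(kabsch_superpose(a, b[1:5, ]), "mismatch")
  # never beaten by random rigid fits
  b2 <- matrix(rnorm(30, sd = 5), 10, 3)
  best <- kabsch_superpose(a, b2)$rmsd
  for (k in 1:100) {
    trk <- rigid_transform(q = random_unit_quat(), t = rnorm(3, 0, 5))
    expect_gte(sqrt(mean(rowSums((apply_rigid(a, trk) - b2)^2))) + 1e-12, best)
  }
})

test_that("per-residue RMSD isolates local deformation after superposition", {
  toy <- make_toy_complex(seed = 22)
  sp <- split_partners(toy$complex, "A_B")
  a <- sp$receptor
  m <- map_residues(a, a)
  expect_true(all(per_residue_rmsd(a, a, m) < 1e-12))
  # rigid whole-body motion vanishes
  set.seed(5)
  moved <- random_rigid_copy(a)
  expect_true(all(per_residue_rmsd(a, moved, map_residues(a, moved)) < 1e-9))
  # one residue displaced by 3 A dominates the profile
  at <- a$atoms
  target <- at$resno == 10
  at$x[target] <- at$x[target] + 3
  bent <- new_structure(at)
  prr <- per_residue_rmsd(a, bent, map_residues(a, bent))
  expect_equal(unname(prr["A:10"]), 3, tolerance = 0.35)
  expect_lt(median(prr[names(prr) != "A:10"]), 0.5)
  expect_equal(names(which.max(prr)), "A:10")
})

test_that("LDDT equals the analytic single-pair value and is rigid-invariant", {
  # two residues: 5 A in reference, 5.7 A in model -> dD = 0.7 -> 0.75
  ref <- ca_structure(matrix(c(0, 0, 0, 5, 0, 0), 2, byrow = TRUE))
  mod <- ca_structure(matrix(c(0, 0, 0, 5.7, 0, 0), 2, byrow = TRUE))
  m <- map_residues(mod, ref)
  out <- lddt(mod, ref, m)
  expect_identical(out$global, 0.75)
  expect_identical(unname(out$per_residue), c(0.75, 0.75))
  # identity scores exactly 1
  toy <- make_toy_complex(seed = 23)
  mm <- map_residues(toy$complex, toy$complex)
  idt <- lddt(toy$complex, toy$complex, mm)
  expect_identical(idt$global, 1)
  expect_true(all(idt$per_residue == 1))
  # invariant under rigid transforms of either structure
  set.seed(9)
  noisy <- set_coords(toy$complex,
                      atom_coords(toy$complex) + rnorm(nrow(toy$complex$atoms) * 3, 0, 0.8))
  base <- lddt(noisy, toy$complex, mm)$global
  expect_equal(lddt(random_rigid_copy(noisy), toy$complex, mm)$global, base,
               tolerance = 1e-9)
  expect_equal(lddt(noisy, random_rigid_copy(toy$complex), mm)$global, base,
               tolerance = 1e-9)
  # no pairs inside the radius is an error
  sparse_r <- ca_structure(matrix(c(0, 0, 0, 50, 0, 0), 2, byrow = TRUE))
  sparse_m <- ca_structure(matrix(c(0, 0, 0, 51, 0, 0), 2, byrow = TRUE))
  expect_error(lddt(sparse_m, sparse_r, map_residues(sparse_m, sparse_r)),
               "inclusion radius")
})

test_that("LDDT decreases with increasing coordinate noise", {
  toy <- make_toy_complex(seed = 24)
  mm <- map_residues(toy$complex, toy$complex)
  n3 <- nrow(toy$complex$atoms) * 3
  sigmas <- c(0.1, 0.5, 1, 2, 5)
  means <- sapply(sigmas, function(s) {
    mean(sapply(1:10, function(k) {
      set.seed(1000 * s + k)
      noisy <- set_coords(toy$complex, atom_coords(toy$complex) + rnorm(n3, 0, s))
      lddt(noisy, toy$complex, mm)$global
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("mobile segment selection applies threshold and minimum run length", {
  ids <- sprintf("A:%d", 1:5)
  prof <- setNames(c(90, 75, 75, 75, 90), ids)
  sel <- select_mobile_residues(prof, 80, 3)
  expect_equal(nrow(sel$segments), 1L)
  expect_equal(sel$residues, ids[2:4])
  # all confident -> empty
  expect_length(select_mobile_residues(setNames(rep(85, 5), ids), 80, 3)$residues, 0)
  # run shorter than min_run discarded, longer kept
  ids2 <- sprintf("A:%d", 1:12)
  prof2 <- setNames(c(90, 70, 70, 90, 70, 70, 70, 70, 70, 90, 90, 90), ids2)
  sel2 <- select_mobile_residues(prof2, 80, 3)
  expect_equal(nrow(sel2$segments), 1L)
  expect_equal(sel2$residues, ids2[5:9])
  # runs do not cross chain boundaries
  ids3 <- c("A:9", "A:10", "B:1", "B:2")
  sel3 <- select_mobile_residues(setNames(rep(60, 4), ids3), 80, 3)
  expect_equal(nrow(sel3$segments), 0L)
  # union property: kept residues are exactly the sub-threshold long runs
  set.seed(77)
  for (k in 1:10) {
    v <- setNames(runif(30, 60, 100), sprintf("A:%d", 1:30))
    sel <- select_mobile_residues(v, 80, 3)
    low <- which(v < 80)
    runs <- split(low, cumsum(c(1, diff(low) != 1)))
    manual <- unlist(runs[vapply(runs, length, 1L) >= 3], use.names = FALSE)
    expect_setequal(sel$residues, names(v)[manual])
  }
})
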