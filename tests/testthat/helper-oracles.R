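# Independent brute-force oracles and random fixture builders. These are
# deliberately written as plain double/quadruple loops straight from the
# definitions, so they share no code path with the package implementations
# they check.

# random structure of n residues, each with 1-3 "heavy" atoms near a random
# residue center inside a cubic box
rand_structure <- function(n, chain = "A", box = 20, atoms_per_res = NULL,
                           b = 90) {
  rows <- list()
  for (i in seq_len(n)) {
    ctr <- runif(3, 0, box)
    k <- if (is.null(atoms_per_res)) sample(1:3, 1) else atoms_per_res
    names_k <- c("CA", "CB", "CG")[seq_len(k)]
    for (j in seq_len(k)) {
      xyz <- ctr + rnorm(3, 0, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, ins = "", resid = "ALA",
        elety = names_k[j], elesy = "C",
        x = xyz[1], y = xyz[2], z = xyz[3], b = b,
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows))
}

# CA-only structure from a coordinate matrix
ca_structure <- function(coords, chain = "A", b = 90, resid = "ALA") {
  n <- nrow(coords)
  new_structure(data.frame(
    chain = chain, resno = seq_len(n), ins = "", resid = resid,
    elety = "CA", elesy = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3], b = b,
    stringsAsFactors = FALSE))
}

# brute-force interface residues: any heavy-atom cross distance <= cutoff
brute_interface_residues <- function(receptor, ligand, cutoff = 8) {
  ra <- receptor$atoms
  la <- ligand$atoms
  rid <- sprintf("%s:%s%s", ra$chain, ra$resno, ra$ins)
  lid <- sprintf("%s:%s%s", la$chain, la$resno, la$ins)
  hits <- character(0)
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (d <= cutoff) hits <- c(hits, rid[i], lid[j])
    }
  }
  unique(hits)
}

# brute-force Cbeta (fallback CA) residue-pair contact count
brute_cb_contacts <- function(receptor, ligand, cutoff = 5) {
  cb_of <- function(s) {
    a <- s$atoms
    ids <- sprintf("%s:%s%s", a$chain, a$resno, a$ins)
    out <- list()
    for (u in unique(ids)) {
      idx <- which(ids == u)
      cb <- idx[a$elety[idx] == "CB"]
      if (length(cb) == 0) cb <- idx[a$elety[idx] == "CA"]
      if (length(cb) > 0) out[[u]] <- c(a$x[cb[1]], a$y[cb[1]], a$z[cb[1]])
    }
    out
  }
  rc <- cb_of(receptor)
  lc <- cb_of(ligand)
  count <- 0L
  for (p in rc) for (q in lc) {
    if (sqrt(sum((p - q)^2)) <= cutoff) count <- count + 1L
  }
  count
}

# brute-force LDDT from the defining equations: ordered pairs i != j with
# reference distance below the inclusion radius; pair score = fraction of
# tolerances passed by |D_true - D_pred|
brute_lddt <- function(ca_model, ca_ref, radius = 10,
                       tolerances = c(0.5, 1, 2, 4)) {
  n <- nrow(ca_ref)
  total <- 0
  npairs <- 0
  per_res <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s_i <- 0
    n_i <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      dt <- sqrt(sum((ca_ref[i, ] - ca_ref[j, ])^2))
      if (dt >= radius) next
      dp <- sqrt(sum((ca_model[i, ] - ca_model[j, ])^2))
      dd <- abs(dt - dp)
      sc <- 0
      for (tol in tolerances) if (dd < tol) sc <- sc + 1
      sc <- sc / length(tolerances)
      total <- total + sc
      npairs <- npairs + 1
      s_i <- s_i + sc
      n_i <- n_i + 1
    }
    if (n_i > 0) per_res[i] <- s_i / n_i
  }
  list(global = total / npairs, per_residue = per_res)
}

# brute-force count of cross Cbeta pairs with lo <= d < hi
brute_cb_contacts_range <- function(receptor, ligand, lo, hi) {
  rc <- get_coords(receptor, "cb")$coords
  lc <- get_coords(ligand, "cb")$coords
  count <- 0L
  for (i in seq_len(nrow(rc))) for (j in seq_len(nrow(lc))) {
    d <- sqrt(sum((rc[i, ] - lc[j, ])^2))
    if (d >= lo && d < hi) count <- count + 1L
  }
  count
}

# brute-force coarse pair potential
brute_pair_potential <- function(a, b, d_clash = 4, d_contact = 8,
                                 k_rep = 5, eps = 1) {
  e <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < d_clash) e <- e + k_rep * (d_clash - d)^2
    else if (d < d_contact) e <- e - eps
  }
  e
}

# brute-force cross-partner residue contact pairs (any heavy atom <= cutoff)
brute_contact_pairs <- function(receptor, ligand, cutoff = 5) {
  ra <- receptor$atoms
  la <- ligand$atoms
  rid <- sprintf("%s:%s%s", ra$chain, ra$resno, ra$ins)
  lid <- sprintf("%s:%s%s", la$chain, la$resno, la$ins)
  keys <- character(0)
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la))) {
    d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                (ra$z[i] - la$z[j])^2)
    if (d <= cutoff) keys <- c(keys, paste(rid[i], lid[j], sep = "|"))
  }
  unique(keys)
}

# random rigid transform applied to a structure
random_rigid_copy <- function(s, trans_scale = 10) {
  q <- random_unit_quat()
  tr <- rigid_transform(q = q, t = rnorm(3, 0, trans_scale))
  set_coords(s, apply_rigid(atom_coords(s), tr))
}

# standard planted-recovery scenario: toy complex, wrong-site start model,
# funnel score centered on the planted native
recovery_case <- function(toy_seed = 3, decoy_seed = 1, start_lrms = 30) {
  toy <- make_toy_complex(seed = toy_seed)
  set.seed(decoy_seed)
  wrong <- make_decoy(toy$native, start_lrms)
  model <- pose_complex(wrong)
  list(toy = toy, model = model,
       confidence = make_confidence(model, baseline = 82),
       score = funnel_score_factory(toy$native))
}

decoy_lrms_all <- function(result, native) {
  vapply(result$decoys,
         function(d) pose_lrms(decoy_to_pose(d, native), native),
         numeric(1))
}
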