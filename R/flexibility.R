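#' Map residues between two structures by per-chain sequence alignment
#'
#' Chains are paired by label (or via `chain_map`) and aligned globally with
#' free end gaps (match +1, mismatch -1, linear gap -2), so unaligned termini
#' are trimmed and gapped positions are excluded. Substituted positions stay
#' mapped. A chain aligning at below 30% identity aborts with an error, since
#' that almost always means the wrong structures were paired.
#'
#' @param a,b `struct3d` structures.
#' @param chain_map optional named character vector mapping chain labels of
#'   `a` to chain labels of `b`; defaults to identical labels.
#' @return List of class `residue_mapping`: `pairs` (data.frame with columns
#'   `id_a`, `id_b`) and `coverage` (named fractions of each structure
#'   mapped).
#' @export
map_residues <- function(a, b, chain_map = NULL) {
  seqs_a <- chain_sequences(a)
  seqs_b <- chain_sequences(b)
  if (is.null(chain_map)) {
    common <- intersect(names(seqs_a), names(seqs_b))
    if (length(common) == 0L) {
      stop("no chain labels in common; supply chain_map")
    }
    chain_map <- setNames(common, common)
  }
  rt_a <- residue_table(a)
  rt_b <- residue_table(b)
  sub_mat <- {
    alpha <- c(LETTERS, "*")
    m <- matrix(-1, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
    diag(m) <- 1
    m
  }
  pairs <- list()
  for (ca in names(chain_map)) {
    cb <- chain_map[[ca]]
    if (is.null(seqs_a[[ca]]) || is.null(seqs_b[[cb]])) {
      stop("chain '", ca, "'/'", cb, "' absent from structure(s)")
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs_a[[ca]]), Biostrings::AAString(seqs_b[[cb]]),
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 2,
      type = "overlap")
    ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    gb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- Biostrings::start(Biostrings::pattern(al)) - 1L
    ib <- Biostrings::start(Biostrings::subject(al)) - 1L
    ids_a <- rt_a$id[rt_a$chain == ca]
    ids_b <- rt_b$id[rt_b$chain == cb]
    pa <- pb <- integer(0)
    n_match <- 0L
    for (k in seq_along(ga)) {
      if (ga[k] != "-") ia <- ia + 1L
      if (gb[k] != "-") ib <- ib + 1L
      if (ga[k] != "-" && gb[k] != "-") {
        pa <- c(pa, ia)
        pb <- c(pb, ib)
        if (ga[k] == gb[k]) n_match <- n_match + 1L
      }
    }
    if (length(pa) == 0L || n_match / length(pa) < 0.30) {
      stop(sprintf(
        "chain %s/%s aligns at %.0f%% identity (<30%%): wrong pairing?",
        ca, cb, if (length(pa)) 100 * n_match / length(pa) else 0))
    }
    pairs[[ca]] <- data.frame(id_a = ids_a[pa], id_b = ids_b[pb],
                              stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  out <- list(pairs = pairs,
              coverage = c(a = nrow(pairs) / nrow(rt_a),
                           b = nrow(pairs) / nrow(rt_b)))
  class(out) <- "residue_mapping"
  out
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rigid fit of point set `coords_a` onto `coords_b` via SVD of
#' the covariance matrix, constrained to a proper rotation
#' (determinant +1).
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates, n >= 3.
#' @return List with `rotation` (3x3), `translation` (length-3) such that
#'   `coords_a %*% t(rotation) + translation` best fits `coords_b`, and the
#'   residual `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate length mismatch")
  if (nrow(coords_a) < 3L) stop("need at least 3 points for superposition")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  ac <- sweep(coords_a, 2, ca)
  bc <- sweep(coords_b, 2, cb)
  h <- crossprod(ac, bc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- ac %*% t(r)
  rmsd <- sqrt(mean(rowSums((fitted - bc)^2)))
  list(rotation = r, translation = as.numeric(cb - ca %*% t(r)), rmsd = rmsd)
}

apply_superposition <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Per-residue Calpha deviation between two conformations
#'
#' Applies a single global Kabsch superposition over all mapped Calpha atoms
#' (so whole-body motion is removed), then reports the Calpha-Calpha
#' distance of each mapped residue. This is the per-residue RMSD between,
#' e.g., unbound and bound conformations of a partner.
#'
#' @param a,b `struct3d` structures.
#' @param mapping a [map_residues()] result between `a` and `b`.
#' @return Named numeric vector (Angstrom), keyed by residue identity in `a`.
#' @export
per_residue_rmsd <- function(a, b, mapping) {
  ca_a <- get_coords(a, "ca")
  ca_b <- get_coords(b, "ca")
  pa <- match(mapping$pairs$id_a, ca_a$residue)
  pb <- match(mapping$pairs$id_b, ca_b$residue)
  ok <- !is.na(pa) & !is.na(pb)
  if (any(!ok)) {
    warning(sum(!ok), " mapped residue(s) lack Calpha; excluded")
  }
  xa <- ca_a$coords[pa[ok], , drop = FALSE]
  xb <- ca_b$coords[pb[ok], , drop = FALSE]
  fit <- kabsch_superpose(xa, xb)
  xa2 <- apply_superposition(xa, fit)
  setNames(sqrt(rowSums((xa2 - xb)^2)), mapping$pairs$id_a[ok])
}

#' Superposition-free local distance difference test (LDDT)
#'
#' Compares conserved Calpha-Calpha distances between a model and a
#' reference. For every ordered residue pair (i, j), i != j, whose reference
#' distance is below the inclusion `radius`, the absolute distance
#' difference is tested against each tolerance; the pair score is the
#' fraction of tolerances passed and the global score averages pair scores
#' over all scored pairs. Per-residue scores restrict the average to pairs
#' involving that residue. The score requires no superposition and is
#' invariant to rigid motion of either structure.
#'
#' @param model,reference `struct3d` structures.
#' @param mapping a [map_residues()] result from `model` to `reference`.
#' @param radius inclusion radius on reference distances (Angstrom).
#' @param tolerances distance-difference tolerances (Angstrom).
#' @return List with `global` (scalar in \[0, 1\]) and `per_residue` (named
#'   by model residue identity).
#' @export
lddt <- function(model, reference, mapping, radius = 10,
                 tolerances = c(0.5, 1, 2, 4)) {
  ca_m <- get_coords(model, "ca")
  ca_r <- get_coords(reference, "ca")
  pm <- match(mapping$pairs$id_a, ca_m$residue)
  pr <- match(mapping$pairs$id_b, ca_r$residue)
  ok <- !is.na(pm) & !is.na(pr)
  xm <- ca_m$coords[pm[ok], , drop = FALSE]
  xr <- ca_r$coords[pr[ok], , drop = FALSE]
  ids <- mapping$pairs$id_a[ok]
  n <- nrow(xr)
  d_true <- as.matrix(stats::dist(xr))
  d_pred <- as.matrix(stats::dist(xm))
  mask <- d_true < radius
  diag(mask) <- FALSE
  if (!any(mask)) stop("no residue pairs within the inclusion radius")
  dd <- abs(d_true - d_pred)
  pair_score <- matrix(0, n, n)
  for (tol in tolerances) pair_score <- pair_score + (dd < tol)
  pair_score <- pair_score / length(tolerances)
  global <- sum(pair_score[mask]) / sum(mask)
  per_res <- vapply(seq_len(n), function(i) {
    js <- which(mask[i, ])
    if (length(js) == 0L) return(NA_real_)
    mean(pair_score[i, js])
  }, numeric(1))
  list(global = global, per_residue = setNames(per_res, ids))
}

parse_residue_id <- function(ids) {
  chain <- sub(":.*$", "", ids)
  rest <- sub("^[^:]*:", "", ids)
  resno <- as.integer(sub("[^-0-9]*$", "", rest))
  ins <- sub("^-?[0-9]+", "", rest)
  data.frame(chain = chain, resno = resno, ins = ins,
             stringsAsFactors = FALSE)
}

#' Select contiguous low-confidence (mobile) residue segments
#'
#' Residues predicted to move on binding are flagged where per-residue pLDDT
#' falls below `threshold` (default 80); maximal runs of consecutive
#' residues (same chain, consecutive author numbering) are kept when at
#' least `min_run` long, giving backbone movers a meaningful lever arm.
#'
#' @param profile named pLDDT vector in structure order.
#' @param threshold pLDDT threshold (residues strictly below are mobile).
#' @param min_run minimum segment length to retain.
#' @return List of class `mobile_selection`: `segments` (data.frame with
#'   `chain`, `start`, `end` identities and `length`) and `residues`
#'   (character vector of all selected residue identities).
#' @export
select_mobile_residues <- function(profile, threshold = 80, min_run = 3) {
  if (length(profile) == 0L) stop("empty confidence profile")
  info <- parse_residue_id(names(profile))
  low <- profile < threshold
  segments <- list()
  residues <- character(0)
  i <- 1L
  n <- length(profile)
  while (i <= n) {
    if (!low[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && low[j + 1L] && info$chain[j + 1L] == info$chain[j] &&
           info$resno[j + 1L] == info$resno[j] + 1L && info$ins[j + 1L] == "") {
      j <- j + 1L
    }
    if (j - i + 1L >= min_run) {
      segments[[length(segments) + 1L]] <-
        data.frame(chain = info$chain[i], start = names(profile)[i],
                   end = names(profile)[j], start_idx = i, end_idx = j,
                   length = j - i + 1L, stringsAsFactors = FALSE)
      residues <- c(residues, names(profile)[i:j])
    }
    i <- j + 1L
  }
  segments <- if (length(segments)) do.call(rbind, segments) else
    data.frame(chain = character(0), start = character(0),
               end = character(0), start_idx = integer(0),
               end_idx = integer(0), length = integer(0))
  rownames(segments) <- NULL
  out <- list(segments = segments, residues = residues,
              threshold = threshold, min_run = min_run)
  class(out) <- "mobile_selection"
  out
}

#' Binding-induced flexibility profile of a partner
#'
#' Convenience wrapper comparing an unbound to a bound conformation:
#' residue mapping, per-residue Calpha RMSD after global superposition, and
#' per-residue plus global LDDT.
#'
#' @param unbound,bound `struct3d` structures of the same protein.
#' @param chain_map optional chain pairing (see [map_residues()]).
#' @return List with `mapping`, `per_residue_rmsd`, `per_residue_lddt`,
#'   `global_lddt`.
#' @export
flexibility_profile <- function(unbound, bound, chain_map = NULL) {
  mapping <- map_residues(unbound, bound, chain_map)
  rms <- per_residue_rmsd(unbound, bound, mapping)
  ld <- lddt(unbound, bound, mapping)
  list(mapping = mapping, per_residue_rmsd = rms,
       per_residue_lddt = ld$per_residue, global_lddt = ld$global)
}
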