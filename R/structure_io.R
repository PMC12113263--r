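#' Protein structures for docking
#'
#' A `struct3d` object is the universal structure record used throughout the
#' package: an ordered atom table (one row per atom, file order preserved)
#' plus the model number it came from. The B-factor column carries per-residue
#' pLDDT on the 0-100 scale for predicted models, following the AlphaFold
#' PDB convention.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `ins`, `resid`
#'   (3-letter residue type), `elety` (atom name), `elesy` (element symbol),
#'   `x`, `y`, `z` (Angstrom) and `b` (B-factor / pLDDT).
#' @param model_id integer model number.
#' @return An object of class `struct3d`.
#' @export
new_structure <- function(atoms, model_id = 1L) {
  stopifnot(is.data.frame(atoms))
  needed <- c("chain", "resno", "ins", "resid", "elety", "elesy",
              "x", "y", "z", "b")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$b < 0)) stop("negative B-factor values")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "struct3d")
}

#' @export
print.struct3d <- function(x, ...) {
  cat(sprintf("<struct3d> %d atoms, %d residues, chains: %s (model %d)\n",
              nrow(x$atoms), n_residues(x),
              paste(chain_labels(x), collapse = ","), x$model_id))
  invisible(x)
}

#' Residue identities in file order
#'
#' Residue identity is `chain:resno` with the insertion code appended when
#' present. Author numbering is preserved verbatim.
#'
#' @param x a `struct3d` object.
#' @return Character vector of unique residue identifiers, one per residue,
#'   in structure order.
#' @export
residue_ids <- function(x) {
  unique(atom_residue_ids(x$atoms))
}

atom_residue_ids <- function(atoms) {
  sprintf("%s:%s%s", atoms$chain, atoms$resno, atoms$ins)
}

#' @rdname residue_ids
#' @export
n_residues <- function(x) length(residue_ids(x))

#' @rdname residue_ids
#' @export
chain_labels <- function(x) unique(x$atoms$chain)

#' Per-residue summary table
#'
#' @param x a `struct3d` object.
#' @return data.frame with one row per residue (structure order): `id`,
#'   `chain`, `resno`, `ins`, `resid`.
#' @export
residue_table <- function(x) {
  ids <- atom_residue_ids(x$atoms)
  keep <- !duplicated(ids)
  out <- data.frame(id = ids[keep],
                    chain = x$atoms$chain[keep],
                    resno = x$atoms$resno[keep],
                    ins = x$atoms$ins[keep],
                    resid = x$atoms$resid[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-letter sequence per chain
#'
#' @param x a `struct3d` object.
#' @return Named list, one character string per chain.
#' @export
chain_sequences <- function(x) {
  rt <- residue_table(x)
  out <- lapply(split(rt, factor(rt$chain, levels = unique(rt$chain))),
                function(d) paste(bio3d::aa321(d$resid), collapse = ""))
  out[unique(rt$chain)]
}

hydrogen_rows <- function(atoms) {
  ele <- toupper(trimws(atoms$elesy))
  is_h <- ele %in% c("H", "D")
  # element column sometimes blank in hand-made files: fall back to atom name
  blank <- is.na(ele) | ele == ""
  if (any(blank)) {
    nm <- toupper(trimws(atoms$elety[blank]))
    is_h[blank] <- grepl("^[0-9]*H", nm)
  }
  is_h
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of the first model; HETATM records (waters, ligands)
#' and hydrogens are skipped. For alternate locations the highest-occupancy
#' conformer is kept (first on ties).
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @return A [new_structure()] object.
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  # drop waters however they were tagged
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in '", path, "'")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest occupancy conformer per atom, first on tie
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(factor(key, levels = unique(key)), -at$o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
  }
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = at$resno,
                      ins = as.character(at$insert),
                      resid = as.character(at$resid),
                      elety = as.character(at$elety),
                      elesy = as.character(at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  atoms <- atoms[!hydrogen_rows(atoms), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no heavy atoms in '", path, "'")
  new_structure(atoms, model_id = 1L)
}

#' Write a structure to a PDB file
#'
#' @param x a `struct3d` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$ins == "", NA, a$ins),
                   o = rep(1, nrow(a)), b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Read a per-residue confidence profile from a scores JSON file
#'
#' Expects an object with key `"plddt"` holding a flat numeric array in
#' structure residue order (the ColabFold scores dialect). Values must lie in
#' \[0, 100\]; inputs on a 0-1 scale (maximum at most 1) are rescaled by 100
#' with a warning.
#'
#' @param path path to the JSON file.
#' @param structure the `struct3d` the profile belongs to (used for residue
#'   keys and length validation).
#' @return Named numeric vector of pLDDT values (0-100), one per residue.
#' @export
read_confidence_json <- function(path, structure) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$plddt)) stop("JSON file has no 'plddt' key: ", path)
  v <- as.numeric(obj$plddt)
  ids <- residue_ids(structure)
  if (length(v) != length(ids)) {
    stop(sprintf("confidence length %d does not match %d residues",
                 length(v), length(ids)))
  }
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100)) {
    stop("pLDDT values outside [0, 100]")
  }
  if (max(v) <= 1.0) {
    warning("pLDDT values appear to be on a 0-1 scale; rescaling by 100")
    v <- v * 100
  }
  setNames(v, ids)
}

#' Per-residue confidence from the B-factor column
#'
#' AlphaFold stores pLDDT in the PDB B-factor column; the per-residue value
#' is taken from the Calpha atom, falling back to the mean over the residue's
#' atoms when Calpha is absent.
#'
#' @param structure a `struct3d` object.
#' @return Named numeric vector of pLDDT values, one per residue.
#' @export
confidence_from_bfactor <- function(structure) {
  a <- structure$atoms
  ids <- atom_residue_ids(a)
  uids <- unique(ids)
  f <- factor(ids, levels = uids)
  v <- vapply(split(seq_len(nrow(a)), f), function(idx) {
    ca <- idx[a$elety[idx] == "CA"]
    if (length(ca) > 0L) a$b[ca[1L]] else mean(a$b[idx])
  }, numeric(1))
  if (all(v == 0)) {
    warning("all B-factors are zero: confidence profile is uniformly ",
            "low-confidence")
  }
  setNames(as.numeric(v), uids)
}

#' Parse a partner specification string
#'
#' `"AB_C"` names chains A and B as the receptor and chain C as the ligand.
#'
#' @param spec partner string, receptor chains left of the underscore.
#' @return List with `receptor_chains` and `ligand_chains`.
#' @export
parse_partners <- function(spec) {
  parts <- strsplit(spec, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(nchar(parts) == 0L)) {
    stop("partner spec must be 'RECEPTORCHAINS_LIGANDCHAINS', got '",
         spec, "'")
  }
  rec <- strsplit(parts[1], "")[[1]]
  lig <- strsplit(parts[2], "")[[1]]
  both <- intersect(rec, lig)
  if (length(both) > 0L) {
    stop("chain(s) on both sides of partner spec: ",
         paste(both, collapse = ","))
  }
  list(receptor_chains = rec, ligand_chains = lig)
}

#' Split a structure into receptor and ligand partners
#'
#' @param structure a `struct3d` object.
#' @param spec partner string (see [parse_partners()]), or a list as returned
#'   by `parse_partners`.
#' @return List with `struct3d` elements `receptor` and `ligand`, residue
#'   order preserved.
#' @export
split_partners <- function(structure, spec) {
  ps <- if (is.character(spec)) parse_partners(spec) else spec
  have <- chain_labels(structure)
  unknown <- setdiff(c(ps$receptor_chains, ps$ligand_chains), have)
  if (length(unknown) > 0L) {
    stop("chain(s) not present in structure: ", paste(unknown, collapse = ","))
  }
  take <- function(chs) {
    new_structure(structure$atoms[structure$atoms$chain %in% chs, ,
                                  drop = FALSE],
                  model_id = structure$model_id)
  }
  list(receptor = take(ps$receptor_chains), ligand = take(ps$ligand_chains))
}

#' Extract an atom-coordinate view of a structure
#'
#' Selections: `"ca"` (one Calpha per residue), `"cb"` (Cbeta, substituting
#' Calpha for glycine or any residue lacking Cbeta), `"backbone"`
#' (N, Calpha, C, O) and `"heavy"` (all non-hydrogen atoms). Residues with
#' none of the selected atoms are skipped and recorded.
#'
#' @param structure a `struct3d` object.
#' @param selection one of `"ca"`, `"cb"`, `"backbone"`, `"heavy"`.
#' @return List with `coords` (n x 3 matrix, Angstrom), `residue` (residue
#'   identity per row), `atom` (atom name per row) and `skipped` (residue
#'   identities with no selected atoms).
#' @export
get_coords <- function(structure, selection = c("ca", "cb", "backbone",
                                                "heavy")) {
  selection <- match.arg(selection)
  a <- structure$atoms
  ids <- atom_residue_ids(a)
  uids <- unique(ids)
  if (selection == "heavy") {
    keep <- which(!hydrogen_rows(a))
  } else if (selection == "backbone") {
    keep <- which(a$elety %in% c("N", "CA", "C", "O"))
  } else if (selection == "ca") {
    keep <- which(a$elety == "CA")
    keep <- keep[!duplicated(ids[keep])]
  } else { # cb with Calpha fallback
    keep <- integer(0)
    for (u in uids) {
      idx <- which(ids == u)
      cb <- idx[a$elety[idx] == "CB"]
      if (length(cb) == 0L) cb <- idx[a$elety[idx] == "CA"]
      if (length(cb) > 0L) keep <- c(keep, cb[1L])
    }
  }
  keep <- sort(keep)
  list(coords = as.matrix(a[keep, c("x", "y", "z"), drop = FALSE]),
       residue = ids[keep],
       atom = a$elety[keep],
       skipped = setdiff(uids, unique(ids[keep])))
}

#' Replace the coordinates of a structure
#'
#' @param structure a `struct3d` object.
#' @param coords n_atoms x 3 matrix in atom order.
#' @return The modified `struct3d`.
#' @export
set_coords <- function(structure, coords) {
  stopifnot(nrow(coords) == nrow(structure$atoms), ncol(coords) == 3L)
  structure$atoms$x <- coords[, 1]
  structure$atoms$y <- coords[, 2]
  structure$atoms$z <- coords[, 3]
  structure
}

#' All heavy-atom coordinates as a matrix
#'
#' @param structure a `struct3d` object.
#' @return n_atoms x 3 numeric matrix.
#' @export
atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}
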