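#' Cross-partner residue contacts of a complex
#'
#' A contact is a receptor-ligand residue pair with any heavy-atom pair
#' within `cutoff` (default 5 Angstrom, the CAPRI native-contact
#' convention).
#'
#' @param receptor,ligand `struct3d` partners.
#' @param cutoff heavy-atom distance cutoff (Angstrom).
#' @return data.frame with columns `receptor` and `ligand` (residue
#'   identities), one row per contacting pair.
#' @export
native_contacts <- function(receptor, ligand, cutoff = 5) {
  ra <- get_coords(receptor, "heavy")
  la <- get_coords(ligand, "heavy")
  pairs <- cpp_pairs_within(ra$coords, la$coords, cutoff)
  if (nrow(pairs) == 0L) {
    return(data.frame(receptor = character(0), ligand = character(0)))
  }
  out <- unique(data.frame(receptor = ra$residue[pairs[, 1]],
                           ligand = la$residue[pairs[, 2]],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

contact_keys <- function(contacts) {
  paste(contacts$receptor, contacts$ligand, sep = "|")
}

eval_mapping <- function(model, reference, mapping) {
  if (is.null(mapping)) map_residues(model, reference) else mapping
}

map_lookup <- function(mapping) {
  setNames(mapping$pairs$id_b, mapping$pairs$id_a)
}

#' Fraction of native contacts reproduced by a model
#'
#' @param model,reference `struct3d` complexes (model and bound reference).
#' @param partners partner spec string or parsed list (applies to both).
#' @param cutoff contact cutoff (Angstrom).
#' @param mapping optional [map_residues()] result from model to reference;
#'   computed from the sequences when omitted.
#' @return fnat in \[0, 1\].
#' @export
fnat <- function(model, reference, partners, cutoff = 5, mapping = NULL) {
  mapping <- eval_mapping(model, reference, mapping)
  sp_m <- split_partners(model, partners)
  sp_r <- split_partners(reference, partners)
  native <- native_contacts(sp_r$receptor, sp_r$ligand, cutoff)
  if (nrow(native) == 0L) stop("reference complex has no native contacts")
  modc <- native_contacts(sp_m$receptor, sp_m$ligand, cutoff)
  lut <- map_lookup(mapping)
  modc$receptor <- lut[modc$receptor]
  modc$ligand <- lut[modc$ligand]
  modc <- modc[!is.na(modc$receptor) & !is.na(modc$ligand), , drop = FALSE]
  length(intersect(contact_keys(modc), contact_keys(native))) / nrow(native)
}

## paired backbone coordinates (model, reference) for the given reference
## residues, matching atoms by name within each mapped residue pair
paired_backbone <- function(model, reference, mapping, ref_residues = NULL) {
  bb_m <- get_coords(model, "backbone")
  bb_r <- get_coords(reference, "backbone")
  pairs <- mapping$pairs
  if (!is.null(ref_residues)) {
    pairs <- pairs[pairs$id_b %in% ref_residues, , drop = FALSE]
  }
  key_m <- paste(bb_m$residue, bb_m$atom)
  xm <- xr <- list()
  for (k in seq_len(nrow(pairs))) {
    rows_r <- which(bb_r$residue == pairs$id_b[k])
    for (rr in rows_r) {
      mm <- match(paste(pairs$id_a[k], bb_r$atom[rr]), key_m)
      if (!is.na(mm)) {
        xm[[length(xm) + 1L]] <- bb_m$coords[mm, ]
        xr[[length(xr) + 1L]] <- bb_r$coords[rr, ]
      }
    }
  }
  list(model = do.call(rbind, xm), reference = do.call(rbind, xr))
}

#' Interface RMSD of a docking model
#'
#' The reference-defined interface comprises residues with any heavy atom
#' within `interface_cutoff` (default 10 Angstrom, CAPRI convention) of the
#' other partner. Backbone atoms (N, Calpha, C, O) of these residues from
#' both partners are jointly superposed (Kabsch) and the residual RMSD is
#' returned.
#'
#' @inheritParams fnat
#' @param interface_cutoff reference interface definition (Angstrom).
#' @return Interface RMSD in Angstrom.
#' @export
interface_rmsd <- function(model, reference, partners,
                           interface_cutoff = 10, mapping = NULL) {
  mapping <- eval_mapping(model, reference, mapping)
  sp_r <- split_partners(reference, partners)
  iface <- find_interface_residues(sp_r$receptor, sp_r$ligand,
                                   interface_cutoff)
  if (length(iface) < 3L) stop("reference interface too small (<3 residues)")
  pb <- paired_backbone(model, reference, mapping, ref_residues = iface)
  if (is.null(pb$model) || nrow(pb$model) < 3L) {
    stop("too few mapped interface backbone atoms")
  }
  kabsch_superpose(pb$model, pb$reference)$rmsd
}

#' Ligand RMSD of a docking model
#'
#' Superposes the model onto the reference using the receptor backbone only,
#' then reports the backbone RMSD of the ligand partner.
#'
#' @inheritParams fnat
#' @return Ligand RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model, reference, partners, mapping = NULL) {
  mapping <- eval_mapping(model, reference, mapping)
  ps <- if (is.character(partners)) parse_partners(partners) else partners
  rt_r <- residue_table(reference)
  rec_ids_r <- rt_r$id[rt_r$chain %in% ps$receptor_chains]
  lig_ids_r <- rt_r$id[rt_r$chain %in% ps$ligand_chains]
  rec <- paired_backbone(model, reference, mapping, ref_residues = rec_ids_r)
  if (is.null(rec$model) || nrow(rec$model) < 3L) {
    stop("too few mapped receptor backbone atoms")
  }
  fit <- kabsch_superpose(rec$model, rec$reference)
  lig <- paired_backbone(model, reference, mapping, ref_residues = lig_ids_r)
  if (is.null(lig$model) || nrow(lig$model) < 1L) {
    stop("no mapped ligand backbone atoms")
  }
  fitted <- apply_superposition(lig$model, fit)
  sqrt(mean(rowSums((fitted - lig$reference)^2)))
}

#' DockQ composite docking-quality score
#'
#' Combines the fraction of native contacts with scaled interface and
#' ligand RMSD terms:
#' `DockQ = (fnat + 1/(1+(Irms/d1)^2) + 1/(1+(Lrms/d2)^2)) / 3`
#' with scaling constants `d1 = 1.5` and `d2 = 8.5` Angstrom.
#'
#' @param fnat_v fraction of native contacts in \[0, 1\].
#' @param irms_v interface RMSD (Angstrom).
#' @param lrms_v ligand RMSD (Angstrom).
#' @param d1,d2 RMSD scaling constants (Angstrom).
#' @return DockQ in \[0, 1\].
#' @export
dockq <- function(fnat_v, irms_v, lrms_v, d1 = 1.5, d2 = 8.5) {
  stopifnot(fnat_v >= 0, fnat_v <= 1, irms_v >= 0, lrms_v >= 0)
  (fnat_v + 1 / (1 + (irms_v / d1)^2) + 1 / (1 + (lrms_v / d2)^2)) / 3
}

#' CAPRI quality class from a DockQ score
#'
#' Bins: incorrect for DockQ < 0.23 (0.23 itself included), acceptable for
#' (0.23, 0.49], medium for (0.49, 0.8) and high for DockQ >= 0.8. A model
#' counts as a docking success when DockQ exceeds 0.23.
#'
#' @param dockq_v DockQ score in \[0, 1\].
#' @return One of `"incorrect"`, `"acceptable"`, `"medium"`, `"high"`.
#' @export
capri_class <- function(dockq_v) {
  stopifnot(dockq_v >= 0, dockq_v <= 1)
  if (dockq_v >= 0.8) "high"
  else if (dockq_v > 0.49) "medium"
  else if (dockq_v > 0.23) "acceptable"
  else "incorrect"
}

#' Full docking-quality evaluation of a model against a reference
#'
#' @inheritParams fnat
#' @return List of class `quality_metrics` with `fnat`, `irms`, `lrms`,
#'   `dockq`, `capri_class` and logical `success` (DockQ > 0.23).
#' @export
quality_metrics <- function(model, reference, partners, mapping = NULL) {
  mapping <- eval_mapping(model, reference, mapping)
  f <- fnat(model, reference, partners, mapping = mapping)
  ir <- interface_rmsd(model, reference, partners, mapping = mapping)
  lr <- ligand_rmsd(model, reference, partners, mapping = mapping)
  q <- dockq(f, ir, lr)
  out <- list(fnat = f, irms = ir, lrms = lr, dockq = q,
              capri_class = capri_class(q), success = q > 0.23)
  class(out) <- "quality_metrics"
  out
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf(paste0("<quality_metrics> fnat %.3f, Irms %.2f A, ",
                     "Lrms %.2f A, DockQ %.3f (%s)\n"),
              x$fnat, x$irms, x$lrms, x$dockq, x$capri_class))
  invisible(x)
}
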