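#' Find interface residues between two docking partners
#'
#' A residue (on either partner) belongs to the interface when any of its
#' heavy atoms lies within `cutoff` of any heavy atom of the other partner
#' (default 8 Angstrom).
#'
#' @param receptor,ligand `struct3d` partners.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return Character vector of residue identities drawn from both partners
#'   (possibly empty).
#' @export
find_interface_residues <- function(receptor, ligand, cutoff = 8) {
  ra <- get_coords(receptor, "heavy")
  la <- get_coords(ligand, "heavy")
  pairs <- cpp_pairs_within(ra$coords, la$coords, cutoff)
  if (nrow(pairs) == 0L) return(character(0))
  unique(c(ra$residue[unique(pairs[, 1])], la$residue[unique(pairs[, 2])]))
}

#' Count cross-partner Cbeta contacts
#'
#' Number of receptor-ligand residue pairs whose Cbeta-Cbeta distance (Calpha
#' for glycine) is at most `cutoff` (default 5 Angstrom).
#'
#' @inheritParams find_interface_residues
#' @param cutoff Cbeta distance cutoff in Angstrom.
#' @return Integer pair count.
#' @export
count_interface_contacts <- function(receptor, ligand, cutoff = 5) {
  rc <- get_coords(receptor, "cb")
  lc <- get_coords(ligand, "cb")
  nrow(cpp_pairs_within(rc$coords, lc$coords, cutoff))
}

#' Mean confidence over interface residues
#'
#' Arithmetic mean of pLDDT over the given interface residue set. An empty
#' interface leaves interface confidence undefined: `NA` is returned and the
#' docking gate must treat the model as a failed docking prediction (see
#' [gate_decision()]).
#'
#' @param profile named pLDDT vector (see [confidence_from_bfactor()]).
#' @param interface character vector of residue identities.
#' @return Mean pLDDT, or `NA_real_` for an empty interface.
#' @export
interface_plddt <- function(profile, interface) {
  if (length(interface) == 0L) return(NA_real_)
  missing_ids <- setdiff(interface, names(profile))
  if (length(missing_ids) > 0L) {
    stop("interface residues absent from confidence profile: ",
         paste(head(missing_ids, 5), collapse = ","))
  }
  mean(profile[interface])
}

#' Mean confidence over the whole complex
#'
#' @param profile named pLDDT vector.
#' @return Mean pLDDT across all residues.
#' @export
average_plddt <- function(profile) {
  if (length(profile) == 0L) stop("empty confidence profile")
  mean(profile)
}

#' Global-versus-local docking gate
#'
#' Decides the sampling branch from the interface confidence of a predicted
#' complex: `"LOCAL"` (refine near the predicted pose) when interface-pLDDT
#' is at or above the threshold, `"GLOBAL"` (full rigid-body search)
#' otherwise. An undefined interface confidence (`NA`, partners not in
#' contact) forces `"GLOBAL"`: a model with no predicted interface is the
#' strongest evidence of a failed docking prediction.
#'
#' @param interface_plddt_value interface-pLDDT on the 0-100 scale (or `NA`).
#' @param threshold gate threshold, default 85.
#' @return `"GLOBAL"` or `"LOCAL"`.
#' @export
gate_decision <- function(interface_plddt_value, threshold = 85) {
  if (is.na(interface_plddt_value)) return("GLOBAL")
  if (interface_plddt_value < 0 || interface_plddt_value > 100) {
    stop("interface-pLDDT must lie in [0, 100]")
  }
  if (interface_plddt_value >= threshold) "LOCAL" else "GLOBAL"
}

#' Interface confidence report for a predicted complex
#'
#' Computes the interface residue set (8 Angstrom heavy-atom rule), Cbeta
#' contact count (5 Angstrom), interface-pLDDT, average pLDDT and the
#' global/local gate verdict for a predicted complex structure.
#'
#' @param structure predicted complex as a `struct3d`.
#' @param partners partner spec string or parsed partner list.
#' @param profile named pLDDT vector; defaults to the B-factor column.
#' @param interface_cutoff heavy-atom interface cutoff (Angstrom).
#' @param contact_cutoff Cbeta contact cutoff (Angstrom).
#' @param gate_threshold interface-pLDDT gate threshold.
#' @return List of class `interface_report`: `interface_residues`,
#'   `n_interface_residues`, `n_interface_contacts`, `interface_plddt`,
#'   `avg_plddt`, `gate`.
#' @export
interface_report <- function(structure, partners,
                             profile = confidence_from_bfactor(structure),
                             interface_cutoff = 8, contact_cutoff = 5,
                             gate_threshold = 85) {
  sp <- split_partners(structure, partners)
  iface <- find_interface_residues(sp$receptor, sp$ligand, interface_cutoff)
  ip <- interface_plddt(profile, iface)
  out <- list(interface_residues = iface,
              n_interface_residues = length(iface),
              n_interface_contacts = count_interface_contacts(
                sp$receptor, sp$ligand, contact_cutoff),
              interface_plddt = ip,
              avg_plddt = average_plddt(profile),
              gate = gate_decision(ip, gate_threshold))
  class(out) <- "interface_report"
  out
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(paste0("<interface_report> %d interface residues, %d contacts, ",
                     "interface-pLDDT %.1f, avg-pLDDT %.1f, gate %s\n"),
              x$n_interface_residues, x$n_interface_contacts,
              if (is.na(x$interface_plddt)) NaN else x$interface_plddt,
              x$avg_plddt, x$gate))
  invisible(x)
}

#' ROC curve and AUC for a docking-quality discriminator
#'
#' Sweeps every observed score value as a threshold (ties collapse to a
#' single threshold) and accumulates true/false positive rates; the AUC is
#' the trapezoid-rule area under the resulting curve. Higher scores are
#' assumed to indicate the positive (near-native) class.
#'
#' @param score numeric metric values, higher = more confident.
#' @param label logical near-native truth labels.
#' @return List with `roc` (data.frame of threshold, fpr, tpr) and `auc`.
#' @export
roc_curve <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.logical(label)
  if (length(unique(label)) < 2L) {
    stop("AUC undefined: both classes must be present")
  }
  thr <- sort(unique(score), decreasing = TRUE)
  np <- sum(label)
  nn <- sum(!label)
  tpr <- vapply(thr, function(t) sum(score >= t & label) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & !label) / nn, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Discrimination analysis of confidence metrics against docking truth
#'
#' Dataset-level assessment of how well AlphaFold-derived metrics separate
#' near-native from incorrectly docked predictions. The truth label is
#' near-native defined as interface RMSD at most 4 Angstrom. For each metric
#' column a full ROC sweep and AUC are computed; a confusion matrix is
#' reported for interface-pLDDT dichotomised at `plddt_threshold`.
#'
#' @param records data.frame with one row per target, containing metric
#'   columns and either a logical `near_native` column or an `irms` column
#'   from which the truth label is derived (`irms <= 4`).
#' @param metrics character vector of metric column names to sweep.
#' @param plddt_threshold threshold for the interface-pLDDT confusion matrix.
#' @param irms_cutoff near-native interface-RMSD cutoff in Angstrom.
#' @return List with `roc` (named list of ROC results per metric), `auc`
#'   (named numeric) and `confusion` (2x2 table: predicted x actual), plus
#'   `accuracy` and `precision` of the thresholded interface-pLDDT call.
#' @export
discrimination_analysis <- function(records,
                                    metrics = intersect(
                                      c("interface_plddt", "avg_plddt",
                                        "n_interface_residues",
                                        "n_interface_contacts"),
                                      names(records)),
                                    plddt_threshold = 85,
                                    irms_cutoff = 4) {
  if (!is.null(records$near_native)) {
    truth <- as.logical(records$near_native)
  } else if (!is.null(records$irms)) {
    truth <- records$irms <= irms_cutoff
  } else {
    stop("records need a 'near_native' or 'irms' column")
  }
  if (nrow(records) < 2L) stop("need at least two records")
  rocs <- lapply(metrics, function(m) roc_curve(records[[m]], truth))
  names(rocs) <- metrics
  conf <- NULL
  acc <- prec <- NA_real_
  if ("interface_plddt" %in% names(records)) {
    pred <- records$interface_plddt >= plddt_threshold
    conf <- table(predicted = factor(pred, levels = c(TRUE, FALSE)),
                  actual = factor(truth, levels = c(TRUE, FALSE)))
    acc <- (conf[1, 1] + conf[2, 2]) / sum(conf)
    prec <- if (sum(conf[1, ]) > 0) conf[1, 1] / sum(conf[1, ]) else NA_real_
  }
  list(roc = rocs,
       auc = vapply(rocs, `[[`, numeric(1), "auc"),
       confusion = conf, accuracy = acc, precision = prec)
}
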