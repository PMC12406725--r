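#' Crosstalk configuration
#'
#' Thresholds for receptor-gated ligand-receptor pair construction and
#' polarization-specificity classification.
#'
#' @param receptor_gate Minimum base-mean transcript expression a receptor
#'   needs in the gating sample (default 1, inclusive).
#' @param fc_high M2/M1 fold-change bound at or above which an interaction
#'   is M2-specific (default 2, inclusive).
#' @param fc_low Fold-change bound at or below which an interaction is
#'   M1-specific (default 0.5, inclusive). Interactions strictly between
#'   the two bounds are pan-macrophage.
#' @param gate_sample Name of the expression-table sample used for gating
#'   (the invasive-fraction sample in the study design).
#' @return A list of class `crosstalk_config`.
#' @export
crosstalk_config <- function(receptor_gate = 1, fc_high = 2, fc_low = 0.5,
                             gate_sample = "gsc_m2cm_invasive") {
  if (!is.numeric(receptor_gate) || receptor_gate < 0) {
    stop("receptor_gate must be a non-negative number", call. = FALSE)
  }
  if (!(is.numeric(fc_low) && is.numeric(fc_high) &&
        0 < fc_low && fc_low < fc_high)) {
    stop("need 0 < fc_low < fc_high", call. = FALSE)
  }
  structure(
    list(receptor_gate = receptor_gate, fc_high = fc_high, fc_low = fc_low,
         gate_sample = gate_sample),
    class = "crosstalk_config"
  )
}

#' Receptor expression gate
#'
#' Genes whose base-mean expression in the gating sample is at or above
#' the threshold; the boundary is inclusive (a base mean of exactly 1
#' passes the default gate).
#'
#' @param expr Expression table (see [read_expression_table()]).
#' @param sample Sample column to gate on.
#' @param threshold Inclusive lower bound (default 1).
#' @return Character vector of gated gene identifiers.
#' @export
gate_receptors <- function(expr, sample, threshold = 1) {
  if (!sample %in% setdiff(names(expr), "gene_id")) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  expr$gene_id[expr[[sample]] >= threshold]
}

#' Polarization-specificity class of a fold change
#'
#' Classifies an M2/M1 fold change: `M2_specific` when `fc >= fc_high`,
#' `M1_specific` when `fc <= fc_low`, `pan` strictly in between. Total on
#' the extended non-negative reals, so condition-exclusive ligands
#' (fc of `Inf` or 0) land in the matching exclusive class.
#'
#' @param fc Numeric vector of extended non-negative fold changes.
#' @param cfg A [crosstalk_config()].
#' @return Character vector in `{"M1_specific", "pan", "M2_specific"}`.
#' @export
classify_polarization <- function(fc, cfg = crosstalk_config()) {
  if (any(is.na(fc)) || any(fc < 0)) {
    stop("fc must be defined and non-negative", call. = FALSE)
  }
  dplyr::case_when(
    fc >= cfg$fc_high ~ "M2_specific",
    fc <= cfg$fc_low  ~ "M1_specific",
    TRUE              ~ "pan"
  )
}

#' Build receptor-gated ligand-receptor interaction records
#'
#' One record per database pair whose ligand is a detected, secreted CM
#' protein and whose receptor passes the expression gate. Each record
#' carries the ligand's M2/M1 fold change, the receptor's base mean in the
#' gating sample, and the polarization class of the fold change. Output is
#' ordered lexicographically by (ligand, receptor) so reports are
#' diffable.
#'
#' @param ligands Character vector of eligible ligand identifiers
#'   (detected after replicate filtering, and secreted).
#' @param summary Condition summary tibble (see [condition_summary()])
#'   covering at least every eligible ligand.
#' @param expr Expression table used for the receptor gate.
#' @param db Ligand-receptor pair database tibble
#'   (see [read_rl_database()]).
#' @param cfg A [crosstalk_config()].
#' @return Tibble of interaction records: `ligand`, `receptor`,
#'   `ligand_fc`, `receptor_base_mean`, `polarization_class`.
#' @export
build_interactions <- function(ligands, summary, expr, db,
                               cfg = crosstalk_config()) {
  missing_sum <- setdiff(ligands, summary$protein_id)
  if (length(missing_sum)) {
    stop("eligible ligand(s) without a condition summary: ",
         paste(missing_sum, collapse = ", "), call. = FALSE)
  }
  gated <- gate_receptors(expr, cfg$gate_sample, cfg$receptor_gate)
  hits <- db[db$ligand %in% ligands & db$receptor %in% gated, , drop = FALSE]
  fc <- summary$fc[match(hits$ligand, summary$protein_id)]
  bm <- expr[[cfg$gate_sample]][match(hits$receptor, expr$gene_id)]
  out <- tibble::tibble(
    ligand = hits$ligand,
    receptor = hits$receptor,
    ligand_fc = fc,
    receptor_base_mean = bm,
    polarization_class = classify_polarization(fc, cfg)
  )
  out[order(out$ligand, out$receptor, method = "radix"), , drop = FALSE]
}

#' Interaction counts per polarization class
#'
#' @param records Interaction tibble from [build_interactions()].
#' @return Named integer vector `c(M1_specific=, M2_specific=, pan=)`;
#'   the three counts always sum to `nrow(records)`.
#' @export
partition_counts <- function(records) {
  classes <- c("M1_specific", "M2_specific", "pan")
  counts <- vapply(classes, function(cl) {
    sum(records$polarization_class == cl)
  }, integer(1))
  stats::setNames(as.integer(counts), classes)
}

#' Unique receptors and ligands of an interaction class
#'
#' @param records Interaction tibble from [build_interactions()].
#' @param class_filter Polarization class to restrict to, or NULL for all
#'   records.
#' @return Named integer vector `c(n_receptors=, n_ligands=)`.
#' @export
unique_members <- function(records, class_filter = NULL) {
  if (!is.null(class_filter)) {
    records <- records[records$polarization_class == class_filter, ,
                       drop = FALSE]
  }
  c(n_receptors = length(unique(records$receptor)),
    n_ligands   = length(unique(records$ligand)))
}
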