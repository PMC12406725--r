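#' Replicate-detection filter for a protein intensity table
#'
#' Label-free identifications seen in fewer than `min_detected` replicates
#' of a condition are treated as spurious: those entries are voided
#' (set to non-detection) for that condition, and proteins left with no
#' detection in either condition are dropped. With the study design of
#' biological triplicates per condition, the default keeps proteins seen in
#' at least 2 of 3 runs of a condition, i.e. identifications present in
#' only one replicate of a sample are filtered out.
#'
#' @param table Protein intensity table (see [read_intensity_table()]).
#' @param min_detected Minimum number of non-missing replicates a condition
#'   needs for its detections to count (default 2).
#' @param conditions Condition labels in the column headers.
#' @return The filtered intensity table; idempotent.
#' @export
filter_by_replicates <- function(table, min_detected = 2,
                                 conditions = c("M1", "M2")) {
  cols <- intensity_columns(table, conditions)
  R <- length(cols[[1]])
  if (min_detected < 1 || min_detected > R) {
    stop("min_detected must lie in [1, ", R, "]", call. = FALSE)
  }
  out <- table
  for (cond in conditions) {
    cc <- cols[[cond]]
    n_det <- rowSums(!is.na(as.matrix(out[cc])))
    void <- n_det > 0 & n_det < min_detected
    for (col in cc) out[[col]][void] <- NA_real_
  }
  any_left <- rowSums(!is.na(as.matrix(out[unlist(cols)]))) > 0
  out[any_left, , drop = FALSE]
}

#' Per-condition detection sets
#'
#' A protein belongs to a condition's detection set when it carries at
#' least `min_detected` non-missing replicates in that condition. Intended
#' for tables already passed through [filter_by_replicates()], where the
#' two notions (any detection / enough detection) coincide.
#'
#' @inheritParams filter_by_replicates
#' @return Named list of character vectors, one per condition.
#' @export
detection_sets <- function(table, min_detected = 2,
                           conditions = c("M1", "M2")) {
  cols <- intensity_columns(table, conditions)
  sets <- lapply(conditions, function(cond) {
    n_det <- rowSums(!is.na(as.matrix(table[cols[[cond]]])))
    table$protein_id[n_det >= min_detected]
  })
  names(sets) <- conditions
  sets
}

#' Two-set Venn decomposition of detection sets
#'
#' @param set_a,set_b Character vectors (e.g. the M1 and M2 detection
#'   sets).
#' @return A list with integer fields `m1_only`, `m2_only`, `both`,
#'   `total`; `m1_only + m2_only + both == total` always.
#' @export
venn_counts <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  both <- length(intersect(set_a, set_b))
  list(
    m1_only = length(set_a) - both,
    m2_only = length(set_b) - both,
    both    = both,
    total   = length(union(set_a, set_b))
  )
}

#' Mean intensity of one protein in one condition
#'
#' Arithmetic mean over the detected (non-missing) replicates only;
#' `NA` when the protein is undetected in that condition.
#'
#' @inheritParams filter_by_replicates
#' @param protein Protein identifier (canonical).
#' @param condition Condition label.
#' @return A single non-negative number, or `NA` when no replicate is
#'   detected.
#' @export
condition_mean <- function(table, protein, condition) {
  cols <- intensity_columns(table, condition)[[condition]]
  row <- which(table$protein_id == protein)
  if (!length(row)) {
    stop("unknown protein: ", protein, call. = FALSE)
  }
  v <- as.numeric(unlist(table[row, cols]))
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' M2/M1 fold change of mean normalized intensity
#'
#' The polarization fold change of a protein: its average normalized M2
#' intensity divided by its average normalized M1 intensity. For proteins
#' detected in only one condition the ratio takes the extended values
#' `Inf` (M2-only) and `0` (M1-only), so condition-exclusive proteins fall
#' into the matching specificity class downstream.
#'
#' @param mean_m2,mean_m1 Numeric vectors of condition means; `NA` encodes
#'   an undefined mean (no detection).
#' @return Numeric vector of extended non-negative fold changes.
#' @export
fold_change <- function(mean_m2, mean_m1) {
  m2 <- ifelse(is.na(mean_m2), 0, mean_m2)
  m1 <- ifelse(is.na(mean_m1), 0, mean_m1)
  if (any(m2 == 0 & m1 == 0)) {
    stop("fold_change: both condition means undefined or zero",
         call. = FALSE)
  }
  ifelse(m1 == 0, Inf, m2 / m1)
}

#' Per-protein condition summary
#'
#' Detection counts, condition means, M2/M1 fold change and detection
#' class for every protein of a replicate-filtered intensity table.
#'
#' @inheritParams filter_by_replicates
#' @return Tibble with one row per protein: `protein_id`,
#'   `n_detected_M1`, `n_detected_M2`, `mean_M1`, `mean_M2`, `fc`,
#'   `detection_class` (one of `"M1_only"`, `"M2_only"`, `"both"`).
#' @export
condition_summary <- function(table, min_detected = 2,
                              conditions = c("M1", "M2")) {
  cols <- intensity_columns(table, conditions)
  m1 <- as.matrix(table[cols[[1]]])
  m2 <- as.matrix(table[cols[[2]]])
  n1 <- rowSums(!is.na(m1))
  n2 <- rowSums(!is.na(m2))
  mean1 <- ifelse(n1 > 0, rowMeans(m1, na.rm = TRUE), NA_real_)
  mean2 <- ifelse(n2 > 0, rowMeans(m2, na.rm = TRUE), NA_real_)
  in1 <- n1 >= min_detected
  in2 <- n2 >= min_detected
  if (any(!in1 & !in2)) {
    stop("condition_summary: table contains proteins detected in ",
         "neither condition; apply filter_by_replicates() first",
         call. = FALSE)
  }
  tibble::tibble(
    protein_id = table$protein_id,
    n_detected_M1 = as.integer(n1),
    n_detected_M2 = as.integer(n2),
    mean_M1 = mean1,
    mean_M2 = mean2,
    fc = fold_change(ifelse(in2, mean2, NA_real_),
                     ifelse(in1, mean1, NA_real_)),
    detection_class = dplyr::case_when(
      in1 & in2 ~ "both",
      in1       ~ "M1_only",
      TRUE      ~ "M2_only"
    )
  )
}

#' Restrict a protein set to the predicted secretome
#'
#' Plain set intersection on canonical identifiers: the computational
#' analogue of keeping only conventionally secreted proteins, motivated by
#' the observation that EV-bound cargo does not carry the proinvasive
#' activity of macrophage conditioned media.
#'
#' @param proteins Character vector of canonical protein identifiers.
#' @param secretome Character vector of predicted-secreted identifiers
#'   (see [read_secretome()]).
#' @return Character vector: `proteins` that are secreted, input order
#'   preserved.
#' @export
filter_secreted <- function(proteins, secretome) {
  unique(proteins[proteins %in% secretome])
}
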