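#' @importFrom rlang .data
NULL

# Delimiter from file extension unless given explicitly; everything the
# pipeline reads/writes is TSV by default, CSV via dialect.
infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_strict <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  readr::read_delim(
    path,
    delim = infer_delim(path, delim),
    na = c("", "NA"),
    show_col_types = FALSE,
    progress = FALSE
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": required column(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Names of the intensity columns of a protein intensity table
#'
#' Columns are recognised by the `<condition>_<replicate>` header dialect,
#' e.g. `M1_1 .. M1_3, M2_1 .. M2_3`.
#'
#' @param table A protein intensity table (see [read_intensity_table()]).
#' @param conditions Character vector of condition labels (default
#'   `c("M1", "M2")`).
#' @return Named list of character vectors, one per condition, each holding
#'   that condition's replicate column names in replicate order.
#' @export
intensity_columns <- function(table, conditions = c("M1", "M2")) {
  cols <- lapply(conditions, function(cond) {
    hits <- grep(paste0("^", cond, "_[0-9]+$"), names(table), value = TRUE)
    reps <- as.integer(sub("^.*_", "", hits))
    hits[order(reps)]
  })
  names(cols) <- conditions
  n_rep <- vapply(cols, length, integer(1))
  if (any(n_rep == 0)) {
    stop("no intensity columns found for condition(s): ",
         paste(conditions[n_rep == 0], collapse = ", "),
         " (expected headers like '", conditions[1], "_1')", call. = FALSE)
  }
  if (length(unique(n_rep)) != 1) {
    stop("conditions carry unequal replicate counts: ",
         paste(sprintf("%s=%d", conditions, n_rep), collapse = ", "),
         call. = FALSE)
  }
  cols
}

#' Read a conditioned-media protein intensity table
#'
#' Rows are proteins, columns are per-condition replicate normalized
#' intensities named `<condition>_<replicate>` (e.g. `M1_1`). A cell that is
#' empty or `NA` means the protein was not detected in that run; by default
#' a literal 0 intensity is also treated as non-detection, the common
#' encoding in label-free pipelines.
#'
#' @param path Path to a TSV (or CSV) file with a `protein_id` column and
#'   intensity columns.
#' @param conditions Condition labels expected in the headers.
#' @param aliases Alias map passed to [harmonize_id()].
#' @param zero_is_missing Treat intensity 0 as non-detection (default TRUE).
#' @param delim Field delimiter; inferred from the extension when NULL.
#' @return A tibble with a canonical `protein_id` column and numeric
#'   intensity columns; `NA` encodes non-detection.
#' @export
read_intensity_table <- function(path, conditions = c("M1", "M2"),
                                 aliases = default_aliases(),
                                 zero_is_missing = TRUE, delim = NULL) {
  df <- read_delim_strict(path, delim)
  require_columns(df, "protein_id", "intensity table")
  cols <- intensity_columns(df, conditions)
  keep <- c("protein_id", unlist(cols, use.names = FALSE))
  df <- df[keep]
  df$protein_id <- harmonize_id(df$protein_id, aliases)
  for (col in unlist(cols, use.names = FALSE)) {
    v <- as.numeric(df[[col]])
    if (any(v < 0, na.rm = TRUE)) {
      stop("intensity table: negative intensity in column ", col,
           call. = FALSE)
    }
    if (zero_is_missing) v[!is.na(v) & v == 0] <- NA_real_
    df[[col]] <- v
  }
  dup <- unique(df$protein_id[duplicated(df$protein_id)])
  if (length(dup)) {
    stop("duplicate protein_id after harmonization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a protein intensity table
#'
#' Inverse of [read_intensity_table()]: non-detection is written as an
#' empty cell so a write/read round trip is the identity.
#'
#' @param table Intensity table tibble.
#' @param path Output path (TSV unless the extension says CSV).
#' @param delim Field delimiter; inferred from the extension when NULL.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path, delim = NULL) {
  readr::write_delim(table, path, delim = infer_delim(path, delim), na = "")
  invisible(path)
}

#' Read a predicted-secreted annotation
#'
#' One gene identifier per row under a `gene_id` column; the file plays the
#' role of a predicted-secreted (conventional secretome) list such as the
#' Human Protein Atlas annotation.
#'
#' @inheritParams read_intensity_table
#' @return Character vector of unique canonical gene identifiers.
#' @export
read_secretome <- function(path, aliases = default_aliases(), delim = NULL) {
  df <- read_delim_strict(path, delim)
  require_columns(df, "gene_id", "secretome annotation")
  unique(harmonize_id(df$gene_id, aliases))
}

#' Read a ligand-receptor pair database
#'
#' Two required columns, `ligand` and `receptor`, one row per annotated
#' cognate interaction. Duplicate (ligand, receptor) rows after
#' canonicalization are dropped with a message reporting how many.
#' Self-pairs (ligand == receptor) are permitted.
#'
#' @inheritParams read_intensity_table
#' @return Tibble with canonical `ligand` and `receptor` columns, unique
#'   rows, ordered as first seen.
#' @export
read_rl_database <- function(path, aliases = default_aliases(), delim = NULL) {
  df <- read_delim_strict(path, delim)
  require_columns(df, c("ligand", "receptor"), "ligand-receptor database")
  df <- tibble::tibble(
    ligand   = harmonize_id(as.character(df$ligand), aliases),
    receptor = harmonize_id(as.character(df$receptor), aliases)
  )
  n0 <- nrow(df)
  df <- dplyr::distinct(df)
  if (nrow(df) < n0) {
    message("read_rl_database: dropped ", n0 - nrow(df),
            " duplicate pair(s)")
  }
  df
}

#' Read a bulk expression table
#'
#' A `gene_id` column plus one numeric column of normalized base-mean
#' expression per named sample.
#'
#' @inheritParams read_intensity_table
#' @return Tibble with canonical `gene_id` and one non-negative numeric
#'   column per sample.
#' @export
read_expression_table <- function(path, aliases = default_aliases(),
                                  delim = NULL) {
  df <- read_delim_strict(path, delim)
  require_columns(df, "gene_id", "expression table")
  samples <- setdiff(names(df), "gene_id")
  if (!length(samples)) {
    stop("expression table: no sample columns", call. = FALSE)
  }
  df$gene_id <- harmonize_id(df$gene_id, aliases)
  for (s in samples) {
    v <- as.numeric(df[[s]])
    if (any(is.na(v)) || any(v < 0)) {
      stop("expression table: sample '", s,
           "' has missing or negative base_mean", call. = FALSE)
    }
    df[[s]] <- v
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id after harmonization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a single-cell cluster marker table
#'
#' One row per (gene, cluster) with the detection statistics of the usual
#' cluster-marker output: `pct.1` (fraction of cells in the cluster
#' detecting the gene), `pct.2` (average such fraction over all other
#' clusters), a log2 fold change and an adjusted p value. Dotted and
#' undotted pct headers are both accepted.
#'
#' @inheritParams read_intensity_table
#' @return Tibble with columns `gene_id`, `cluster_id`, `pct1`, `pct2`,
#'   `log2_fc`, `p_adj`.
#' @export
read_marker_table <- function(path, aliases = default_aliases(),
                              delim = NULL) {
  df <- read_delim_strict(path, delim)
  names(df)[names(df) == "pct.1"] <- "pct1"
  names(df)[names(df) == "pct.2"] <- "pct2"
  names(df)[names(df) == "avg_log2FC"] <- "log2_fc"
  for (col in c("gene_id", "cluster_id", "pct1", "pct2", "log2_fc", "p_adj")) {
    if (!col %in% names(df)) {
      stop("marker table: ", sub("pct", "pct.", col, fixed = TRUE),
           " missing", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    gene_id    = harmonize_id(as.character(df$gene_id), aliases),
    cluster_id = as.character(df$cluster_id),
    pct1       = as.numeric(df$pct1),
    pct2       = as.numeric(df$pct2),
    log2_fc    = as.numeric(df$log2_fc),
    p_adj      = as.numeric(df$p_adj)
  )
  if (any(is.na(out$pct1)) || any(out$pct1 < 0 | out$pct1 > 1) ||
      any(is.na(out$pct2)) || any(out$pct2 < 0 | out$pct2 > 1)) {
    stop("marker table: pct.1/pct.2 must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(out$p_adj) & (out$p_adj < 0 | out$p_adj > 1))) {
    stop("marker table: p_adj must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Read a cluster annotation table
#'
#' Maps each cluster to a cell type (`malignant`, `TAM`, `T_cell`, `other`)
#' and, for TAM clusters only, optionally an ontogeny
#' (`microglia` or `BMD`).
#'
#' @inheritParams read_intensity_table
#' @return Tibble with columns `cluster_id`, `cell_type` and `ontogeny`
#'   (`NA` for non-TAM clusters).
#' @export
read_cluster_annotation <- function(path, delim = NULL) {
  df <- read_delim_strict(path, delim)
  require_columns(df, c("cluster_id", "cell_type"), "cluster annotation")
  out <- tibble::tibble(
    cluster_id = as.character(df$cluster_id),
    cell_type  = as.character(df$cell_type),
    ontogeny   = if ("ontogeny" %in% names(df)) as.character(df$ontogeny)
                 else NA_character_
  )
  bad_type <- setdiff(out$cell_type, c("malignant", "TAM", "T_cell", "other"))
  if (length(bad_type)) {
    stop("cluster annotation: unknown cell_type: ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  stray <- !is.na(out$ontogeny) & out$cell_type != "TAM"
  if (any(stray)) {
    stop("cluster annotation: ontogeny given for non-TAM cluster(s): ",
         paste(out$cluster_id[stray], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(out$cluster_id)) {
    stop("cluster annotation: duplicate cluster_id", call. = FALSE)
  }
  out
}

#' Read a differential-expression table
#'
#' Columns `gene_id`, `log2_fc`, `p_adj` as produced by a bulk or
#' pseudobulk differential-expression analysis.
#'
#' @inheritParams read_intensity_table
#' @return Tibble with canonical `gene_id`, numeric `log2_fc` and `p_adj`.
#' @export
read_deg_table <- function(path, aliases = default_aliases(), delim = NULL) {
  df <- read_delim_strict(path, delim)
  require_columns(df, c("gene_id", "log2_fc", "p_adj"), "DEG table")
  out <- tibble::tibble(
    gene_id = harmonize_id(as.character(df$gene_id), aliases),
    log2_fc = as.numeric(df$log2_fc),
    p_adj   = as.numeric(df$p_adj)
  )
  if (any(!is.na(out$p_adj) & (out$p_adj < 0 | out$p_adj > 1))) {
    stop("DEG table: p_adj must lie in [0, 1]", call. = FALSE)
  }
  out
}
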