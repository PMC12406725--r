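#' Pipeline configuration
#'
#' Aggregates every input path and threshold of the crosstalk pipeline:
#' the 2-of-3 replicate detection filter, the receptor base-mean gate of 1,
#' the polarization fold-change bounds 2 and 0.5, the DEG cutoffs
#' (|log2FC| >= 1, padj < 0.05) and the BMD DEG ranking cutoff
#' (padj < 1e-3).
#'
#' @param intensity,secretome,rl_db,expression Paths to the required
#'   input tables.
#' @param markers,cluster_annotation,bmd_degs Optional single-cell inputs;
#'   prioritization runs only when `markers` and `cluster_annotation` are
#'   both given.
#' @param out_dir Output directory.
#' @param min_detected Replicate-detection filter threshold.
#' @param zero_is_missing Treat 0 intensity as non-detection.
#' @param crosstalk A [crosstalk_config()].
#' @param deg_lfc_min,deg_padj_max Generic DEG filter bounds.
#' @param bmd_padj_max,top_k BMD DEG ranking bounds.
#' @param ontogeny_ratio Passed to [ontogeny_call()].
#' @param conditions Condition labels of the intensity table headers.
#' @param aliases Alias map used by every reader.
#' @return A list of class `pipeline_config` (not yet validated; see
#'   [validate_config()]).
#' @export
pipeline_config <- function(intensity, secretome, rl_db, expression,
                            out_dir,
                            markers = NULL, cluster_annotation = NULL,
                            bmd_degs = NULL,
                            min_detected = 2, zero_is_missing = TRUE,
                            crosstalk = crosstalk_config(),
                            deg_lfc_min = 1, deg_padj_max = 0.05,
                            bmd_padj_max = 1e-3, top_k = 3,
                            ontogeny_ratio = 1.5,
                            conditions = c("M1", "M2"),
                            aliases = default_aliases()) {
  structure(
    list(intensity = intensity, secretome = secretome, rl_db = rl_db,
         expression = expression, out_dir = out_dir, markers = markers,
         cluster_annotation = cluster_annotation, bmd_degs = bmd_degs,
         min_detected = min_detected, zero_is_missing = zero_is_missing,
         crosstalk = crosstalk, deg_lfc_min = deg_lfc_min,
         deg_padj_max = deg_padj_max, bmd_padj_max = bmd_padj_max,
         top_k = top_k, ontogeny_ratio = ontogeny_ratio,
         conditions = conditions, aliases = aliases),
    class = "pipeline_config"
  )
}

#' All validation problems of a pipeline configuration
#'
#' Collects every problem instead of failing at the first, so a config
#' file can be fixed in one pass.
#'
#' @param config A [pipeline_config()] or a plain list with the same
#'   fields.
#' @return Character vector of problems; empty when the config is valid.
#' @export
config_errors <- function(config) {
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  for (f in c("intensity", "secretome", "rl_db", "expression")) {
    p <- config[[f]]
    if (is.null(p)) need(FALSE, paste0("missing required path: ", f))
    else need(file.exists(p), paste0(f, ": file not found: ", p))
  }
  for (f in c("markers", "cluster_annotation", "bmd_degs")) {
    p <- config[[f]]
    if (!is.null(p)) need(file.exists(p), paste0(f, ": file not found: ", p))
  }
  if (!is.null(config$markers) && is.null(config$cluster_annotation)) {
    need(FALSE, "markers given without cluster_annotation")
  }
  need(!is.null(config$out_dir), "missing out_dir")
  ct <- config$crosstalk
  need(is.numeric(ct$receptor_gate) && ct$receptor_gate >= 0,
       "receptor_gate must be >= 0")
  need(is.numeric(ct$fc_low) && is.numeric(ct$fc_high) &&
         0 < ct$fc_low && ct$fc_low < ct$fc_high,
       "fc_low < fc_high required (both > 0)")
  need(is.numeric(config$min_detected) && config$min_detected >= 1,
       "min_detected must be >= 1")
  need(is.numeric(config$deg_padj_max) && config$deg_padj_max > 0 &&
         config$deg_padj_max <= 1, "deg_padj_max must lie in (0, 1]")
  need(is.numeric(config$bmd_padj_max) && config$bmd_padj_max > 0 &&
         config$bmd_padj_max <= 1, "bmd_padj_max must lie in (0, 1]")
  need(is.numeric(config$ontogeny_ratio) && config$ontogeny_ratio >= 1,
       "ontogeny_ratio must be >= 1")
  errs
}

#' Validate a pipeline configuration
#'
#' Accepts a [pipeline_config()] object or the path of a YAML file whose
#' keys mirror the constructor's arguments (`crosstalk:` as a nested
#' block). Reports every problem at once.
#'
#' @param config Config object or YAML path.
#' @return The validated `pipeline_config`; errors carry the full problem
#'   list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- config_from_yaml(config)
  }
  errs <- config_errors(config)
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  config
}

config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  ct <- do.call(crosstalk_config, as.list(y$crosstalk %||% list()))
  y$crosstalk <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # relative paths resolve against the config file's directory
  base <- dirname(normalizePath(path))
  for (f in c("intensity", "secretome", "rl_db", "expression", "markers",
              "cluster_annotation", "bmd_degs", "out_dir")) {
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]])) {
      y[[f]] <- file.path(base, y[[f]])
    }
  }
  do.call(pipeline_config, c(y, list(crosstalk = ct)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full crosstalk pipeline
#'
#' Executes the stages in order — replicate-detection filtering,
#' detection-set decomposition, condition summaries and fold changes,
#' secretome restriction, receptor gating and pair construction,
#' polarization classification, and (when single-cell inputs are present)
#' ligand prioritization — then writes `interactions.tsv`,
#' `priorities.tsv`, `venn.json` and `report.json` into the output
#' directory. Fully deterministic: identical config and inputs give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()] or YAML config path; validated
#'   first.
#' @param quiet Suppress per-stage progress messages.
#' @return The run report (a list), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (!quiet) message("[tamtalk] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  tab <- stage("read_inputs", read_intensity_table(
    config$intensity, conditions = config$conditions,
    aliases = config$aliases, zero_is_missing = config$zero_is_missing))
  secretome <- stage("read_inputs",
                     read_secretome(config$secretome, config$aliases))
  db <- stage("read_inputs", read_rl_database(config$rl_db, config$aliases))
  expr <- stage("read_inputs",
                read_expression_table(config$expression, config$aliases))
  say("inputs: ", nrow(tab), " proteins, ", length(secretome),
      " secreted ids, ", nrow(db), " DB pairs, ", nrow(expr),
      " expression genes")

  filt <- stage("replicate_filter",
                filter_by_replicates(tab, config$min_detected,
                                     config$conditions))
  sets <- stage("detection", detection_sets(filt, config$min_detected,
                                            config$conditions))
  venn <- venn_counts(sets[[1]], sets[[2]])
  say("replicate filter: ", nrow(filt), " proteins retained (",
      venn$m1_only, " M1-only, ", venn$m2_only, " M2-only, ",
      venn$both, " both)")

  summ <- stage("summary", condition_summary(filt, config$min_detected,
                                             config$conditions))
  detected <- union(sets[[1]], sets[[2]])
  ligands <- filter_secreted(detected, secretome)
  say("secretome filter: ", length(ligands), " detected secreted ligands")

  records <- stage("crosstalk",
                   build_interactions(ligands, summ, expr, db,
                                      config$crosstalk))
  part <- partition_counts(records)
  say("crosstalk: ", nrow(records), " pairs (",
      part[["M1_specific"]], " M1-specific, ",
      part[["M2_specific"]], " M2-specific, ", part[["pan"]], " pan)")

  priorities <- NULL
  top_bmd <- NULL
  if (!is.null(config$markers)) {
    markers <- stage("prioritize",
                     read_marker_table(config$markers, config$aliases))
    annotation <- stage("prioritize",
                        read_cluster_annotation(config$cluster_annotation))
    m2_ligands <- unique(
      records$ligand[records$polarization_class == "M2_specific"])
    priorities <- stage("prioritize", suppressMessages(
      prioritize_ligands(m2_ligands, markers, annotation,
                         config$ontogeny_ratio)))
    say("prioritize: ", sum(priorities$tam_predominant), " of ",
        nrow(priorities), " M2-specific ligands TAM-predominant")
    if (!is.null(config$bmd_degs)) {
      degs <- stage("prioritize",
                    read_deg_table(config$bmd_degs, config$aliases))
      top_bmd <- stage("prioritize", suppressMessages(
        rank_bmd_degs(degs, config$bmd_padj_max, config$top_k)))
      say("prioritize: top BMD DEGs: ", paste(top_bmd, collapse = ", "))
    }
  }

  stopifnot(venn$m1_only + venn$m2_only + venn$both == venn$total,
            sum(part) == nrow(records))
  report <- list(
    package = "tamtalk",
    version = as.character(utils::packageVersion("tamtalk")),
    n_proteins_input = nrow(tab),
    n_proteins_filtered = nrow(filt),
    venn = venn,
    n_detected_secreted_ligands = length(ligands),
    n_interactions = nrow(records),
    partition = as.list(part),
    unique_members = list(
      all = as.list(unique_members(records)),
      M2_specific = as.list(unique_members(records, "M2_specific")),
      M1_specific = as.list(unique_members(records, "M1_specific")),
      pan = as.list(unique_members(records, "pan"))
    ),
    tam_predominant_ligands =
      if (!is.null(priorities)) {
        priorities$ligand[priorities$tam_predominant]
      },
    bmd_ligands =
      if (!is.null(priorities)) {
        priorities$ligand[priorities$tam_predominant &
                            priorities$ontogeny %in% "BMD"]
      },
    top_bmd_degs = top_bmd,
    config = list(
      min_detected = config$min_detected,
      zero_is_missing = config$zero_is_missing,
      receptor_gate = config$crosstalk$receptor_gate,
      gate_sample = config$crosstalk$gate_sample,
      fc_high = config$crosstalk$fc_high,
      fc_low = config$crosstalk$fc_low,
      deg_lfc_min = config$deg_lfc_min,
      deg_padj_max = config$deg_padj_max,
      bmd_padj_max = config$bmd_padj_max,
      top_k = config$top_k,
      ontogeny_ratio = config$ontogeny_ratio
    )
  )

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character()
  stage("write_outputs", tryCatch({
    readr::write_tsv(records, out("interactions.tsv"))
    written <- c(written, out("interactions.tsv"))
    if (!is.null(priorities)) {
      readr::write_tsv(priorities, out("priorities.tsv"), na = "")
      written <- c(written, out("priorities.tsv"))
    }
    jsonlite::write_json(venn, out("venn.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, out("venn.json"))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }, error = function(e) {
    unlink(written)
    stop(conditionMessage(e), call. = FALSE)
  }))
  say("outputs written to ", config$out_dir)
  invisible(report)
}
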