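#' Cluster enrichment score
#'
#' pct.1 divided by pct.2: the detection fraction of a gene within a
#' cluster relative to the average detection fraction across all other
#' clusters. A gene detected in the cluster but nowhere else scores
#' `Inf`; a gene undetected in the cluster scores 0 (including the 0/0
#' case — a gene absent everywhere is not enriched).
#'
#' @param pct1,pct2 Numeric vectors in `[0, 1]`.
#' @return Numeric vector of extended non-negative enrichment scores.
#' @export
enrichment_score <- function(pct1, pct2) {
  ok <- function(x) is.numeric(x) && !any(is.na(x)) && all(x >= 0 & x <= 1)
  if (!ok(pct1) || !ok(pct2)) {
    stop("pct1 and pct2 must lie in [0, 1]", call. = FALSE)
  }
  ifelse(pct1 == 0, 0, ifelse(pct2 == 0, Inf, pct1 / pct2))
}

#' Detection matrix container
#'
#' Bundles a cells x genes logical detection matrix with per-cell cluster
#' labels. This is the oracle substrate for pct.1/pct.2 statistics: marker
#' tables can be recomputed from it by direct per-cell counting.
#'
#' @param detect Logical matrix, cells in rows, genes in named columns.
#' @param clusters Character (or coercible) vector of cluster labels, one
#'   per cell.
#' @return A list of class `detection_matrix`.
#' @export
detection_matrix <- function(detect, clusters) {
  if (!is.matrix(detect) || !is.logical(detect)) {
    stop("detect must be a logical matrix", call. = FALSE)
  }
  if (is.null(colnames(detect))) {
    stop("detect must have gene column names", call. = FALSE)
  }
  clusters <- as.character(clusters)
  if (length(clusters) != nrow(detect) || anyNA(clusters)) {
    stop("clusters must label every cell", call. = FALSE)
  }
  if (length(unique(clusters)) < 2) {
    stop("need at least 2 clusters", call. = FALSE)
  }
  structure(list(detect = detect, clusters = clusters),
            class = "detection_matrix")
}

#' pct.1 and pct.2 of one gene in one cluster
#'
#' `pct1` is the fraction of the cluster's cells detecting the gene.
#' `pct2` is by default the unweighted mean of the per-cluster detection
#' fractions over all other clusters (each other cluster contributes
#' equally regardless of size); `other = "pooled"` instead pools all
#' non-cluster cells into one fraction.
#'
#' @param dm A [detection_matrix()].
#' @param gene Gene (column) name.
#' @param cluster Cluster label.
#' @param other How to average the other clusters: `"mean"` (default) or
#'   `"pooled"`.
#' @return Named numeric vector `c(pct1=, pct2=)`.
#' @export
compute_pcts <- function(dm, gene, cluster, other = c("mean", "pooled")) {
  other <- match.arg(other)
  if (!gene %in% colnames(dm$detect)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  if (!cluster %in% dm$clusters) {
    stop("unknown or empty cluster: ", cluster, call. = FALSE)
  }
  v <- dm$detect[, gene]
  in_cl <- dm$clusters == cluster
  pct1 <- sum(v[in_cl]) / sum(in_cl)
  pct2 <- if (other == "pooled") {
    sum(v[!in_cl]) / sum(!in_cl)
  } else {
    others <- setdiff(unique(dm$clusters), cluster)
    mean(vapply(others, function(cl) {
      idx <- dm$clusters == cl
      sum(v[idx]) / sum(idx)
    }, numeric(1)))
  }
  c(pct1 = pct1, pct2 = pct2)
}

#' Marker table from a detection matrix
#'
#' Computes pct.1/pct.2 for every (gene, cluster) combination via
#' [compute_pcts()], plus the enrichment-based log2 fold change and a
#' BH-adjusted Fisher exact p value contrasting detection inside vs
#' outside the cluster.
#'
#' @inheritParams compute_pcts
#' @return Marker table tibble (`gene_id`, `cluster_id`, `pct1`, `pct2`,
#'   `log2_fc`, `p_adj`) in the same shape [read_marker_table()] returns.
#' @export
marker_table_from_matrix <- function(dm, other = c("mean", "pooled")) {
  other <- match.arg(other)
  genes <- colnames(dm$detect)
  clusters <- sort(unique(dm$clusters), method = "radix")
  grid <- expand.grid(gene_id = genes, cluster_id = clusters,
                      stringsAsFactors = FALSE)
  pct <- mapply(function(g, cl) compute_pcts(dm, g, cl, other),
                grid$gene_id, grid$cluster_id)
  eps <- 1e-9  # pseudo-fraction so exclusive detection has a finite lfc
  p_raw <- mapply(function(g, cl) {
    v <- dm$detect[, g]
    in_cl <- dm$clusters == cl
    tab <- matrix(c(sum(v & in_cl), sum(!v & in_cl),
                    sum(v & !in_cl), sum(!v & !in_cl)), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, grid$gene_id, grid$cluster_id)
  p1 <- unname(pct["pct1", ])
  p2 <- unname(pct["pct2", ])
  tibble::tibble(
    gene_id    = grid$gene_id,
    cluster_id = grid$cluster_id,
    pct1       = p1,
    pct2       = p2,
    log2_fc    = log2((p1 + eps) / (p2 + eps)),
    p_adj      = stats::p.adjust(unname(p_raw), method = "BH")
  )
}

#' Annotate clusters from marker gene sets
#'
#' Assigns each cluster the cell type whose marker genes have the highest
#' mean enrichment score in it (ties broken by mean pct.1, then by
#' lexicographic cell-type name). Explicit per-cluster overrides, as
#' studies usually publish ("cluster 17 represents T lymphocytes"), win
#' over marker scoring. A cluster in which no marker gene appears is
#' assigned `"other"` with a warning.
#'
#' @param markers Marker table tibble.
#' @param marker_sets Named list mapping cell type to a character vector
#'   of marker genes; sets must be non-empty and pairwise disjoint.
#' @param overrides Optional named character vector `cluster_id ->
#'   cell_type`.
#' @return Cluster annotation tibble (`cluster_id`, `cell_type`,
#'   `ontogeny = NA`).
#' @export
annotate_clusters_by_markers <- function(markers, marker_sets,
                                         overrides = NULL) {
  if (!length(marker_sets) || any(!lengths(marker_sets))) {
    stop("marker_sets must be non-empty", call. = FALSE)
  }
  all_genes <- unlist(marker_sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("marker_sets must be disjoint", call. = FALSE)
  }
  clusters <- sort(unique(markers$cluster_id), method = "radix")
  types <- sort(names(marker_sets), method = "radix")
  cell_type <- vapply(clusters, function(cl) {
    rows <- markers[markers$cluster_id == cl, , drop = FALSE]
    score <- vapply(types, function(ty) {
      hit <- rows[rows$gene_id %in% marker_sets[[ty]], , drop = FALSE]
      if (!nrow(hit)) return(c(-Inf, -Inf))
      # Inf-safe mean: rank enrichment by finite surrogate
      enr <- enrichment_score(hit$pct1, hit$pct2)
      enr[is.infinite(enr)] <- .Machine$double.xmax
      c(mean(enr), mean(hit$pct1))
    }, numeric(2))
    if (all(score[1, ] == -Inf)) return(NA_character_)
    best <- order(-score[1, ], -score[2, ], tolower(types),
                  method = "radix")[1]
    types[best]
  }, character(1))
  none <- is.na(cell_type)
  if (any(none)) {
    warning("no marker gene present for cluster(s): ",
            paste(clusters[none], collapse = ", "),
            "; assigned 'other'", call. = FALSE)
    cell_type[none] <- "other"
  }
  if (!is.null(overrides)) {
    hit <- match(clusters, names(overrides))
    cell_type[!is.na(hit)] <- unname(overrides[hit[!is.na(hit)]])
  }
  tibble::tibble(cluster_id = clusters, cell_type = unname(cell_type),
                 ontogeny = NA_character_)
}

# Per-ligand enrichment over clusters with the deterministic argmax
# tie-break: higher enrichment, then higher pct1, then lower cluster_id.
best_cluster_row <- function(ligand, markers) {
  rows <- markers[markers$gene_id == ligand, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  enr <- enrichment_score(rows$pct1, rows$pct2)
  ord <- order(-ifelse(is.infinite(enr), .Machine$double.xmax, enr),
               -rows$pct1, rows$cluster_id, method = "radix")
  cbind(rows[ord[1], , drop = FALSE], enrichment = enr[ord[1]])
}

#' Is a ligand predominantly expressed by TAM clusters?
#'
#' "Predominantly expressed" is operationalized as: the cluster where the
#' ligand's enrichment score is maximal (ties: higher pct.1, then lower
#' cluster id) is annotated as a TAM cluster.
#'
#' @param ligand Gene identifier.
#' @param markers Marker table tibble.
#' @param annotation Cluster annotation tibble.
#' @return List with `tam_predominant` (logical), `best_cluster`
#'   (cluster id or `NA` if the ligand is absent from the table) and
#'   `enrichment` (score in the best cluster).
#' @export
tam_predominant <- function(ligand, markers, annotation) {
  best <- best_cluster_row(ligand, markers)
  if (is.null(best)) {
    message("tam_predominant: ligand absent from marker table: ", ligand)
    return(list(tam_predominant = FALSE, best_cluster = NA_character_,
                enrichment = NA_real_))
  }
  ty <- annotation$cell_type[match(best$cluster_id, annotation$cluster_id)]
  if (is.na(ty)) {
    stop("cluster not annotated: ", best$cluster_id, call. = FALSE)
  }
  list(tam_predominant = identical(ty, "TAM"),
       best_cluster = best$cluster_id,
       enrichment = best$enrichment)
}

#' Microglia vs bone-marrow-derived ontogeny call for a TAM ligand
#'
#' Compares the ligand's maximum enrichment score among BMD-annotated TAM
#' clusters against its maximum among microglia-annotated clusters; the
#' larger side is called when it exceeds the other by at least
#' `ontogeny_ratio`, otherwise `"mixed"`.
#'
#' @inheritParams tam_predominant
#' @param ontogeny_ratio Minimum max-enrichment ratio for a one-sided
#'   call (default 1.5).
#' @return One of `"BMD"`, `"microglia"`, `"mixed"`.
#' @export
ontogeny_call <- function(ligand, markers, annotation,
                          ontogeny_ratio = 1.5) {
  tam <- annotation[annotation$cell_type == "TAM", , drop = FALSE]
  if (!nrow(tam) || all(is.na(tam$ontogeny))) {
    stop("annotation carries no TAM ontogeny", call. = FALSE)
  }
  max_enr <- function(cluster_ids) {
    rows <- markers[markers$gene_id == ligand &
                      markers$cluster_id %in% cluster_ids, , drop = FALSE]
    if (!nrow(rows)) return(0)
    max(enrichment_score(rows$pct1, rows$pct2))
  }
  bmd <- max_enr(tam$cluster_id[tam$ontogeny %in% "BMD"])
  mic <- max_enr(tam$cluster_id[tam$ontogeny %in% "microglia"])
  if (bmd > mic * ontogeny_ratio) "BMD"
  else if (mic > bmd * ontogeny_ratio) "microglia"
  else "mixed"
}

#' Filter a differential-expression table
#'
#' Keeps genes with `|log2_fc| >= lfc_min` (inclusive) and
#' `p_adj < padj_max` (strict), the standard effect-size plus significance
#' cutoff.
#'
#' @param degs DEG tibble (`gene_id`, `log2_fc`, `p_adj`).
#' @param lfc_min Inclusive absolute log2 fold-change bound (default 1).
#' @param padj_max Strict adjusted-p bound (default 0.05).
#' @return The filtered tibble.
#' @export
filter_degs <- function(degs, lfc_min = 1, padj_max = 0.05) {
  degs[abs(degs$log2_fc) >= lfc_min & degs$p_adj < padj_max, ,
       drop = FALSE]
}

#' Top-k genes upregulated in BMD TAMs
#'
#' For a BMD-vs-microglia contrast with positive log2 fold change meaning
#' "up in BMD": keeps genes at `p_adj < padj_max` with `log2_fc > 0`,
#' orders by descending fold change (ties: ascending p, then gene name)
#' and returns the first `k`.
#'
#' @inheritParams filter_degs
#' @param padj_max Strict adjusted-p bound (default 1e-3).
#' @param k Number of genes to return (default 3). Fewer survivors are
#'   returned as-is with a message.
#' @return Character vector of up to `k` gene identifiers, ranked.
#' @export
rank_bmd_degs <- function(degs, padj_max = 1e-3, k = 3) {
  up <- degs[degs$p_adj < padj_max & degs$log2_fc > 0, , drop = FALSE]
  ord <- order(-up$log2_fc, up$p_adj, up$gene_id, method = "radix")
  ranked <- up$gene_id[ord]
  if (length(ranked) < k) {
    message("rank_bmd_degs: only ", length(ranked),
            " gene(s) pass the cutoff (k = ", k, ")")
    return(ranked)
  }
  ranked[seq_len(k)]
}

#' Prioritize candidate ligands against single-cell cluster statistics
#'
#' For each candidate ligand (typically the unique ligands of the
#' M2-specific interaction class) determines whether it is predominantly
#' expressed by TAM clusters, and for TAM-predominant ligands calls its
#' ontogeny preference when the annotation carries one. Rows are ordered
#' by TAM predominance, then descending best enrichment, then ligand name.
#'
#' @param ligands Character vector of candidate ligand identifiers.
#' @param markers Marker table tibble.
#' @param annotation Cluster annotation tibble.
#' @param ontogeny_ratio Passed to [ontogeny_call()].
#' @return Tibble: `ligand`, `tam_predominant`, `best_cluster`,
#'   `enrichment`, `ontogeny` (`NA` unless TAM-predominant and ontogeny
#'   is annotated).
#' @export
prioritize_ligands <- function(ligands, markers, annotation,
                               ontogeny_ratio = 1.5) {
  has_ontogeny <- any(!is.na(annotation$ontogeny))
  rows <- lapply(unique(ligands), function(lg) {
    tp <- tam_predominant(lg, markers, annotation)
    onto <- if (tp$tam_predominant && has_ontogeny) {
      ontogeny_call(lg, markers, annotation, ontogeny_ratio)
    } else NA_character_
    tibble::tibble(ligand = lg, tam_predominant = tp$tam_predominant,
                   best_cluster = tp$best_cluster,
                   enrichment = tp$enrichment, ontogeny = onto)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(ligand = character(),
                          tam_predominant = logical(),
                          best_cluster = character(),
                          enrichment = numeric(),
                          ontogeny = character()))
  }
  key <- ifelse(is.infinite(out$enrichment), .Machine$double.xmax,
                out$enrichment)
  key[is.na(key)] <- -1
  out[order(-out$tam_predominant, -key, out$ligand, method = "radix"), ,
      drop = FALSE]
}
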