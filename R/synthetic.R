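# Run code under a private RNG state so generators are pure functions of
# (params, seed) and never disturb the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scenario parameters
#'
#' Parameters of the seeded generators that emulate every pipeline input
#' with planted ground truth. The default scenario is sized to the study's
#' scale: 1,093 conditioned-media proteins of which 207 are planted
#' M1-exclusive and 63 M2-exclusive, biological triplicates per
#' polarization state, a 3,631-pair interaction database with roughly 7%
#' planted cognate pairs, and a cluster-structured single-cell detection
#' matrix carrying the candidate TAM ligands.
#'
#' @param seed Mandatory integer seed; every generator derives its RNG
#'   stream from it.
#' @param n_proteins Total proteins in the intensity table.
#' @param n_m1_only,n_m2_only Planted condition-exclusive proteins (the
#'   other condition is fully non-detected by design).
#' @param n_m2_specific,n_m1_specific Planted two-condition proteins with
#'   the M2-high / M1-high effect; the remaining two-condition proteins
#'   are planted pan (effect 1).
#' @param effect_fc Named numeric vector of planted true M2/M1 intensity
#'   ratios per class (defaults 4, 0.25, 1).
#' @param dropout Per-replicate non-detection probability in `[0, 1)`.
#' @param dropout_model `"iid"` (default) or `"intensity"`, where lower
#'   intensities drop out more often (logistic in log intensity with the
#'   same marginal rate).
#' @param R Replicates per condition.
#' @param intensity_log_mean,intensity_log_sd Log-normal replicate
#'   intensity base (natural log scale); `protein_log_sd` adds
#'   between-protein abundance spread.
#' @param frac_secreted Fraction of proteins planted as conventionally
#'   secreted.
#' @param n_receptors Genes in the bulk expression table.
#' @param frac_gated Fraction of receptors planted above the expression
#'   gate.
#' @param receptor_gate,gate_margin Gate threshold and the open margin
#'   kept around it (no planted mass within `gate_margin` of the gate).
#' @param n_db_pairs Rows of the ligand-receptor database.
#' @param frac_cognate Fraction of database rows planted cognate
#'   (detected secreted ligand x gated receptor); the rest are decoys that
#'   fail at least one side.
#' @param n_cells,n_clusters Single-cell matrix size; clusters are labeled
#'   `"0" .. "n_clusters-1"` with near-equal sizes.
#' @param tam_clusters,bmd_clusters TAM cluster labels and the subset of
#'   them planted as bone-marrow-derived (the rest of the TAM clusters are
#'   microglia); remaining clusters are malignant.
#' @param planted_tam_genes Candidate ligand genes planted as
#'   TAM-expressed; `planted_bmd_genes` (a subset) are planted only in BMD
#'   TAM clusters.
#' @param planted_pct1 Detection probability of planted genes in their
#'   planted clusters; `background_pct` elsewhere.
#' @param n_background_genes Unstructured genes detected uniformly at
#'   `background_pct`.
#' @param gate_sample Name of the gating sample column in the generated
#'   expression table.
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(seed,
                            n_proteins = 1093,
                            n_m1_only = 207,
                            n_m2_only = 63,
                            n_m2_specific = 206,
                            n_m1_specific = 206,
                            effect_fc = c(M2_specific = 4, M1_specific = 0.25,
                                          pan = 1),
                            dropout = 0,
                            dropout_model = c("iid", "intensity"),
                            R = 3,
                            intensity_log_mean = log(1e5),
                            intensity_log_sd = 0.25,
                            protein_log_sd = 1,
                            frac_secreted = 0.3,
                            n_receptors = 2000,
                            frac_gated = 0.6,
                            receptor_gate = 1,
                            gate_margin = 0.1,
                            n_db_pairs = 3631,
                            frac_cognate = 0.07,
                            n_cells = 800,
                            n_clusters = 8,
                            tam_clusters = c("2", "3", "6", "7"),
                            bmd_clusters = c("2", "3"),
                            planted_tam_genes = c("ECM1", "A2M", "APOE",
                                                  "GAS6", "BIGH3", "S100A9",
                                                  "MMP9", "GRN", "APOC2",
                                                  "LYZ"),
                            planted_bmd_genes = c("BIGH3", "S100A9", "LYZ"),
                            planted_pct1 = 0.8,
                            background_pct = 0.05,
                            n_background_genes = 40,
                            gate_sample = "gsc_m2cm_invasive") {
  if (missing(seed) || !is.numeric(seed) || is.na(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  dropout_model <- match.arg(dropout_model)
  p <- list(
    seed = as.integer(seed), n_proteins = n_proteins,
    n_m1_only = n_m1_only, n_m2_only = n_m2_only,
    n_m2_specific = n_m2_specific, n_m1_specific = n_m1_specific,
    effect_fc = effect_fc, dropout = dropout,
    dropout_model = dropout_model, R = R,
    intensity_log_mean = intensity_log_mean,
    intensity_log_sd = intensity_log_sd, protein_log_sd = protein_log_sd,
    frac_secreted = frac_secreted, n_receptors = n_receptors,
    frac_gated = frac_gated, receptor_gate = receptor_gate,
    gate_margin = gate_margin, n_db_pairs = n_db_pairs,
    frac_cognate = frac_cognate, n_cells = n_cells,
    n_clusters = n_clusters, tam_clusters = as.character(tam_clusters),
    bmd_clusters = as.character(bmd_clusters),
    planted_tam_genes = planted_tam_genes,
    planted_bmd_genes = planted_bmd_genes,
    planted_pct1 = planted_pct1, background_pct = background_pct,
    n_background_genes = n_background_genes, gate_sample = gate_sample
  )
  n_excl <- p$n_m1_only + p$n_m2_only
  n_eff <- p$n_m2_specific + p$n_m1_specific
  if (n_excl + n_eff > p$n_proteins) {
    stop("planted class counts exceed n_proteins", call. = FALSE)
  }
  fracs <- c(p$dropout, p$frac_secreted, p$frac_gated, p$frac_cognate,
             p$planted_pct1, p$background_pct)
  if (any(fracs < 0 | fracs > 1) || p$dropout >= 1) {
    stop("fractions must lie in [0, 1] (dropout < 1)", call. = FALSE)
  }
  if (!all(p$bmd_clusters %in% p$tam_clusters) ||
      !all(p$tam_clusters %in% as.character(seq_len(p$n_clusters) - 1))) {
    stop("tam_clusters/bmd_clusters outside cluster range", call. = FALSE)
  }
  if (!all(p$planted_bmd_genes %in% p$planted_tam_genes)) {
    stop("planted_bmd_genes must be a subset of planted_tam_genes",
         call. = FALSE)
  }
  structure(p, class = "scenario_params")
}

#' Generate a synthetic conditioned-media proteomics table
#'
#' Plants a polarization design: each protein gets a detection design
#' (both conditions, M1-only or M2-only) and a true M2/M1 effect ratio.
#' Replicate intensities are log-normal; the replicate base value is
#' shared between conditions and the M2 column is the base times the
#' planted effect, so at zero dropout the empirical fold change equals the
#' planted ratio exactly. Non-detection is then masked per replicate with
#' probability `dropout`. The planted candidate TAM ligand genes are
#' embedded among the secreted M2-specific proteins so that downstream
#' single-cell prioritization has matching identifiers.
#'
#' @param params A [scenario_params()].
#' @return List with `table` (protein intensity tibble) and `truth`
#'   (tibble: `protein_id`, `secreted`, `detection_design`,
#'   `planted_class`, `effect_fc`).
#' @export
generate_proteomics <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_proteins
    n_pan <- n - p$n_m1_only - p$n_m2_only - p$n_m2_specific -
      p$n_m1_specific
    design <- c(rep("M1_only", p$n_m1_only), rep("M2_only", p$n_m2_only),
                rep("both", n - p$n_m1_only - p$n_m2_only))
    class <- c(rep("M1_specific", p$n_m1_only),
               rep("M2_specific", p$n_m2_only),
               rep("M2_specific", p$n_m2_specific),
               rep("M1_specific", p$n_m1_specific),
               rep("pan", n_pan))
    effect <- unname(p$effect_fc[ifelse(design == "both", class, "pan")])
    effect[design != "both"] <- NA_real_
    secreted <- rep(FALSE, n)
    secreted[sample.int(n, round(p$frac_secreted * n))] <- TRUE

    ids <- sprintf("G%04d", seq_len(n))
    # embed the candidate ligand gene names among secreted M2-specific
    # two-condition proteins so sc prioritization sees them
    host <- which(design == "both" & class == "M2_specific" & secreted)
    k <- min(length(p$planted_tam_genes), length(host))
    ids[host[seq_len(k)]] <- p$planted_tam_genes[seq_len(k)]

    base <- matrix(
      stats::rlnorm(n * p$R,
                    meanlog = p$intensity_log_mean +
                      stats::rnorm(n, 0, p$protein_log_sd),
                    sdlog = p$intensity_log_sd),
      nrow = n
    )
    m1 <- base
    m2 <- base * ifelse(is.na(effect), 1, effect)
    m1[design == "M2_only", ] <- NA_real_
    m2[design == "M1_only", ] <- NA_real_

    drop_mask <- function(x) {
      pr <- if (p$dropout_model == "iid" || p$dropout == 0) {
        matrix(p$dropout, nrow(x), ncol(x))
      } else {
        lx <- log(x)
        mu <- mean(lx, na.rm = TRUE)
        sd <- stats::sd(lx, na.rm = TRUE)
        if (!is.finite(sd) || sd == 0) sd <- 1
        pr <- stats::plogis(stats::qlogis(p$dropout) - (lx - mu) / sd)
        pr[is.na(pr)] <- 0
        pr
      }
      x[matrix(stats::runif(length(x)), nrow(x)) < pr] <- NA_real_
      x
    }
    m1 <- drop_mask(m1)
    m2 <- drop_mask(m2)

    colnames(m1) <- sprintf("M1_%d", seq_len(p$R))
    colnames(m2) <- sprintf("M2_%d", seq_len(p$R))
    tab <- tibble::as_tibble(cbind(m1, m2))
    tab <- tibble::add_column(tab, protein_id = ids, .before = 1)
    truth <- tibble::tibble(
      protein_id = ids, secreted = secreted, detection_design = design,
      planted_class = class, effect_fc = effect
    )
    list(table = tab, truth = truth)
  })
}

#' Generate a synthetic bulk expression table
#'
#' Gated receptors get base means at least `gate_margin` above the gate,
#' non-gated receptors at least `gate_margin` below, so the gate recovers
#' the planted set exactly whenever the margin is positive. A second
#' (non-gating) sample column is included so sample selection is
#' exercised.
#'
#' @param params A [scenario_params()].
#' @return List with `table` (expression tibble) and `gated` (character
#'   vector of planted gated receptor ids).
#' @export
generate_expression <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  p <- params
  with_seed(p$seed + 1L, {
    ids <- sprintf("R%04d", seq_len(p$n_receptors))
    n_gated <- round(p$frac_gated * p$n_receptors)
    gated <- rep(FALSE, p$n_receptors)
    gated[sample.int(p$n_receptors, n_gated)] <- TRUE
    bm <- numeric(p$n_receptors)
    bm[gated] <- p$receptor_gate + p$gate_margin +
      stats::rlnorm(n_gated, meanlog = 2, sdlog = 1.5)
    lo <- max(p$receptor_gate - p$gate_margin, 0)
    bm[!gated] <- stats::runif(p$n_receptors - n_gated, 0, lo)
    tab <- tibble::tibble(gene_id = ids, bm1 = bm,
                          bm2 = bm * stats::rlnorm(p$n_receptors, 0, 0.3))
    names(tab)[2] <- p$gate_sample
    names(tab)[3] <- "gsc_control"
    list(table = tab, gated = ids[gated])
  })
}

#' Generate a synthetic ligand-receptor pair database
#'
#' Mixes planted cognate pairs (detected secreted ligand x planted gated
#' receptor) with decoys built to fail at least one side of the join:
#' a non-secreted ligand, an ungated receptor, or a ligand absent from the
#' proteome entirely. Row order is shuffled; pairs are unique.
#'
#' @param params A [scenario_params()].
#' @param proteins Proteomics truth tibble from [generate_proteomics()].
#' @param gated Character vector of planted gated receptors from
#'   [generate_expression()].
#' @return List with `db` (tibble `ligand`, `receptor`) and `cognate`
#'   (logical vector marking planted cognate rows of `db`).
#' @export
generate_rl_db <- function(params, proteins, gated) {
  stopifnot(inherits(params, "scenario_params"))
  p <- params
  with_seed(p$seed + 2L, {
    eligible <- proteins$protein_id[proteins$secreted]
    non_eligible <- proteins$protein_id[!proteins$secreted]
    n_cog <- round(p$frac_cognate * p$n_db_pairs)
    n_dec <- p$n_db_pairs - n_cog
    if (!length(eligible) || !length(gated)) {
      stop("scenario plants no eligible ligands or no gated receptors",
           call. = FALSE)
    }
    draw_pairs <- function(n, lig_pool, rec_pool) {
      tibble::tibble(
        ligand = sample(lig_pool, n, replace = TRUE),
        receptor = sample(rec_pool, n, replace = TRUE)
      )
    }
    uniquify <- function(make, n, avoid = NULL) {
      out <- dplyr::distinct(make(n))
      if (!is.null(avoid)) {
        out <- dplyr::anti_join(out, avoid, by = c("ligand", "receptor"))
      }
      tries <- 0
      while (nrow(out) < n && tries < 100) {
        extra <- make(n - nrow(out))
        out <- dplyr::distinct(dplyr::bind_rows(out, extra))
        if (!is.null(avoid)) {
          out <- dplyr::anti_join(out, avoid, by = c("ligand", "receptor"))
        }
        tries <- tries + 1
      }
      if (nrow(out) < n) {
        stop("could not draw enough unique pairs", call. = FALSE)
      }
      out[seq_len(n), , drop = FALSE]
    }
    # the planted candidate ligands must participate in at least one
    # cognate pair each, as the study's candidates arise from the pair
    # list; the remaining cognate rows are drawn at random
    planted <- intersect(p$planted_tam_genes, eligible)
    planted <- planted[seq_len(min(length(planted), n_cog))]
    seeded <- tibble::tibble(
      ligand = planted,
      receptor = sample(gated, length(planted), replace = TRUE)
    )
    cognate <- if (n_cog > nrow(seeded)) {
      dplyr::bind_rows(
        seeded,
        uniquify(function(n) draw_pairs(n, eligible, gated),
                 n_cog - nrow(seeded), avoid = seeded)
      )
    } else {
      seeded
    }
    ungated <- setdiff(sprintf("R%04d", seq_len(p$n_receptors)), gated)
    all_rec <- sprintf("R%04d", seq_len(p$n_receptors))
    novel <- sprintf("X%05d", seq_len(max(n_dec, 1)))
    make_decoy <- function(n) {
      mode <- sample.int(3, n, replace = TRUE)
      lig <- character(n)
      rec <- character(n)
      pools_ok <- length(non_eligible) > 0 && length(ungated) > 0
      if (!pools_ok) mode[] <- 3L
      lig[mode == 1] <- sample(non_eligible, sum(mode == 1), replace = TRUE)
      rec[mode == 1] <- sample(all_rec, sum(mode == 1), replace = TRUE)
      lig[mode == 2] <- sample(eligible, sum(mode == 2), replace = TRUE)
      rec[mode == 2] <- sample(ungated, sum(mode == 2), replace = TRUE)
      lig[mode == 3] <- sample(novel, sum(mode == 3), replace = TRUE)
      rec[mode == 3] <- sample(all_rec, sum(mode == 3), replace = TRUE)
      tibble::tibble(ligand = lig, receptor = rec)
    }
    decoys <- if (n_dec > 0) {
      uniquify(make_decoy, n_dec, avoid = cognate)
    } else {
      tibble::tibble(ligand = character(), receptor = character())
    }
    db <- dplyr::bind_rows(cognate, decoys)
    flag <- c(rep(TRUE, nrow(cognate)), rep(FALSE, nrow(decoys)))
    ord <- sample.int(nrow(db))
    list(db = db[ord, , drop = FALSE], cognate = flag[ord])
  })
}

#' Generate a synthetic single-cell detection dataset
#'
#' Cells are split near-evenly into clusters; malignant and TAM marker
#' genes are detected at high probability in their own clusters, planted
#' candidate ligands at `planted_pct1` in their planted TAM clusters
#' (BMD-restricted for `planted_bmd_genes`, all TAM clusters otherwise)
#' and `background_pct` elsewhere, and unstructured background genes at
#' `background_pct` everywhere. Returns the detection matrix, the marker
#' table computed from it, the true cluster annotation, and a
#' BMD-vs-microglia differential-detection table derived from the matrix
#' itself (pooled fractions, Fisher exact test, BH adjustment; positive
#' log2 fold change = up in BMD).
#'
#' @param params A [scenario_params()].
#' @return List with `dm` ([detection_matrix()]), `markers` (tibble),
#'   `annotation` (tibble with ontogeny), `bmd_degs` (tibble) and
#'   `truth` (tibble: `gene_id`, `planted_clusters`, `planted_ontogeny`).
#' @export
generate_sc_markers <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  p <- params
  with_seed(p$seed + 3L, {
    clusters <- as.character(seq_len(p$n_clusters) - 1)
    mic_clusters <- setdiff(p$tam_clusters, p$bmd_clusters)
    mal_clusters <- setdiff(clusters, p$tam_clusters)
    cell_cl <- sample(rep_len(clusters, p$n_cells))

    mal_markers <- c("GAP43", "GPM6B", "SEC61G", "PTN")
    tam_markers <- c("C1QA", "C1QB", "C1QC", "TYROBP", "CD68")
    bg_genes <- sprintf("BG%03d", seq_len(p$n_background_genes))
    genes <- c(mal_markers, tam_markers, p$planted_tam_genes, bg_genes)

    # per-gene detection probability by cluster
    prob_for <- function(gene) {
      pr <- rep(p$background_pct, p$n_clusters)
      names(pr) <- clusters
      if (gene %in% mal_markers) {
        pr[mal_clusters] <- 0.7
      } else if (gene %in% tam_markers) {
        pr[p$tam_clusters] <- 0.7
      } else if (gene %in% p$planted_bmd_genes) {
        pr[p$bmd_clusters] <- p$planted_pct1
      } else if (gene %in% p$planted_tam_genes) {
        pr[p$tam_clusters] <- p$planted_pct1
      } else {
        pr[] <- p$background_pct
      }
      pr
    }
    detect <- vapply(genes, function(g) {
      pr <- prob_for(g)[cell_cl]
      stats::runif(p$n_cells) < pr
    }, logical(p$n_cells))
    dm <- detection_matrix(detect, cell_cl)
    markers <- marker_table_from_matrix(dm)
    annotation <- tibble::tibble(
      cluster_id = clusters,
      cell_type = ifelse(clusters %in% p$tam_clusters, "TAM", "malignant"),
      ontogeny = dplyr::case_when(
        clusters %in% p$bmd_clusters ~ "BMD",
        clusters %in% mic_clusters ~ "microglia",
        TRUE ~ NA_character_
      )
    )
    bmd_cells <- cell_cl %in% p$bmd_clusters
    mic_cells <- cell_cl %in% mic_clusters
    bmd_degs <- dplyr::bind_rows(lapply(genes, function(g) {
      kb <- sum(detect[bmd_cells, g]); nb <- sum(bmd_cells)
      km <- sum(detect[mic_cells, g]); nm <- sum(mic_cells)
      pv <- stats::fisher.test(matrix(c(kb, nb - kb, km, nm - km), 2))$p.value
      tibble::tibble(
        gene_id = g,
        log2_fc = log2(((kb + 0.5) / (nb + 1)) / ((km + 0.5) / (nm + 1))),
        p_adj = pv
      )
    }))
    bmd_degs$p_adj <- stats::p.adjust(bmd_degs$p_adj, method = "BH")
    truth <- tibble::tibble(
      gene_id = p$planted_tam_genes,
      planted_clusters = ifelse(p$planted_tam_genes %in% p$planted_bmd_genes,
                                paste(p$bmd_clusters, collapse = ","),
                                paste(p$tam_clusters, collapse = ",")),
      planted_ontogeny = ifelse(p$planted_tam_genes %in% p$planted_bmd_genes,
                                "BMD", "mixed")
    )
    list(dm = dm, markers = markers, annotation = annotation,
         bmd_degs = bmd_degs, truth = truth)
  })
}

#' Generate a complete synthetic scenario
#'
#' Runs every generator off one seed and bundles the tables with the
#' planted truth.
#'
#' @param params A [scenario_params()].
#' @param sc Also generate the single-cell dataset (default TRUE; the
#'   proteomics/crosstalk stages do not need it).
#' @return A list of class `scenario` with fields `params`, `proteomics`,
#'   `expression`, `db` and (optionally) `sc`.
#' @export
generate_scenario <- function(params, sc = TRUE) {
  prot <- generate_proteomics(params)
  expr <- generate_expression(params)
  db <- generate_rl_db(params, prot$truth, expr$gated)
  out <- list(params = params, proteomics = prot, expression = expr,
              db = db, sc = if (sc) generate_sc_markers(params))
  class(out) <- "scenario"
  out
}

#' Expected pipeline counts from planted truth
#'
#' An independent brute-force oracle: enumerates the planted design
#' (secreted flags, detection designs, planted effects, gated receptors,
#' database rows) and derives the Venn decomposition, cognate pair count,
#' polarization-class partition and unique-member counts without touching
#' any pipeline code path. Classification is re-derived inline from the
#' planted effect ratio against the configured thresholds. Valid as an
#' exact expectation for zero-dropout scenarios.
#'
#' @param scenario A [generate_scenario()] result (or a list with the same
#'   `proteomics`, `expression`, `db` fields).
#' @param fc_high,fc_low Class bounds (defaults 2 and 0.5, inclusive).
#' @return List with `venn`, `n_pairs`, `partition` (named counts),
#'   `unique_m2` (receptors/ligands of the M2-specific class) and
#'   `unique_all`.
#' @export
expected_counts <- function(scenario, fc_high = 2, fc_low = 0.5) {
  truth <- scenario$proteomics$truth
  gated <- scenario$expression$gated
  db <- scenario$db$db

  venn <- list(
    m1_only = sum(truth$detection_design == "M1_only"),
    m2_only = sum(truth$detection_design == "M2_only"),
    both    = sum(truth$detection_design == "both"),
    total   = nrow(truth)
  )
  eligible <- truth$protein_id[truth$secreted]
  cls <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cls[i] <- if (truth$detection_design[i] == "M2_only") "M2_specific"
      else if (truth$detection_design[i] == "M1_only") "M1_specific"
      else if (truth$effect_fc[i] >= fc_high) "M2_specific"
      else if (truth$effect_fc[i] <= fc_low) "M1_specific"
      else "pan"
  }
  names(cls) <- truth$protein_id

  keep <- db$ligand %in% eligible & db$receptor %in% gated
  pairs <- db[keep, , drop = FALSE]
  pair_cls <- unname(cls[pairs$ligand])
  partition <- c(
    M1_specific = sum(pair_cls == "M1_specific"),
    M2_specific = sum(pair_cls == "M2_specific"),
    pan         = sum(pair_cls == "pan")
  )
  m2 <- pairs[pair_cls == "M2_specific", , drop = FALSE]
  list(
    venn = venn,
    n_pairs = nrow(pairs),
    partition = partition,
    unique_m2 = c(n_receptors = length(unique(m2$receptor)),
                  n_ligands = length(unique(m2$ligand))),
    unique_all = c(n_receptors = length(unique(pairs$receptor)),
                   n_ligands = length(unique(pairs$ligand)))
  )
}

#' Write a scenario to disk as a pipeline input bundle
#'
#' Writes every generated table in the on-disk form the readers expect,
#' plus the planted truth as JSON, into one directory.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
write_scenario_bundle <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  truth <- scenario$proteomics$truth
  paths <- list(
    intensity = path("intensity.tsv"),
    secretome = path("secretome.tsv"),
    rl_db = path("rl_db.tsv"),
    expression = path("expression.tsv"),
    truth = path("truth.json")
  )
  write_intensity_table(scenario$proteomics$table, paths$intensity)
  readr::write_tsv(
    tibble::tibble(gene_id = truth$protein_id[truth$secreted]),
    paths$secretome
  )
  readr::write_tsv(scenario$db$db, paths$rl_db)
  readr::write_tsv(scenario$expression$table, paths$expression)
  if (!is.null(scenario$sc)) {
    paths$markers <- path("markers.tsv")
    paths$cluster_annotation <- path("cluster_annotation.tsv")
    paths$bmd_degs <- path("bmd_degs.tsv")
    readr::write_tsv(scenario$sc$markers, paths$markers)
    readr::write_tsv(scenario$sc$annotation, paths$cluster_annotation,
                     na = "")
    readr::write_tsv(scenario$sc$bmd_degs, paths$bmd_degs)
  }
  jsonlite::write_json(
    list(
      proteins = truth,
      gated_receptors = scenario$expression$gated,
      cognate = scenario$db$cognate,
      sc_truth = if (!is.null(scenario$sc)) scenario$sc$truth
    ),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null", na = "null"
  )
  invisible(paths)
}
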