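#' Run the full two-cohort blood-transcriptome study pipeline
#'
#' Drives every stage on a synthetic study generated from `config`:
#' simulate -> detection repair -> quantile normalization -> ComBat ->
#' PCA/Grubbs -> sex residualization -> per-cohort moderated-t DE ->
#' random-effects meta-analysis -> platform Z-scoring -> cell-type
#' signature scores, composites and subgroups -> cell-type assignment
#' enrichment -> GWAS proximity resampling -> cross-validated diagnostic
#' classification -> survival signature chain (screen, cluster,
#' representatives, stepwise, concordance CV, AFT contrast).
#'
#' @param config a [sim_config()]; its `seed` drives the simulation.
#' @param reference optional `cell_reference`; generated from
#'   `config$seed` when NULL.
#' @param cv_trials diagnostic CV trials (default 200).
#' @param surv_trials survival CV trials (default 100).
#' @param gwas_trials resampling trials for the GWAS null (default 2000).
#' @param cv_method diagnostic classifier (default "logistic").
#' @param out_dir when non-NULL, writes the declared TSV/JSON artifacts
#'   there (expression, detection p, samples, genes, loci, DE/meta tables,
#'   signatures, scores, CV and survival summaries, truth record).
#' @return list with the intermediate and final results of every stage.
#' @export
run_study_pipeline <- function(config = sim_config(), reference = NULL,
                               cv_trials = 200, surv_trials = 100,
                               gwas_trials = 2000,
                               cv_method = "logistic", out_dir = NULL) {
  if (is.null(reference)) {
    reference <- generate_reference(n_genes = config$n_genes,
                                    seed = config$seed)
  }
  sim <- generate_cohorts(config, reference)
  s <- sim$samples
  s1 <- s[s$cohort == "C1", ]
  s2 <- s[s$cohort == "C2", ]

  prep_cohort <- function(expr, detp, ss) {
    rep <- orient_detection_pvalues(expr, detp)
    qn <- quantile_normalize(expr)
    cb <- combat_adjust(qn, ss$batch, ss[, c("group", "sex")])
    pcs <- pca_scores(cb, k = 3)
    outliers <- detect_outliers_grubbs(pcs)
    keep <- !ss$sample_id %in% outliers$flagged
    list(x = residualize_sex(cb[, keep, drop = FALSE], ss$sex[keep]),
         z = zscore_by_platform(cb[, keep, drop = FALSE],
                                rep("P", sum(keep))),
         mask = detection_filter(rep$detp[, keep, drop = FALSE]),
         flipped = rep$flipped, outliers = outliers$flagged,
         samples = ss[keep, ])
  }
  p1 <- prep_cohort(sim$expr1, sim$detp1, s1)
  p2 <- prep_cohort(sim$expr2, sim$detp2, s2)

  de1 <- moderated_ttest(p1$x[p1$mask, , drop = FALSE], p1$samples$group)
  de2 <- moderated_ttest(p2$x[p2$mask, , drop = FALSE], p2$samples$group)
  meta <- meta_pipeline(de1, de2)

  kept <- dplyr::bind_rows(p1$samples, p2$samples)
  shared <- intersect(rownames(p1$z), rownames(p2$z))
  z <- cbind(p1$z[shared, , drop = FALSE],
             p2$z[shared, , drop = FALSE])[, kept$sample_id]

  sigs <- lapply(reference$cell_types, function(ct)
    select_signature_genes(reference, ct))
  names(sigs) <- reference$cell_types
  scores <- compute_signature_scores(z, sigs)
  composites <- composite_scores(scores)
  subgroups <- assign_subgroups(composites)

  ranking <- stats::setNames(meta$table$meta_log2fc, meta$table$gene_id)
  assignment <- assign_cell_types(names(ranking), reference)
  ct_enrich <- assignment_enrichment(assignment, meta$increased,
                                     names(ranking))

  up <- sim$truth$degs$gene[sim$truth$degs$lfc > 0]
  up_markers <- unlist(lapply(config$prop_multipliers, function(m)
    reference$truth$gene[reference$truth$cell_type %in%
                           names(m)[m > 1]]), use.names = FALSE)
  targets <- union(up, up_markers)
  loci <- generate_gwas(sim$genes, target_genes = targets, n_loci = 215,
                        near_fraction = 0.6, max_offset_bp = 9000,
                        seed = config$seed + 3L)
  n_top <- min(500, length(meta$increased) + length(meta$decreased))
  top_meta <- meta$table$gene_id[order(meta$table$meta_p)][seq_len(max(10, n_top))]
  gwas_null <- gwas_distance_null(top_meta, sim$genes$gene_id, sim$genes,
                                  loci, n_trials = gwas_trials,
                                  seed = config$seed + 4L)
  gwas_prox <- gwas_proximity_overlap(top_meta, sim$genes$gene_id,
                                      sim$genes, loci)

  cv <- run_cv(z, kept, method = cv_method, n_genes = min(450, nrow(z)),
               pc_frac = 0.14, n_trials = cv_trials,
               seed = config$seed + 5L)

  surv <- generate_survival(kept, z, config, seed = config$seed + 1L)
  pts <- surv$samples[!is.na(surv$samples$surv_time), ]
  screen <- genomewide_cox_screen(z, surv$samples)
  cand <- screen$gene_id[screen$p < 0.15]
  surv_chain <- NULL
  if (length(cand) >= 2) {
    clusters <- cluster_genes(z[, pts$sample_id], cand,
                              target_n_groups = max(2, round(length(cand) / 13.4)))
    reps <- select_representatives(clusters, screen)
    step <- stepwise_cox(z, reps, surv$samples)
    cv_surv <- cv_survival(z, surv$samples,
                           if (length(step$selected)) step$selected else reps,
                           n_trials = surv_trials,
                           seed = config$seed + 6L)
    surv_chain <- list(clusters = clusters, representatives = reps,
                       stepwise = step, cv = cv_surv)
  }
  aft <- if (length(surv$truth$gene)) {
    aft_median_contrast(z[surv$truth$gene[1], pts$sample_id],
                        cox_covariate_frame(pts, c("age", "sex",
                                                   "onset_site", "cohort")),
                        pts$surv_time, pts$event)
  }

  result <- list(config = config, reference = reference, sim = sim,
                 prep1 = p1, prep2 = p2, de1 = de1, de2 = de2, meta = meta,
                 z = z, samples = kept, signatures = sigs, scores = scores,
                 composites = composites, subgroups = subgroups,
                 assignment = assignment, ct_enrichment = ct_enrich,
                 loci = loci, gwas_null = gwas_null, gwas_prox = gwas_prox,
                 cv = cv, survival = surv, screen = screen,
                 surv_chain = surv_chain, aft = aft)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_expression_tsv(result$sim$expr1, p("expr_C1.tsv"))
  write_expression_tsv(result$sim$expr2, p("expr_C2.tsv"))
  write_expression_tsv(result$sim$detp1, p("detp_C1.tsv"))
  write_expression_tsv(result$sim$detp2, p("detp_C2.tsv"))
  write_samples_tsv(result$samples, p("samples.tsv"))
  write_genes_tsv(result$sim$genes, p("genes.tsv"))
  write_loci_bed(result$loci, p("loci.bed"))
  readr::write_tsv(result$de1$table, p("de_C1.tsv"))
  readr::write_tsv(result$de2$table, p("de_C2.tsv"))
  readr::write_tsv(result$meta$table, p("meta_de.tsv"))
  write_signatures_tsv(result$signatures, p("signatures.tsv"))
  readr::write_tsv(result$scores, p("signature_scores.tsv"))
  readr::write_tsv(result$subgroups, p("subgroups.tsv"))
  readr::write_tsv(result$ct_enrichment, p("celltype_enrichment.tsv"))
  readr::write_tsv(result$gwas_prox$table, p("gwas_proximity.tsv"))
  readr::write_tsv(result$screen, p("cox_screen.tsv"))
  jsonlite::write_json(
    list(cv_diagnostic = as.list(result$cv$summary),
         cv_survival = if (!is.null(result$surv_chain))
           as.list(result$surv_chain$cv$summary),
         stepwise_selected = if (!is.null(result$surv_chain))
           result$surv_chain$stepwise$selected,
         gwas_empirical_p = result$gwas_null$p,
         aft = if (!is.null(result$aft)) as.list(result$aft)),
    p("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_truth_json(c(result$sim$truth[c("degs", "sex_genes",
                                        "flipped_samples")],
                     list(surv_genes = result$survival$truth,
                          props = result$sim$truth$props)),
                   p("truth.json"))
  invisible(out_dir)
}
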