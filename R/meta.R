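#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-cohort effect estimates with inverse-variance weights under a
#' random-effects model. The between-study variance is the DerSimonian-Laird
#' moment estimator `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' with fixed-effect weights `w = 1/se^2`; the pooled estimate uses
#' `w* = 1/(se^2 + tau2)` and its p-value comes from the normal z test.
#' Fully vectorized: each argument may be a matrix-like set of rows
#' (genes) x studies.
#'
#' @param b numeric matrix (rows = features, cols = studies) or vector of
#'   per-study estimates for one feature.
#' @param se matching standard errors, all > 0.
#' @return tibble: est, se, tau_sq, q_stat, p, plus per-study inputs kept by
#'   the caller.
#' @export
pool_random_effects <- function(b, se) {
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  if (is.vector(se)) se <- matrix(se, nrow = 1)
  stopifnot(identical(dim(b), dim(se)), ncol(b) >= 2)
  if (any(se <= 0)) stop("all standard errors must be positive")
  k <- ncol(b)
  w <- 1 / se^2
  sw <- rowSums(w)
  b_fe <- rowSums(w * b) / sw
  q <- rowSums(w * (b - b_fe)^2)
  c_den <- sw - rowSums(w^2) / sw
  tau_sq <- pmax(0, (q - (k - 1)) / c_den)
  w_star <- 1 / (se^2 + tau_sq)
  sws <- rowSums(w_star)
  est <- rowSums(w_star * b) / sws
  se_pooled <- 1 / sqrt(sws)
  z <- est / se_pooled
  tibble::tibble(
    est = est, se = se_pooled, tau_sq = tau_sq, q_stat = q,
    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  )
}

#' Cross-cohort random-effects meta-analysis of differential expression
#'
#' Restricted to genes present (and detection-filtered) in both cohorts,
#' pools the per-cohort log2 fold-changes and standard errors with
#' [pool_random_effects()], applies Benjamini-Hochberg across genes, and
#' calls meta-DEGs at the standard thresholds.
#'
#' @param de1,de2 `de_result` objects (or their tables) from the two cohorts.
#' @param shared_genes optional explicit gene set; default is the
#'   intersection of the two tables.
#' @param fc_up,fc_down,fdr_max DEG thresholds passed to [call_degs()].
#' @return list of class `meta_de_result`: `table` (gene_id, meta_log2fc,
#'   meta_se, tau_sq, q_stat, meta_p, meta_fdr, log2fc_1, se_1, log2fc_2,
#'   se_2), `increased`, `decreased`.
#' @export
meta_pipeline <- function(de1, de2, shared_genes = NULL,
                          fc_up = 1.10, fc_down = 0.909, fdr_max = 0.10) {
  t1 <- de_table(de1)
  t2 <- de_table(de2)
  if (is.null(shared_genes)) {
    shared_genes <- intersect(t1$gene_id, t2$gene_id)
  }
  if (length(shared_genes) == 0) stop("no shared genes between cohorts")
  t1 <- t1[match(shared_genes, t1$gene_id), ]
  t2 <- t2[match(shared_genes, t2$gene_id), ]
  pooled <- pool_random_effects(cbind(t1$log2fc, t2$log2fc),
                                cbind(t1$se, t2$se))
  tab <- tibble::tibble(
    gene_id = shared_genes,
    meta_log2fc = pooled$est,
    meta_se = pooled$se,
    tau_sq = pooled$tau_sq,
    q_stat = pooled$q_stat,
    meta_p = pooled$p,
    meta_fdr = bh_adjust(pooled$p),
    log2fc_1 = t1$log2fc, se_1 = t1$se,
    log2fc_2 = t2$log2fc, se_2 = t2$se
  )
  degs <- call_degs(
    tibble::tibble(gene_id = tab$gene_id, log2fc = tab$meta_log2fc,
                   fdr = tab$meta_fdr),
    fc_up = fc_up, fc_down = fc_down, fdr_max = fdr_max)
  structure(list(table = tab, increased = degs$increased,
                 decreased = degs$decreased),
            class = "meta_de_result")
}

#' @export
print.meta_de_result <- function(x, ...) {
  cat("<meta_de_result> ", nrow(x$table), " shared genes; ",
      length(x$increased), " increased / ", length(x$decreased),
      " decreased meta-DEGs\n", sep = "")
  invisible(x)
}
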