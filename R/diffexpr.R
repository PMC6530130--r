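#' Remove sex effects by per-gene residualization
#'
#' Regresses each gene on a 0-1 sex indicator and returns the residuals,
#' which are exactly uncorrelated with sex. Equivalent to centering each
#' gene within each sex group.
#'
#' @param expr genes x samples matrix.
#' @param sex character vector ("M"/"F") or 0-1 indicator per sample.
#' @return residual matrix, same shape.
#' @export
residualize_sex <- function(expr, sex) {
  stopifnot(length(sex) == ncol(expr))
  ind <- if (is.numeric(sex)) sex else as.numeric(sex == "M")
  if (length(unique(ind)) < 2) stop("both sexes must be present")
  out <- expr
  for (v in unique(ind)) {
    idx <- ind == v
    out[, idx] <- expr[, idx, drop = FALSE] -
      rowMeans(expr[, idx, drop = FALSE])
  }
  out
}

#' Two-group moderated-t differential expression
#'
#' Fits a per-gene two-group linear model and shrinks the residual variances
#' toward a common prior with empirical Bayes (limma lmFit/eBayes): the
#' posterior variance is `(d0*s0^2 + d*s^2) / (d0 + d)` with `(d0, s0^2)`
#' estimated by moment matching on the log sample variances, and the
#' moderated t is referenced to `d0 + d` degrees of freedom.
#'
#' @param expr genes x samples matrix (typically sex-residualized log2).
#' @param group factor/character with exactly two levels; the log2
#'   fold-change is `case - control`.
#' @param case,control the group labels to contrast (defaults "ALS", "CTL");
#'   samples with other labels are dropped.
#' @param detect_frac optional named per-gene detected fraction carried into
#'   the output.
#' @return list of class `de_result`: `table` (tibble: gene_id, log2fc, se,
#'   t_mod, p, fdr, mean_expr, detect_frac) and `fit_info`
#'   (d0, s0_sq, d_resid).
#' @export
moderated_ttest <- function(expr, group, case = "ALS", control = "CTL",
                            detect_frac = NULL) {
  keep <- group %in% c(case, control)
  expr <- expr[, keep, drop = FALSE]
  group <- group[keep]
  if (sum(group == case) < 2 || sum(group == control) < 2) {
    stop("need at least 2 samples per group")
  }
  design <- cbind(Intercept = 1, grp = as.numeric(group == case))
  fit <- limma::eBayes(limma::lmFit(expr, design))
  se <- sqrt(fit$s2.post) * fit$stdev.unscaled[, "grp"]
  tab <- tibble::tibble(
    gene_id = rownames(expr),
    log2fc = unname(fit$coefficients[, "grp"]),
    se = unname(se),
    t_mod = unname(fit$t[, "grp"]),
    p = unname(fit$p.value[, "grp"]),
    fdr = unname(bh_adjust(fit$p.value[, "grp"])),
    mean_expr = unname(fit$Amean),
    detect_frac = if (is.null(detect_frac)) NA_real_
      else unname(detect_frac[rownames(expr)])
  )
  structure(
    list(table = tab,
         fit_info = list(d0 = fit$df.prior, s0_sq = fit$s2.prior,
                         d_resid = unname(fit$df.residual[1]))),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", nrow(x$table), " genes; prior df = ",
      format(x$fit_info$d0, digits = 4), "\n", sep = "")
  print(x$table, n = 5)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param pvals numeric vector in \[0, 1\].
#' @return adjusted values, same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes at fold-change and FDR thresholds
#'
#' A gene is increased iff `2^log2fc > fc_up` and `fdr < fdr_max`, decreased
#' iff `2^log2fc < fc_down` and `fdr < fdr_max` (strict inequalities).
#'
#' @param de a `de_result`, `meta_de_result`, or a tibble with `gene_id`,
#'   `log2fc` (or `meta_log2fc`) and `fdr` (or `meta_fdr`).
#' @param fc_up,fc_down linear fold-change thresholds (defaults 1.10, 0.909).
#' @param fdr_max FDR ceiling (default 0.10).
#' @return list: `increased`, `decreased` (character vectors of gene ids).
#' @export
call_degs <- function(de, fc_up = 1.10, fc_down = 0.909, fdr_max = 0.10) {
  tab <- de_table(de)
  fc <- 2^tab$log2fc
  list(
    increased = tab$gene_id[fc > fc_up & tab$fdr < fdr_max],
    decreased = tab$gene_id[fc < fc_down & tab$fdr < fdr_max]
  )
}

de_table <- function(de) {
  if (inherits(de, "de_result")) de <- de$table
  if (inherits(de, "meta_de_result")) de <- de$table
  tab <- tibble::as_tibble(de)
  if (!"log2fc" %in% names(tab) && "meta_log2fc" %in% names(tab)) {
    tab$log2fc <- tab$meta_log2fc
  }
  if (!"fdr" %in% names(tab) && "meta_fdr" %in% names(tab)) {
    tab$fdr <- tab$meta_fdr
  }
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(tab)))
  tab
}
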