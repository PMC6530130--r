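#' Square-root rank weights for signature genes
#'
#' The rank-1 (most specific) gene receives preliminary weight `n`, rank 2
#' weight `n - 1`, and so on; square roots are taken and scaled by the
#' maximum, so the final weight of rank r is `sqrt(n + 1 - r) / sqrt(n)`
#' (for the default 100-gene scheme, `sqrt(101 - r) / 10`).
#'
#' @param n signature length.
#' @return numeric vector of length `n`, strictly decreasing, max 1.
#' @export
signature_weights <- function(n = 100) {
  sqrt(n + 1 - seq_len(n)) / sqrt(n)
}

#' Select cell-type signature genes from a reference compendium
#'
#' Two-group moderated-t comparison of the target cell type against the
#' pooled other types; among genes elevated in the target, the `n_p` with
#' lowest p-values are re-sorted by fold change and the `n_fc` with highest
#' FC become the signature, ranked (and sqrt-rank weighted) by FC.
#'
#' @param reference a `cell_reference` (or any list with `profiles` and
#'   `sample_types`).
#' @param target cell-type label to build the signature for.
#' @param n_p genes retained at the p-value stage (default 150).
#' @param n_fc final signature length (default 100).
#' @return list of class `signature_def`: `label`, `genes` (ordered, rank 1
#'   first), `weights`, `table` (gene, rank, log2fc, p, weight).
#' @export
select_signature_genes <- function(reference, target, n_p = 150, n_fc = 100) {
  stopifnot(target %in% reference$sample_types, n_fc <= n_p)
  grp <- ifelse(reference$sample_types == target, "target", "rest")
  de <- moderated_ttest(reference$profiles, grp,
                        case = "target", control = "rest")$table
  # elevation must exceed numerical noise in the least-squares fit
  up <- de[de$log2fc > 1e-9, ]
  if (nrow(up) < n_fc) {
    stop("only ", nrow(up), " genes elevated in ", target,
         "; need at least ", n_fc)
  }
  top_p <- up[order(up$p), ][seq_len(min(n_p, nrow(up))), ]
  sig <- top_p[order(-top_p$log2fc), ][seq_len(n_fc), ]
  w <- signature_weights(n_fc)
  structure(
    list(label = target, genes = sig$gene_id, weights = w,
         table = tibble::tibble(gene = sig$gene_id, rank = seq_len(n_fc),
                                log2fc = sig$log2fc, p = sig$p, weight = w)),
    class = "signature_def"
  )
}

#' @export
print.signature_def <- function(x, ...) {
  cat("<signature_def> ", x$label, ": ", length(x$genes),
      " genes, top = ", x$genes[1], "\n", sep = "")
  invisible(x)
}

#' Weighted signature scores per sample
#'
#' Score of a sample for a signature is the sqrt-rank-weighted mean of its
#' Z-scored expression over the signature genes present in the matrix.
#' When genes are missing the weights are renormalized over the present
#' genes; coverage below `min_coverage` triggers a warning (an error if no
#' gene is present).
#'
#' @param expr_z genes x samples matrix, Z-scored per platform.
#' @param signatures a `signature_def` or list of them.
#' @param min_coverage warn below this fraction of signature genes present.
#' @return tibble of class `score_matrix`: sample_id plus one column per
#'   signature label; attribute `coverage` records per-signature coverage.
#' @export
compute_signature_scores <- function(expr_z, signatures, min_coverage = 0.5) {
  if (inherits(signatures, "signature_def")) signatures <- list(signatures)
  ids <- colnames(expr_z) %||% sprintf("s%03d", seq_len(ncol(expr_z)))
  out <- tibble::tibble(sample_id = ids)
  coverage <- numeric(0)
  for (sig in signatures) {
    present <- sig$genes %in% rownames(expr_z)
    cov <- mean(present)
    coverage[sig$label] <- cov
    if (!any(present)) stop("no signature genes present for ", sig$label)
    if (cov < min_coverage) {
      warning("signature ", sig$label, " coverage ", round(cov, 2),
              "; weights renormalized over present genes")
    }
    w <- sig$weights[present]
    z <- expr_z[sig$genes[present], , drop = FALSE]
    out[[sig$label]] <- as.vector(crossprod(z, w)) / sum(w)
  }
  attr(out, "coverage") <- coverage
  class(out) <- c("score_matrix", class(out))
  out
}

#' Myeloid and lymphoid composite scores
#'
#' Unweighted means of the myeloid-lineage (DC, MP, MC, NP, PL, RBC, ES)
#' and lymphoid-lineage (CD8, CD4, GDT, NK, B) cell-type scores.
#'
#' @param scores a `score_matrix` tibble containing all constituent columns.
#' @param myeloid,lymphoid constituent label sets.
#' @return tibble: sample_id, myeloid, lymphoid.
#' @export
composite_scores <- function(scores,
                             myeloid = c("DC", "MP", "MC", "NP", "PL",
                                         "RBC", "ES"),
                             lymphoid = c("CD8", "CD4", "GDT", "NK", "B")) {
  missing <- setdiff(c(myeloid, lymphoid), names(scores))
  if (length(missing)) {
    stop("missing constituent score(s): ", paste(missing, collapse = ", "))
  }
  tibble::tibble(
    sample_id = scores$sample_id,
    myeloid = rowMeans(as.matrix(scores[myeloid])),
    lymphoid = rowMeans(as.matrix(scores[lymphoid]))
  )
}

#' Threshold-based myeloid/lymphoid subgroup assignment
#'
#' Myeloid group: myeloid score > t and lymphoid score < -t; lymphoid
#' group: myeloid score < -t and lymphoid score > t; all other samples are
#' unassigned.
#'
#' @param composites tibble from [composite_scores()].
#' @param t threshold (default 0.05).
#' @return tibble: sample_id, myeloid, lymphoid, subgroup.
#' @export
assign_subgroups <- function(composites, t = 0.05) {
  stopifnot(all(is.finite(composites$myeloid)),
            all(is.finite(composites$lymphoid)))
  subgroup <- dplyr::case_when(
    composites$myeloid > t & composites$lymphoid < -t ~ "myeloid",
    composites$myeloid < -t & composites$lymphoid > t ~ "lymphoid",
    TRUE ~ "unassigned"
  )
  dplyr::mutate(composites, subgroup = subgroup)
}

#' M1/M2 macrophage polarization signatures
#'
#' Applies the standard signature-selection scheme to a polarized-macrophage
#' reference: the M1 signature comes from M1 vs (M2 + non-polarized), the
#' M2 signature from M2 vs (M1 + non-polarized).
#'
#' @param m_reference a `cell_reference`-like list whose `sample_types`
#'   contain "M1", "M2" and at least one other (non-polarized) class.
#' @param n_p,n_fc selection sizes as in [select_signature_genes()].
#' @return list with elements `M1` and `M2`, each a `signature_def`.
#' @export
polarization_signatures <- function(m_reference, n_p = 150, n_fc = 100) {
  st <- m_reference$sample_types
  for (cls in c("M1", "M2")) {
    if (!cls %in% st) stop("reference lacks class ", cls)
  }
  if (!any(!st %in% c("M1", "M2"))) stop("reference lacks non-polarized samples")
  sigs <- lapply(c("M1", "M2"), function(cls) {
    select_signature_genes(m_reference, cls, n_p = n_p, n_fc = n_fc)
  })
  names(sigs) <- c("M1", "M2")
  sigs
}
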