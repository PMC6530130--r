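#' Repair flipped detection p-values
#'
#' Bead-array detection p-values should correlate negatively with intensity.
#' Samples whose Spearman correlation between detection p and intensity
#' exceeds +0.90 are taken to store 1 - p and are flipped back. Samples with
#' constant detection p (correlation undefined) are left unchanged with a
#' warning.
#'
#' @param expr genes x samples log2 intensity matrix.
#' @param detp matching detection p-value matrix.
#' @param r_flip Spearman correlation above which a sample is flipped.
#' @return list: `detp` (repaired matrix), `flipped` (sample ids),
#'   `unrepairable` (sample ids with undefined correlation).
#' @export
orient_detection_pvalues <- function(expr, detp, r_flip = 0.90) {
  stopifnot(identical(dim(expr), dim(detp)), nrow(expr) >= 3)
  flipped <- character(0)
  unrepairable <- character(0)
  for (j in seq_len(ncol(detp))) {
    if (stats::sd(detp[, j]) == 0) {
      unrepairable <- c(unrepairable, colnames(detp)[j])
      next
    }
    r <- stats::cor(detp[, j], expr[, j], method = "spearman")
    if (is.finite(r) && r > r_flip) {
      detp[, j] <- 1 - detp[, j]
      flipped <- c(flipped, colnames(detp)[j])
    }
  }
  if (length(unrepairable)) {
    warning("constant detection p-values; left unchanged for sample(s): ",
            paste(unrepairable, collapse = ", "))
  }
  list(detp = detp, flipped = flipped, unrepairable = unrepairable)
}

#' Normal-exponential background correction
#'
#' Per sample, fits the normal-exponential convolution model (normally
#' distributed background plus exponentially distributed signal) by maximum
#' likelihood and replaces each intensity with the posterior expected signal,
#' which is strictly positive. Estimation and correction are delegated to
#' limma's normexp machinery (saddle-point fit used as fallback if the MLE
#' fails).
#'
#' @param expr genes x samples matrix.
#' @param log_scale if `TRUE` (default) `expr` holds log2 intensities and is
#'   exponentiated before correction; the result is returned on log2 scale.
#' @return corrected matrix, same shape and scale convention as the input.
#' @export
background_correct_normexp <- function(expr, log_scale = TRUE) {
  if (any(!is.finite(expr))) stop("non-finite intensities")
  x <- if (log_scale) 2^expr else expr
  out <- apply(x, 2, function(col) {
    par <- tryCatch(limma::normexp.fit(col, method = "mle")$par,
                    error = function(e)
                      limma::normexp.fit(col, method = "saddle")$par)
    limma::normexp.signal(par, col)
  })
  dimnames(out) <- dimnames(expr)
  if (log_scale) log2(out) else out
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same distribution: the mean of
#' the order statistics across samples. Ties within a column receive the
#' average of the tied quantiles.
#'
#' @param expr genes x samples matrix, no missing values.
#' @return normalized matrix.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(ncol(expr) >= 2)
  if (anyNA(expr)) stop("missing values; impute or drop before normalizing")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Collapse probes to genes by highest average expression
#'
#' For genes measured by several probes, keeps the probe with the highest
#' mean across samples; exact ties are broken toward the lexicographically
#' smallest probe id.
#'
#' @param expr probes x samples matrix (rownames are probe ids).
#' @param probe_map data frame with columns `probe` and `gene` covering all
#'   probes of `expr`.
#' @return genes x samples matrix (rownames are gene ids).
#' @export
collapse_probes <- function(expr, probe_map) {
  if (is.null(probe_map) || nrow(probe_map) == 0) stop("empty probe map")
  stopifnot(all(rownames(expr) %in% probe_map$probe))
  map <- probe_map[match(rownames(expr), probe_map$probe), ]
  keep <- tibble::tibble(probe = rownames(expr),
                         gene = map$gene,
                         avg = rowMeans(expr)) |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$avg), .data$probe) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  out <- expr[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  out
}

#' Restrict an expression matrix to protein-coding genes
#'
#' @param expr genes x samples matrix.
#' @param genes gene tibble with `gene_id` and logical `coding`.
#' @return filtered matrix (row order preserved).
#' @export
filter_protein_coding <- function(expr, genes) {
  stopifnot(all(rownames(expr) %in% genes$gene_id))
  coding <- genes$gene_id[genes$coding]
  out <- expr[rownames(expr) %in% coding, , drop = FALSE]
  if (nrow(out) == 0) warning("no protein-coding genes retained")
  out
}

#' Detection-based gene filter
#'
#' Keeps a gene iff it is detected (`detection p < alpha`) in strictly more
#' than `floor(min_frac * n_samples)` samples.
#'
#' @param detp genes x samples detection p-value matrix.
#' @param min_frac minimum detected fraction (default 0.20).
#' @param alpha detection call threshold (default 0.05).
#' @return named logical vector over genes.
#' @export
detection_filter <- function(detp, min_frac = 0.20, alpha = 0.05) {
  if (is.null(detp)) stop("detection p-values required")
  n_det <- rowSums(detp < alpha)
  n_det > floor(min_frac * ncol(detp))
}

#' Per-platform Z-scoring
#'
#' Within each platform, centers and scales every gene to mean 0 / sd 1.
#' Genes constant within a platform are set to 0 there, with a warning.
#'
#' @param expr genes x samples matrix.
#' @param platform character vector of platform labels per sample.
#' @return Z-scored matrix.
#' @export
zscore_by_platform <- function(expr, platform) {
  stopifnot(length(platform) == ncol(expr))
  out <- expr
  n_const <- 0L
  for (pf in unique(platform)) {
    idx <- platform == pf
    m <- rowMeans(expr[, idx, drop = FALSE])
    s <- apply(expr[, idx, drop = FALSE], 1, stats::sd)
    z <- (expr[, idx, drop = FALSE] - m) / s
    const <- s == 0
    if (any(const)) {
      z[const, ] <- 0
      n_const <- n_const + sum(const)
    }
    out[, idx] <- z
  }
  if (n_const > 0) warning(n_const, " constant gene/platform combinations set to 0")
  out
}
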