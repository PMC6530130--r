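#' Principal-component scores of samples
#'
#' Centers each gene and decomposes the sample covariance; the sign of each
#' component is fixed by forcing its largest-absolute gene loading positive,
#' so scores are reproducible across platforms and BLAS builds.
#'
#' @param expr genes x samples matrix.
#' @param k number of components.
#' @param scale. also scale genes to unit variance before decomposition.
#' @return list of class `pc_scores`: `scores` (samples x k), `loadings`
#'   (genes x k), `var_explained` (variance of each component),
#'   `total_var` (total variance of the centered data).
#' @export
pca_scores <- function(expr, k = 2, scale. = FALSE) {
  if (k <= 0) stop("k must be positive")
  k <- as.integer(k)
  stopifnot(k <= min(dim(expr)))
  x <- t(scale(t(expr), center = TRUE, scale = scale.))
  sv <- svd(x, nu = k, nv = k)
  load <- sv$u
  scores <- sv$v %*% diag(sv$d[seq_len(k)], k, k)
  flip <- vapply(seq_len(k), function(j) {
    l <- load[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  dimnames(scores) <- list(colnames(expr), paste0("PC", seq_len(k)))
  dimnames(load) <- list(rownames(expr), paste0("PC", seq_len(k)))
  structure(
    list(scores = scores, loadings = load,
         var_explained = sv$d[seq_len(k)]^2 / (ncol(expr) - 1),
         total_var = sum(x^2) / (ncol(expr) - 1)),
    class = "pc_scores"
  )
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Location/scale parametric ComBat via the sva package, with biological
#' covariates (e.g. group, sex) protected through the model matrix. A single
#' batch returns the input unchanged; a singleton batch is an error naming
#' the batch.
#'
#' @param expr genes x samples matrix.
#' @param batch character/factor batch labels per sample.
#' @param covariates optional data frame of covariates to preserve.
#' @return adjusted matrix.
#' @export
combat_adjust <- function(expr, batch, covariates = NULL) {
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(expr))
  tab <- table(batch)
  if (length(tab) < 2) {
    message("single batch; returning input unchanged")
    return(expr)
  }
  if (any(tab < 2)) {
    stop("singleton batch(es): ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mod <- stats::model.matrix(~ ., data = covariates)
  }
  out <- suppressMessages(
    sva::ComBat(dat = expr, batch = batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  dimnames(out) <- dimnames(expr)
  out
}

#' Grubbs outlier screen on principal-component axes
#'
#' Applies the single-outlier Grubbs test (maximum studentized deviation,
#' two-sided) to each of the requested PC axes, flagging the extreme sample
#' on any axis where the test is significant. At most `max_iter` rounds of
#' removal are performed per axis.
#'
#' @param pcs a `pc_scores` object.
#' @param axes PC axes to test (default first 2).
#' @param alpha significance level.
#' @param max_iter maximum removal rounds per axis.
#' @return list of class `outlier_report`: `flagged` (sample ids) and
#'   `tests` tibble (axis, sample, statistic, p).
#' @export
detect_outliers_grubbs <- function(pcs, axes = 1:2, alpha = 0.05,
                                   max_iter = 1) {
  scores <- pcs$scores
  if (nrow(scores) < 3) stop("need at least 3 samples for the Grubbs test")
  axes <- axes[axes <= ncol(scores)]
  flagged <- character(0)
  tests <- list()
  for (ax in axes) {
    x <- scores[, ax]
    for (it in seq_len(max_iter)) {
      gt <- grubbs_statistic(x)
      tests[[length(tests) + 1]] <- tibble::tibble(
        axis = colnames(scores)[ax], sample = gt$sample,
        statistic = gt$g, p = gt$p)
      if (gt$p < alpha) {
        flagged <- union(flagged, gt$sample)
        x <- x[names(x) != gt$sample]
        if (length(x) < 3) break
      } else break
    }
  }
  structure(list(flagged = flagged, tests = dplyr::bind_rows(tests)),
            class = "outlier_report")
}

# two-sided Grubbs test for one outlier: G = max|x - mean|/sd with p-value
# from the t-distribution bound p = 2n * P(T_{n-2} > t), capped at 1
grubbs_statistic <- function(x) {
  n <- length(x)
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  g <- dev[i] / stats::sd(x)
  t2 <- n * (n - 2) * g^2 / ((n - 1)^2 - n * g^2)
  p <- if (t2 < 0) 0 else 2 * n * stats::pt(sqrt(t2), df = n - 2,
                                            lower.tail = FALSE)
  list(sample = names(x)[i] %||% as.character(i), g = unname(g),
       p = min(1, p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
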