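#' Single-gene diagnostic AUC
#'
#' AUC as the probability that a randomly chosen case value exceeds a
#' randomly chosen control value, with half credit for ties (Mann-Whitney
#' relation), plus a DeLong-style normal-approximation confidence interval
#' and sensitivity/specificity at the Youden-optimal cut.
#'
#' @param values numeric marker values.
#' @param labels logical or two-level vector; `TRUE` (or the second level)
#'   is the case class.
#' @param conf_level CI level (default 0.95).
#' @return tibble: auc, ci_low, ci_high, sensitivity, specificity, cutoff.
#' @export
single_gene_auc <- function(values, labels, conf_level = 0.95) {
  is_case <- as_case(labels)
  x <- values[is_case]; y <- values[!is_case]
  if (length(x) == 0 || length(y) == 0) stop("both classes must be present")
  # placement values: psi = 1 if case > control, 0.5 tie, 0 otherwise
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
  auc <- mean(v10)
  s2 <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * sqrt(s2)))
  cuts <- sort(unique(values))
  youden <- vapply(cuts, function(cu)
    mean(x > cu) + mean(y <= cu) - 1, numeric(1))
  best <- which.max(youden)
  tibble::tibble(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 sensitivity = mean(x > cuts[best]),
                 specificity = mean(y <= cuts[best]),
                 cutoff = cuts[best])
}

as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("labels must have exactly two classes")
  case_level <- if ("ALS" %in% lv) "ALS" else lv[2]
  as.character(labels) == case_level
}

#' Class-balanced disjoint train/test split
#'
#' Draws `train_per_class` and `test_per_class` samples per class without
#' replacement (disjoint by construction). When a class is too small the
#' requested sizes are scaled down proportionally (logged via message).
#'
#' @param labels logical/two-level class labels, named by sample id (or
#'   positions are returned).
#' @param train_per_class,test_per_class requested sizes (defaults 296/100).
#' @param seed integer seed.
#' @param auto_scale scale down proportionally when samples are scarce.
#' @return list: `train`, `test` (indices into `labels`), `scale` (applied
#'   scaling factor).
#' @export
cv_split <- function(labels, train_per_class = 296, test_per_class = 100,
                     seed = NULL, auto_scale = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  is_case <- as_case(labels)
  n_min <- min(sum(is_case), sum(!is_case))
  need <- train_per_class + test_per_class
  scale_f <- 1
  if (n_min < need) {
    if (!auto_scale) stop("insufficient samples: need ", need,
                          " per class, have ", n_min)
    scale_f <- n_min / need
    test_per_class <- max(1, floor(test_per_class * scale_f))
    train_per_class <- min(n_min - test_per_class,
                           max(2, floor(train_per_class * scale_f)))
    message("cv_split scaled to ", train_per_class, "+", test_per_class,
            " per class")
  }
  pick <- function(idx) {
    s <- sample(idx, train_per_class + test_per_class)
    list(train = s[seq_len(train_per_class)],
         test = s[train_per_class + seq_len(test_per_class)])
  }
  a <- pick(which(is_case)); b <- pick(which(!is_case))
  list(train = c(a$train, b$train), test = c(a$test, b$test),
       scale = scale_f)
}

#' Leakage-free PC feature construction
#'
#' Ranks genes by training-set moderated-t p-value, keeps the top
#' `n_genes`, fits a PCA on the training samples only and projects both
#' partitions onto the training loadings.
#'
#' @param train_expr,test_expr genes x samples matrices (same gene panel).
#' @param train_labels class labels for the training samples.
#' @param n_genes number of input genes.
#' @param pc_count number of PC features.
#' @return list: `train` (samples x pc), `test`, `genes` (selected ids).
#' @export
pc_feature_pipeline <- function(train_expr, test_expr, train_labels,
                                n_genes, pc_count) {
  stopifnot(n_genes <= nrow(train_expr))
  if (pc_count > min(n_genes, ncol(train_expr))) {
    stop("pc_count exceeds the achievable rank")
  }
  is_case <- as_case(train_labels)
  de <- moderated_ttest(train_expr,
                        ifelse(is_case, "ALS", "CTL"))$table
  sel <- de$gene_id[order(de$p)][seq_len(n_genes)]
  xtr <- t(train_expr[sel, , drop = FALSE])
  ctr <- colMeans(xtr)
  xtr <- sweep(xtr, 2, ctr)
  sv <- svd(xtr, nu = 0, nv = pc_count)
  rot <- sv$v
  xte <- sweep(t(test_expr[sel, , drop = FALSE]), 2, ctr)
  list(train = xtr %*% rot, test = xte %*% rot, genes = sel)
}

#' Fit a classifier and evaluate it on a held-out test set
#'
#' Supports unpenalized logistic regression, random forest and RBF-kernel
#' SVM. Reports the held-out confusion matrix, accuracy, sensitivity,
#' specificity, and a McNemar test of confusion-matrix marginal homogeneity
#' (chi-squared with continuity correction; exact binomial when the
#' off-diagonal total is below 25; p = 1 when it is zero).
#'
#' @param train_features,test_features samples x features matrices.
#' @param train_labels,test_labels logical (TRUE = case) or two-level labels.
#' @param method one of "logistic", "random_forest", "svm_rbf".
#' @param hyperparams list: `ntree`, `mtry` (random forest), `cost`,
#'   `gamma` (svm).
#' @return tibble: accuracy, sensitivity, specificity, tp, fp, fn, tn,
#'   mcnemar_p.
#' @export
train_and_evaluate <- function(train_features, test_features,
                               train_labels, test_labels,
                               method = c("logistic", "random_forest",
                                          "svm_rbf"),
                               hyperparams = list()) {
  method <- match.arg(method)
  ytr <- factor(ifelse(as_case(train_labels), "case", "ctrl"),
                levels = c("ctrl", "case"))
  yte <- as_case(test_labels)
  hp <- utils::modifyList(list(ntree = 400, mtry = NULL, cost = 1,
                               gamma = NULL), hyperparams)
  dtr <- data.frame(train_features)
  dte <- data.frame(test_features)
  colnames(dte) <- colnames(dtr)
  pred <- switch(
    method,
    logistic = {
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = cbind(dtr, y = ytr), family = "binomial"))
      suppressWarnings(
        stats::predict(fit, newdata = dte, type = "response")) > 0.5
    },
    random_forest = {
      mtry <- hp$mtry %||% max(1, floor(sqrt(ncol(dtr))))
      mtry <- min(mtry, ncol(dtr))
      fit <- randomForest::randomForest(
        x = dtr, y = ytr, ntree = hp$ntree, mtry = mtry)
      stats::predict(fit, newdata = dte) == "case"
    },
    svm_rbf = {
      gamma <- hp$gamma %||% (1 / ncol(dtr))
      fit <- e1071::svm(x = as.matrix(dtr), y = ytr, kernel = "radial",
                        cost = hp$cost, gamma = gamma)
      stats::predict(fit, newdata = as.matrix(dte)) == "case"
    }
  )
  tp <- sum(pred & yte); fp <- sum(pred & !yte)
  fn <- sum(!pred & yte); tn <- sum(!pred & !yte)
  tibble::tibble(
    accuracy = (tp + tn) / length(yte),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, fp = fp, fn = fn, tn = tn,
    mcnemar_p = mcnemar_p(fp, fn)
  )
}

# McNemar marginal-homogeneity p from the off-diagonal counts
mcnemar_p <- function(b, cc, exact_below = 25) {
  n <- b + cc
  if (n == 0) return(1)
  if (n < exact_below) {
    return(stats::binom.test(b, n, 0.5)$p.value)
  }
  stat <- (abs(b - cc) - 1)^2 / n
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Cross-validated multigene diagnostic evaluation
#'
#' Repeats: class-balanced train/test split (ALS vs pooled CTL/MIM), gene
#' ranking and PCA on the training partition only, classifier fit and
#' held-out evaluation. Reports per-trial metrics, their means and the
#' fraction of trials with a significant McNemar test.
#'
#' @param expr genes x samples matrix (e.g. platform Z-scored).
#' @param samples sample tibble with `sample_id` and `group`.
#' @param method classifier, see [train_and_evaluate()].
#' @param n_genes input genes per trial (default 450).
#' @param pc_frac fraction of input genes kept as PC features (default
#'   0.14, i.e. 63 PCs at 450 genes).
#' @param n_trials number of CV trials.
#' @param train_per_class,test_per_class requested split sizes.
#' @param include_mim pool MIM with CTL as the non-ALS class (default TRUE).
#' @param hyperparams passed to [train_and_evaluate()].
#' @param seed integer seed.
#' @return list of class `cv_outcome`: `trials` (tibble), `summary`
#'   (tibble: accuracy, sensitivity, specificity, mcnemar_sig_frac,
#'   n_trials).
#' @export
run_cv <- function(expr, samples, method = "logistic",
                   n_genes = 450, pc_frac = 0.14, n_trials = 100,
                   train_per_class = 296, test_per_class = 100,
                   include_mim = TRUE, hyperparams = list(), seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  keep <- samples$group %in% c("ALS", "CTL", if (include_mim) "MIM")
  samples <- samples[keep, ]
  expr <- expr[, samples$sample_id, drop = FALSE]
  labels <- samples$group == "ALS"
  n_genes <- min(n_genes, nrow(expr))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_trials)
  trials <- purrr::map_dfr(seq_len(n_trials), function(i) {
    sp <- suppressMessages(
      cv_split(labels, train_per_class, test_per_class, seed = seeds[i]))
    pc_count <- max(1, min(floor(pc_frac * n_genes),
                           length(sp$train) - 1))
    feats <- pc_feature_pipeline(expr[, sp$train, drop = FALSE],
                                 expr[, sp$test, drop = FALSE],
                                 labels[sp$train], n_genes, pc_count)
    train_and_evaluate(feats$train, feats$test,
                       labels[sp$train], labels[sp$test],
                       method = method, hyperparams = hyperparams)
  })
  structure(
    list(trials = trials,
         summary = tibble::tibble(
           method = method,
           accuracy = mean(trials$accuracy),
           sensitivity = mean(trials$sensitivity),
           specificity = mean(trials$specificity),
           mcnemar_sig_frac = mean(trials$mcnemar_p < 0.05),
           n_trials = n_trials)),
    class = "cv_outcome"
  )
}

#' @export
print.cv_outcome <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<cv_outcome> %s: accuracy %.3f, sensitivity %.3f, specificity %.3f (McNemar sig. %.2f, %d trials)\n",
    s$method, s$accuracy, s$sensitivity, s$specificity,
    s$mcnemar_sig_frac, s$n_trials))
  invisible(x)
}

#' Sweep the (input genes x PC fraction) grid of the CV harness
#'
#' @param expr,samples,method,n_trials,seed as in [run_cv()].
#' @param gene_grid,pc_frac_grid grid axes.
#' @param ... further arguments to [run_cv()].
#' @return tibble: n_genes, pc_frac, accuracy, sensitivity, specificity,
#'   mcnemar_sig_frac, sorted by accuracy.
#' @export
run_cv_grid <- function(expr, samples, method = "logistic",
                        gene_grid = c(100, 250, 450),
                        pc_frac_grid = c(0.05, 0.14, 0.3),
                        n_trials = 25, seed = 1L, ...) {
  grid <- tidyr::expand_grid(n_genes = gene_grid, pc_frac = pc_frac_grid)
  purrr::pmap_dfr(grid, function(n_genes, pc_frac) {
    cv <- run_cv(expr, samples, method = method, n_genes = n_genes,
                 pc_frac = pc_frac, n_trials = n_trials, seed = seed, ...)
    dplyr::mutate(cv$summary, n_genes = n_genes, pc_frac = pc_frac,
                  .before = 1)
  }) |>
    dplyr::arrange(dplyr::desc(.data$accuracy))
}
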