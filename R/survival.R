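#' Covariate-adjusted Cox model for one expression feature
#'
#' Fits a proportional-hazards model (Efron tie handling) of survival on a
#' single feature plus clinical covariates. The feature is standardized to
#' unit SD so the hazard ratio is per 1 SD of expression.
#'
#' @param x numeric feature values (one per patient).
#' @param covariates data frame of clinical covariates (may be NULL).
#' @param time,event survival time and 0/1 event indicator.
#' @param standardize divide `x` by its SD (default TRUE).
#' @param conf_level Wald CI level.
#' @return tibble: hr, ci_low, ci_high, p, coef, se, loglik, n_events.
#' @export
cox_fit <- function(x, covariates = NULL, time, event, standardize = TRUE,
                    conf_level = 0.95) {
  if (sum(event) == 0) stop("zero events")
  if (standardize) {
    s <- stats::sd(x)
    if (s == 0) stop("constant feature cannot be standardized")
    x <- x / s
  }
  df <- data.frame(x = x)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = df, ties = "efron")
  if (!is.null(fit$info) || any(!is.finite(stats::coef(fit)))) {
    stop("Cox model did not converge")
  }
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients["x", ]
  ci <- sm$conf.int["x", ]
  tibble::tibble(
    hr = unname(co["exp(coef)"]),
    ci_low = unname(ci[3]), ci_high = unname(ci[4]),
    p = unname(co["Pr(>|z|)"]),
    coef = unname(co["coef"]), se = unname(co["se(coef)"]),
    loglik = fit$loglik[2], n_events = sum(event)
  )
}

#' Genome-wide covariate-adjusted Cox screen
#'
#' One Cox fit per gene passing the detection filter (gene detectable in
#' more than `min_detect` of the patients), with BH adjustment across
#' genes. Per-gene failures are recorded, not fatal.
#'
#' @param expr genes x patients matrix.
#' @param samples patient tibble with `sample_id`, `surv_time`, `event` and
#'   the covariate columns named in `covariate_cols`.
#' @param detp optional detection p-value matrix for the filter.
#' @param min_detect detection fraction threshold (default 0.20, strict >).
#' @param covariate_cols clinical covariates to adjust for.
#' @return tibble of class `cox_screen`: gene_id, hr, ci_low, ci_high, p,
#'   fdr, coef; attribute `frac_sig` = fraction with p < 0.05.
#' @export
genomewide_cox_screen <- function(expr, samples, detp = NULL,
                                  min_detect = 0.20,
                                  covariate_cols = c("age", "sex",
                                                     "onset_site", "cohort")) {
  pts <- samples[!is.na(samples$surv_time), ]
  stopifnot(nrow(pts) > 0, all(pts$sample_id %in% colnames(expr)))
  x <- expr[, pts$sample_id, drop = FALSE]
  if (!is.null(detp)) {
    keep <- detection_filter(detp[, pts$sample_id, drop = FALSE],
                             min_frac = min_detect)
    x <- x[keep[rownames(x)], , drop = FALSE]
  }
  covs <- cox_covariate_frame(pts, covariate_cols)
  rows <- purrr::map(rownames(x), function(g) {
    res <- tryCatch(
      cox_fit(x[g, ], covs, pts$surv_time, pts$event),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::mutate(res[, c("hr", "ci_low", "ci_high", "p", "coef")],
                  gene_id = g, .before = 1)
  })
  tab <- dplyr::bind_rows(rows)
  tab$fdr <- bh_adjust(tab$p)
  attr(tab, "frac_sig") <- mean(tab$p < 0.05)
  class(tab) <- c("cox_screen", class(tab))
  tab
}

cox_covariate_frame <- function(pts, covariate_cols) {
  covariate_cols <- intersect(covariate_cols, names(pts))
  if (length(covariate_cols) == 0) return(NULL)
  covs <- as.data.frame(pts[covariate_cols])
  drop <- vapply(covs, function(col) length(unique(col)) < 2, logical(1))
  covs <- covs[, !drop, drop = FALSE]
  if (ncol(covs) == 0) NULL else covs
}

#' Cluster genes on the |1 - r| correlation distance
#'
#' Average-linkage hierarchical clustering of genes on pairwise
#' `|1 - Pearson r|`, cut to exactly `target_n_groups` groups. Genes with
#' undefined correlations (constant across patients) become singleton
#' groups with a warning.
#'
#' @param expr genes x samples matrix.
#' @param gene_subset genes to cluster (default all rows).
#' @param target_n_groups number of groups after cutting the tree.
#' @return tibble: gene_id, group.
#' @export
cluster_genes <- function(expr, gene_subset = rownames(expr),
                          target_n_groups) {
  x <- expr[gene_subset, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 genes to cluster")
  const <- apply(x, 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) assigned singleton groups")
  }
  ok <- rownames(x)[!const]
  target_core <- max(1, target_n_groups - sum(const))
  r <- stats::cor(t(x[ok, , drop = FALSE]))
  d <- stats::as.dist(abs(1 - r))
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, k = min(target_core, length(ok)))
  out <- tibble::tibble(gene_id = ok, group = as.integer(grp))
  if (any(const)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      gene_id = rownames(x)[const],
      group = max(out$group) + seq_len(sum(const))))
  }
  out
}

#' Pick one representative gene per cluster
#'
#' Per group, the gene with the smallest Cox p-value; ties broken by larger
#' |log HR|, then lexicographic gene id.
#'
#' @param clusters tibble from [cluster_genes()].
#' @param cox_table `cox_screen` tibble covering all clustered genes.
#' @return character vector of representative gene ids.
#' @export
select_representatives <- function(clusters, cox_table) {
  stopifnot(all(clusters$gene_id %in% cox_table$gene_id))
  dplyr::left_join(clusters, cox_table, by = "gene_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$p, -abs(.data$coef), .data$gene_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::pull(.data$gene_id)
}

#' Stepwise Cox variable selection with LRT entry/stay criteria
#'
#' Forward step: add the candidate with the smallest likelihood-ratio p if
#' below `p_enter`. Backward step: drop any included gene whose drop-one
#' LRT p exceeds `p_stay` (worst first). Clinical covariates are always
#' retained. Terminates when stable, at `max_steps`, or when a model state
#' repeats (oscillation guard, with warning).
#'
#' @param expr genes x patients matrix of candidate genes (standardized
#'   internally to unit SD).
#' @param candidates candidate gene ids (rows of `expr`).
#' @param samples patient tibble (see [genomewide_cox_screen()]).
#' @param covariate_cols clinical covariates.
#' @param p_enter,p_stay entry/stay thresholds (default 0.15).
#' @param max_steps maximum forward/backward sweeps.
#' @return list of class `stepwise_cox`: `selected` (ordered by entry),
#'   `table` (gene, coef, hr, lrt_chi2, lrt_p from the final drop-one
#'   tests), `loglik`, `fit` (the final coxph object), `n_steps`.
#' @export
stepwise_cox <- function(expr, candidates, samples,
                         covariate_cols = c("age", "sex", "onset_site",
                                            "cohort"),
                         p_enter = 0.15, p_stay = 0.15, max_steps = 50) {
  pts <- samples[!is.na(samples$surv_time), ]
  x <- expr[candidates, pts$sample_id, drop = FALSE]
  x <- x / apply(x, 1, stats::sd)
  covs <- cox_covariate_frame(pts, covariate_cols)
  surv <- survival::Surv(pts$surv_time, pts$event)

  fit_model <- function(genes) {
    df <- as.data.frame(if (length(genes)) t(x[genes, , drop = FALSE])
                        else matrix(nrow = nrow(pts), ncol = 0))
    if (length(genes)) colnames(df) <- genes
    if (!is.null(covs)) df <- cbind(df, covs)
    if (ncol(df) == 0) df$.null <- 1
    survival::coxph(surv ~ ., data = df, ties = "efron")
  }

  included <- character(0)
  seen <- character(0)
  ll_cur <- fit_model(included)$loglik[2]
  n_steps <- 0
  repeat {
    n_steps <- n_steps + 1
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      lls <- vapply(pool, function(g)
        tryCatch(fit_model(c(included, g))$loglik[2],
                 error = function(e) NA_real_), numeric(1))
      lrt_p <- stats::pchisq(2 * (lls - ll_cur), df = 1, lower.tail = FALSE)
      best <- which.min(lrt_p)
      if (length(best) && is.finite(lrt_p[best]) && lrt_p[best] < p_enter) {
        included <- c(included, pool[best])
        ll_cur <- lls[best]
        changed <- TRUE
      }
    }
    # backward
    repeat {
      if (length(included) == 0) break
      lls_red <- vapply(included, function(g)
        fit_model(setdiff(included, g))$loglik[2], numeric(1))
      drop_p <- stats::pchisq(2 * (ll_cur - lls_red), df = 1,
                              lower.tail = FALSE)
      worst <- which.max(drop_p)
      if (drop_p[worst] > p_stay) {
        ll_cur <- lls_red[worst]
        included <- setdiff(included, included[worst])
        changed <- TRUE
      } else break
    }
    if (!changed || n_steps >= max_steps) break
    state <- paste(sort(included), collapse = ",")
    if (state %in% seen) {
      warning("stepwise selection revisited a model state; terminating")
      break
    }
    seen <- c(seen, state)
  }

  fit <- fit_model(included)
  tab <- tibble::tibble(gene = character(0), coef = numeric(0),
                        hr = numeric(0), lrt_chi2 = numeric(0),
                        lrt_p = numeric(0))
  if (length(included)) {
    ll_full <- fit$loglik[2]
    rows <- purrr::map_dfr(included, function(g) {
      ll_red <- fit_model(setdiff(included, g))$loglik[2]
      chi2 <- 2 * (ll_full - ll_red)
      tibble::tibble(gene = g,
                     coef = unname(stats::coef(fit)[g]),
                     hr = exp(unname(stats::coef(fit)[g])),
                     lrt_chi2 = chi2,
                     lrt_p = stats::pchisq(chi2, 1, lower.tail = FALSE))
    })
    tab <- rows
  }
  structure(list(selected = included, table = tab,
                 loglik = fit$loglik[2], fit = fit, n_steps = n_steps),
            class = "stepwise_cox")
}

#' @export
print.stepwise_cox <- function(x, ...) {
  cat("<stepwise_cox> ", length(x$selected), " gene(s) selected after ",
      x$n_steps, " sweep(s)\n", sep = "")
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Likelihood-ratio test of nested models
#'
#' @param ll_full,ll_reduced maximized log-likelihoods (full >= reduced up
#'   to `tol`).
#' @param df degrees-of-freedom difference (> 0).
#' @param tol negative-chi2 tolerance for numerical noise.
#' @return tibble: chi2, df, p.
#' @export
likelihood_ratio_test <- function(ll_full, ll_reduced, df, tol = 1e-8) {
  if (df <= 0) stop("df must be positive")
  chi2 <- 2 * (ll_full - ll_reduced)
  if (chi2 < -tol) stop("full model log-likelihood below reduced model: not nested?")
  chi2 <- max(0, chi2)
  tibble::tibble(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Concordance between a risk score and survival outcomes
#'
#' `harrell`: fraction of comparable patient pairs ordered correctly by the
#' linear predictor (ties counted 1/2), computed via survival::concordance.
#' `heagerty_zheng`: incident/dynamic AUC at each event time (rank of the
#' failing patient's predictor within the risk set), integrated with
#' weights proportional to `2 * f(t) * S(t)` from the Kaplan-Meier curve.
#'
#' @param lp linear predictor (higher = higher risk).
#' @param time,event survival outcome.
#' @param method "harrell" (default) or "heagerty_zheng".
#' @return concordance value in \[0, 1\].
#' @export
concordance_index <- function(lp, time, event,
                              method = c("harrell", "heagerty_zheng")) {
  method <- match.arg(method)
  if (sum(event) == 0) stop("no events: no comparable pairs")
  if (method == "harrell") {
    cf <- survival::concordance(survival::Surv(time, event) ~ lp,
                                reverse = TRUE)
    return(unname(cf$concordance))
  }
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  ev_times <- sort(unique(time[event == 1]))
  auc <- w <- numeric(length(ev_times))
  s_prev <- 1
  for (i in seq_along(ev_times)) {
    t0 <- ev_times[i]
    at_risk <- time >= t0
    cases <- which(time == t0 & event == 1)
    ctrls <- which(at_risk & !(time == t0 & event == 1))
    if (length(ctrls) == 0) { auc[i] <- NA; next }
    auc[i] <- mean(vapply(cases, function(ci)
      mean((lp[ci] > lp[ctrls]) + 0.5 * (lp[ci] == lp[ctrls])),
      numeric(1)))
    s_t <- summary(km, times = t0, extend = TRUE)$surv
    w[i] <- 2 * (s_prev - s_t) * s_t
    s_prev <- s_t
  }
  ok <- !is.na(auc) & w > 0
  if (!any(ok)) stop("no comparable pairs")
  sum(auc[ok] * w[ok]) / sum(w[ok])
}

#' Cross-validated survival prediction with a fixed gene signature
#'
#' Repeats: random train/test partition of the patients, Cox fit of the
#' base model (clinical covariates only) and the full model (covariates +
#' signature genes) on the training set, concordance of the test-set linear
#' predictors. Optionally re-runs stepwise gene selection inside every
#' trial (`reselect = TRUE`) to expose the optimism of in-sample selection.
#'
#' @param expr genes x patients matrix.
#' @param samples patient tibble with survival fields and covariates.
#' @param gene_set signature genes (fixed before CV unless `reselect`).
#' @param n_trials number of partitions.
#' @param train_n,test_n patients per partition (scaled down
#'   proportionally when fewer are available).
#' @param covariate_cols clinical covariates.
#' @param method concordance method.
#' @param reselect re-run [stepwise_cox()] inside each training partition.
#' @param min_events trials whose test draw has fewer events are skipped.
#' @param seed integer seed.
#' @return list of class `cv_survival`: `trials` (tibble: trial, c_base,
#'   c_full), `summary` (mean_base, mean_full, gain, n_trials, n_skipped).
#' @export
cv_survival <- function(expr, samples, gene_set, n_trials = 100,
                        train_n = 296, test_n = 100,
                        covariate_cols = c("age", "sex", "onset_site",
                                           "cohort"),
                        method = "harrell", reselect = FALSE,
                        min_events = 3, seed = 1L) {
  pts <- samples[!is.na(samples$surv_time), ]
  n <- nrow(pts)
  if (train_n + test_n > n) {
    f <- n / (train_n + test_n)
    test_n <- max(min_events + 2, floor(test_n * f))
    train_n <- n - test_n
    message("cv_survival scaled to ", train_n, "+", test_n, " patients")
  }
  x <- expr[, pts$sample_id, drop = FALSE]
  covs <- cox_covariate_frame(pts, covariate_cols)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_trials)
  n_skipped <- 0
  rows <- purrr::map_dfr(seq_len(n_trials), function(i) {
    set.seed(seeds[i])
    tr <- sample.int(n, train_n)
    te <- sample(setdiff(seq_len(n), tr), test_n)
    if (sum(pts$event[te]) < min_events || sum(pts$event[tr]) < min_events) {
      n_skipped <<- n_skipped + 1
      return(NULL)
    }
    genes <- gene_set
    if (reselect) {
      genes <- stepwise_cox(x[, tr, drop = FALSE], gene_set, pts[tr, ],
                            covariate_cols = covariate_cols)$selected
    }
    fit_lp <- function(gene_subset) {
      dtr <- cox_design(x, gene_subset, covs, tr)
      dte <- cox_design(x, gene_subset, covs, te)
      fit <- survival::coxph(
        survival::Surv(pts$surv_time[tr], pts$event[tr]) ~ .,
        data = dtr, ties = "efron")
      as.vector(stats::predict(fit, newdata = dte, type = "lp"))
    }
    lp_base <- fit_lp(character(0))
    lp_full <- fit_lp(genes)
    tibble::tibble(
      trial = i,
      c_base = concordance_index(lp_base, pts$surv_time[te],
                                 pts$event[te], method = method),
      c_full = concordance_index(lp_full, pts$surv_time[te],
                                 pts$event[te], method = method))
  })
  structure(
    list(trials = rows,
         summary = tibble::tibble(
           mean_base = mean(rows$c_base), mean_full = mean(rows$c_full),
           gain = mean(rows$c_full) - mean(rows$c_base),
           n_trials = nrow(rows), n_skipped = n_skipped)),
    class = "cv_survival")
}

cox_design <- function(x, genes, covs, idx) {
  df <- as.data.frame(if (length(genes))
    t(x[genes, idx, drop = FALSE]) else matrix(nrow = length(idx), ncol = 0))
  if (length(genes)) colnames(df) <- genes
  if (!is.null(covs)) df <- cbind(df, covs[idx, , drop = FALSE])
  if (ncol(df) == 0) df$.null <- 1
  df
}

#' @export
print.cv_survival <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_survival> base C %.3f, full C %.3f (gain %.3f, %d trials)\n",
              s$mean_base, s$mean_full, s$gain, s$n_trials))
  invisible(x)
}

#' Exhaustive survival-association search over signature-score combinations
#'
#' Fits covariate-adjusted Cox models for every combination of 1..max_k
#' score columns and ranks combinations by the likelihood-ratio p against
#' the covariates-only model.
#'
#' @param scores `score_matrix` tibble (sample_id + score columns).
#' @param samples patient tibble with survival fields.
#' @param max_k largest combination size (default 3).
#' @param covariate_cols clinical covariates.
#' @return tibble: combination, k, chi2, df, p, sorted by p.
#' @export
score_combination_search <- function(scores, samples, max_k = 3,
                                     covariate_cols = c("age", "sex",
                                                        "onset_site",
                                                        "cohort")) {
  score_cols <- setdiff(names(scores), "sample_id")
  if (max_k > length(score_cols)) stop("max_k exceeds the number of scores")
  pts <- samples[!is.na(samples$surv_time), ]
  sc <- scores[match(pts$sample_id, scores$sample_id), ]
  covs <- cox_covariate_frame(pts, covariate_cols)
  surv <- survival::Surv(pts$surv_time, pts$event)
  fit_ll <- function(cols) {
    df <- as.data.frame(sc[cols])
    if (!is.null(covs)) df <- cbind(df, covs)
    if (ncol(df) == 0) df$.null <- 1
    survival::coxph(surv ~ ., data = df, ties = "efron")$loglik[2]
  }
  ll0 <- fit_ll(character(0))
  combos <- purrr::map(seq_len(max_k), function(k)
    utils::combn(score_cols, k, simplify = FALSE)) |>
    purrr::flatten()
  purrr::map_dfr(combos, function(cols) {
    lrt <- likelihood_ratio_test(fit_ll(cols), ll0, df = length(cols))
    tibble::tibble(combination = paste(cols, collapse = "+"),
                   k = length(cols), chi2 = lrt$chi2, df = lrt$df,
                   p = lrt$p)
  }) |>
    dplyr::arrange(.data$p)
}

#' Median-survival contrast from an accelerated failure time model
#'
#' Fits a Weibull AFT model of survival on one feature plus covariates and
#' returns the ratio of predicted median survival at the feature's high
#' (default 80th percentile) vs low (20th) values, covariates held at
#' reference levels.
#'
#' @param x feature values.
#' @param covariates data frame or NULL.
#' @param time,event survival outcome.
#' @param lo,hi quantiles contrasted (defaults 0.20 / 0.80).
#' @return tibble: ratio, median_lo, median_hi, coef, p.
#' @export
aft_median_contrast <- function(x, covariates = NULL, time, event,
                                lo = 0.20, hi = 0.80) {
  if (sum(event) < 10) stop("need at least 10 events")
  q <- stats::quantile(x, c(lo, hi))
  if (q[[2]] == q[[1]]) {
    warning("feature quantiles equal; ratio is 1")
    return(tibble::tibble(ratio = 1, median_lo = NA_real_,
                          median_hi = NA_real_, coef = NA_real_,
                          p = NA_real_))
  }
  df <- data.frame(x = x)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- survival::survreg(survival::Surv(time, event) ~ ., data = df,
                           dist = "weibull")
  if (any(!is.finite(stats::coef(fit)))) stop("AFT model did not converge")
  beta <- stats::coef(fit)["x"]
  # Weibull AFT: log median is linear in covariates, so the contrast is
  # exp(beta * (q_hi - q_lo)) exactly
  ratio <- exp(unname(beta) * (q[[2]] - q[[1]]))
  med_scale <- log(2)^fit$scale
  mu0 <- stats::coef(fit)[1]
  p <- summary(fit)$table["x", "p"]
  tibble::tibble(ratio = ratio,
                 median_lo = exp(mu0 + unname(beta) * q[[1]]) * med_scale,
                 median_hi = exp(mu0 + unname(beta) * q[[2]]) * med_scale,
                 coef = unname(beta), p = p)
}

#' Predicted median-survival spread of a fitted Cox model
#'
#' Computes each patient's predicted median survival from the fitted
#' baseline hazard, then contrasts two reference patients: the one whose
#' predicted median is nearest the `hi` quantile of predicted medians
#' (favorable) and the one nearest the `lo` quantile (risk). Medians not
#' reached within the observed follow-up are flagged as extrapolated (NA).
#'
#' @param fit a coxph fit.
#' @param newdata data frame of the patients to evaluate.
#' @param lo,hi quantiles of the predicted-median distribution.
#' @return list of class `survival_spread`: `ratio` (favorable/risk median),
#'   `favorable`, `risk` (row indices), `medians` (per patient),
#'   `extrapolated` (logical).
#' @export
predicted_survival_spread <- function(fit, newdata, lo = 0.20, hi = 0.80) {
  sf <- survival::survfit(fit, newdata = newdata)
  med <- summary(sf)$table[, "median"]
  extrapolated <- any(is.na(med))
  if (extrapolated) {
    warning("some predicted medians not reached within follow-up")
  }
  q <- stats::quantile(med, c(lo, hi), na.rm = TRUE)
  risk <- which.min(abs(med - q[[1]]))
  fav <- which.min(abs(med - q[[2]]))
  structure(list(ratio = med[fav] / med[risk], favorable = fav, risk = risk,
                 medians = med, extrapolated = extrapolated),
            class = "survival_spread")
}
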