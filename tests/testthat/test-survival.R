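test_that("Cox fit returns per-SD hazard ratios with exposed log-likelihood", {
  sv <- fix_surv()
  pts <- sv$samples
  g <- sv$truth$gene[1]
  out <- cox_fit(sv$expr[g, pts$sample_id],
                 pts[, c("age", "sex", "onset_site")],
                 pts$surv_time, pts$event)
  expect_true(out$ci_low <= out$hr && out$hr <= out$ci_high)
  expect_gt(out$hr, 1)                       # planted positive log HR
  expect_lt(out$p, 1e-4)
  expect_error(cox_fit(rnorm(10), NULL, rexp(10), rep(0, 10)), "zero events")
  expect_error(cox_fit(rep(1, 10), NULL, rexp(10), rep(1, 10)), "constant")
})

test_that("the genome-wide screen ranks planted genes first and filters detection", {
  sv <- fix_surv()
  scr <- genomewide_cox_screen(sv$expr[1:500, ], sv$samples)
  expect_true(all(c("gene_id", "hr", "p", "fdr") %in% names(scr)))
  planted <- intersect(sv$truth$gene, rownames(sv$expr)[1:500])
  if (length(planted)) {
    expect_true(all(scr$p[match(planted, scr$gene_id)] < 0.01))
  }
  # detection filter: a gene detected in 19% of patients is excluded
  detp <- matrix(1, 3, nrow(sv$samples),
                 dimnames = list(rownames(sv$expr)[1:3],
                                 sv$samples$sample_id))
  n <- nrow(sv$samples)
  detp[1, seq_len(floor(0.19 * n))] <- 0.01
  detp[2, seq_len(ceiling(0.25 * n))] <- 0.01
  scr2 <- genomewide_cox_screen(sv$expr[1:3, ], sv$samples, detp = detp)
  expect_false(rownames(sv$expr)[1] %in% scr2$gene_id)
  expect_true(rownames(sv$expr)[2] %in% scr2$gene_id)
})

test_that("gene clustering follows the |1 - r| metric and survives constant genes", {
  set.seed(33)
  n <- 40
  base <- rnorm(n)
  x <- rbind(a = base, b = base * 2 + 1,            # r = 1
             c = -base + 0.5,                        # r = -1 with a
             d = rnorm(n), e = rep(2, n))            # constant
  colnames(x) <- sprintf("s%02d", 1:n)
  expect_warning(cl <- cluster_genes(x, target_n_groups = 3), "constant")
  grp <- setNames(cl$group, cl$gene_id)
  expect_equal(grp[["a"]], grp[["b"]])
  expect_false(grp[["a"]] == grp[["c"]])
  expect_equal(sum(cl$gene_id == "e"), 1)
  expect_error(cluster_genes(x["a", , drop = FALSE], target_n_groups = 1),
               "2 genes")
})

test_that("clustering recovers planted correlation blocks exactly", {
  set.seed(34)
  n <- 60
  make_block <- function(k) {
    f <- rnorm(n)
    t(sapply(seq_len(k), function(i) f + rnorm(n, sd = 0.2)))
  }
  x <- rbind(make_block(5), make_block(5), make_block(5))
  rownames(x) <- sprintf("g%02d", 1:15)
  colnames(x) <- sprintf("s%02d", 1:n)
  cl <- cluster_genes(x, target_n_groups = 3)
  truth <- rep(1:3, each = 5)
  # identical partitions up to label permutation
  expect_equal(length(unique(cl$group)), 3)
  tab <- table(cl$group, truth)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
})

test_that("representatives minimize p with documented tie-breaks", {
  clusters <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                             group = c(1, 1, 2, 3))
  cox_tab <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                            p = c(0.01, 0.10, 0.5, 0.5),
                            coef = c(0.1, 0.9, 0.2, 0.2))
  expect_setequal(select_representatives(clusters, cox_tab),
                  c("a", "c", "d"))
  # tie on p: larger |log HR| wins
  tie <- tibble::tibble(gene_id = c("x", "y"), group = 1)
  tie_tab <- tibble::tibble(gene_id = c("x", "y"), p = c(0.2, 0.2),
                            coef = c(0.1, -0.8))
  expect_equal(select_representatives(tie, tie_tab), "y")
})

test_that("stepwise selection keeps a strong gene and drops noise", {
  sv <- fix_surv()
  strong <- sv$truth$gene[1]
  set.seed(35)
  cand <- c(strong, sample(setdiff(rownames(sv$expr)[1:200],
                                   sv$truth$gene), 20))
  st <- stepwise_cox(sv$expr, cand, sv$samples)
  expect_true(strong %in% st$selected)
  expect_true(all(st$table$lrt_p <= 0.15 + 1e-12))
  expect_lte(length(st$selected), 8)
  # empty when nothing is marginally associated
  null_cand <- setdiff(rownames(sv$expr)[201:215], sv$truth$gene)
  st0 <- stepwise_cox(sv$expr, null_cand, sv$samples, p_enter = 1e-6)
  expect_length(st0$selected, 0)
  expect_s3_class(tidy(st), "tbl_df")
})

test_that("perfectly collinear strong candidates keep exactly one member", {
  sv <- fix_surv()
  strong <- sv$truth$gene[1]
  x <- sv$expr[c(strong, "g1999", "g2000"), ]
  x["g1999", ] <- x[strong, ]                # exact copy
  st <- stepwise_cox(x, rownames(x), sv$samples)
  expect_equal(sum(c(strong, "g1999") %in% st$selected), 1)
})

test_that("Harrell concordance matches exhaustive pairwise enumeration", {
  expect_equal(concordance_index(c(1.0, 0.5, 0.7), c(1, 2, 3),
                                 c(1, 1, 1)), 2 / 3)
  # perfect risk ordering
  expect_equal(concordance_index(3:1, c(1, 2, 3), c(1, 1, 1)), 1)
  set.seed(36)
  n <- 120
  lp <- rnorm(n); time <- rexp(n); event <- rbinom(n, 1, 0.7)
  brute <- {
    conc <- disc <- ties <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      # comparable iff the earlier time is an event
      ti <- time[i]; tj <- time[j]
      first <- if (ti < tj) i else if (tj < ti) j else NA
      if (is.na(first) || event[if (ti < tj) i else j] == 0) next
      other <- if (first == i) j else i
      if (lp[first] > lp[other]) conc <- conc + 1
      else if (lp[first] < lp[other]) disc <- disc + 1
      else ties <- ties + 1
    }
    (conc + 0.5 * ties) / (conc + disc + ties)
  }
  expect_equal(concordance_index(lp, time, event), brute, tolerance = 1e-12)
})

test_that("Heagerty-Zheng concordance behaves sensibly", {
  sv <- fix_surv()
  pts <- sv$samples
  z <- sv$expr[sv$truth$gene, pts$sample_id]
  lp <- as.vector(crossprod(z / apply(z, 1, sd), sv$truth$loghr))
  hz <- concordance_index(lp, pts$surv_time, pts$event,
                          method = "heagerty_zheng")
  ha <- concordance_index(lp, pts$surv_time, pts$event)
  expect_true(hz > 0.6 && hz <= 1)
  expect_lt(abs(hz - ha), 0.1)
  set.seed(37)
  null <- concordance_index(rnorm(200), rexp(200), rbinom(200, 1, 0.7),
                            method = "heagerty_zheng")
  expect_lt(abs(null - 0.5), 0.08)
})

test_that("likelihood ratio tests are additive over nested drops", {
  expect_equal(likelihood_ratio_test(-100, -100, 1)$p, 1)
  expect_equal(likelihood_ratio_test(-98.08, -100, 1)$chi2, 3.84)
  expect_equal(likelihood_ratio_test(-98.08, -100, 1)$p, 0.050,
               tolerance = 1e-2)
  expect_error(likelihood_ratio_test(-100, -99, 1, tol = 1e-8), "nested")
  expect_error(likelihood_ratio_test(-99, -100, 0), "df")
  a <- likelihood_ratio_test(-95, -97, 1)$chi2
  b <- likelihood_ratio_test(-97, -100, 1)$chi2
  ab <- likelihood_ratio_test(-95, -100, 2)$chi2
  expect_equal(a + b, ab, tolerance = 1e-6)
})

test_that("score combination search finds the informative score and collapses duplicates", {
  sv <- fix_surv()
  pts <- sv$samples
  z <- sv$expr[sv$truth$gene, pts$sample_id]
  lp <- as.vector(crossprod(z / apply(z, 1, sd), sv$truth$loghr))
  set.seed(38)
  scores <- tibble::tibble(sample_id = pts$sample_id,
                           signal = lp,
                           noise1 = rnorm(nrow(pts)),
                           dup = lp)
  out <- score_combination_search(scores, sv$samples, max_k = 2)
  best1 <- out[out$k == 1, ]
  expect_true(best1$combination[1] %in% c("signal", "dup"))
  # duplicated column adds nothing: same p as the singleton
  p_single <- out$p[out$combination == "signal"]
  p_dup <- out$p[out$combination == "signal+dup"]
  expect_equal(p_single, p_dup, tolerance = 1e-8)
  expect_error(score_combination_search(scores, sv$samples, max_k = 9),
               "max_k")
})

test_that("cross-validated survival models separate signal from noise genes", {
  sv <- fix_surv()
  cv_sig <- cv_survival(sv$expr, sv$samples, sv$truth$gene,
                        n_trials = 25, seed = 39)
  expect_gte(cv_sig$summary$gain, 0.08)
  set.seed(40)
  noise_genes <- sample(setdiff(rownames(sv$expr), sv$truth$gene), 5)
  cv_null <- cv_survival(sv$expr, sv$samples, noise_genes,
                         n_trials = 25, seed = 39)
  expect_lte(abs(cv_null$summary$gain), 0.02)
  expect_s3_class(tidy(cv_sig), "tbl_df")
  expect_named(glance(cv_sig), c("mean_base", "mean_full", "gain",
                                 "n_trials", "n_skipped"))
})

test_that("AFT contrasts recover the closed-form Weibull median ratio", {
  sv <- fix_surv()
  pts <- sv$samples
  cfg <- sim_config()
  # mean relative error of the fitted hi/lo median ratio against the
  # closed-form Weibull value exp(beta * (q80 - q20)), over planted genes
  rel_err <- vapply(seq_along(sv$truth$gene), function(i) {
    x <- sv$expr[sv$truth$gene[i], pts$sample_id]
    others <- t(sv$expr[sv$truth$gene[-i], pts$sample_id, drop = FALSE])
    covs <- cbind(as.data.frame(others),
                  pts[, c("age", "sex", "onset_site")])
    out <- aft_median_contrast(x, covs, pts$surv_time, pts$event)
    beta_true <- -sv$truth$loghr[i] / (cfg$weibull_shape * sd(x))
    expected <- exp(beta_true * (quantile(x, 0.8) - quantile(x, 0.2)))
    abs(out$ratio - expected) / expected
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
  # a feature with no effect gives a ratio of 1
  set.seed(41)
  out0 <- aft_median_contrast(rnorm(nrow(pts)), NULL,
                              pts$surv_time, pts$event)
  expect_lt(abs(out0$ratio - 1), 0.05)
  expect_warning(aft_median_contrast(rep(1, nrow(pts)), NULL,
                                     pts$surv_time, pts$event),
                 "quantiles")
})

test_that("predicted survival spread widens with planted signal", {
  sv <- fix_surv()
  pts <- sv$samples
  z <- t(sv$expr[sv$truth$gene, pts$sample_id])
  colnames(z) <- paste0("x", seq_len(ncol(z)))
  df <- data.frame(z)
  df$surv <- survival::Surv(pts$surv_time, pts$event)
  fit <- survival::coxph(
    stats::reformulate(colnames(z), response = "surv"), data = df)
  sp <- suppressWarnings(predicted_survival_spread(fit, df))
  expect_gte(sp$ratio, 1.5)
  # null model: spread near 1
  null_fit <- survival::coxph(
    survival::Surv(time, event) ~ noise,
    data = data.frame(noise = rnorm(nrow(pts)), time = pts$surv_time,
                      event = pts$event))
  sp0 <- predicted_survival_spread(
    null_fit, data.frame(noise = rnorm(nrow(pts))))
  expect_lt(abs(sp0$ratio - 1), 0.25)
})
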