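test_that("signature weights equal sqrt(101 - r)/10 for the 100-gene scheme", {
  w <- signature_weights(100)
  expect_equal(w, sqrt(101 - 1:100) / 10)
  expect_equal(w[1], 1.0)
  expect_equal(w[100], 0.1)
  expect_true(all(diff(w) < 0))
})

test_that("signature selection recovers planted markers", {
  ref <- fix_reference()
  sigs <- fix_signatures()
  for (ct in c("NP", "RBC", "B")) {
    truth <- ref$truth$gene[ref$truth$cell_type == ct]
    jac <- length(intersect(sigs[[ct]]$genes, truth)) /
      length(union(sigs[[ct]]$genes, truth))
    expect_gte(jac, 0.95)
  }
})

test_that("signature selection honors sizes, ordering and error contracts", {
  ref <- fix_reference()
  sig <- select_signature_genes(ref, "NP")
  expect_length(sig$genes, 100)
  expect_true(all(diff(sig$table$log2fc) <= 0))   # FC-ordered ranks
  # n_p = n_fc: the FC re-sort permutes but keeps the same membership
  a <- select_signature_genes(ref, "NP", n_p = 120, n_fc = 120)
  de <- moderated_ttest(ref$profiles,
                        ifelse(ref$sample_types == "NP", "target", "rest"),
                        case = "target", control = "rest")$table
  up <- de[de$log2fc > 0, ]
  lowest_p <- up$gene_id[order(up$p)][1:120]
  expect_setequal(a$genes, lowest_p)
  expect_error(select_signature_genes(ref, "NP", n_p = 3000, n_fc = 3000),
               "elevated")
})

test_that("two-type toy signatures are headed by their own markers", {
  set.seed(24)
  prof <- matrix(rnorm(400 * 8, mean = 6, sd = 0.2), 400, 8,
                 dimnames = list(sprintf("g%03d", 1:400), NULL))
  prof[1, 1:4] <- prof[1, 1:4] + 3        # marker of type A
  prof[2, 5:8] <- prof[2, 5:8] + 3        # marker of type B
  ref <- structure(list(profiles = prof,
                        sample_types = rep(c("A", "B"), each = 4),
                        cell_types = c("A", "B")),
                   class = "cell_reference")
  sa <- select_signature_genes(ref, "A", n_p = 20, n_fc = 10)
  sb <- select_signature_genes(ref, "B", n_p = 20, n_fc = 10)
  expect_equal(sa$genes[1], "g001")
  expect_equal(sb$genes[1], "g002")
})

test_that("signature scores are weighted means of Z-scores", {
  z <- rbind(g1 = c(0.5, 1), g2 = c(-1, 1), g3 = c(2, 1))
  colnames(z) <- c("s1", "s2")
  sig <- structure(list(label = "T", genes = c("g1", "g2", "g3"),
                        weights = signature_weights(3)),
                   class = "signature_def")
  out <- compute_signature_scores(z, sig)
  w <- sqrt(c(3, 2, 1)) / sqrt(3)
  expect_equal(out$T[1], sum(w * c(0.5, -1, 2)) / sum(w))
  expect_equal(out$T[2], 1)              # constant z = 1 -> score 1
})

test_that("missing signature genes renormalize weights with coverage warning", {
  z <- rbind(g1 = c(1, -1), g2 = c(0.5, 0))
  colnames(z) <- c("s1", "s2")
  sig <- structure(list(label = "T",
                        genes = c("g1", "g2", "g3", "g4", "g5"),
                        weights = signature_weights(5)),
                   class = "signature_def")
  expect_warning(out <- compute_signature_scores(z, sig), "coverage")
  w <- signature_weights(5)[1:2]
  expect_equal(out$T[1], sum(w * c(1, 0.5)) / sum(w))
  sig$genes <- c("x1", "x2")
  sig$weights <- signature_weights(2)
  expect_error(compute_signature_scores(z, sig), "no signature genes")
})

test_that("scores are invariant to per-gene affine rescaling of the raw matrix", {
  sim <- fix_sim()
  expr <- sim$expr1[1:300, ]
  sigs <- fix_signatures()
  sig <- sigs$NP
  z1 <- zscore_by_platform(expr, rep("V3", ncol(expr)))
  scale_f <- runif(nrow(expr), 0.5, 3)
  shift <- rnorm(nrow(expr), sd = 5)
  z2 <- zscore_by_platform(expr * scale_f + shift, rep("V3", ncol(expr)))
  keep <- intersect(sig$genes, rownames(expr))
  sig$weights <- sig$weights[sig$genes %in% keep]
  sig$genes <- keep
  s1 <- compute_signature_scores(z1, sig)
  s2 <- compute_signature_scores(z2, sig)
  expect_lt(max(abs(s1$NP - s2$NP)), 1e-10)
})

test_that("scores track planted proportions and identify pure-type samples", {
  sim <- fix_sim()
  scores <- fix_scores()
  props <- sim$truth$props[scores$sample_id, ]
  rho <- cor(scores$NP, props[, "NP"], method = "spearman")
  expect_gte(rho, 0.8)
  # pure-type mixtures: matched cell type scores highest
  ref <- fix_reference()
  sigs <- fix_signatures()
  lin <- reference_linear_means(ref)
  pure <- log2(lin)                     # one pure sample per type
  colnames(pure) <- ref$cell_types
  z <- zscore_by_platform(pure, rep("P", ncol(pure)))
  sc <- compute_signature_scores(z, sigs)
  top <- apply(as.matrix(sc[ref$cell_types]), 1, function(r)
    ref$cell_types[which.max(r)])
  expect_gte(mean(top == sc$sample_id), 0.9)
})

test_that("composite scores and subgroup thresholds are applied verbatim", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"),
                       DC = 0.2, MP = 0.2, MC = 0.2, NP = 0.2, PL = 0.2,
                       RBC = 0.2, ES = c(0.2, 0.7, 0.2),
                       CD8 = -0.2, CD4 = -0.2, GDT = -0.2, NK = -0.2,
                       B = c(-0.2, -0.2, 0.2))
  comp <- composite_scores(sc)
  expect_equal(comp$myeloid[1], 0.2)
  expect_equal(comp$myeloid[2], (0.2 * 6 + 0.7) / 7)
  expect_equal(comp$lymphoid[3], (-0.2 * 4 + 0.2) / 5)
  expect_error(composite_scores(sc[, -2]), "DC")
  cases <- tibble::tibble(sample_id = c("m", "l", "u", "u2"),
                          myeloid = c(0.2, -0.1, 0.0, 0.06),
                          lymphoid = c(-0.2, 0.1, 0.0, 0.06))
  out <- assign_subgroups(cases)
  expect_equal(out$subgroup, c("myeloid", "lymphoid", "unassigned",
                               "unassigned"))
})

test_that("polarization signatures recover planted markers and reject degenerate input", {
  set.seed(25)
  prof <- matrix(rnorm(600 * 9, mean = 6, sd = 0.3), 600, 9,
                 dimnames = list(sprintf("g%03d", 1:600), NULL))
  m1 <- 1:30; m2 <- 31:60
  prof[m1, 1:3] <- prof[m1, 1:3] + 2.5
  prof[m2, 4:6] <- prof[m2, 4:6] + 2.5
  ref <- structure(list(profiles = prof,
                        sample_types = rep(c("M1", "M2", "M0"), each = 3),
                        cell_types = c("M1", "M2", "M0")),
                   class = "cell_reference")
  sigs <- polarization_signatures(ref, n_p = 40, n_fc = 30)
  expect_gte(length(intersect(sigs$M1$genes, rownames(prof)[m1])) / 30,
             0.9)
  expect_gte(length(intersect(sigs$M2$genes, rownames(prof)[m2])) / 30,
             0.9)
  # a pure M1 profile scores higher on the M1 signature
  z <- zscore_by_platform(prof, rep("P", 9))
  sc <- compute_signature_scores(z, sigs)
  expect_gt(mean(sc$M1[1:3]), mean(sc$M2[1:3]))
  # identical class profiles leave nothing elevated
  flat <- ref
  flat$profiles <- matrix(rep(prof[, 1], 9), ncol = 9,
                          dimnames = dimnames(prof))
  expect_error(polarization_signatures(flat, n_p = 40, n_fc = 30))
  expect_error(polarization_signatures(
    structure(list(profiles = prof, sample_types = rep("M1", 9),
                   cell_types = "M1"), class = "cell_reference")),
    "M2")
})
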