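#' Generate two synthetic blood-expression cohorts with known ground truth
#'
#' Builds genes x samples log2 expression for two cohorts on partially
#' overlapping gene panels. Each sample is a log2-transformed
#' proportion-weighted linear-scale mixture of the purified reference
#' profiles, with planted direct DEG effects on ALS samples, a sex effect,
#' an index-contiguous batch shift within each cohort, a platform offset on
#' C2, and Gaussian noise. Detection p-values follow a decreasing sigmoid of
#' intensity with uniform noise; a configured fraction of samples has them
#' stored flipped (1 - p), emulating the orientation defect the repair step
#' fixes.
#'
#' @param config a [sim_config()].
#' @param reference a `cell_reference` from [generate_reference()] whose
#'   panel size equals `config$n_genes`.
#' @return list with `expr1`, `detp1`, `expr2`, `detp2` (cohort matrices on
#'   their own panels), `samples` (tibble), `genes` (tibble), and `truth`
#'   (list: planted DEGs, per-sample proportions, sex genes, flipped sample
#'   ids, batch/platform shift vectors).
#' @export
generate_cohorts <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "cell_reference"))
  if (nrow(reference$profiles) != config$n_genes) {
    stop("reference panel (", nrow(reference$profiles),
         " genes) does not match config$n_genes (", config$n_genes, ")")
  }
  set.seed(config$seed)
  gene_ids <- rownames(reference$profiles)
  n_genes <- config$n_genes
  types <- reference$cell_types

  # panels: shared block + even split of the remainder
  n_extra <- n_genes - config$n_shared
  shared <- gene_ids[seq_len(config$n_shared)]
  extra <- gene_ids[config$n_shared + seq_len(n_extra)]
  panel1 <- c(shared, extra[seq_len(n_extra / 2)])
  panel2 <- c(shared, extra[n_extra / 2 + seq_len(n_extra / 2)])

  samples <- build_sample_table(config)
  n <- nrow(samples)

  # planted per-sample cell-type proportions
  props <- draw_proportions(samples, config, types)

  # mixture in linear scale
  lin_means <- reference_linear_means(reference)[, types, drop = FALSE]
  expr <- log2(lin_means %*% t(props))
  dimnames(expr) <- list(gene_ids, samples$sample_id)

  # planted DEGs: half up, half down, restricted to the shared panel so
  # both cohorts carry the signal (and the meta-analysis can see it)
  deg_pool <- setdiff(shared, reference$truth$gene[reference$truth$cell_type %in%
                                                     c("NP", "RBC")])
  n_deg <- config$n_deg
  deg_genes <- if (n_deg > 0) sample(deg_pool, n_deg) else character(0)
  deg_lfc <- rep(c(config$deg_lfc, -config$deg_lfc), length.out = n_deg)
  if (n_deg > 0) {
    als <- samples$group == "ALS"
    expr[deg_genes, als] <- expr[deg_genes, als] + deg_lfc
  }

  # sex effect on a random gene subset (male-additive)
  sex_genes <- if (config$n_sex_genes > 0) {
    sample(setdiff(shared, deg_genes), config$n_sex_genes)
  } else character(0)
  if (length(sex_genes)) {
    male <- samples$sex == "M"
    expr[sex_genes, male] <- expr[sex_genes, male] + config$sex_effect
  }

  # batch: additive per-gene shift on the second index block of each cohort
  batch_shift <- list()
  for (co in c("C1", "C2")) {
    in_b2 <- samples$cohort == co & samples$batch == paste0(co, "_B2")
    shift <- stats::rnorm(n_genes, sd = config$batch_shift_sd)
    expr[, in_b2] <- expr[, in_b2] + shift
    batch_shift[[co]] <- shift
  }

  # platform offset on all C2 samples
  plat_shift <- stats::rnorm(n_genes, sd = config$platform_offset_sd)
  is_c2 <- samples$cohort == "C2"
  expr[, is_c2] <- expr[, is_c2] + plat_shift

  expr <- expr + matrix(stats::rnorm(n_genes * n, sd = config$noise_sd),
                        nrow = n_genes)

  # detection p: decreasing sigmoid of intensity + uniform noise
  detp <- detection_p_model(expr, config)
  flip_pool <- samples$sample_id
  n_flip <- round(config$detect_flip_frac * n)
  flipped <- if (n_flip > 0) sort(sample(flip_pool, n_flip)) else character(0)
  detp[, flipped] <- 1 - detp[, flipped]

  genes <- build_gene_table(gene_ids, seed = config$seed + 7L)

  truth <- list(
    degs = tibble::tibble(gene = deg_genes, lfc = deg_lfc),
    props = props,
    sex_genes = sex_genes,
    flipped_samples = flipped,
    batch_shift = batch_shift,
    platform_shift = plat_shift,
    seed = config$seed
  )

  list(
    expr1 = expr[panel1, samples$cohort == "C1"],
    detp1 = detp[panel1, samples$cohort == "C1"],
    expr2 = expr[panel2, samples$cohort == "C2"],
    detp2 = detp[panel2, samples$cohort == "C2"],
    samples = samples,
    genes = genes,
    truth = truth
  )
}

build_sample_table <- function(config) {
  grp <- c(rep("ALS", config$n1_als), rep("CTL", config$n1_ctl),
           rep("ALS", config$n2_als), rep("CTL", config$n2_ctl),
           rep("MIM", config$n2_mim))
  cohort <- c(rep("C1", config$n1_als + config$n1_ctl),
              rep("C2", config$n2_als + config$n2_ctl + config$n2_mim))
  n <- length(grp)
  sample_id <- sprintf("s%04d", seq_len(n))
  p_male <- ifelse(grp == "ALS", 0.6, 0.5)
  sex <- ifelse(stats::runif(n) < p_male, "M", "F")
  age <- round(pmin(90, pmax(20, ifelse(
    grp == "ALS", stats::rnorm(n, 62, 10), stats::rnorm(n, 55, 12)))), 1)
  onset <- ifelse(grp == "ALS",
                  ifelse(stats::runif(n) < 0.7, "spinal", "bulbar"),
                  NA_character_)
  batch <- character(n)
  for (co in c("C1", "C2")) {
    idx <- which(cohort == co)
    n_b1 <- floor(config$batch_frac * length(idx))
    batch[idx] <- paste0(co, c(rep("_B1", n_b1),
                               rep("_B2", length(idx) - n_b1)))
  }
  tibble::tibble(
    sample_id = sample_id,
    cohort = cohort,
    platform = ifelse(cohort == "C1", "V3", "V4"),
    batch = batch,
    group = grp,
    sex = sex,
    age = age,
    onset_site = onset,
    surv_time = NA_real_,
    event = NA_integer_
  )
}

draw_proportions <- function(samples, config, types) {
  base <- config$base_props[types]
  props <- matrix(NA_real_, nrow = nrow(samples), ncol = length(types),
                  dimnames = list(samples$sample_id, types))
  for (i in seq_len(nrow(samples))) {
    mean_p <- base
    mult <- config$prop_multipliers[[samples$group[i]]]
    if (!is.null(mult)) {
      mean_p[names(mult)] <- mean_p[names(mult)] * mult
      mean_p <- mean_p / sum(mean_p)
    }
    if (is.infinite(config$dirichlet_conc)) {
      props[i, ] <- mean_p / sum(mean_p)
    } else {
      g <- stats::rgamma(length(types), shape = mean_p * config$dirichlet_conc)
      props[i, ] <- g / sum(g)
    }
  }
  props
}

detection_p_model <- function(expr, config) {
  # noise enters on the logit scale so the strong negative rank
  # correlation with intensity survives in the sigmoid's saturated tails
  x0 <- apply(expr, 2, stats::quantile, probs = config$detect_mid_q)
  eta <- -config$detect_slope * sweep(expr, 2, x0) +
    matrix(stats::runif(length(expr), -config$detect_noise,
                        config$detect_noise), nrow = nrow(expr))
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  dimnames(p) <- dimnames(expr)
  p
}

#' Build a synthetic gene annotation table
#'
#' Assigns each gene a chromosome, a 1-based inclusive span, a coding flag
#' and a RefSeq-style prefix (coding genes get "NM_").
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_chrom number of chromosomes.
#' @param chrom_size chromosome length in bp.
#' @param coding_frac fraction of genes flagged protein-coding.
#' @param seed integer seed.
#' @return tibble: gene_id, symbol, coding, chrom, start, end, refseq_prefix.
#' @export
build_gene_table <- function(gene_ids, n_chrom = 22, chrom_size = 5e7,
                             coding_frac = 0.9, seed = 1L) {
  set.seed(seed)
  n <- length(gene_ids)
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  len <- round(stats::runif(n, 5e3, 1e5))
  start <- round(stats::runif(n, 1, chrom_size - len))
  coding <- stats::runif(n) < coding_frac
  tibble::tibble(
    gene_id = gene_ids,
    symbol = toupper(gene_ids),
    coding = coding,
    chrom = chrom,
    start = start,
    end = start + len - 1,
    refseq_prefix = ifelse(coding, "NM_", "XR_")
  )
}

#' Fill in Weibull survival outcomes for ALS samples
#'
#' Event times follow a proportional-hazards Weibull model whose log hazard
#' is linear in age, sex, site of onset and the (per-SD standardized)
#' expression of a planted gene set. Censoring is independent uniform with
#' its upper bound calibrated so the expected censored fraction equals
#' `config$cens_frac`.
#'
#' @param samples sample tibble (needs `group`, `age`, `sex`, `onset_site`).
#' @param expr genes x samples log2 matrix covering the ALS samples.
#' @param config a [sim_config()].
#' @param surv_genes optional character vector of planted genes; default
#'   draws `config$n_surv_genes` genes from `rownames(expr)`.
#' @param seed seed; default `config$seed + 1`.
#' @return list: `samples` with `surv_time`/`event` filled for ALS rows, and
#'   `truth` tibble (gene, loghr).
#' @export
generate_survival <- function(samples, expr, config,
                              surv_genes = NULL, seed = NULL) {
  als <- samples$group == "ALS"
  if (!any(als)) stop("no ALS samples to assign survival outcomes to")
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)

  n_g <- config$n_surv_genes
  if (is.null(surv_genes)) {
    surv_genes <- if (n_g > 0) sample(rownames(expr), n_g) else character(0)
  }
  stopifnot(all(surv_genes %in% rownames(expr)))
  loghr <- rep(c(config$surv_loghr, -config$surv_loghr),
               length.out = length(surv_genes))

  ids <- samples$sample_id[als]
  stopifnot(all(ids %in% colnames(expr)))
  lp <- 0.03 * (samples$age[als] - mean(samples$age[als])) +
    0.1 * (samples$sex[als] == "M") +
    0.4 * (samples$onset_site[als] %in% "bulbar")
  if (length(surv_genes)) {
    z <- t(scale(t(expr[surv_genes, ids, drop = FALSE])))
    lp <- lp + as.vector(crossprod(z, loghr))
  }

  k <- config$weibull_shape
  lambda <- config$median_surv / log(2)^(1 / k)
  u <- stats::runif(length(lp))
  t_event <- lambda * (-log(u) * exp(-lp))^(1 / k)

  if (config$cens_frac > 0) {
    # choose the uniform censoring bound so E[fraction censored] = target
    cens_mean <- function(cmax) mean(pmin(t_event / cmax, 1))
    cmax <- stats::uniroot(function(cm) cens_mean(cm) - config$cens_frac,
                           lower = max(t_event) * 1e-3,
                           upper = max(t_event) * 1e4,
                           extendInt = "downX")$root
    c_time <- stats::runif(length(lp), 0, cmax)
  } else {
    c_time <- rep(Inf, length(lp))
  }
  event <- as.integer(t_event <= c_time)
  time <- pmin(t_event, c_time)

  samples$surv_time[als] <- time
  samples$event[als] <- event
  list(samples = samples,
       truth = tibble::tibble(gene = surv_genes, loghr = loghr))
}

#' Place GWAS loci with controlled proximity to target genes
#'
#' A `near_fraction` of loci is placed within `max_offset_bp` of a randomly
#' chosen target gene (inside the gene span when `max_offset_bp = 0`); the
#' remainder is uniform over the chromosomes present in the gene table.
#'
#' @param genes gene tibble from [build_gene_table()].
#' @param target_genes character vector of target gene ids (subset of
#'   `genes$gene_id`); required when `near_fraction > 0`.
#' @param n_loci number of loci (default 215).
#' @param near_fraction fraction of loci placed near targets.
#' @param max_offset_bp maximum distance from a target gene span.
#' @param seed integer seed.
#' @return tibble of class `gwas_loci`: chrom, position.
#' @export
generate_gwas <- function(genes, target_genes = character(0), n_loci = 215,
                          near_fraction = 0, max_offset_bp = 10000,
                          seed = 1L) {
  if (near_fraction > 0 && length(target_genes) == 0) {
    stop("near_fraction > 0 requires non-empty target_genes")
  }
  stopifnot(all(target_genes %in% genes$gene_id))
  set.seed(seed)
  n_near <- round(near_fraction * n_loci)
  loci <- tibble::tibble(chrom = character(0), position = numeric(0))
  if (n_near > 0) {
    # round-robin over shuffled targets: all targets covered whenever
    # n_near >= |target_genes|
    picked <- sample(rep_len(sample(target_genes), n_near))
    tg <- genes[match(picked, genes$gene_id), ]
    pos <- round(stats::runif(n_near, tg$start - max_offset_bp,
                              tg$end + max_offset_bp))
    loci <- tibble::tibble(chrom = tg$chrom, position = pmax(1, pos))
  }
  n_far <- n_loci - n_near
  if (n_far > 0) {
    chroms <- unique(genes$chrom)
    far_chrom <- sample(chroms, n_far, replace = TRUE)
    far_pos <- round(stats::runif(n_far, 1, max(genes$end)))
    loci <- dplyr::bind_rows(loci, tibble::tibble(chrom = far_chrom,
                                                  position = far_pos))
  }
  class(loci) <- c("gwas_loci", class(loci))
  loci
}
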