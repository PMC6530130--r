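#' Rank-based cumulative enrichment of a gene set
#'
#' Sorts genes by score (descending), tracks the cumulative fraction of the
#' gene set recovered as a function of rank fraction, and summarizes the
#' displacement from the diagonal as a signed area statistic
#' (`mean(cumulative fraction - rank fraction)`, bounded by +/-0.5). The
#' p-value is a two-sided Wilcoxon rank-sum test of set vs complement
#' scores.
#'
#' @param ranking named numeric vector of per-gene scores.
#' @param gene_set character vector, non-empty proper subset of the names.
#' @return list of class `rank_enrichment`: `area_stat`, `u_stat`, `p`,
#'   `curve` (tibble: rank_frac, cum_frac).
#' @export
rank_enrichment_curve <- function(ranking, gene_set) {
  stopifnot(!is.null(names(ranking)))
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% names(ranking))) {
    stop("gene_set must be a subset of the ranking domain")
  }
  n <- length(ranking)
  m <- length(gene_set)
  if (m == 0 || m >= n) stop("gene_set must be a non-empty proper subset")
  ord <- order(ranking, decreasing = TRUE)
  member <- names(ranking)[ord] %in% gene_set
  cum_frac <- cumsum(member) / m
  rank_frac <- seq_len(n) / n
  area <- mean(cum_frac - rank_frac)
  wt <- stats::wilcox.test(ranking[gene_set],
                           ranking[setdiff(names(ranking), gene_set)],
                           alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  structure(
    list(area_stat = area, u_stat = unname(wt$statistic), p = wt$p.value,
         curve = tibble::tibble(rank_frac = rank_frac, cum_frac = cum_frac)),
    class = "rank_enrichment"
  )
}

#' Fisher's exact test of two-set overlap
#'
#' Builds the 2x2 membership table of `set_a` x `set_b` within `universe`
#' and tests it two-sided (minimum-likelihood method, via fisher.test).
#' When a zero cell occurs, the reported odds ratio uses the Haldane
#' +0.5 correction and is flagged.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector defining the background.
#' @return tibble: a, b, c, d (counts: both, A only, B only, neither),
#'   odds_ratio, p, haldane (flag).
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  set_a <- unique(intersect(set_a, universe))
  set_b <- unique(intersect(set_b, universe))
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("both sets must be non-empty within the universe")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  cc <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  m <- matrix(c(a, cc, b, d), 2)
  ft <- stats::fisher.test(m, alternative = "two.sided")
  zero <- any(m == 0)
  or <- if (zero) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  tibble::tibble(a = a, b = b, c = cc, d = d,
                 odds_ratio = or, p = ft$p.value, haldane = zero)
}

#' Assign genes to the cell type where they are most highly expressed
#'
#' Each gene goes to the cell type with the highest mean reference
#' expression. A gene is unassigned when no cell type reaches detectable
#' expression in at least `detect_min_frac` of that type's samples;
#' detectability uses reference detection p-values < 0.05 when available,
#' otherwise an expression floor at the `floor_q` quantile of the reference.
#' Exact ties go to the first cell type in canonical order (with a warning).
#'
#' @param genes character vector of gene ids to assign.
#' @param reference a `cell_reference`; optional element `detection_p`
#'   (same shape as `profiles`) switches on detection-based calls.
#' @param detect_min_frac minimum detected fraction within a type.
#' @param floor_q quantile of all reference values used as the expression
#'   floor when no detection p-values exist.
#' @return tibble: gene, cell_type (NA = unassigned).
#' @export
assign_cell_types <- function(genes, reference, detect_min_frac = 0.10,
                              floor_q = 0.25) {
  prof <- reference$profiles
  missing <- setdiff(genes, rownames(prof))
  if (length(missing)) {
    warning(length(missing), " gene(s) absent from the reference; unassigned")
  }
  present <- intersect(genes, rownames(prof))
  types <- reference$cell_types
  as_gene_matrix <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = length(present),
                                     dimnames = list(present, types))
    x
  }
  mean_by_type <- as_gene_matrix(vapply(types, function(ct)
    rowMeans(prof[present, reference$sample_types == ct, drop = FALSE]),
    numeric(length(present))))
  detected <- if (!is.null(reference$detection_p)) {
    reference$detection_p[present, , drop = FALSE] < 0.05
  } else {
    floor_val <- stats::quantile(prof, floor_q)
    prof[present, , drop = FALSE] > floor_val
  }
  det_frac <- as_gene_matrix(vapply(types, function(ct)
    rowMeans(detected[, reference$sample_types == ct, drop = FALSE]),
    numeric(length(present))))
  any_det <- apply(det_frac >= detect_min_frac, 1, any)
  ties <- apply(mean_by_type, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) warning(sum(ties), " tie(s) broken toward canonical order")
  best <- types[apply(mean_by_type, 1, which.max)]
  best[!any_det] <- NA_character_
  out <- tibble::tibble(gene = genes,
                        cell_type = NA_character_)
  out$cell_type[match(present, out$gene)] <- best
  out
}

#' Per-cell-type Fisher enrichment of a DEG set among assigned genes
#'
#' For each cell type, tests the 2x2 of (assigned to type) x (in DEG set)
#' over the universe and applies Benjamini-Hochberg across cell types.
#'
#' @param assignment tibble from [assign_cell_types()].
#' @param deg_set character vector of DEGs (subset of `universe`).
#' @param universe background gene set.
#' @return tibble: cell_type, a, b, c, d, odds_ratio, p, fdr, sorted by p.
#' @export
assignment_enrichment <- function(assignment, deg_set, universe) {
  types <- unique(stats::na.omit(assignment$cell_type))
  rows <- purrr::map_dfr(types, function(ct) {
    genes_ct <- assignment$gene[assignment$cell_type %in% ct]
    dplyr::mutate(fisher_overlap(genes_ct, deg_set, universe),
                  cell_type = ct, .before = 1)
  })
  rows$fdr <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$p)
}

#' Screen external gene-level signatures for correspondence with a DEG pair
#'
#' For each external signature (per-gene signed log10 p, positive =
#' increased), computes the median signed log10 p within the top increased
#' and top decreased DEG sets, and a two-sided rank-sum p comparing the two
#' sets' values. Signatures covering less than half of either set are
#' skipped with a warning. Sign-consistent signatures (increased median >
#' decreased median) are ranked first, by p.
#'
#' @param signatures long tibble: signature_id, gene, signed_log10p.
#' @param inc_top,dec_top disjoint character vectors (e.g. top-100 increased
#'   / decreased DEGs).
#' @param min_coverage minimum fraction of each set a signature must cover.
#' @return tibble: signature_id, n_inc, n_dec, median_inc, median_dec, p,
#'   sign_consistent, rank.
#' @export
signature_correspondence_screen <- function(signatures, inc_top, dec_top,
                                            min_coverage = 0.5) {
  stopifnot(length(intersect(inc_top, dec_top)) == 0)
  res <- signatures |>
    dplyr::group_by(.data$signature_id) |>
    dplyr::group_map(function(df, key) {
      vi <- df$signed_log10p[df$gene %in% inc_top]
      vd <- df$signed_log10p[df$gene %in% dec_top]
      if (length(vi) < min_coverage * length(inc_top) ||
          length(vd) < min_coverage * length(dec_top)) {
        warning("signature ", key$signature_id,
                " skipped: coverage below ", min_coverage)
        return(NULL)
      }
      wt <- stats::wilcox.test(vi, vd, exact = FALSE)
      tibble::tibble(signature_id = key$signature_id,
                     n_inc = length(vi), n_dec = length(vd),
                     median_inc = stats::median(vi),
                     median_dec = stats::median(vd),
                     p = wt$p.value,
                     sign_consistent = stats::median(vi) > stats::median(vd))
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) return(res)
  res <- dplyr::arrange(res, dplyr::desc(.data$sign_consistent), .data$p)
  res$rank <- seq_len(nrow(res))
  res
}
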