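#' Nearest GWAS-locus distance per gene
#'
#' Point-to-interval distance in bp between each gene span (1-based
#' inclusive) and its nearest locus on the same chromosome: 0 when the
#' locus falls inside the span, `Inf` for genes on chromosomes without loci.
#'
#' @param genes gene tibble (gene_id, chrom, start, end).
#' @param loci loci tibble (chrom, position).
#' @return named numeric vector of distances over `genes$gene_id`.
#' @export
nearest_locus_distance <- function(genes, loci) {
  if (nrow(loci) == 0) stop("empty loci set")
  d <- rep(Inf, nrow(genes))
  for (ch in unique(genes$chrom)) {
    pos <- loci$position[loci$chrom == ch]
    if (length(pos) == 0) next
    gi <- which(genes$chrom == ch)
    s <- genes$start[gi]; e <- genes$end[gi]
    dm <- vapply(pos, function(p) pmax(0, pmax(s - p, p - e)),
                 numeric(length(gi)))
    d[gi] <- if (length(gi) == 1) min(dm) else apply(dm, 1, min)
  }
  stats::setNames(d, genes$gene_id)
}

#' Proximity of top-ranked DEGs to GWAS loci
#'
#' Compares the fraction of a top-N gene set lying within each distance
#' threshold of a locus against the remaining universe genes, with a
#' two-sided Fisher exact p per threshold.
#'
#' @param ranked_degs character vector (the top-N set).
#' @param universe background gene ids (must contain `ranked_degs`).
#' @param genes gene tibble with coordinates covering the universe.
#' @param loci loci tibble.
#' @param thresholds ascending bp grid (default c(0, 1e3, 9e3, 1e4, 5e4,
#'   1e5)).
#' @return list of class `proximity_result`: `distances` (named vector),
#'   `table` (tibble: threshold, n_deg_within, n_bg_within, frac_deg,
#'   frac_bg, odds_ratio, p).
#' @export
gwas_proximity_overlap <- function(ranked_degs, universe, genes, loci,
                                   thresholds = c(0, 1e3, 9e3, 1e4, 5e4, 1e5)) {
  stopifnot(all(ranked_degs %in% universe),
            !is.unsorted(thresholds))
  genes <- genes[genes$gene_id %in% universe, ]
  d <- nearest_locus_distance(genes, loci)
  is_deg <- names(d) %in% ranked_degs
  rows <- purrr::map_dfr(thresholds, function(th) {
    within <- d <= th
    m <- matrix(c(sum(within & is_deg), sum(!within & is_deg),
                  sum(within & !is_deg), sum(!within & !is_deg)), 2)
    ft <- stats::fisher.test(m)
    tibble::tibble(threshold = th,
                   n_deg_within = m[1, 1], n_bg_within = m[1, 2],
                   frac_deg = m[1, 1] / sum(is_deg),
                   frac_bg = m[1, 2] / sum(!is_deg),
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  structure(list(distances = d, table = rows), class = "proximity_result")
}

#' Resampling null for the mean nearest-locus distance of a gene set
#'
#' Compares the observed mean nearest-locus distance of `top_set` against a
#' null built by drawing `n_trials` same-size gene sets uniformly without
#' replacement from the universe. The empirical p-value uses the add-one
#' rule `(1 + #{null <= observed}) / (n_trials + 1)` and is therefore never
#' zero.
#'
#' @param top_set character vector of genes (e.g. top-500 DEGs).
#' @param universe background gene ids.
#' @param genes,loci coordinate inputs as in [gwas_proximity_overlap()].
#' @param n_trials number of resampling trials (default 10000).
#' @param seed integer seed.
#' @return list of class `proximity_null`: `observed`, `null` (vector of
#'   null means), `p`, `n_trials`.
#' @export
gwas_distance_null <- function(top_set, universe, genes, loci,
                               n_trials = 10000, seed = 1L) {
  if (length(top_set) > length(universe)) {
    stop("top_set larger than universe")
  }
  if (n_trials < 100) warning("n_trials < 100: empirical p will be coarse")
  genes <- genes[genes$gene_id %in% universe, ]
  d <- nearest_locus_distance(genes, loci)
  d <- d[is.finite(d)]
  d <- d[order(names(d))]   # invariant to input gene order
  obs <- mean(d[names(d) %in% top_set])
  set.seed(seed)
  m <- sum(names(d) %in% top_set)
  null <- vapply(seq_len(n_trials), function(i) mean(sample(d, m)),
                 numeric(1))
  p <- (1 + sum(null <= obs)) / (n_trials + 1)
  structure(list(observed = obs, null = null, p = p, n_trials = n_trials),
            class = "proximity_null")
}
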