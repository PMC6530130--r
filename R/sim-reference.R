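#' Default whole-blood cell types
#'
#' Canonical ordering of the twelve immune/erythroid cell types used
#' throughout the package: neutrophils (NP), monocytes (MC), dendritic cells
#' (DC), macrophages (MP), platelets (PL), erythroid lineage cells (RBC),
#' eosinophils (ES), CD4 and CD8 T cells, gamma-delta T cells (GDT), B cells
#' and NK cells.
#'
#' @export
blood_cell_types <- function() {
  c("NP", "MC", "DC", "MP", "PL", "RBC", "ES",
    "CD4", "CD8", "GDT", "B", "NK")
}

#' Generate a purified cell-type reference compendium
#'
#' Simulates log2 expression profiles for purified samples of each cell type,
#' planting `markers_per_type` marker genes per type whose mean expression in
#' the owning type exceeds the pooled mean of all other types by at least
#' `log2(marker_fc)`. The elevation contract is enforced deterministically:
#' if sampling noise erodes a planted contrast below the nominal fold change,
#' the owning type's samples are shifted up to restore it.
#'
#' @param n_genes total number of genes on the reference panel.
#' @param cell_types character vector of cell-type labels (canonical order).
#' @param markers_per_type number of marker genes planted per cell type.
#' @param marker_fc linear fold elevation of a marker in its own type
#'   relative to the pooled other types. `marker_fc = 1` plants no signal.
#' @param samples_per_type purified samples simulated per cell type (>= 2).
#' @param noise_sd per-sample log2 Gaussian noise.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return A list of class `cell_reference` with elements `profiles`
#'   (genes x reference-samples log2 matrix), `sample_types` (cell type of
#'   each reference column), `cell_types`, and `truth`, a tibble with one row
#'   per planted marker (`gene`, `cell_type`).
#' @export
generate_reference <- function(n_genes = 2000,
                               cell_types = blood_cell_types(),
                               markers_per_type = 100,
                               marker_fc = 4,
                               samples_per_type = 5,
                               noise_sd = 0.3,
                               seed = 1L) {
  stopifnot(samples_per_type >= 2, marker_fc >= 1, noise_sd >= 0)
  n_types <- length(cell_types)
  if (n_genes < n_types * markers_per_type) {
    stop("n_genes (", n_genes, ") is smaller than cell_types x markers_per_type (",
         n_types * markers_per_type, ")")
  }
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))

  # disjoint marker blocks; overlap impossible by construction, but the
  # contract is still asserted for safety
  marker_idx <- matrix(seq_len(n_types * markers_per_type),
                       nrow = markers_per_type)
  if (anyDuplicated(as.vector(marker_idx)) > 0) {
    stop("overlapping marker assignments")
  }

  base <- stats::runif(n_genes, min = 5, max = 10)
  delta <- log2(marker_fc)
  n_samples <- n_types * samples_per_type
  sample_types <- rep(cell_types, each = samples_per_type)

  mu <- matrix(base, nrow = n_genes, ncol = n_types)
  for (k in seq_len(n_types)) {
    mu[marker_idx[, k], k] <- mu[marker_idx[, k], k] + delta
  }

  profiles <- mu[, rep(seq_len(n_types), each = samples_per_type)] +
    matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
           nrow = n_genes)
  dimnames(profiles) <- list(
    gene_ids,
    paste0(rep(cell_types, each = samples_per_type), "_",
           rep(seq_len(samples_per_type), times = n_types))
  )

  if (marker_fc > 1) {
    for (k in seq_len(n_types)) {
      own <- sample_types == cell_types[k]
      idx <- marker_idx[, k]
      gap <- rowMeans(profiles[idx, own, drop = FALSE]) -
        rowMeans(profiles[idx, !own, drop = FALSE])
      short <- pmax(0, delta - gap)
      if (any(short > 0)) {
        profiles[idx, own] <- profiles[idx, own] + short
      }
    }
  }

  truth <- tibble::tibble(
    gene = gene_ids[as.vector(marker_idx)],
    cell_type = rep(cell_types, each = markers_per_type)
  )
  if (marker_fc <= 1) truth <- truth[0, ]

  structure(
    list(profiles = profiles,
         sample_types = sample_types,
         cell_types = cell_types,
         samples_per_type = rep(samples_per_type, n_types),
         truth = truth,
         seed = seed),
    class = "cell_reference"
  )
}

#' @export
print.cell_reference <- function(x, ...) {
  cat("<cell_reference> ", nrow(x$profiles), " genes, ",
      ncol(x$profiles), " purified samples across ",
      length(x$cell_types), " cell types\n", sep = "")
  invisible(x)
}

#' Mean linear-scale profile per cell type
#'
#' @param reference a `cell_reference`.
#' @return genes x cell-types matrix of mean linear-scale (2^log2) expression.
#' @keywords internal
reference_linear_means <- function(reference) {
  vapply(reference$cell_types, function(ct) {
    rowMeans(2^reference$profiles[, reference$sample_types == ct, drop = FALSE])
  }, numeric(nrow(reference$profiles)))
}
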