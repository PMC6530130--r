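#' Read and write the package's plain-text interchange formats
#'
#' Expression and detection-p matrices travel as TSV with a `gene_id`
#' column and one column per sample; sample and gene tables as plain TSV;
#' loci as BED (0-based half-open, converted to/from the package's 1-based
#' representation); signatures as long TSV (label, rank, gene, weight);
#' truth records as JSON.
#'
#' @param expr genes x samples matrix.
#' @param path file path.
#' @name bloodtx_io
NULL

#' @rdname bloodtx_io
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(expr)),
                     tibble::as_tibble(expr)),
    path)
  invisible(path)
}

#' @rdname bloodtx_io
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  m
}

#' @rdname bloodtx_io
#' @param samples sample tibble.
#' @export
write_samples_tsv <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname bloodtx_io
#' @export
read_samples_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname bloodtx_io
#' @param genes gene tibble (1-based inclusive coordinates).
#' @export
write_genes_tsv <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

#' @rdname bloodtx_io
#' @export
read_genes_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname bloodtx_io
#' @export
write_genes_bed <- function(genes, path) {
  readr::write_tsv(
    tibble::tibble(chrom = genes$chrom,
                   start = genes$start - 1,   # 0-based half-open
                   end = genes$end,
                   name = genes$gene_id),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname bloodtx_io
#' @param loci loci tibble (chrom, position; 1-based).
#' @export
write_loci_bed <- function(loci, path) {
  readr::write_tsv(
    tibble::tibble(chrom = loci$chrom,
                   start = loci$position - 1,
                   end = loci$position),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname bloodtx_io
#' @export
read_loci_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                        show_col_types = FALSE)
  out <- tibble::tibble(chrom = df$chrom, position = df$end)
  class(out) <- c("gwas_loci", class(out))
  out
}

#' @rdname bloodtx_io
#' @param signatures list of `signature_def` objects.
#' @export
write_signatures_tsv <- function(signatures, path) {
  if (inherits(signatures, "signature_def")) signatures <- list(signatures)
  long <- purrr::map_dfr(signatures, function(s)
    dplyr::mutate(s$table[c("rank", "gene", "weight")], label = s$label,
                  .before = 1))
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname bloodtx_io
#' @export
read_signatures_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  lapply(split(long, long$label), function(df) {
    df <- df[order(df$rank), ]
    structure(list(label = df$label[1], genes = df$gene,
                   weights = df$weight,
                   table = tibble::tibble(gene = df$gene, rank = df$rank,
                                          log2fc = NA_real_, p = NA_real_,
                                          weight = df$weight)),
              class = "signature_def")
  })
}

#' @rdname bloodtx_io
#' @param truth truth-record list from the generators.
#' @export
write_truth_json <- function(truth, path) {
  truth$props <- if (!is.null(truth$props)) {
    cbind(sample_id = rownames(truth$props), as.data.frame(truth$props))
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
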