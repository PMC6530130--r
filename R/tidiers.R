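#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-gene table of a differential-expression fit
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return the per-gene tibble.
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$table),
                 d0 = x$fit_info$d0, s0_sq = x$fit_info$s0_sq,
                 d_resid = x$fit_info$d_resid)
}

#' Tidy a meta-analysis result
#'
#' @param x a `meta_de_result`.
#' @param ... unused.
#' @export
tidy.meta_de_result <- function(x, ...) x$table

#' @rdname tidy.meta_de_result
#' @export
glance.meta_de_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$table),
                 n_increased = length(x$increased),
                 n_decreased = length(x$decreased))
}

#' Tidy a stepwise Cox selection
#'
#' @param x a `stepwise_cox`.
#' @param ... unused.
#' @return drop-one LRT table of the final model.
#' @export
tidy.stepwise_cox <- function(x, ...) x$table

#' @rdname tidy.stepwise_cox
#' @export
glance.stepwise_cox <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 loglik = x$loglik, n_steps = x$n_steps)
}

#' Tidy a cross-validated diagnostic outcome
#'
#' @param x a `cv_outcome`.
#' @param ... unused.
#' @return per-trial metric tibble.
#' @export
tidy.cv_outcome <- function(x, ...) x$trials

#' @rdname tidy.cv_outcome
#' @export
glance.cv_outcome <- function(x, ...) x$summary

#' Tidy a cross-validated survival outcome
#'
#' @param x a `cv_survival`.
#' @param ... unused.
#' @export
tidy.cv_survival <- function(x, ...) x$trials

#' @rdname tidy.cv_survival
#' @export
glance.cv_survival <- function(x, ...) x$summary
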