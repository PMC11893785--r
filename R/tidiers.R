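#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Fisher exact test result
#'
#' @param x A `fisher_exact` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (odds ratio), `p.value`,
#'   `method`.
#' @export
tidy.fisher_exact <- function(x, ...) {
  tibble::tibble(
    estimate = x$odds_ratio, p.value = x$p_two_sided, method = x$method
  )
}

#' @rdname tidy.fisher_exact
#' @export
glance.fisher_exact <- function(x, ...) tidy.fisher_exact(x)

#' Tidy a Spearman correlation result
#'
#' @param x A `spearman_exact` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (rho), `p.value`, `n`, `method`.
#' @export
tidy.spearman_exact <- function(x, ...) {
  tibble::tibble(
    estimate = x$rho, p.value = x$p, n = x$n, method = x$method
  )
}

#' @rdname tidy.spearman_exact
#' @export
glance.spearman_exact <- function(x, ...) tidy.spearman_exact(x)
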