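#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an extremal report
#'
#' @param x An `extremal_report`.
#' @param ... Unused.
#' @return A tibble with one row per extremal shape (columns `kind`, `f`,
#'   `n`, `domain`, `method`, `which` (`"min"`/`"max"`), `value`, `tree`).
#' @method tidy extremal_report
#' @export
tidy.extremal_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(which = "min", value = x$min_value, tree = x$min_keys),
    tibble(which = "max", value = x$max_value, tree = x$max_keys)
  ) |>
    dplyr::mutate(kind = x$kind, f = x$f, n = x$n, domain = x$domain,
                  method = x$method, .before = 1)
}

#' @rdname tidy.extremal_report
#' @return For `glance()`: a one-row tibble summarising the report.
#' @method glance extremal_report
#' @export
glance.extremal_report <- function(x, ...) {
  tibble(
    kind = x$kind, f = x$f, n = x$n, domain = x$domain, method = x$method,
    min_value = x$min_value, max_value = x$max_value,
    n_minimizers = length(x$min_keys), n_maximizers = length(x$max_keys)
  )
}

#' Tidy a function certificate
#'
#' @param x A `fun_certificate` from [classify_function()].
#' @param ... Unused.
#' @return A one-row tibble of the certified flags.
#' @method tidy fun_certificate
#' @export
tidy.fun_certificate <- function(x, ...) {
  tibble(
    label = x$label,
    increasing = x$increasing, strictly_increasing = x$strictly_increasing,
    convex = x$convex, strictly_convex = x$strictly_convex,
    concave = x$concave, strictly_concave = x$strictly_concave,
    affine = x$affine, slope = x$slope, intercept = x$intercept,
    two_positive = x$two_positive, non_negative = x$non_negative,
    domain_min = x$domain_min, domain_bound = x$domain_bound,
    method = x$method
  )
}
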