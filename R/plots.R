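#' Plot the distribution of a functional over all shapes
#'
#' Evaluates the functional on every enumerated shape with `n` leaves and
#' plots the sorted values, highlighting the minimizing and maximizing
#' shapes. Useful for seeing how sharply a shape function separates
#' balanced from imbalanced shapes.
#'
#' @inheritParams enumerate_extremes
#' @return A ggplot object.
#' @export
plot_phi_distribution <- function(kind, f, n, domain = c("binary", "arbitrary")) {
  kind <- norm_kind(kind)
  domain <- match.arg(domain)
  f <- as_shape_fun(f)
  df <- phi_table(enumerate_shapes(n, domain), kind, f) |>
    dplyr::arrange(.data$value) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      extreme = dplyr::case_when(
        .data$value <= min(.data$value) + 1e-9 ~ "minimum",
        .data$value >= max(.data$value) - 1e-9 ~ "maximum",
        TRUE ~ "interior"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                   colour = .data$extreme)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(minimum = "#2166ac",
                                            maximum = "#b2182b",
                                            interior = "grey50")) +
    ggplot2::labs(
      x = sprintf("shape rank (of %d)", nrow(df)),
      y = sprintf("functional value (f = %s)", f$label),
      colour = NULL,
      title = sprintf("%s-sequence functional over all %s shapes with n = %d",
                      kind, domain, n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a shape function and its increments
#'
#' Shows `f` on the integer grid together with its first differences, which
#' is how the certificate decides monotonicity and convexity (decreasing
#' increments mean concave, increasing mean convex).
#'
#' @param object A `shape_fun`.
#' @param upto Largest integer argument plotted.
#' @param ... Unused.
#' @return A ggplot object; the subtitle states the certified properties.
#' @method autoplot shape_fun
#' @export
autoplot.shape_fun <- function(object, upto = 16, ...) {
  cert <- classify_function(object, domain_bound = max(upto, 8))
  f_desc <- paste(c(
    if (cert$strictly_increasing) "strictly increasing"
    else if (cert$increasing) "increasing" else "not increasing",
    if (cert$strictly_convex) "strictly convex"
    else if (cert$strictly_concave) "strictly concave"
    else if (cert$affine) sprintf("affine (m = %g, a = %g)", cert$slope,
                                  cert$intercept),
    if (cert$two_positive) "2-positive"
  ), collapse = ", ")
  xs <- seq(object$domain_min, upto)
  ys <- object$fn(xs)
  df <- dplyr::bind_rows(
    tibble(x = xs, value = ys, panel = "f(x)"),
    tibble(x = xs[-1], value = diff(ys), panel = "increment f(x) - f(x-1)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(title = sprintf("shape function %s", object$label),
                  subtitle = f_desc, x = "x", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
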