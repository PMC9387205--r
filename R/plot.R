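# ggplot2 views of fits and color tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the 2D projections of an encoded color table
#'
#' Shows the colored cloud projected onto the a*b*, a*L*, and b*L* planes,
#' each point drawn in its assigned color -- the standard way to inspect how
#' the cloud sits inside the color space.
#'
#' @param object A color table from [encode_colors()] (needs the Lab
#'   columns, i.e. format `"both"` or `"lab"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot colorcloud_table
#' @export
autoplot.colorcloud_table <- function(object, ...) {
  need <- c("L", "a", "b")
  if (!all(need %in% names(object))) {
    stop("autoplot needs the Lab columns; encode with format = \"both\" or \"lab\"",
         call. = FALSE)
  }
  col <- if ("hex" %in% names(object)) object$hex else lab_to_hex(
    as.matrix(object[, need]), clamp = TRUE)
  long <- dplyr::bind_rows(
    tibble::tibble(projection = "a* / b*", u = object$a, v = object$b, color = col),
    tibble::tibble(projection = "a* / L*", u = object$a, v = object$L, color = col),
    tibble::tibble(projection = "b* / L*", u = object$b, v = object$L, color = col)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$u, .data$v, color = .data$color)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_color_identity() +
    ggplot2::facet_wrap(~projection, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Point cloud embedded in CIELAB") +
    ggplot2::theme_minimal()
}

#' Plot multi-start objectives of a color fit
#'
#' One point per optimizer start, ranked by objective; diagnoses whether the
#' multi-start found one dominant solution or several competitive ones.
#'
#' @param object A `colorcloud_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot colorcloud_fit
#' @export
autoplot.colorcloud_fit <- function(object, ...) {
  alt <- dplyr::mutate(object$alternatives, rank = dplyr::row_number())
  ggplot2::ggplot(alt, ggplot2::aes(.data$rank, .data$objective)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$objective, linetype = "dashed") +
    ggplot2::labs(x = "start (ranked)", y = "objective",
                  title = "Multi-start fit objectives") +
    ggplot2::theme_minimal()
}
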