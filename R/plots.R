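# ggplot2 visualisation of tracks and calls. The layout mirrors the browser
# views a manual screen inspects: per-base signal over the repeat unit with
# the annotated elements underneath.

#' @keywords internal
annotation_layer <- function(annotation, ymin, ymax) {
  f <- annotation[annotation$kind %in% c("gene", "promoter"), ]
  list(
    ggplot2::geom_rect(
      data = tibble::tibble(start = f$start, end = f$end, kind = f$kind),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = ymin, ymax = ymax, fill = .data$kind),
      inherit.aes = FALSE, alpha = 0.5
    ),
    ggplot2::geom_text(
      data = tibble::tibble(x = (f$start + f$end) / 2, name = f$name),
      ggplot2::aes(x = .data$x, y = (ymin + ymax) / 2, label = .data$name),
      inherit.aes = FALSE, size = 2.5, angle = 0, vjust = 0.5
    ),
    ggplot2::scale_fill_manual(values = c(gene = "grey70", promoter = "goldenrod"),
                               name = NULL)
  )
}

#' Plot a coverage track
#'
#' @param object A `coverage_track`.
#' @param annotation Optional `histone_annotation` drawn under the signal.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_track
#' @export
autoplot.coverage_track <- function(object, annotation = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.8) +
    ggplot2::labs(x = "position in repeat unit (bp)", y = "coverage (1 bp bins)") +
    ggplot2::theme_minimal()
  if (!is.null(annotation)) {
    ymax <- max(object$count)
    p <- p + annotation_layer(annotation, -0.08 * ymax, -0.02 * ymax)
  }
  p
}

#' Plot a log2 ratio track
#'
#' @param object A `ratio_track`.
#' @param annotation Optional `histone_annotation` drawn under the signal.
#' @param peaks Optional peak tibble; called intervals are shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ratio_track
#' @export
autoplot.ratio_track <- function(object, annotation = NULL, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$log2_ratio)) +
    ggplot2::geom_line(colour = "maroon", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position in repeat unit (bp)",
                  y = "log2(ChIP / input)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = tibble::tibble(start = peaks$start,
                            end = pmin(peaks$end, attr(object, "unit_length"))),
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "maroon", alpha = 0.15
    )
  }
  if (!is.null(annotation)) {
    rng <- range(object$log2_ratio)
    p <- p + annotation_layer(annotation,
                              rng[1L] - 0.12 * diff(rng),
                              rng[1L] - 0.04 * diff(rng))
  }
  p
}

#' Plot a candidate call: ratio track, peaks, and element annotation
#'
#' @param object A `candidate_call` (with its `ratio` track retained).
#' @param annotation A `histone_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot candidate_call
#' @export
autoplot.candidate_call <- function(object, annotation = histone_annotation(), ...) {
  if (is.null(object$ratio)) {
    abort("this call carries no ratio track to plot (combined or deserialized call)")
  }
  autoplot.ratio_track(object$ratio, annotation = annotation,
                       peaks = object$emergent_peaks) +
    ggplot2::ggtitle(sprintf("%s%s", toupper(object$label),
                             if (length(object$flags)) {
                               paste0(" [", paste(object$flags, collapse = ","), "]")
                             } else ""))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
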