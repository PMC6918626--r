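#' Tidy a decomposition into one row per transcript path
#'
#' @param x An `sf_decomposition`.
#' @param ... Unused.
#' @return A tibble with `path_id`, `n_vertices`, `vertices` (comma-joined
#'   chain) and `abundance`.
#' @method tidy sf_decomposition
#' @export
tidy.sf_decomposition <- function(x, ...) {
  tibble(
    path_id = x$paths$path_id,
    n_vertices = map_int(x$paths$vertices, length),
    vertices = map_chr(x$paths$vertices, paste, collapse = ","),
    abundance = x$paths$abundance
  )
}

#' One-row summary of a decomposition
#'
#' @param x An `sf_decomposition`.
#' @param ... Unused.
#' @method glance sf_decomposition
#' @export
glance.sf_decomposition <- function(x, ...) {
  tibble(
    n_paths = nrow(x$paths),
    l1_deviation = x$l1_deviation,
    n_phasing_paths = nrow(x$phasing),
    phasing_covered = nrow(x$phasing) == 0L || !anyNA(x$phasing$path_id)
  )
}

#' Tidy an evaluation into one row per prediction
#'
#' @param x An `sf_eval`.
#' @param ... Unused.
#' @method tidy sf_eval
#' @export
tidy.sf_eval <- function(x, ...) {
  x$pred_matches
}

#' One-row summary of an evaluation
#'
#' @param x An `sf_eval`.
#' @param ... Unused.
#' @method glance sf_eval
#' @export
glance.sf_eval <- function(x, ...) {
  tibble(
    n_reference_known = x$n_reference_known,
    n_predicted = x$n_predicted,
    n_correct = x$n_correct,
    sensitivity = x$sensitivity,
    precision = x$precision,
    pr_auc = x$pr_auc,
    potential_novel = x$potential_novel,
    n_nic = x$n_nic,
    n_nnc = x$n_nnc
  )
}

#' Plot the precision-recall curve of an evaluation
#'
#' @param object An `sf_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sf_eval
#' @export
autoplot.sf_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve,
                  ggplot2::aes(x = .data$sensitivity, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Sensitivity (recall)", y = "Precision",
      title = sprintf("PR curve over coverage thresholds (AUC = %.3f)",
                      object$pr_auc)
    ) +
    ggplot2::theme_minimal()
}

#' Sketch a splice graph
#'
#' Partial exons as weighted boxes on the genome axis, junction edges as
#' arcs, adjacency edges as flat connectors.
#'
#' @param object A `splice_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot splice_graph
#' @export
autoplot.splice_graph <- function(object, ...) {
  v <- object$vertices
  e <- filter(object$edges, .data$kind %in% c("junction", "adjacency"))
  e <- mutate(e,
              x = (v$start[.data$from] + v$end[.data$from]) / 2,
              xend = (v$start[.data$to] + v$end[.data$to]) / 2,
              y = ifelse(.data$kind == "junction", 1.25, 1.0),
              yend = ifelse(.data$kind == "junction", 1.25, 1.0))
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = v,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0.9,
                   ymax = 1.1, fill = .data$weight)
    ) +
    ggplot2::geom_curve(
      data = filter(e, .data$kind == "junction"),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 1.1, yend = 1.1,
                   linewidth = .data$weight),
      curvature = -0.3
    ) +
    ggplot2::geom_segment(
      data = filter(e, .data$kind == "adjacency"),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 1.0, yend = 1.0,
                   linewidth = .data$weight)
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::labs(
      x = sprintf("%s (%s)", object$chrom, object$strand), y = NULL,
      fill = "coverage", linewidth = "reads",
      title = "Splice graph: partial exons and junctions"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
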