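#' Plot an edit table as a taxon-by-position status map
#'
#' @param object an `edit_table`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot edit_table
#' @export
autoplot.edit_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      status = factor(.data$status,
                                      levels = edit_status_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$taxon,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_point(data = dplyr::filter(df, .data$excluded),
                        shape = 4, size = 1.5, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      EDITED_C = "#d95f02", UNEDITED_C = "#7570b3", GENOMIC_T = "#1b9e77",
      OTHER = "grey60", MISSING = "grey90"), drop = FALSE) +
    ggplot2::labs(x = "alignment position", y = NULL, fill = "status",
                  title = paste("Edited sites:", attr(object, "gene"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-taxon edited-site vs third-position change rates
#'
#' @param object a `rate_summary`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot rate_summary
#' @export
autoplot.rate_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$third_rate, y = .data$es_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$fisher_p < 0.05),
                        na.rm = TRUE) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#d95f02",
                                           `FALSE` = "grey30"),
                                na.value = "grey80") +
    ggplot2::labs(x = "C-to-T rate, 3rd codon positions",
                  y = "C-to-T rate, edited sites",
                  color = "Fisher p < 0.05") +
    ggplot2::theme_minimal()
}

#' Plot a contrast set with its regression through the origin
#'
#' @param object a `contrast_set` with x and y contrasts.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot contrast_set
#' @export
autoplot.contrast_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  stopifnot(all(c("delta_x", "delta_y") %in% names(df)))
  slope <- if (nrow(df) >= 3 && sum(df$delta_x^2) > 0)
    regression_through_origin(df)$slope else NA_real_
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_x,
                                        y = .data$delta_y)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey80") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "contrast in x", y = "contrast in y",
                  subtitle = paste0("standardization: ",
                                    attr(object, "standardization"))) +
    ggplot2::theme_minimal()
  if (!is.na(slope))
    p <- p + ggplot2::geom_abline(slope = slope, intercept = 0,
                                  color = "#d95f02")
  p
}

#' Plot a dated tree's node ages against path lengths
#'
#' @param object a `dated_tree`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot dated_tree
#' @export
autoplot.dated_tree <- function(object, ...) {
  tree <- object$tree
  depth <- ape::node.depth.edgelength(tree)
  df <- tibble::tibble(node = names(object$ages),
                       age = unname(object$ages),
                       depth = depth,
                       is_tip = names(object$ages) %in% tree$tip.label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$age,
                                   shape = .data$is_tip)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "root-to-node path length (substitutions/site)",
                  y = "smoothed age (Ma)", shape = "tip") +
    ggplot2::theme_minimal()
}

#' @method tidy edit_history
#' @export
tidy.edit_history <- function(x, ...) tibble::as_tibble(x$events)

#' @method glance edit_history
#' @export
glance.edit_history <- function(x, ...) {
  tibble::tibble(n_characters = ncol(x$matrix),
                 length = sum(x$recon$lengths),
                 gains = sum(x$branch_events$gains),
                 losses = sum(x$branch_events$losses),
                 mode = x$mode)
}

#' @method tidy fitch_recon
#' @export
tidy.fitch_recon <- function(x, ...) {
  tibble::tibble(character = seq_along(x$lengths), length = x$lengths)
}
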