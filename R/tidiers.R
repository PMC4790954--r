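#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy qtl_scan
#' @export
tidy.qtl_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) %in% c("group", "cM", "marker", "bp",
                                               "lod", "a", "d")])
}

#' @method glance qtl_scan
#' @export
glance.qtl_scan <- function(x, ...) {
  i <- which.max(x$lod)
  tibble::tibble(trait = attr(x, "trait") %||% NA_character_,
                 model = attr(x, "model"), n = attr(x, "n"),
                 n_positions = nrow(x), max_lod = x$lod[i],
                 peak_group = x$group[i], peak_cM = x$cM[i])
}

#' @method tidy joint_scan
#' @export
tidy.joint_scan <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance joint_scan
#' @export
glance.joint_scan <- function(x, ...) {
  ok <- which(!is.na(x$neglog10p))
  i <- ok[which.max(x$neglog10p[ok])]
  tibble::tibble(traits = paste(attr(x, "traits"), collapse = "+"),
                 n = attr(x, "n"), n_positions = nrow(x),
                 max_neglog10p = x$neglog10p[i],
                 peak_group = x$group[i], peak_cM = x$cM[i])
}

#' @method tidy cmst_result
#' @export
tidy.cmst_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance cmst_result
#' @export
glance.cmst_result <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), best_aic = attr(x, "best_aic"),
                 best_bic = attr(x, "best_bic"))
}

#' @method tidy genetic_map
#' @export
tidy.genetic_map <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance map_stats
#' @export
glance.map_stats <- function(x, ...) {
  tibble::tibble(n_markers = x$n_markers, n_groups = x$n_groups,
                 total_cM = x$total_cM,
                 density_cM_per_marker = x$density_cM_per_marker,
                 mb_per_cM = x$mb_per_cM, max_gap_cM = x$max_gap_cM,
                 coverage_fraction = x$coverage_fraction,
                 mean_collinearity_rho = mean(x$collinearity_rho, na.rm = TRUE))
}

#' LOD profile plot
#'
#' @param object A `qtl_scan`.
#' @param threshold Optional genome-wide LOD threshold to draw.
#' @param ... Unused.
#' @return A ggplot object: LOD against map position, faceted by linkage
#'   group.
#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cM, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Map position (cM)", y = "LOD",
                  title = attr(object, "trait")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Joint-scan profile plot
#'
#' @param object A `joint_scan`.
#' @param threshold Optional profile threshold to draw.
#' @param ... Unused.
#' @return A ggplot object of `-log10 p` against position per group.
#' @method autoplot joint_scan
#' @export
autoplot.joint_scan <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cM, y = .data$neglog10p)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Map position (cM)", y = expression(-log[10] ~ p),
                  title = paste(attr(object, "traits"), collapse = " + ")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Linkage-map chart
#'
#' @param object A `genetic_map`.
#' @param ... Unused.
#' @return A ggplot object: marker positions as rungs on one bar per
#'   linkage group.
#' @method autoplot genetic_map
#' @export
autoplot.genetic_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$group), y = .data$cM)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$group), linewidth = 2,
                       colour = "grey80") +
    ggplot2::geom_point(shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Linkage group", y = "Position (cM)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
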