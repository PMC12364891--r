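#' Plot an axial slice with optional mask overlays
#'
#' Greyscale raster of one z-slice of a volume with vessel masks overlaid
#' in color — the standard QC view for checking segmentation against the
#' underlying T1w contrast.
#'
#' @param volume an [hv_volume].
#' @param z slice index (default: middle slice).
#' @param left,right optional [hv_mask] overlays.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, z = NULL, left = NULL, right = NULL) {
  stopifnot(inherits(volume, "hv_volume"))
  d <- dim(volume$data)
  if (is.null(z)) z <- d[3] %/% 2L
  sl <- volume$data[, , z]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z), fill = "SI") +
    ggplot2::theme_minimal()
  add_mask <- function(p, mask, colour) {
    if (is.null(mask)) return(p)
    m <- mask$mask[, , z]
    if (!any(m)) return(p)
    md <- df[as.vector(m), c("x", "y")]
    p + ggplot2::geom_tile(data = md, fill = colour, alpha = 0.6)
  }
  p <- add_mask(p, left, "cyan")
  add_mask(p, right, "magenta")
}

#' Forest plot of mediation-grid indirect effects
#'
#' One row per model, point estimate with the percentile-bootstrap CI;
#' significant models (CI excluding 0) highlighted.
#'
#' @param object an `hv_grid_result` from [run_grid()].
#' @param effect which effect to display.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.hv_grid_result <- function(object, effect = c("indirect", "direct", "total"),
                                    ...) {
  effect <- match.arg(effect)
  est_col <- c(indirect = "indirect", direct = "c_prime", total = "total")[effect]
  df <- dplyr::filter(object, !.data$failed)
  df$model <- paste(df$x, df$m, df$y, sep = " → ")
  df$estimate <- df[[est_col]]
  df$lo <- df[[paste0("ci_", effect, "_low")]]
  df$hi <- df[[paste0("ci_", effect, "_high")]]
  df$sig <- df[[paste0("significant_", effect)]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$model, .data$estimate),
                                   colour = .data$sig)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "CI excl. 0") +
    ggplot2::labs(x = paste(effect, "effect"), y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
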