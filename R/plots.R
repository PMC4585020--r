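#' Fragment-map plot of an assay design
#'
#' One horizontal segment per cleavage fragment along the amplicon, with
#' CpG-unit fragments coloured by measurability and CpG sites marked —
#' the quick visual check that every CpG of interest falls in its own
#' measurable fragment.
#'
#' @param object An `assay_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assay_report <- function(object, ...) {
  fr <- object$fragments
  u <- object$units
  fr$kind <- ifelse(fr$n_cpg > 0, "CpG unit", "silent")
  fr$measurable <- FALSE
  fr$measurable[match(u$fragment, fr$fragment)] <- u$measurable
  fr$status <- dplyr::case_when(
    fr$kind == "silent" ~ "silent",
    fr$measurable ~ "measurable unit",
    TRUE ~ "unmeasurable unit")
  sites <- tibble(position = object$amplicon$cpg_sites,
                  site = seq_along(object$amplicon$cpg_sites))
  ggplot2::ggplot(fr) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$fwd_start, xend = .data$fwd_end,
                   y = 1, yend = 1, colour = .data$status),
      linewidth = 4, lineend = "butt") +
    ggplot2::geom_point(data = sites,
                        ggplot2::aes(x = .data$position, y = 1.15),
                        shape = 25, fill = "red", size = 2) +
    ggplot2::geom_text(data = sites,
                       ggplot2::aes(x = .data$position, y = 1.3,
                                    label = .data$site), size = 3) +
    ggplot2::scale_colour_manual(values = c(
      "measurable unit" = "#2166AC", "unmeasurable unit" = "#B2182B",
      "silent" = "grey70")) +
    ggplot2::scale_y_continuous(limits = c(0.7, 1.5), breaks = NULL) +
    ggplot2::labs(x = "position on amplicon (bp)", y = NULL,
                  colour = NULL,
                  title = sprintf("Fragment map: %s", object$amplicon$name),
                  subtitle = object$verdict) +
    ggplot2::theme_minimal()
}

#' Plot a toy spectrum
#' @param object A `toy_spectrum`.
#' @param ... Unused.
#' @return A ggplot of intensity over mass, peak centres marked.
#' @export
autoplot.toy_spectrum <- function(object, ...) {
  df <- tibble(mass = object$mass, intensity = object$intensity)
  ggplot2::ggplot(df, ggplot2::aes(.data$mass, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$peaks$center,
                        linetype = "dotted", colour = "grey60") +
    ggplot2::labs(x = "mass (Da)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Success-rate bar plot of a QC run
#' @param object A `qc_result`.
#' @param ... Unused.
#' @return A ggplot; the dashed line marks the success cut-off.
#' @export
autoplot.qc_result <- function(object, ...) {
  r <- object$success_rates
  r$retained <- r$unit %in% unique(object$matrix$unit)
  ggplot2::ggplot(r, ggplot2::aes(.data$unit, .data$success_rate,
                                  fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$params$success_cutoff,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166AC",
                                          `FALSE` = "#B2182B")) +
    ggplot2::labs(x = NULL, y = "success rate", fill = "retained") +
    ggplot2::theme_minimal()
}
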