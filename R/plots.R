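#' @exportS3Method generics::tidy
tidy.motif_profile <- function(x, ...) {
  out <- x
  attributes(out)[c("motif", "flank", "n_occurrences", "site_values")] <- NULL
  class(out) <- setdiff(class(out), "motif_profile")
  as_tibble(out)
}

#' @exportS3Method generics::glance
glance.motif_profile <- function(x, ...) {
  tibble(motif = attr(x, "motif"), flank = attr(x, "flank"),
         n_occurrences = attr(x, "n_occurrences"),
         n_positions = nrow(x))
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("IPD profile of ", attr(x, "motif"), " (", attr(x, "n_occurrences"),
      " occurrences, flank ", attr(x, "flank"), ")\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Error-bar plot of a motif IPD profile
#'
#' Mean IPD with standard-error bars per relative position; motif
#' positions are labelled with the motif letters, flanks with their
#' offsets.
#'
#' @param object A [motif_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_profile <- function(object, ...) {
  motif <- attr(object, "motif")
  chars <- strsplit(motif, "")[[1]]
  labs <- vapply(object$rel_pos, function(r) {
    if (r >= 0 && r < length(chars)) chars[r + 1L] else as.character(r)
  }, character(1))
  df <- tidy(object)
  df$label <- factor(labs, levels = unique(labs[order(object$rel_pos)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_pos, y = .data$mean_ipd)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ipd - .data$se,
                   ymax = .data$mean_ipd + .data$se),
      width = 0.3
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$rel_pos,
                                labels = as.character(df$label)) +
    ggplot2::labs(x = paste0("position (motif ", motif, ")"),
                  y = "mean IPD") +
    ggplot2::theme_minimal()
}

#' Log2 IPD histogram plot
#' @param object An [ipd_log2_histogram()] result.
#' @param ... Unused.
#' @return A ggplot faceted by base label.
#' @export
autoplot.ipd_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$bin_right[1] - object$bin_left[1]) +
    ggplot2::facet_wrap(~base_label, scales = "free_y") +
    ggplot2::labs(x = "log2 mean IPD", y = "sites") +
    ggplot2::theme_minimal()
}

#' Replicate log2-ratio spread versus minimum coverage
#' @param object A [replicate_ratio_by_coverage()] result.
#' @param ... Unused.
#' @return A ggplot of the interquartile band and sd of the log2 ratios.
#' @export
autoplot.replicate_ratio <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$min_coverage)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sd), linetype = "dashed") +
    ggplot2::labs(x = "minimum read coverage (both replicates)",
                  y = "log2 IPD ratio (band: IQR; dashed: sd)") +
    ggplot2::theme_minimal()
}
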