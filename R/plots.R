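#' Plot a digestion curve
#'
#' Percentage of NM-bound DNA over digestion time, one line per condition,
#' with the default zone windows marked.
#'
#' @param object A `digestion_curve` tibble.
#' @param breakpoints Zone window boundaries to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.digestion_curve <- function(object, breakpoints = c(5, 15, 30, 60),
                                     ...) {
  ggplot(object, aes(x = .data$time_min, y = .data$pct_bound,
                     colour = .data$condition)) +
    geom_vline(xintercept = breakpoints, linetype = "dotted",
               colour = "grey60") +
    geom_line() +
    geom_point(size = 1) +
    scale_y_continuous(limits = c(0, 100)) +
    labs(x = "DNase I digestion time (min)",
         y = "% total DNA bound to the NM",
         colour = NULL,
         title = "Nucleoid DNA digestion kinetics") +
    theme_minimal()
}

#' Plot an amplicon call matrix
#'
#' Presence/absence tile map of the call matrix, columns in digestion-time
#' order.
#'
#' @param object An `amplicon_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amplicon_calls <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df, cols = all_of(call_columns()),
                              names_to = "column", values_to = "call")
  long$column <- factor(long$column, levels = call_columns())
  long$sign <- parse_calls(long$call)$sign
  long$amplicon <- factor(long$amplicon, levels = rev(unique(df$amplicon)))
  p <- ggplot(long, aes(x = .data$column, y = .data$amplicon,
                        fill = .data$sign)) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = c(`+` = "#2166ac", `-` = "grey85")) +
    labs(x = "Digestion time point (topological zone)", y = NULL,
         fill = "call") +
    theme_minimal()
  if ("condition" %in% names(long)) p <- p + facet_wrap(~condition)
  p
}

#' Plot a zone shift report
#'
#' Per-amplicon control and test zone ordinals joined by a segment;
#' upward segments are movements towards the NM.
#'
#' @param object A `zone_shift` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_shift <- function(object, ...) {
  df <- as_tibble(object)
  df$amplicon <- factor(df$amplicon, levels = df$amplicon)
  ggplot(df, aes(x = .data$amplicon)) +
    geom_segment(aes(xend = .data$amplicon, y = .data$ordinal_control,
                     yend = .data$ordinal_test),
                 arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")),
                 colour = "grey40") +
    geom_point(aes(y = .data$ordinal_control), colour = "#2166ac", size = 2) +
    scale_y_continuous(breaks = 0:4, labels = zone_levels(),
                       limits = c(0, 4)) +
    labs(x = "Amplicon", y = "Topological zone (towards NM →)",
         title = "Zone shifts relative to the NM") +
    theme_minimal()
}

#' Plot model concordance profiles
#'
#' Concordance of each replication model with the observed assignment as
#' a function of S-phase progress.
#'
#' @param object A `model_verdict` from [discriminate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_verdict <- function(object, ...) {
  ggplot(object$scores, aes(x = .data$s, y = .data$concordance,
                            colour = .data$model)) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "S-phase progress s (fraction of loop DNA replicated)",
         y = "Concordance with observed zones",
         colour = NULL,
         title = paste0("Replication-model discrimination (winner: ",
                        object$winner, ")")) +
    theme_minimal()
}
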