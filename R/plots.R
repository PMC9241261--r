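#' Plot mean FP counts by damage type and sample group
#'
#' Bar chart of the average per-sample FP count, split by damage type and
#' sample group, with standard-error bars. Requires \pkg{ggplot2}.
#'
#' @param metrics per-sample metric table with `group` and the per-type
#'   count columns (`n_indel`, `n_gc_to_at`, `n_gc_to_ta`, `n_other`).
#' @return A ggplot object.
#' @export
plot_fp_types <- function(metrics) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  type_cols <- c(INDEL = "n_indel", GC_TO_AT = "n_gc_to_at",
                 GC_TO_TA = "n_gc_to_ta", OTHER = "n_other")
  long <- do.call(rbind, lapply(names(type_cols), function(tp) {
    data.frame(group = metrics$group, damage_type = tp,
               count = metrics[[type_cols[[tp]]]], stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(count ~ group + damage_type, long, function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  })
  agg <- cbind(agg[c("group", "damage_type")], as.data.frame(agg$count))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$damage_type, y = .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = "damage type", y = "mean FP calls per sample") +
    ggplot2::theme_minimal()
}

#' Violin plot of FP rates by sample group
#'
#' @param metrics per-sample metric table with `group` and
#'   `fpr_per_million`.
#' @return A ggplot object.
#' @export
plot_fpr_groups <- function(metrics) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$group,
                                        y = .data$fpr_per_million)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, size = 1) +
    ggplot2::labs(x = NULL, y = "false positives per million bases") +
    ggplot2::theme_minimal()
}
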