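#' Waterfall plot of repeat decompositions
#'
#' One horizontal bar per read, sorted by ascending tract length, coloured
#' by motif (pure GAA in green), the standard visualization for repeat
#' configurations in long reads.
#'
#' @param profiles A profile tibble from [profile_reads()], or a waterfall
#'   tibble from [waterfall_matrix()].
#' @param max_reads Downsample to at most this many reads (evenly across
#'   the length ordering) to keep plots readable.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(profiles, max_reads = 100L) {
  wf <- if ("tokens" %in% names(profiles)) waterfall_matrix(profiles) else profiles
  if (nrow(wf) == 0L) {
    stop("nothing to plot: no sized reads", call. = FALSE)
  }
  ranks <- sort(unique(wf$read_rank))
  if (length(ranks) > max_reads) {
    keep <- ranks[round(seq(1L, length(ranks), length.out = max_reads))]
    wf <- wf[wf$read_rank %in% keep, , drop = FALSE]
    wf$read_rank <- match(wf$read_rank, keep)
  }
  pal <- c(
    "GAA" = "#2ca02c",
    "GCAGAA" = "#1f77b4",
    "GCAGAAGAA" = "#ff7f0e",
    "GCAGCAGAA" = "#9467bd",
    "GCAGAAGAAGAA" = "#8c564b",
    "GCAGAAGAAGAAGAA" = "#e377c2",
    "NOISE" = "grey70"
  )
  ggplot2::ggplot(wf) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 3, xmax = .data$end / 3,
      ymin = .data$read_rank - 0.45, ymax = .data$read_rank + 0.45,
      fill = .data$motif
    )) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(
      x = "position in tract (repeat units)", y = "read (sorted by tract length)",
      fill = "motif"
    ) +
    ggplot2::theme_minimal()
}

#' Allele-size distribution across cohort groups
#'
#' Jittered per-individual best-allele sizes per group with the penetrance
#' boundaries drawn (solid at the full-penetrance minimum, dashed at the
#' incomplete-penetrance minimum).
#'
#' @param calls Call tibble from [call_cohort()].
#' @param thresholds A [classification_thresholds()].
#' @param min_units Only plot alleles at least this size (drops wild-type
#'   alleles when plotting `"wgs"`-mode calls).
#' @return A ggplot object.
#' @export
plot_cohort_sizes <- function(calls, thresholds = classification_thresholds(),
                              min_units = NULL) {
  long <- dplyr::bind_rows(
    dplyr::transmute(calls,
      group = .data$group, units = .data$allele1_units,
      class = .data$allele1_class
    ),
    dplyr::transmute(calls,
      group = .data$group, units = .data$allele2_units,
      class = .data$allele2_class
    )
  )
  long <- long[!is.na(long$units), , drop = FALSE]
  if (!is.null(min_units)) long <- long[long$units >= min_units, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$units, colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = thresholds$full_penetrance_min) +
    ggplot2::geom_hline(yintercept = thresholds$incomplete_min, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "repeat units", colour = "configuration") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.pipeline_result <- function(object, ...) {
  plot_waterfall(object$waterfall, ...)
}
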