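#' Plot QC metrics with threshold reference lines
#'
#' One panel per metric; points are coloured by exclusion verdict and the
#' dashed line marks the threshold.
#'
#' @param object An `mc_qc` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mc_qc
#' @export
autoplot.mc_qc <- function(object, ...) {
  thr <- attr(object, "thresholds") %||% qc_thresholds()
  long <- tidy.mc_qc(object)
  long$excluded <- object$excluded[match(long$sample, object$sample)]
  lines <- tibble(
    metric = c("alignment_rate", "saturation", "cpg_enrichment",
               "cpg_coverage_5x"),
    threshold = c(thr$min_alignment_rate, thr$min_saturation,
                  thr$min_enrichment, thr$min_cpg_coverage_5x)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value,
                                     colour = .data$excluded)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = NULL, colour = "excluded") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot one or more Methylation Distributions
#'
#' Mean rpm per bin against CpG-content class; the area under each curve is
#' that sample's GMI.
#'
#' @param object An `mc_distribution`, or a named list of them.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mc_distribution
#' @export
autoplot.mc_distribution <- function(object, ...) {
  tbl <- if (inherits(object, "mc_distribution")) {
    dplyr::mutate(as_tibble(object), sample = "sample")
  } else {
    bind_rows(lapply(names(object), function(nm)
      dplyr::mutate(as_tibble(object[[nm]]), sample = nm)))
  }
  tbl <- tbl[!is.na(tbl$mean_rpm), ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$class, y = .data$mean_rpm,
                                    colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "CpG content class (CpGs per bin)",
                  y = "mean rpm per bin") +
    ggplot2::theme_bw()
}

#' Volcano-style overview of a differential methylation result
#'
#' @param object An `mc_diffmeth` tibble.
#' @param ... Unused.
#' @return A ggplot of adjusted p-values by locus rank.
#' @method autoplot mc_diffmeth
#' @export
autoplot.mc_diffmeth <- function(object, ...) {
  tbl <- as_tibble(object)
  tbl <- tbl[order(tbl$p_adjusted), ]
  tbl$rank <- seq_len(nrow(tbl))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$rank,
                                    y = -log10(pmax(.data$p_adjusted, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = "locus rank", y = "-log10 adjusted p") +
    ggplot2::theme_bw()
}

#' Box plot of one locus across groups
#'
#' The per-locus view used to inspect significant differentially methylated
#' loci.
#'
#' @param fm An `mc_fmatrix` with groups.
#' @param locus Locus name (rowname of the matrix).
#' @return A ggplot.
#' @export
plot_locus <- function(fm, locus) {
  stopifnot(inherits(fm, "mc_fmatrix"))
  if (!locus %in% rownames(fm$values)) stop("unknown locus: ", locus, call. = FALSE)
  long <- as_tibble(fm)
  long <- long[long$locus == locus, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$rpm)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(title = locus, x = NULL, y = "rpm") +
    ggplot2::theme_bw()
}

#' Plot a dendrogram with tracked group colours
#'
#' Base-graphics dendrogram whose leaf labels are coloured per a
#' [track_groups()] assignment (colouring applied through
#' [stats::dendrapply()]).
#'
#' @param hc An `hclust`/`mc_dendrogram`.
#' @param colors Optional tibble from [track_groups()] (rows for this
#'   dendrogram or a `sample`/`color` table).
#' @param ... Passed to [plot()].
#' @return Invisibly, the dendrogram object plotted.
#' @export
plot_dendrogram <- function(hc, colors = NULL, ...) {
  dend <- stats::as.dendrogram(hc)
  if (!is.null(colors)) {
    cmap <- stats::setNames(colors$color, colors$sample)
    dend <- stats::dendrapply(dend, function(node) {
      if (stats::is.leaf(node)) {
        col <- cmap[attr(node, "label")]
        if (!is.na(col)) {
          attr(node, "nodePar") <- c(attr(node, "nodePar"),
                                     list(lab.col = unname(col)))
        }
      }
      node
    })
  }
  graphics::plot(dend, ...)
  invisible(dend)
}
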