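#' Two-group rank-sum test for one locus
#'
#' Two-sided Wilcoxon rank-sum p-value for the rpm values of one locus in two
#' groups. The exact null distribution is used when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with midranks, tie-corrected variance and continuity correction. A locus
#' whose values are identical across both groups carries no information and
#' returns p = 1 (keeping downstream FDR adjustment well defined).
#'
#' @param a,b Numeric rpm vectors (each length >= 1).
#' @return Two-sided p-value.
#' @export
wilcoxon_locus <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups need values", call. = FALSE)
  if (length(unique(c(a, b))) == 1L) return(1)
  exact <- (length(a) + length(b) <= 20L) && !anyDuplicated(c(a, b))
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
  if (is.na(p)) return(1)
  min(p, 1)
}

#' Multi-group rank test for one locus
#'
#' Kruskal-Wallis H with tie correction, p from chi-square on k - 1 degrees
#' of freedom. Two groups delegate to [wilcoxon_locus()]; an all-identical
#' locus returns p = 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return p-value.
#' @export
kruskal_locus <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  if (length(groups) == 2L) return(wilcoxon_locus(groups[[1L]], groups[[2L]]))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) return(1)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  p <- suppressWarnings(stats::kruskal.test(values, g)$p.value)
  if (is.na(p)) return(1)
  min(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, in the input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential methylation across groups for every locus of a feature class
#'
#' Tests each locus of the feature matrix across its sample groups — the
#' Wilcoxon rank-sum test for two groups, Kruskal-Wallis for more — then
#' adjusts across all loci of the feature class by Benjamini-Hochberg.
#' Per-group medians and quartiles are reported for box-plot style summaries.
#'
#' @param fm An `mc_fmatrix` with group labels (see [set_groups()]).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return An `mc_diffmeth` tibble: `locus`, `chrom`, `start`, `end`,
#'   `median_<group>`, `q25_<group>`, `q75_<group>`, `p_value`, `p_adjusted`,
#'   `significant`; ordered as the feature set. Attributes: `alpha`, `test`,
#'   `feature_class`.
#' @export
differential_features <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "mc_fmatrix"))
  check_scalar_num(alpha, "alpha", min = 0, max = 1)
  if (is.null(fm$groups)) stop("feature matrix has no group labels", call. = FALSE)
  glabels <- unique(unname(fm$groups))
  if (length(glabels) < 2L) stop("need at least 2 groups", call. = FALSE)
  cols_by_group <- lapply(glabels, function(g) which(fm$groups == g))
  if (any(lengths(cols_by_group) == 0L)) {
    stop("group without samples: ",
         glabels[lengths(cols_by_group) == 0L][1L], call. = FALSE)
  }
  v <- fm$values
  pvals <- vapply(seq_len(nrow(v)), function(i) {
    kruskal_locus(lapply(cols_by_group, function(cols) v[i, cols]))
  }, numeric(1))
  out <- fm$loci
  names(out)[names(out) == "name"] <- "locus"
  out <- out[, c("locus", "chrom", "start", "end")]
  for (k in seq_along(glabels)) {
    sub <- v[, cols_by_group[[k]], drop = FALSE]
    out[[paste0("median_", glabels[k])]] <- apply(sub, 1, stats::median)
    out[[paste0("q25_", glabels[k])]] <- apply(sub, 1, stats::quantile, probs = 0.25)
    out[[paste0("q75_", glabels[k])]] <- apply(sub, 1, stats::quantile, probs = 0.75)
  }
  out$p_value <- pvals
  out$p_adjusted <- fdr_adjust(pvals)
  out$significant <- out$p_adjusted <= alpha
  structure(out, alpha = alpha,
            test = if (length(glabels) == 2L) "wilcoxon" else "kruskal-wallis",
            feature_class = fm$feature_class,
            class = c("mc_diffmeth", class(out)))
}

#' @method tidy mc_diffmeth
#' @export
tidy.mc_diffmeth <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance mc_diffmeth
#' @export
glance.mc_diffmeth <- function(x, ...) {
  tibble(feature_class = attr(x, "feature_class"),
         test = attr(x, "test"),
         alpha = attr(x, "alpha"),
         n_loci = nrow(x),
         n_significant = sum(x$significant),
         min_p_adjusted = if (nrow(x)) min(x$p_adjusted) else NA_real_)
}

#' Write differential methylation results
#'
#' @param res An `mc_diffmeth` tibble.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_diffmeth <- function(res, path) {
  write_tsv_quiet(as_tibble(res), path)
  invisible(path)
}
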