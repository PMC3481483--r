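#' Classify bins by CpG content
#'
#' Each bin is labelled with the number of CpG dimers whose C lies inside it,
#' counting a dimer straddling the bin boundary for the earlier bin (straddle
#' on). Classes above `cap` are pooled into the top class: sparse high-CpG
#' tails would otherwise produce unstable means.
#'
#' @param genome `mc_genome`.
#' @param cpg_index [index_cpg_sites()] result.
#' @param bin_size Bin width matching the bin tracks (default 500).
#' @param cap Highest distinct class (default 30); `Inf` disables pooling.
#' @return An `mc_classes` list: `$bin_size`, `$cap`, `$classes` (named list
#'   of per-chromosome integer vectors).
#' @export
classify_bins <- function(genome, cpg_index, bin_size = 500, cap = 30) {
  chroms <- genome$chroms
  classes <- vector("list", nrow(chroms))
  names(classes) <- chroms$name
  for (i in seq_len(nrow(chroms))) {
    len <- chroms$length[i]
    nb <- as.integer(ceiling(len / bin_size))
    pos <- cpg_index$positions[[chroms$name[i]]]
    bounds <- c(seq(0L, by = bin_size, length.out = nb), len)
    cnt <- diff(findInterval(bounds - 1L, pos))
    if (is.finite(cap)) cnt <- pmin(cnt, as.integer(cap))
    classes[[i]] <- as.integer(cnt)
  }
  structure(list(bin_size = as.integer(bin_size), cap = cap, classes = classes),
            class = "mc_classes")
}

#' Methylation Distribution of a sample
#'
#' For each CpG-content class, the number of bins in that class and the mean
#' rpm per bin (sum of rpms divided by the number of bins). Empty classes have
#' `n_bins = 0` and an undefined mean (`NA`).
#'
#' @param bt An `mc_bintrack`.
#' @param classes [classify_bins()] result on the same grid.
#' @return An `mc_distribution` tibble: `class`, `n_bins`, `mean_rpm`,
#'   covering classes `0..cap`.
#' @export
methylation_distribution <- function(bt, classes) {
  stopifnot(inherits(bt, "mc_bintrack"), inherits(classes, "mc_classes"))
  if (bt$bin_size != classes$bin_size) {
    stop("bin grids differ: track ", bt$bin_size, " vs classes ",
         classes$bin_size, call. = FALSE)
  }
  common <- bt$chroms$name
  if (!all(common %in% names(classes$classes))) {
    stop("classification missing chromosome(s): ",
         paste(setdiff(common, names(classes$classes)), collapse = ", "),
         call. = FALSE)
  }
  cls <- unlist(classes$classes[common], use.names = FALSE)
  rpm <- unlist(bt$rpm[common], use.names = FALSE)
  if (length(cls) != length(rpm)) {
    stop("track and classification have different bin counts", call. = FALSE)
  }
  cmax <- max(cls)
  n_bins <- tabulate(cls + 1L, nbins = cmax + 1L)
  sums <- vapply(0:cmax, function(c) sum(rpm[cls == c]), numeric(1))
  out <- tibble(class = 0:cmax, n_bins = n_bins,
                mean_rpm = ifelse(n_bins > 0, sums / n_bins, NA_real_))
  structure(out, class = c("mc_distribution", class(out)))
}

#' Global Methylation Indicator of a sample
#'
#' Area under the Methylation Distribution curve (mean rpm per bin versus
#' CpG-content class) by the trapezoidal rule, interpolating linearly across
#' empty classes. A single scalar summarising genome-wide methylation; it
#' scales linearly with rpm.
#'
#' @param md An `mc_distribution` (or tibble with `class`, `n_bins`,
#'   `mean_rpm`).
#' @return Non-negative scalar.
#' @export
compute_gmi <- function(md) {
  pts <- md[!is.na(md$mean_rpm) & md$n_bins > 0, ]
  if (nrow(pts) < 2L) {
    stop("GMI needs at least 2 CpG-content classes with defined means",
         call. = FALSE)
  }
  x <- pts$class
  y <- pts$mean_rpm
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' GMI table for a cohort
#'
#' @param tracks Named list of `mc_bintrack`s.
#' @param classes [classify_bins()] result.
#' @param groups Optional named character vector (sample -> group).
#' @return Tibble `sample`, `group`, `gmi`.
#' @export
gmi_table <- function(tracks, classes, groups = NULL) {
  stopifnot(!is.null(names(tracks)))
  tibble(
    sample = names(tracks),
    group = if (is.null(groups)) NA_character_ else unname(groups[names(tracks)]),
    gmi = vapply(tracks, function(bt)
      compute_gmi(methylation_distribution(bt, classes)), numeric(1))
  )
}

#' Compare GMI between two groups by Welch t-test
#'
#' Two-sided Welch (unequal variance) t-test on per-sample GMI values. The
#' first group in order of appearance is the reference, so swapping group
#' order negates the statistic. Degenerate zero-variance inputs with equal
#' means return t = 0, p = 1.
#'
#' @param gmis Tibble with columns `sample`, `group`, `gmi`; exactly two
#'   groups with >= 2 samples each.
#' @return An `mc_gmi_test` list: `$statistic`, `$p_value`, `$df`,
#'   `$group_means` (named), `$n` (named).
#' @export
compare_gmi <- function(gmis) {
  stopifnot(all(c("group", "gmi") %in% names(gmis)))
  glabels <- unique(gmis$group)
  if (length(glabels) != 2L) stop("compare_gmi needs exactly 2 groups", call. = FALSE)
  x <- gmis$gmi[gmis$group == glabels[1L]]
  y <- gmis$gmi[gmis$group == glabels[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  res <- tryCatch(
    stats::t.test(x, y, var.equal = FALSE),
    error = function(e) NULL # essentially constant data
  )
  if (is.null(res)) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    res <- list(statistic = c(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf),
                p.value = if (same) 1 else 0,
                parameter = c(df = NA_real_))
  }
  structure(
    list(statistic = unname(res$statistic),
         p_value = res$p.value,
         df = unname(res$parameter),
         group_means = stats::setNames(c(mean(x), mean(y)), glabels),
         n = stats::setNames(c(length(x), length(y)), glabels)),
    class = "mc_gmi_test"
  )
}

#' @export
print.mc_gmi_test <- function(x, ...) {
  cat(sprintf("<mc_gmi_test> Welch t = %.3f, p = %.4g; means: %s\n",
              x$statistic, x$p_value,
              paste(sprintf("%s = %.3f", names(x$group_means), x$group_means),
                    collapse = ", ")))
  invisible(x)
}

#' @method tidy mc_gmi_test
#' @export
tidy.mc_gmi_test <- function(x, ...) {
  tibble(group = names(x$group_means), mean_gmi = unname(x$group_means),
         n = unname(x$n))
}

#' @method glance mc_gmi_test
#' @export
glance.mc_gmi_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = x$df)
}

#' Write Methylation Distributions for several samples
#'
#' @param distributions Named list of `mc_distribution` tibbles.
#' @param path Output path (tab-separated; columns `sample`, `class`,
#'   `n_bins`, `mean_rpm`).
#' @return `path`, invisibly.
#' @export
write_distributions <- function(distributions, path) {
  tbl <- bind_rows(lapply(names(distributions), function(nm) {
    d <- as_tibble(distributions[[nm]])
    d$sample <- nm
    d[, c("sample", "class", "n_bins", "mean_rpm")]
  }))
  write_tsv_quiet(tbl, path)
  invisible(path)
}
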