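#' Filter loci by minimum mean rpm and coefficient of variation
#'
#' A locus is retained when its mean rpm across samples is strictly greater
#' than `min_avg_rpm` AND its CV (sample standard deviation / mean; defined
#' as 0 for an all-zero locus) is strictly greater than `min_cv`. The mean
#' filter removes loci that were not pulled down well (noise); the CV filter
#' keeps the loci with the largest differences among samples.
#'
#' @param fm An `mc_fmatrix`.
#' @param min_avg_rpm,min_cv Non-negative thresholds (strict `>`).
#' @return Filtered `mc_fmatrix`.
#' @export
filter_loci <- function(fm, min_avg_rpm = 0, min_cv = 0) {
  stopifnot(inherits(fm, "mc_fmatrix"))
  check_scalar_num(min_avg_rpm, "min_avg_rpm", min = 0)
  check_scalar_num(min_cv, "min_cv", min = 0)
  means <- rowMeans(fm$values)
  cvs <- apply(fm$values, 1, locus_cv)
  keep <- means > min_avg_rpm & cvs > min_cv
  new_fmatrix(fm$values[keep, , drop = FALSE], fm$loci[keep, , drop = FALSE],
              groups = fm$groups, feature_class = fm$feature_class)
}

#' Rescale each locus by its mean
#'
#' Divides every locus row by its average rpm so each retained row has mean
#' exactly 1; Pearson correlation then weights low- and high-rpm loci evenly
#' instead of being dominated by the high ones. Idempotent.
#'
#' @param fm An `mc_fmatrix` whose loci all have positive mean (guaranteed
#'   after [filter_loci()] with `min_avg_rpm > 0`).
#' @return Rescaled `mc_fmatrix`.
#' @export
rescale_loci <- function(fm) {
  stopifnot(inherits(fm, "mc_fmatrix"))
  means <- rowMeans(fm$values)
  if (any(means <= 0)) {
    stop("locus with non-positive mean cannot be rescaled: ",
         rownames(fm$values)[means <= 0][1L], call. = FALSE)
  }
  new_fmatrix(fm$values / means, fm$loci, groups = fm$groups,
              feature_class = fm$feature_class)
}

#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` over the locus vectors of samples `i` and `j`;
#' symmetric with zero diagonal, range `[0, 2]`.
#'
#' @param fm An `mc_fmatrix` with >= 2 loci.
#' @return A [stats::dist] object over samples.
#' @export
pearson_distance <- function(fm) {
  stopifnot(inherits(fm, "mc_fmatrix"))
  v <- fm$values
  if (nrow(v) < 2L) stop("need at least 2 loci after filtering", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample column: ", colnames(v)[sds == 0][1L], call. = FALSE)
  }
  stats::as.dist(1 - stats::cor(v))
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' McQuitty (WPGMA) linkage by default: the distance from a merged cluster to
#' any other is the plain average of its two children's distances,
#' `d(ab, k) = (d(a, k) + d(b, k)) / 2`. Ties in the minimum distance are
#' broken by the smallest (left-most) pair of cluster indices so dendrograms
#' are reproducible across platforms. Returns a standard `hclust` object
#' (usable with [stats::cutree()], plotting, etc.).
#'
#' @param d A [stats::dist] or symmetric non-negative matrix.
#' @param method One of `"mcquitty"`, `"average"`, `"single"`, `"complete"`.
#' @return An object of classes `mc_dendrogram`, `hclust`.
#' @export
hierarchical_cluster <- function(d, method = c("mcquitty", "average", "single",
                                               "complete")) {
  method <- match.arg(method)
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || !isTRUE(all.equal(dm, t(dm)))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(dm < 0)) stop("negative distances are not allowed", call. = FALSE)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 samples to cluster", call. = FALSE)
  labels <- rownames(dm) %||% as.character(seq_len(n))
  D <- dm
  diag(D) <- Inf
  code <- -seq_len(n) # hclust convention: negative leaf, positive merge row
  size <- rep(1L, n)
  alive <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(alive)
    sub <- D[idx, idx, drop = FALSE]
    best <- min(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- idx[hit[1L, 1L]]
    j <- idx[hit[1L, 2L]]
    pair <- sort(c(code[i], code[j]))
    merge[s, ] <- if (all(pair < 0)) rev(pair) else pair
    height[s] <- best
    others <- idx[idx != i & idx != j]
    if (length(others)) {
      dnew <- switch(method,
        mcquitty = (D[i, others] + D[j, others]) / 2,
        average = (size[i] * D[i, others] + size[j] * D[j, others]) /
          (size[i] + size[j]),
        single = pmin(D[i, others], D[j, others]),
        complete = pmax(D[i, others], D[j, others])
      )
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    alive[j] <- FALSE
    size[i] <- size[i] + size[j]
    code[i] <- s
  }
  structure(
    list(merge = merge, height = height, order = merge_order(merge),
         labels = labels, method = method, dist.method = "pearson",
         call = match.call()),
    class = c("mc_dendrogram", "hclust")
  )
}

# left-to-right leaf order by iterative traversal of the merge table
merge_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

# leaf label sets of every internal node, as canonical keys
node_leafsets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get <- function(x) if (x < 0L) hc$labels[-x] else sets[[x]]
    sets[[s]] <- sort(c(get(hc$merge[s, 1L]), get(hc$merge[s, 2L])))
  }
  sets
}

clade_keys <- function(hc) {
  vapply(node_leafsets(hc), paste, "", collapse = "\r")
}

#' Bootstrap support for a sample dendrogram
#'
#' Resamples loci (rows of the feature matrix) with replacement, reclusters,
#' and scores each internal node of the reference dendrogram by the fraction
#' of replicates containing the identical leaf set. With several scales
#' (relative resample sizes), an approximately unbiased (AU) p-value is
#' fitted per node from the scale-vs-proportion curve via the standard
#' two-parameter (signed distance `v`, curvature `c`) probit regression:
#' `qnorm(1 - bp_r) = v * sqrt(r) + c / sqrt(r)`, `AU = pnorm(c - v)`.
#' With the single scale 1 the plain bootstrap proportion is reported and
#' `au` is `NA`.
#'
#' @param fm Filtered (and optionally rescaled) `mc_fmatrix`.
#' @param B Replicates per scale (>= 1).
#' @param seed Integer seed; same seed, same supports.
#' @param scales Relative resample sizes (default 1; multiscale grid such as
#'   `seq(0.5, 1.4, 0.1)` enables AU fitting).
#' @param method Linkage passed to [hierarchical_cluster()].
#' @return The reference `mc_dendrogram` with attribute `support`: a tibble
#'   `node`, `n_leaves`, `bp`, `au`.
#' @export
bootstrap_support <- function(fm, B = 100, seed = 1L, scales = 1,
                              method = "mcquitty") {
  stopifnot(inherits(fm, "mc_fmatrix"))
  check_scalar_num(B, "B", min = 1)
  n_loci <- nrow(fm$values)
  if (n_loci < 2L) stop("need at least 2 loci to bootstrap", call. = FALSE)
  ref <- hierarchical_cluster(pearson_distance(fm), method = method)
  keys <- clade_keys(ref)
  n_nodes <- length(keys)
  hits <- matrix(0, n_nodes, length(scales))
  valid <- numeric(length(scales))
  withr::with_seed(seed, {
    for (si in seq_along(scales)) {
      m <- max(2L, round(scales[si] * n_loci))
      for (b in seq_len(B)) {
        idx <- sample.int(n_loci, m, replace = TRUE)
        v <- fm$values[idx, , drop = FALSE]
        sds <- apply(v, 2, stats::sd)
        if (any(sds == 0)) next # degenerate resample; drop from denominator
        hc <- hierarchical_cluster(stats::as.dist(1 - stats::cor(v)),
                                   method = method)
        hits[, si] <- hits[, si] + (keys %in% clade_keys(hc))
        valid[si] <- valid[si] + 1
      }
    }
  })
  bp_mat <- sweep(hits, 2, pmax(valid, 1), "/")
  i1 <- which.min(abs(scales - 1))
  au <- rep(NA_real_, n_nodes)
  if (length(scales) > 1L) {
    for (k in seq_len(n_nodes)) {
      au[k] <- fit_au(bp_mat[k, ], scales, valid)
    }
  }
  support <- tibble(node = seq_len(n_nodes),
                    n_leaves = lengths(node_leafsets(ref)),
                    bp = bp_mat[, i1],
                    au = au)
  attr(ref, "support") <- support
  ref
}

# probit fit of the multiscale curve; weighted by the binomial information
fit_au <- function(bp, scales, nboot) {
  usable <- nboot > 0
  bp <- bp[usable]; scales <- scales[usable]; nboot <- nboot[usable]
  if (all(bp >= 1)) return(1)
  if (all(bp <= 0)) return(0)
  eps <- 1 / (max(nboot) + 1)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  z <- stats::qnorm(1 - bpc)
  x1 <- sqrt(scales)
  x2 <- 1 / sqrt(scales)
  w <- nboot * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  fit <- stats::lm(z ~ 0 + x1 + x2, weights = w)
  v <- stats::coef(fit)[["x1"]]
  cc <- stats::coef(fit)[["x2"]]
  stats::pnorm(cc - v)
}

#' Track reference cluster membership across dendrograms
#'
#' Cuts the reference dendrogram into `cut_size` clusters, keeps the `k`
#' largest (by membership), assigns each a colour in left-to-right dendrogram
#' order (defaults blue/red for `k = 2`), and colours the leaves of every
#' other dendrogram by their reference cluster. Leaves outside the tracked
#' clusters — and leaves absent from the reference — get the neutral colour
#' (black).
#'
#' @param reference An `hclust`/`mc_dendrogram`.
#' @param k Number of clusters to track (default 2).
#' @param others Named list of further dendrograms sharing (a subset of) the
#'   reference leaves.
#' @param cut_size Number of clusters to cut the reference into before taking
#'   the `k` largest (default `k`).
#' @param palette Colours for the tracked clusters.
#' @param neutral Colour for untracked leaves.
#' @return Tibble `dendrogram`, `sample`, `cluster` (NA when untracked),
#'   `color`, with the reference listed as `"reference"`.
#' @export
track_groups <- function(reference, k = 2, others = list(), cut_size = k,
                         palette = c("blue", "red", "darkgreen", "orange",
                                     "purple", "brown"),
                         neutral = "black") {
  n_leaves <- length(reference$labels)
  if (k > n_leaves) stop("k exceeds the leaf count", call. = FALSE)
  if (cut_size < k) stop("cut_size must be at least k", call. = FALSE)
  if (k > length(palette)) stop("palette too small for k clusters", call. = FALSE)
  cut <- stats::cutree(reference, k = cut_size)
  sizes <- sort(table(cut), decreasing = TRUE)
  tracked <- as.integer(names(sizes)[seq_len(k)])
  # colour order follows dendrogram left-to-right position of each cluster
  leaf_pos <- match(reference$labels, reference$labels[reference$order])
  first_pos <- vapply(tracked, function(cl) min(leaf_pos[cut == cl]), numeric(1))
  tracked <- tracked[order(first_pos)]
  color_of <- stats::setNames(palette[seq_len(k)], tracked)
  assign_one <- function(hc, nm) {
    cl <- cut[match(hc$labels, names(cut))]
    cl[!cl %in% tracked] <- NA
    tibble(dendrogram = nm, sample = hc$labels,
           cluster = cl,
           color = ifelse(is.na(cl), neutral, color_of[as.character(cl)]))
  }
  dends <- c(list(reference = reference), others)
  if (is.null(names(dends)) || any(!nzchar(names(dends)[-1]))) {
    names(dends) <- c("reference", paste0("dendrogram_", seq_along(others)))
  }
  bind_rows(lapply(names(dends), function(nm) assign_one(dends[[nm]], nm)))
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths derive from merge heights; internal node labels carry
#' bootstrap support (when present) as `bp` or `au` values.
#'
#' @param hc An `hclust`/`mc_dendrogram`.
#' @param path Output path; `NULL` returns the Newick string.
#' @param support Which support values to write as internal labels:
#'   `"bp"`, `"au"`, or `"none"`.
#' @return The Newick string, invisibly when written.
#' @export
export_newick <- function(hc, path = NULL, support = c("bp", "au", "none")) {
  support <- match.arg(support)
  sup <- attr(hc, "support")
  lab <- function(node) {
    if (support == "none" || is.null(sup)) return("")
    val <- sup[[support]][sup$node == node]
    if (length(val) != 1L || is.na(val)) "" else format(val, digits = 4)
  }
  heights <- hc$height
  rec <- function(node, parent_h) {
    if (node < 0L) {
      return(sprintf("%s:%s", hc$labels[-node], format(parent_h, digits = 8)))
    }
    inner <- paste(rec(hc$merge[node, 1L], heights[node]),
                   rec(hc$merge[node, 2L], heights[node]), sep = ",")
    sprintf("(%s)%s:%s", inner, lab(node),
            format(parent_h - heights[node], digits = 8))
  }
  root <- nrow(hc$merge)
  nwk <- sprintf("(%s,%s)%s;",
                 rec(hc$merge[root, 1L], heights[root]),
                 rec(hc$merge[root, 2L], heights[root]),
                 lab(root))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Export the clustered (ordered) matrix for heatmap drawing
#'
#' @param fm The `mc_fmatrix` that was clustered.
#' @param hc The dendrogram over its samples.
#' @param path Output path; `NULL` returns the reordered matrix.
#' @return Matrix with columns in dendrogram order (invisibly when written).
#' @export
export_ordered_matrix <- function(fm, hc, path = NULL) {
  ord <- hc$labels[hc$order]
  m <- fm$values[, ord, drop = FALSE]
  if (is.null(path)) return(m)
  tbl <- data.frame(locus = rownames(m), m, check.names = FALSE)
  write_tsv_quiet(tbl, path)
  invisible(m)
}
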