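#' Assemble and validate a pipeline configuration
#'
#' Flat key-value configuration (a list, or a path to a YAML file with the
#' same keys) driving [run_pipeline()]. Required: `genome` (FASTA),
#' `manifest` (TSV with columns `sample`, `group`, `path` or `sam`/`bed`,
#' optional `format`, `n_pass_filter`), `out_dir`. Optional: `features`
#' (named list class -> BED path), `bin_size` (500), `extension` (300),
#' `alpha` (0.05), `min_avg_rpm` (0), `min_cv` (0), `rescale` (TRUE),
#' `bootstrap` (0 = plain dendrogram), `n_levels` (10), `seed` (1),
#' `thresholds` (list of [qc_thresholds()] arguments), `gmi_cap` (30).
#'
#' @param config List or YAML path.
#' @return Validated `mc_config` list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(bin_size = 500, extension = 300, alpha = 0.05,
                   min_avg_rpm = 0, min_cv = 0, rescale = TRUE, bootstrap = 0,
                   n_levels = 10, seed = 1L, gmi_cap = 30,
                   features = list(), thresholds = list())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("genome", "manifest", "out_dir")) {
    if (is.null(config[[nm]])) {
      stop("pipeline config lacks required field '", nm, "'", call. = FALSE)
    }
  }
  for (nm in c("genome", "manifest")) {
    if (!file.exists(config[[nm]])) {
      stop("config field '", nm, "': file not found: ", config[[nm]],
           call. = FALSE)
    }
  }
  for (bed in unlist(config$features)) {
    if (!file.exists(bed)) stop("feature BED not found: ", bed, call. = FALSE)
  }
  config$thresholds <- do.call(qc_thresholds, config$thresholds)
  structure(config, class = "mc_config")
}

#' Run the analysis pipeline
#'
#' Executes the stages in dependency order — import (with deduplication),
#' qc, bin, features, then diff / gmi / cluster / tracks — writing each
#' stage's outputs under `out_dir` so stages can also be run one at a time
#' across separate calls (later stages reload the intermediate files).
#' Samples excluded by QC are dropped from every downstream stage and listed
#' in the report. With fixed config and seed, reruns are byte-identical.
#'
#' @param config An [pipeline_config()] (or list/YAML path coercible to one).
#' @param stages Subset of
#'   `c("import", "qc", "bin", "features", "diff", "gmi", "cluster", "tracks")`.
#' @return An `mc_pipeline` report: tibble `stage`, `status`, `outputs`
#'   (semicolon-joined paths), with attributes `excluded` (character vector)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config, stages = c("import", "qc", "bin", "features",
                                            "diff", "gmi", "cluster", "tracks")) {
  if (!inherits(config, "mc_config")) config <- pipeline_config(config)
  all_stages <- c("import", "qc", "bin", "features", "diff", "gmi", "cluster",
                  "tracks")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hashed <- unclass(config)
  hashed$out_dir <- NULL # analysis parameters only: reruns elsewhere match
  provenance <- sprintf("methcapr %s | config %s",
                        as.character(utils::packageVersion("methcapr")),
                        rlang::hash(hashed))
  genome <- load_genome(config$genome)
  cpg_idx <- index_cpg_sites(genome)
  manifest <- read.table(config$manifest, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(manifest$path)) {
    manifest$path <- manifest$bed %||% manifest$sam
    manifest$format <- if (is.null(manifest$bed)) "sam" else "bed"
  }
  if (is.null(manifest$format)) {
    manifest$format <- ifelse(grepl("\\.sam$", manifest$path), "sam", "bed")
  }
  groups <- stats::setNames(as.character(manifest$group), manifest$sample)
  report <- list()
  log_stage <- function(stage, outputs) {
    report[[stage]] <<- tibble(stage = stage, status = "completed",
                               outputs = paste(outputs, collapse = ";"))
  }

  import_dir <- file.path(out, "import")
  readsets <- NULL
  load_readsets <- function(samples = manifest$sample) {
    if (!is.null(readsets)) return(readsets[samples])
    rs <- lapply(samples, function(s) {
      f <- file.path(import_dir, paste0(s, ".bed"))
      if (!file.exists(f)) {
        stop("missing import artifact for sample '", s,
             "'; run the import stage first", call. = FALSE)
      }
      row <- manifest[manifest$sample == s, ]
      r <- import_alignments(f, format = "bed", genome = genome,
                             n_pass_filter = (row$n_pass_filter %||% NA_real_)[1L])
      r$n_unique_aligned <- (row$n_unique %||% r$n_unique_aligned)[1L]
      r$n_after_dedup <- nrow(r$reads)
      r
    })
    stats::setNames(rs, samples)
  }

  if ("import" %in% stages) {
    dir.create(import_dir, showWarnings = FALSE)
    meta <- list()
    readsets <- stats::setNames(vector("list", nrow(manifest)), manifest$sample)
    for (i in seq_len(nrow(manifest))) {
      s <- manifest$sample[i]
      npf <- if (is.null(manifest$n_pass_filter)) NA_real_ else manifest$n_pass_filter[i]
      rs <- import_alignments(manifest$path[i], format = manifest$format[i],
                              genome = genome, n_pass_filter = npf)
      n_unique <- rs$n_unique_aligned
      rs <- remove_duplicates(rs)
      readsets[[s]] <- rs
      bed <- data.frame(rs$reads$chrom, rs$reads$start, rs$reads$end,
                        paste0("r", seq_len(nrow(rs$reads))), 0L,
                        rs$reads$strand)
      write.table(bed, file.path(import_dir, paste0(s, ".bed")), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      meta[[s]] <- tibble(sample = s, n_unique = n_unique,
                          n_dedup = rs$n_after_dedup)
    }
    manifest <- merge(manifest, bind_rows(meta), by = "sample", sort = FALSE)
    write_tsv_quiet(manifest, file.path(import_dir, "imported.tsv"), provenance)
    log_stage("import", import_dir)
  } else if (file.exists(file.path(import_dir, "imported.tsv"))) {
    manifest <- read.table(file.path(import_dir, "imported.tsv"), header = TRUE,
                           sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  }

  qc_path <- file.path(out, "qc_summary.tsv")
  excluded <- character(0)
  if ("qc" %in% stages) {
    readsets <- readsets %||% load_readsets()
    # alignment_rate needs the library totals from the manifest
    for (s in names(readsets)) {
      if (!is.null(manifest$n_pass_filter)) {
        readsets[[s]]$n_pass_filter <- manifest$n_pass_filter[manifest$sample == s]
      }
      if (!is.null(manifest$n_unique)) {
        readsets[[s]]$n_unique_aligned <- manifest$n_unique[manifest$sample == s]
      }
    }
    qc <- compute_qc(readsets, genome, cpg_idx, bin_size = config$bin_size,
                     extension = config$extension,
                     thresholds = config$thresholds, seed = config$seed)
    write_tsv_quiet(as_tibble(qc), qc_path, provenance)
    log_stage("qc", qc_path)
  }
  if (file.exists(qc_path)) {
    qc_tbl <- read.table(qc_path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
    excluded <- qc_tbl$sample[qc_tbl$excluded]
  }
  retained <- setdiff(manifest$sample, excluded)

  counts_dir <- file.path(out, "counts")
  tracks_objs <- NULL
  load_tracks <- function() {
    if (!is.null(tracks_objs)) return(tracks_objs)
    files <- file.path(counts_dir, paste0(retained, ".mcbc"))
    if (!all(file.exists(files))) {
      stop("missing binned counts; run the bin stage first", call. = FALSE)
    }
    stats::setNames(lapply(files, read_counts), retained)
  }

  if ("bin" %in% stages) {
    dir.create(counts_dir, showWarnings = FALSE)
    readsets <- readsets %||% load_readsets()
    tracks_objs <- lapply(readsets[retained], function(rs) {
      count_bins(rs, genome, bin_size = config$bin_size,
                 extension = config$extension)
    })
    # round-trip through the codec so in-memory and on-disk runs agree at f32
    for (s in retained) {
      write_counts(tracks_objs[[s]], file.path(counts_dir, paste0(s, ".mcbc")))
    }
    tracks_objs <- stats::setNames(
      lapply(retained, function(s) read_counts(file.path(counts_dir, paste0(s, ".mcbc")))),
      retained)
    log_stage("bin", counts_dir)
  }

  feature_dir <- file.path(out, "features")
  fmatrices <- NULL
  load_fmatrices <- function() {
    if (!is.null(fmatrices)) return(fmatrices)
    if (length(config$features) == 0L) return(list())
    tr <- load_tracks()
    fms <- lapply(names(config$features), function(cl) {
      fs <- read_features(config$features[[cl]], cl)
      validate_features(fs, genome)
      extract_feature_counts(tr, fs, groups = groups)
    })
    stats::setNames(fms, names(config$features))
  }

  if ("features" %in% stages && length(config$features)) {
    dir.create(feature_dir, showWarnings = FALSE)
    tracks_objs <- tracks_objs %||% load_tracks()
    fmatrices <- load_fmatrices()
    outs <- vapply(names(fmatrices), function(cl) {
      p <- file.path(feature_dir, paste0(cl, "_matrix.tsv"))
      fm <- fmatrices[[cl]]
      write_tsv_quiet(data.frame(locus = rownames(fm$values), fm$values,
                                 check.names = FALSE), p, provenance)
      s <- aggregate_feature_summary(fm)
      write_tsv_quiet(s$samples, file.path(feature_dir, paste0(cl, "_sample_summary.tsv")))
      p
    }, character(1))
    log_stage("features", outs)
  }

  if ("diff" %in% stages && length(config$features)) {
    diff_dir <- file.path(out, "diff")
    dir.create(diff_dir, showWarnings = FALSE)
    fmatrices <- fmatrices %||% load_fmatrices()
    outs <- vapply(names(fmatrices), function(cl) {
      res <- differential_features(fmatrices[[cl]], alpha = config$alpha)
      p <- file.path(diff_dir, paste0(cl, "_diffmeth.tsv"))
      write_tsv_quiet(as_tibble(res), p, provenance)
      p
    }, character(1))
    log_stage("diff", outs)
  }

  if ("gmi" %in% stages) {
    gmi_dir <- file.path(out, "gmi")
    dir.create(gmi_dir, showWarnings = FALSE)
    tracks_objs <- tracks_objs %||% load_tracks()
    classes <- classify_bins(genome, cpg_idx, bin_size = config$bin_size,
                             cap = config$gmi_cap)
    dists <- lapply(tracks_objs, methylation_distribution, classes = classes)
    write_distributions(dists, file.path(gmi_dir, "distributions.tsv"))
    gt <- gmi_table(tracks_objs, classes, groups = groups)
    write_tsv_quiet(gt, file.path(gmi_dir, "gmi.tsv"), provenance)
    outs <- file.path(gmi_dir, c("distributions.tsv", "gmi.tsv"))
    if (length(unique(gt$group)) == 2L && all(table(gt$group) >= 2L)) {
      cmp <- compare_gmi(gt)
      write_tsv_quiet(glance(cmp), file.path(gmi_dir, "gmi_test.tsv"))
      outs <- c(outs, file.path(gmi_dir, "gmi_test.tsv"))
    }
    log_stage("gmi", outs)
  }

  if ("cluster" %in% stages && length(config$features)) {
    cl_dir <- file.path(out, "cluster")
    dir.create(cl_dir, showWarnings = FALSE)
    fmatrices <- fmatrices %||% load_fmatrices()
    dends <- list()
    outs <- character(0)
    for (cl in names(fmatrices)) {
      fm <- filter_loci(fmatrices[[cl]], config$min_avg_rpm, config$min_cv)
      if (nrow(fm$values) < 2L) next
      if (isTRUE(config$rescale)) fm <- rescale_loci(fm)
      hc <- if (config$bootstrap > 0) {
        bootstrap_support(fm, B = config$bootstrap, seed = config$seed)
      } else {
        hierarchical_cluster(pearson_distance(fm))
      }
      dends[[cl]] <- hc
      nwk <- file.path(cl_dir, paste0(cl, ".nwk"))
      export_newick(hc, nwk)
      export_ordered_matrix(fm, hc, file.path(cl_dir, paste0(cl, "_ordered.tsv")))
      outs <- c(outs, nwk)
    }
    if (length(dends) >= 1L && length(dends[[1L]]$labels) >= 2L) {
      colors <- track_groups(dends[[1L]], k = 2, others = dends[-1L])
      write_tsv_quiet(colors, file.path(cl_dir, "group_colors.tsv"))
      outs <- c(outs, file.path(cl_dir, "group_colors.tsv"))
    }
    log_stage("cluster", outs)
  }

  if ("tracks" %in% stages) {
    tr_dir <- file.path(out, "tracks")
    dir.create(tr_dir, showWarnings = FALSE)
    tracks_objs <- tracks_objs %||% load_tracks()
    readsets <- readsets %||% load_readsets(retained)
    outs <- character(0)
    for (s in retained) {
      bg <- file.path(tr_dir, paste0(s, ".bedGraph"))
      export_bedgraph(tracks_objs[[s]], bg, name = s)
      hm <- export_heatmap_track(tracks_objs[[s]], n_levels = config$n_levels)
      write_heatmap_track(hm, file.path(tr_dir, paste0(s, "_heatmap.tsv")))
      export_read_track(readsets[[s]], file.path(tr_dir, paste0(s, "_reads.tsv")))
      outs <- c(outs, bg)
    }
    log_stage("tracks", outs)
  }

  rep_tbl <- bind_rows(report)
  write_tsv_quiet(rep_tbl, file.path(out, "run_report.tsv"), provenance)
  structure(rep_tbl, excluded = excluded, out_dir = out,
            class = c("mc_pipeline", class(rep_tbl)))
}

#' @export
print.mc_pipeline <- function(x, ...) {
  cat(sprintf("<mc_pipeline> %d stage(s) under %s; excluded: %s\n",
              nrow(x), attr(x, "out_dir"),
              if (length(attr(x, "excluded"))) paste(attr(x, "excluded"),
                                                     collapse = ", ") else "none"))
  NextMethod()
}
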