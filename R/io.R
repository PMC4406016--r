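# On-disk formats and the umbrella pipeline runner.
# Conventions: probe tables and gene annotations use 0-based half-open
# coordinates (BED dialect); SEG output converts to 1-based inclusive at the
# boundary. All tables are plain TSV/CSV.

#' Read a probe-level copy-number table
#'
#' TSV with header columns probe, chrom, start, end followed by one column
#' of raw log2 ratios per sample. Coordinates are validated (start < end),
#' duplicate probe ids are a hard error, unsorted input is sorted with a
#' warning, and per-sample missing counts are logged in the cohort QC slot.
#'
#' @param path file path.
#' @param thresholds [state_thresholds()] stored on the cohort.
#' @return a `cna_cohort` of raw ratios (one profile per sample column).
#' @export
read_probe_table <- function(path, thresholds = state_thresholds()) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c("probe", "chrom", "start", "end")
  assert_that(all(need %in% names(d)),
              "probe table needs columns probe, chrom, start, end")
  assert_that(ncol(d) > 4, "probe table needs at least one sample column")
  if (!is.numeric(d$start) || !is.numeric(d$end))
    stop("non-numeric coordinates in probe table")
  bad <- which(d$start >= d$end)
  if (length(bad))
    stop("probe rows with start >= end at line(s): ",
         paste(bad + 1, collapse = ", "))
  dup <- d$probe[duplicated(d$probe)]
  if (length(dup))
    stop("duplicated probe id(s): ", paste(unique(dup), collapse = ", "))
  o <- order(d$chrom, d$start)
  if (!identical(o, seq_len(nrow(d)))) {
    warning("probe table was not sorted by (chrom, start); sorting",
            call. = FALSE)
    d <- d[o, , drop = FALSE]
  }
  grid <- d[, need]
  rownames(grid) <- NULL
  ratio <- as.matrix(d[, setdiff(names(d), need), drop = FALSE])
  rownames(ratio) <- grid$probe
  x <- cna_cohort(grid, ratio, thresholds)
  x$qc$missing_per_sample <- colSums(!is.finite(ratio))
  x
}

#' Write a probe-level table (raw or cbs ratios)
#' @param x a `cna_cohort`.
#' @param path output file.
#' @param what `"ratio"`, `"cbs"` or `"state"` matrix to write.
#' @export
write_probe_table <- function(x, path, what = c("ratio", "cbs", "state")) {
  what <- match.arg(what)
  m <- x[[what]]
  if (is.null(m)) stop("cohort has no ", what, " matrix")
  d <- cbind(x$grid, as.data.frame(m))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write segments in SEG format (1-based inclusive coordinates)
#' @param x a segmented `cna_cohort`.
#' @param path output file.
#' @export
write_seg <- function(x, path) {
  if (is.null(x$seg)) stop("cohort is not segmented")
  rows <- lapply(sample_ids(x), function(s) {
    tb <- segments_table(x, s)
    if (nrow(tb) == 0) return(NULL)
    data.frame(sample = s, chrom = tb$chrom, start = tb$start + 1,
               end = tb$end, n_probes = tb$n_probes, seg_mean = tb$seg_mean)
  })
  d <- do.call(rbind, rows)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with columns sample, timepoint, ki67_baseline, ki67_2wk. The decrease
#' and responder flag are derived via [classify_responder()]; rows with a
#' missing 2-week value are retained with an undefined flag. Negative Ki67
#' is a hard error.
#'
#' @param path file path.
#' @return data.frame with derived response columns.
#' @export
read_clinical <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("sample", "ki67_baseline", "ki67_2wk")
  assert_that(all(need %in% names(d)),
              "clinical table needs sample, ki67_baseline, ki67_2wk")
  classify_responder(d)
}

#' Write a clinical table (CSV)
#' @param clinical data.frame.
#' @param path output file.
#' @export
write_clinical <- function(clinical, path) {
  write.table(clinical, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation in BED dialect
#'
#' Tab-separated, 0-based half-open: chrom, start, end, gene_id and
#' optionally symbol (no header, or a header line starting with "chrom").
#'
#' @param path file path.
#' @return validated gene annotation data.frame.
#' @export
read_gene_bed <- function(path) {
  first <- readLines(path, n = 1)
  header <- startsWith(first, "chrom")
  d <- read.table(path, header = header, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!header) {
    names(d)[1:4] <- c("chrom", "start", "end", "gene_id")
    if (ncol(d) >= 5) names(d)[5] <- "symbol"
  }
  gene_annotation(d)
}

#' Write a gene annotation in BED dialect
#' @param genes annotation data.frame.
#' @param path output file.
#' @export
write_gene_bed <- function(genes, path) {
  cols <- intersect(c("chrom", "start", "end", "gene_id", "symbol"),
                    names(genes))
  write.table(genes[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (TSV, first column gene_id)
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write an expression matrix (TSV)
#' @param expr matrix, genes x samples.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a model fold-change table (TSV: gene_id, fold_change)
#' @param path file path.
#' @return data.frame.
#' @export
read_foldchange <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  assert_that(all(c("gene_id", "fold_change") %in% names(d)),
              "fold-change table needs gene_id, fold_change")
  if (any(d$fold_change <= 0, na.rm = TRUE))
    stop("fold changes must be positive")
  d
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline stages. Unknown keys are rejected,
#' and each value is validated by its owning constructor.
#'
#' @param thresholds [state_thresholds()].
#' @param alpha,min_width,n_perm segmentation parameters.
#' @param pattern [pattern_params()].
#' @param q_threshold,min_group,min_samples,gap_probes,gap_bp,min_fc
#'   integration parameters.
#' @param margin,min_probes paired-analysis parameters.
#' @param seed integer master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = state_thresholds(),
                            alpha = 0.01, min_width = 3, n_perm = 200,
                            pattern = pattern_params(),
                            q_threshold = 0.05, min_group = 3,
                            min_samples = 10, gap_probes = 2, gap_bp = 1e6,
                            min_fc = 1.5, margin = 0.05, min_probes = 3,
                            seed = 1L) {
  stopifnot(inherits(thresholds, "state_thresholds"),
            inherits(pattern, "pattern_params"),
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' `thresholds` and `pattern` blocks mirror [state_thresholds()] and
#' [pattern_params()]. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)),
                   c("thresholds", "pattern"))
  unknown <- setdiff(names(y), c(known, "thresholds", "pattern"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$thresholds)) {
    bad <- setdiff(names(y$thresholds), names(formals(state_thresholds)))
    if (length(bad)) stop("unknown thresholds key(s): ",
                          paste(bad, collapse = ", "))
    args$thresholds <- do.call(state_thresholds, y$thresholds)
  }
  if (!is.null(y$pattern)) {
    bad <- setdiff(names(y$pattern), names(formals(pattern_params)))
    if (length(bad)) stop("unknown pattern key(s): ",
                          paste(bad, collapse = ", "))
    args$pattern <- do.call(pattern_params, y$pattern)
  }
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  y <- unclass(config)
  y$thresholds <- unclass(y$thresholds)
  y$pattern <- unclass(y$pattern)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Hash of the effective configuration
#' @param config a `pipeline_config`.
#' @return md5 string; changes iff any effective parameter changes.
#' @export
config_hash <- function(config) {
  object_md5(lapply(unclass(config), unclass))
}

#' Run the full pipeline on files or in-memory inputs
#'
#' Stage order: segment, call states, instability metrics and pattern
#' classification, integrative screen (when expression + clinical + genes
#' are given), paired analysis (when a post-treatment table is given).
#' Every output lands in `out_dir`; `report.json` records the config hash,
#' seed and per-stage counts. Identical inputs, config and seed produce a
#' byte-identical bundle.
#'
#' @param cn probe table path or `cna_cohort` (pre-treatment / baseline).
#' @param out_dir output directory (created).
#' @param expr,clinical,genes,foldchange optional paths or objects for the
#'   integrative screen.
#' @param post optional probe table path or cohort of matched post-treatment
#'   samples (columns aligned pair-wise with `cn`).
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the stage results and `bundle_hash`.
#' @export
run_pipeline <- function(cn, out_dir, expr = NULL, clinical = NULL,
                         genes = NULL, foldchange = NULL, post = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  load_cn <- function(obj) {
    if (inherits(obj, "cna_cohort")) { obj$thresholds <- config$thresholds; obj }
    else read_probe_table(obj, config$thresholds)
  }
  counts <- list()
  cohort <- stage("read", load_cn(cn))
  counts$samples <- ncol(cohort$ratio)

  cohort <- stage("segment",
    segment_cohort(cohort, config$alpha, config$min_width, config$n_perm,
                   seed = config$seed))
  cohort <- stage("call_states", call_states(cohort))
  write_seg(cohort, file.path(out_dir, "segments.seg"))
  write_probe_table(cohort, file.path(out_dir, "states.tsv"), "state")

  pga <- stage("metrics", proportion_genome_altered(cohort))
  write.table(data.frame(sample = names(pga), pga = pga),
              file.path(out_dir, "pga.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  freq <- frequency_plot_table(cohort)
  write.table(freq, file.path(out_dir, "frequency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  calls <- stage("classify_pattern", classify_pattern(cohort, config$pattern))
  write.table(calls, file.path(out_dir, "patterns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts$patterns <- as.list(table(calls$label))

  integration <- NULL
  if (!is.null(expr) || !is.null(clinical) || !is.null(genes)) {
    stage("integrate", {
      if (is.null(expr)) stop("missing input: expression matrix")
      if (is.null(clinical)) stop("missing input: clinical table")
      if (is.null(genes)) stop("missing input: gene annotation")
      em <- if (is.matrix(expr)) expr else read_expression(expr)
      cl <- if (is.data.frame(clinical)) classify_responder(clinical)
            else read_clinical(clinical)
      ga <- if (is.data.frame(genes)) gene_annotation(genes)
            else read_gene_bed(genes)
      fc <- if (is.null(foldchange)) NULL
            else if (is.data.frame(foldchange)) foldchange
            else read_foldchange(foldchange)
      integration <<- run_integration(
        cohort, em, cl, ga, fc, q_threshold = config$q_threshold,
        min_group = config$min_group, min_samples = config$min_samples,
        gap_probes = config$gap_probes, gap_bp = config$gap_bp,
        min_fc = config$min_fc)
    })
    write.table(integration$branch1, file.path(out_dir, "branch1.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(integration$branch2, file.path(out_dir, "branch2.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(integration$branch3, file.path(out_dir, "branch3.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(integration$loci, file.path(out_dir, "loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(integration$report, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(integration$prioritized))
      write.table(integration$prioritized,
                  file.path(out_dir, "candidates_prioritized.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    counts$genes_tested_branch1 <- sum(!is.na(integration$branch1$p))
    counts$genes_tested_branch2 <- sum(!is.na(integration$branch2$p))
    counts$loci <- nrow(integration$loci)
    counts$candidates <- sum(integration$report$candidate)
  }

  paired <- NULL
  if (!is.null(post)) {
    stage("paired", {
      pc <- load_cn(post)
      pc <- segment_cohort(pc, config$alpha, config$min_width, config$n_perm,
                           seed = config$seed + 1L)
      pc <- call_states(pc)
      gfc <- grouped_frequency_comparison(cohort, pc, config$q_threshold)
      clu <- cluster_matched_cohort(cohort, pc)
      priv <- detect_private_amplicons(cohort, pc, config$min_probes,
                                       config$margin)
      paired <<- list(frequency = gfc, clustering = clu, private = priv)
    })
    write.table(paired$frequency, file.path(out_dir, "paired_frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(paired$clustering$adjacency,
                file.path(out_dir, "paired_adjacency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(paired$private, file.path(out_dir, "private_amplicons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$pairs_adjacent <- paired$clustering$n_adjacent
    counts$private_amplicons <- nrow(paired$private)
  }

  report <- list(config_hash = config_hash(config), seed = config$seed,
                 counts = counts)
  writeLines(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                           pretty = TRUE)),
             file.path(out_dir, "report.json"))
  bundle <- files_md5(list.files(out_dir, full.names = TRUE))
  invisible(list(cohort = cohort, pga = pga, patterns = calls,
                 integration = integration, paired = paired,
                 report = report, bundle_hash = bundle))
}
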