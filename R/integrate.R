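# The integrative screen: map probe-level copy number to genes, then run
# three branches across samples —
#   branch 1: Pearson correlation of gene-level cbs ratio with expression
#             (copy-number-regulated genes);
#   branch 2: Mann-Whitney of expression with amplification as the grouping
#             variable, kept only when the amplified median is higher
#             (overexpressed-when-amplified);
#   branch 3: Spearman correlation of probe-level cbs ratio with the 2-week
#             Ki67 decrease, merged into signed loci —
# and intersect them: a candidate is flagged in branches 1 and 2 and maps
# inside a negative-direction (poor-response) branch-3 locus. An optional
# resistance-model fold-change filter prioritizes the candidates.

#' Validate a gene annotation table
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open), optional symbol; unique ids, start < end.
#' @return the validated, (chrom, start)-sorted data.frame.
#' @export
gene_annotation <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end")
  assert_that(all(need %in% names(genes)),
              "gene annotation needs gene_id, chrom, start, end")
  assert_that(!anyDuplicated(genes$gene_id), "duplicate gene ids")
  assert_that(all(genes$start < genes$end), "genes need start < end")
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}

#' Gene-level summary of a probe-level matrix
#'
#' For each gene, the median over the probes whose (half-open) intervals
#' overlap the gene's interval; genes with no overlapping probe fall back to
#' the nearest probe within `max_nearest_distance` bp (else NA).
#' @noRd
gene_level_matrix <- function(mat, grid, genes, max_nearest_distance = 0) {
  ng <- nrow(genes)
  out <- matrix(NA_real_, ng, ncol(mat),
                dimnames = list(genes$gene_id, colnames(mat)))
  nearest_used <- logical(ng)
  n_probes <- integer(ng)
  if (ng == 0 || nrow(grid) == 0) {
    return(list(values = out, nearest = nearest_used, n_probes = n_probes))
  }
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(grid$chrom == ch)
    if (length(pi) == 0) {
      warning("annotation chromosome absent from probe grid: ", ch,
              call. = FALSE)
      next
    }
    # half-open intervals -> 1-based closed for IRanges
    gr <- IRanges::IRanges(genes$start[gi] + 1, genes$end[gi])
    pr <- IRanges::IRanges(grid$start[pi] + 1, grid$end[pi])
    hits <- IRanges::findOverlaps(gr, pr)
    byg <- split(pi[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    for (k in names(byg)) {
      g <- gi[as.integer(k)]
      rows <- byg[[k]]
      n_probes[g] <- length(rows)
      out[g, ] <- if (length(rows) == 1) mat[rows, ]
        else if (length(rows) == 2) colMeans(mat[rows, , drop = FALSE],
                                             na.rm = TRUE)
        else apply(mat[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    }
    miss <- setdiff(seq_along(gi), as.integer(names(byg)))
    if (length(miss) && max_nearest_distance > 0) {
      nd <- IRanges::distanceToNearest(gr[miss], pr)
      for (j in seq_along(miss)) {
        h <- nd[j]
        if (length(h) == 0) next
        if (S4Vectors::mcols(h)$distance <= max_nearest_distance) {
          g <- gi[miss[j]]
          row <- pi[S4Vectors::subjectHits(h)]
          out[g, ] <- mat[row, ]
          nearest_used[g] <- TRUE
          n_probes[g] <- 1L
        }
      }
    }
  }
  out[!is.finite(out)] <- NA_real_
  list(values = out, nearest = nearest_used, n_probes = n_probes)
}

#' Map probe-level copy number to genes
#'
#' Gene-level cbs ratio = median of the segment-mean log2 ratios of all
#' probes overlapping the gene's genomic interval (half-open overlap); genes
#' in probe deserts fall back to the nearest probe within
#' `max_nearest_distance` (flagged), else stay missing. Gene-level states are
#' called by thresholding the gene-level ratio (not by probe-state vote).
#'
#' @param x a segmented `cna_cohort`.
#' @param genes gene annotation (see [gene_annotation()]).
#' @param max_nearest_distance bp; 0 disables the nearest-probe fallback.
#' @param thresholds optional [state_thresholds()]; defaults to the cohort's.
#' @return a `gene_cn` object: `ratio` and `state` gene x sample matrices,
#'   `genes`, `nearest` flag, `n_probes` per gene.
#' @export
map_probes_to_genes <- function(x, genes, max_nearest_distance = 0,
                                thresholds = NULL) {
  stopifnot(inherits(x, "cna_cohort"))
  if (is.null(x$cbs)) stop("cohort is not segmented")
  genes <- gene_annotation(genes)
  thr <- thresholds %||% x$thresholds
  gm <- gene_level_matrix(x$cbs, x$grid, genes, max_nearest_distance)
  structure(list(ratio = gm$values,
                 state = call_states(gm$values, thr),
                 genes = genes, nearest = gm$nearest,
                 n_probes = gm$n_probes, thresholds = thr),
            class = "gene_cn")
}

#' @export
print.gene_cn <- function(x, ...) {
  cat(sprintf("gene_cn: %d genes x %d samples (%d with no overlapping probe)\n",
              nrow(x$ratio), ncol(x$ratio), sum(rowSums(is.finite(x$ratio)) == 0)))
  invisible(x)
}

#' Align two sample-id sets, erroring below a minimum
#' @noRd
shared_samples <- function(a, b, min_samples, what) {
  sh <- intersect(a, b)
  if (length(sh) < min_samples)
    stop(sprintf("%s: only %d shared samples (minimum %d)", what,
                 length(sh), min_samples), call. = FALSE)
  sh
}

#' Branch 1: copy-number-regulated genes
#'
#' Per-gene Pearson correlation of gene-level cbs ratio with expression
#' across shared samples, BH-adjusted across all tested genes; a gene is
#' flagged when q < `q_threshold`.
#'
#' @param gcn a `gene_cn` from [map_probes_to_genes()].
#' @param expr expression matrix (gene x sample; rownames = gene ids).
#' @param q_threshold BH-adjusted significance threshold.
#' @param min_samples minimum shared samples.
#' @return data.frame (gene_id, r, p, q, n, flag); untested genes (missing
#'   data) carry NA and a reason.
#' @export
copy_number_regulated_genes <- function(gcn, expr, q_threshold = 0.05,
                                        min_samples = 10) {
  stopifnot(inherits(gcn, "gene_cn"))
  sh <- shared_samples(colnames(gcn$ratio), colnames(expr), min_samples,
                       "copy_number_regulated_genes")
  gene_ids <- intersect(rownames(gcn$ratio), rownames(expr))
  cn <- gcn$ratio[gene_ids, sh, drop = FALSE]
  ex <- expr[gene_ids, sh, drop = FALSE]
  r <- p <- rep(NA_real_, length(gene_ids))
  n <- integer(length(gene_ids))
  reason <- rep(NA_character_, length(gene_ids))
  # vectorized Pearson for the complete rows; loop the rest
  complete <- rowSums(!is.finite(cn)) == 0 & rowSums(!is.finite(ex)) == 0
  if (any(complete)) {
    A <- cn[complete, , drop = FALSE]; B <- ex[complete, , drop = FALSE]
    A <- A - rowMeans(A); B <- B - rowMeans(B)
    sa <- rowSums(A^2); sb <- rowSums(B^2)
    ok <- sa > 0 & sb > 0
    rr <- rep(NA_real_, nrow(A))
    rr[ok] <- pmin(1, pmax(-1, rowSums(A * B)[ok] / sqrt(sa[ok] * sb[ok])))
    m <- length(sh)
    tt <- rr * sqrt((m - 2) / pmax(1e-300, 1 - rr^2))
    pp <- ifelse(abs(rr) == 1, 0, 2 * pt(-abs(tt), df = m - 2))
    r[complete] <- rr; p[complete] <- pmin(1, pp)
    n[complete] <- m
    reason[complete][!ok] <- "zero variance"
  }
  for (i in which(!complete)) {
    ok <- is.finite(cn[i, ]) & is.finite(ex[i, ])
    n[i] <- sum(ok)
    if (n[i] < min_samples) { reason[i] <- "too few samples"; next }
    tr <- pearson_test(cn[i, ok], ex[i, ok])
    r[i] <- tr$statistic; p[i] <- tr$p; reason[i] <- tr$reason
  }
  q <- bh_adjust(p)
  data.frame(gene_id = gene_ids, r = r, p = p, q = q, n = n,
             flag = !is.na(q) & q < q_threshold, reason = reason,
             row.names = NULL)
}

#' Branch 2: overexpressed-when-amplified genes
#'
#' Per gene with at least `min_group` amplified and `min_group` non-amplified
#' samples: Mann-Whitney on expression with amplification (gene state = amp)
#' as the grouping variable, BH-adjusted. The flag additionally requires the
#' amplified-group median expression to exceed the non-amplified median
#' (overexpression direction).
#'
#' @inheritParams copy_number_regulated_genes
#' @param min_group minimum samples per amplification group.
#' @return data.frame (gene_id, u, p, q, n_amp, n_other, amp_median_higher,
#'   flag, reason).
#' @export
overexpressed_when_amplified <- function(gcn, expr, min_group = 3,
                                         q_threshold = 0.05) {
  stopifnot(inherits(gcn, "gene_cn"))
  sh <- intersect(colnames(gcn$ratio), colnames(expr))
  gene_ids <- intersect(rownames(gcn$ratio), rownames(expr))
  st <- gcn$state[gene_ids, sh, drop = FALSE]
  ex <- expr[gene_ids, sh, drop = FALSE]
  out <- data.frame(gene_id = gene_ids, u = NA_real_, p = NA_real_,
                    q = NA_real_, n_amp = 0L, n_other = 0L,
                    amp_median_higher = NA, flag = FALSE,
                    reason = NA_character_, row.names = NULL)
  for (i in seq_along(gene_ids)) {
    ok <- !is.na(st[i, ]) & is.finite(ex[i, ])
    amp <- ok & st[i, ] == STATE_CODES[["amp"]]
    oth <- ok & st[i, ] != STATE_CODES[["amp"]]
    out$n_amp[i] <- sum(amp); out$n_other[i] <- sum(oth)
    if (sum(amp) < min_group || sum(oth) < min_group) {
      out$reason[i] <- "group below min_group"
      next
    }
    tr <- mann_whitney_test(ex[i, amp], ex[i, oth])
    out$u[i] <- tr$statistic; out$p[i] <- tr$p
    out$amp_median_higher[i] <- median(ex[i, amp]) > median(ex[i, oth])
  }
  out$q <- bh_adjust(out$p)
  out$flag <- !is.na(out$q) & out$q < q_threshold &
    !is.na(out$amp_median_higher) & out$amp_median_higher
  out
}

#' Branch 3: copy number vs Ki67-response correlation
#'
#' Spearman correlation of the cbs ratio (per probe, or per gene) with the
#' two-week Ki67 decrease (%) across samples, BH-adjusted. A negative rho
#' means higher copy number goes with a smaller Ki67 fall, i.e. poor
#' response.
#'
#' @param x a segmented `cna_cohort` (level `"probe"`) or a `gene_cn`
#'   (level `"gene"`).
#' @param clinical clinical table with columns sample, ki67_baseline,
#'   ki67_2wk (see [classify_responder()]); samples missing the 2-week value
#'   are excluded and counted.
#' @param level `"probe"` or `"gene"`.
#' @param q_threshold BH threshold stored with the result.
#' @param min_samples minimum samples with both data types.
#' @return data.frame (unit id + position columns, rho, p, q, sign,
#'   significant) with attribute `n_excluded`.
#' @export
cn_response_correlation <- function(x, clinical, level = c("probe", "gene"),
                                    q_threshold = 0.05, min_samples = 10) {
  level <- match.arg(level)
  if (level == "probe") {
    stopifnot(inherits(x, "cna_cohort"))
    if (is.null(x$cbs)) stop("cohort is not segmented")
    mat <- x$cbs
    meta <- x$grid
  } else {
    stopifnot(inherits(x, "gene_cn"))
    mat <- x$ratio
    meta <- data.frame(probe = x$genes$gene_id, chrom = x$genes$chrom,
                       start = x$genes$start, end = x$genes$end)
  }
  cl <- classify_responder(clinical)
  usable <- cl$sample[!is.na(cl$ki67_decrease)]
  n_excluded <- nrow(cl) - length(usable)
  sh <- shared_samples(colnames(mat), usable, min_samples,
                       "cn_response_correlation")
  dec <- setNames(cl$ki67_decrease, cl$sample)[sh]
  mat <- mat[, sh, drop = FALSE]
  rho <- p <- rep(NA_real_, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    tr <- spearman_test(mat[i, ], dec)
    rho[i] <- tr$statistic; p[i] <- tr$p
  }
  q <- bh_adjust(p)
  out <- cbind(meta,
               data.frame(rho = rho, p = p, q = q,
                          sign = ifelse(is.na(rho), NA, sign(rho)),
                          significant = !is.na(q) & q < q_threshold,
                          row.names = NULL))
  attr(out, "n_excluded") <- n_excluded
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Merge significant response-associated probes into loci
#'
#' Maximal runs of significant probes of one sign within a chromosome,
#' tolerating up to `gap_probes` interleaved non-significant probes provided
#' the genomic gap stays within `gap_bp`. Genes are assigned to a locus by
#' full interval containment.
#'
#' @param probe_results probe-level output of [cn_response_correlation()].
#' @param gap_probes maximum non-significant probes bridged inside a locus.
#' @param gap_bp maximum genomic span (bp) of a bridged gap.
#' @param genes optional gene annotation for containment assignment.
#' @return data.frame (locus, chrom, start, end, direction, n_probes,
#'   best_q, genes) where `genes` is a comma-separated id list.
#' @export
merge_significant_loci <- function(probe_results, gap_probes = 2,
                                   gap_bp = 1e6, genes = NULL) {
  pr <- probe_results
  loci <- list()
  for (ch in unique(pr$chrom)) {
    d <- pr[pr$chrom == ch, , drop = FALSE]
    sig <- which(d$significant)
    if (!length(sig)) next
    cur <- sig[1]
    runs <- list()
    for (i in sig[-1]) {
      last <- cur[length(cur)]
      same_sign <- d$sign[i] == d$sign[last]
      gapn <- i - last - 1
      gapw <- d$start[i] - d$end[last]
      if (same_sign && gapn <= gap_probes && gapw <= gap_bp) {
        cur <- c(cur, i)
      } else {
        runs[[length(runs) + 1]] <- cur
        cur <- i
      }
    }
    runs[[length(runs) + 1]] <- cur
    for (rr in runs) {
      loci[[length(loci) + 1]] <- data.frame(
        chrom = ch, start = d$start[rr[1]], end = d$end[rr[length(rr)]],
        direction = d$sign[rr[1]], n_probes = length(rr),
        best_q = min(d$q[rr], na.rm = TRUE))
    }
  }
  if (!length(loci))
    return(data.frame(locus = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      direction = numeric(), n_probes = integer(),
                      best_q = numeric(), genes = character()))
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus = seq_len(nrow(out)), out)
  out$genes <- ""
  if (!is.null(genes)) {
    genes <- gene_annotation(genes)
    for (k in seq_len(nrow(out))) {
      inside <- genes$chrom == out$chrom[k] &
        genes$start >= out$start[k] & genes$end <= out$end[k]
      out$genes[k] <- paste(genes$gene_id[inside], collapse = ",")
    }
  }
  rownames(out) <- NULL
  out
}

#' Ki67-based responder classification
#'
#' decrease% = 100 (baseline - 2wk) / baseline; a responder is a case whose
#' Ki67 falls by strictly more than 50% at 2 weeks (a fall of exactly 50% is
#' a non-responder). Zero baselines or missing 2-week values give an
#' undefined flag with a recorded reason.
#'
#' @param clinical data.frame with columns sample, ki67_baseline, ki67_2wk
#'   (non-negative), or two numeric vectors via `ki67_2wk`.
#' @param ki67_2wk when `clinical` is a numeric baseline vector, the matching
#'   2-week values.
#' @return the clinical table with added ki67_decrease, responder,
#'   responder_reason columns.
#' @export
classify_responder <- function(clinical, ki67_2wk = NULL) {
  if (is.numeric(clinical)) {
    clinical <- data.frame(sample = seq_along(clinical),
                           ki67_baseline = clinical, ki67_2wk = ki67_2wk)
  }
  need <- c("sample", "ki67_baseline", "ki67_2wk")
  assert_that(all(need %in% names(clinical)),
              "clinical table needs sample, ki67_baseline, ki67_2wk")
  if (any(clinical$ki67_baseline < 0 | clinical$ki67_2wk < 0, na.rm = TRUE))
    stop("Ki67 values must be non-negative")
  base <- clinical$ki67_baseline
  two <- clinical$ki67_2wk
  dec <- 100 * (base - two) / base
  reason <- rep(NA_character_, nrow(clinical))
  bad_base <- is.na(base) | base == 0
  reason[bad_base] <- "baseline missing or zero"
  reason[!bad_base & is.na(two)] <- "missing 2-week value"
  dec[bad_base] <- NA_real_
  clinical$ki67_decrease <- dec
  clinical$responder <- ifelse(is.na(dec), NA, dec > 50)
  clinical$responder_reason <- reason
  clinical
}

#' Intersect the three branches into a candidate report
#'
#' A candidate gene is flagged in branch 1 (copy-number-regulated) and
#' branch 2 (overexpressed-when-amplified), and maps inside a branch-3 locus
#' whose direction corresponds to poor response (negative rho: higher copy
#' number, smaller Ki67 fall). Full per-gene evidence is retained.
#'
#' @param branch1 output of [copy_number_regulated_genes()].
#' @param branch2 output of [overexpressed_when_amplified()].
#' @param loci output of [merge_significant_loci()] (with gene assignment).
#' @param poor_response_direction locus direction that marks poor response.
#' @return a `candidate_report` data.frame with per-branch statistics, flags
#'   and the intersection membership.
#' @export
intersect_candidates <- function(branch1, branch2, loci,
                                 poor_response_direction = -1) {
  gene_ids <- union(branch1$gene_id, branch2$gene_id)
  if (!length(gene_ids)) stop("empty gene universe")
  poor_loci <- loci[!is.na(loci$direction) &
                      loci$direction == poor_response_direction, ,
                    drop = FALSE]
  loci_genes <- unique(unlist(strsplit(paste(poor_loci$genes, collapse = ","),
                                       ",")))
  loci_genes <- loci_genes[nzchar(loci_genes)]
  b1 <- branch1[match(gene_ids, branch1$gene_id), ]
  b2 <- branch2[match(gene_ids, branch2$gene_id), ]
  out <- data.frame(
    gene_id = gene_ids,
    r = b1$r, r_q = b1$q, branch1 = !is.na(b1$flag) & b1$flag,
    u = b2$u, u_q = b2$q, amp_freq = b2$n_amp / pmax(1, b2$n_amp + b2$n_other),
    branch2 = !is.na(b2$flag) & b2$flag,
    branch3 = gene_ids %in% loci_genes,
    row.names = NULL)
  out$candidate <- out$branch1 & out$branch2 & out$branch3
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf(paste0("candidate_report: %d genes; branch1 %d, branch2 %d, ",
                     "branch3 %d, candidates %d\n"),
              nrow(x), sum(x$branch1), sum(x$branch2), sum(x$branch3),
              sum(x$candidate)))
  if (any(x$candidate))
    cat("  candidates:", paste(x$gene_id[x$candidate], collapse = ", "), "\n")
  invisible(x)
}

#' Resistance-model prioritization filter
#'
#' Retains candidates whose expression fold change in a resistance model
#' (e.g. a long-term estrogen-deprived line over its parental line) is at
#' least `min_fc`. Candidates absent from the table are kept with a
#' no-model-data flag by default, or dropped.
#'
#' @param report a `candidate_report`.
#' @param foldchange data.frame (gene_id, fold_change), ratios > 0.
#' @param min_fc minimum fold change.
#' @param missing_action `"keep"` (flagged) or `"drop"`.
#' @return the report restricted to candidates, with `fold_change`,
#'   `model_upregulated` and `no_model_data` columns.
#' @export
model_prioritization_filter <- function(report, foldchange, min_fc = 1.5,
                                        missing_action = c("keep", "drop")) {
  missing_action <- match.arg(missing_action)
  assert_that(all(c("gene_id", "fold_change") %in% names(foldchange)),
              "foldchange table needs gene_id, fold_change")
  if (any(foldchange$fold_change <= 0, na.rm = TRUE))
    stop("fold changes must be positive")
  cand <- report[report$candidate, , drop = FALSE]
  fc <- foldchange$fold_change[match(cand$gene_id, foldchange$gene_id)]
  cand$fold_change <- fc
  cand$no_model_data <- is.na(fc)
  cand$model_upregulated <- !is.na(fc) & fc >= min_fc
  keep <- cand$model_upregulated | (cand$no_model_data &
                                      missing_action == "keep")
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse multi-probe expression rows to genes
#'
#' When several expression probes map to one gene, keep the probe with the
#' largest variance (default) or average them.
#'
#' @param expr expression matrix with one row per probe.
#' @param gene_ids gene id for every row.
#' @param method `"max_var"` or `"mean"`.
#' @return matrix with one row per gene.
#' @export
collapse_expression <- function(expr, gene_ids,
                                method = c("max_var", "mean")) {
  method <- match.arg(method)
  stopifnot(nrow(expr) == length(gene_ids))
  idx <- split(seq_len(nrow(expr)), gene_ids)
  rows <- t(vapply(idx, function(i) {
    if (method == "mean") colMeans(expr[i, , drop = FALSE])
    else expr[i[which.max(apply(expr[i, , drop = FALSE], 1, var))], ]
  }, numeric(ncol(expr))))
  colnames(rows) <- colnames(expr)
  rows
}

#' Run the full integrative screen
#'
#' Convenience wrapper: maps probes to genes, runs the three branches, merges
#' branch-3 loci, intersects, and (optionally) applies the model filter.
#'
#' @param cohort a segmented, state-called `cna_cohort`.
#' @param expr expression matrix (genes x samples).
#' @param clinical clinical table (see [classify_responder()]).
#' @param genes gene annotation.
#' @param foldchange optional model fold-change table.
#' @param q_threshold BH threshold used by every branch.
#' @param min_group branch-2 minimum group size.
#' @param min_samples branch-1/3 minimum shared samples.
#' @param gap_probes,gap_bp branch-3 locus-merge tolerances.
#' @param min_fc model-filter fold-change threshold.
#' @param max_nearest_distance probe->gene fallback distance (bp).
#' @return a `cna_integration` list: `gene_cn`, `branch1`, `branch2`,
#'   `branch3`, `loci`, `report`, `prioritized` (NULL without a fold-change
#'   table), `params`.
#' @export
run_integration <- function(cohort, expr, clinical, genes,
                            foldchange = NULL, q_threshold = 0.05,
                            min_group = 3, min_samples = 10,
                            gap_probes = 2, gap_bp = 1e6, min_fc = 1.5,
                            max_nearest_distance = 0) {
  gcn <- map_probes_to_genes(cohort, genes, max_nearest_distance)
  b1 <- copy_number_regulated_genes(gcn, expr, q_threshold, min_samples)
  b2 <- overexpressed_when_amplified(gcn, expr, min_group, q_threshold)
  b3 <- cn_response_correlation(cohort, clinical, "probe", q_threshold,
                                min_samples)
  loci <- merge_significant_loci(b3, gap_probes, gap_bp, genes)
  report <- intersect_candidates(b1, b2, loci)
  pri <- if (!is.null(foldchange))
    model_prioritization_filter(report, foldchange, min_fc) else NULL
  structure(list(gene_cn = gcn, branch1 = b1, branch2 = b2, branch3 = b3,
                 loci = loci, report = report, prioritized = pri,
                 params = list(q_threshold = q_threshold,
                               min_group = min_group,
                               min_samples = min_samples,
                               gap_probes = gap_probes, gap_bp = gap_bp,
                               min_fc = min_fc)),
            class = "cna_integration")
}

#' @export
print.cna_integration <- function(x, ...) {
  cat("integrative copy-number / expression / Ki67 screen\n")
  cat(sprintf("  branch 1 (CN-regulated):            %d genes flagged\n",
              sum(x$branch1$flag, na.rm = TRUE)))
  cat(sprintf("  branch 2 (overexpressed-when-amp):  %d genes flagged\n",
              sum(x$branch2$flag, na.rm = TRUE)))
  cat(sprintf("  branch 3 (CN vs dKi67):             %d loci (%d poor-response)\n",
              nrow(x$loci), sum(x$loci$direction == -1)))
  print(x$report)
  invisible(x)
}
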