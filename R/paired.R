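# Matched pre/post-treatment comparisons: per-probe McNemar tests of
# aberration frequency, Ward clustering of the pooled categorical states,
# and detection of amplicons private to one member of a pair.

#' @noRd
check_pairing <- function(pre, post) {
  stopifnot(inherits(pre, "cna_cohort"), inherits(post, "cna_cohort"))
  if (!identical(pre$grid, post$grid))
    stop("pre and post cohorts must share one probe grid")
  if (ncol(pre$ratio) != ncol(post$ratio))
    stop("pre and post cohorts must have the same number of samples")
  invisible(TRUE)
}

#' Grouped per-probe frequency comparison of matched pairs
#'
#' For every probe and aberration class (gain-or-amp, loss, amp-only), an
#' exact McNemar test (two-sided binomial on the discordant pairs) of
#' whether the aberration is more frequent pre- than post-treatment,
#' BH-adjusted across all performed tests. Probes with zero discordant pairs
#' in a class carry NA (the paired test is undefined there) and do not enter
#' the adjustment.
#'
#' @param pre,post state-called `cna_cohort`s on the same grid, columns
#'   aligned pair-wise.
#' @param q_threshold BH significance threshold.
#' @param min_pairs minimum number of pairs required.
#' @return data.frame (probe, chrom, start, end, class, n_pre_only,
#'   n_post_only, p, q, significant) with attribute `n_significant`.
#' @export
grouped_frequency_comparison <- function(pre, post, q_threshold = 0.05,
                                         min_pairs = 5) {
  check_pairing(pre, post)
  if (is.null(pre$state) || is.null(post$state))
    stop("states not called on both cohorts")
  n_pairs <- ncol(pre$ratio)
  if (n_pairs < min_pairs)
    stop(sprintf("need at least %d pairs (got %d)", min_pairs, n_pairs))
  classes <- list(gain = function(s) !is.na(s) & s >= 1,
                  loss = function(s) !is.na(s) & s <= -1,
                  amp  = function(s) !is.na(s) & s == 2)
  out <- list()
  for (cl in names(classes)) {
    a <- classes[[cl]](pre$state)
    b <- classes[[cl]](post$state)
    pre_only <- rowSums(a & !b)
    post_only <- rowSums(!a & b)
    disc <- pre_only + post_only
    p <- rep(NA_real_, nrow(pre$grid))
    test <- which(disc > 0)
    for (i in test)
      p[i] <- binom.test(pre_only[i], disc[i], 0.5)$p.value
    out[[cl]] <- cbind(pre$grid,
                       data.frame(class = cl, n_pre_only = pre_only,
                                  n_post_only = post_only, p = p,
                                  row.names = NULL))
  }
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  res$significant <- !is.na(res$q) & res$q < q_threshold
  rownames(res) <- NULL
  attr(res, "n_significant") <- sum(res$significant)
  res
}

#' Ward clustering of a matched cohort with pair-adjacency summary
#'
#' Clusters all 2n samples on their encoded categorical states
#' (loss = -1, NC = 0, gain = +1, amp = +2) with Euclidean/Ward
#' ([ward_cluster()]), and reports per pair whether its two members merge
#' with each other before either merges with any other sample (i.e. form a
#' two-leaf cluster).
#'
#' @param pre,post state-called `cna_cohort`s, columns aligned pair-wise.
#' @return list: `tree` (hclust), `adjacency` (data.frame pair, pre, post,
#'   adjacent), `n_adjacent`.
#' @export
cluster_matched_cohort <- function(pre, post) {
  check_pairing(pre, post)
  if (is.null(pre$state) || is.null(post$state))
    stop("states not called on both cohorts")
  n_pairs <- ncol(pre$ratio)
  if (n_pairs < 2) stop("need at least 2 pairs")
  X <- t(cbind(pre$state, post$state))
  X[is.na(X)] <- 0
  tree <- ward_cluster(X)
  # a pair is adjacent when its two leaves merge as singletons
  leaf_pairs <- tree$merge[tree$merge[, 1] < 0 & tree$merge[, 2] < 0, ,
                           drop = FALSE]
  adjacent <- logical(n_pairs)
  for (p in seq_len(n_pairs)) {
    i <- p; j <- n_pairs + p    # column positions of the pair's members
    adjacent[p] <- any(leaf_pairs[, 1] == -min(i, j) &
                         leaf_pairs[, 2] == -max(i, j) |
                       leaf_pairs[, 1] == -max(i, j) &
                         leaf_pairs[, 2] == -min(i, j))
  }
  list(tree = tree,
       adjacency = data.frame(pair = seq_len(n_pairs),
                              pre = colnames(pre$ratio),
                              post = colnames(post$ratio),
                              adjacent = adjacent),
       n_adjacent = sum(adjacent))
}

#' Detect amplicons private to one member of a matched pair
#'
#' An amplified run (>= `min_probes` consecutive amplification-state probes)
#' in one member is reported as private when the other member's mean cbs
#' ratio over the same interval stays below `gain_min - margin`; the margin
#' guards against near-threshold artifacts where both samples straddle the
#' cutoff. Symmetric over members; descriptive (no per-event p-value).
#'
#' @param pre,post state-called `cna_cohort`s, columns aligned pair-wise.
#' @param min_probes minimum probes in an amplified run.
#' @param margin log2-ratio guard below the gain threshold.
#' @return data.frame (pair, member, chrom, start, end, n_probes, peak_cbs,
#'   other_mean_cbs).
#' @export
detect_private_amplicons <- function(pre, post, min_probes = 3,
                                     margin = 0.05) {
  check_pairing(pre, post)
  if (is.null(pre$state) || is.null(post$state))
    stop("states not called on both cohorts")
  gain_min <- pre$thresholds$gain_min
  out <- list()
  scan <- function(self, other, member, p) {
    runs <- amplicon_census(self, p, max_width = Inf)
    runs <- runs[runs$n_probes >= min_probes, , drop = FALSE]
    for (k in seq_len(nrow(runs))) {
      ii <- which(self$grid$chrom == runs$chrom[k] &
                    self$grid$start >= runs$start[k] &
                    self$grid$end <= runs$end[k])
      other_mean <- mean(other$cbs[ii, p], na.rm = TRUE)
      if (is.finite(other_mean) && other_mean < gain_min - margin) {
        out[[length(out) + 1]] <<- data.frame(
          pair = p, member = member, chrom = runs$chrom[k],
          start = runs$start[k], end = runs$end[k],
          n_probes = runs$n_probes[k], peak_cbs = runs$peak_cbs[k],
          other_mean_cbs = other_mean)
      }
    }
  }
  for (p in seq_len(ncol(pre$ratio))) {
    scan(pre, post, "pre", p)
    scan(post, pre, "post", p)
  }
  if (!length(out))
    return(data.frame(pair = integer(), member = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      n_probes = integer(), peak_cbs = numeric(),
                      other_mean_cbs = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
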