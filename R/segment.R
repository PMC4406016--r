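# Simplified circular binary segmentation of each chromosome's ordered log2
# ratios: recursively accept the changepoint pair ("arc" vs its complement
# within the current window) maximising the pooled two-sample |t|, whenever
# its permutation p-value falls below alpha. A boundary arc degenerates to a
# single binary split. No wrap across window boundaries and no prune/undo
# step; the interface is pluggable so a full CBS implementation can be
# substituted.

#' Segment one chromosome's ratio vector (C++ core)
#'
#' @param y numeric vector of log2 ratios in genomic order (no NAs).
#' @param alpha significance level for accepting a split.
#' @param min_width minimum probes per segment.
#' @param n_perm permutations for the split p-value.
#' @return integer vector of 1-based segment end indices.
#' @export
cbs_segment <- function(y, alpha = 0.01, min_width = 3, n_perm = 200) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 100)
    warning("n_perm < 100: permutation p-values are coarse", call. = FALSE)
  if (length(y) == 0) return(integer(0))
  .cbs_segment_ends(y, alpha, as.integer(min_width), as.integer(n_perm))
}

#' Reference R implementation of the same segmentation (slow path)
#'
#' Kept as an independently coded route for verification; identical split
#' criterion, full (non-early-stopping) permutation loop.
#' @inheritParams cbs_segment
#' @return integer vector of 1-based segment end indices.
#' @export
cbs_segment_r <- function(y, alpha = 0.01, min_width = 3, n_perm = 200) {
  stopifnot(all(is.finite(y)))
  n <- length(y)
  if (n == 0) return(integer(0))
  # max-|t| arc (i, j]: y[(i+1)..j] vs its complement in the window; i = 0
  # or j = m degenerates to a single split. Children must be >= min_width.
  best <- function(v) {
    m <- length(v)
    if (m < 2 * min_width) return(NULL)
    cs <- c(0, cumsum(v)); css <- c(0, cumsum(v^2))
    S <- cs[m + 1]; SS <- css[m + 1]
    out <- list(t = -1)
    for (i in 0:(m - min_width)) {
      if (i != 0 && i < min_width) next
      js <- (i + min_width):m
      js <- js[js == m | m - js >= min_width]
      js <- js[m - (js - i) >= min_width]
      if (!length(js)) next
      n1 <- js - i; n2 <- m - n1
      s1 <- cs[js + 1] - cs[i + 1]; ss1 <- css[js + 1] - css[i + 1]
      m1 <- s1 / n1; m2 <- (S - s1) / n2
      rss <- pmax(0, (ss1 - n1 * m1^2) + ((SS - ss1) - n2 * m2^2))
      t <- ifelse(rss <= 0 | m <= 2,
                  ifelse(m1 == m2, 0, Inf),
                  abs(m1 - m2) / sqrt(rss / (m - 2) * (1 / n1 + 1 / n2)))
      k <- which.max(t)
      if (t[k] > out$t) out <- list(i = i, j = js[k], t = t[k])
    }
    if (out$t < 0) NULL else out
  }
  ends <- integer(0)
  recurse <- function(lo, hi) {  # half-open probe index window
    v <- y[(lo + 1):hi]
    b <- best(v)
    if (!is.null(b) && b$t > 0) {
      exceed <- 0L
      for (k in seq_len(n_perm)) {
        bp <- best(sample(v))
        if (bp$t >= b$t) exceed <- exceed + 1L
      }
      p <- (1 + exceed) / (1 + n_perm)
      if (p < alpha) {
        if (b$i > 0) recurse(lo, lo + b$i)
        recurse(lo + b$i, lo + b$j)
        if (b$j < hi - lo) recurse(lo + b$j, hi)
        return(invisible(NULL))
      }
    }
    ends <<- c(ends, hi)
    invisible(NULL)
  }
  recurse(0L, n)
  sort(ends)
}

#' Segment every sample of a cohort
#'
#' Runs the simplified CBS per chromosome and per sample, assigns each probe a
#' segment id and its segment-mean ("cbs") log2 ratio. Missing ratios are
#' dropped before segmentation (the probe keeps NA segment/cbs) and counted
#' in the cohort QC log; probes missing in more than `qc_missing_frac` of
#' samples are flagged.
#'
#' @param x a `cna_cohort`.
#' @param alpha significance level for accepting a split.
#' @param min_width minimum probes per segment.
#' @param n_perm permutations per split test (values below 100 degrade the
#'   p-value resolution and trigger a warning).
#' @param seed optional integer seed for the permutation RNG.
#' @param qc_missing_frac missingness fraction above which a probe is flagged.
#' @return the cohort with `seg`, `cbs` filled in.
#' @export
segment_cohort <- function(x, alpha = 0.01, min_width = 3, n_perm = 200,
                           seed = NULL, qc_missing_frac = 0.1) {
  stopifnot(inherits(x, "cna_cohort"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 100)
    warning("n_perm < 100: permutation p-values are coarse", call. = FALSE)
  run <- function() {
    P <- nrow(x$grid); S <- ncol(x$ratio)
    seg <- matrix(NA_integer_, P, S, dimnames = dimnames(x$ratio))
    cbs <- matrix(NA_real_, P, S, dimnames = dimnames(x$ratio))
    chrom_idx <- split(seq_len(P), x$grid$chrom)
    # keep genomic order of chromosomes
    chrom_idx <- chrom_idx[order(vapply(chrom_idx, min, 1L))]
    dropped <- integer(S); names(dropped) <- colnames(x$ratio)
    for (s in seq_len(S)) {
      segid <- 0L
      for (ci in chrom_idx) {
        y <- x$ratio[ci, s]
        ok <- is.finite(y)
        dropped[s] <- dropped[s] + sum(!ok)
        yv <- y[ok]
        if (length(yv) == 0) next
        ends <- .cbs_segment_ends(yv, alpha, as.integer(min_width),
                                  as.integer(n_perm))
        starts <- c(1L, head(ends, -1) + 1L)
        pos <- ci[ok]
        for (k in seq_along(ends)) {
          segid <- segid + 1L
          ii <- pos[starts[k]:ends[k]]
          seg[ii, s] <- segid
          cbs[ii, s] <- mean(yv[starts[k]:ends[k]])
        }
      }
    }
    x$seg <- seg
    x$cbs <- cbs
    x$qc$dropped_probes <- dropped
    miss_frac <- rowMeans(!is.finite(x$ratio))
    x$qc$high_missing_probes <- x$grid$probe[miss_frac > qc_missing_frac]
    x$qc$segmentation <- list(alpha = alpha, min_width = min_width,
                              n_perm = n_perm)
    x
  }
  with_seed(seed, run())
}
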