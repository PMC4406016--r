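# Categorical copy-number state calling from segment-mean log2 ratios, plus
# the metrics derived from states: proportion of genome altered, amplicon
# census, cohort frequency tables.

#' Copy-number state thresholds
#'
#' Cutoffs on the segment-mean log2 ratio defining the four categorical
#' states: cbs <= `loss_max` is a loss, cbs >= `amp_min` an amplification,
#' `gain_min` <= cbs < `amp_min` a gain, anything else no change (NC). The
#' defaults mirror common practice for ~32K tiling BAC platforms; they are
#' configuration, not canon.
#'
#' @param loss_max upper log2-ratio bound for a loss (negative).
#' @param gain_min lower bound for a gain (positive).
#' @param amp_min lower bound for an amplification (> gain_min).
#' @return a `state_thresholds` object.
#' @export
state_thresholds <- function(loss_max = -0.12, gain_min = 0.12,
                             amp_min = 0.45) {
  if (!(loss_max < 0 && 0 < gain_min && gain_min < amp_min))
    stop("thresholds must satisfy loss_max < 0 < gain_min < amp_min")
  structure(list(loss_max = loss_max, gain_min = gain_min, amp_min = amp_min),
            class = "state_thresholds")
}

#' Call categorical states from cbs ratios
#'
#' @param x a segmented `cna_cohort`, or a numeric vector/matrix of
#'   segment-mean log2 ratios.
#' @param thresholds a [state_thresholds()] object; for a cohort the stored
#'   thresholds are the default.
#' @return for a cohort, the cohort with `state` filled (integer codes
#'   loss = -1, NC = 0, gain = 1, amp = 2); otherwise an object shaped like
#'   `x` with the codes.
#' @export
call_states <- function(x, thresholds = NULL) {
  if (inherits(x, "cna_cohort")) {
    if (is.null(x$cbs)) stop("cohort is not segmented; run segment_cohort()")
    thr <- thresholds %||% x$thresholds
    x$state <- call_states(x$cbs, thr)
    x$thresholds <- thr
    return(x)
  }
  thr <- thresholds %||% state_thresholds()
  stopifnot(inherits(thr, "state_thresholds"))
  st <- ifelse(x <= thr$loss_max, STATE_CODES[["loss"]],
        ifelse(x >= thr$amp_min, STATE_CODES[["amp"]],
        ifelse(x >= thr$gain_min, STATE_CODES[["gain"]],
               STATE_CODES[["NC"]])))
  storage.mode(st) <- "integer"
  st[!is.finite(x)] <- NA_integer_
  st
}

#' Proportion of the genome altered
#'
#' Fraction of the profiled genome in a non-NC state (losses, gains and
#' amplifications all count as altered), per sample. Probe-count weighting by
#' default (the tiling grid is near-uniform); base-pair weighting optionally.
#' Probes with missing states are excluded from the denominator.
#'
#' @param x a state-called `cna_cohort`.
#' @param weight `"probe"` or `"bp"`.
#' @return named numeric vector in `[0, 1]`, one value per sample.
#' @export
proportion_genome_altered <- function(x, weight = c("probe", "bp")) {
  stopifnot(inherits(x, "cna_cohort"))
  if (is.null(x$state)) stop("states not called; run call_states()")
  if (nrow(x$grid) == 0) stop("empty profile")
  weight <- match.arg(weight)
  w <- if (weight == "probe") rep(1, nrow(x$grid)) else
    (x$grid$end - x$grid$start)
  apply(x$state, 2, function(st) {
    ok <- !is.na(st)
    if (!any(ok)) return(NA_real_)
    sum(w[ok & st != 0]) / sum(w[ok])
  })
}

#' Census of amplified runs in one sample
#'
#' Maximal runs of consecutive amplification-state probes within a
#' chromosome, annotated with genomic span, probe count, peak segment-mean
#' ratio and a focal flag (span <= `max_width`).
#'
#' @param x a state-called `cna_cohort`.
#' @param sample sample id or index.
#' @param max_width focality threshold in base pairs.
#' @return data.frame (chrom, start, end, n_probes, peak_cbs, width, focal).
#' @export
amplicon_census <- function(x, sample, max_width = 20e6) {
  stopifnot(inherits(x, "cna_cohort"))
  if (is.null(x$state)) stop("states not called")
  st <- x$state[, sample]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      peak_cbs = numeric(), width = numeric(),
                      focal = logical())
  amp <- !is.na(st) & st == STATE_CODES[["amp"]]
  if (!any(amp)) return(empty)
  g <- x$grid
  # runs broken at chromosome boundaries or non-amplified probes
  brk <- c(TRUE, g$chrom[-1] != g$chrom[-nrow(g)])
  runid <- cumsum(brk | c(TRUE, diff(amp) != 0))
  keep <- split(which(amp), runid[amp])
  out <- do.call(rbind, lapply(keep, function(i) {
    data.frame(chrom = g$chrom[i[1]], start = g$start[i[1]],
               end = g$end[i[length(i)]], n_probes = length(i),
               peak_cbs = max(x$cbs[i, sample]),
               width = g$end[i[length(i)]] - g$start[i[1]])
  }))
  out$focal <- out$width <= max_width
  rownames(out) <- NULL
  out
}

#' Per-probe aberration frequencies across a cohort
#'
#' For every probe, the fraction of samples gained (gain or amplification),
#' lost, and amplified — the two dialects of a cohort frequency plot (the
#' gain+amp panel and the amplification-only panel).
#'
#' @param x a state-called `cna_cohort` (all samples share the grid by
#'   construction).
#' @return data.frame (probe, chrom, start, end, frac_gain, frac_loss,
#'   frac_amp), fractions among samples with a non-missing state.
#' @export
frequency_plot_table <- function(x) {
  stopifnot(inherits(x, "cna_cohort"))
  if (is.null(x$state)) stop("states not called")
  st <- x$state
  n_ok <- rowSums(!is.na(st))
  fg <- rowSums(st >= 1, na.rm = TRUE) / pmax(1, n_ok)
  fl <- rowSums(st <= -1, na.rm = TRUE) / pmax(1, n_ok)
  fa <- rowSums(st == 2, na.rm = TRUE) / pmax(1, n_ok)
  cbind(x$grid,
        data.frame(frac_gain = fg, frac_loss = fl, frac_amp = fa,
                   row.names = NULL))
}
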