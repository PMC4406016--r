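# The cna_cohort container: one probe grid shared by all samples, plus
# per-probe matrices of raw log2 ratios and (after segmentation / state
# calling) segment ids, segment-mean ("cbs") ratios and categorical states.
# State codes: loss = -1, NC = 0, gain = +1, amplification = +2.

STATE_CODES <- c(loss = -1L, NC = 0L, gain = 1L, amp = 2L)

#' Decode integer state codes to labels
#' @param code integer vector with values in -1, 0, 1, 2 (NA allowed).
#' @return character vector of labels loss/NC/gain/amp.
#' @export
state_labels <- function(code) {
  out <- rep(NA_character_, length(code))
  for (nm in names(STATE_CODES)) out[code == STATE_CODES[[nm]] & !is.na(code)] <- nm
  out
}

#' Validate a probe grid
#' @noRd
validate_grid <- function(grid) {
  need <- c("probe", "chrom", "start", "end")
  assert_that(all(need %in% names(grid)),
              "probe grid needs columns probe, chrom, start, end")
  assert_that(!anyDuplicated(grid$probe), "duplicate probe ids in grid")
  assert_that(all(grid$start < grid$end), "probe intervals need start < end")
  o <- order(grid$chrom, grid$start)
  if (!identical(o, seq_len(nrow(grid))))
    stop("probe grid must be sorted by (chrom, start)")
  invisible(grid)
}

#' Build a copy-number cohort
#'
#' @param grid data.frame with columns probe, chrom, start, end
#'   (0-based half-open coordinates), sorted by (chrom, start).
#' @param ratio numeric matrix of raw log2 ratios, probes x samples; rownames
#'   must match `grid$probe`.
#' @param thresholds a [state_thresholds()] object (stored, applied by
#'   [call_states()]).
#' @return an object of class `cna_cohort`.
#' @export
cna_cohort <- function(grid, ratio, thresholds = state_thresholds()) {
  grid <- as.data.frame(grid)
  validate_grid(grid)
  ratio <- as.matrix(ratio)
  if (nrow(grid) > 0 && nrow(ratio) != nrow(grid))
    stop("ratio matrix rows must match the probe grid")
  if (is.null(rownames(ratio)) && nrow(ratio) > 0)
    rownames(ratio) <- grid$probe
  if (nrow(ratio) > 0)
    assert_that(identical(rownames(ratio), as.character(grid$probe)),
                "ratio rownames must equal grid probe ids, in order")
  if (is.null(colnames(ratio)))
    colnames(ratio) <- sprintf("S%02d", seq_len(ncol(ratio)))
  structure(
    list(grid = grid, ratio = ratio, seg = NULL, cbs = NULL, state = NULL,
         thresholds = thresholds, qc = list()),
    class = "cna_cohort")
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat(sprintf("cna_cohort: %d probes on %d chromosomes, %d sample(s)\n",
              nrow(x$grid), length(unique(x$grid$chrom)), ncol(x$ratio)))
  cat("  segmented:", !is.null(x$cbs), " states called:", !is.null(x$state), "\n")
  invisible(x)
}

#' @export
summary.cna_cohort <- function(object, ...) {
  print(object)
  if (!is.null(object$state)) {
    pga <- proportion_genome_altered(object)
    cat(sprintf("  proportion of genome altered: median %.3f (range %.3f-%.3f)\n",
                median(pga), min(pga), max(pga)))
  }
  invisible(object)
}

#' Number of samples / sample names
#' @param x a `cna_cohort`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$ratio)

#' Per-sample segment table
#'
#' Collapses the per-probe segment assignment of one sample into one row per
#' segment, with genomic span, probe count, segment-mean log2 ratio and (if
#' called) state.
#'
#' @param x a segmented `cna_cohort`.
#' @param sample sample id or index.
#' @return data.frame (chrom, start, end, n_probes, seg_mean, state).
#' @export
segments_table <- function(x, sample) {
  stopifnot(inherits(x, "cna_cohort"))
  if (is.null(x$seg)) stop("cohort is not segmented")
  s <- x$seg[, sample]
  keep <- !is.na(s)
  g <- x$grid[keep, , drop = FALSE]
  sk <- s[keep]
  cb <- x$cbs[keep, sample]
  st <- if (!is.null(x$state)) x$state[keep, sample] else rep(NA_integer_, sum(keep))
  if (nrow(g) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_probes = integer(), seg_mean = numeric(),
                      state = integer()))
  idx <- split(seq_len(nrow(g)), sk)
  idx <- idx[order(vapply(idx, min, 1L))]
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(chrom = g$chrom[i[1]], start = min(g$start[i]),
               end = max(g$end[i]), n_probes = length(i),
               seg_mean = cb[i[1]], state = st[i[1]])
  }))
  rownames(out) <- NULL
  out
}
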