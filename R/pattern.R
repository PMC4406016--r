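# Rule-based operationalization of the Hicks genomic patterns:
#   simplex   — few broad (near whole-chromosome) gains/losses
#   sawtooth  — many narrow alternating gains/losses across most chromosomes
#   firestorm — simplex-like background plus >= 1 focal amplicon
# The verbal criteria come from the pattern taxonomy; every numeric threshold
# here is an explicit, configurable operationalization (non-canonical).

#' Pattern-classification parameters
#'
#' @param broad_fraction fraction of a chromosome's profiled length a segment
#'   must span to count as broad.
#' @param sawtooth_min_segments_per_chrom altered narrow segments a
#'   chromosome needs to count as fragmented.
#' @param sawtooth_chrom_fraction fraction of chromosomes that must be
#'   fragmented for a sawtooth call.
#' @param firestorm_focal_width maximum genomic span (bp) of a focal
#'   amplicon.
#' @param firestorm_min_amp_probes minimum probes in a focal amplicon.
#' @return a `pattern_params` object.
#' @export
pattern_params <- function(broad_fraction = 0.5,
                           sawtooth_min_segments_per_chrom = 5,
                           sawtooth_chrom_fraction = 0.8,
                           firestorm_focal_width = 20e6,
                           firestorm_min_amp_probes = 3) {
  stopifnot(broad_fraction > 0, broad_fraction <= 1,
            sawtooth_chrom_fraction > 0, sawtooth_chrom_fraction <= 1,
            sawtooth_min_segments_per_chrom >= 1,
            firestorm_focal_width > 0, firestorm_min_amp_probes >= 1)
  structure(list(broad_fraction = broad_fraction,
                 sawtooth_min_segments_per_chrom = sawtooth_min_segments_per_chrom,
                 sawtooth_chrom_fraction = sawtooth_chrom_fraction,
                 firestorm_focal_width = firestorm_focal_width,
                 firestorm_min_amp_probes = firestorm_min_amp_probes),
            class = "pattern_params")
}

#' Classify copy-number profiles into genomic patterns
#'
#' Rule order (precedence firestorm > sawtooth > simplex, since a firestorm
#' is a simplex-like profile plus an amplicon):
#' 1. firestorm if the profile carries >= 1 amplified run of at least
#'    `firestorm_min_amp_probes` probes spanning <= `firestorm_focal_width`;
#' 2. else sawtooth if at least `sawtooth_chrom_fraction` of chromosomes each
#'    carry >= `sawtooth_min_segments_per_chrom` altered segments, all
#'    narrower than `broad_fraction` of the chromosome;
#' 3. else simplex.
#'
#' @param x a segmented, state-called `cna_cohort`.
#' @param params a [pattern_params()] object.
#' @return data.frame of class `pattern_calls`: sample, label, and the
#'   evidence behind each rule (focal amplicon count, fragmented-chromosome
#'   fraction, altered segment count).
#' @export
classify_pattern <- function(x, params = pattern_params()) {
  stopifnot(inherits(x, "cna_cohort"), inherits(params, "pattern_params"))
  if (is.null(x$seg)) stop("profile not segmented")
  if (is.null(x$state)) stop("states not called")
  chrom_len <- tapply(x$grid$end, x$grid$chrom, max) -
    tapply(x$grid$start, x$grid$chrom, min)
  n_chrom <- length(chrom_len)
  res <- lapply(sample_ids(x), function(s) {
    segs <- segments_table(x, s)
    segs$width <- segs$end - segs$start
    altered <- segs[segs$state != 0 & !is.na(segs$state), , drop = FALSE]
    # rule 1: focal amplicon
    amps <- amplicon_census(x, s, max_width = params$firestorm_focal_width)
    focal <- amps[amps$focal & amps$n_probes >= params$firestorm_min_amp_probes, ,
                  drop = FALSE]
    # rule 2: fragmentation
    narrow <- altered[altered$width <
                        params$broad_fraction * chrom_len[altered$chrom], ,
                      drop = FALSE]
    broad_by_chrom <- table(factor(altered$chrom[altered$width >=
                          params$broad_fraction * chrom_len[altered$chrom]],
                          levels = names(chrom_len)))
    narrow_by_chrom <- table(factor(narrow$chrom, levels = names(chrom_len)))
    fragmented <- narrow_by_chrom >= params$sawtooth_min_segments_per_chrom &
      broad_by_chrom == 0
    frac_frag <- sum(fragmented) / n_chrom
    label <- if (nrow(focal) > 0) "firestorm"
      else if (frac_frag >= params$sawtooth_chrom_fraction) "sawtooth"
      else "simplex"
    data.frame(sample = s, label = label,
               n_focal_amplicons = nrow(focal),
               n_fragmented_chrom = sum(fragmented),
               frac_fragmented_chrom = frac_frag,
               n_altered_segments = nrow(altered),
               n_broad_altered = nrow(altered) - nrow(narrow))
  })
  out <- do.call(rbind, res)
  class(out) <- c("pattern_calls", "data.frame")
  out
}

#' @export
print.pattern_calls <- function(x, ...) {
  cat("genomic pattern calls:\n")
  print(table(x$label))
  invisible(x)
}

#' Compare a covariate across pattern groups
#'
#' Kruskal-Wallis (default) or, for exactly two groups, Mann-Whitney
#' comparison of a per-sample covariate (e.g. baseline Ki67 or its 2-week
#' decrease) across the pattern labels.
#'
#' @param calls a `pattern_calls` data.frame (or factor/character of labels).
#' @param covariate numeric vector aligned with `calls`.
#' @param test `"kruskal_wallis"` or `"mann_whitney"`.
#' @return a `cna_test` with an added `group_medians` field.
#' @export
pattern_vs_covariate <- function(calls, covariate,
                                 test = c("kruskal_wallis", "mann_whitney")) {
  test <- match.arg(test)
  labels <- if (is.data.frame(calls)) calls$label else as.character(calls)
  stopifnot(length(labels) == length(covariate))
  ok <- !is.na(labels) & is.finite(covariate)
  groups <- split(covariate[ok], labels[ok])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need >= 2 non-empty groups")
  if (any(lengths(groups) < 2)) {
    warning("a group has fewer than 2 members; returning NA", call. = FALSE)
    res <- new_test_result(test, NA_real_, NA_real_, sum(lengths(groups)),
                           reason = "group with < 2 members")
    res$group_medians <- vapply(groups, median, 1.0)
    return(res)
  }
  res <- if (test == "kruskal_wallis") kruskal_wallis_test(groups)
    else {
      if (length(groups) != 2) stop("mann_whitney requires exactly 2 groups")
      mann_whitney_test(groups[[1]], groups[[2]])
    }
  res$group_medians <- vapply(groups, median, 1.0)
  res
}
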