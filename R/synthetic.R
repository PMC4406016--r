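# Synthetic cohort generator with planted ground truth. Emulates the study
# design the pipeline targets: a ~32,000-probe tiled BAC grid, profiles drawn
# from the simplex/sawtooth/firestorm archetypes, recurrent amplicons of
# varying magnitude, expression with cis-dosage coupling at planted genes,
# and a planted "resistance" amplicon whose carriers show an attenuated
# two-week Ki67 decrease. Every downstream stage gets a parameter-recovery
# oracle from the returned truth object.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: 50 samples on a
#' 32,000-probe, 23-chromosome grid at 100 kb spacing; 1,000 genes of which
#' 20 are dosage-coupled at 1.5 expression units per log2-ratio unit; one
#' recurrent resistance amplicon carried by 30% of samples that attenuates
#' the Ki67 decrease by 30 percentage points; Gaussian noise sd 0.1 (log2
#' ratios) and 0.5 (expression); pattern mix 13:23:48
#' (simplex:sawtooth:firestorm).
#'
#' @param n_samples samples in the cohort.
#' @param n_probes probes on the grid (remainder probes go to the last
#'   chromosome).
#' @param n_chromosomes chromosomes (equal length unless `chrom_lengths`).
#' @param probe_spacing probe pitch in bp; probes are `probe_spacing` wide.
#' @param chrom_lengths optional vector of per-chromosome probe counts
#'   overriding the equal split.
#' @param n_genes genes in the annotation.
#' @param gene_width gene interval width in bp.
#' @param n_dosage_genes planted dosage-coupled genes.
#' @param dosage_coupling expression units per log2-ratio unit.
#' @param planted_dosage_genes optional named numeric vector (gene id ->
#'   coupling) overriding the automatic choice; ids must exist in the
#'   generated annotation.
#' @param n_recurrent_regions recurrent aberration regions (the resistance
#'   amplicon is one of them).
#' @param recurrent_region_probes probes spanned by each recurrent region.
#' @param recurrent_carrier_prob per-sample carrier probability of each
#'   non-resistance recurrent region.
#' @param recurrent_magnitude length-2 range of the planted log2 ratio of a
#'   carried recurrent region.
#' @param carrier_fraction carrier probability of the resistance amplicon.
#' @param resistance_magnitude length-2 range of the resistance amplicon's
#'   planted log2 ratio (kept above the amplification threshold).
#' @param attenuation Ki67-decrease attenuation in percentage points for
#'   resistance-amplicon carriers.
#' @param noise_sd_cn Gaussian noise sd on probe log2 ratios.
#' @param noise_sd_expr Gaussian noise sd on expression values.
#' @param pattern_mix named fractions (simplex, sawtooth, firestorm) summing
#'   to 1.
#' @param ki67_baseline_meanlog,ki67_baseline_sdlog log-normal parameters of
#'   baseline Ki67 (%).
#' @param ki67_decrease_mean,ki67_decrease_sd Normal parameters of the
#'   two-week Ki67 decrease (%) for non-carriers; values are truncated to
#'   `[-100, 100]`.
#' @param expr_baseline_mean,expr_baseline_sd per-gene expression baseline.
#' @param seed master seed; all stage seeds derive from it in fixed order.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 50,
                       n_probes = 32000,
                       n_chromosomes = 23,
                       probe_spacing = 1e5,
                       chrom_lengths = NULL,
                       n_genes = 1000,
                       gene_width = 5e4,
                       n_dosage_genes = 20,
                       dosage_coupling = 1.5,
                       planted_dosage_genes = NULL,
                       n_recurrent_regions = 5,
                       recurrent_region_probes = 30,
                       recurrent_carrier_prob = 0.5,
                       recurrent_magnitude = c(0.4, 1.2),
                       carrier_fraction = 0.3,
                       resistance_magnitude = c(0.8, 1.2),
                       attenuation = 30,
                       noise_sd_cn = 0.1,
                       noise_sd_expr = 0.5,
                       pattern_mix = c(simplex = 13, sawtooth = 23,
                                       firestorm = 48) / 84,
                       ki67_baseline_meanlog = log(20),
                       ki67_baseline_sdlog = 0.5,
                       ki67_decrease_mean = 60,
                       ki67_decrease_sd = 10,
                       expr_baseline_mean = 7,
                       expr_baseline_sd = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  assert_that(n_samples >= 0, "n_samples must be >= 0")
  assert_that(n_probes >= 1 && n_chromosomes >= 1,
              "need at least one probe and one chromosome")
  assert_that(n_genes >= 0 && probe_spacing > 0, "invalid gene/spacing config")
  assert_that(abs(sum(pattern_mix) - 1) < 1e-8, "pattern_mix must sum to 1")
  assert_that(all(pattern_mix >= 0), "pattern_mix fractions must be >= 0")
  assert_that(carrier_fraction >= 0 && carrier_fraction <= 1,
              "carrier_fraction must lie in [0, 1]")
  assert_that(noise_sd_cn >= 0 && noise_sd_expr >= 0, "noise sds must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Generate the ordered probe grid
#'
#' Probes tile each chromosome contiguously at `probe_spacing` pitch,
#' 0-based half-open. The probe count is split equally across chromosomes;
#' remainder probes are assigned to the last chromosome.
#'
#' @param config a [sim_config()].
#' @return data.frame (probe, chrom, start, end), sorted by (chrom, start).
#' @export
generate_probe_grid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes; k <- config$n_chromosomes
  if (n < 1 || k < 1) stop("invalid config: zero probes or chromosomes")
  per <- config$chrom_lengths %||%
    c(rep(n %/% k, k - 1), n %/% k + n %% k)
  assert_that(length(per) == k && sum(per) == n && all(per >= 1),
              "chrom_lengths must be positive and sum to n_probes")
  chrom <- rep(sprintf("chr%02d", seq_len(k)), per)  # zero-padded: lexicographic = genomic order
  offset <- unlist(lapply(per, function(m) seq_len(m) - 1L), use.names = FALSE)
  start <- offset * config$probe_spacing
  grid <- data.frame(
    probe = sprintf("bac%05d", seq_len(n)),
    chrom = chrom, start = start, end = start + config$probe_spacing,
    stringsAsFactors = FALSE)
  validate_grid(grid)
  grid
}

#' @noRd
chrom_probe_index <- function(grid) {
  idx <- split(seq_len(nrow(grid)), grid$chrom)
  idx[order(vapply(idx, min, 1L))]
}

#' Planted mean profile for one archetype
#'
#' Returns the noiseless per-probe mean vector plus the planted segment map.
#' simplex: 1-3 whole-chromosome gains/losses at +-0.3; sawtooth: alternating
#' narrow +-0.3 segments tiling ~90% of chromosomes; firestorm: a simplex
#' background plus 1-2 focal amplicons at log2 ratio 1.0.
#' @noRd
archetype_means <- function(pattern, grid) {
  idx <- chrom_probe_index(grid)
  n_chrom <- length(idx)
  mu <- numeric(nrow(grid))
  segs <- list()
  add_seg <- function(i, m) {
    mu[i] <<- mu[i] + m
    segs[[length(segs) + 1]] <<- data.frame(
      chrom = grid$chrom[i[1]], start = grid$start[i[1]],
      end = grid$end[i[length(i)]], mean = m)
  }
  simplex_background <- function() {
    k <- sample(1:3, 1)
    ch <- sample(n_chrom, k)
    for (c in ch) add_seg(idx[[c]], sample(c(-0.3, 0.3), 1))
    ch
  }
  if (pattern == "simplex") {
    simplex_background()
  } else if (pattern == "sawtooth") {
    # irregular alternating narrow segments: random widths and magnitudes
    # (a balanced square wave would be an adversarial, unrealistic case for
    # any variance-ratio changepoint statistic)
    frag <- sample(n_chrom, ceiling(0.9 * n_chrom))
    for (c in frag) {
      i <- idx[[c]]
      n_seg <- max(1L, min(6L, length(i) %/% 8L))
      w <- 6L + stats::rmultinom(1, length(i) - 6L * n_seg,
                                 rep(1, n_seg))[, 1]
      bounds <- c(0L, cumsum(w))
      sgn <- sample(c(-1, 1), 1)
      for (s in seq_len(n_seg)) {
        ii <- i[(bounds[s] + 1):bounds[s + 1]]
        # asymmetric depths, as in real sawtooth genomes: gains capped well
        # below the amplification cutoff, losses allowed deeper
        m <- if (sgn > 0) runif(1, 0.2, 0.4) else -runif(1, 0.2, 0.7)
        add_seg(ii, m)
        sgn <- -sgn
      }
    }
  } else if (pattern == "firestorm") {
    bg <- simplex_background()
    n_amp <- sample(1:2, 1)
    for (a in seq_len(n_amp)) {
      c <- sample(n_chrom, 1)
      i <- idx[[c]]
      w <- min(length(i), sample(5:15, 1))
      at <- sample(length(i) - w + 1, 1)
      add_seg(i[at:(at + w - 1)], 1.0)
    }
  } else stop("unknown pattern label: ", pattern)
  list(mu = mu,
       segments = if (length(segs)) do.call(rbind, segs) else
         data.frame(chrom = character(), start = numeric(), end = numeric(),
                    mean = numeric()))
}

#' Generate a single archetype profile
#'
#' @param pattern one of "simplex", "sawtooth", "firestorm".
#' @param grid probe grid from [generate_probe_grid()].
#' @param noise_sd Gaussian noise sd on the log2 ratios.
#' @param seed integer seed (reproducible).
#' @return list with `ratio` (per-probe log2 ratios), `truth` (planted
#'   segment map: chrom, start, end, mean).
#' @export
generate_archetype_profile <- function(pattern, grid, noise_sd = 0.1,
                                       seed = NULL) {
  pattern <- match.arg(pattern, c("simplex", "sawtooth", "firestorm"))
  with_seed(seed, {
    arch <- archetype_means(pattern, grid)
    list(ratio = arch$mu + rnorm(length(arch$mu), 0, noise_sd),
         truth = arch$segments, pattern = pattern)
  })
}

#' Deterministic placement of recurrent regions
#'
#' Region 1 is the resistance amplicon, centred on chromosome
#' min(11, n_chromosomes) (echoing the common 11q13 amplicon); the remaining
#' regions are centred on chromosomes spread across the rest of the genome.
#' @noRd
place_recurrent_regions <- function(config, grid) {
  idx <- chrom_probe_index(grid)
  n_chrom <- length(idx)
  res_chrom <- min(11L, n_chrom)
  others <- setdiff(seq_len(n_chrom), res_chrom)
  n_other <- config$n_recurrent_regions - 1L
  chroms <- c(res_chrom,
              if (n_other > 0 && length(others) > 0)
                others[unique(pmax(1, round(seq(1, length(others),
                                                length.out = n_other))))]
              else integer(0))
  out <- lapply(seq_along(chroms), function(r) {
    i <- idx[[chroms[r]]]
    w <- min(length(i), config$recurrent_region_probes)
    at <- max(1L, (length(i) - w) %/% 2L)
    probes <- i[at:(at + w - 1)]
    data.frame(region = r, chrom = grid$chrom[probes[1]],
               start = grid$start[probes[1]],
               end = grid$end[probes[length(probes)]],
               first_probe = probes[1], last_probe = probes[length(probes)],
               resistance = r == 1L)
  })
  do.call(rbind, out)
}

#' Generate a full synthetic cohort
#'
#' Produces copy-number profiles (raw ratios on the shared grid), an
#' expression matrix with cis-dosage coupling at the planted genes, a
#' clinical table with baseline and two-week Ki67, a gene annotation, and the
#' ground truth needed for parameter-recovery tests. Carriers of the planted
#' resistance amplicon have their mean Ki67 decrease attenuated by
#' `config$attenuation` percentage points.
#'
#' @param config a [sim_config()].
#' @return a `cna_sim` list: `cohort` (a [cna_cohort()] of raw ratios),
#'   `expression` (genes x samples), `clinical`, `genes` (annotation),
#'   `truth`, `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  grid <- generate_probe_grid(config)
  seeds <- derive_seeds(config$seed, 6)
  n <- config$n_samples
  samples <- if (n > 0) sprintf("case%03d", seq_len(n)) else character(0)

  # stage 1: pattern labels
  labels <- with_seed(seeds[1], {
    if (n == 0) character(0) else
      sample(names(config$pattern_mix), n, replace = TRUE,
             prob = config$pattern_mix)
  })

  # stage 2: archetype backbones (noiseless means)
  M <- matrix(0, nrow(grid), max(n, 0),
              dimnames = list(grid$probe, samples))
  backbone_truth <- vector("list", n)
  with_seed(seeds[2], {
    for (s in seq_len(n)) {
      arch <- archetype_means(labels[s], grid)
      M[, s] <- arch$mu
      backbone_truth[[s]] <- arch$segments
    }
  })

  # stage 3: recurrent regions (placement deterministic, carriage random)
  regions <- place_recurrent_regions(config, grid)
  carriers <- matrix(FALSE, nrow(regions), max(n, 0))
  with_seed(seeds[3], {
    for (r in seq_len(nrow(regions))) {
      pr <- if (regions$resistance[r]) config$carrier_fraction
            else config$recurrent_carrier_prob
      rng <- if (regions$resistance[r]) config$resistance_magnitude
             else config$recurrent_magnitude
      # carrier fraction planted as an exact count so recovery rates
      # measure the detector, not binomial fluctuation of the plant
      carry <- logical(max(n, 0))
      if (n > 0) carry[sample(n, round(pr * n))] <- TRUE
      mag <- runif(max(n, 0), rng[1], rng[2])
      ii <- regions$first_probe[r]:regions$last_probe[r]
      for (s in which(carry)) M[ii, s] <- M[ii, s] + mag[s]
      carriers[r, ] <- carry
    }
  })

  # stage 4: gene annotation + planted couplings
  genes <- generate_gene_annotation(config, grid, regions)
  coupling <- setNames(rep(0, nrow(genes)), genes$gene_id)
  if (!is.null(config$planted_dosage_genes)) {
    ids <- names(config$planted_dosage_genes)
    missing <- setdiff(ids, genes$gene_id)
    if (length(missing))
      stop("coupling specified for gene(s) absent from annotation: ",
           paste(missing, collapse = ", "))
    coupling[ids] <- config$planted_dosage_genes
  } else {
    coupling[genes$gene_id[genes$planted_dosage]] <- config$dosage_coupling
  }

  # true gene-level copy number: median of planted probe means over the
  # gene's overlapping probes
  gene_cn_true <- gene_level_matrix(M, grid, genes,
                                    max_nearest_distance = 0)$values

  # stage 5: expression
  expr <- with_seed(seeds[4], {
    base <- rnorm(nrow(genes), config$expr_baseline_mean,
                  config$expr_baseline_sd)
    E <- base + coupling * gene_cn_true +
      matrix(rnorm(length(gene_cn_true), 0, config$noise_sd_expr),
             nrow(genes), max(n, 0))
    dimnames(E) <- list(genes$gene_id, samples)
    E
  })

  # stage 6: Ki67
  res_carrier <- if (n > 0) carriers[1, ] else logical(0)
  clinical <- with_seed(seeds[5], {
    baseline <- rlnorm(max(n, 0), config$ki67_baseline_meanlog,
                       config$ki67_baseline_sdlog)
    mu_dec <- config$ki67_decrease_mean - config$attenuation * res_carrier
    decrease <- pmin(100, pmax(-100,
      rnorm(max(n, 0), mu_dec, config$ki67_decrease_sd)))
    data.frame(sample = samples,
               timepoint = rep("baseline", length(samples)),
               ki67_baseline = baseline,
               ki67_2wk = baseline * (1 - decrease / 100),
               stringsAsFactors = FALSE)
  })

  # stage 7: probe noise
  ratio <- with_seed(seeds[6],
    M + matrix(rnorm(length(M), 0, config$noise_sd_cn), nrow(M), ncol(M)))

  truth <- list(
    pattern = setNames(labels, samples),
    backbone_segments = setNames(backbone_truth, samples),
    regions = regions,
    region_carriers = carriers,
    resistance_carriers = setNames(res_carrier, samples),
    dosage_genes = names(coupling)[coupling != 0],
    resistance_gene = genes$gene_id[genes$resistance_gene][1],
    coupling = coupling,
    gene_cn_true = gene_cn_true,
    probe_means = M)
  structure(list(cohort = cna_cohort(grid, ratio),
                 expression = expr, clinical = clinical,
                 genes = genes[, c("gene_id", "symbol", "chrom", "start",
                                   "end")],
                 truth = truth, config = config),
            class = "cna_sim")
}

#' @export
print.cna_sim <- function(x, ...) {
  cat(sprintf("cna_sim: %d samples, %d probes, %d genes (%d dosage-coupled)\n",
              x$config$n_samples, nrow(x$cohort$grid), nrow(x$genes),
              length(x$truth$dosage_genes)))
  cat(sprintf("  resistance amplicon %s:%d-%d, %d carrier(s)\n",
              x$truth$regions$chrom[1], x$truth$regions$start[1],
              x$truth$regions$end[1], sum(x$truth$resistance_carriers)))
  invisible(x)
}

#' Gene annotation with planted genes inside the recurrent regions
#' @noRd
generate_gene_annotation <- function(config, grid, regions) {
  ng <- config$n_genes
  if (ng == 0)
    return(data.frame(gene_id = character(), symbol = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      planted_dosage = logical(), resistance_gene = logical()))
  n_dos <- min(config$n_dosage_genes, ng)
  # planted dosage genes: exactly one inside the resistance region (the
  # planted resistance gene), the rest round-robin across the other regions
  region_for <- if (nrow(regions) > 1)
    c(1L, rep(2:nrow(regions), length.out = n_dos - 1L))
  else rep(1L, n_dos)
  planted <- lapply(seq_len(n_dos), function(g) {
    r <- regions[region_for[g], ]
    span <- r$end - r$start
    k <- sum(region_for[seq_len(g)] == region_for[g])  # index within region
    kmax <- sum(region_for == region_for[g])
    at <- r$start + floor(span * k / (kmax + 1))
    data.frame(chrom = r$chrom, start = at,
               end = min(at + config$gene_width, r$end),
               resistance_gene = r$resistance & k == 1L)
  })
  planted <- do.call(rbind, planted)
  # remaining genes evenly spaced across the genome
  n_rest <- ng - n_dos
  idx <- chrom_probe_index(grid)
  chrom_spans <- data.frame(
    chrom = vapply(idx, function(i) grid$chrom[i[1]], ""),
    start = vapply(idx, function(i) min(grid$start[i]), 1.0),
    end = vapply(idx, function(i) max(grid$end[i]), 1.0))
  total <- sum(chrom_spans$end - chrom_spans$start)
  pos <- (seq_len(max(n_rest, 0)) - 0.5) / max(n_rest, 1) * total
  cum <- cumsum(chrom_spans$end - chrom_spans$start)
  rest <- NULL
  if (n_rest > 0) {
    ci <- findInterval(pos, c(0, head(cum, -1)), rightmost.closed = FALSE)
    rest <- data.frame(
      chrom = chrom_spans$chrom[ci],
      start = chrom_spans$start[ci] + pos - c(0, head(cum, -1))[ci],
      end = NA_real_, resistance_gene = FALSE)
    rest$end <- rest$start + config$gene_width
  }
  out <- rbind(cbind(planted, planted_dosage = TRUE),
               if (!is.null(rest)) cbind(rest, planted_dosage = FALSE))
  out <- out[order(out$chrom, out$start), ]
  out$gene_id <- sprintf("g%04d", seq_len(nrow(out)))
  out$symbol <- toupper(out$gene_id)
  rownames(out) <- NULL
  out[, c("gene_id", "symbol", "chrom", "start", "end",
          "planted_dosage", "resistance_gene")]
}

#' Generate matched pre/post-treatment profile pairs
#'
#' Each pair shares one archetype backbone; both members add independent
#' probe noise. `n_private_amplicons` pairs additionally receive one focal
#' amplicon present in exactly one member (placed on a chromosome the
#' backbone leaves unaltered), and the truth records which member.
#'
#' @param config a [sim_config()] (noise level and pattern mix are taken
#'   from it).
#' @param n_pairs number of matched pairs.
#' @param n_private_amplicons pairs that get a private amplicon
#'   (<= `n_pairs`).
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with cohorts `pre` and `post` (raw ratios), and `truth`
#'   (pair labels, private-amplicon records with member and interval).
#' @export
generate_matched_pairs <- function(config = sim_config(), n_pairs = 19,
                                   n_private_amplicons = 2, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(n_private_amplicons <= n_pairs,
              "n_private_amplicons must be <= n_pairs")
  grid <- generate_probe_grid(config)
  idx <- chrom_probe_index(grid)
  with_seed(seed %||% config$seed, {
    labels <- sample(names(config$pattern_mix), n_pairs, replace = TRUE,
                     prob = config$pattern_mix)
    pre <- matrix(0, nrow(grid), n_pairs)
    post <- matrix(0, nrow(grid), n_pairs)
    priv_pairs <- if (n_private_amplicons > 0)
      sort(sample(n_pairs, n_private_amplicons)) else integer(0)
    priv <- list()
    for (p in seq_len(n_pairs)) {
      arch <- archetype_means(labels[p], grid)
      mu_pre <- arch$mu; mu_post <- arch$mu
      if (p %in% priv_pairs) {
        # a chromosome the backbone leaves unaltered, so the other member
        # sits far below the gain threshold over the amplicon
        quiet <- which(vapply(idx, function(i) all(arch$mu[i] == 0), TRUE))
        c <- if (length(quiet)) quiet[sample(length(quiet), 1)]
             else sample(length(idx), 1)
        i <- idx[[c]]
        w <- min(length(i) - 7L, sample(8:12, 1))
        # keep >= 3 probes of flank on both sides: changepoints closer to a
        # chromosome edge than the segmentation min-width are unresolvable
        at <- sample(4:(length(i) - w - 2L), 1)
        ii <- i[at:(at + w - 1)]
        member <- sample(c("pre", "post"), 1)
        if (member == "pre") mu_pre[ii] <- mu_pre[ii] + 1.0
        else mu_post[ii] <- mu_post[ii] + 1.0
        priv[[length(priv) + 1]] <- data.frame(
          pair = p, member = member, chrom = grid$chrom[ii[1]],
          start = grid$start[ii[1]], end = grid$end[ii[length(ii)]],
          n_probes = w)
      }
      pre[, p] <- mu_pre + rnorm(nrow(grid), 0, config$noise_sd_cn)
      post[, p] <- mu_post + rnorm(nrow(grid), 0, config$noise_sd_cn)
    }
    ids <- sprintf("pt%02d", seq_len(n_pairs))
    dimnames(pre) <- list(grid$probe, paste0(ids, "_pre"))
    dimnames(post) <- list(grid$probe, paste0(ids, "_post"))
    list(pre = cna_cohort(grid, pre), post = cna_cohort(grid, post),
         truth = list(pattern = setNames(labels, ids),
                      private_amplicons = if (length(priv))
                        do.call(rbind, priv) else
                        data.frame(pair = integer(), member = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), n_probes = integer())),
         config = config)
  })
}
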