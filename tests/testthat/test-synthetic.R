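# The synthetic cohort generator: grid construction, determinism, planted
# truth, and the degenerate configurations.

test_that("probe grids are sorted, unique, non-overlapping", {
  cfg <- sim_config(n_probes = 10, n_chromosomes = 2, probe_spacing = 1e5)
  g <- generate_probe_grid(cfg)
  expect_equal(nrow(g), 10)
  expect_equal(sum(g$chrom == "chr01"), 5)
  expect_equal(g$start[g$chrom == "chr01"], seq(0, 4e5, by = 1e5))
  # single probe covers [0, spacing)
  g1 <- generate_probe_grid(sim_config(n_probes = 1, n_chromosomes = 1))
  expect_equal(g1$start, 0)
  expect_equal(g1$end, 1e5)
  # remainder probes go to the last chromosome
  g <- generate_probe_grid(sim_config(n_probes = 32000, n_chromosomes = 23))
  expect_equal(nrow(g), 32000)
  expect_false(anyDuplicated(g$probe) > 0)
  expect_false(is.unsorted(order(g$chrom, g$start)))
  per <- table(g$chrom)
  expect_equal(unname(per[["chr23"]]), 1391 + 32000 %% 23)
  # within a chromosome probes do not overlap
  by_chr <- split(g, g$chrom)
  expect_true(all(vapply(by_chr, function(d)
    all(d$start[-1] >= d$end[-nrow(d)]), TRUE)))
  expect_error(sim_config(n_probes = 0), "at least one")
  expect_error(sim_config(n_chromosomes = 0), "at least one")
})

test_that("archetype profiles honour their pattern contracts", {
  cfg <- sim_config(n_probes = 920, n_chromosomes = 23)
  grid <- generate_probe_grid(cfg)
  # zero noise: ratios equal the planted segment means everywhere
  prof <- generate_archetype_profile("simplex", grid, noise_sd = 0,
                                     seed = 201)
  mu <- rep(0, nrow(grid))
  for (k in seq_len(nrow(prof$truth))) {
    ii <- grid$chrom == prof$truth$chrom[k] &
      grid$start >= prof$truth$start[k] & grid$end <= prof$truth$end[k]
    mu[ii] <- mu[ii] + prof$truth$mean[k]
  }
  expect_equal(prof$ratio, mu)
  # simplex alters 1-3 whole chromosomes
  chroms <- unique(prof$truth$chrom)
  expect_true(length(chroms) >= 1 && length(chroms) <= 3)
  spans <- tapply(grid$end, grid$chrom, max)
  expect_true(all(prof$truth$end - prof$truth$start == spans[prof$truth$chrom]))
  # firestorm plants at least one focal amplicon above the amp threshold
  prof <- generate_archetype_profile("firestorm", grid, noise_sd = 0,
                                     seed = 202)
  amp <- prof$truth[prof$truth$mean >= 0.45, ]
  expect_gte(nrow(amp), 1)
  expect_true(all(amp$end - amp$start <= 20e6))
  # sawtooth fragments >= 80% of chromosomes with >= 5 narrow segments
  prof <- generate_archetype_profile("sawtooth", grid, noise_sd = 0,
                                     seed = 203)
  per_chrom <- table(prof$truth$chrom)
  expect_gte(length(per_chrom), ceiling(0.8 * 23))
  expect_true(all(per_chrom >= 5))
  expect_true(all(prof$truth$end - prof$truth$start <
                    0.5 * spans[prof$truth$chrom]))
  expect_error(generate_archetype_profile("spiral", grid), "arg")
})

test_that("identical seeds reproduce outputs byte-wise", {
  cfg <- sim_config(n_samples = 6, n_probes = 230, n_chromosomes = 23,
                    n_genes = 40, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  p1 <- generate_archetype_profile("firestorm", a$cohort$grid, 0.1, seed = 5)
  p2 <- generate_archetype_profile("firestorm", a$cohort$grid, 0.1, seed = 5)
  expect_identical(p1$ratio, p2$ratio)
  mp1 <- generate_matched_pairs(cfg, 4, 2, seed = 9)
  mp2 <- generate_matched_pairs(cfg, 4, 2, seed = 9)
  expect_identical(serialize(mp1, NULL), serialize(mp2, NULL))
})

test_that("cohorts share sample ids across all four outputs", {
  m <- medium_cohort()
  sim <- m$sim
  expect_equal(colnames(sim$cohort$ratio), sim$clinical$sample)
  expect_equal(colnames(sim$expression), sim$clinical$sample)
  expect_equal(names(sim$truth$pattern), sim$clinical$sample)
  expect_equal(names(sim$truth$resistance_carriers), sim$clinical$sample)
  # planted dosage genes exist in the annotation, resistance gene among them
  expect_true(all(sim$truth$dosage_genes %in% sim$genes$gene_id))
  expect_true(sim$truth$resistance_gene %in% sim$truth$dosage_genes)
  # resistance gene lies inside the resistance region
  g <- sim$genes[sim$genes$gene_id == sim$truth$resistance_gene, ]
  reg <- sim$truth$regions[1, ]
  expect_equal(g$chrom, reg$chrom)
  expect_true(g$start >= reg$start && g$end <= reg$end)
  # planted carrier count is exact
  expect_equal(sum(sim$truth$resistance_carriers),
               round(0.3 * sim$config$n_samples))
})

test_that("dosage coupling drives expression, zero coupling does not", {
  cfg <- sim_config(n_samples = 50, n_probes = 460, n_chromosomes = 23,
                    n_genes = 60, n_dosage_genes = 10, seed = 31)
  sim <- generate_cohort(cfg)
  r_planted <- vapply(sim$truth$dosage_genes, function(g)
    cor(sim$truth$gene_cn_true[g, ], sim$expression[g, ]), 1.0)
  expect_true(all(r_planted > 0.6))  # coupling 1.5, noise 0.5
  # coupling 0: planted correlation vanishes
  cfg0 <- sim_config(n_samples = 50, n_probes = 460, n_chromosomes = 23,
                     n_genes = 60, n_dosage_genes = 10, dosage_coupling = 0,
                     seed = 32)
  sim0 <- generate_cohort(cfg0)
  r0 <- vapply(rownames(sim0$expression), function(g)
    cor(sim0$truth$gene_cn_true[g, ], sim0$expression[g, ]), 1.0)
  r0 <- r0[is.finite(r0)]
  expect_lt(abs(mean(r0)), 3 / sqrt(50))
})

test_that("attenuation shifts carrier Ki67 decreases, zero does not", {
  cfg <- sim_config(n_samples = 200, n_probes = 230, n_chromosomes = 23,
                    n_genes = 20, attenuation = 0, seed = 41)
  sim <- generate_cohort(cfg)
  cl <- classify_responder(sim$clinical)
  carrier <- sim$truth$resistance_carriers
  d <- cl$ki67_decrease
  sem <- sqrt(var(d[carrier]) / sum(carrier) +
                var(d[!carrier]) / sum(!carrier))
  expect_lt(abs(mean(d[carrier]) - mean(d[!carrier])), 2 * sem)
  cfg30 <- sim_config(n_samples = 200, n_probes = 230, n_chromosomes = 23,
                      n_genes = 20, attenuation = 30, seed = 41)
  sim30 <- generate_cohort(cfg30)
  cl30 <- classify_responder(sim30$clinical)
  carrier30 <- sim30$truth$resistance_carriers
  expect_equal(mean(cl30$ki67_decrease[carrier30]) -
                 mean(cl30$ki67_decrease[!carrier30]), -30, tolerance = 5)
})

test_that("degenerate configurations stay well-defined", {
  cfg <- sim_config(n_samples = 0, n_probes = 46, n_chromosomes = 23,
                    n_genes = 10)
  sim <- generate_cohort(cfg)
  expect_equal(ncol(sim$cohort$ratio), 0)
  expect_equal(ncol(sim$expression), 0)
  expect_equal(nrow(sim$clinical), 0)
  # coupling for a non-existent gene errors
  cfg <- sim_config(n_samples = 3, n_probes = 46, n_chromosomes = 23,
                    n_genes = 10,
                    planted_dosage_genes = c(gX999 = 1.5))
  expect_error(generate_cohort(cfg), "absent from annotation")
  expect_error(sim_config(pattern_mix = c(simplex = 0.5, sawtooth = 0.4,
                                          firestorm = 0.2)), "sum to 1")
  expect_error(sim_config(carrier_fraction = 1.5), "carrier_fraction")
})

test_that("matched pairs share backbones and plant private amplicons", {
  cfg <- sim_config(n_probes = 460, n_chromosomes = 23, noise_sd_cn = 0)
  mp <- generate_matched_pairs(cfg, n_pairs = 6, n_private_amplicons = 0,
                               seed = 51)
  # zero noise, no private events: members are identical
  expect_equal(mp$pre$ratio[, 1], unname(mp$post$ratio[, 1]),
               ignore_attr = TRUE)
  expect_equal(nrow(mp$truth$private_amplicons), 0)
  mp <- generate_matched_pairs(cfg, n_pairs = 19, n_private_amplicons = 2,
                               seed = 52)
  tr <- mp$truth$private_amplicons
  expect_equal(nrow(tr), 2)
  for (k in 1:2) {
    ii <- which(mp$pre$grid$chrom == tr$chrom[k] &
                  mp$pre$grid$start >= tr$start[k] &
                  mp$pre$grid$end <= tr$end[k])
    with_amp <- if (tr$member[k] == "pre") mp$pre else mp$post
    without <- if (tr$member[k] == "pre") mp$post else mp$pre
    expect_true(all(with_amp$ratio[ii, tr$pair[k]] >= 0.9))
    expect_true(all(abs(without$ratio[ii, tr$pair[k]]) < 0.1))
  }
  expect_error(generate_matched_pairs(cfg, 3, 5), "n_private")
})
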