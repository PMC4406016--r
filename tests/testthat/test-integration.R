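# Probe-to-gene mapping, the three branches, locus merging, responder rule,
# intersection and the model filter.

toy_gcn <- function(ratio, thresholds = state_thresholds()) {
  genes <- data.frame(gene_id = rownames(ratio), chrom = "chr01",
                      start = seq(0, by = 1e5,
                                  length.out = nrow(ratio)),
                      end = seq(5e4, by = 1e5, length.out = nrow(ratio)))
  structure(list(ratio = ratio, state = call_states(ratio, thresholds),
                 genes = genes, nearest = rep(FALSE, nrow(ratio)),
                 n_probes = rep(1L, nrow(ratio)), thresholds = thresholds),
            class = "gene_cn")
}

test_that("probe-to-gene mapping takes the median of overlapping probes", {
  grid <- small_grid(1, 10)                       # probes at 0..1e6
  co <- one_sample_cohort(grid, rep(0, 10))
  co$seg <- matrix(1L, 10, 1)
  co$cbs <- matrix(seq(0.1, 1.0, by = 0.1), 10, 1,
                   dimnames = dimnames(co$ratio))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr01",
    start = c(0, 250e3, 2e6),          # gA covers probes 1-3, gB probes 3-4
    end = c(280e3, 399e3, 2.05e6))     # gC inside probe 10's span? no: probe 10 ends at 1e6
  genes$start[3] <- 920e3; genes$end[3] <- 960e3  # gC inside probe 10
  gcn <- map_probes_to_genes(co, genes)
  expect_equal(unname(gcn$ratio["gA", 1]), 0.2)   # median(0.1, 0.2, 0.3)
  expect_equal(unname(gcn$ratio["gB", 1]), 0.35)  # median(0.3, 0.4)
  expect_equal(unname(gcn$ratio["gC", 1]), 1.0)
  # a gene in a probe desert: missing without fallback, nearest with it
  genes2 <- data.frame(gene_id = "gD", chrom = "chr02",
                       start = 0, end = 5e4)
  expect_warning(gcn2 <- map_probes_to_genes(co, genes2), "absent")
  expect_true(is.na(gcn2$ratio["gD", 1]))
  # gene beyond the grid end on a present chromosome
  genes3 <- data.frame(gene_id = "gE", chrom = "chr01",
                       start = 5e6, end = 5.05e6)
  gcn3 <- map_probes_to_genes(co, genes3, max_nearest_distance = 0)
  expect_true(is.na(gcn3$ratio["gE", 1]))
  gcn3 <- map_probes_to_genes(co, genes3, max_nearest_distance = 5e6)
  expect_equal(unname(gcn3$ratio["gE", 1]), 1.0)
  expect_true(gcn3$nearest)
  # gene state comes from thresholding the gene-level median
  expect_equal(unname(gcn$state["gA", 1]), 1L)
  expect_equal(unname(gcn$state["gC", 1]), 2L)
})

test_that("gene annotations are validated", {
  expect_error(gene_annotation(data.frame(gene_id = "a", chrom = "chr01",
                                          start = 10, end = 10)), "start")
  expect_error(gene_annotation(data.frame(gene_id = c("a", "a"),
                                          chrom = "chr01", start = c(1, 2),
                                          end = c(5, 6))), "duplicate")
})

test_that("branch 1 recovers planted dosage genes and behaves under null", {
  m <- medium_cohort()
  sim <- m$sim
  gcn <- map_probes_to_genes(m$cohort, sim$genes)
  b1 <- copy_number_regulated_genes(gcn, sim$expression)
  planted <- sim$truth$dosage_genes
  expect_gte(mean(b1$flag[b1$gene_id %in% planted]), 0.9)
  expect_lte(mean(b1$flag[!b1$gene_id %in% planted]), 0.05)
  expect_true(all(b1$q >= b1$p, na.rm = TRUE))
  # permuting expression columns empties the branch (on average)
  set.seed(61)
  ex <- sim$expression[, sample(ncol(sim$expression))]
  colnames(ex) <- colnames(sim$expression)
  b1n <- copy_number_regulated_genes(gcn, ex)
  expect_lte(mean(b1n$flag, na.rm = TRUE), 0.05)
  # too few shared samples is an explicit error
  expect_error(copy_number_regulated_genes(gcn, sim$expression[, 1:5]),
               "shared samples")
})

test_that("branch 2 flags overexpression with the direction filter", {
  set.seed(71)
  n_amp <- 5; n_oth <- 42
  ratio <- rbind(gHI = c(rep(1.0, n_amp), rep(0, n_oth)),
                 gLO = c(rep(1.0, n_amp), rep(0, n_oth)),
                 gNU = c(rep(1.0, n_amp), rep(0, n_oth)))
  colnames(ratio) <- sprintf("s%02d", 1:(n_amp + n_oth))
  gcn <- toy_gcn(ratio)
  expr <- rbind(gHI = c(rnorm(n_amp, 8), rnorm(n_oth, 5)),
                gLO = c(rnorm(n_amp, 2), rnorm(n_oth, 5)),
                gNU = rnorm(n_amp + n_oth, 5))
  colnames(expr) <- colnames(ratio)
  b2 <- overexpressed_when_amplified(gcn, expr)
  expect_true(b2$flag[b2$gene_id == "gHI"])
  expect_false(b2$flag[b2$gene_id == "gLO"])  # significant but wrong direction
  expect_false(b2$flag[b2$gene_id == "gNU"])
  # amplified samples all above: exact p matches the enumeration oracle at
  # reduced n (5 amplified vs 8 non-amplified, all distinct)
  a <- expr["gHI", 1:5]; b <- expr["gHI", 6:13]
  expect_equal(mann_whitney_test(a, b)$p, mw_enum_p(a, b), tolerance = 1e-12)
  # group below min_group: NA with reason
  ratio2 <- ratio; ratio2["gHI", ] <- c(rep(1, 2), rep(0, n_amp + n_oth - 2))
  b2 <- overexpressed_when_amplified(toy_gcn(ratio2), expr)
  expect_true(is.na(b2$p[b2$gene_id == "gHI"]))
  expect_match(b2$reason[b2$gene_id == "gHI"], "min_group")
})

test_that("branch 3 finds the planted resistance region with q < 0.05", {
  m <- medium_cohort()
  sim <- m$sim
  b3 <- cn_response_correlation(m$cohort, sim$clinical)
  reg <- sim$truth$regions[1, ]
  ii <- which(b3$chrom == reg$chrom & b3$start >= reg$start &
                b3$end <= reg$end)
  expect_true(any(b3$significant[ii]))
  expect_true(all(b3$rho[ii] < 0))      # poor response: negative direction
  # genome-wide significant calls stay concentrated at the planted region
  expect_lte(sum(b3$significant) , length(ii) + 0.01 * nrow(b3))
  # permuting Ki67 kills the branch
  set.seed(81)
  cl <- sim$clinical
  perm <- sample(nrow(cl))
  cl[, c("ki67_baseline", "ki67_2wk")] <- cl[perm, c("ki67_baseline",
                                                     "ki67_2wk")]
  b3n <- cn_response_correlation(m$cohort, cl)
  expect_lte(mean(b3n$significant, na.rm = TRUE), 0.05)
})

test_that("locus merging respects gaps, spans and sign flips", {
  pr <- data.frame(probe = sprintf("p%02d", 1:20), chrom = "chr01",
                   start = seq(0, by = 1e5, length.out = 20),
                   end = seq(1e5, by = 1e5, length.out = 20),
                   rho = -0.5, p = 0.001, q = 0.01, sign = -1,
                   significant = FALSE)
  pr$significant[3:7] <- TRUE
  loci <- merge_significant_loci(pr)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_probes, 5)
  expect_equal(loci$direction, -1)
  # two runs separated by 10 non-significant probes stay two loci
  pr2 <- pr; pr2$significant[c(2:4, 15:17)] <- TRUE; pr2$significant[5:7] <- FALSE
  expect_equal(nrow(merge_significant_loci(pr2)), 2)
  # a gap of <= 2 probes within the bp tolerance is bridged
  pr3 <- pr; pr3$significant[c(3:5, 8:10)] <- TRUE; pr3$significant[6:7] <- FALSE
  expect_equal(nrow(merge_significant_loci(pr3)), 1)
  expect_equal(merge_significant_loci(pr3, gap_probes = 1) |> nrow(), 2)
  # sign flip splits the run
  pr4 <- pr; pr4$significant[3:8] <- TRUE; pr4$sign[6:8] <- 1
  loci4 <- merge_significant_loci(pr4)
  expect_equal(nrow(loci4), 2)
  expect_equal(sort(loci4$direction), c(-1, 1))
  # gene containment annotation
  genes <- data.frame(gene_id = c("gIn", "gOut"), chrom = "chr01",
                      start = c(3.2e5, 1.5e6), end = c(3.6e5, 1.9e6))
  loci <- merge_significant_loci(pr, genes = genes)
  expect_equal(loci$genes, "gIn")
})

test_that("the responder rule is strict at 50%", {
  cl <- data.frame(sample = c("a", "b", "c", "d"),
                   ki67_baseline = c(20, 20, 0, 20),
                   ki67_2wk = c(8, 10, 5, NA))
  out <- classify_responder(cl)
  expect_equal(out$ki67_decrease[1], 60)
  expect_true(out$responder[1])
  expect_equal(out$ki67_decrease[2], 50)
  expect_false(out$responder[2])                    # exactly 50% is not a response
  expect_true(is.na(out$responder[3]))
  expect_match(out$responder_reason[3], "baseline")
  expect_true(is.na(out$responder[4]))
  expect_match(out$responder_reason[4], "2-week")
  expect_error(classify_responder(data.frame(sample = "x",
                                             ki67_baseline = -1,
                                             ki67_2wk = 2)),
               "non-negative")
})

test_that("intersection is a strict three-way AND", {
  b1 <- data.frame(gene_id = c("A", "B", "C", "D", "E"),
                   r = 0.5, p = 0.01, q = 0.02, n = 20,
                   flag = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  b2 <- data.frame(gene_id = c("A", "B", "C", "D", "E"), u = 1, p = 0.01,
                   q = 0.02, n_amp = 5, n_other = 15,
                   amp_median_higher = TRUE,
                   flag = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  loci <- data.frame(locus = 1:2, chrom = "chr01", start = c(0, 5e6),
                     end = c(1e6, 6e6), direction = c(-1, 1),
                     n_probes = 5, best_q = 0.01,
                     genes = c("C,D,E", "B"))
  rep <- intersect_candidates(b1, b2, loci)
  expect_equal(rep$gene_id[rep$candidate], "C")
  # candidate implies every branch flag
  expect_true(all(rep$branch1[rep$candidate] & rep$branch2[rep$candidate] &
                    rep$branch3[rep$candidate]))
  # only poor-response (negative) loci feed branch 3: B is in a +1 locus
  expect_false(rep$branch3[rep$gene_id == "B"])
  # empty branch empties the intersection
  b2$flag[] <- FALSE
  expect_equal(sum(intersect_candidates(b1, b2, loci)$candidate), 0)
  expect_error(intersect_candidates(b1[0, ], b2[0, ], loci), "empty")
})

test_that("the model filter keeps upregulated and flags missing genes", {
  rep <- data.frame(gene_id = c("A", "B", "C"), r = 0.5, r_q = 0.01,
                    branch1 = TRUE, u = 1, u_q = 0.01, amp_freq = 0.2,
                    branch2 = TRUE, branch3 = TRUE, candidate = TRUE)
  fc <- data.frame(gene_id = c("A", "B", "C"),
                   fold_change = c(2.0, 1.1, 1.6))
  out <- model_prioritization_filter(rep, fc, min_fc = 1.5)
  expect_equal(out$gene_id, c("A", "C"))
  expect_equal(model_prioritization_filter(rep, fc, min_fc = 1.0)$gene_id,
               c("A", "B", "C"))
  # empty table, drop mode -> empty; keep mode -> all kept, flagged
  none <- data.frame(gene_id = character(), fold_change = numeric())
  expect_equal(nrow(model_prioritization_filter(rep, none,
                                                missing_action = "drop")), 0)
  kept <- model_prioritization_filter(rep, none, missing_action = "keep")
  expect_equal(kept$gene_id, c("A", "B", "C"))
  expect_true(all(kept$no_model_data))
  expect_error(model_prioritization_filter(rep,
    data.frame(gene_id = "A", fold_change = -2)), "positive")
})

test_that("expression collapse keeps the max-variance probe or averages", {
  expr <- rbind(c(1, 2, 3), c(10, 0, 20), c(5, 5, 5))
  colnames(expr) <- c("s1", "s2", "s3")
  out <- collapse_expression(expr, c("g1", "g1", "g2"))
  expect_equal(unname(out["g1", ]), c(10, 0, 20))   # higher variance row
  out <- collapse_expression(expr, c("g1", "g1", "g2"), method = "mean")
  expect_equal(unname(out["g1", ]), c(5.5, 1, 11.5))
})

test_that("the full screen recovers the planted resistance gene", {
  m <- medium_cohort()
  sim <- m$sim
  fc <- data.frame(gene_id = sim$truth$resistance_gene, fold_change = 2.0)
  res <- run_integration(m$cohort, sim$expression, sim$clinical, sim$genes,
                         foldchange = fc)
  cand <- res$report$gene_id[res$report$candidate]
  expect_true(sim$truth$resistance_gene %in% cand)
  expect_lte(length(cand), 5)
  expect_true(sim$truth$resistance_gene %in% res$prioritized$gene_id)
})
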