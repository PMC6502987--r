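test_that("empirical decile bins slice the sample exactly as sort-and-slice does", {
  p <- seq(0.05, 0.95, by = 0.1)
  part <- make_bins(p)
  expect_equal(sort(tabulate(part$bin, 10)), rep(1L, 10))

  set.seed(31)
  p2 <- runif(1000)
  part2 <- make_bins(p2)
  expect_equal(unname(tabulate(part2$bin, 10)), rep(100L, 10))
  # oracle: bin of the k-th smallest p (descending index) by slicing
  ord <- order(p2)
  slice <- rep(10:1, each = 100)          # lowest p -> bin 10
  expect_equal(part2$bin[ord], slice)
})

test_that("fixed edges assign boundary p-values to the bin they close", {
  part <- make_bins(c(0.90, 0.886, 0.054, 0.0), mode = "fixed",
                    edges = decile_edges_published)
  expect_equal(part$bin, c(1L, 2L, 10L, 10L))
  # an exact interior edge belongs to the interval it bounds above
  expect_equal(assign_bins(0.140, part), 9L)
  expect_equal(assign_bins(1, part), 1L)
})

test_that("non-finite p-values and tied edges are refused", {
  expect_error(make_bins(c(0.1, NA)), "non-finite")
  expect_error(make_bins(rep(0.5, 100)), "tied")
})

test_that("fold-change score follows the printed formula and its reciprocal", {
  # bin composition matches the genome: both conventions give exactly 1
  expect_equal(fscore(1000, 100, 100, 10, "bc_over_ad"), 1)
  expect_equal(fscore(1000, 100, 100, 10, "obs_over_exp"), 1)
  expect_equal(fscore(1000, 100, 100, 20, "bc_over_ad"), 0.5)
  expect_equal(fscore(1000, 100, 100, 20, "obs_over_exp"), 2)
  expect_true(is.na(fscore(1000, 100, 100, 0, "bc_over_ad")))
  expect_equal(fscore(1000, 100, 100, 0, "obs_over_exp"), 0)

  set.seed(7)
  for (i in 1:200) {
    a <- sample(10:1000, 1); b <- sample(0:a, 1)
    c <- sample(0:a, 1); d <- sample(0:min(b, c), 1)
    f1 <- fscore(a, b, c, d, "bc_over_ad")
    f2 <- fscore(a, b, c, d, "obs_over_exp")
    if (!is.na(f1) && !is.na(f2) && f2 > 0)
      expect_equal(f1, 1 / f2, tolerance = 1e-12)
  }
})

test_that("two-sided Fisher p matches the enumeration oracle on the worked tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  # pmf over k = 0..3 is {1,9,9,1}/20; every table is <= the observed 9/20
  expect_equal(fisher_exact_2x2(matrix(c(2, 1, 1, 2), 2))$p_value, 1)
  # only the two perfectly discordant tables qualify; C(20,10) = 184756
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / 184756, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(10, 20), c(20, 10)))$p_value,
               fisher_oracle(rbind(c(10, 20), c(20, 10))), tolerance = 1e-12)
  z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))
  expect_equal(z$p_value, 1)
  expect_true(z$zero_margin)
})

test_that("per-bin enrichment conserves counts and handles point masses", {
  set.seed(13)
  ann <- mock_annotated(
    p_value = runif(600),
    lineage = sample(c(NA, "MD", "AD"), 600, TRUE, prob = c(0.5, 0.3, 0.2)))
  part <- make_bins(ann$p_value)
  enr <- enrichment_by_bin(ann, part)
  for (l in c("MD", "AD")) {
    sub <- enr[enr$lineage == l]
    expect_equal(sum(sub$n_bin_in_sites), sub$n_genome_in_sites[1])
    expect_equal(sum(sub$n_bin_total), sub$n_genome_total[1])
  }
  # every analyzed SNP occupies exactly one bin
  expect_equal(sum(tabulate(part$bin, 10)), nrow(ann))

  # all MD-site SNPs forced into the lowest-p bin
  p <- c(runif(400, 0.2, 1), runif(100, 0, 0.05))
  lin <- c(rep(NA_character_, 400), rep("MD", 100))
  part2 <- make_bins(p, mode = "fixed", edges = decile_edges_published)
  enr2 <- enrichment_by_bin(mock_annotated(p, lin), part2)
  md <- enr2[enr2$lineage == "MD"]
  a <- md$n_genome_total[1]
  expect_equal(md$f_obs_over_exp[md$bin_index == 10],
               a / md$n_bin_total[md$bin_index == 10])
  expect_true(all(md$f_obs_over_exp[md$bin_index != 10] == 0,
                  na.rm = TRUE))
})

test_that("per-bin ratio contrast reproduces the hypergeometric oracle", {
  # one bin holding MD 10 risk / 20 protective vs AD 20 risk / 10 protective
  pol <- c(rep("derived_risk", 10), rep("derived_protective", 20),
           rep("derived_risk", 20), rep("derived_protective", 10))
  lin <- rep(c("MD", "AD"), each = 30)
  ann <- mock_annotated(p_value = rep(0.25, 60), lineage = lin,
                        polarity = pol)
  part <- make_bins(ann$p_value, n_bins = 2, mode = "fixed",
                    edges = c(1, 0.5, 0))
  rat <- ratio_by_bin(ann, part)
  b2 <- rat[rat$bin_index == 2]
  expect_equal(b2[b2$lineage == "MD"]$risk_protective_ratio, 0.5)
  expect_equal(b2[b2$lineage == "AD"]$risk_protective_ratio, 2)
  expect_equal(b2$p_ratio_md_vs_ad[1],
               fisher_oracle(rbind(c(10, 20), c(20, 10))), tolerance = 1e-12)
  expect_equal(b2$p_ratio_md_vs_ad[1], 0.019383, tolerance = 1e-4)
  # the empty bin is NA, not 1
  expect_true(all(is.na(rat[rat$bin_index == 1]$p_ratio_md_vs_ad)))
})

test_that("Fisher p equals the enumeration oracle across random small tables", {
  set.seed(3)
  for (i in 1:200) {
    tab <- matrix(sample(0:15, 4, TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("overall contrasts pool counts over bins", {
  pol <- c(rep("derived_risk", 15), rep("derived_protective", 15),
           rep("derived_risk", 15), rep("derived_protective", 15))
  lin <- rep(c("MD", "AD"), each = 30)
  set.seed(9)
  ann <- mock_annotated(p_value = runif(60), lineage = lin, polarity = pol)
  part <- make_bins(ann$p_value, n_bins = 2, mode = "fixed",
                    edges = c(1, 0.5, 0))
  ov <- overall_contrast(bin_result_table(ann, part))
  # identical pooled counts across lineages: p = 1, equal ratios
  expect_equal(ov$ratio$p_pooled_md_vs_ad, 1)
  expect_equal(ov$ratio$pooled_ratio_md, ov$ratio$pooled_ratio_ad)
  expect_equal(ov$enrichment$p_pooled_md_vs_ad, 1)
  expect_equal(unname(ov$ratio$pooled_counts),
               c(15, 15, 15, 15))
})

test_that("under a scattered null no bin shows spurious enrichment", {
  set.seed(99)
  hits <- vapply(1:100, function(i) {
    ann <- mock_annotated(
      p_value = runif(800),
      lineage = sample(c(NA, "MD", "AD"), 800, TRUE,
                       prob = c(0.6, 0.2, 0.2)))
    enr <- enrichment_by_bin(ann, make_bins(ann$p_value))
    any(enr$p_enrichment_md_vs_ad < 0.005, na.rm = TRUE)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})
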