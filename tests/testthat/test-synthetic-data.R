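test_that("the generator is a pure function of its configuration", {
  cfg <- sim_config(n_snps = 400, n_md_sites = 120, n_ad_sites = 90,
                    seed = 3)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$gwas, b$gwas)
  expect_identical(a$sites, b$sites)
  expect_identical(a$maf, b$maf)
  expect_identical(a$panel$dosages, b$panel$dosages)
  da <- tempfile(); db <- tempfile()
  write_sim_dataset(a, da); write_sim_dataset(b, db)
  for (f in c("gwas.tsv", "sites.tsv", "maf.tsv", "panel.vcf"))
    expect_identical(readLines(file.path(da, f)),
                     readLines(file.path(db, f)))
})

test_that("panel LD structure: r2 = 1 blocks are exact copies; cross-block r2 matches the null expectation", {
  cfg <- sim_config(n_snps = 200, n_md_sites = 10, n_ad_sites = 10,
                    n_ld_blocks = 20, within_block_r2 = 1, seed = 9)
  p <- simulate_panel(cfg)
  block <- attr(p, "block")
  for (b in unique(block)) {
    rows <- which(block == b)
    ref <- p$dosages[rows[1], ]
    for (r in rows[-1]) {
      expect_identical(p$dosages[r, ], ref)
      expect_equal(compute_r2(p$dosages[rows[1], ], p$dosages[r, ]), 1)
    }
  }

  # across blocks, dosages are independent; E[r^2] of independent samples
  # is 1/(n_samples - 1)
  cfg2 <- sim_config(n_snps = 500, n_md_sites = 10, n_ad_sites = 10,
                     n_ld_blocks = 50, within_block_r2 = 0.5,
                     n_samples_panel = 100, seed = 11)
  p2 <- simulate_panel(cfg2)
  block2 <- attr(p2, "block")
  set.seed(1)
  i <- sample(nrow(p2$dosages), 20000, replace = TRUE)
  j <- sample(nrow(p2$dosages), 20000, replace = TRUE)
  keep <- block2[i] != block2[j]
  i <- i[keep][1:10000]; j <- j[keep][1:10000]
  r2 <- vapply(seq_along(i), function(k)
    compute_r2(p2$dosages[i[k], ], p2$dosages[j[k], ]), numeric(1))
  expect_equal(mean(r2, na.rm = TRUE), 1 / (100 - 1), tolerance = 0.3)
})

test_that("within-block r2 approaches the configured target", {
  cfg <- sim_config(n_snps = 300, n_md_sites = 10, n_ad_sites = 10,
                    n_ld_blocks = 30, within_block_r2 = 0.5,
                    n_samples_panel = 200, seed = 21)
  p <- simulate_panel(cfg)
  block <- attr(p, "block")
  r2 <- unlist(lapply(unique(block), function(b) {
    rows <- which(block == b)
    utils::combn(rows, 2, function(ij)
      compute_r2(p$dosages[ij[1], ], p$dosages[ij[2], ]))
  }))
  expect_equal(mean(r2, na.rm = TRUE), 0.5, tolerance = 0.1)
})

test_that("injected protective excess is realized at the configured rate", {
  # theta = 2: derived-protective share 2/3; check within the binomial
  # 95% interval at n = 5000
  cfg <- sim_config(n_snps = 6000, n_md_sites = 5000, n_ad_sites = 500,
                    overlap_fraction = 1, protective_excess_md = 2, seed = 1)
  d <- simulate_catalog_and_gwas(cfg)
  md <- d$truth$realized$MD
  share <- md[["n_protective"]] / (md[["n_protective"]] + md[["n_risk"]])
  half_width <- 1.96 * sqrt((2 / 9) / 5000)
  expect_lt(abs(share - 2 / 3), half_width)
  # null lineage stays balanced
  ad <- d$truth$realized$AD
  expect_equal(ad[["n_protective"]] / (ad[["n_protective"]] + ad[["n_risk"]]),
               0.5, tolerance = 0.1)
  # realized counts partition the overlapped sites
  expect_equal(md[["n_risk"]] + md[["n_protective"]], 5000)
})

test_that("realized theta converges to the configured theta at large n", {
  cfg <- sim_config(n_snps = 51000, n_md_sites = 50000, n_ad_sites = 500,
                    overlap_fraction = 1, protective_excess_md = 2, seed = 2)
  d <- simulate_catalog_and_gwas(cfg)
  expect_equal(unname(d$truth$realized$MD[["theta"]]), 2, tolerance = 0.02)
})

test_that("pure-null p-values are uniform and polarity-independent", {
  # a single KS draw at alpha = 0.01 fails 1% of the time by design, so
  # assert the pass *rate* over independent generator seeds instead
  pass <- vapply(1:20, function(s) {
    cfg <- sim_config(n_snps = 5000, n_md_sites = 1000, n_ad_sites = 1000,
                      assoc_effect_fraction = 0, p_coupling = 0, seed = s)
    d <- simulate_catalog_and_gwas(cfg)
    suppressWarnings(stats::ks.test(d$gwas$p_value, "punif"))$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("generated files re-read cleanly through the readers with zero rejects", {
  cfg <- sim_config(n_snps = 500, n_md_sites = 150, n_ad_sites = 110,
                    seed = 6)
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  paths <- write_sim_dataset(sim, dir)
  g <- suppressMessages(read_gwas(paths[["gwas"]], canonical_dialect()))
  s <- suppressMessages(read_site_catalog(paths[["sites"]]))
  m <- suppressMessages(read_maf_table(paths[["maf"]]))
  expect_length(attr(g, "rejects"), 0L)
  expect_length(attr(s, "rejects"), 0L)
  expect_length(attr(m, "rejects"), 0L)
  expect_equal(nrow(g), cfg$n_snps)
  expect_equal(nrow(s), cfg$n_md_sites + cfg$n_ad_sites)
  # and the VCF round-trips into the same dosage matrix
  p <- read_panel_vcf(paths[["panel"]])
  expect_equal(unname(p$dosages), unname(sim$panel$dosages))
  expect_equal(p$pos, sim$panel$pos)
})

test_that("site-overlapping SNP MAFs respect the human-specific frequency ceiling", {
  cfg <- sim_config(n_snps = 2000, n_md_sites = 600, n_ad_sites = 440,
                    seed = 8)
  d <- simulate_catalog_and_gwas(cfg)
  site_ids <- d$truth$table$snp_id[!is.na(d$truth$table$lineage)]
  site_maf <- d$maf$maf[d$maf$snp_id %in% site_ids]
  expect_true(all(site_maf < 0.1))
  expect_true(all(d$maf$maf > 0 & d$maf$maf <= 0.5))
  # the ceiling is a switch, not a law of the generator
  cfg2 <- sim_config(n_snps = 2000, n_md_sites = 600, n_ad_sites = 440,
                     force_low_maf_at_sites = FALSE, seed = 8)
  d2 <- simulate_catalog_and_gwas(cfg2)
  site_maf2 <- d2$maf$maf[d2$maf$snp_id %in% site_ids]
  expect_gt(max(site_maf2), 0.1)
})

test_that("overlap larger than the SNP set is rejected", {
  cfg <- sim_config(n_snps = 100, n_md_sites = 90, n_ad_sites = 90,
                    overlap_fraction = 1, seed = 1)
  expect_error(simulate_catalog_and_gwas(cfg), "overlap exceeds")
})
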