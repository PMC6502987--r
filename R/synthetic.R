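# Synthetic-data generator. Emulates the four pipeline inputs -- GWAS
# summary statistics, the MD/AD site catalog, a MAF table, and a genotype
# reference panel with block LD structure -- with exact ground truth, so
# every downstream stage is testable without restricted-access downloads.
#
# Summary statistics are generated directly (no individual-level
# case/control genotypes): the analysis consumes only summary statistics,
# and direct generation makes the ground truth exact.

#' Simulation configuration
#'
#' Defaults are scaled-down analogues of the study conditions the pipeline
#' was designed for: a catalog with ~1.4x more MD than AD sites, of which
#' 28.5% (MD) and 31.0% (AD) are polymorphic in the GWAS, site variants
#' held below MAF 0.1, and small log-additive odds ratios.
#'
#' @param n_snps number of GWAS SNPs.
#' @param n_md_sites,n_ad_sites catalog sizes per lineage class.
#' @param overlap_fraction length-2 numeric `c(md=, ad=)` (a single value
#'   is recycled): share of catalog sites that are polymorphic GWAS SNPs.
#' @param n_samples_panel reference-panel sample count (>= 4).
#' @param n_ld_blocks number of independent LD blocks the SNPs occupy,
#'   laid out over up to 22 chromosomes with multi-megabase gaps between
#'   blocks. The default, one block per ~5 SNPs, leaves a realistic
#'   fraction of the SNP set standing after greedy pruning; small block
#'   counts give the near-total collapse expected of equicorrelated
#'   blocks.
#' @param within_block_r2 target pairwise dosage r-squared inside a block;
#'   1 gives identical dosage vectors, 0 gives independence.
#' @param maf_beta_params shape pair of the Beta MAF spectrum (truncated
#'   to `(0, 0.5]`); the default `c(0.5, 5)` is rare-skewed.
#' @param protective_excess_md,protective_excess_ad theta >= 1: the factor
#'   by which derived-protective outnumber derived-risk alleles among
#'   site-overlapping SNPs of that lineage. A SNP is drawn
#'   derived-protective with probability `theta / (1 + theta)`; theta = 1
#'   is the null.
#' @param assoc_effect_fraction share of SNPs given a true association
#'   (left-skewed p-values, `Beta(0.2, 1)`); the rest are null (uniform).
#' @param p_coupling optional coupling in `[0, 1]` concentrating the
#'   polarity excess in low-p SNPs: with coupling `c > 0` the effective
#'   theta at p-value `p` is `theta^((1-p)^(4c))`. At `c = 0` (default)
#'   p-values are independent of polarity, so any detected polarity signal
#'   is attributable to the injected theta. The coupling is a
#'   demonstration construct, recorded in output metadata.
#' @param or_log_sd standard deviation of per-SNP log odds ratios.
#' @param strand_ambiguous_fraction share of site allele pairs drawn
#'   complementary (A/T or C/G); 0 by default so ground truth is fully
#'   resolvable.
#' @param force_low_maf_at_sites keep site-overlapping SNP MAFs strictly
#'   below 0.1 (the frequency ceiling of human-specific variants); set
#'   `FALSE` to exercise the MAF filter itself.
#' @param seed integer seed; the whole generator is a pure function of
#'   the configuration.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 10000L,
                       n_md_sites = 3000L, n_ad_sites = 2200L,
                       overlap_fraction = c(md = 0.285, ad = 0.310),
                       n_samples_panel = 120L,
                       n_ld_blocks = max(1L, as.integer(n_snps) %/% 5L),
                       within_block_r2 = 0.5,
                       maf_beta_params = c(0.5, 5),
                       protective_excess_md = 1,
                       protective_excess_ad = 1,
                       assoc_effect_fraction = 0.05,
                       p_coupling = 0,
                       or_log_sd = 0.08,
                       strand_ambiguous_fraction = 0,
                       force_low_maf_at_sites = TRUE,
                       seed = 1L) {
  ov <- rep_len(as.numeric(overlap_fraction), 2L)
  names(ov) <- c("md", "ad")
  cfg <- list(n_snps = as.integer(n_snps),
              n_md_sites = as.integer(n_md_sites),
              n_ad_sites = as.integer(n_ad_sites),
              overlap_fraction = ov,
              n_samples_panel = as.integer(n_samples_panel),
              n_ld_blocks = as.integer(n_ld_blocks),
              within_block_r2 = within_block_r2,
              maf_beta_params = as.numeric(maf_beta_params),
              protective_excess_md = protective_excess_md,
              protective_excess_ad = protective_excess_ad,
              assoc_effect_fraction = assoc_effect_fraction,
              p_coupling = p_coupling,
              or_log_sd = or_log_sd,
              strand_ambiguous_fraction = strand_ambiguous_fraction,
              force_low_maf_at_sites = isTRUE(force_low_maf_at_sites),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_snps > 0L, n_md_sites > 0L, n_ad_sites > 0L,
              all(ov > 0), all(ov <= 1),
              n_ld_blocks > 0L, within_block_r2 >= 0, within_block_r2 <= 1,
              length(maf_beta_params) == 2L, all(maf_beta_params > 0),
              protective_excess_md >= 1, protective_excess_ad >= 1,
              assoc_effect_fraction >= 0, assoc_effect_fraction <= 1,
              p_coupling >= 0, p_coupling <= 1, or_log_sd > 0)
  })
  structure(cfg, class = "sim_config")
}

# Beta draw truncated to (0, upper] by rejection; the acceptance mass is
# large for the supported shape/upper combinations, so this terminates.
.rbeta_trunc <- function(n, shape, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rbeta(max(n, 64L), shape[1], shape[2])
    out <- c(out, x[x > 0 & x < upper])
  }
  out[seq_len(n)]
}

#' Simulate a genotype reference panel with block LD
#'
#' SNPs are laid out on one chromosome in `n_ld_blocks` blocks separated
#' by multi-megabase gaps. Within a block every site is a noisy copy of a
#' shared latent haplotype pair: each haplotype allele copies the latent
#' allele with probability `1 - m` and is redrawn fresh otherwise, with
#' `m = 1 - within_block_r2^(1/4)` so the expected pairwise dosage
#' r-squared inside the block equals `within_block_r2`. Blocks are
#' mutually independent.
#'
#' @param config a [sim_config()].
#' @return `panel_genotypes` with attribute `block` (per-site block
#'   index).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_panel < 4L)
    stop("n_samples_panel must be at least 4")
  set.seed(config$seed)
  n <- config$n_snps
  nb <- config$n_ld_blocks
  ns <- config$n_samples_panel
  block <- sort(rep_len(seq_len(nb), n))
  max_block <- max(tabulate(block))
  stride <- 2e6 + 1000 * max_block          # keeps blocks > 1 Mb apart
  within <- unlist(lapply(tabulate(block), seq_len), use.names = FALSE)
  # blocks spread over up to 22 chromosomes so positions stay in integer
  # range at any block count
  n_chr <- min(22L, nb)
  bpc <- ceiling(nb / n_chr)
  chrom_of_block <- rep(seq_len(n_chr), each = bpc)[seq_len(nb)]
  rank_in_chrom <- unlist(lapply(tabulate(chrom_of_block), seq_len),
                          use.names = FALSE)
  chrom <- as.character(chrom_of_block[block])
  pos <- as.integer((rank_in_chrom[block] - 1L) * stride +
                      (within - 1L) * 1000 + 1)
  m <- 1 - config$within_block_r2^(1 / 4)

  dos <- matrix(0L, n, ns)
  for (b in seq_len(nb)) {
    rows <- which(block == b)
    f <- runif(1, 0.1, 0.45)
    h1 <- rbinom(ns, 1L, f)
    h2 <- rbinom(ns, 1L, f)
    k <- length(rows)
    redraw1 <- matrix(runif(k * ns) < m, k, ns)
    redraw2 <- matrix(runif(k * ns) < m, k, ns)
    fresh1 <- matrix(rbinom(k * ns, 1L, f), k, ns)
    fresh2 <- matrix(rbinom(k * ns, 1L, f), k, ns)
    x1 <- matrix(rep(h1, each = k), k, ns)
    x2 <- matrix(rep(h2, each = k), k, ns)
    x1[redraw1] <- fresh1[redraw1]
    x2[redraw2] <- fresh2[redraw2]
    dos[rows, ] <- x1 + x2
  }
  panel <- panel_genotypes(dos, chrom = chrom, pos = pos,
                           snp_id = paste0("rs", seq_len(n)))
  data.table::setattr(panel, "block", block)
  panel
}

#' Simulate the site catalog, GWAS summary statistics and MAF table
#'
#' The configured overlap fraction of catalog sites coincides with GWAS
#' SNP positions (sharing rsIDs); the remainder are monomorphic in the
#' GWAS. For an overlapped site the SNP's alleles are the site's
#' ancestral/derived pair, its polarity is drawn derived-protective with
#' probability `theta / (1 + theta)` for the lineage's theta, and the
#' odds ratio's direction is made consistent with the drawn polarity
#' (log-normal magnitude, sign flipped when the effect allele is the
#' ancestral one). Null SNPs get uniform p-values; effect SNPs get
#' left-skewed ones. MAFs follow the configured Beta spectrum truncated
#' to `(0, 0.5]`, with site-overlapping SNPs held strictly below 0.1
#' unless disabled.
#'
#' @param config a [sim_config()].
#' @param panel optional `panel_genotypes` from [simulate_panel()] built
#'   from the same config; when supplied, GWAS SNPs take the panel's
#'   coordinates (and are therefore all resolvable by the LD pruner).
#'   `NULL` lays SNPs on a plain grid, sufficient for analyses that do
#'   not prune.
#' @return list with elements `sites`, `gwas`, `maf` (data.tables in the
#'   reader-canonical layouts) and `truth` (per-SNP ground truth plus
#'   realized per-lineage risk/protective counts and theta).
#' @export
simulate_catalog_and_gwas <- function(config, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_snps
  n_ov_md <- round(config$n_md_sites * config$overlap_fraction[["md"]])
  n_ov_ad <- round(config$n_ad_sites * config$overlap_fraction[["ad"]])
  if (n_ov_md + n_ov_ad > n)
    stop("requested site overlap exceeds the number of GWAS SNPs")

  if (!is.null(panel)) {
    stopifnot(inherits(panel, "panel_genotypes"),
              nrow(panel$dosages) == n)
    chrom <- panel$chrom; pos <- panel$pos; snp_id <- panel$snp_id
    block <- attr(panel, "block")
  } else {
    chrom <- rep("1", n)
    pos <- as.integer(seq_len(n) * 5000L)
    snp_id <- paste0("rs", seq_len(n))
    block <- rep(NA_integer_, n)
  }

  ov_idx <- sample.int(n, n_ov_md + n_ov_ad)
  lineage <- rep(NA_character_, n)
  lineage[ov_idx[seq_len(n_ov_md)]] <- "MD"
  lineage[ov_idx[n_ov_md + seq_len(n_ov_ad)]] <- "AD"

  # allele pairs: ancestral uniform; derived excludes the complement
  # unless the pair is deliberately strand-ambiguous
  anc <- sample(.NUCS, n, replace = TRUE)
  ambig <- runif(n) < config$strand_ambiguous_fraction
  der <- character(n)
  for (a in .NUCS) {
    i <- which(anc == a & !ambig)
    choices <- setdiff(.NUCS, c(a, .COMP[[a]]))
    der[i] <- sample(choices, length(i), replace = TRUE)
    j <- which(anc == a & ambig)
    der[j] <- .COMP[[a]]
  }

  # association p-values
  is_effect <- runif(n) < config$assoc_effect_fraction
  p <- runif(n)
  if (any(is_effect)) p[is_effect] <- rbeta(sum(is_effect), 0.2, 1)

  # polarity of site-overlapping SNPs, optionally coupled to p
  theta <- ifelse(lineage == "MD", config$protective_excess_md,
                  config$protective_excess_ad)
  w <- if (config$p_coupling > 0) (1 - p)^(4 * config$p_coupling) else 1
  theta_eff <- theta^w
  prot <- runif(n) < theta_eff / (1 + theta_eff)
  prot[is.na(lineage)] <- NA

  # odds ratios: magnitude log-normal; for site SNPs the sign is forced
  # so the derived allele's direction matches the drawn polarity
  ln_or <- rnorm(n, 0, config$or_log_sd)
  effect_is_derived <- runif(n) < 0.5
  site <- !is.na(lineage)
  ln_derived <- ifelse(prot[site], -abs(ln_or[site]), abs(ln_or[site]))
  ln_or[site] <- ifelse(effect_is_derived[site], ln_derived, -ln_derived)
  odds_ratio <- exp(ln_or)

  allele_effect <- ifelse(effect_is_derived, der, anc)
  allele_other <- ifelse(effect_is_derived, anc, der)

  maf <- .rbeta_trunc(n, config$maf_beta_params, 0.5 + 1e-12)
  maf <- pmin(maf, 0.5)
  if (config$force_low_maf_at_sites && any(site))
    maf[site] <- .rbeta_trunc(sum(site), config$maf_beta_params, 0.1)

  gwas <- data.table::data.table(
    snp_id = snp_id, chrom = chrom, pos = pos,
    allele_effect = allele_effect, allele_other = allele_other,
    odds_ratio = odds_ratio, p_value = p)

  # catalog: overlapped sites share the GWAS coordinates and rsIDs;
  # the rest are monomorphic positions beyond the GWAS range
  n_mono_md <- config$n_md_sites - n_ov_md
  n_mono_ad <- config$n_ad_sites - n_ov_ad
  n_mono <- n_mono_md + n_mono_ad
  mono_pos <- as.integer(max(pos) + 1e6 + seq_len(n_mono) * 1000L)
  mono_anc <- sample(.NUCS, n_mono, replace = TRUE)
  mono_der <- vapply(mono_anc, function(a)
    sample(setdiff(.NUCS, c(a, .COMP[[a]])), 1L), character(1))
  sites <- data.table::rbindlist(list(
    data.table::data.table(
      snp_id = snp_id[site], chrom = chrom[site], pos = pos[site],
      allele_ancestral = anc[site], allele_derived = der[site],
      lineage = lineage[site]),
    data.table::data.table(
      snp_id = paste0("ms", seq_len(n_mono)),
      chrom = "1", pos = mono_pos,
      allele_ancestral = mono_anc, allele_derived = mono_der,
      lineage = rep(c("MD", "AD"), c(n_mono_md, n_mono_ad)))))
  data.table::setorder(sites, lineage, chrom, pos)

  maf_tab <- data.table::data.table(snp_id = snp_id, maf = maf)

  truth_tab <- data.table::data.table(
    snp_id = snp_id, lineage = lineage, block = block,
    true_polarity = ifelse(is.na(prot), NA_character_,
                           ifelse(prot, "derived_protective", "derived_risk")))
  realized <- lapply(c(MD = "MD", AD = "AD"), function(l) {
    pr <- prot[!is.na(lineage) & lineage == l]
    c(n_risk = sum(!pr), n_protective = sum(pr),
      theta = if (sum(!pr) > 0) sum(pr) / sum(!pr) else NA_real_)
  })
  truth <- list(table = truth_tab, realized = realized,
                p_coupling = config$p_coupling)

  list(sites = sites, gwas = gwas, maf = maf_tab, truth = truth)
}

#' Simulate a complete dataset (panel + catalog + GWAS + MAF)
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `sites`, `gwas`, `maf`, `truth`, `config`;
#'   class `sim_dataset`.
#' @export
simulate_dataset <- function(config) {
  panel <- simulate_panel(config)
  rest <- simulate_catalog_and_gwas(config, panel)
  structure(c(list(panel = panel), rest, list(config = config)),
            class = "sim_dataset")
}

#' Write a simulated dataset in the dialects the readers consume
#'
#' Emits `gwas.tsv`, `sites.tsv`, `maf.tsv` (canonical headers) and
#' `panel.vcf`. Same configuration and seed give byte-identical files.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gwas = file.path(dir, "gwas.tsv"),
             sites = file.path(dir, "sites.tsv"),
             maf = file.path(dir, "maf.tsv"),
             panel = file.path(dir, "panel.vcf"))
  data.table::fwrite(sim$gwas, paths[["gwas"]], sep = "\t", quote = FALSE)
  data.table::fwrite(sim$sites, paths[["sites"]], sep = "\t", quote = FALSE)
  data.table::fwrite(sim$maf, paths[["maf"]], sep = "\t", quote = FALSE)
  write_panel_vcf(sim$panel, paths[["panel"]])
  paths
}
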