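# End-to-end orchestration: (simulate | read) -> prune -> join/annotate
# -> bin -> enrichment + ratio -> tables and run summary, with a batch
# mode that applies the identical pipeline to several GWAS datasets
# (the cross-disorder design).

#' Deterministic per-stage child seed
#'
#' One global seed fans out to per-stage seeds so each stage is
#' individually reproducible; `stage` is a small integer unique to
#' (dataset, stage).
#'
#' @param seed global integer seed.
#' @param stage stage index.
#' @return integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 16807) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param datasets named list of dataset descriptors; each is either
#'   `list(sim = sim_config(...))` or `list(paths = list(gwas=, sites=,
#'   maf=, panel=), dialect = gwas_dialect(...))` (dialect optional,
#'   canonical headers assumed). A bare `sim_config` is accepted and
#'   wrapped as a single dataset named `"dataset1"`.
#' @param prune a [prune_config()]; its seed is overridden by the
#'   fanned-out stage seed.
#' @param do_prune run LD pruning (needs a panel).
#' @param maf_threshold strict MAF upper bound, default 0.1.
#' @param maf_filter_scope `"both"` (default): the MAF filter applies to
#'   the enrichment and the ratio analysis; `"enrichment_only"`: the
#'   ratio analysis uses all pruned, site-joined SNPs.
#' @param n_bins,bin_mode,edges binning controls, see [make_bins()].
#' @param fscore_convention `"bc_over_ad"` (the published form) or
#'   `"obs_over_exp"`; both columns are always computed, this names the
#'   headline convention in the run summary.
#' @param seed global seed.
#' @param out_dir if non-`NULL`, per-dataset result TSVs, input copies
#'   and JSON run summaries are written here.
#' @return list of class `run_config`.
#' @export
run_config <- function(datasets,
                       prune = prune_config(),
                       do_prune = TRUE,
                       maf_threshold = 0.1,
                       maf_filter_scope = c("both", "enrichment_only"),
                       n_bins = 10L,
                       bin_mode = c("empirical", "fixed"),
                       edges = NULL,
                       fscore_convention = c("bc_over_ad", "obs_over_exp"),
                       seed = 1L,
                       out_dir = NULL) {
  if (inherits(datasets, "sim_config"))
    datasets <- list(dataset1 = list(sim = datasets))
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            !is.null(names(datasets)), all(nzchar(names(datasets))))
  for (d in datasets) {
    if (!is.null(d$paths)) {
      missing_paths <- !vapply(unlist(d$paths), file.exists, logical(1))
      if (any(missing_paths))
        stop("input path(s) do not exist: ",
             paste(unlist(d$paths)[missing_paths], collapse = ", "))
    } else if (is.null(d$sim)) {
      stop("each dataset needs either $sim or $paths")
    }
  }
  structure(list(datasets = datasets, prune = prune, do_prune = do_prune,
                 maf_threshold = maf_threshold,
                 maf_filter_scope = match.arg(maf_filter_scope),
                 n_bins = as.integer(n_bins),
                 bin_mode = match.arg(bin_mode), edges = edges,
                 fscore_convention = match.arg(fscore_convention),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.merge_bin_tables <- function(enr, rat) {
  out <- merge(enr, rat[, !c("p_upper", "p_lower")],
               by = c("bin_index", "lineage"), sort = FALSE)
  data.table::setorder(out, lineage, bin_index)
  data.table::setcolorder(out, .BIN_RESULT_COLS)
  out[]
}

.run_one <- function(name, dset, config, dataset_index) {
  seed_of <- function(stage) stage_seed(config$seed,
                                        dataset_index * 10L + stage)
  counts <- list()
  input_digests <- NULL

  if (!is.null(dset$sim)) {
    sim_cfg <- dset$sim
    sim_cfg$seed <- seed_of(1L)
    sim <- if (config$do_prune) simulate_dataset(sim_cfg) else {
      structure(c(list(panel = NULL),
                  simulate_catalog_and_gwas(sim_cfg),
                  list(config = sim_cfg)), class = "sim_dataset")
    }
    gwas <- sim$gwas; sites <- sim$sites; maf_tab <- sim$maf
    panel <- sim$panel
    truth <- sim$truth
    if (!is.null(config$out_dir)) {
      in_dir <- file.path(config$out_dir, paste0(name, "_inputs"))
      if (!is.null(panel)) {
        paths <- write_sim_dataset(sim, in_dir)
      } else {
        dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
        paths <- c(gwas = file.path(in_dir, "gwas.tsv"),
                   sites = file.path(in_dir, "sites.tsv"),
                   maf = file.path(in_dir, "maf.tsv"))
        data.table::fwrite(gwas, paths[["gwas"]], sep = "\t", quote = FALSE)
        data.table::fwrite(sites, paths[["sites"]], sep = "\t", quote = FALSE)
        data.table::fwrite(maf_tab, paths[["maf"]], sep = "\t", quote = FALSE)
      }
      input_digests <- as.list(setNames(unname(tools::md5sum(paths)),
                                        names(paths)))
    }
  } else {
    dialect <- if (is.null(dset$dialect)) canonical_dialect() else dset$dialect
    gwas <- read_gwas(dset$paths$gwas, dialect)
    sites <- read_site_catalog(dset$paths$sites)
    maf_tab <- read_maf_table(dset$paths$maf)
    panel <- if (!is.null(dset$paths$panel))
      read_panel_vcf(dset$paths$panel) else NULL
    truth <- NULL
    p_in <- unlist(dset$paths)
    input_digests <- as.list(setNames(unname(tools::md5sum(p_in)),
                                      names(p_in)))
    counts$read_rejects <- list(gwas = attr(gwas, "rejects"),
                                sites = attr(sites, "rejects"),
                                maf = attr(maf_tab, "rejects"))
  }
  counts$n_gwas <- nrow(gwas)

  if (config$do_prune) {
    if (is.null(panel)) stop("[prune] no reference panel available")
    pc <- config$prune
    pc$seed <- seed_of(2L)
    pr <- ld_prune(gwas, panel, pc)
    gwas <- gwas[gwas$snp_id %in% pr$retained]
    counts$prune <- list(n_retained = length(pr$retained),
                         n_removed = length(pr$removed),
                         n_pairs_flagged = pr$n_pairs_flagged,
                         n_unresolved = pr$n_unresolved)
  }

  joined <- join_sites(gwas, sites)
  counts$join <- as.list(attr(joined, "join_stats"))
  joined <- attach_maf(joined, maf_tab)
  joined <- annotate_polarity(joined)
  counts$polarity <- as.list(table(joined$polarity, useNA = "no"))
  counts$polarity_unresolved_reasons <-
    as.list(table(joined$polarity_reason, useNA = "no"))

  analyzed <- maf_filter(joined, config$maf_threshold)
  counts$n_maf_filtered <- nrow(analyzed)
  if (nrow(analyzed) < config$n_bins)
    stop("[bin] fewer analyzed SNPs than bins")
  partition <- make_bins(analyzed$p_value, config$n_bins,
                         config$bin_mode, config$edges)
  enr <- enrichment_by_bin(analyzed, partition)

  if (config$maf_filter_scope == "both") {
    rat <- ratio_by_bin(analyzed, partition)
  } else {
    ratio_univ <- joined[is.na(joined$exclusion_reason) |
                           joined$exclusion_reason == "no_maf"]
    part2 <- partition
    part2$bin <- assign_bins(ratio_univ$p_value, partition)
    rat <- ratio_by_bin(ratio_univ, part2)
  }
  results <- .merge_bin_tables(enr, rat)
  overall <- overall_contrast(results)

  summary <- list(
    dataset = name,
    seed = config$seed,
    stage_seeds = list(simulate = seed_of(1L), prune = seed_of(2L)),
    config = list(
      do_prune = config$do_prune,
      prune_window_bp = config$prune$window_bp,
      prune_r2_threshold = config$prune$r2_threshold,
      maf_threshold = config$maf_threshold,
      maf_filter_scope = config$maf_filter_scope,
      n_bins = config$n_bins, bin_mode = config$bin_mode,
      fscore_convention = config$fscore_convention,
      sim = if (!is.null(dset$sim)) unclass(dset$sim) else NULL),
    input_digests = input_digests,
    counts = counts,
    bin_edges = partition$edges,
    overall = overall)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bin_results(results,
                      file.path(config$out_dir,
                                paste0(name, "_bin_results.tsv")))
    write_run_summary(summary,
                      file.path(config$out_dir,
                                paste0(name, "_run_summary.json")))
  }
  list(bin_results = results, overall = overall, summary = summary,
       annotated = joined, truth = truth, partition = partition)
}

#' Run the full analysis pipeline
#'
#' Stage order: LD pruning first (the statistical tests assume
#' independent SNPs), then site joining, MAF attachment and filtering,
#' polarity classification, decile binning, and finally the enrichment
#' and ratio analyses with their per-bin and overall contrasts. Identical
#' configuration and seed give byte-identical output files. In batch
#' mode every dataset runs through the identical pipeline with its own
#' fanned-out stage seeds.
#'
#' @param config a [run_config()].
#' @return list of class `run_bundle`: one element per dataset (each with
#'   `bin_results`, `overall`, `summary`, `annotated`, `truth`,
#'   `partition`) plus the echoed `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- vector("list", length(config$datasets))
  names(out) <- names(config$datasets)
  for (i in seq_along(config$datasets)) {
    name <- names(config$datasets)[i]
    message("== dataset ", name, " ==")
    out[[i]] <- tryCatch(
      .run_one(name, config$datasets[[i]], config, i),
      error = function(e) stop("[", name, "] ", conditionMessage(e),
                               call. = FALSE))
  }
  structure(list(datasets = out, config = config), class = "run_bundle")
}

#' Human-readable run report
#'
#' @param bundle a `run_bundle` from [run_pipeline()].
#' @param digits significant digits for printed numbers.
#' @return the bundle, invisibly; the report is printed.
#' @export
report <- function(bundle, digits = 3) {
  stopifnot(inherits(bundle, "run_bundle"))
  cfg <- bundle$config
  cat("archaicsel run report\n")
  cat(sprintf(
    "  seed %d | prune: %s (window %g bp, r2 > %g) | MAF < %g (%s) | %d %s bins | F convention: %s\n\n",
    cfg$seed, if (cfg$do_prune) "on" else "off", cfg$prune$window_bp,
    cfg$prune$r2_threshold, cfg$maf_threshold, cfg$maf_filter_scope,
    cfg$n_bins, cfg$bin_mode, cfg$fscore_convention))
  fcol <- if (cfg$fscore_convention == "bc_over_ad")
    "f_bc_over_ad" else "f_obs_over_exp"
  for (name in names(bundle$datasets)) {
    d <- bundle$datasets[[name]]
    cat("--", name, "--\n")
    br <- d$bin_results
    for (l in c("MD", "AD")) {
      cat(sprintf(" lineage %s (b = %d of a = %d analyzed SNPs)\n", l,
                  br[br$lineage == l]$n_genome_in_sites[1],
                  br[br$lineage == l]$n_genome_total[1]))
      sub <- br[br$lineage == l,
                c("bin_index", "p_upper", "p_lower", "n_bin_total",
                  "n_bin_in_sites", fcol, "n_derived_risk",
                  "n_derived_protective", "risk_protective_ratio",
                  "p_enrichment_md_vs_ad", "p_ratio_md_vs_ad"),
                with = FALSE]
      print(data.frame(lapply(sub, function(x)
        if (is.numeric(x)) signif(x, digits) else x)), row.names = FALSE)
    }
    ov <- d$overall
    cat(sprintf(
      " overall: enrichment MD-vs-AD pooled p = %s; homogeneity p (MD %s, AD %s)\n",
      signif(ov$enrichment$p_pooled_md_vs_ad, digits),
      signif(ov$enrichment$p_homogeneity_md, digits),
      signif(ov$enrichment$p_homogeneity_ad, digits)))
    cat(sprintf(
      "          ratio MD %s, AD %s; MD-vs-AD pooled p = %s\n\n",
      signif(ov$ratio$pooled_ratio_md, digits),
      signif(ov$ratio$pooled_ratio_ad, digits),
      signif(ov$ratio$p_pooled_md_vs_ad, digits)))
  }
  invisible(bundle)
}
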