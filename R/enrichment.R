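# Decile binning of association p-values, the fold-change enrichment
# score over the a/b/c/d contingency counts, derived-risk /
# derived-protective ratios, and Fisher exact contrasts of MD vs AD
# sites per bin and overall.

#' Partition p-values into decile bins
#'
#' Bins are indexed from the highest-p decile (bin 1) down to the
#' lowest-p decile (bin `n_bins`). Each interval is closed on its high-p
#' side and half-open on its low-p side, except the lowest interval which
#' is closed at 0; a p-value lying exactly on an interior edge therefore
#' falls into the bin whose upper edge it is. In `empirical` mode the
#' edges are sample quantiles of the supplied p-values (outer edges fixed
#' at 1 and 0); in `fixed` mode a caller-supplied edge list is applied
#' verbatim.
#'
#' @param p finite p-values in `[0, 1]`.
#' @param n_bins number of bins (default 10).
#' @param mode `"empirical"` or `"fixed"`.
#' @param edges for `fixed` mode: `n_bins + 1` strictly monotone edges
#'   (either order accepted; stored descending).
#' @return object of class `bin_partition`: `edges` (descending),
#'   `n_bins`, `mode`, and `bin` (the per-value bin index).
#' @export
make_bins <- function(p, n_bins = 10L, mode = c("empirical", "fixed"),
                      edges = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(p))) stop("non-finite p-values")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  if (mode == "empirical") {
    if (length(p) < n_bins)
      stop("need at least n_bins p-values for empirical edges")
    qs <- quantile(p, probs = seq_len(n_bins - 1L) / n_bins, names = FALSE)
    edges <- c(1, rev(qs), 0)
  } else {
    if (is.null(edges) || length(edges) != n_bins + 1L)
      stop("fixed mode needs n_bins + 1 edges")
    edges <- sort(as.numeric(edges), decreasing = TRUE)
  }
  if (anyDuplicated(edges))
    stop("tied bin edges; cannot form ", n_bins, " distinct bins")
  partition <- structure(list(edges = edges, n_bins = as.integer(n_bins),
                              mode = mode),
                         class = "bin_partition")
  partition$bin <- assign_bins(p, partition)
  partition
}

#' @rdname make_bins
#' @param partition an existing `bin_partition` whose edges are reused.
#' @export
assign_bins <- function(p, partition) {
  stopifnot(inherits(partition, "bin_partition"))
  asc <- rev(partition$edges)
  idx <- cut(p, breaks = asc, right = TRUE, include.lowest = TRUE,
             labels = FALSE)
  partition$n_bins + 1L - idx
}

#' Fold-change enrichment score
#'
#' Over the counts `a` (all analyzed SNPs genome-wide), `b` (those within
#' MD or AD sites), `c` (SNPs in the queried p-value bin) and `d` (bin
#' SNPs within sites), the score as published is `(b*c) / (a*d)`
#' (`"bc_over_ad"`, the default); its reciprocal `(a*d) / (b*c)`
#' (`"obs_over_exp"`) is the observed proportion `d/c` over the expected
#' proportion `b/a`. The two conventions are exact reciprocals whenever
#' both are defined; every result records which one was used.
#'
#' @param a,b,c,d nonnegative counts (vectorized); must satisfy `b <= a`,
#'   `d <= c`, `d <= b`.
#' @param convention `"bc_over_ad"` or `"obs_over_exp"`.
#' @return numeric score, `NA` where the denominator is zero.
#' @export
fscore <- function(a, b, c, d, convention = c("bc_over_ad", "obs_over_exp")) {
  convention <- match.arg(convention)
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0),
            all(b <= a), all(d <= c), all(d <= b))
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (convention == "bc_over_ad") {
    out <- ifelse(a * d == 0, NA_real_, (b * c) / (a * d))
  } else {
    out <- ifelse(b * c == 0, NA_real_, (a * d) / (b * c))
  }
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Standard two-sided definition: the sum of hypergeometric probabilities
#' of all tables with the observed margins whose point probability does
#' not exceed the observed table's. A table with any zero margin carries
#' no information; by convention its p-value is 1, flagged in the result.
#'
#' @param tab 2x2 matrix of nonnegative integers.
#' @return list with `p_value`, `odds_ratio` (conditional MLE, `NA` for
#'   zero-margin tables) and `zero_margin`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_, zero_margin = TRUE))
  ft <- fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       zero_margin = FALSE)
}

.fisher_p <- function(x11, x12, x21, x22) {
  fisher_exact_2x2(matrix(c(x11, x21, x12, x22), 2L))$p_value
}

#' Per-bin enrichment of site-overlapping SNPs
#'
#' For each bin and lineage, forms the contingency counts (`a` and `b`
#' computed on the identical analyzed SNP universe used for binning, so
#' that per lineage the bin counts conserve: sum of `d` = `b`, sum of
#' `c` = `a`), both F-score conventions, the per-bin MD-vs-AD membership
#' contrast (Fisher on `[[d_MD, c - d_MD], [d_AD, c - d_AD]]`) and each
#' lineage's bin-vs-rest-of-genome contrast.
#'
#' @param annotated analyzed (pruned, MAF-filtered) table including the
#'   genome-wide background rows (`lineage` `NA` for SNPs outside sites).
#' @param partition `bin_partition` built on (or aligned with) the same
#'   rows; `annotated` and `partition$bin` must have equal length.
#' @return `data.table`, one row per (bin, lineage), with counts,
#'   F-scores and p-values; `NA` marks undefined cells. Empty bins give
#'   undefined F and `NA` contrast p.
#' @export
enrichment_by_bin <- function(annotated, partition) {
  g <- data.table::as.data.table(annotated)
  stopifnot(nrow(g) == length(partition$bin))
  nb <- partition$n_bins
  bin <- partition$bin
  a <- nrow(g)
  res <- data.table::rbindlist(lapply(c("MD", "AD"), function(l) {
    in_l <- !is.na(g$lineage) & g$lineage == l
    b <- sum(in_l)
    dt <- data.table::data.table(
      bin_index = seq_len(nb),
      p_upper = partition$edges[seq_len(nb)],
      p_lower = partition$edges[seq_len(nb) + 1L],
      lineage = l,
      n_genome_total = a,
      n_genome_in_sites = b,
      n_bin_total = vapply(seq_len(nb), function(k) sum(bin == k), integer(1)),
      n_bin_in_sites = vapply(seq_len(nb), function(k) sum(bin == k & in_l),
                              integer(1)))
    dt[, f_bc_over_ad := fscore(n_genome_total, n_genome_in_sites,
                                n_bin_total, n_bin_in_sites, "bc_over_ad")]
    dt[, f_obs_over_exp := fscore(n_genome_total, n_genome_in_sites,
                                  n_bin_total, n_bin_in_sites,
                                  "obs_over_exp")]
    dt
  }))
  # per-bin MD vs AD membership contrast (same value for both rows)
  md <- res[lineage == "MD"]; ad <- res[lineage == "AD"]
  p_enr <- vapply(seq_len(nb), function(k) {
    ck <- md$n_bin_total[k]
    if (ck == 0L) return(NA_real_)
    .fisher_p(md$n_bin_in_sites[k], ck - md$n_bin_in_sites[k],
              ad$n_bin_in_sites[k], ck - ad$n_bin_in_sites[k])
  }, numeric(1))
  res[, p_enrichment_md_vs_ad := rep(p_enr, 2L)]
  # each lineage against the rest of the analyzed genome
  res[, p_lineage_vs_background := vapply(seq_len(.N), function(i) {
    ck <- n_bin_total[i]; dk <- n_bin_in_sites[i]
    bk <- n_genome_in_sites[i]; ak <- n_genome_total[i]
    if (ck == 0L || ak == ck) return(NA_real_)
    .fisher_p(dk, ck - dk, bk - dk, (ak - ck) - (bk - dk))
  }, numeric(1))]
  res[]
}

#' Per-bin derived-risk / derived-protective ratios
#'
#' Counts polarity-resolved SNPs per bin and lineage, forms the
#' risk:protective ratio (undefined when the protective count is 0) and
#' the per-bin MD-vs-AD polarity contrast, a Fisher exact test on
#' `[[risk_MD, protective_MD], [risk_AD, protective_AD]]`. Bins with zero
#' resolved SNPs in either lineage give `NA` for that contrast.
#'
#' @inheritParams enrichment_by_bin
#' @return `data.table`, one row per (bin, lineage).
#' @export
ratio_by_bin <- function(annotated, partition) {
  g <- data.table::as.data.table(annotated)
  stopifnot(nrow(g) == length(partition$bin))
  nb <- partition$n_bins
  bin <- partition$bin
  resolved <- !is.na(g$polarity) &
    g$polarity %in% c("derived_risk", "derived_protective")
  res <- data.table::rbindlist(lapply(c("MD", "AD"), function(l) {
    in_l <- resolved & g$lineage == l
    data.table::data.table(
      bin_index = seq_len(nb),
      p_upper = partition$edges[seq_len(nb)],
      p_lower = partition$edges[seq_len(nb) + 1L],
      lineage = l,
      n_derived_risk = vapply(seq_len(nb), function(k)
        sum(bin == k & in_l & g$polarity == "derived_risk"), integer(1)),
      n_derived_protective = vapply(seq_len(nb), function(k)
        sum(bin == k & in_l & g$polarity == "derived_protective"),
        integer(1)))
  }))
  res[, risk_protective_ratio :=
        ifelse(n_derived_protective == 0, NA_real_,
               n_derived_risk / n_derived_protective)]
  md <- res[lineage == "MD"]; ad <- res[lineage == "AD"]
  p_rat <- vapply(seq_len(nb), function(k) {
    n_md <- md$n_derived_risk[k] + md$n_derived_protective[k]
    n_ad <- ad$n_derived_risk[k] + ad$n_derived_protective[k]
    if (n_md == 0L || n_ad == 0L) return(NA_real_)
    .fisher_p(md$n_derived_risk[k], md$n_derived_protective[k],
              ad$n_derived_risk[k], ad$n_derived_protective[k])
  }, numeric(1))
  res[, p_ratio_md_vs_ad := rep(p_rat, 2L)]
  res[]
}

#' Full per-bin result table
#'
#' Merges [enrichment_by_bin()] and [ratio_by_bin()] into the long-format
#' (bin x lineage) table written by [write_bin_results()].
#'
#' @inheritParams enrichment_by_bin
#' @return `data.table` with the fixed result-column layout.
#' @export
bin_result_table <- function(annotated, partition) {
  enr <- enrichment_by_bin(annotated, partition)
  rat <- ratio_by_bin(annotated, partition)
  out <- merge(enr, rat[, !c("p_upper", "p_lower")],
               by = c("bin_index", "lineage"), sort = FALSE)
  data.table::setorder(out, lineage, bin_index)
  data.table::setcolorder(out, .BIN_RESULT_COLS)
  out[]
}

#' Overall MD-vs-AD contrasts across all bins
#'
#' Pools the per-bin tables by summing counts over bins (the default
#' aggregation) and tests the pooled 2x2 with Fisher's exact test, for
#' both the membership (enrichment) and polarity (ratio) contrasts. Also
#' emits, per lineage, a chi-square homogeneity test of the site
#' proportion across bins, and a Fisher's-method combination of the
#' per-bin p-values, so both readings of an "overall p-value across all
#' bins" are available. The aggregation used is recorded in the result.
#'
#' @param bin_results table from [bin_result_table()] (or one carrying
#'   the same columns).
#' @return named list of pooled counts, ratios and p-values.
#' @export
overall_contrast <- function(bin_results) {
  br <- data.table::as.data.table(bin_results)
  md <- br[lineage == "MD"]; ad <- br[lineage == "AD"]
  a <- md$n_genome_total[1L]
  b_md <- md$n_genome_in_sites[1L]; b_ad <- ad$n_genome_in_sites[1L]
  risk_md <- sum(md$n_derived_risk); prot_md <- sum(md$n_derived_protective)
  risk_ad <- sum(ad$n_derived_risk); prot_ad <- sum(ad$n_derived_protective)

  homog <- function(side) {
    keep <- side$n_bin_total > 0L
    if (sum(keep) < 2L) return(NA_real_)
    m <- rbind(side$n_bin_in_sites[keep],
               side$n_bin_total[keep] - side$n_bin_in_sites[keep])
    suppressWarnings(chisq.test(m)$p.value)
  }
  combine_bins <- function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    stat <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
    pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  }

  list(
    aggregation = "pooled 2x2 over bins, Fisher exact (default); per-bin Fisher combination and per-lineage chi-square homogeneity also reported",
    enrichment = list(
      p_pooled_md_vs_ad = .fisher_p(b_md, a - b_md, b_ad, a - b_ad),
      p_homogeneity_md = homog(md),
      p_homogeneity_ad = homog(ad),
      p_combined_bins = combine_bins(
        md$p_enrichment_md_vs_ad[!duplicated(md$bin_index)])),
    ratio = list(
      pooled_counts = c(risk_md = risk_md, protective_md = prot_md,
                        risk_ad = risk_ad, protective_ad = prot_ad),
      pooled_ratio_md = if (prot_md > 0) risk_md / prot_md else NA_real_,
      pooled_ratio_ad = if (prot_ad > 0) risk_ad / prot_ad else NA_real_,
      p_pooled_md_vs_ad = .fisher_p(risk_md, prot_md, risk_ad, prot_ad),
      p_combined_bins = combine_bins(
        md$p_ratio_md_vs_ad[!duplicated(md$bin_index)])))
}
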