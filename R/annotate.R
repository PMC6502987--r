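# MAF attachment and filtering, and polarization of GWAS effect
# directions against the catalog's ancestral allele.

#' Attach minor allele frequencies to an annotated GWAS table
#'
#' SNPs without a MAF entry are marked excluded with reason `"no_maf"`
#' (counted, not fatal).
#'
#' @param annotated table from [join_sites()].
#' @param maf_table table from [read_maf_table()].
#' @return the table with `maf` filled and `exclusion_reason` updated.
#' @export
attach_maf <- function(annotated, maf_table) {
  g <- data.table::copy(data.table::as.data.table(annotated))
  m <- data.table::as.data.table(maf_table)
  idx <- match(g$snp_id, m$snp_id)
  g[, maf := m$maf[idx]]
  miss <- is.na(idx)
  g[miss & is.na(exclusion_reason), exclusion_reason := "no_maf"]
  if (any(miss))
    message("attach_maf: ", sum(miss), " SNP(s) without a MAF entry excluded")
  g[]
}

#' Apply the MAF filter
#'
#' Retains SNPs with `maf` strictly below the threshold, matching the
#' frequency ceiling of human-specific variants; SNPs at exactly the
#' threshold are excluded. SNPs already carrying an exclusion reason are
#' dropped as well.
#'
#' @param annotated table with `maf` attached.
#' @param threshold strict upper bound, default 0.1.
#' @return filtered table.
#' @export
maf_filter <- function(annotated, threshold = 0.1) {
  g <- data.table::as.data.table(annotated)
  out <- g[!is.na(maf) & maf < threshold & is.na(exclusion_reason)]
  message(sprintf("maf_filter: %d of %d SNPs retained at MAF < %g",
                  nrow(out), nrow(g), threshold))
  out
}

#' Polarize one or more GWAS records against the ancestral allele
#'
#' The risk allele is the effect allele when `OR > 1` and the other
#' allele when `OR < 1`. If the site's ancestral allele equals one GWAS
#' allele directly, the derived GWAS allele is the non-ancestral one;
#' when neither matches directly, both GWAS alleles are complemented and
#' matching is retried — except for strand-ambiguous A/T and C/G SNPs,
#' which are never complement-resolved. The call is `derived_risk` when
#' the derived allele is the risk allele (the ancestral allele then being
#' protective) and `derived_protective` when it is the protective allele.
#'
#' Unresolved reasons: `"no_direction"` (`OR` exactly 1),
#' `"strand_ambiguous"` (A/T or C/G SNP requiring complementing),
#' `"allele_mismatch"` (ancestral allele matches neither GWAS allele in
#' either orientation).
#'
#' @param allele_effect,allele_other GWAS alleles (vectors).
#' @param odds_ratio per-effect-allele odds ratio.
#' @param allele_ancestral the site's ancestral allele.
#' @return `data.table` with columns `polarity` (`derived_risk`,
#'   `derived_protective`, `unresolved`) and `polarity_reason` (`NA` when
#'   resolved).
#' @export
classify_polarity <- function(allele_effect, allele_other, odds_ratio,
                              allele_ancestral) {
  n <- length(allele_effect)
  stopifnot(length(allele_other) == n, length(odds_ratio) == n,
            length(allele_ancestral) == n)
  polarity <- rep("unresolved", n)
  reason <- rep(NA_character_, n)

  direct <- allele_ancestral == allele_effect |
    allele_ancestral == allele_other
  ambiguous <- allele_other == .COMP[allele_effect]
  comp_match <- !direct &
    (allele_ancestral == .COMP[allele_effect] |
       allele_ancestral == .COMP[allele_other])

  no_dir <- odds_ratio == 1
  # an A/T or C/G pair maps onto itself under complementing, so whenever
  # the direct match fails on such a SNP no orientation can be trusted
  strand <- !no_dir & !direct & ambiguous
  mismatch <- !no_dir & !direct & !ambiguous & !comp_match
  resolvable <- !no_dir & (direct | (comp_match & !ambiguous))

  reason[mismatch] <- "allele_mismatch"
  reason[strand] <- "strand_ambiguous"
  reason[no_dir] <- "no_direction"

  # after complementing both alleles the ancestral state maps onto the
  # original effect/other slots, so polarity is decided on those slots
  anc_is_effect <- ifelse(direct, allele_ancestral == allele_effect,
                          allele_ancestral == .COMP[allele_effect])
  derived_is_effect <- !anc_is_effect
  risk_is_effect <- odds_ratio > 1
  derived_is_risk <- derived_is_effect == risk_is_effect
  polarity[resolvable & derived_is_risk] <- "derived_risk"
  polarity[resolvable & !derived_is_risk] <- "derived_protective"

  data.table::data.table(polarity = polarity, polarity_reason = reason)
}

#' Polarize all site-overlapping SNPs of an annotated table
#'
#' Applies [classify_polarity()] to every row joined to a site; rows
#' without a site keep `polarity = NA`. Unresolved SNPs stay in the table
#' (they are excluded from the ratio analysis downstream, with counted
#' reasons).
#'
#' @param annotated table from [join_sites()] (MAF columns optional).
#' @return the table with `polarity` and `polarity_reason` filled.
#' @export
annotate_polarity <- function(annotated) {
  g <- data.table::copy(data.table::as.data.table(annotated))
  site <- !is.na(g$lineage)
  if (any(site)) {
    cls <- classify_polarity(g$allele_effect[site], g$allele_other[site],
                             g$odds_ratio[site], g$allele_ancestral[site])
    g[site, polarity := cls$polarity]
    g[site, polarity_reason := cls$polarity_reason]
    unres <- table(cls$polarity_reason)
    msg <- sprintf("annotate_polarity: %d resolved, %d unresolved",
                   sum(cls$polarity != "unresolved"),
                   sum(cls$polarity == "unresolved"))
    if (length(unres))
      msg <- paste0(msg, " (", paste(sprintf("%s: %d", names(unres), unres),
                                     collapse = ", "), ")")
    message(msg)
  }
  g[]
}
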