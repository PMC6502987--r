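# Readers, writers and the join between GWAS summary statistics and the
# human-specific-site catalog. All tables are data.tables with fixed,
# canonical column names; every reader validates rows and reports reject
# counts by reason so that accepted + rejected always equals the input
# row count.

#' Column-name mapping for a GWAS summary-statistics file
#'
#' Maps the canonical field names used throughout the package onto the
#' column headers actually present in a file. The default corresponds to
#' the PGC "daner" convention (`SNP`/`CHR`/`BP`/`A1`/`A2`/`OR`/`P`); the
#' synthetic generator writes canonical headers, for which
#' `gwas_dialect(snp_id = "snp_id", chrom = "chrom", ...)` or simply
#' [canonical_dialect()] is used.
#'
#' @param snp_id,chrom,pos,allele_effect,allele_other,odds_ratio,p_value
#'   column header carrying each canonical field.
#' @return named list mapping canonical names to file headers.
#' @export
gwas_dialect <- function(snp_id = "SNP", chrom = "CHR", pos = "BP",
                         allele_effect = "A1", allele_other = "A2",
                         odds_ratio = "OR", p_value = "P") {
  list(snp_id = snp_id, chrom = chrom, pos = pos,
       allele_effect = allele_effect, allele_other = allele_other,
       odds_ratio = odds_ratio, p_value = p_value)
}

#' @rdname gwas_dialect
#' @export
canonical_dialect <- function() {
  do.call(gwas_dialect, as.list(setNames(.GWAS_COLS, .GWAS_COLS)))
}

.reject_summary <- function(reason) {
  r <- reason[!is.na(reason)]
  if (!length(r)) return(integer(0))
  tab <- table(r)
  setNames(as.integer(tab), names(tab))
}

.announce <- function(what, n_in, n_ok, rejects) {
  msg <- sprintf("%s: %d rows read, %d accepted, %d rejected",
                 what, n_in, n_ok, n_in - n_ok)
  if (length(rejects))
    msg <- paste0(msg, " (", paste(sprintf("%s: %d", names(rejects), rejects),
                                   collapse = ", "), ")")
  message(msg)
}

#' Read GWAS summary statistics
#'
#' Reads a delimited text file of per-SNP association summaries. Rows are
#' validated against the domain invariants: alleles must be single
#' nucleotides in `A/C/G/T` and differ; the odds ratio must be a positive
#' number; the p-value must lie in `[0, 1]`; `(chrom, pos)` must be unique
#' (the first occurrence is kept, later duplicates are rejected with a
#' warning). Multi-allelic or otherwise malformed rows are rejected, never
#' fatal; a missing mandatory column is a hard error.
#'
#' @param path delimited text file with a header.
#' @param dialect column-name mapping from [gwas_dialect()].
#' @return `data.table` with canonical columns `snp_id, chrom, pos,
#'   allele_effect, allele_other, odds_ratio, p_value`. Attributes
#'   `n_input` and `rejects` (named integer vector of reason counts) carry
#'   the audit trail.
#' @export
read_gwas <- function(path, dialect = gwas_dialect()) {
  stopifnot(all(.GWAS_COLS %in% names(dialect)))
  raw <- data.table::fread(path, colClasses = "character",
                           na.strings = c("NA", ""), showProgress = FALSE)
  want <- unlist(dialect[.GWAS_COLS], use.names = FALSE)
  missing_cols <- setdiff(want, names(raw))
  if (length(missing_cols))
    stop("GWAS file ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  dt <- raw[, want, with = FALSE]
  data.table::setnames(dt, .GWAS_COLS)
  dt[, chrom := as.character(chrom)]
  dt[, pos := suppressWarnings(as.integer(pos))]
  dt[, allele_effect := toupper(allele_effect)]
  dt[, allele_other := toupper(allele_other)]
  dt[, odds_ratio := suppressWarnings(as.numeric(odds_ratio))]
  dt[, p_value := suppressWarnings(as.numeric(p_value))]

  reason <- rep(NA_character_, nrow(dt))
  bad_pos <- is.na(dt$pos) | dt$pos < 1L | is.na(dt$chrom)
  bad_allele <- !(dt$allele_effect %in% .NUCS) |
    !(dt$allele_other %in% .NUCS) |
    (dt$allele_effect == dt$allele_other)
  bad_or <- is.na(dt$odds_ratio) | dt$odds_ratio <= 0
  bad_p <- is.na(dt$p_value) | dt$p_value < 0 | dt$p_value > 1
  reason[bad_p] <- "bad_p_value"
  reason[bad_or] <- "bad_odds_ratio"
  reason[bad_allele] <- "bad_allele"
  reason[bad_pos] <- "bad_position"

  ok <- is.na(reason)
  # a row is a duplicate only relative to an earlier *accepted* row
  key <- paste(dt$chrom, dt$pos)
  first_ok <- !duplicated(ifelse(ok, key, paste0("bad", seq_along(key))))
  dup <- ok & !first_ok
  reason[dup] <- "duplicate_position"
  if (any(dup))
    warning(sum(dup), " GWAS row(s) with duplicated (chrom, pos) rejected; ",
            "first occurrence kept", call. = FALSE)

  out <- dt[is.na(reason)]
  rejects <- .reject_summary(reason)
  .announce("read_gwas", nrow(dt), nrow(out), rejects)
  data.table::setattr(out, "n_input", nrow(dt))
  data.table::setattr(out, "rejects", rejects)
  out[]
}

#' Read a human-specific-site catalog
#'
#' Each row is one genomic site carrying its ancestral allele (state of the
#' chimpanzee outgroup), its derived allele, and its lineage class:
#' `MD` (modern-human-specific: archaic genomes carry the derived allele,
#' modern humans the ancestral one at > 90% frequency) or `AD`
#' (archaic-human-specific, the converse). Rows with a lineage outside
#' `{MD, AD}`, invalid alleles, `ancestral == derived`, or a duplicated
#' `(chrom, pos)` are rejected and counted.
#'
#' @param path headered TSV with columns `chrom, pos, snp_id (optional),
#'   allele_ancestral, allele_derived, lineage`.
#' @return validated `data.table`; attributes `n_input`, `rejects`, and
#'   `lineage_counts`.
#' @export
read_site_catalog <- function(path) {
  raw <- data.table::fread(path, colClasses = "character",
                           na.strings = c("NA", ""), showProgress = FALSE)
  need <- c("chrom", "pos", "allele_ancestral", "allele_derived", "lineage")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("site catalog lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"snp_id" %in% names(raw)) raw[, snp_id := NA_character_]
  dt <- raw[, c("snp_id", need), with = FALSE]
  dt[, pos := suppressWarnings(as.integer(pos))]
  dt[, allele_ancestral := toupper(allele_ancestral)]
  dt[, allele_derived := toupper(allele_derived)]

  if (nrow(dt) == 0L) {
    warning("site catalog ", path, " is empty", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(dt))
  reason[!(dt$lineage %in% c("MD", "AD"))] <- "bad_lineage"
  bad_allele <- !(dt$allele_ancestral %in% .NUCS) |
    !(dt$allele_derived %in% .NUCS) |
    dt$allele_ancestral == dt$allele_derived
  reason[bad_allele] <- "bad_allele"
  reason[is.na(dt$pos) | dt$pos < 1L] <- "bad_position"
  ok <- is.na(reason)
  key <- paste(dt$chrom, dt$pos)
  first_ok <- !duplicated(ifelse(ok, key, paste0("bad", seq_along(key))))
  reason[ok & !first_ok] <- "duplicate_position"

  out <- dt[is.na(reason)]
  rejects <- .reject_summary(reason)
  lin <- c(MD = sum(out$lineage == "MD"), AD = sum(out$lineage == "AD"))
  .announce("read_site_catalog", nrow(dt), nrow(out), rejects)
  message(sprintf("  lineage counts: MD %d, AD %d", lin[["MD"]], lin[["AD"]]))
  data.table::setattr(out, "n_input", nrow(dt))
  data.table::setattr(out, "rejects", rejects)
  data.table::setattr(out, "lineage_counts", lin)
  out[]
}

#' Read a minor-allele-frequency table
#'
#' @param path headered TSV with columns `snp_id`, `maf`.
#' @return `data.table` with one row per `snp_id`, `0 <= maf <= 0.5`.
#'   Exact duplicate rows collapse to one; conflicting duplicates keep the
#'   first value with a warning (counted as `maf_conflict` rejects).
#' @export
read_maf_table <- function(path) {
  dt <- data.table::fread(path, select = c("snp_id", "maf"),
                          colClasses = list(character = "snp_id"),
                          na.strings = c("NA", ""), showProgress = FALSE)
  n_in <- nrow(dt)
  reason <- rep(NA_character_, n_in)
  reason[is.na(dt$maf) | dt$maf < 0 | dt$maf > 0.5] <- "bad_maf"
  ok <- is.na(reason)
  exact_dup <- ok & duplicated(dt)
  reason[exact_dup] <- "duplicate_identical"
  # remaining duplicated ids after exact-duplicate removal disagree on maf
  still_dup <- is.na(reason) &
    duplicated(ifelse(is.na(reason), dt$snp_id, paste0("bad", seq_len(n_in))))
  reason[still_dup] <- "maf_conflict"
  if (any(still_dup))
    warning(sum(still_dup), " conflicting duplicate MAF row(s); ",
            "first value kept", call. = FALSE)
  out <- dt[is.na(reason)]
  rejects <- .reject_summary(reason)
  .announce("read_maf_table", n_in, nrow(out), rejects)
  data.table::setattr(out, "n_input", n_in)
  data.table::setattr(out, "rejects", rejects)
  out[]
}

#' Join GWAS SNPs to human-specific sites
#'
#' Cross-table join keyed on rsID first, then on `(chrom, pos)`, mirroring
#' the catalog's dual keying. A GWAS SNP joins at most one site. When a
#' SNP's rsID matches a site whose coordinates disagree with the SNP's
#' coordinates, the pair is excluded rather than guessed
#' (`exclusion_reason = "key_conflict"`).
#'
#' @param gwas validated GWAS table from [read_gwas()].
#' @param sites validated catalog from [read_site_catalog()].
#' @return the GWAS table with added columns `site_snp_id,
#'   allele_ancestral, allele_derived, lineage, join_key, maf, polarity,
#'   polarity_reason, exclusion_reason`. Rows joined to no site have
#'   `lineage = NA`. Attribute `join_stats` reports counts per lineage and
#'   unjoined/conflict counts.
#' @export
join_sites <- function(gwas, sites) {
  g <- data.table::copy(data.table::as.data.table(gwas))
  s <- data.table::as.data.table(sites)
  gkey <- paste(g$chrom, g$pos)
  skey <- paste(s$chrom, s$pos)
  m_rs <- match(g$snp_id, s$snp_id, incomparables = NA)
  m_co <- match(gkey, skey)
  conflict <- !is.na(m_rs) & skey[m_rs] != gkey
  use <- ifelse(conflict, NA_integer_, ifelse(!is.na(m_rs), m_rs, m_co))

  g[, site_snp_id := s$snp_id[use]]
  g[, allele_ancestral := s$allele_ancestral[use]]
  g[, allele_derived := s$allele_derived[use]]
  g[, lineage := s$lineage[use]]
  g[, join_key := ifelse(is.na(use), NA_character_,
                         ifelse(!is.na(m_rs) & !conflict, "rsid", "coord"))]
  g[, maf := NA_real_]
  g[, polarity := ifelse(is.na(use), NA_character_, "unresolved")]
  g[, polarity_reason := NA_character_]
  g[, exclusion_reason := ifelse(conflict, "key_conflict", NA_character_)]

  stats_ <- c(joined_md = sum(g$lineage == "MD", na.rm = TRUE),
              joined_ad = sum(g$lineage == "AD", na.rm = TRUE),
              unjoined = sum(is.na(g$lineage) & !conflict),
              key_conflict = sum(conflict))
  message(sprintf(
    "join_sites: %d MD, %d AD joined; %d unjoined; %d key conflict(s)",
    stats_[["joined_md"]], stats_[["joined_ad"]], stats_[["unjoined"]],
    stats_[["key_conflict"]]))
  data.table::setattr(g, "join_stats", stats_)
  g[]
}

# fixed column order of the result table; byte-exact regression tests and
# the round-trip invariant depend on it
.BIN_RESULT_COLS <- c(
  "bin_index", "p_upper", "p_lower", "lineage",
  "n_genome_total", "n_genome_in_sites", "n_bin_total", "n_bin_in_sites",
  "f_bc_over_ad", "f_obs_over_exp",
  "n_derived_risk", "n_derived_protective", "risk_protective_ratio",
  "p_enrichment_md_vs_ad", "p_lineage_vs_background", "p_ratio_md_vs_ad")

#' Write / read the per-bin result table
#'
#' One row per (bin, lineage) with all counts, both F-score conventions,
#' derived-risk/derived-protective counts and ratio, and the Fisher
#' p-values. Tab-delimited, `NA` sentinel, fixed column order, so repeated
#' runs under one seed are byte-identical and a write/read round trip
#' reproduces identical values.
#'
#' @param results long-format `data.table` as produced by
#'   [bin_result_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_bin_results <- function(results, path) {
  stopifnot(all(.BIN_RESULT_COLS %in% names(results)))
  data.table::fwrite(results[, .BIN_RESULT_COLS, with = FALSE], path,
                     sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_bin_results
#' @export
read_bin_results <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA",
                    colClasses = list(character = "lineage"),
                    showProgress = FALSE)
}

#' Write the machine-readable run summary
#'
#' JSON echo of the configuration, seeds, input digests, stage-by-stage
#' reject/filter counts and the overall contrast p-values — the audit
#' trail of a pipeline run.
#'
#' @param summary named list.
#' @param path output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
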