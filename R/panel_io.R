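# Genotype reference panel: a sites x samples dosage matrix used only for
# LD computation. Dosages count copies of the ALT allele (0/1/2, NA for
# missing).

#' Construct a genotype panel
#'
#' @param dosages integer/numeric matrix, sites in rows, samples in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param chrom,pos site coordinates (1-based), one per row.
#' @param snp_id optional site identifiers.
#' @return object of class `panel_genotypes`.
#' @export
panel_genotypes <- function(dosages, chrom, pos, snp_id = NULL) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(chrom), length(chrom) == length(pos))
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(snp_id)) snp_id <- paste0(chrom, ":", pos)
  structure(list(dosages = dosages, chrom = as.character(chrom),
                 pos = as.integer(pos), snp_id = as.character(snp_id),
                 n_samples = ncol(dosages)),
            class = "panel_genotypes")
}

#' @export
print.panel_genotypes <- function(x, ...) {
  cat(sprintf("<panel_genotypes> %d sites x %d samples, %d chromosome(s)\n",
              nrow(x$dosages), x$n_samples, length(unique(x$chrom))))
  invisible(x)
}

#' Read a genotype panel from a VCF
#'
#' Converts the GT field of a VCF (plain or bgzipped) into ALT-allele
#' dosages. Only biallelic records are kept; genotypes with any missing
#' allele become `NA`.
#'
#' @param path VCF file.
#' @return `panel_genotypes`.
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  keep <- !grepl(",", alt)
  gt <- gt[keep, , drop = FALSE]
  # count '1' alleles irrespective of phasing separator
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- !is.na(gt) & !grepl("\\.", gt)
  counts <- vapply(strsplit(gt[clean], "[/|]"),
                   function(a) sum(a == "1"), integer(1))
  dos[clean] <- counts
  panel_genotypes(dos,
                  chrom = vcfR::getCHROM(v)[keep],
                  pos = vcfR::getPOS(v)[keep],
                  snp_id = vcfR::getID(v)[keep])
}

#' Write a genotype panel as a plain-text VCF
#'
#' Minimal VCFv4.2 writer (GT only, unphased). The REF/ALT alleles default
#' to placeholders when the panel does not carry real alleles; the LD
#' pruner consumes only the dosages.
#'
#' @param panel `panel_genotypes`.
#' @param path output path (plain text).
#' @param ref,alt per-site allele vectors; recycled defaults `"A"`/`"G"`.
#' @export
write_panel_vcf <- function(panel, path, ref = "A", alt = "G") {
  n <- nrow(panel$dosages)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n, panel$n_samples)
  ok <- !is.na(panel$dosages)
  gt[ok] <- gt_map[panel$dosages[ok] + 1L]
  samples <- sprintf("S%04d", seq_len(panel$n_samples))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos, panel$snp_id, ref, alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
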