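# Independent oracles and small fixture builders. The Fisher oracle
# enumerates hypergeometric tables from binomial coefficients directly,
# sharing no code path with the implementation under test.

fisher_oracle <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(n, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# minimal annotated table for binning/counting tests: only the columns
# the enrichment and ratio operations read
mock_annotated <- function(p_value, lineage = NA_character_,
                           polarity = NA_character_) {
  n <- length(p_value)
  data.table::data.table(
    snp_id = paste0("rs", seq_len(n)),
    p_value = p_value,
    lineage = rep_len(lineage, n),
    polarity = rep_len(polarity, n))
}

# write a small daner-style GWAS file and return its path
write_daner <- function(lines, dir = tempdir()) {
  path <- tempfile("gwas", fileext = ".tsv", tmpdir = dir)
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tOR\tP", lines), path)
  path
}

decile_edges_published <- c(1, 0.886, 0.781, 0.671, 0.559, 0.443,
                            0.336, 0.233, 0.140, 0.054, 0)
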