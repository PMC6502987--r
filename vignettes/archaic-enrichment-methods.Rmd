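---
title: "Methods: enrichment of GWAS alleles at human-specific sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment of GWAS alleles at human-specific sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archaicsel)
```

## The question and the markers

Since the modern human lineage split from Neanderthals and Denisovans,
alleles have continued to arise and fix on both branches. Comparing
archaic genomes with modern ones, polarized against the chimpanzee
outgroup, yields two marker classes:

* **MD sites** (modern-human-specific): the archaic genomes carry the
  derived allele while modern humans carry the ancestral allele, fixed or
  at high (> 90%) frequency.
* **AD sites** (archaic-human-specific): the converse — modern humans
  carry the derived state where the archaic genomes remained ancestral.

If a polygenic disorder's risk alleles have been under recent negative
(purifying) selection in modern humans, then among disorder-associated
SNPs that happen to fall in these marker sites, the *derived* allele
should disproportionately be the *protective* allele at MD sites —
derived variation that survived in modern humans — and the derived-risk
class should be relatively enriched at AD sites. `archaicsel` implements
this comparison as a reusable pipeline over GWAS summary statistics,
with a synthetic-data generator standing in for the restricted-access
inputs (consortium GWAS downloads, the archaic site catalog, a 1000
Genomes-scale reference panel).

## Pipeline model

The pipeline consumes four inputs — GWAS summary statistics, the MD/AD
site catalog, a MAF table and a genotype reference panel (VCF) — all
required to share one genome build (the tool performs no liftover).
Stages, in order:

1. **LD pruning.** The downstream contingency tests assume approximately
   independent SNPs, so the SNP set is greedily pruned first: within a
   1 Mb window, any pair with dosage `r² > 0.2` (computed on the
   reference panel) loses one member, chosen with equal priority by a
   fair coin, until no such pair remains.
2. **Site join.** GWAS SNPs join catalog sites by rsID first, then by
   `(chrom, pos)`; a SNP whose rsID points at a site with different
   coordinates is excluded as a key conflict rather than guessed.
3. **MAF filter.** Only SNPs with MAF strictly below 0.1 are analyzed
   (human-specific variants occur at this frequency or below; the filter
   removes the frequency confound between site SNPs and the background).
4. **Polarization.** Each site-overlapping SNP is classified
   derived-risk or derived-protective from the GWAS effect direction and
   the site's ancestral allele (details below).
5. **Binning and contrasts.** Association p-values are cut into decile
   bins; per bin the pipeline computes fold-change enrichment scores per
   lineage, the MD-vs-AD membership contrast, risk:protective ratios and
   the MD-vs-AD polarity contrast (Fisher exact tests), plus pooled
   overall contrasts.

### The fold-change score

With `a` the number of analyzed SNPs genome-wide, `b` those inside MD
(or AD) sites, `c` the SNPs in the queried p-value bin and `d` the bin's
SNPs inside sites, the enrichment statistic circulates in two exactly
reciprocal orientations:

* `bc_over_ad` — `(b·c)/(a·d)`, the form in which the statistic is
  usually printed (the package default), and
* `obs_over_exp` — `(a·d)/(b·c)` = `(d/c)/(b/a)`, the observed site
  proportion in the bin over the genome-wide expectation, which is the
  verbal definition of a fold change.

Because the printed formula and the verbal definition are mutual
reciprocals, every result table carries **both** columns and the run
summary names the headline convention; under the null both equal 1.
Undefined values (zero denominators, empty bins) are reported as `NA`
with the counts still present, never silently dropped.

### Polarity rules

The risk allele is the effect allele when `OR > 1`, the other allele
when `OR < 1`; `OR = 1` exactly has no direction (`no_direction`). If
the site's ancestral allele equals one GWAS allele directly, the derived
GWAS allele is the other one. When neither matches, both GWAS alleles
are complemented and matching is retried — except for A/T and C/G SNPs,
which map onto themselves under complementing and are conservatively
excluded (`strand_ambiguous`) whenever the direct match fails. The call
is `derived_risk` when the derived allele is the risk allele, otherwise
`derived_protective`. The classification is invariant under swapping the
allele columns with `OR → 1/OR`, which the tests assert for every
record.

### Binning

Bins are indexed from the highest-p decile (bin 1) to the lowest (bin
10). Intervals are closed on their high-p side and half-open below, the
lowest closed at 0, so a p-value on an interior edge belongs to the bin
that edge bounds above. Default edges are empirical deciles of the
analyzed (post-prune, post-filter) SNP set — published decile edge lists
are plainly data-derived — and a `fixed` mode accepts an explicit edge
list for replication-style runs. Tied edges (mass points in p) are
refused rather than silently merged. The genome-wide denominators `a`
and `b` are always computed on the identical filtered universe that was
binned; mixing universes would break the conservation law
`Σd = b, Σc = a` that the tests enforce on every run.

### Fisher tests and the overall contrast

All 2×2 contrasts use the standard two-sided Fisher exact definition
(sum of hypergeometric point probabilities not exceeding the observed
table's); the test suite verifies this against an exhaustive
enumeration oracle for every table with margins up to 30, at 1e-9.
Zero-margin tables carry no information and report `p = 1`, flagged.
Per-bin p-values are reported raw, without multiple-testing correction
across bins. The "overall" contrast pools the per-bin 2×2 tables by
summing counts over bins (default), and the run also emits a
Fisher's-method combination of per-bin p-values and, per lineage, a
chi-square homogeneity test of the site proportion across bins — the
aggregation actually used is recorded in the run summary, since an
"overall p across bins" admits more than one reading.

## LD pruning details

`r²` is the squared Pearson correlation of unphased genotype dosages
over pairwise-complete samples (the composite r² PLINK computes without
phasing); pairs with fewer than 4 complete samples or a constant vector
are undefined and unflagged. Flagged pairs are processed in ascending
`(chrom, pos_left, pos_right)` order; the removal coin for a pair is a
deterministic function of the seed and the pair identity (derived from
per-SNP uniform keys), so which member dies does not depend on which
other pairs happened to be flagged. SNPs absent from the panel pass
through untested and counted — dropping them would bias the enrichment
denominator.

Two consequences worth knowing. Pruning is idempotent by construction.
Raising the threshold can only unflag pairs, and with pair-local coins
the retained set grows monotonically whenever the looser threshold's
flagged graph nests inside the stricter one's (e.g. equicorrelated
blocks); under equal-priority *random* removal this monotonicity is not
a theorem in full generality, because a pair flagged only at the
stricter threshold can redirect which member of a later pair survives.
Note also that equal-priority removal differs from the common practice
of preferentially keeping the more significant SNP; the package follows
the equal-priority rule deliberately, since preferring low-p SNPs would
distort the p-value-bin composition that the enrichment statistic then
measures.

## The synthetic-data generator

The generator emulates the four inputs with exact ground truth:

* **Panel.** SNPs in `n_ld_blocks` equicorrelated blocks over up to 22
  chromosomes, blocks separated by > 1 Mb gaps. Each site is a noisy
  copy of a per-block latent haplotype pair; the per-site redraw rate
  `m = 1 − r²_target^(1/4)` makes the expected pairwise dosage r² equal
  the target. Default block size ~5 SNPs leaves a realistic fraction of
  the set standing after pruning; equicorrelated blocks at the default
  target collapse to about one survivor each, which is the intended
  stress of the pruning contract, not an accident.
* **Catalog and GWAS.** Defaults mirror the field's observed scale
  ratios: ~1.4× more MD than AD catalog sites, of which 28.5% / 31.0%
  are polymorphic in the GWAS. For an overlapped site the SNP's alleles
  are the ancestral/derived pair; its polarity is drawn
  derived-protective with probability `θ/(1+θ)` (θ =
  `protective_excess_md` or `_ad`, θ = 1 the null), and the odds
  ratio's sign is forced consistent with the drawn polarity (log-normal
  magnitude, `or_log_sd = 0.08`, typical of common-variant GWAS).
  Allele pairs exclude complements by default so every site SNP is
  resolvable; `strand_ambiguous_fraction` reintroduces them on demand.
* **P-values.** A fraction `assoc_effect_fraction` (default 0.05) of
  SNPs get left-skewed `Beta(0.2, 1)` p-values, the rest uniform.
  P-values are independent of polarity by default, so any detected
  polarity signal is attributable to the injected θ alone; the optional
  `p_coupling` parameter (effective `θ^((1-p)^(4c))`) concentrates the
  excess at low p to mimic a selection gradient across bins. No
  quantitative model links association strength to polarity in real
  data; the coupling is a demonstration construct and is recorded in
  the ground-truth metadata.
* **MAF.** `Beta(0.5, 5)` truncated to `(0, 0.5]` — a rare-skewed
  spectrum — with site-overlapping SNPs held strictly below 0.1, since
  that ceiling is the empirical motivation for the filter;
  `force_low_maf_at_sites = FALSE` disables it to test the filter.

What the generator does **not** emulate: coalescent LD decay (blocks
are exchangeable inside, independent outside), demographic history,
introgression tracts, allele-frequency-dependent effect sizes, or any
real linkage between association strength and evolutionary class.
Passing tests therefore demonstrate the *pipeline's* correctness and
calibration, not that real data would show any particular signal.

## Numerical and design choices

* Duplicate `(chrom, pos)` GWAS rows: first occurrence kept, later ones
  rejected with a warning (a deterministic rule is required; none is
  standard).
* Multi-allelic rows are rejected at read time and counted.
* The MAF filter applies by default to both the enrichment and the
  ratio analysis (`maf_filter_scope = "both"`) for internal
  consistency; `"enrichment_only"` restricts it to the enrichment side,
  since the filter's published motivation concerns the enrichment
  denominator.
* One global seed fans out to per-stage child seeds
  (`stage_seed(seed, dataset*10 + stage)`), so stages replayed
  individually reproduce the orchestrated run exactly; the test suite
  asserts this composability and byte-identical reruns.
* Output tables are tab-delimited with an `NA` sentinel and fixed
  column order, so regression comparisons can be byte-exact.

## Problem sizes used in the tests

The validation suite runs at desk scale, chosen to finish in minutes on
one core while leaving the statistical checks well-powered: the pruning
contract on 1,000 SNPs in 20 blocks with exhaustive all-pairs
verification; polarity exactness on ~3,600 overlapped sites; null
calibration of the per-bin ratio test over 2,000 replicates of 2,000
resolved SNPs (rejection rate at α = 0.05 required in [0.03, 0.07]);
and recovery of an injected θ = 2 from 200 replicates of 5,000 resolved
SNPs per lineage (pooled MD ratio in [1/2.3, 1/1.7] in ≥ 95% of
replicates, pooled contrast p < 0.001 in ≥ 99%). The Fisher
implementation is checked against exhaustive enumeration for all 2×2
tables with margins ≤ 30.

## Known limitations

* The pipeline consumes odds ratios for direction only; effect-size
  magnitudes, standard errors and genome-wide-significance thresholding
  are out of scope.
* Indels are not modeled; records are strictly single-nucleotide.
* Strand-ambiguous SNPs are excluded rather than frequency-resolved;
  with real data this discards a predictable ~1/3 of ambiguous pairs'
  information.
* The chi-square homogeneity test uses the asymptotic distribution and
  is unreliable for very sparse bins (it is reported alongside, never
  alone).
* `fisher.test`'s two-sided p uses a relative tolerance of 1e-7 when
  comparing point probabilities; tables engineered to sit exactly on
  that knife edge could flip a term, which is far below the resolution
  of any quantity reported here.
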