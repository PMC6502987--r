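# Greedy window-based LD pruning against a genotype reference panel:
# within a physical window, any SNP pair whose dosage r-squared exceeds
# the threshold loses one member, chosen with equal priority (a fair,
# seed-deterministic coin), until no such pair remains.

#' Pruning parameters
#'
#' @param window_bp physical window: pairs with `|pos_i - pos_j| <=
#'   window_bp` on one chromosome are candidates. Default 1 Mb.
#' @param r2_threshold pairs above this squared-correlation are flagged.
#'   Default 0.2.
#' @param seed drives the equal-priority removal coin.
#' @export
prune_config <- function(window_bp = 1e6, r2_threshold = 0.2, seed = 1L) {
  stopifnot(window_bp > 0, r2_threshold > 0, r2_threshold < 1)
  structure(list(window_bp = window_bp, r2_threshold = r2_threshold,
                 seed = as.integer(seed)),
            class = "prune_config")
}

#' Squared Pearson correlation of two dosage vectors
#'
#' The composite (genotypic) r-squared computed on unphased dosages over
#' pairwise-complete samples — the statistic PLINK reports without
#' phasing. Undefined (`NA`) when fewer than 4 complete pairs remain or
#' either vector is constant over them; callers must treat such pairs as
#' unflagged.
#'
#' @param x,y equal-length dosage vectors (`0/1/2`, `NA` allowed).
#' @return r-squared in `[0, 1]`, or `NA` when undefined.
#' @export
compute_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 4L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  cor(x, y)^2
}

#' Greedy LD pruning of a GWAS SNP set
#'
#' Flagged pairs (same chromosome, within `window_bp`, r-squared above
#' threshold) are processed in ascending `(chrom, pos_left, pos_right)`
#' order; from each pair still intact, one member is removed by a fair
#' coin; pairs already broken by earlier removals are skipped. The coin
#' for a pair is a deterministic function of the seed and the pair
#' identity, so the outcome does not depend on which other pairs were
#' flagged. SNPs not resolvable in the panel, or whose r-squared is
#' undefined, pass through untested (silently dropping them would bias
#' the enrichment denominator) and are counted.
#'
#' @param gwas GWAS table with `snp_id`, `chrom`, `pos`.
#' @param panel `panel_genotypes` reference.
#' @param config a [prune_config()].
#' @return object of class `prune_result`: `retained` and `removed` SNP
#'   id vectors (disjoint, union = input), `n_pairs_flagged`,
#'   `n_unresolved`, and the seed used.
#' @export
ld_prune <- function(gwas, panel, config = prune_config()) {
  g <- data.table::as.data.table(gwas)[, .(snp_id, chrom, pos)]
  if (nrow(g) == 0L)
    return(structure(list(retained = character(0), removed = character(0),
                          n_pairs_flagged = 0L, n_unresolved = 0L,
                          seed = config$seed), class = "prune_result"))
  row_in_panel <- match(paste(g$chrom, g$pos),
                        paste(panel$chrom, panel$pos))
  unresolved <- is.na(row_in_panel)
  if (any(unresolved))
    message("ld_prune: ", sum(unresolved),
            " SNP(s) not in the panel retained untested")

  res <- g[!unresolved]
  res[, .panel_row := row_in_panel[!unresolved]]
  data.table::setorder(res, chrom, pos)          # canonical order
  k <- nrow(res)
  set.seed(config$seed)
  u <- runif(k)                                   # per-SNP coin keys
  alive <- rep(TRUE, k)
  n_flagged <- 0L
  dos <- panel$dosages
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      if (!alive[i]) next
      for (j in (i + 1L):k) {
        if (res$chrom[j] != res$chrom[i] ||
            res$pos[j] - res$pos[i] > config$window_bp) break
        if (!alive[j]) next
        r2 <- compute_r2(dos[res$.panel_row[i], ], dos[res$.panel_row[j], ])
        if (!is.na(r2) && r2 > config$r2_threshold) {
          n_flagged <- n_flagged + 1L
          if ((u[i] + u[j]) %% 1 < 0.5) {          # fair pair coin
            alive[i] <- FALSE
            break
          } else {
            alive[j] <- FALSE
          }
        }
      }
    }
  }
  retained <- c(res$snp_id[alive], g$snp_id[unresolved])
  removed <- res$snp_id[!alive]
  structure(list(retained = sort(retained), removed = sort(removed),
                 n_pairs_flagged = n_flagged,
                 n_unresolved = sum(unresolved),
                 seed = config$seed),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf(
    "<prune_result> %d retained, %d removed, %d pair(s) flagged, %d untested (seed %d)\n",
    length(x$retained), length(x$removed), x$n_pairs_flagged,
    x$n_unresolved, x$seed))
  invisible(x)
}
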