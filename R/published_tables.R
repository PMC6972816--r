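#' Published per-locus diversity reference table
#'
#' The rarefied (18 individuals, 100 draws) per-locus mean number of alleles
#' (Na), observed (Ho) and expected (He) heterozygosity reported for the
#' four field populations of the two-region wildcat / domestic cat survey:
#' Pyrenean wildcats (`PO_wild`), northeastern wildcats (`NE_wild`),
#' Pyrenean domestic cats (`PO_domestic`) and northeastern domestic cats
#' (`NE_domestic`), over the 22-locus microsatellite panel. Shipped as
#' plain-text data; used as the worked example for the column-summary
#' operation.
#'
#' @return Data frame `locus, population, na, ho, he` (22 loci x 4
#'   populations).
#' @export
published_locus_diversity <- function() {
  path <- system.file("extdata", "locus_diversity_reference.csv",
                      package = "wildhyb", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expected resampling inclusion counts
#'
#' Bookkeeping of the resampling design: drawing `n_draw` individuals
#' without replacement from a pool of `n_pool`, `n_datasets` times, fixes
#' the total number of inclusions at `n_datasets * n_draw`, so the mean
#' inclusion count per pool member is `n_datasets * n_draw / n_pool`
#' regardless of seed. The function verifies this by actually drawing, and
#' also reports the empirical spread.
#'
#' @param n_pool Pool size (default 371, the domestic cats available).
#' @param n_draw Individuals drawn per dataset (default 70).
#' @param n_datasets Number of resampled datasets (default 30).
#' @param seed Integer seed.
#' @return List `counts` (per pool member), `mean`, `sd`.
#' @export
resampling_inclusion_counts <- function(n_pool = 371, n_draw = 70,
                                        n_datasets = 30, seed = 1) {
  stopifnot(n_draw <= n_pool)
  set.seed(seed)
  counts <- integer(n_pool)
  for (d in seq_len(n_datasets)) {
    take <- sample.int(n_pool, n_draw)
    counts[take] <- counts[take] + 1L
  }
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts))
}
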