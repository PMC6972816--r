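#' Per-locus, per-population diversity summaries
#'
#' For each population and locus: number of alleles `Na` among called
#' genotypes, `Na_5pct` (alleles with sample frequency above 0.05), observed
#' heterozygosity `Ho`, unbiased expected heterozygosity
#' `He = 2n/(2n-1) * (1 - sum p_i^2)` (Nei 1978, as FSTAT/Genetix report),
#' and the Brookfield null-allele estimate.
#'
#' @param ds A [wh_dataset()].
#' @param by Metadata column defining populations (`NULL` pools everyone).
#' @param unbiased Use the unbiased He estimator (default) or plain gene
#'   diversity `1 - sum p_i^2`.
#' @return Data frame with one row per locus x population; loci with no
#'   called genotype are flagged (`ok = FALSE`, statistics `NA`).
#' @export
locus_summaries <- function(ds, by = "population", unbiased = TRUE) {
  stopifnot(inherits(ds, "wh_dataset"))
  groups <- if (is.null(by)) rep("all", length(ds$ids)) else as.character(ds$meta[[by]])
  rows <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    for (l in seq_along(ds$loci)) {
      a <- ds$a[sel, l]; b <- ds$b[sel, l]
      called <- !is.na(a)
      n <- sum(called)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(locus = ds$loci[l], population = g, n = 0L,
                     na = NA_integer_, na_5pct = NA_integer_, ho = NA_real_,
                     he = NA_real_, null_freq = NA_real_, ok = FALSE)
        next
      }
      al <- c(a[called], b[called])
      p <- as.numeric(table(al)) / (2 * n)
      ho <- mean(a[called] != b[called])
      he <- 1 - sum(p^2)
      if (unbiased) he <- he * 2 * n / (2 * n - 1)
      rows[[length(rows) + 1L]] <-
        data.frame(locus = ds$loci[l], population = g, n = n,
                   na = length(p), na_5pct = sum(p > 0.05), ho = ho, he = he,
                   null_freq = null_allele_freq(ho, he), ok = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Column means and SDs of a per-locus summary table
#'
#' The "Mean"/"SD" rows of a per-locus diversity table: arithmetic mean and
#' sample standard deviation over loci of each statistic, per population.
#'
#' @param tab Data frame as returned by [locus_summaries()] (or any table
#'   with `population` plus numeric statistic columns).
#' @param stats_cols Columns to summarise.
#' @return Data frame `population, statistic, mean, sd`.
#' @export
summarize_locus_table <- function(tab, stats_cols = c("na", "ho", "he")) {
  rows <- list()
  for (g in unique(tab$population)) {
    sub <- tab[tab$population == g, , drop = FALSE]
    for (s in stats_cols) {
      v <- sub[[s]]
      rows[[length(rows) + 1L]] <-
        data.frame(population = g, statistic = s,
                   mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Rarefied diversity by repeated subsampling
#'
#' Draws `n_individuals` without replacement from every population,
#' `n_reps` times, computes [locus_summaries()] on each draw, and averages
#' the per-locus statistics across repeats. Equalises sample sizes before
#' comparing allelic richness.
#'
#' @param ds A [wh_dataset()].
#' @param n_individuals Individuals drawn per population (default 18, the
#'   smallest field population).
#' @param n_reps Number of repeated draws (default 100).
#' @param seed Integer seed.
#' @param by Population column.
#' @return List with `per_locus` (mean na/ho/he per locus x population over
#'   repeats) and `overall` (means over loci).
#' @export
rarefied_diversity <- function(ds, n_individuals = 18, n_reps = 100, seed = 1,
                               by = "population") {
  stopifnot(inherits(ds, "wh_dataset"))
  groups <- as.character(ds$meta[[by]])
  for (g in unique(groups))
    if (sum(groups == g) < n_individuals)
      stop("population ", g, " has fewer than ", n_individuals, " individuals")
  set.seed(seed)
  acc <- NULL
  for (r in seq_len(n_reps)) {
    take <- unlist(lapply(unique(groups), function(g)
      sample(which(groups == g), n_individuals)))
    tab <- locus_summaries(subset_dataset(ds, individuals = take), by = by)
    tab <- tab[order(tab$population, tab$locus), ]
    if (is.null(acc)) {
      acc <- tab[c("locus", "population")]
      acc$na <- 0; acc$ho <- 0; acc$he <- 0
    }
    acc$na <- acc$na + tab$na / n_reps
    acc$ho <- acc$ho + tab$ho / n_reps
    acc$he <- acc$he + tab$he / n_reps
  }
  list(per_locus = acc,
       overall = summarize_locus_table(acc)[, c("population", "statistic", "mean")])
}

#' Hardy-Weinberg test by allele-copy permutation
#'
#' The statistic is the Weir-Cockerham within-population inbreeding
#' coefficient f (F_IS) at the locus; the null distribution re-pairs the 2n
#' allele copies into random genotypes. Two-sided p-value with the
#' `(b+1)/(m+1)` plus-one estimator.
#'
#' @param ds A [wh_dataset()].
#' @param locus Locus name.
#' @param population Population label (column `population`).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return List `f`, `p`, `n`, `monomorphic`; a monomorphic locus returns
#'   `p = 1` flagged.
#' @export
hwe_test <- function(ds, locus, population, n_perm = 999, seed = 1) {
  stopifnot(inherits(ds, "wh_dataset"), n_perm >= 1)
  sel <- ds$meta$population == population
  l <- match(locus, ds$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  a <- ds$a[sel, l]; b <- ds$b[sel, l]
  called <- !is.na(a)
  a <- a[called]; b <- b[called]
  n <- length(a)
  if (n < 5) stop("fewer than 5 called genotypes at ", locus, " in ", population)
  if (length(unique(c(a, b))) < 2L)
    return(list(f = NA_real_, p = 1, n = n, monomorphic = TRUE))
  fobs <- wc_f_single(a, b)
  set.seed(seed)
  copies <- c(a, b)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(copies)
    fstar <- wc_f_single(perm[seq_len(n)], perm[n + seq_len(n)])
    if (!is.na(fstar) && abs(fstar) >= abs(fobs)) exceed <- exceed + 1L
  }
  list(f = fobs, p = (exceed + 1) / (n_perm + 1), n = n, monomorphic = FALSE)
}

#' Bonferroni adjustment for a family of tests
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Family-wise level (default 0.05).
#' @return Data frame `p`, `p_adj` (capped at 1), `significant`.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  padj <- pmin(pvals * length(pvals), 1)
  data.frame(p = pvals, p_adj = padj, significant = padj < alpha)
}

#' Linkage (genotypic) disequilibrium test between two loci
#'
#' Log-likelihood ratio G statistic on the two-locus genotype contingency
#' table, with a null built by permuting one locus's genotypes across
#' individuals.
#'
#' @param ds A [wh_dataset()].
#' @param locus1,locus2 Locus names.
#' @param population Population label.
#' @param n_perm Permutations (must be >= 1).
#' @param seed Integer seed.
#' @return List `G`, `p`, `n`.
#' @export
ld_test <- function(ds, locus1, locus2, population, n_perm = 999, seed = 1) {
  stopifnot(inherits(ds, "wh_dataset"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  sel <- ds$meta$population == population
  l1 <- match(locus1, ds$loci); l2 <- match(locus2, ds$loci)
  if (is.na(l1) || is.na(l2)) stop("unknown locus name")
  ok <- sel & !is.na(ds$a[, l1]) & !is.na(ds$a[, l2])
  n <- sum(ok)
  if (n < 5) stop("fewer than 5 individuals called at both loci")
  g1 <- paste(ds$a[ok, l1], ds$b[ok, l1])
  g2 <- paste(ds$a[ok, l2], ds$b[ok, l2])
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- tab > 0
    2 * sum(tab[idx] * log(tab[idx] / e[idx]))
  }
  Gobs <- gstat(g1, g2)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm))
    if (gstat(g1, sample(g2)) >= Gobs) exceed <- exceed + 1L
  list(G = Gobs, p = (exceed + 1) / (n_perm + 1), n = n)
}

#' Brookfield estimate of the null-allele frequency
#'
#' Estimator 1: `r = (He - Ho) / (1 + He)`, clamped at zero when there is no
#' heterozygote deficit.
#'
#' @param ho,he Observed and expected heterozygosity.
#' @return Estimated null-allele frequency in `[0, 1]`.
#' @export
null_allele_freq <- function(ho, he) pmax(0, (he - ho) / (1 + he))

#' Binomial test of the null-allele explanation for a heterozygote deficit
#'
#' Under a null allele at the Brookfield frequency `r`, non-amplifying
#' (blank) individuals are null homozygotes, expected at rate `r^2`. The
#' observed number of blanks is tested against `Binomial(n_total, r^2)`. A
#' locus shows evidence of null alleles driving a Hardy-Weinberg departure
#' when the HWE test rejects while this test does not reject the null-allele
#' explanation.
#'
#' @param ds A [wh_dataset()].
#' @param locus Locus name.
#' @param population Population label.
#' @return List `r_null`, `n_blank`, `n_total`, `p` (binomial test), and
#'   `flag_ho_he` when Ho > He forced the clamp.
#' @export
null_allele_test <- function(ds, locus, population) {
  sel <- ds$meta$population == population
  l <- match(locus, ds$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  a <- ds$a[sel, l]; b <- ds$b[sel, l]
  blank <- sum(is.na(a)); n_tot <- length(a)
  tab <- locus_summaries(subset_dataset(ds, individuals = which(sel),
                                        loci = l), by = NULL)
  r <- null_allele_freq(tab$ho, tab$he)
  p <- stats::binom.test(blank, n_tot, p = max(r^2, .Machine$double.eps))$p.value
  list(r_null = r, n_blank = blank, n_total = n_tot, p = p,
       flag_ho_he = tab$ho > tab$he)
}
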