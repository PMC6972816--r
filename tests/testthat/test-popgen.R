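test_that("locus summaries handle monomorphic and single-individual cases", {
  ds <- make_dataset(matrix(c(1L, 1L, 1L), 3, 1), matrix(c(1L, 1L, 1L), 3, 1))
  tab <- locus_summaries(ds, by = NULL)
  expect_equal(tab$na, 1L)
  expect_equal(tab$ho, 0)
  expect_equal(tab$he, 0)
  # single heterozygous individual: Ho = 1, unbiased He = (2/1)(1 - 0.5) = 1
  ds1 <- make_dataset(matrix(1L, 1, 1), matrix(2L, 1, 1))
  tab1 <- locus_summaries(ds1, by = NULL)
  expect_equal(tab1$ho, 1)
  expect_equal(tab1$he, 1)
  # zero called genotypes flagged
  ds0 <- make_dataset(matrix(NA_integer_, 2, 1), matrix(NA_integer_, 2, 1))
  expect_false(locus_summaries(ds0, by = NULL)$ok)
})

test_that("Na counts alleles above the 5% frequency cutoff separately", {
  # 20 genotypes: allele 3 appears once out of 40 copies (2.5% <= 5%)
  a <- matrix(c(rep(1L, 19), 3L), 20, 1)
  b <- matrix(rep(2L, 20), 20, 1)
  tab <- locus_summaries(make_dataset(a, b), by = NULL)
  expect_equal(tab$na, 3L)
  expect_equal(tab$na_5pct, 2L)
})

test_that("the published per-locus table reproduces its printed column summaries", {
  tab <- published_locus_diversity()
  s <- summarize_locus_table(tab)
  get <- function(pop, st, col) s[s$population == pop & s$statistic == st, col]
  expect_equal(round(get("PO_wild", "na", "mean"), 2), 6.32)
  expect_equal(round(get("NE_wild", "na", "mean"), 2), 8.00)
  expect_equal(round(get("PO_domestic", "na", "mean"), 2), 8.26)
  expect_equal(round(get("NE_domestic", "na", "mean"), 2), 9.14)
  expect_equal(round(get("PO_wild", "na", "sd"), 2), 2.10)
})

test_that("rarefaction is exhaustive at n and bounded by the full sample", {
  m <- pop_model(n_loci = 8, n_alleles = 6, F = 0.1)
  sim <- simulate_parental_pops(m, c(A = 18, B = 25), seed = 3)
  full <- locus_summaries(sim$dataset)
  rar <- rarefied_diversity(sim$dataset, n_individuals = 18, n_reps = 20,
                            seed = 1)
  # population of exactly 18: every draw is the whole population
  a_full <- full[full$population == "A", ]
  a_rar <- rar$per_locus[rar$per_locus$population == "A", ]
  expect_equal(a_rar$na[order(a_rar$locus)], a_full$na[order(a_full$locus)])
  # subsampling can only lose alleles
  merged <- merge(rar$per_locus, full, by = c("locus", "population"),
                  suffixes = c("_rar", "_full"))
  expect_true(all(merged$na_rar <= merged$na_full + 1e-12))
  expect_error(rarefied_diversity(sim$dataset, n_individuals = 30),
               "fewer than")
})

test_that("rarefied allelic richness preserves a true diversity ordering", {
  ok <- 0
  for (s in 1:3) {
    rich <- simulate_parental_pops(pop_model(n_loci = 10, n_alleles = 10, F = 0.05),
                                   c(hi = 30, x = 2), seed = s)$dataset
    poor <- simulate_parental_pops(pop_model(n_loci = 10, n_alleles = 3, F = 0.05),
                                   c(lo = 30, x = 2), seed = s + 10)$dataset
    both <- make_dataset(rbind(rich$a[1:30, ], poor$a[1:30, ]),
                         rbind(rich$b[1:30, ], poor$b[1:30, ]),
                         population = rep(c("hi", "lo"), each = 30))
    rar <- rarefied_diversity(both, n_individuals = 18, n_reps = 20, seed = s)
    ov <- rar$overall
    if (ov$mean[ov$population == "hi" & ov$statistic == "na"] >
        ov$mean[ov$population == "lo" & ov$statistic == "na"]) ok <- ok + 1
  }
  expect_equal(ok, 3)
})

test_that("HWE permutation test is calibrated under the null and extreme under excess", {
  # type-I calibration: HWE-simulated loci rejected at about the nominal rate
  m <- pop_model(n_loci = 100, n_alleles = 5, F = 0.1)
  ds <- simulate_parental_pops(m, c(A = 40, B = 0), seed = 6)$dataset
  p <- vapply(ds$loci, function(l) hwe_test(ds, l, "A", n_perm = 199,
                                            seed = 17)$p, numeric(1))
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.0); expect_lte(rej, 0.12)   # binomial(100, .05) band
  # all-heterozygote sample: f = -1 and small p
  ds2 <- make_dataset(matrix(1L, 20, 1), matrix(2L, 20, 1), population = "A")
  ht <- hwe_test(ds2, "L1", "A", n_perm = 999, seed = 1)
  expect_equal(ht$f, -1)
  expect_lt(ht$p, 0.05)
  # monomorphic convention
  ds3 <- make_dataset(matrix(1L, 10, 1), matrix(1L, 10, 1), population = "A")
  expect_true(hwe_test(ds3, "L1", "A")$monomorphic)
  expect_equal(hwe_test(ds3, "L1", "A")$p, 1)
})

test_that("Bonferroni correction multiplies and caps", {
  out <- bonferroni(c(0.002, 0.5), alpha = 0.05)
  expect_equal(out$p_adj[1], 0.002 * 2)
  expect_equal(bonferroni(rep(0.002, 22))$p_adj[1], 0.044)
  expect_true(bonferroni(rep(0.002, 22))$significant[1])
  expect_equal(bonferroni(c(0.9, 0.9))$p_adj[1], 1)
})

test_that("linkage test is calibrated under independence and extreme under duplication", {
  m <- pop_model(n_loci = 12, n_alleles = 4, F = 0.1)
  ds <- simulate_parental_pops(m, c(A = 40, B = 0), seed = 8)$dataset
  prs <- utils::combn(ds$loci, 2)
  p <- vapply(seq_len(ncol(prs)), function(i)
    ld_test(ds, prs[1, i], prs[2, i], "A", n_perm = 99, seed = i)$p, numeric(1))
  expect_lte(mean(p < 0.05), 0.15)
  # duplicated locus: maximal dependence, p at the permutation floor
  dup <- make_dataset(cbind(ds$a[, 1], ds$a[, 1]), cbind(ds$b[, 1], ds$b[, 1]),
                      population = "A")
  ldd <- ld_test(dup, "L1", "L2", "A", n_perm = 99, seed = 1)
  expect_equal(ldd$p, 1 / 100)
  expect_error(ld_test(ds, "L1", "L2", "A", n_perm = 0), "at least 1")
})

test_that("Brookfield null-allele estimation recovers a simulated null allele", {
  expect_equal(null_allele_freq(0.8, 0.8), 0)
  expect_equal(null_allele_freq(0.6, 0.8), 0.2 / 1.8)
  expect_equal(null_allele_freq(0.9, 0.8), 0)  # clamped
  # null allele at frequency 0.15: carriers look homozygous, null homozygotes blank
  est <- vapply(1:15, function(s) {
    set.seed(s)
    n <- 200
    p <- c(0.15, rep(0.85 / 5, 5))       # allele 1 is the null
    a <- sample(1:6, n, TRUE, p); b <- sample(1:6, n, TRUE, p)
    obs_a <- ifelse(a == 1L & b == 1L, NA, ifelse(a == 1L, b, a))
    obs_b <- ifelse(a == 1L & b == 1L, NA, ifelse(b == 1L, obs_a, b))
    ds <- make_dataset(matrix(as.integer(obs_a)), matrix(as.integer(obs_b)),
                       population = "A")
    null_allele_test(ds, "L1", "A")$r_null
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 0.15), 0.05)
})
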