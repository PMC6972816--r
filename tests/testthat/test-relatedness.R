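even_freqs <- function(L, k) {
  stats::setNames(lapply(seq_len(L), function(l)
    stats::setNames(rep(1 / k, k), seq_len(k))), paste0("L", seq_len(L)))
}

test_that("identical genotypes with rare alleles drive k2 toward 1", {
  L <- 20
  fr <- even_freqs(L, 20)                       # rare alleles (freq 0.05)
  g <- list(a = stats::setNames(rep(1L, L), names(fr)),
            b = stats::setNames(rep(2L, L), names(fr)))
  est <- ml_relatedness(g, g, fr)
  expect_gt(est$k2, 0.95)
  expect_gt(est$r, 0.95)
})

test_that("the likelihood at the optimum dominates the unrelated corner", {
  set.seed(3)
  fr <- even_freqs(15, 6)
  for (i in 1:5) {
    g1 <- list(a = sample(1:6, 15, TRUE), b = sample(1:6, 15, TRUE))
    g2 <- list(a = sample(1:6, 15, TRUE), b = sample(1:6, 15, TRUE))
    est <- ml_relatedness(g1, g2, fr)
    unrel <- sum(log(vapply(1:15, function(l) {
      p <- fr[[l]]
      gp <- function(x, y) if (x == y) p[[x]]^2 else 2 * p[[x]] * p[[y]]
      gp(g1$a[l], g1$b[l]) * gp(g2$a[l], g2$b[l])
    }, numeric(1))))
    expect_gte(est$loglik, unrel - 1e-9)
  }
})

test_that("grid-refined estimates agree with the brute-force oracle", {
  set.seed(5)
  sim <- simulate_parental_pops(pop_model(n_loci = 12, n_alleles = 6, F = 0.1),
                                c(A = 30, B = 0), seed = 5)
  po <- simulate_pairs(sim$pop_freqs$A, "parent_offspring", n = 10, seed = 6)
  fr <- allele_freqs(po, by = NULL)$all
  for (i in seq_len(10)) {
    g1 <- genotype_of(po, paste0("pair", i, "_1"))
    g2 <- genotype_of(po, paste0("pair", i, "_2"))
    ours <- ml_relatedness(g1, g2, fr)
    orc <- oracle_relatedness(g1, g2, fr)
    expect_gte(ours$loglik, orc$loglik - 1e-9)  # finer grid can only improve
    expect_lt(abs(ours$r - orc$r), 0.011)
  }
})

test_that("relatedness estimates are invariant to locus order and relabeling", {
  set.seed(8)
  fr <- even_freqs(10, 5)
  g1 <- list(a = sample(1:5, 10, TRUE), b = sample(1:5, 10, TRUE))
  g2 <- list(a = sample(1:5, 10, TRUE), b = sample(1:5, 10, TRUE))
  base <- ml_relatedness(g1, g2, fr)
  perm <- sample(10)
  pg <- function(g) list(a = g$a[perm], b = g$b[perm])
  est_p <- ml_relatedness(pg(g1), pg(g2), fr[perm])
  expect_equal(est_p$r, base$r)
  # relabel alleles 1..5 -> 11..15 consistently
  relab <- function(x) x + 10L
  fr2 <- lapply(fr, function(p) stats::setNames(p, relab(1:5)))
  g1r <- list(a = relab(g1$a), b = relab(g1$b))
  g2r <- list(a = relab(g2$a), b = relab(g2$b))
  expect_equal(ml_relatedness(g1r, g2r, fr2)$r, base$r)
})

test_that("pedigree relationships are recovered on synthetic pairs", {
  sim <- simulate_parental_pops(pop_model(), c(A = 2, B = 0), seed = 9)
  po <- simulate_pairs(sim$pop_freqs$A, "parent_offspring", n = 60, seed = 10)
  fr <- allele_freqs(po, by = NULL)$all
  r_po <- vapply(1:60, function(i)
    ml_relatedness(genotype_of(po, paste0("pair", i, "_1")),
                   genotype_of(po, paste0("pair", i, "_2")), fr)$r, numeric(1))
  expect_lt(abs(mean(r_po) - 0.5), 0.05)
  un <- simulate_pairs(sim$pop_freqs$A, "unrelated", n = 60, seed = 11)
  fru <- allele_freqs(un, by = NULL)$all
  r_un <- vapply(1:60, function(i)
    ml_relatedness(genotype_of(un, paste0("pair", i, "_1")),
                   genotype_of(un, paste0("pair", i, "_2")), fru)$r, numeric(1))
  expect_lt(abs(mean(r_un)), 0.05)
})

test_that("the all-pairs matrix has the right size and is order-invariant", {
  sim <- simulate_parental_pops(pop_model(n_loci = 12, n_alleles = 6, F = 0.1),
                                c(A = 8, B = 0), seed = 12)
  rm1 <- relatedness_matrix(sim$dataset, leave_pair_out = FALSE)
  expect_equal(nrow(rm1$pairs), 8 * 7 / 2)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  rm2 <- relatedness_matrix(subset_dataset(sim$dataset, individuals = perm),
                            leave_pair_out = FALSE)
  key <- function(p) paste(pmin(p$id1, p$id2), pmax(p$id1, p$id2))
  m <- match(key(rm1$pairs), key(rm2$pairs))
  expect_equal(rm1$pairs$r, rm2$pairs$r[m])
  expect_lt(rm1$summary[["mean"]], 0.1)   # unrelated population
})

test_that("pairwise distances follow their definition", {
  co <- data.frame(id = c("A", "B"), x = c(0, 3), y = c(0, 4))
  pd <- pair_distances(co)
  expect_equal(pd$pairs$distance, 5)
  co2 <- data.frame(id = c("A", "A", "B"), x = c(0, 0, 4), y = c(0, 2, 0))
  pd2 <- pair_distances(co2)
  expect_equal(pd2$pairs$distance, mean(c(4, sqrt(20))), tolerance = 1e-12)
  co3 <- rbind(co, data.frame(id = "C", x = NA, y = NA))
  expect_equal(pair_distances(co3)$excluded, "C")
})

test_that("the distance model finds kin clustering and stays calibrated without it", {
  sim <- simulate_parental_pops(pop_model(F = 0.05), c(A = 2, B = 0), seed = 40)
  sig_on <- 0; sig_off <- 0
  for (s in 1:5) {
    fam <- simulate_families(sim$pop_freqs$A, n_families = 7, n_unrelated = 6,
                             seed = 60 + s)
    rel <- relatedness_matrix(fam, leave_pair_out = FALSE)$pairs
    sexes <- stats::setNames(fam$meta$sex, fam$meta$id)
    for (clu in c(TRUE, FALSE)) {
      co <- simulate_coordinates(fam, kin_clustering = clu, noise_sd = 200,
                                 seed = 80 + s + 100 * clu)
      mm <- merge(rel, pair_distances(co)$pairs)
      dm <- distance_model(mm, sexes)
      pooled <- dm[dm$stratum == "pooled", ]
      expect_true(pooled$r2 >= 0 && pooled$r2 <= 1)
      if (clu && pooled$p < 0.05 && pooled$slope < 0) sig_on <- sig_on + 1
      if (!clu && pooled$p < 0.05) sig_off <- sig_off + 1
    }
  }
  expect_gte(sig_on, 4)
  expect_lte(sig_off, 2)
  # constant relatedness is refused
  const <- data.frame(id1 = letters[1:10], id2 = LETTERS[1:10],
                      distance = stats::runif(10), r = 0.2)
  sx <- stats::setNames(rep("F", 20), c(letters[1:10], LETTERS[1:10]))
  expect_error(distance_model(const, sx), "constant")
})
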