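sim_two_pops <- function(seed, n = 40, F = 0.15) {
  simulate_parental_pops(pop_model(F = F), c(wild = n, domestic = n),
                         seed = seed)
}

test_that("K = 1 gives degenerate ancestry and intervals", {
  ds <- sim_two_pops(1, n = 10)$dataset
  ar <- fit_admixture(ds, K = 1, burnin = 50, iters = 200, thin = 2, seed = 1)
  expect_true(all(ar$q == 1))
  expect_true(all(ar$cri90$lo == 1) && all(ar$cri90$hi == 1))
  expect_error(fit_admixture(ds, K = 50), "exceeds")
})

test_that("fixed seed reproduces the whole fit", {
  ds <- sim_two_pops(2, n = 12)$dataset
  a1 <- fit_admixture(ds, K = 2, burnin = 100, iters = 300, seed = 11)
  a2 <- fit_admixture(ds, K = 2, burnin = 100, iters = 300, seed = 11)
  expect_identical(a1$q, a2$q)
  expect_identical(a1$loglik_trace, a2$loglik_trace)
})

test_that("posterior ancestry rows sum to one and intervals bracket the mean", {
  ds <- sim_two_pops(3, n = 15)$dataset
  for (model in c("independent", "correlated")) {
    ar <- fit_admixture(ds, K = 2, burnin = 200, iters = 600, seed = 4,
                        model = model)
    expect_equal(unname(rowSums(ar$q)), rep(1, 30), tolerance = 1e-9)
    expect_true(all(ar$cri90$lo <= ar$q + 1e-9))
    expect_true(all(ar$cri90$hi >= ar$q - 1e-9))
  }
})

test_that("parental and F1 ancestry is recovered on synthetic data", {
  ok_par <- 0; f1_in <- 0; f1_tot <- 0
  for (s in 1:3) {
    sim <- sim_two_pops(s + 20, n = 50)
    f1 <- simulate_hybrids(sim$pop_freqs$wild, sim$pop_freqs$domestic, "F1",
                           15, seed = s + 40)
    ds <- bind_datasets(list(sim$dataset, f1))
    ar <- fit_admixture(ds, K = 2, burnin = 500, iters = 1500, seed = s)
    ref <- list(ds$ids[grep("^wild", ds$ids)], ds$ids[grep("^domestic", ds$ids)])
    ar <- align_clusters(ar, ref)
    qw <- mean(ar$q[grep("^wild", ar$ids), 1])
    qd <- mean(ar$q[grep("^domestic", ar$ids), 2])
    if (qw > 0.9 && qd > 0.9) ok_par <- ok_par + 1
    qf <- ar$q[match(f1$ids, ar$ids), 1]
    f1_in <- f1_in + sum(qf > 0.25 & qf < 0.75)
    f1_tot <- f1_tot + length(qf)
  }
  expect_equal(ok_par, 3)
  expect_gte(f1_in / f1_tot, 0.9)
})

test_that("true F1 ancestry is covered by the 90% credibility interval", {
  sim <- sim_two_pops(9, n = 50)
  f1 <- simulate_hybrids(sim$pop_freqs$wild, sim$pop_freqs$domestic, "F1",
                         40, seed = 90)
  ds <- bind_datasets(list(sim$dataset, f1))
  ar <- fit_admixture(ds, K = 2, burnin = 500, iters = 2000, seed = 7)
  ii <- match(f1$ids, ar$ids)
  covered <- mean(ar$cri90$lo[ii, 1] <= 0.5 & ar$cri90$hi[ii, 1] >= 0.5)
  expect_gte(covered, 0.75)
})

test_that("permuting cluster labels leaves the data likelihood unchanged", {
  sim <- sim_two_pops(5, n = 20)
  ds <- sim$dataset
  ar <- fit_admixture(ds, K = 2, burnin = 200, iters = 600, seed = 2)
  loglik_of <- function(q, freqs) {
    ll <- 0
    for (l in seq_along(ds$loci)) {
      pf <- freqs[[l]]
      for (i in seq_along(ds$ids)) {
        for (x in c(ds$a[i, l], ds$b[i, l])) {
          if (is.na(x)) next
          ll <- ll + log(sum(q[i, ] * pf[, as.character(x)]))
        }
      }
    }
    ll
  }
  ll1 <- loglik_of(ar$q, ar$cluster_freqs)
  ll2 <- loglik_of(ar$q[, 2:1], lapply(ar$cluster_freqs, function(m) m[2:1, ]))
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("Evanno's deltaK follows its arithmetic and finds the true K", {
  # constructed table: L = (-100, -50, -48, -47), sd = 1 at every K
  ll <- list(`1` = c(-101, -99), `2` = c(-51, -49), `3` = c(-49, -47),
             `4` = c(-48, -46))
  # sd of each pair is sqrt(2); rescale to sd 1
  ll <- lapply(ll, function(v) mean(v) + (v - mean(v)) / stats::sd(v))
  ev <- evanno_delta_k(ll)
  expect_equal(unname(ev$delta_k["2"]), 48)
  expect_equal(unname(ev$delta_k["3"]), 1)
  expect_equal(ev$best_k, 2L)
  # exactly linear mean with positive sd: zero curvature everywhere
  lin <- list(`1` = c(-10, -12), `2` = c(-8, -10), `3` = c(-6, -8))
  expect_equal(unname(evanno_delta_k(lin)$delta_k), 0)
  expect_error(evanno_delta_k(list(`1` = 1:2, `2` = 1:2)), "3")
})

test_that("two-population data selects K = 2 by deltaK", {
  sim <- sim_two_pops(6, n = 30, F = 0.2)
  ll <- list()
  for (K in 1:4) {
    ll[[as.character(K)]] <- vapply(1:3, function(r) {
      ar <- fit_admixture(sim$dataset, K = K, burnin = 300, iters = 900,
                          seed = 100 * K + r)
      mean_loglik(ar, burnin = 300)
    }, numeric(1))
  }
  expect_equal(evanno_delta_k(ll)$best_k, 2L)
})

test_that("cluster alignment recovers identity and constructed swaps", {
  sim <- sim_two_pops(7, n = 15)
  ds <- sim$dataset
  ar <- fit_admixture(ds, K = 2, burnin = 200, iters = 600, seed = 3)
  ref <- list(ds$ids[ds$meta$population == "wild"],
              ds$ids[ds$meta$population == "domestic"])
  base <- align_clusters(ar, ref)
  again <- align_clusters(base, ref)
  expect_identical(attr(again, "perm"), 1:2)
  expect_equal(base$q, again$q)
  swapped <- base
  swapped$q <- swapped$q[, 2:1]
  colnames(swapped$q) <- c("k1", "k2")
  fixed <- align_clusters(swapped, ref)
  expect_identical(attr(fixed, "perm"), c(2L, 1L))
  expect_equal(unname(fixed$q), unname(base$q))
})
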