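rs_of <- function(reps) {
  # reps: list of length-2L vectors c(a..., b...) per repeat over shared loci
  a <- do.call(rbind, lapply(reps, `[[`, 1))
  b <- do.call(rbind, lapply(reps, `[[`, 2))
  replicate_set("s1", a, b)
}

test_that("consensus building follows the unanimity / dropout / conflict rules", {
  # unanimity on a heterozygote
  rs <- rs_of(list(list(matrix(1L), matrix(2L)), list(matrix(1L), matrix(2L))))
  cons <- build_consensus(rs)
  expect_equal(unname(c(cons$a, cons$b)), c(1L, 2L))
  # homozygote explained by dropout of allele 2
  rs <- rs_of(list(list(matrix(1L), matrix(1L)), list(matrix(1L), matrix(2L))))
  cons <- build_consensus(rs)
  expect_equal(unname(c(cons$a, cons$b)), c(1L, 2L))
  expect_false(cons$conflict[[1]])
  # three distinct alleles: conflict, consensus missing
  rs <- rs_of(list(list(matrix(1L), matrix(2L)), list(matrix(3L), matrix(3L))))
  cons <- build_consensus(rs)
  expect_true(is.na(cons$a[[1]]))
  expect_true(cons$conflict[[1]])
  # all repeats missing -> missing, no conflict
  rs <- rs_of(list(list(matrix(NA_integer_), matrix(NA_integer_))))
  cons <- build_consensus(rs)
  expect_true(is.na(cons$a[[1]]) && !cons$conflict[[1]])
  # disagreeing homozygotes cannot be reconciled
  rs <- rs_of(list(list(matrix(1L), matrix(1L)), list(matrix(2L), matrix(2L))))
  cons <- build_consensus(rs)
  expect_true(is.na(cons$a[[1]]) && cons$conflict[[1]])
  expect_error(replicate_set("x", matrix(1L, 0, 1), matrix(1L, 0, 1)),
               "at least one")
})

test_that("heterozygote confirmation needs two sightings from three repeats", {
  a <- matrix(c(1L, 1L, 1L), 3, 1); b <- matrix(c(2L, 1L, 1L), 3, 1)
  cons <- build_consensus(replicate_set("s", a, b))
  expect_equal(unname(c(cons$a, cons$b)), c(1L, 1L))  # het seen once: homozygote wins
  b2 <- matrix(c(2L, 2L, 1L), 3, 1)
  cons2 <- build_consensus(replicate_set("s", a, b2))
  expect_equal(unname(c(cons2$a, cons2$b)), c(1L, 2L))
})

test_that("quality-index contributions are 1, 0.5 and 0 per the scoring rules", {
  a <- matrix(c(1L, 1L, NA), 3, 1); b <- matrix(c(2L, 1L, NA), 3, 1)
  rs <- replicate_set("s", a, b)
  cons <- list(a = c(L1 = 1L), b = c(L1 = 2L), conflict = c(L1 = FALSE))
  qi <- quality_index(rs, cons)
  expect_equal(unname(qi$per_repeat[, 1]), c(1, 0.5, 0))
  expect_equal(qi$per_locus[[1]], 0.5)
  expect_equal(qi$sample_qi, 0.5)
})

test_that("QI is invariant to repeat order and locus order", {
  set.seed(9)
  a <- matrix(sample(c(1:3, NA), 12, TRUE), 3, 4)
  b <- a; b[!is.na(b)] <- b[!is.na(b)] + sample(0:1, sum(!is.na(b)), TRUE)
  rs <- replicate_set("s", a, b)
  qi <- quality_index(rs)
  perm_r <- sample(3); perm_l <- sample(4)
  qi_r <- quality_index(replicate_set("s", a[perm_r, ], b[perm_r, ]))
  qi_l <- quality_index(replicate_set("s", a[, perm_l], b[, perm_l]))
  expect_equal(qi_r$sample_qi, qi$sample_qi)
  expect_equal(qi_l$sample_qi, qi$sample_qi)
})

test_that("with failures only, QI equals the amplification success fraction", {
  m <- pop_model(n_loci = 10, n_alleles = 4, F = 0.1)
  ds <- simulate_parental_pops(m, c(A = 8, B = 0), seed = 2)$dataset
  reps <- simulate_replicates(ds, error_model(0, 0.3, 3), seed = 5)
  for (rs in reps) {
    qi <- quality_index(rs)
    called_frac <- mean(!is.na(rs$a))
    # loci where every repeat failed contribute 0 either way
    expect_equal(qi$sample_qi, called_frac)
  }
})

test_that("sample filters apply the strict QI and first-pass rules", {
  tab <- data.frame(sample = c("a", "b", "c", "d"),
                    qi = c(0.9, 0.6, 1.0, 0.95),
                    first_pass_loci = c(10, 12, 22, 4))
  res <- filter_samples(tab)
  expect_setequal(res$retained, c("a", "c"))
  expect_equal(res$n_dropped_first_pass, 1)  # d: 4 loci at first pass
  expect_equal(res$n_dropped_qi, 1)          # b: QI 0.6 exactly is out
})

test_that("genotype matching implements rules (a), (b) and (c)", {
  g <- function(a, b) list(a = a, b = b)
  v1 <- g(rep(1L, 22), rep(2L, 22))
  expect_true(match_genotypes(v1, v1))                     # (a)
  v2 <- v1; v2$a[1:11] <- NA; v2$b[1:11] <- NA
  expect_false(match_genotypes(v1, v2))                    # 11 missing: too many
  v3 <- v1; v3$a[1:10] <- NA; v3$b[1:10] <- NA
  expect_true(match_genotypes(v1, v3))                     # (b): 10 is allowed
  v4 <- v1; v4$a[5] <- 2L                                  # (2,2) vs (1,2): dropout
  expect_true(match_genotypes(v1, v4))                     # (c)
  v5 <- v1; v5$a[5] <- 3L; v5$b[5] <- 3L                   # (3,3) vs (1,2): no
  expect_false(match_genotypes(v1, v5))
  v6 <- v1; v6$a[5] <- 2L; v6$a[6] <- 2L                   # two differences
  expect_false(match_genotypes(v1, v6))
})

test_that("genotype matching is symmetric on random pairs", {
  set.seed(11)
  for (i in 1:30) {
    a1 <- sample(c(1:4, NA), 22, TRUE); b1 <- ifelse(is.na(a1), NA, sample(1:4, 22, TRUE))
    a2 <- a1; b2 <- b1
    flip <- sample(22, 3)
    a2[flip] <- sample(c(1:4, NA), 3, TRUE)
    b2[flip] <- ifelse(is.na(a2[flip]), NA, sample(1:4, 3, TRUE))
    g1 <- list(a = pmin(a1, b1), b = pmax(a1, b1))
    g2 <- list(a = pmin(a2, b2), b = pmax(a2, b2))
    expect_identical(match_genotypes(g1, g2), match_genotypes(g2, g1))
  }
})

test_that("collapsing groups matching samples and keeps disjoint ones apart", {
  g <- function(a, b) list(a = a, b = b)
  v1 <- g(rep(1L, 22), rep(2L, 22))
  v1b <- v1; v1b$a[3] <- NA; v1b$b[3] <- NA
  v2 <- g(rep(3L, 22), rep(4L, 22))
  res <- collapse_individuals(list(s1 = v1, s2 = v1b, s3 = v2))
  expect_equal(length(res$dataset$ids), 2L)
  expect_equal(sort(unname(res$n_samples)), c(1L, 2L))
  expect_equal(res$map$individual[1], res$map$individual[2])
  res2 <- collapse_individuals(list(x = v1, y = v2))
  expect_equal(length(res2$dataset$ids), 2L)
})

test_that("individual recovery from replicated noisy samples succeeds at default rates", {
  # one noninvasive sample per true individual: after consensus building and
  # filtering, collapsing must neither merge distinct individuals nor split
  # samples, so the recovered count equals the retained-sample count
  hits <- 0
  for (s in 1:10) {
    m <- pop_model(n_loci = 22, n_alleles = 8, F = 0.1)
    ds <- simulate_parental_pops(m, c(A = 12, B = 0), seed = s)$dataset
    reps <- simulate_replicates(ds, error_model(), seed = s + 100)
    qc <- run_qc(reps)
    if (!is.null(qc$collapse) &&
        length(qc$collapse$dataset$ids) == length(qc$filter$retained))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})
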