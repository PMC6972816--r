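#' Two-population F-model for microsatellite frequencies
#'
#' Defines the ancestral allele frequencies and the drift parameter `F` used
#' to derive two diverged parental gene pools (wild and domestic). Each
#' population's per-locus frequencies are drawn from a Dirichlet centred on
#' the ancestral vector with concentration `(1 - F) / F` (the correlated
#' allele-frequencies prior), so larger `F` means stronger drift and higher
#' realised F_ST between the parental pools.
#'
#' @param n_loci Number of loci (default 22, the study panel size).
#' @param n_alleles Alleles per locus (scalar or length-`n_loci`).
#' @param F Drift parameter, strictly in (0, 1). The default 0.15 targets the
#'   wild-domestic differentiation observed in the field (F_ST about
#'   0.15-0.17).
#' @param ancestral_freqs Optional list of per-locus probability vectors; by
#'   default uniform over the locus's alleles.
#' @return An object of class `wh_popmodel`.
#' @export
pop_model <- function(n_loci = 22, n_alleles = 8, F = 0.15,
                      ancestral_freqs = NULL) {
  stopifnot(n_loci >= 1, F > 0, F < 1)
  n_alleles <- rep_len(n_alleles, n_loci)
  if (is.null(ancestral_freqs))
    ancestral_freqs <- lapply(n_alleles, function(k) rep(1 / k, k))
  stopifnot(length(ancestral_freqs) == n_loci)
  for (p in ancestral_freqs)
    if (abs(sum(p) - 1) > 1e-12 || any(p < 0))
      stop("every ancestral frequency vector must be a probability vector")
  structure(list(n_loci = n_loci, n_alleles = n_alleles, F = F,
                 ancestral_freqs = ancestral_freqs),
            class = "wh_popmodel")
}

#' Noninvasive genotyping error model
#'
#' Per-repeat error process applied to true genotypes: with probability
#' `failure_rate` a locus fails to amplify (all-missing); otherwise a
#' heterozygote loses one uniformly chosen allele with probability
#' `dropout_rate` and is observed as a false homozygote. Defaults are loosely
#' motivated by typical faecal/hair amplification success and are tunable.
#'
#' @param dropout_rate Per-heterozygous-genotype per-repeat dropout probability.
#' @param failure_rate Per-locus per-repeat amplification failure probability.
#' @param n_repeats Repeats per sample (2-4 for noninvasive material).
#' @return An object of class `wh_errormodel`.
#' @export
error_model <- function(dropout_rate = 0.2, failure_rate = 0.15, n_repeats = 3) {
  stopifnot(dropout_rate >= 0, dropout_rate <= 1,
            failure_rate >= 0, failure_rate <= 1, n_repeats >= 1)
  structure(list(dropout_rate = dropout_rate, failure_rate = failure_rate,
                 n_repeats = as.integer(n_repeats)),
            class = "wh_errormodel")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1  # numeric underflow guard
  x / sum(x)
}

draw_genotypes_hwe <- function(freqs, n, loci) {
  L <- length(freqs)
  A <- matrix(NA_integer_, n, L); B <- A
  for (l in seq_len(L)) {
    codes <- as.integer(names(freqs[[l]]))
    A[, l] <- sample(codes, n, replace = TRUE, prob = freqs[[l]])
    B[, l] <- sample(codes, n, replace = TRUE, prob = freqs[[l]])
  }
  colnames(A) <- loci; colnames(B) <- loci
  list(a = A, b = B)
}

name_freqs <- function(p) stats::setNames(p, seq_along(p))

#' Simulate two parental populations under the F-model
#'
#' Draws each population's per-locus frequencies from the Dirichlet prior
#' centred on the model's ancestral frequencies, then genotypes individuals
#' under Hardy-Weinberg equilibrium (two independent gamete draws per locus).
#'
#' @param model A [pop_model()].
#' @param n_per_pop Named integer vector of sample sizes, e.g.
#'   `c(wild = 42, domestic = 371)`. At least one must be positive.
#' @param seed Integer seed; the simulation is a pure function of
#'   (inputs, seed).
#' @param pop_names Optional names when `n_per_pop` is unnamed.
#' @return List with `dataset` (a [wh_dataset()], `meta$population` set) and
#'   `pop_freqs` (per-population per-locus frequency vectors, allele codes
#'   `1..k`).
#' @export
simulate_parental_pops <- function(model, n_per_pop = c(wild = 200, domestic = 200),
                                   seed = 1, pop_names = NULL) {
  stopifnot(inherits(model, "wh_popmodel"))
  if (all(n_per_pop == 0)) stop("at least one population must have n > 0")
  if (is.null(names(n_per_pop)))
    names(n_per_pop) <- pop_names %||% paste0("pop", seq_along(n_per_pop))
  set.seed(seed)
  loci <- paste0("L", seq_len(model$n_loci))
  conc <- (1 - model$F) / model$F
  pop_freqs <- lapply(names(n_per_pop), function(p)
    stats::setNames(lapply(model$ancestral_freqs,
                           function(pa) name_freqs(rdirichlet1(pa * conc))),
                    loci))
  names(pop_freqs) <- names(n_per_pop)
  parts <- list()
  for (p in names(n_per_pop)) {
    n <- n_per_pop[[p]]
    if (n == 0) next
    g <- draw_genotypes_hwe(pop_freqs[[p]], n, loci)
    rownames(g$a) <- paste0(p, "_", seq_len(n))
    parts[[p]] <- wh_dataset(g$a, g$b,
                             data.frame(id = rownames(g$a), population = p,
                                        morphology = if (grepl("wild", p)) "silvestris" else "catus",
                                        stringsAsFactors = FALSE))
  }
  list(dataset = bind_datasets(parts), pop_freqs = pop_freqs)
}

draw_f1 <- function(freqs_a, freqs_b, n) {
  L <- length(freqs_a)
  A <- matrix(NA_integer_, n, L); B <- A
  for (l in seq_len(L)) {
    A[, l] <- sample(as.integer(names(freqs_a[[l]])), n, TRUE, freqs_a[[l]])
    B[, l] <- sample(as.integer(names(freqs_b[[l]])), n, TRUE, freqs_b[[l]])
  }
  list(a = A, b = B)
}

# one gamete per locus from an F1 parent: each of its two alleles w.p. 1/2
f1_gamete <- function(f1) {
  pick <- matrix(stats::runif(length(f1$a)) < 0.5, nrow(f1$a))
  ifelse(pick, f1$a, f1$b)
}

#' Simulate hybrid-class individuals from parental allele frequencies
#'
#' Gamete-level simulation of the four hybrid classes from two parental gene
#' pools: `F1` = one gamete from each pool; `F2` = one gamete from each of
#' two freshly simulated F1 parents; `BC_A`/`BC_B` = one F1 gamete plus one
#' gamete drawn from pool A/B frequencies. Loci are independent.
#'
#' @param freqs_a,freqs_b Per-locus named frequency vectors for the two
#'   pools (same loci, e.g. from [simulate_parental_pops()] or
#'   [allele_freqs()]).
#' @param class One of `"F1"`, `"F2"`, `"BC_A"`, `"BC_B"`.
#' @param n Number of simulants.
#' @param seed Integer seed.
#' @param prefix ID prefix.
#' @return A [wh_dataset()] with `meta$class` set.
#' @export
simulate_hybrids <- function(freqs_a, freqs_b, class, n, seed = 1,
                             prefix = class) {
  if (!identical(names(freqs_a), names(freqs_b)))
    stop("the two frequency sets must cover identical loci")
  if (!class %in% c("F1", "F2", "BC_A", "BC_B"))
    stop("unknown hybrid class: ", class)
  set.seed(seed)
  loci <- names(freqs_a)
  g <- switch(class,
    F1 = draw_f1(freqs_a, freqs_b, n),
    F2 = {
      p1 <- draw_f1(freqs_a, freqs_b, n); p2 <- draw_f1(freqs_a, freqs_b, n)
      list(a = f1_gamete(p1), b = f1_gamete(p2))
    },
    BC_A = {
      p1 <- draw_f1(freqs_a, freqs_b, n)
      list(a = f1_gamete(p1), b = draw_genotypes_hwe(freqs_a, n, loci)$a)
    },
    BC_B = {
      p1 <- draw_f1(freqs_a, freqs_b, n)
      list(a = f1_gamete(p1), b = draw_genotypes_hwe(freqs_b, n, loci)$a)
    })
  colnames(g$a) <- loci; colnames(g$b) <- loci
  rownames(g$a) <- paste0(prefix, "_", seq_len(n))
  wh_dataset(g$a, g$b, data.frame(id = rownames(g$a), class = class,
                                  stringsAsFactors = FALSE))
}

#' Simulate replicated noninvasive genotyping of a dataset
#'
#' Applies the [error_model()] independently per sample, repeat and locus:
#' amplification failure makes the locus missing; allelic dropout turns a
#' heterozygote into an apparent homozygote (one allele, uniformly chosen,
#' is lost). Homozygotes are never altered.
#'
#' @param ds True genotypes, a [wh_dataset()].
#' @param em An [error_model()].
#' @param seed Integer seed.
#' @return A list of [replicate_set()] objects, one per individual, named by
#'   ID.
#' @export
simulate_replicates <- function(ds, em, seed = 1) {
  stopifnot(inherits(ds, "wh_dataset"), inherits(em, "wh_errormodel"))
  set.seed(seed)
  L <- length(ds$loci)
  out <- lapply(seq_along(ds$ids), function(i) {
    A <- matrix(rep(ds$a[i, ], each = em$n_repeats), em$n_repeats)
    B <- matrix(rep(ds$b[i, ], each = em$n_repeats), em$n_repeats)
    fail <- matrix(stats::runif(em$n_repeats * L) < em$failure_rate,
                   em$n_repeats)
    het <- !is.na(A) & A != B
    drop <- het & matrix(stats::runif(em$n_repeats * L) < em$dropout_rate,
                         em$n_repeats)
    keep_a <- matrix(stats::runif(em$n_repeats * L) < 0.5, em$n_repeats)
    # dropout: surviving allele duplicated into an apparent homozygote
    B[drop & keep_a] <- A[drop & keep_a]
    A[drop & !keep_a] <- B[drop & !keep_a]
    A[fail] <- NA; B[fail] <- NA
    colnames(A) <- ds$loci; colnames(B) <- ds$loci
    replicate_set(ds$ids[i], A, B,
                  material = ds$meta$material[i] %||% "feces")
  })
  stats::setNames(out, ds$ids)
}

#' Simulate full-sib family structure within one gene pool
#'
#' Parents are drawn under HWE from the pool frequencies; each family's
#' offspring are independent Mendelian draws from the same parent pair
#' (full sibs). Used to make the kinship-vs-distance analysis testable.
#'
#' @param freqs Per-locus named frequency vectors.
#' @param n_families Number of full-sib groups.
#' @param sib_range Family sizes drawn uniformly from this range (2-4 by
#'   default, the smallest structure that supports the spatial regression).
#' @param n_unrelated Additional unrelated individuals.
#' @param seed Integer seed.
#' @param population Population label written to metadata.
#' @return A [wh_dataset()] with `meta$family` (`NA` for unrelated) and
#'   `meta$sex` assigned at random.
#' @export
simulate_families <- function(freqs, n_families = 10, sib_range = c(2, 4),
                              n_unrelated = 10, seed = 1,
                              population = "wild") {
  set.seed(seed)
  loci <- names(freqs)
  sizes <- sample(seq(sib_range[1], sib_range[2]), n_families, replace = TRUE)
  parts <- list(); fam_labels <- character(0)
  mendel_child <- function(par) {
    pick1 <- stats::runif(length(loci)) < 0.5
    pick2 <- stats::runif(length(loci)) < 0.5
    list(a = ifelse(pick1, par$m$a, par$m$b),
         b = ifelse(pick2, par$f$a, par$f$b))
  }
  A <- list(); B <- list(); fams <- character(0)
  for (f in seq_len(n_families)) {
    par <- list(m = draw_genotypes_hwe(freqs, 1, loci),
                f = draw_genotypes_hwe(freqs, 1, loci))
    par <- list(m = list(a = par$m$a[1, ], b = par$m$b[1, ]),
                f = list(a = par$f$a[1, ], b = par$f$b[1, ]))
    for (s in seq_len(sizes[f])) {
      ch <- mendel_child(par)
      A[[length(A) + 1L]] <- ch$a; B[[length(B) + 1L]] <- ch$b
      fams <- c(fams, paste0("fam", f))
    }
  }
  if (n_unrelated > 0) {
    g <- draw_genotypes_hwe(freqs, n_unrelated, loci)
    for (i in seq_len(n_unrelated)) {
      A[[length(A) + 1L]] <- g$a[i, ]; B[[length(B) + 1L]] <- g$b[i, ]
      fams <- c(fams, NA)
    }
  }
  A <- do.call(rbind, A); B <- do.call(rbind, B)
  colnames(A) <- loci; colnames(B) <- loci
  rownames(A) <- paste0(population, "_", seq_len(nrow(A)))
  wh_dataset(A, B, data.frame(id = rownames(A), population = population,
                              family = fams,
                              sex = sample(c("F", "M"), nrow(A), TRUE),
                              stringsAsFactors = FALSE))
}

#' Simulate parent-offspring or unrelated pairs
#'
#' Convenience generator for relatedness calibration: each pair is drawn from
#' the pool frequencies, the offspring of a parent-offspring pair inheriting
#' one allele per locus from the parent and one from the pool.
#'
#' @param freqs Per-locus named frequency vectors.
#' @param relationship `"parent_offspring"` or `"unrelated"`.
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return A [wh_dataset()] of `2n` individuals; `meta$pair` indexes the
#'   pairs, members suffixed `_1`/`_2`.
#' @export
simulate_pairs <- function(freqs, relationship = c("parent_offspring", "unrelated"),
                           n = 100, seed = 1) {
  relationship <- match.arg(relationship)
  set.seed(seed)
  loci <- names(freqs)
  p1 <- draw_genotypes_hwe(freqs, n, loci)
  p2 <- draw_genotypes_hwe(freqs, n, loci)
  if (relationship == "parent_offspring") {
    pick <- matrix(stats::runif(n * length(loci)) < 0.5, n)
    p2$a <- ifelse(pick, p1$a, p1$b)  # one allele from the parent
  }
  A <- rbind(p1$a, p2$a); B <- rbind(p1$b, p2$b)
  colnames(A) <- loci; colnames(B) <- loci
  rownames(A) <- c(paste0("pair", seq_len(n), "_1"),
                   paste0("pair", seq_len(n), "_2"))
  wh_dataset(A, B, data.frame(id = rownames(A),
                              pair = rep(seq_len(n), 2),
                              stringsAsFactors = FALSE))
}

#' Simulate sampling coordinates, with or without kin clustering
#'
#' With clustering on, members of a family (from `meta$family`) share a
#' spatial centre drawn uniformly on the study rectangle and individual
#' positions are the centre plus isotropic Gaussian noise; unrelated
#' individuals (and everyone when clustering is off) are placed uniformly.
#'
#' @param ds A [wh_dataset()]; kin clustering requires `meta$family`.
#' @param kin_clustering Logical.
#' @param area Study rectangle side length in metres (square
#'   `[0, area] x [0, area]`; default 20 km, the order of the field study
#'   areas).
#' @param noise_sd Within-family scatter (metres) when clustering is on.
#' @param seed Integer seed.
#' @return Data frame `id, x, y` (one row per individual).
#' @export
simulate_coordinates <- function(ds, kin_clustering = TRUE, area = 20000,
                                 noise_sd = 500, seed = 1) {
  stopifnot(inherits(ds, "wh_dataset"))
  set.seed(seed)
  n <- length(ds$ids)
  x <- stats::runif(n, 0, area); y <- stats::runif(n, 0, area)
  if (kin_clustering) {
    fam <- ds$meta$family
    if (is.null(fam)) stop("kin clustering requires meta$family labels")
    for (f in unique(fam[!is.na(fam)])) {
      sel <- which(!is.na(fam) & fam == f)
      cx <- stats::runif(1, 0, area); cy <- stats::runif(1, 0, area)
      x[sel] <- cx + stats::rnorm(length(sel), 0, noise_sd)
      y[sel] <- cy + stats::rnorm(length(sel), 0, noise_sd)
    }
  }
  data.frame(id = ds$ids, x = x, y = y, stringsAsFactors = FALSE)
}

#' Empirical calibration from the drift parameter F to realised F_ST
#'
#' Simulates parental pairs over a grid of `F` values and reports the
#' multilocus Weir-Cockerham theta realised at each, averaged over seeds.
#'
#' @param F_grid Drift values to probe.
#' @param model_args Arguments passed to [pop_model()] besides `F`.
#' @param n_per_pop Sample sizes per population.
#' @param n_seeds Seeds averaged per grid point.
#' @return Data frame `F, mean_fst, sd_fst`.
#' @export
calibrate_fst <- function(F_grid = seq(0.05, 0.3, by = 0.05),
                          model_args = list(), n_per_pop = c(A = 100, B = 100),
                          n_seeds = 5) {
  res <- lapply(F_grid, function(Fv) {
    fst <- vapply(seq_len(n_seeds), function(s) {
      sim <- simulate_parental_pops(do.call(pop_model, c(model_args, list(F = Fv))),
                                    n_per_pop, seed = s * 1000 + round(Fv * 100))
      wc_fstats(sim$dataset)$theta
    }, numeric(1))
    data.frame(F = Fv, mean_fst = mean(fst), sd_fst = stats::sd(fst))
  })
  do.call(rbind, res)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
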