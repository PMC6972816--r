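#' Maximum-likelihood pairwise relatedness
#'
#' Estimates the IBD-mode coefficients (k0, k1, k2) -- the probabilities
#' that a pair shares zero, one or two alleles identical by descent -- by
#' maximising the product over shared-called loci of the genotype-pair
#' likelihood `k0 S0 + k1 S1 + k2 S2` given population allele frequencies,
#' where S0/S1/S2 are the standard genotype-pair probabilities under 0/1/2
#' shared IBD alleles. Maximisation is a deterministic grid search over the
#' 2-simplex: coarse step 0.02, then local refinement to step 0.001.
#' Relatedness is `r = k2 + k1/2`.
#'
#' @param g1,g2 Genotype vectors (lists `a`, `b`) over the same loci, e.g.
#'   from [genotype_of()].
#' @param freqs Per-locus named allele-frequency vectors covering every
#'   observed allele (an observed allele at frequency 0 is an error).
#' @param min_loci Minimum shared-called loci (default 5).
#' @return List `k0`, `k1`, `k2`, `r`, `loglik`, `n_loci`.
#' @export
ml_relatedness <- function(g1, g2, freqs, min_loci = 5) {
  S <- pair_ibd_probs(g1, g2, freqs)
  if (nrow(S) < min_loci)
    stop("fewer than ", min_loci, " loci called in both individuals")
  obj <- function(k0, k2) {
    k1 <- 1 - k0 - k2
    sum(log(pmax(k0 * S[, 1] + k1 * S[, 2] + k2 * S[, 3], 1e-300)))
  }
  best <- grid_search_simplex(obj, step = 0.02)
  best <- grid_search_simplex(obj, step = 0.001,
                              centre = best, window = 0.02)
  k0 <- best[1]; k2 <- best[2]; k1 <- 1 - k0 - k2
  list(k0 = k0, k1 = k1, k2 = k2, r = k2 + k1 / 2,
       loglik = obj(k0, k2), n_loci = nrow(S))
}

# per-locus S0,S1,S2 for a pair; rows = shared-called loci
pair_ibd_probs <- function(g1, g2, freqs) {
  loci <- names(freqs)
  stopifnot(length(g1$a) == length(loci))
  rows <- list()
  for (l in seq_along(loci)) {
    a1 <- g1$a[[l]]; b1 <- g1$b[[l]]; a2 <- g2$a[[l]]; b2 <- g2$b[[l]]
    if (is.na(a1) || is.na(a2)) next
    p <- freqs[[l]]
    pa <- function(x) {
      v <- p[as.character(x)]
      if (is.na(v) || v == 0)
        stop("observed allele ", x, " has frequency 0 at ", loci[l])
      unname(v)
    }
    pg <- function(a, b) if (a == b) pa(a)^2 else 2 * pa(a) * pa(b)
    s0 <- pg(a1, b1) * pg(a2, b2)
    s2 <- if (a1 == a2 && b1 == b2) pg(a1, b1) else 0
    # one shared IBD allele
    s1 <- if (a1 == b1 && a2 == b2) {                 # (a,a) vs (c,c)
      if (a1 == a2) pa(a1)^3 else 0
    } else if (a1 == b1) {                            # (a,a) vs het
      if (a2 == a1) pa(a1)^2 * pa(b2)
      else if (b2 == a1) pa(a1)^2 * pa(a2)
      else 0
    } else if (a2 == b2) {                            # het vs (a,a)
      if (a1 == a2) pa(a2)^2 * pa(b1)
      else if (b1 == a2) pa(a2)^2 * pa(a1)
      else 0
    } else {                                          # het vs het
      sh <- intersect(c(a1, b1), c(a2, b2))
      if (length(sh) == 2) pa(a1) * pa(b1) * (pa(a1) + pa(b1))
      else if (length(sh) == 1) {
        o1 <- setdiff(c(a1, b1), sh); o2 <- setdiff(c(a2, b2), sh)
        pa(sh) * pa(o1) * pa(o2)
      } else 0
    }
    rows[[length(rows) + 1L]] <- c(s0, s1, s2)
  }
  do.call(rbind, rows) %||% matrix(numeric(0), 0, 3)
}

# maximize obj(k0, k2) over the simplex k0,k2>=0, k0+k2<=1
grid_search_simplex <- function(obj, step, centre = NULL, window = NULL) {
  if (is.null(centre)) {
    k0s <- seq(0, 1, by = step)
  } else {
    k0s <- seq(max(0, centre[1] - window), min(1, centre[1] + window), by = step)
  }
  best <- c(NA, NA); bestv <- -Inf
  for (k0 in k0s) {
    if (is.null(centre)) {
      k2s <- seq(0, 1 - k0, by = step)
    } else {
      lo2 <- max(0, centre[2] - window)
      hi2 <- min(1 - k0, centre[2] + window)
      if (hi2 < lo2) next
      k2s <- seq(lo2, hi2, by = step)
    }
    for (k2 in k2s) {
      v <- obj(k0, k2)
      if (v > bestv) { bestv <- v; best <- c(k0, k2) }
    }
  }
  best
}

#' All-pairs relatedness within a population
#'
#' @param ds A [wh_dataset()].
#' @param population Population label (`NULL` uses everyone).
#' @param leave_pair_out Recompute allele frequencies excluding the focal
#'   pair (default, reduces small-sample bias); otherwise full-sample
#'   frequencies.
#' @param min_loci Passed to [ml_relatedness()].
#' @return List with `pairs` (data frame `id1, id2, k0, k1, k2, r`) and
#'   `summary` (mean, sd, range of r).
#' @export
relatedness_matrix <- function(ds, population = NULL, leave_pair_out = TRUE,
                               min_loci = 5) {
  stopifnot(inherits(ds, "wh_dataset"))
  ids <- if (is.null(population)) ds$ids
         else ds$ids[ds$meta$population == population]
  sub <- subset_dataset(ds, individuals = ids)
  full <- allele_freqs(sub, by = NULL)$all
  rows <- list()
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    fr <- if (leave_pair_out && n > 4)
      allele_freqs(sub, by = NULL, exclude = ids[c(i, j)])$all else full
    # leave-pair-out can zero an allele private to the pair; fall back then
    est <- tryCatch(
      ml_relatedness(genotype_of(sub, ids[i]), genotype_of(sub, ids[j]), fr,
                     min_loci = min_loci),
      error = function(e) ml_relatedness(genotype_of(sub, ids[i]),
                                         genotype_of(sub, ids[j]), full,
                                         min_loci = min_loci))
    rows[[length(rows) + 1L]] <-
      data.frame(id1 = ids[i], id2 = ids[j], k0 = est$k0, k1 = est$k1,
                 k2 = est$k2, r = est$r, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       summary = c(mean = mean(pairs$r), sd = stats::sd(pairs$r),
                   min = min(pairs$r), max = max(pairs$r)))
}

#' Pairwise geographic distances
#'
#' Euclidean distances on projected coordinates; individuals sampled several
#' times contribute the mean over all cross-pairs of their sampling
#' locations. Individuals without coordinates are excluded (and listed).
#'
#' @param coords Data frame `id, x, y`, one row per sampling.
#' @param ids Individuals to include (default: all present in `coords`).
#' @return List with `pairs` (data frame `id1, id2, distance`) and
#'   `excluded` (IDs without coordinates).
#' @export
pair_distances <- function(coords, ids = NULL) {
  stopifnot(all(c("id", "x", "y") %in% names(coords)))
  ids <- ids %||% unique(coords$id)
  coords <- coords[!is.na(coords$x) & !is.na(coords$y), ]
  have <- ids %in% coords$id
  excluded <- ids[!have]
  ids <- ids[have]
  locs <- split(coords[c("x", "y")], factor(coords$id, levels = ids))
  n <- length(ids)
  rows <- list()
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    li <- locs[[i]]; lj <- locs[[j]]
    dsum <- 0
    for (u in seq_len(nrow(li))) for (v in seq_len(nrow(lj)))
      dsum <- dsum + sqrt((li$x[u] - lj$x[v])^2 + (li$y[u] - lj$y[v])^2)
    rows[[length(rows) + 1L]] <-
      data.frame(id1 = ids[i], id2 = ids[j],
                 distance = dsum / (nrow(li) * nrow(lj)),
                 stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, rows), excluded = excluded)
}

#' Linear model of pairwise distance on relatedness and sex
#'
#' Ordinary least squares of geographic distance on relatedness within each
#' sex stratum (FF, MM) and pooled with the pair sex class as a covariate,
#' with the F-test for the relatedness coefficient. An optional Mantel-style
#' permutation p-value permutes individual identities (rows/columns of the
#' relatedness matrix jointly) to respect the non-independence of pairs.
#'
#' @param pairs Data frame with columns `id1, id2, distance, r`.
#' @param sex Named character vector mapping individual ID to `"F"`/`"M"`.
#' @param n_perm Mantel permutations (0 disables; 999 typical).
#' @param seed Integer seed for the permutations.
#' @return Data frame with one row per stratum (`FF`, `MM`, `pooled`):
#'   `slope`, `F`, `df`, `p`, `r2`, and `p_mantel` when requested.
#' @export
distance_model <- function(pairs, sex, n_perm = 0, seed = 1) {
  stopifnot(all(c("id1", "id2", "distance", "r") %in% names(pairs)))
  s1 <- sex[pairs$id1]; s2 <- sex[pairs$id2]
  pairs$sex_class <- ifelse(s1 == s2, paste0(s1, s2), "FM")
  fit_stats <- function(df, formula) {
    if (length(unique(df$r)) < 2L) stop("relatedness constant in stratum")
    fit <- stats::lm(formula, data = df)
    an <- stats::anova(fit)
    i <- match("r", rownames(an))
    data.frame(slope = stats::coef(fit)[["r"]], F = an$`F value`[i],
               df = an$Df[i], p = an$`Pr(>F)`[i],
               r2 = summary(fit)$r.squared)
  }
  strata <- list(FF = pairs[pairs$sex_class == "FF", ],
                 MM = pairs[pairs$sex_class == "MM", ],
                 pooled = pairs)
  rows <- list()
  for (nm in names(strata)) {
    df <- strata[[nm]]
    if (nrow(df) < 10) next
    form <- if (nm == "pooled" && length(unique(df$sex_class)) > 1)
      distance ~ r + sex_class else distance ~ r
    st <- fit_stats(df, form)
    st$stratum <- nm
    if (n_perm > 0) {
      set.seed(seed)
      ids <- unique(c(df$id1, df$id2))
      robs <- st$F
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        relab <- stats::setNames(sample(ids), ids)
        dfp <- df
        dfp$id1 <- relab[df$id1]; dfp$id2 <- relab[df$id2]
        key <- function(x, y) paste(pmin(x, y), pmax(x, y))
        dfp$r <- df$r[match(key(dfp$id1, dfp$id2), key(df$id1, df$id2))]
        stp <- tryCatch(fit_stats(dfp, form), error = function(e) NULL)
        if (!is.null(stp) && stp$F >= robs) exceed <- exceed + 1L
      }
      st$p_mantel <- (exceed + 1) / (n_perm + 1)
    }
    rows[[nm]] <- st
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("stratum", setdiff(names(out), "stratum"))]
}
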