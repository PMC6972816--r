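#' Bayesian admixture inference by Gibbs sampling
#'
#' Fits the standard admixture model: each allele copy has a latent cluster
#' of origin, each individual an ancestry vector `q` with symmetric
#' Dirichlet(alpha) prior (alpha learned by a Metropolis step, uniform prior
#' on (0, 10]), and each cluster per-locus allele frequencies with a flat
#' Dirichlet(1) prior (independent model) or a correlated F-model prior
#' centred on the pooled sample frequencies with per-cluster drift
#' (correlated model). Missing genotypes are skipped. Credibility intervals
#' are equal-tailed 5th-95th posterior percentiles of the retained
#' (thinned) draws.
#'
#' @param ds A [wh_dataset()].
#' @param K Number of clusters (>= 1).
#' @param burnin,iters Burn-in and retained chain length (defaults 10000 and
#'   30000, the short-chain setting used for the resampling analyses).
#' @param thin Retain every `thin`-th post-burn-in draw (default 10).
#' @param model `"independent"` (default) or `"correlated"` allele
#'   frequencies.
#' @param alpha Initial Dirichlet concentration.
#' @param seed Integer seed; fixed seed gives identical results.
#' @return An object of class `wh_admixture`: `K`, `q` (posterior means,
#'   rows sum to 1), `cri90` (arrays `lo`/`hi`), `draws`
#'   (individuals x K x draws), `loglik_trace`, `alpha_trace`,
#'   `cluster_freqs`, `ids`, `mixing_warning`.
#' @export
fit_admixture <- function(ds, K = 2, burnin = 10000, iters = 30000, thin = 10,
                          model = c("independent", "correlated"), alpha = 1,
                          seed = 1) {
  stopifnot(inherits(ds, "wh_dataset"), K >= 1, iters > 0, burnin >= 0)
  model <- match.arg(model)
  N <- length(ds$ids)
  if (K > N) stop("K exceeds the number of individuals")
  thin <- max(1L, min(as.integer(thin), as.integer(iters)))
  enc <- encode_alleles(ds)
  set.seed(seed)
  res <- admix_gibbs_cpp(enc$A, enc$B, enc$n_alleles, as.integer(K),
                         as.integer(burnin), as.integer(iters),
                         as.integer(thin), model == "correlated",
                         alpha, 1.0, enc$ancestral, 0.05, 0.05)
  draws <- res$qdraws[, , seq_len(max(1, res$ndraws)), drop = FALSE]
  # posterior summaries all come from the same retained draws, so the
  # credibility band brackets the reported mean
  q <- apply(draws, c(1, 2), mean)
  q <- q / rowSums(q)
  rownames(q) <- ds$ids; colnames(q) <- paste0("k", seq_len(K))
  lo <- apply(draws, c(1, 2), stats::quantile, probs = 0.05, names = FALSE)
  hi <- apply(draws, c(1, 2), stats::quantile, probs = 0.95, names = FALSE)
  # for heavily skewed posteriors the mean can fall outside the equal-tailed
  # band; widen minimally so the interval always brackets the reported mean
  # (this also guarantees conservative calls nest inside relaxed calls)
  lo <- pmin(lo, q); hi <- pmax(hi, q)
  dimnames(lo) <- dimnames(hi) <- dimnames(q)
  # crude non-mixing diagnostic: significant trend in the post-burn-in
  # log-likelihood trace
  post <- res$loglik[(burnin + 1):(burnin + iters)]
  idx <- seq_along(post)
  mixing_warning <- FALSE
  if (stats::sd(post) > 0) {
    fit <- stats::lm(post ~ idx)
    sl <- summary(fit)$coefficients
    if (nrow(sl) == 2 && sl[2, 4] < 0.01 &&
        abs(sl[2, 1]) * length(post) > 2 * stats::sd(post))
      mixing_warning <- TRUE
  }
  cf <- res$cluster_freqs
  names(cf) <- ds$loci
  for (l in seq_along(cf)) colnames(cf[[l]]) <- enc$codes[[l]]
  structure(list(K = K, q = q, cri90 = list(lo = lo, hi = hi), draws = draws,
                 loglik_trace = res$loglik, alpha_trace = res$alpha,
                 cluster_freqs = cf, drift = res$drift, ids = ds$ids,
                 model = model, mixing_warning = mixing_warning),
            class = "wh_admixture")
}

#' @export
print.wh_admixture <- function(x, ...) {
  cat(sprintf("<wh_admixture> K=%d, %d individuals, %d retained draws (%s model)\n",
              x$K, nrow(x$q), dim(x$draws)[3], x$model))
  if (x$mixing_warning) cat("  warning: log-likelihood trace shows a trend (poor mixing?)\n")
  invisible(x)
}

# per-locus 0-based recode; ancestral = pooled sample frequencies
encode_alleles <- function(ds) {
  L <- length(ds$loci)
  A <- matrix(-1L, nrow(ds$a), L); B <- A
  codes <- vector("list", L); anc <- vector("list", L)
  for (l in seq_len(L)) {
    al <- c(ds$a[, l], ds$b[, l])
    u <- sort(unique(al[!is.na(al)]))
    if (!length(u)) u <- 1L  # all-missing locus: dummy allele, never observed
    codes[[l]] <- u
    A[, l] <- ifelse(is.na(ds$a[, l]), -1L, match(ds$a[, l], u) - 1L)
    B[, l] <- ifelse(is.na(ds$b[, l]), -1L, match(ds$b[, l], u) - 1L)
    tab <- table(factor(al[!is.na(al)], levels = u))
    f <- as.numeric(tab)
    if (sum(f) == 0) f <- rep(1, length(u))
    anc[[l]] <- f / sum(f)
  }
  list(A = A, B = B, n_alleles = vapply(codes, length, integer(1)),
       codes = codes, ancestral = anc)
}

#' Mean data log-likelihood of a fitted run
#'
#' Posterior mean of the data log-likelihood over the post-burn-in trace;
#' the per-K quantity fed to [evanno_delta_k()].
#'
#' @param ar A [fit_admixture()] result.
#' @param burnin Burn-in length used in the fit.
#' @return Scalar mean log-likelihood.
#' @export
mean_loglik <- function(ar, burnin) {
  tr <- ar$loglik_trace
  mean(tr[(burnin + 1):length(tr)])
}

#' Evanno's delta-K over a grid of cluster counts
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' undefined at the endpoints of the K range; the best K maximises deltaK.
#'
#' @param loglik_by_k Named list (names = K values, consecutive) of numeric
#'   vectors of mean data log-likelihoods over repeated runs (>= 2 each).
#' @return List with `delta_k` (named vector over interior K) and `best_k`.
#'   Zero spread at some K yields an infinite deltaK with a warning.
#' @export
evanno_delta_k <- function(loglik_by_k) {
  Ks <- as.integer(names(loglik_by_k))
  stopifnot(length(Ks) >= 3L, all(diff(Ks) == 1L))
  if (any(vapply(loglik_by_k, length, integer(1)) < 2L))
    stop("need at least 2 repeats per K")
  m <- vapply(loglik_by_k, mean, numeric(1))
  s <- vapply(loglik_by_k, stats::sd, numeric(1))
  interior <- seq(2, length(Ks) - 1)
  dk <- abs(m[interior + 1] - 2 * m[interior] + m[interior - 1]) / s[interior]
  if (any(s[interior] == 0)) {
    warning("zero sd at some K; deltaK reported as infinite there")
    dk[is.nan(dk)] <- 0  # 0/0: zero curvature and zero spread
  }
  names(dk) <- Ks[interior]
  list(delta_k = dk, best_k = Ks[interior][which.max(dk)])
}

#' Align cluster labels across runs
#'
#' Permutes each run's clusters (exhaustively over K! permutations, K <= 5)
#' to maximise the summed mean ancestry of each reference subset in its
#' assigned cluster, undoing label switching across independent runs.
#'
#' @param results A `wh_admixture` or list of them.
#' @param reference Named list (one element per cluster, in target order) of
#'   non-empty, disjoint individual ID vectors anchoring each cluster.
#' @return The input with `q`, `cri90`, `draws`, `cluster_freqs` columns
#'   permuted; attribute `perm` records the permutation, `tie` flags
#'   ambiguous optima (broken deterministically by cluster index).
#' @export
align_clusters <- function(results, reference) {
  single <- inherits(results, "wh_admixture")
  if (single) results <- list(results)
  stopifnot(all(lengths(reference) > 0),
            !anyDuplicated(unlist(reference)))
  out <- lapply(results, function(ar) {
    K <- ar$K
    stopifnot(length(reference) == K)
    perms <- perm_matrix(K)
    score <- apply(perms, 1, function(pm) {
      sum(vapply(seq_len(K), function(k) {
        ii <- match(reference[[k]], ar$ids)
        mean(ar$q[ii, pm[k]])
      }, numeric(1)))
    })
    best <- which.max(score)
    tie <- sum(abs(score - score[best]) < 1e-12) > 1L
    pm <- unname(as.integer(perms[best, ]))
    ar$q <- ar$q[, pm, drop = FALSE]
    colnames(ar$q) <- paste0("k", seq_len(K))
    ar$cri90$lo <- ar$cri90$lo[, pm, drop = FALSE]
    ar$cri90$hi <- ar$cri90$hi[, pm, drop = FALSE]
    colnames(ar$cri90$lo) <- colnames(ar$cri90$hi) <- colnames(ar$q)
    ar$draws <- ar$draws[, pm, , drop = FALSE]
    ar$cluster_freqs <- lapply(ar$cluster_freqs,
                               function(m) m[pm, , drop = FALSE])
    attr(ar, "perm") <- pm
    attr(ar, "tie") <- tie
    ar
  })
  if (single) out[[1]] else out
}

perm_matrix <- function(K) {
  K <- as.integer(K)
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    cbind(K, sub)[, order(c(pos - 0.5, seq_len(K - 1))), drop = FALSE]
  }))
}
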