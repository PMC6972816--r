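#' Weir & Cockerham (1984) variance components and F-statistics
#'
#' Multilocus estimators of theta (F_ST), f (F_IS) and F (F_IT) from the
#' per-allele variance components a (among populations), b (among
#' individuals within populations) and c (within individuals), summed over
#' alleles and loci. Per-locus sample sizes count called genotypes only.
#'
#' @param ds A [wh_dataset()] with `meta$population` (or `by` column).
#' @param populations Subset of population labels to use (default all).
#' @param by Population column.
#' @return List with `theta`, `f`, `F`, the summed `components`
#'   (`a`, `b`, `c`), per-population F_IS (`fis_by_pop`), and the pairwise
#'   `FstMatrix` (`theta_pair`, symmetric, `NA` diagonal).
#' @export
wc_fstats <- function(ds, populations = NULL, by = "population") {
  stopifnot(inherits(ds, "wh_dataset"))
  pops <- as.character(ds$meta[[by]])
  populations <- populations %||% unique(pops)
  if (length(populations) < 2L)
    stop("need at least 2 populations for theta")
  sel <- pops %in% populations
  comp <- wc_components(ds$a[sel, , drop = FALSE], ds$b[sel, , drop = FALSE],
                        pops[sel])
  if (comp["a"] + comp["b"] + comp["c"] == 0)
    stop("theta undefined: all loci monomorphic over the selected populations")
  fis <- vapply(populations, function(p) {
    s <- pops == p
    wc_fis_pop(ds$a[s, , drop = FALSE], ds$b[s, , drop = FALSE])
  }, numeric(1))
  np <- length(populations)
  tp <- matrix(NA_real_, np, np, dimnames = list(populations, populations))
  if (np > 1) for (i in seq_len(np - 1)) for (j in seq(i + 1, np)) {
    s <- pops %in% populations[c(i, j)]
    cij <- wc_components(ds$a[s, , drop = FALSE], ds$b[s, , drop = FALSE],
                         pops[s])
    tp[i, j] <- tp[j, i] <- cij["a"] / (cij["a"] + cij["b"] + cij["c"])
  }
  list(theta = comp[["a"]] / sum(comp),
       f = 1 - comp[["c"]] / (comp[["b"]] + comp[["c"]]),
       F = 1 - comp[["c"]] / sum(comp),
       components = comp,
       fis_by_pop = fis,
       theta_pair = tp)
}

# Summed W&C (1984) components over loci and alleles.
# a,b: allele matrices (individuals x loci); pop: labels per individual.
wc_components <- function(A, B, pop) {
  pop <- as.character(pop)
  pops <- unique(pop)
  r <- length(pops)
  tot <- c(a = 0, b = 0, c = 0)
  for (l in seq_len(ncol(A))) {
    al <- A[, l]; bl <- B[, l]
    called <- !is.na(al)
    ni <- vapply(pops, function(p) sum(called & pop == p), numeric(1))
    if (sum(ni >= 1) < 2) next
    use <- ni >= 1
    pu <- pops[use]; ni <- ni[use]; ru <- length(pu)
    nbar <- mean(ni)
    nc <- (ru * nbar - sum(ni^2) / (ru * nbar)) / (ru - 1)
    alleles <- sort(unique(c(al[called], bl[called])))
    if (length(alleles) < 2) next
    for (alle in alleles) {
      pi <- vapply(pu, function(p) {
        s <- called & pop == p
        (sum(al[s] == alle) + sum(bl[s] == alle)) / (2 * sum(s))
      }, numeric(1))
      hi <- vapply(pu, function(p) {
        s <- called & pop == p
        sum((al[s] == alle) != (bl[s] == alle)) / sum(s)  # heterozygous for this allele
      }, numeric(1))
      pbar <- sum(ni * pi) / (ru * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((ru - 1) * nbar)
      hbar <- sum(ni * hi) / (ru * nbar)
      a_c <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (ru - 1) / ru * s2 - hbar / 4) / (nbar - 1))
      b_c <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (ru - 1) / ru * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_c <- hbar / 2
      tot <- tot + c(a = a_c, b = b_c, c = c_c)
    }
  }
  tot
}

# Single-population W&C f (F_IS): components b and c with the
# among-population terms absent.
wc_fis_pop <- function(A, B) {
  bt <- 0; ct <- 0
  for (l in seq_len(ncol(A))) {
    al <- A[, l]; bl <- B[, l]
    called <- !is.na(al)
    n <- sum(called)
    if (n < 2) next
    alleles <- sort(unique(c(al[called], bl[called])))
    if (length(alleles) < 2) next
    for (alle in alleles) {
      p <- (sum(al[called] == alle) + sum(bl[called] == alle)) / (2 * n)
      h <- sum((al[called] == alle) != (bl[called] == alle)) / n
      bt <- bt + n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      ct <- ct + h / 2
    }
  }
  if (bt + ct == 0) return(NA_real_)
  1 - ct / (bt + ct)
}

# per-locus f for a single locus given allele vectors (used by hwe_test)
wc_f_single <- function(a, b) {
  wc_fis_pop(matrix(a, ncol = 1), matrix(b, ncol = 1))
}

#' Permutation test of pairwise F_ST
#'
#' Shuffles individuals between the two populations and recomputes theta;
#' one-sided p-value (differentiation larger than observed) with the
#' plus-one estimator.
#'
#' @param ds A [wh_dataset()].
#' @param pair Character vector of two population labels.
#' @param n_perm Permutations (default 1000, as in the field workflow).
#' @param seed Integer seed.
#' @return List `theta`, `p`.
#' @export
fst_perm_test <- function(ds, pair, n_perm = 1000, seed = 1) {
  stopifnot(length(pair) == 2L)
  pops <- as.character(ds$meta$population)
  sel <- which(pops %in% pair)
  A <- ds$a[sel, , drop = FALSE]; B <- ds$b[sel, , drop = FALSE]
  labs <- pops[sel]
  comp <- wc_components(A, B, labs)
  tobs <- comp[["a"]] / sum(comp)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    pl <- sample(labs)
    cp <- wc_components(A, B, pl)
    if (cp[["a"]] / sum(cp) >= tobs) exceed <- exceed + 1L
  }
  list(theta = tobs, p = (exceed + 1) / (n_perm + 1))
}

#' Principal component analysis of genotypes
#'
#' Individuals x allele-indicator matrix (per-allele counts halved to
#' frequencies 0/0.5/1), missing entries imputed by the column mean, columns
#' centred; eigen-decomposition of the covariance matrix. Axis signs follow
#' a deterministic convention: the largest-|loading| coordinate of each axis
#' is made positive.
#'
#' @param ds A [wh_dataset()].
#' @param n_axes Number of leading axes to return.
#' @return List with `scores` (individuals x axes), `explained`
#'   (per-axis variance fractions), `eigenvalues`, `dropped` (all-missing
#'   allele columns removed).
#' @export
pca_genotypes <- function(ds, n_axes = 4) {
  stopifnot(inherits(ds, "wh_dataset"), length(ds$ids) >= 2L)
  X <- allele_dosage(ds)
  allna <- colSums(!is.na(X)) == 0L
  if (any(allna)) {
    warning(sum(allna), " all-missing allele columns dropped")
    X <- X[, !allna, drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    m <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- m
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  ev <- sv$d^2 / max(1, (nrow(X) - 1))
  k <- min(n_axes, ncol(sv$u))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- ds$ids
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, explained = ev / sum(ev), eigenvalues = ev,
       dropped = sum(allna))
}

# individuals x alleles dosage matrix (counts / 2), NA when locus missing
allele_dosage <- function(ds) {
  cols <- list()
  for (l in seq_along(ds$loci)) {
    al <- c(ds$a[, l], ds$b[, l])
    alleles <- sort(unique(al[!is.na(al)]))
    for (alle in alleles) {
      v <- (as.numeric(ds$a[, l] == alle) + as.numeric(ds$b[, l] == alle)) / 2
      cols[[paste0(ds$loci[l], ".", alle)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ds$ids
  X
}
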