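# Independent oracles and fixture builders shared across the suite.

# Small dataset built by hand from explicit allele matrices.
make_dataset <- function(a, b, population = NULL, ...) {
  a <- as.matrix(a); b <- as.matrix(b)
  default_ids <- if (nrow(a)) paste0("ind", seq_len(nrow(a))) else character(0)
  meta <- data.frame(id = rownames(a) %||% default_ids,
                     stringsAsFactors = FALSE)
  if (!is.null(population)) meta$population <- population
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  if (nrow(a)) rownames(a) <- meta$id
  wh_dataset(a, b, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force Weir & Cockerham (1984) estimators, written independently of
# the package implementation: explicit loops, no shared code.
oracle_wc <- function(a_mat, b_mat, pop) {
  pops <- unique(pop)
  r <- length(pops)
  A_sum <- 0; B_sum <- 0; C_sum <- 0
  for (l in seq_len(ncol(a_mat))) {
    av <- a_mat[, l]; bv <- b_mat[, l]
    keep <- !is.na(av)
    n_i <- sapply(pops, function(p) sum(keep & pop == p))
    if (sum(n_i >= 1) < 2) next
    sel <- n_i >= 1
    pops_l <- pops[sel]; n_i <- n_i[sel]; r_l <- length(pops_l)
    n_bar <- sum(n_i) / r_l
    n_c <- (r_l * n_bar - sum(n_i^2) / (r_l * n_bar)) / (r_l - 1)
    alleles <- sort(unique(c(av[keep], bv[keep])))
    if (length(alleles) < 2) next
    for (al in alleles) {
      p_i <- numeric(r_l); h_i <- numeric(r_l)
      for (k in seq_len(r_l)) {
        rows <- which(keep & pop == pops_l[k])
        cnt <- 0; het <- 0
        for (i in rows) {
          cnt <- cnt + (av[i] == al) + (bv[i] == al)
          if ((av[i] == al) + (bv[i] == al) == 1) het <- het + 1
        }
        p_i[k] <- cnt / (2 * length(rows))
        h_i[k] <- het / length(rows)
      }
      p_bar <- sum(n_i * p_i) / (r_l * n_bar)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r_l - 1) * n_bar)
      h_bar <- sum(n_i * h_i) / (r_l * n_bar)
      a_comp <- (n_bar / n_c) *
        (s2 - (1 / (n_bar - 1)) *
           (p_bar * (1 - p_bar) - ((r_l - 1) / r_l) * s2 - h_bar / 4))
      b_comp <- (n_bar / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - ((r_l - 1) / r_l) * s2 -
           ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
      c_comp <- h_bar / 2
      A_sum <- A_sum + a_comp; B_sum <- B_sum + b_comp; C_sum <- C_sum + c_comp
    }
  }
  list(theta = A_sum / (A_sum + B_sum + C_sum),
       f = 1 - C_sum / (B_sum + C_sum))
}

# Brute-force ML relatedness: full grid over the simplex at step 0.01,
# with its own genotype-pair probability code derived by direct enumeration:
# under one shared IBD allele, g2 = {IBD copy of a uniformly chosen g1
# allele} + {one fresh draw from the pool}.
oracle_relatedness <- function(g1, g2, freqs) {
  locus_s <- lapply(seq_along(freqs), function(l) {
    x1 <- g1$a[[l]]; y1 <- g1$b[[l]]; x2 <- g2$a[[l]]; y2 <- g2$b[[l]]
    if (is.na(x1) || is.na(x2)) return(NULL)
    p <- freqs[[l]]
    f <- function(z) unname(p[as.character(z)])
    gp <- function(x, y) if (x == y) f(x)^2 else 2 * f(x) * f(y)
    s0 <- gp(x1, y1) * gp(x2, y2)
    s2 <- if (x1 == x2 && y1 == y2) gp(x1, y1) else 0
    p2_given_ib <- function(ib) {
      if (x2 == y2) { if (ib == x2) f(x2) else 0 }
      else if (ib == x2) f(y2)
      else if (ib == y2) f(x2)
      else 0
    }
    s1 <- gp(x1, y1) * (0.5 * p2_given_ib(x1) + 0.5 * p2_given_ib(y1))
    c(s0, s1, s2)
  })
  S <- do.call(rbind, locus_s)
  ll_of <- function(k0, k2)
    sum(log(pmax(k0 * S[, 1] + (1 - k0 - k2) * S[, 2] + k2 * S[, 3], 1e-300)))
  best <- c(-Inf, NA, NA)
  for (k0 in seq(0, 1, by = 0.01)) for (k2 in seq(0, 1 - k0, by = 0.01)) {
    v <- ll_of(k0, k2)
    if (v > best[1]) best <- c(v, k0, k2)
  }
  k0 <- best[2]; k2 <- best[3]
  list(k0 = k0, k1 = 1 - k0 - k2, k2 = k2, r = k2 + (1 - k0 - k2) / 2,
       loglik = best[1])
}
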