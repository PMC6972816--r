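#' Hybrid genotype-frequency classes
#'
#' Each class is a mixture over ordered pairs of allele origins (pool A or
#' pool B) per locus: pure A = (AA:1), pure B = (BB:1), F1 = (AB:1),
#' F2 = (AA:1/4, AB:1/2, BB:1/4), BC_A = (AA:1/2, AB:1/2),
#' BC_B = (BB:1/2, AB:1/2).
#' @keywords internal
class_kernels <- function() {
  list(pureA = c(AA = 1, AB = 0, BB = 0),
       pureB = c(AA = 0, AB = 0, BB = 1),
       F1    = c(AA = 0, AB = 1, BB = 0),
       F2    = c(AA = 0.25, AB = 0.5, BB = 0.25),
       BC_A  = c(AA = 0.5, AB = 0.5, BB = 0),
       BC_B  = c(AA = 0, AB = 0.5, BB = 0.5))
}

# genotype probability under an origin pair: for genotype (i,j),
# P = pX_i pY_j + pX_j pY_i when i != j, pX_i pY_i when i = j.
pair_genotype_prob <- function(pX, pY, i, j) {
  if (i == j) pX[i] * pY[i] else pX[i] * pY[j] + pX[j] * pY[i]
}

#' EM classifier over hybrid genotype-frequency classes
#'
#' Deterministic EM over the class set: the E-step computes per-individual
#' class responsibilities from the product over loci of the class's
#' origin-pair mixture of genotype probabilities; the M-step updates the
#' class proportions and, in `"joint"` mode, the two pools' allele
#' frequencies from the expected allele-origin counts. In
#' `"fixed-from-references"` mode the frequencies are estimated once from
#' declared pure reference individuals and held fixed.
#'
#' @param ds A [wh_dataset()].
#' @param classes Subset of `c("pureA","pureB","F1","F2","BC_A","BC_B")`;
#'   must include both pure classes.
#' @param freq_mode `"joint"` or `"fixed-from-references"`.
#' @param ref_a,ref_b Individual IDs of pure references for pools A and B
#'   (required in fixed mode; used for initialisation in joint mode when
#'   given).
#' @param max_iter,tol Convergence controls: stop when the largest change in
#'   any responsibility falls below `tol`.
#' @param seed Integer seed (random initialisation when no references).
#' @return An object of class `wh_hybridclasses`: `posterior`
#'   (individuals x classes, rows sum to 1), `class_prop`, `freqs`
#'   (pool A and B), `loglik` (per-iteration trace, non-decreasing),
#'   `converged`, `modal_class`.
#' @export
em_hybrid_classes <- function(ds, classes = c("pureA", "pureB", "F1", "F2",
                                              "BC_A", "BC_B"),
                              freq_mode = c("joint", "fixed-from-references"),
                              ref_a = NULL, ref_b = NULL,
                              max_iter = 200, tol = 1e-6, seed = 1) {
  stopifnot(inherits(ds, "wh_dataset"))
  freq_mode <- match.arg(freq_mode)
  kernels <- class_kernels()
  if (!all(classes %in% names(kernels))) stop("unknown class label")
  if (!all(c("pureA", "pureB") %in% classes))
    stop("the class set must include both pure classes")
  if (freq_mode == "fixed-from-references" &&
      (length(ref_a) == 0 || length(ref_b) == 0))
    stop("fixed mode needs non-empty pure reference sets for both pools")
  N <- length(ds$ids); L <- length(ds$loci); C <- length(classes)
  set.seed(seed)

  freq_from <- function(idx, l) {
    al <- c(ds$a[idx, l], ds$b[idx, l]); al <- al[!is.na(al)]
    u <- locus_codes[[l]]
    cnt <- table(factor(al, levels = u)) + 0.5  # light smoothing, no zero freq
    as.numeric(cnt) / sum(cnt)
  }
  locus_codes <- lapply(seq_len(L), function(l) {
    al <- c(ds$a[, l], ds$b[, l]); sort(unique(al[!is.na(al)]))
  })

  init_idx_a <- if (length(ref_a)) match(ref_a, ds$ids) else
    sample(N, max(2, ceiling(N / 4)))
  init_idx_b <- if (length(ref_b)) match(ref_b, ds$ids) else
    sample(setdiff(seq_len(N), init_idx_a), max(2, ceiling(N / 4)))
  pa <- lapply(seq_len(L), function(l) freq_from(init_idx_a, l))
  pb <- lapply(seq_len(L), function(l) freq_from(init_idx_b, l))

  # per-individual per-locus genotype index (into codes); NA = missing
  gi <- matrix(NA_integer_, N, L); gj <- gi
  for (l in seq_len(L)) {
    gi[, l] <- match(ds$a[, l], locus_codes[[l]])
    gj[, l] <- match(ds$b[, l], locus_codes[[l]])
  }

  pair_probs <- function() {
    # list over loci of N x 3 matrices: P(genotype | AA), (AB), (BB)
    lapply(seq_len(L), function(l) {
      out <- matrix(NA_real_, N, 3)
      pA <- pa[[l]]; pB <- pb[[l]]
      ii <- gi[, l]; jj <- gj[, l]
      ok <- !is.na(ii)
      same <- ok & ii == jj
      diff <- ok & ii != jj
      out[same, 1] <- pA[ii[same]]^2
      out[same, 2] <- pA[ii[same]] * pB[ii[same]]
      out[same, 3] <- pB[ii[same]]^2
      out[diff, 1] <- 2 * pA[ii[diff]] * pA[jj[diff]]
      out[diff, 2] <- pA[ii[diff]] * pB[jj[diff]] + pA[jj[diff]] * pB[ii[diff]]
      out[diff, 3] <- 2 * pB[ii[diff]] * pB[jj[diff]]
      out
    })
  }

  pi_c <- rep(1 / C, C)
  resp <- matrix(1 / C, N, C)
  loglik <- numeric(0)
  converged <- FALSE
  W <- do.call(rbind, kernels[classes])  # C x 3 mixture weights

  for (iter in seq_len(max_iter)) {
    pp <- pair_probs()
    # E-step: log-likelihood per individual per class
    ll_ic <- matrix(0, N, C)
    for (l in seq_len(L)) {
      m <- pp[[l]] %*% t(W)          # N x C: P(genotype_l | class)
      ok <- !is.na(m[, 1])
      ll_ic[ok, ] <- ll_ic[ok, ] + log(pmax(m[ok, , drop = FALSE], 1e-300))
    }
    lw <- sweep(ll_ic, 2, log(pi_c), "+")
    mx <- apply(lw, 1, max)
    wexp <- exp(lw - mx)
    denom <- rowSums(wexp)
    new_resp <- wexp / denom
    loglik <- c(loglik, sum(mx + log(denom)))
    delta <- max(abs(new_resp - resp))
    resp <- new_resp
    # M-step
    pi_c <- pmax(colMeans(resp), 1e-12); pi_c <- pi_c / sum(pi_c)
    if (freq_mode == "joint") {
      pp_cur <- pp
      for (l in seq_len(L)) {
        u <- locus_codes[[l]]
        cntA <- rep(1e-6, length(u)); cntB <- rep(1e-6, length(u))
        ii <- gi[, l]; jj <- gj[, l]
        ok <- which(!is.na(ii))
        pA <- pa[[l]]; pB <- pb[[l]]
        m_l <- pp_cur[[l]] %*% t(W)            # N x C: P(g_l | class)
        for (i in ok) {
          # expected pair-type counts: sum over classes of the class's
          # within-class pair posterior, weighted by its responsibility
          pr <- pp_cur[[l]][i, ]                    # P(g | AA), (AB), (BB)
          wclass <- resp[i, ] / pmax(m_l[i, ], 1e-300)
          post <- pr * as.vector(t(W) %*% wclass)
          if (sum(post) <= 0) next
          post <- post / sum(post)
          a1 <- ii[i]; a2 <- jj[i]
          # AA pair: both copies from pool A
          cntA[a1] <- cntA[a1] + post[1]; cntA[a2] <- cntA[a2] + post[1]
          # BB pair: both copies from pool B
          cntB[a1] <- cntB[a1] + post[3]; cntB[a2] <- cntB[a2] + post[3]
          # AB pair: attribute each copy by relative likelihood
          if (a1 == a2) {
            cntA[a1] <- cntA[a1] + post[2]; cntB[a1] <- cntB[a1] + post[2]
          } else {
            w12 <- pA[a1] * pB[a2]; w21 <- pA[a2] * pB[a1]
            s <- w12 + w21
            if (s > 0) {
              cntA[a1] <- cntA[a1] + post[2] * w12 / s
              cntB[a2] <- cntB[a2] + post[2] * w12 / s
              cntA[a2] <- cntA[a2] + post[2] * w21 / s
              cntB[a1] <- cntB[a1] + post[2] * w21 / s
            }
          }
        }
        pa[[l]] <- cntA / sum(cntA)
        pb[[l]] <- cntB / sum(cntB)
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within max_iter; returning current state")
  colnames(resp) <- classes
  rownames(resp) <- ds$ids
  structure(list(posterior = resp, class_prop = stats::setNames(pi_c, classes),
                 freqs = list(A = pa, B = pb), loglik = loglik,
                 converged = converged,
                 modal_class = classes[max.col(resp, ties.method = "first")],
                 ids = ds$ids),
            class = "wh_hybridclasses")
}

#' @export
print.wh_hybridclasses <- function(x, ...) {
  cat(sprintf("<wh_hybridclasses> %d individuals, classes: %s\n",
              nrow(x$posterior), paste(colnames(x$posterior), collapse = ", ")))
  print(table(x$modal_class))
  invisible(x)
}
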