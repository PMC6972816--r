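#' Replicated genotypes for one noninvasive sample
#'
#' Holds the 1-4 repeated genotypings of a single sample over a common locus
#' panel. Blood samples genotyped once are valid single-repeat sets.
#'
#' @param sample Sample ID.
#' @param a,b Integer matrices (repeats x loci) of allele pairs; `NA` marks
#'   missing, with `is.na(a) == is.na(b)`.
#' @param material Sample material (`"blood"`, `"hair"`, `"feces"`).
#' @return An object of class `wh_replicates`.
#' @export
replicate_set <- function(sample, a, b, material = "feces") {
  a <- as.matrix(a); b <- as.matrix(b)
  storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
  if (!identical(dim(a), dim(b)) ||
      !identical(unname(is.na(a)), unname(is.na(b))))
    stop("replicate allele matrices must match in shape and missingness")
  if (nrow(a) < 1L) stop("a replicate set needs at least one repeat")
  if (is.null(colnames(a))) colnames(a) <- paste0("L", seq_len(ncol(a)))
  colnames(b) <- colnames(a)
  swap <- !is.na(a) & a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  structure(list(sample = sample, a = a, b = b, loci = colnames(a),
                 n_repeats = nrow(a), material = material),
            class = "wh_replicates")
}

#' Build the consensus genotype of a replicate set
#'
#' Per-locus rules: a heterozygote seen in the repeats becomes the consensus
#' if it meets the confirmation rule (`min_het_obs`); apparent homozygotes
#' among the other repeats are explained by allelic dropout when their allele
#' is contained in that heterozygote. If only homozygotes are observed and
#' they agree, the consensus is that homozygote. Three or more distinct
#' alleles across repeats -- or two disagreeing homozygotes, which no single
#' observed genotype explains -- leave the locus missing with a conflict
#' flag.
#'
#' @param rs A [replicate_set()].
#' @param min_het_obs Repeats in which a heterozygote must be seen before it
#'   is accepted: by default 1 when at most 2 repeats amplified at the locus
#'   and 2 when 3 or more did (multi-tube safeguard; amplification failures
#'   do not count against confirmation).
#' @return List with integer vectors `a`, `b` (the consensus, named by
#'   locus) and logical `conflict` per locus.
#' @export
build_consensus <- function(rs, min_het_obs = NULL) {
  stopifnot(inherits(rs, "wh_replicates"))
  L <- length(rs$loci)
  ca <- rep(NA_integer_, L); cb <- rep(NA_integer_, L)
  conflict <- rep(FALSE, L)
  for (l in seq_len(L)) {
    a <- rs$a[, l]; b <- rs$b[, l]
    called <- !is.na(a)
    if (!any(called)) next
    a <- a[called]; b <- b[called]
    need <- min_het_obs %||% (if (sum(called) <= 2L) 1L else 2L)
    alleles <- unique(c(a, b))
    if (length(alleles) >= 3L) { conflict[l] <- TRUE; next }
    het <- a != b
    if (any(het)) {
      if (sum(het) >= need) {           # confirmed heterozygote
        ca[l] <- a[het][1]; cb[l] <- b[het][1]
      } else {                          # unconfirmed: fall back on homozygotes
        ha <- a[!het]
        if (length(ha) && length(unique(ha)) == 1L &&
            ha[1] %in% c(a[het][1], b[het][1])) {
          ca[l] <- ha[1]; cb[l] <- ha[1]
        } else conflict[l] <- TRUE
      }
    } else {
      if (length(unique(a)) == 1L) { ca[l] <- a[1]; cb[l] <- a[1] }
      else conflict[l] <- TRUE          # disagreeing homozygotes
    }
  }
  list(a = stats::setNames(ca, rs$loci), b = stats::setNames(cb, rs$loci),
       conflict = stats::setNames(conflict, rs$loci))
}

#' Quality index of a replicate set against its consensus
#'
#' Each repeat at each locus contributes 1 when it reproduces the consensus
#' genotype, 0.5 when it is a homozygote while the consensus is heterozygote
#' (the allelic-dropout signature), and 0 when it is missing; any other
#' disagreement also scores 0. Per-locus QI is the mean over repeats and the
#' per-sample QI the mean over loci. Single-repeat (blood) samples score 1
#' by construction and are flagged as such.
#'
#' @param rs A [replicate_set()].
#' @param consensus Output of [build_consensus()]; computed if missing.
#' @return List with `per_repeat` (repeats x loci score matrix), `per_locus`,
#'   `sample_qi`, and `single_repeat` flag.
#' @export
quality_index <- function(rs, consensus = NULL) {
  stopifnot(inherits(rs, "wh_replicates"))
  cons <- consensus %||% build_consensus(rs)
  L <- length(rs$loci)
  sc <- matrix(0, rs$n_repeats, L, dimnames = list(NULL, rs$loci))
  for (l in seq_len(L)) {
    ca <- cons$a[[l]]; cb <- cons$b[[l]]
    for (r in seq_len(rs$n_repeats)) {
      a <- rs$a[r, l]; b <- rs$b[r, l]
      sc[r, l] <-
        if (is.na(a)) {
          0                                   # missing repeat
        } else if (is.na(ca)) {
          0                                   # no consensus to agree with
        } else if (a == ca && b == cb) {
          1                                   # consensus reproduced
        } else if (a == b && ca != cb) {
          0.5                                 # false homozygote vs het consensus
        } else 0
    }
  }
  list(per_repeat = sc, per_locus = colMeans(sc), sample_qi = mean(colMeans(sc)),
       single_repeat = rs$n_repeats == 1L)
}

#' Apply the sample-retention filters
#'
#' Drops samples whose first genotyping amplified fewer than
#' `min_first_pass_loci` loci, then samples whose quality index is not
#' strictly above `min_qi` (QI = 0.6 exactly is discarded). Single-repeat
#' blood samples carry QI 1 by convention and pass the QI filter.
#'
#' @param qi_table Data frame with columns `sample`, `qi`,
#'   `first_pass_loci` (loci amplified at the first genotyping).
#' @param min_qi Strict lower bound on QI (default 0.6).
#' @param min_first_pass_loci Minimum loci amplified at first pass (default 5).
#' @return List with `retained` (character vector of sample IDs),
#'   `n_dropped_first_pass`, `n_dropped_qi`, and the annotated table.
#' @export
filter_samples <- function(qi_table, min_qi = 0.6, min_first_pass_loci = 5) {
  stopifnot(all(c("sample", "qi", "first_pass_loci") %in% names(qi_table)))
  fp_fail <- qi_table$first_pass_loci < min_first_pass_loci
  qi_fail <- !fp_fail & qi_table$qi <= min_qi
  qi_table$retained <- !fp_fail & !qi_fail
  list(retained = qi_table$sample[qi_table$retained],
       n_dropped_first_pass = sum(fp_fail),
       n_dropped_qi = sum(qi_fail),
       table = qi_table)
}

#' Do two consensus genotype vectors represent the same individual?
#'
#' Matching rules: (a) the vectors are identical; (b) they differ only at
#' loci where one of them is missing, and loci missing in either vector
#' number at most `max_missing`; (c) exactly one locus differs between
#' called genotypes and the difference is a heterozygote versus a homozygote
#' whose allele the heterozygote contains (allelic dropout), with missing
#' loci again bounded by `max_missing`.
#'
#' @param g1,g2 Lists with integer vectors `a` and `b` over the same locus
#'   panel (e.g. from [build_consensus()] or [genotype_of()]).
#' @param max_missing Bound on loci missing in either vector (default 10).
#' @return Logical; symmetric in its arguments.
#' @export
match_genotypes <- function(g1, g2, max_missing = 10) {
  stopifnot(length(g1$a) == length(g2$a))
  m1 <- is.na(g1$a); m2 <- is.na(g2$a)
  n_missing <- sum(m1 | m2)
  both <- !m1 & !m2
  diff <- both & (g1$a != g2$a | g1$b != g2$b)
  nd <- sum(diff)
  if (nd == 0L) {
    if (identical(m1, m2)) return(TRUE)      # rule (a): fully identical
    return(n_missing <= max_missing)         # rule (b)
  }
  if (nd > 1L || n_missing > max_missing) return(FALSE)
  l <- which(diff)
  het1 <- g1$a[l] != g1$b[l]; het2 <- g2$a[l] != g2$b[l]
  if (het1 == het2) return(FALSE)  # need het vs homozygote
  het <- if (het1) c(g1$a[l], g1$b[l]) else c(g2$a[l], g2$b[l])
  hom <- if (het1) g2$a[l] else g1$a[l]
  hom %in% het
}

#' Collapse matching samples into unique individuals
#'
#' Groups samples by single linkage under [match_genotypes()] and builds one
#' consensus genotype per individual by applying the consensus rules to the
#' member samples' consensus vectors. Triads where A matches B and B matches
#' C but A does not match C are still grouped (single linkage) but flagged.
#'
#' @param genotypes Named list of consensus genotypes (each a list `a`, `b`).
#' @param meta Optional data frame (column `sample`) carried per sample.
#' @param max_missing Passed to [match_genotypes()].
#' @return List with `dataset` (a [wh_dataset()] of unique individuals),
#'   `map` (data frame `sample`, `individual`), `n_samples` per individual,
#'   and `inconsistent` (individuals whose group is not a clique).
#' @export
collapse_individuals <- function(genotypes, meta = NULL, max_missing = 10) {
  n <- length(genotypes)
  stopifnot(n >= 1L)
  ids <- names(genotypes) %||% paste0("s", seq_len(n))
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairs_match <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)[-seq_len(i)]) {
    m <- match_genotypes(genotypes[[i]], genotypes[[j]], max_missing)
    pairs_match[i, j] <- pairs_match[j, i] <- m
    if (m) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <- ri }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), match(comp, unique(comp)))
  L <- length(genotypes[[1]]$a)
  loci <- names(genotypes[[1]]$a) %||% paste0("L", seq_len(L))
  A <- matrix(NA_integer_, length(groups), L,
              dimnames = list(paste0("ind", seq_along(groups)), loci))
  B <- A
  inconsistent <- logical(length(groups))
  for (g in seq_along(groups)) {
    mem <- groups[[g]]
    if (length(mem) > 1L)
      inconsistent[g] <- !all(pairs_match[mem, mem][upper.tri(diag(length(mem)))])
    ra <- do.call(rbind, lapply(genotypes[mem], `[[`, "a"))
    rb <- do.call(rbind, lapply(genotypes[mem], `[[`, "b"))
    cons <- build_consensus(replicate_set(paste0("grp", g), ra, rb))
    A[g, ] <- cons$a; B[g, ] <- cons$b
  }
  map <- data.frame(sample = ids,
                    individual = rownames(A)[match(comp, unique(comp))],
                    stringsAsFactors = FALSE)
  md <- data.frame(id = rownames(A),
                   n_samples = as.integer(table(map$individual)[rownames(A)]),
                   stringsAsFactors = FALSE)
  list(dataset = wh_dataset(A, B, md), map = map,
       n_samples = stats::setNames(md$n_samples, md$id),
       inconsistent = stats::setNames(inconsistent, rownames(A)))
}

#' Run the full QC stage on a set of replicate sets
#'
#' Convenience wrapper: consensus, QI, filters, and collapse into unique
#' individuals.
#'
#' @param repsets List of [replicate_set()] objects.
#' @param min_qi,min_first_pass_loci Filter settings (see [filter_samples()]).
#' @param max_missing Matching bound (see [match_genotypes()]).
#' @return List with `qi_table`, `filter`, `collapse` (on retained samples).
#' @export
run_qc <- function(repsets, min_qi = 0.6, min_first_pass_loci = 5,
                   max_missing = 10) {
  cons <- lapply(repsets, build_consensus)
  qi <- lapply(seq_along(repsets),
               function(i) quality_index(repsets[[i]], cons[[i]]))
  tab <- data.frame(
    sample = vapply(repsets, `[[`, "", "sample"),
    qi = vapply(seq_along(qi), function(i)
      if (qi[[i]]$single_repeat) 1.0 else qi[[i]]$sample_qi, numeric(1)),
    first_pass_loci = vapply(repsets, function(r) sum(!is.na(r$a[1, ])),
                             integer(1)),
    stringsAsFactors = FALSE)
  flt <- filter_samples(tab, min_qi, min_first_pass_loci)
  keep <- match(flt$retained, tab$sample)
  col <- if (length(keep))
    collapse_individuals(stats::setNames(cons[keep], tab$sample[keep]),
                         max_missing = max_missing)
  else NULL
  list(qi_table = tab, filter = flt, collapse = col)
}
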