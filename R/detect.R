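#' Configuration of the resampling hybrid-detection procedure
#'
#' Defaults are the study conditions: 30 resampled datasets each drawing 70
#' of the 371 northeastern domestic cats (all other individuals always
#' included), 200 simulated parentals per subspecies, 30 simulated hybrids
#' per class (F1 and both first-generation backcrosses), reference-parental
#' cutoff q > 0.9, fixed general-analysis threshold 0.8, and the at-least-15
#' samplings rule for individual calls.
#'
#' @param n_domestic_per_dataset,n_datasets Resampling design.
#' @param n_sim_parentals,n_sim_hybrids Simulated reference set sizes.
#' @param ref_q_cutoff Strict q cutoff selecting reference parentals.
#' @param fixed_threshold General-analysis threshold.
#' @param individual_call_min Minimum detections for an individual-level call.
#' @param ci_level Confidence level for population rates.
#' @param burnin,iters Per-dataset MCMC settings (short chains).
#' @return An object of class `wh_detectconfig`.
#' @export
detection_config <- function(n_domestic_per_dataset = 70, n_datasets = 30,
                             n_sim_parentals = 200, n_sim_hybrids = 30,
                             ref_q_cutoff = 0.9, fixed_threshold = 0.8,
                             individual_call_min = 15, ci_level = 0.95,
                             burnin = 10000, iters = 30000) {
  stopifnot(n_domestic_per_dataset > 0, n_datasets > 0, n_sim_parentals > 0,
            n_sim_hybrids > 0, ref_q_cutoff > 0, ref_q_cutoff < 1,
            fixed_threshold > 0, fixed_threshold < 1)
  structure(as.list(environment()), class = "wh_detectconfig")
}

#' Select reference parental individuals from an aligned admixture run
#'
#' Individuals with mean ancestry strictly above the cutoff toward a cluster
#' join that cluster's reference set (q = cutoff exactly is excluded).
#'
#' @param ar An aligned K=2 [fit_admixture()] result.
#' @param cutoff Strict q cutoff (default 0.9).
#' @return List of two character vectors of IDs, named by cluster column.
#' @export
select_reference_parentals <- function(ar, cutoff = 0.9) {
  stopifnot(inherits(ar, "wh_admixture"), ar$K == 2)
  sets <- lapply(1:2, function(k) ar$ids[ar$q[, k] > cutoff])
  names(sets) <- colnames(ar$q)
  if (any(lengths(sets) == 0))
    stop("empty reference set: threshold calibration impossible")
  sets
}

#' Calibrate the detection threshold from simulated parentals
#'
#' The threshold is the lowest own-cluster q reached by any simulated
#' parental individual of either subspecies.
#'
#' @param sim_parental_q Numeric vector of own-cluster q values of simulated
#'   pure individuals (both subspecies pooled).
#' @return Scalar threshold.
#' @export
calibrate_threshold <- function(sim_parental_q) {
  stopifnot(length(sim_parental_q) >= 1)
  min(sim_parental_q)
}

#' Classify individuals as hybrids against a threshold
#'
#' Conservative rule: hybrid iff own-cluster mean q < threshold. Relaxed
#' rule: hybrid iff the lower bound of the own-cluster 90% credibility
#' interval < threshold. Every conservative hybrid is a relaxed hybrid.
#'
#' @param ar An aligned [fit_admixture()] result (K=2).
#' @param threshold Threshold in (0, 1).
#' @param own_cluster Integer vector (1 or 2 per individual) giving each
#'   individual's own cluster; by default the cluster with higher mean q.
#' @return Data frame `id, own_cluster, q, cri_lo, hybrid_conservative,
#'   hybrid_relaxed`.
#' @export
classify_hybrids <- function(ar, threshold, own_cluster = NULL) {
  stopifnot(inherits(ar, "wh_admixture"), ar$K == 2,
            threshold > 0, threshold < 1)
  own <- own_cluster %||% max.col(ar$q, ties.method = "first")
  idx <- cbind(seq_along(ar$ids), own)
  q <- ar$q[idx]
  lo <- ar$cri90$lo[idx]
  data.frame(id = ar$ids, own_cluster = own, q = q, cri_lo = lo,
             hybrid_conservative = q < threshold,
             hybrid_relaxed = lo < threshold,
             stringsAsFactors = FALSE)
}

#' General admixture analysis with the fixed 0.8 threshold
#'
#' Fits the K=2 admixture model on the full dataset, aligns clusters to the
#' morphological subspecies labels, and classifies everyone against the
#' fixed threshold under both rules. The individual's own cluster is the one
#' its morphology points to when known, otherwise the majority cluster.
#'
#' @param ds A [wh_dataset()] with `meta$morphology`.
#' @param fixed_threshold Threshold (default 0.8).
#' @param seed Integer seed.
#' @param ... Passed to [fit_admixture()] (e.g. `burnin`, `iters`).
#' @return List with `admixture` (aligned run, cluster 1 = domestic,
#'   cluster 2 = wildcat) and `calls` (from [classify_hybrids()]).
#' @export
run_general_analysis <- function(ds, fixed_threshold = 0.8, seed = 1, ...) {
  stopifnot(inherits(ds, "wh_dataset"))
  ar <- fit_admixture(ds, K = 2, seed = seed, ...)
  ref <- morphology_reference(ds)
  ar <- align_clusters(ar, ref)
  own <- ifelse(ds$meta$morphology %in% "silvestris", 2L,
         ifelse(ds$meta$morphology %in% "catus", 1L,
                max.col(ar$q, ties.method = "first")))
  calls <- classify_hybrids(ar, fixed_threshold, own_cluster = own)
  list(admixture = ar, calls = calls)
}

morphology_reference <- function(ds) {
  morph <- ds$meta$morphology
  if (is.null(morph)) stop("dataset lacks meta$morphology")
  ref <- list(ds$ids[morph %in% "catus"], ds$ids[morph %in% "silvestris"])
  if (any(lengths(ref) == 0))
    stop("need individuals of both morphologies to anchor the clusters")
  ref
}

#' Simulation-calibrated resampling hybrid detection
#'
#' For each resampled dataset: (1) draw `n_domestic_per_dataset` individuals
#' without replacement from the designated domestic pool, keeping everyone
#' else; (2) fit the K=2 admixture model (short chain) and align to the
#' morphological labels; (3) select reference parentals (q > cutoff) and
#' simulate parental and hybrid genotypes from the reference sets' allele
#' frequencies; (4) fit the model to the simulants alone (aligned via the
#' simulated parentals) and set the detection threshold at the lowest
#' simulated-parental own-cluster q; (5) classify the resampled real
#' individuals under both rules. Per-individual detection counts and
#' per-population per-dataset rates accumulate over datasets; rates are
#' summarised by their mean and empirical percentile confidence interval.
#' Datasets where a reference set comes out empty are skipped with a
#' recorded warning and the denominators adjusted.
#'
#' @param ds A [wh_dataset()] with `meta$population` and `meta$morphology`.
#' @param cfg A [detection_config()].
#' @param subsample_population Population label whose individuals are
#'   subsampled each dataset (the oversampled domestic pool).
#' @param seed Integer seed driving the whole procedure.
#' @return An object of class `wh_calltable`: `individuals` (per-individual
#'   `times_sampled`, `times_hybrid_conservative`, `times_hybrid_relaxed`,
#'   fractions, `final_call`), `rates` (per population and mode: mean and CI
#'   bounds in percent), `per_dataset` rates, `thresholds`, `n_skipped`.
#' @export
run_resampling <- function(ds, cfg = detection_config(),
                           subsample_population, seed = 1) {
  stopifnot(inherits(ds, "wh_dataset"), inherits(cfg, "wh_detectconfig"))
  pops <- as.character(ds$meta$population)
  pool <- which(pops == subsample_population)
  if (length(pool) < cfg$n_domestic_per_dataset)
    stop("population ", subsample_population, " smaller than the per-dataset draw")
  others <- setdiff(seq_along(ds$ids), pool)
  set.seed(seed)
  dataset_seeds <- sample.int(2^31 - 10, cfg$n_datasets)
  n_sampled <- stats::setNames(integer(length(ds$ids)), ds$ids)
  n_cons <- n_sampled; n_rel <- n_sampled
  per_dataset <- list(); thresholds <- numeric(0); n_skipped <- 0L
  for (d in seq_len(cfg$n_datasets)) {
    set.seed(dataset_seeds[d])
    take <- sort(c(others, sample(pool, cfg$n_domestic_per_dataset)))
    sub <- subset_dataset(ds, individuals = take)
    res <- tryCatch(
      one_resampling_pass(sub, cfg, seed = dataset_seeds[d]),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_skipped <- n_skipped + 1L
      warning(sprintf("dataset %d skipped: %s", d, conditionMessage(res)))
      next
    }
    thresholds <- c(thresholds, res$threshold)
    n_sampled[sub$ids] <- n_sampled[sub$ids] + 1L
    n_cons[res$calls$id[res$calls$hybrid_conservative]] <-
      n_cons[res$calls$id[res$calls$hybrid_conservative]] + 1L
    n_rel[res$calls$id[res$calls$hybrid_relaxed]] <-
      n_rel[res$calls$id[res$calls$hybrid_relaxed]] + 1L
    rates <- stats::aggregate(
      cbind(conservative = res$calls$hybrid_conservative,
            relaxed = res$calls$hybrid_relaxed),
      by = list(population = pops[take]), FUN = function(x) 100 * mean(x))
    rates$dataset <- d
    per_dataset[[length(per_dataset) + 1L]] <- rates
  }
  if (!length(per_dataset)) stop("every resampled dataset failed")
  pd <- do.call(rbind, per_dataset)
  alpha <- 1 - cfg$ci_level
  rate_rows <- list()
  for (g in unique(pd$population)) for (mode in c("conservative", "relaxed")) {
    v <- pd[pd$population == g, mode]
    rate_rows[[length(rate_rows) + 1L]] <- data.frame(
      population = g, mode = mode, mean = mean(v),
      ci_lo = unname(stats::quantile(v, alpha / 2, type = 7)),
      ci_hi = unname(stats::quantile(v, 1 - alpha / 2, type = 7)))
  }
  individuals <- data.frame(
    id = ds$ids, population = pops,
    times_sampled = as.integer(n_sampled),
    times_hybrid_conservative = as.integer(n_cons),
    times_hybrid_relaxed = as.integer(n_rel),
    frac_hybrid_conservative = ifelse(n_sampled > 0, n_cons / n_sampled, NA),
    frac_hybrid_relaxed = ifelse(n_sampled > 0, n_rel / n_sampled, NA),
    final_call_conservative = n_cons >= cfg$individual_call_min,
    final_call_relaxed = n_rel >= cfg$individual_call_min,
    stringsAsFactors = FALSE)
  structure(list(individuals = individuals,
                 rates = do.call(rbind, rate_rows),
                 per_dataset = pd, thresholds = thresholds,
                 n_skipped = n_skipped, config = cfg),
            class = "wh_calltable")
}

# one full pass: fit, select references, simulate, calibrate, classify
one_resampling_pass <- function(sub, cfg, seed) {
  ar <- fit_admixture(sub, K = 2, burnin = cfg$burnin, iters = cfg$iters,
                      seed = seed)
  ar <- align_clusters(ar, morphology_reference(sub))
  refs <- select_reference_parentals(ar, cfg$ref_q_cutoff)   # k1=domestic, k2=wild
  fa <- allele_freqs(subset_dataset(sub, individuals = refs[[1]]), by = NULL)$all
  fb <- allele_freqs(subset_dataset(sub, individuals = refs[[2]]), by = NULL)$all
  drop_empty <- vapply(fa, length, integer(1)) == 0 |
                vapply(fb, length, integer(1)) == 0
  if (any(drop_empty)) { fa <- fa[!drop_empty]; fb <- fb[!drop_empty] }
  if (!length(fa)) stop("reference sets share no called loci")
  simsets <- list(
    simulate_hybrids(fa, fa, "F1", cfg$n_sim_parentals, seed = seed + 1,
                     prefix = "simA"),    # pure A: both gametes from pool A
    simulate_hybrids(fb, fb, "F1", cfg$n_sim_parentals, seed = seed + 2,
                     prefix = "simB"),
    simulate_hybrids(fa, fb, "F1", cfg$n_sim_hybrids, seed = seed + 3,
                     prefix = "simF1"),
    simulate_hybrids(fa, fb, "BC_A", cfg$n_sim_hybrids, seed = seed + 4,
                     prefix = "simBCdom"),
    simulate_hybrids(fa, fb, "BC_B", cfg$n_sim_hybrids, seed = seed + 5,
                     prefix = "simBCwild"))
  sim <- bind_datasets(simsets)
  ars <- fit_admixture(sim, K = 2, burnin = cfg$burnin, iters = cfg$iters,
                       seed = seed + 6)
  ars <- align_clusters(ars, list(simsets[[1]]$ids, simsets[[2]]$ids))
  par_q <- c(ars$q[match(simsets[[1]]$ids, ars$ids), 1],
             ars$q[match(simsets[[2]]$ids, ars$ids), 2])
  thr <- calibrate_threshold(par_q)
  own <- ifelse(sub$meta$morphology %in% "silvestris", 2L, 1L)
  calls <- classify_hybrids(ar, thr, own_cluster = own)
  list(threshold = thr, calls = calls, admixture = ar)
}

#' Method-agreement table over the detection approaches
#'
#' Combines the six detection routes (general conservative/relaxed,
#' resampling conservative/relaxed, EM with F1 only, EM with backcrosses)
#' into one boolean table per individual plus the count of agreeing
#' approaches.
#'
#' @param general Result of [run_general_analysis()].
#' @param resampling A `wh_calltable` from [run_resampling()].
#' @param em_f1 A [em_hybrid_classes()] fit whose class set is
#'   pure + F1 only.
#' @param em_bc A fit including backcrosses (and F1/F2).
#' @return Data frame of six logical columns plus `n_detections`.
#' @export
consensus_calls <- function(general, resampling, em_f1, em_bc) {
  ids <- general$calls$id
  stopifnot(identical(sort(ids), sort(resampling$individuals$id)),
            identical(sort(ids), sort(em_f1$ids)),
            identical(sort(ids), sort(em_bc$ids)))
  ri <- resampling$individuals[match(ids, resampling$individuals$id), ]
  hyb_classes <- c("F1", "F2", "BC_A", "BC_B")
  em_hybrid <- function(em) {
    cls <- em$modal_class[match(ids, em$ids)]
    cls %in% hyb_classes
  }
  out <- data.frame(
    id = ids,
    general_conservative = general$calls$hybrid_conservative,
    general_relaxed = general$calls$hybrid_relaxed,
    resampling_conservative = ri$final_call_conservative,
    resampling_relaxed = ri$final_call_relaxed,
    em_f1 = em_hybrid(em_f1),
    em_backcross = em_hybrid(em_bc),
    stringsAsFactors = FALSE)
  out$n_detections <- rowSums(out[, -1])
  out
}
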