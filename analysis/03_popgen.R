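#!/usr/bin/env Rscript
# Diversity and differentiation of the four populations: rarefied per-locus
# Na/Ho/He (18 individuals, 100 draws, as in the field protocol), HWE and
# linkage permutation tests with Bonferroni correction, Brookfield
# null-allele screening, the pairwise Weir-Cockerham F_ST matrix with 1,000
# permutations, and a genotype PCA.
suppressPackageStartupMessages(library(wildhyb))

ds <- read_dataset("results/study_genotypes.csv", "csv")
truth <- utils::read.csv("results/study_truth.csv")
pure <- subset_dataset(ds, individuals = truth$class == "pure")

rar <- rarefied_diversity(pure, n_individuals = 18, n_reps = 100, seed = 3)
utils::write.csv(rar$per_locus, "results/popgen_rarefied_per_locus.csv",
                 row.names = FALSE)
summ <- summarize_locus_table(rar$per_locus)
utils::write.csv(summ, "results/popgen_rarefied_summary.csv",
                 row.names = FALSE)
cat("rarefied diversity (18 ind x 100 draws), mean over loci:\n")
print(utils::head(summ[summ$statistic == "na", ], 4))

# HWE per locus within each population (199 permutations, Bonferroni per pop)
hwe_rows <- list()
for (p in unique(pure$meta$population)) {
  pv <- vapply(pure$loci, function(l)
    tryCatch(hwe_test(pure, l, p, n_perm = 199, seed = 11)$p,
             error = function(e) NA_real_), numeric(1))
  adj <- rep(NA_real_, length(pv))
  adj[!is.na(pv)] <- bonferroni(pv[!is.na(pv)])$p_adj
  hwe_rows[[p]] <- data.frame(population = p, locus = pure$loci,
                              p = pv, p_bonferroni = adj)
}
hwe <- do.call(rbind, hwe_rows)
utils::write.csv(hwe, "results/popgen_hwe.csv", row.names = FALSE)
cat(sprintf("\nHWE: %d of %d locus-population tests significant after Bonferroni\n",
            sum(hwe$p_bonferroni < 0.05, na.rm = TRUE), sum(!is.na(hwe$p))))

# linkage disequilibrium within the largest population (sampled locus pairs)
prs <- utils::combn(pure$loci, 2)
set.seed(4); take <- sample(ncol(prs), 40)
ld <- data.frame(locus1 = prs[1, take], locus2 = prs[2, take])
ld$p <- vapply(seq_len(nrow(ld)), function(i)
  ld_test(pure, ld$locus1[i], ld$locus2[i], "NE_domestic",
          n_perm = 99, seed = i)$p, numeric(1))
ld$p_bonferroni <- bonferroni(ld$p)$p_adj
utils::write.csv(ld, "results/popgen_ld.csv", row.names = FALSE)
cat(sprintf("LD: %d of %d sampled pairs significant after Bonferroni\n",
            sum(ld$p_bonferroni < 0.05), nrow(ld)))

# null alleles (Brookfield) per locus in the NE domestic population
na_tab <- do.call(rbind, lapply(pure$loci, function(l) {
  nt <- null_allele_test(pure, l, "NE_domestic")
  data.frame(locus = l, r_null = nt$r_null, p_blank = nt$p)
}))
utils::write.csv(na_tab, "results/popgen_null_alleles.csv", row.names = FALSE)

# pairwise F_ST with permutation tests
fs <- wc_fstats(pure)
pops <- rownames(fs$theta_pair)
fst_rows <- list()
for (i in seq_len(length(pops) - 1)) for (j in seq(i + 1, length(pops))) {
  pt <- fst_perm_test(pure, c(pops[i], pops[j]), n_perm = 1000, seed = 5)
  fst_rows[[length(fst_rows) + 1L]] <-
    data.frame(pop1 = pops[i], pop2 = pops[j],
               theta = pt$theta, p = pt$p)
}
fst <- do.call(rbind, fst_rows)
utils::write.csv(fst, "results/popgen_fst.csv", row.names = FALSE)
cat("\npairwise Weir-Cockerham F_ST:\n"); print(fst, digits = 3)

pc <- pca_genotypes(ds)
sc <- data.frame(id = ds$ids, population = ds$meta$population,
                 pc$scores[, 1:2])
utils::write.csv(sc, "results/popgen_pca_scores.csv", row.names = FALSE)
cat(sprintf("\nPCA: axis 1 explains %.1f%%, axis 2 %.1f%% of variance\n",
            100 * pc$explained[1], 100 * pc$explained[2]))
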