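#!/usr/bin/env Rscript
# Build the synthetic two-region study that the rest of the workflow
# analyses: a wild and a domestic gene pool diverged to F_ST ~ 0.15, each
# with two regional populations (northeastern France, NE; Pyrenees, PO),
# unbalanced sample sizes mirroring the field design (371 NE domestic cats
# vs 42 NE wildcats, 18 PO wildcats, 21 PO domestic cats), a handful of F1
# and first-generation backcross hybrids in the NE (none in the PO), and
# replicated noninvasive genotyping of the PO samples under the dropout /
# failure error model. Everything downstream reads the CSVs written here.
suppressPackageStartupMessages(library(wildhyb))
dir.create("results", showWarnings = FALSE)
seed <- 20260928

# top level: wild vs domestic gene pools (22 loci x 8 alleles, F = 0.15)
top <- simulate_parental_pops(pop_model(F = 0.15),
                              c(wild = 2, domestic = 2), seed = seed)
# regional populations drift mildly from their subspecies pool
wild_reg <- simulate_parental_pops(
  pop_model(ancestral_freqs = unname(top$pop_freqs$wild), F = 0.04),
  c(NE_wild = 38, PO_wild = 18), seed = seed + 1)
dom_reg <- simulate_parental_pops(
  pop_model(ancestral_freqs = unname(top$pop_freqs$domestic), F = 0.02),
  c(NE_domestic = 360, PO_domestic = 21), seed = seed + 2)

# hybrids live in the NE: 4 F1-ish wildcats and 11 backcrossed domestic cats
f1_w <- simulate_hybrids(wild_reg$pop_freqs$NE_wild, dom_reg$pop_freqs$NE_domestic,
                         "F1", 4, seed = seed + 3, prefix = "NE_wild_f1")
bc_d <- simulate_hybrids(wild_reg$pop_freqs$NE_wild, dom_reg$pop_freqs$NE_domestic,
                         "BC_B", 11, seed = seed + 4, prefix = "NE_dom_bc")
f1_w$meta$population <- "NE_wild";     f1_w$meta$morphology <- "silvestris"
bc_d$meta$population <- "NE_domestic"; bc_d$meta$morphology <- "catus"

ds <- bind_datasets(list(wild_reg$dataset, dom_reg$dataset, f1_w, bc_d))
ds$meta$morphology <- ifelse(grepl("wild", ds$meta$population),
                             "silvestris", "catus")
ds$meta$sex <- sample(c("F", "M"), length(ds$ids), TRUE)
ds$meta$material <- ifelse(ds$meta$population == "PO_wild", "feces",
                    ifelse(ds$meta$population == "PO_domestic", "hair", "blood"))
truth <- data.frame(id = ds$ids,
                    class = c(rep("pure", 38 + 18 + 360 + 21),
                              rep("F1", 4), rep("BC_domestic", 11)))

write_dataset(ds, "results/study_genotypes.csv", "csv")
utils::write.csv(truth, "results/study_truth.csv", row.names = FALSE)

# (replicated noninvasive genotyping of the PO samples is derived in
# 02_qc.R from these genotypes with its own fixed seed)

# coordinates: kin-clustered wildcat families for the spatial analysis
fam <- simulate_families(wild_reg$pop_freqs$NE_wild, n_families = 10,
                         n_unrelated = 12, seed = seed + 6,
                         population = "NE_wild_spatial")
coords <- simulate_coordinates(fam, kin_clustering = TRUE, noise_sd = 400,
                               seed = seed + 7)
write_dataset(fam, "results/spatial_genotypes.csv", "csv")
utils::write.csv(coords, "results/spatial_coordinates.csv", row.names = FALSE)

tab <- table(ds$meta$population)
cat("simulated study written to results/:\n")
cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
cat("  realised wild-domestic F_ST (NE):",
    round(wc_fstats(subset_dataset(ds, individuals = ds$meta$population %in%
             c("NE_wild", "NE_domestic") & truth$class == "pure"))$theta, 3), "\n")
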