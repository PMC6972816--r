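---
title: "Detecting wildcat-domestic cat hybridization from microsatellites: models and methods"
author: "wildhyb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting wildcat-domestic cat hybridization from microsatellites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

European wildcats (*Felis silvestris silvestris*) hybridize with
free-ranging domestic cats (*F. s. catus*). Surveys of local populations
genotype cats at a panel of autosomal microsatellites (here 22 loci),
often from noninvasive material (feces, hair) that suffers allelic dropout
and amplification failure, and ask three questions: how genetically
diverse and differentiated are the wild and domestic populations; which
individuals carry admixed ancestry; and whether close kin cluster in
space. `wildhyb` implements that whole chain as testable package code,
with a synthetic-data generator standing in for field data so every stage
can be exercised and calibrated end to end.

## Synthetic data: what it emulates

`pop_model()` + `simulate_parental_pops()` implement the correlated
allele-frequencies F-model: each parental pool's per-locus frequencies are
drawn from a Dirichlet centred on an ancestral vector with concentration
$(1-F)/F$, and genotypes are two independent gamete draws (HWE). $F$ is a
drift parameter, not an F_ST estimate; the mapping to realised
differentiation is empirical and exposed via `calibrate_fst()`. At the
panel used throughout (22 loci, 8 alleles each), $F = 0.15$ realises a
multilocus Weir-Cockerham $\theta$ within about $\pm 0.05$ of 0.15 —
the range reported for wild-domestic differentiation in the field
(0.15-0.17) — which is why 0.15 is the default.

`simulate_hybrids()` draws hybrid classes at the gamete level: an F1 takes
one gamete from each pool; an F2 takes one gamete from each of two freshly
simulated F1 parents; a first-generation backcross takes an F1 gamete plus
a parental gamete. `simulate_replicates()` applies the noninvasive error
model per repeat and locus: amplification failure (whole locus missing)
then allelic dropout (a heterozygote loses one uniformly chosen allele and
is seen as a false homozygote). Dropout is applied per genotype-repeat
rather than per allele copy because that is how dropout manifests and is
diagnosed in repeat-based QC. The field study reports amplification
success near 74-82% but no dropout rate; the defaults (dropout 0.2,
failure 0.15, 3 repeats) are chosen once as plausible for degraded faecal
DNA and are knobs, not claims.

`simulate_families()` produces full-sib groups of 2-4 (the smallest
pedigree structure that makes the kinship-distance regression testable)
and `simulate_coordinates()` places families around shared spatial centres
(or everyone uniformly, for the null). What the generator does *not*
emulate: mutation processes, multi-generation pedigrees beyond the four
hybrid classes, isolation by distance within populations, and genotyping
artefacts other than dropout/failure (e.g. stutter miscalls). Passing
tests therefore demonstrate correctness of the machinery and its
behaviour under the stated statistical structure, not robustness to every
feature of real field data.

## Consensus genotyping and the quality index

For each noninvasive sample genotyped 2-4 times, `build_consensus()`
reconciles repeats per locus. A heterozygote is accepted when seen in at
least one successful repeat if at most two repeats amplified, and in at
least two if three or more did (the multi-tube safeguard; failures do not
count against confirmation — otherwise a locus with a single successful
amplification could never reach consensus, contradicting the convention
that error-free data lose quality only to amplification failure).
Apparent homozygotes whose allele is contained in the accepted
heterozygote are attributed to dropout. Three or more distinct alleles
across repeats — or two disagreeing homozygotes, which no observed
genotype explains — leave the locus missing with a conflict flag.

`quality_index()` scores each repeat at each locus 1 (consensus
reproduced), 0.5 (homozygote against a heterozygous consensus — the
dropout signature) or 0 (missing, or any other disagreement), averaging
over repeats then loci. Samples are dropped when fewer than five loci
amplified at the first pass or when QI is not strictly above 0.6; blood
samples genotyped once carry QI 1 by convention and are flagged as
single-repeat.

`match_genotypes()` decides whether two consensus vectors are the same
individual: identical; or differing only by missing data at no more than
ten loci; or differing at exactly one called locus by a
dropout-explainable heterozygote-homozygote pair. The ten-locus bound is
counted over the union of loci missing in either vector, and rule (c)
tolerates missing data under the same bound — the three rules are
alternatives in spirit, and real noninvasive consensus pairs combine one
dropout with some missingness. `collapse_individuals()` groups samples by
single linkage under these rules (flagging non-transitive triads) and
rebuilds one consensus per individual.

## Diversity and differentiation

`locus_summaries()` reports Na, Na above 5% frequency, observed
heterozygosity, and unbiased expected heterozygosity
$\tfrac{2n}{2n-1}(1 - \sum_i p_i^2)$ — the estimator the classical
FSTAT/Genetix workflow prints (plain gene diversity is a flag away).
`rarefied_diversity()` equalises sample sizes (default 18 individuals,
100 draws) before comparing allelic richness. `wc_fstats()` implements
the Weir-Cockerham (1984) variance components $a, b, c$ summed over
alleles and loci, with per-locus sample sizes from called genotypes only;
a dual, independently coded brute-force implementation serves as the test
oracle at tolerance 1e-12. On duplicated tiny samples $\theta$ is slightly
negative rather than exactly zero — a finite-sample property of the
estimator, so the no-structure tests assert closeness, not identity.

Permutation tests follow standard practice: HWE re-pairs the $2n$ allele
copies; linkage permutes one locus's genotypes across individuals (G
statistic on the two-locus table); pairwise F_ST shuffles individuals
between populations (1,000 permutations by default). All report the
conservative $(b+1)/(m+1)$ p-value, so the attainable floor is
$1/(m+1)$. The Brookfield estimator
$\hat r = \max(0, (H_e - H_o)/(1 + H_e))$ screens for null alleles, with
a binomial test of observed blank individuals against the expected
$n \hat r^2$. The study protocol nominally discards HWE-deviating loci
yet its own summary tables retain the full panel; discarding is therefore
a config decision left to the analysis scripts, default off.

`pca_genotypes()` builds the individuals x allele-dosage matrix (counts
halved), imputes missing cells by column means, centres, and
eigen-decomposes; axis signs are fixed deterministically (largest-|loading|
coordinate positive).

## Admixture model

`fit_admixture()` is a Gibbs sampler (compiled core) for the standard
admixture model: each allele copy carries a latent cluster of origin;
individual ancestry vectors have a symmetric Dirichlet($\alpha$) prior
with $\alpha$ learned by a Metropolis step (uniform prior on (0, 10],
proposal SD 0.05 — conventional defaults); cluster allele frequencies have
a flat Dirichlet(1) prior (independent model) or a correlated F-model
prior centred on the pooled sample frequencies with per-cluster drift
updated by Metropolis. The correlated model fixes its ancestral vector at
the pooled frequencies to keep the frequency update conjugate; the
independent model is the default because the detection pipeline is
threshold-calibrated per dataset, which absorbs the (small) difference,
and it mixes faster. Missing genotypes are skipped, not imputed. Default
chain lengths are 10,000 burn-in + 30,000 iterations — the short-chain
setting used for the resampling analyses; the longer 100k/300k setting is
a parameter away. Every 10th post-burn-in draw is retained.

Reported q-values are posterior means of the retained draws; 90%
credibility intervals are the equal-tailed 5th-95th percentiles of the
same draws (the equal-tailed convention is an implementation decision —
the field convention is not stated anywhere authoritative). For extremely
skewed posteriors the mean can fall outside the equal-tailed band, so the
band is widened minimally to bracket the reported mean; this also makes
the conservative detection rule nest inside the relaxed rule by
construction. A linear-trend check on the post-burn-in log-likelihood
trace raises a non-mixing warning (never an error).

`evanno_delta_k()` implements
$\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}(L(K))$
over repeated runs, undefined at the endpoints; `align_clusters()` undoes
label switching by exhaustively permuting columns (K ≤ 5, so at most 120
permutations) to maximise the reference subsets' mean ancestry, with
deterministic index tie-breaking.

## Hybrid classes without MCMC

`em_hybrid_classes()` is a deterministic EM over genotype-frequency
classes — pure A, pure B, F1 (origin pair AB at every locus), F2
(AA:¼, AB:½, BB:¼), and the two backcrosses (AA or BB:½, AB:½) — the
same class kernels the NewHybrids/Snapclust family uses, substituting EM
for MCMC so results are exactly reproducible. Genotype probabilities
under an origin pair are products of pool frequencies; the E-step computes
class responsibilities and, per class, pair-type posteriors; the joint
M-step re-estimates pool frequencies from expected allele-origin counts
(pair posteriors must be normalised within class before weighting by
responsibilities — the observed-data log-likelihood is monotone, and the
tests assert it). In fixed mode the pools come from declared pure
references and only the mixing proportions move. At 22 microsatellites and
F_ST near 0.15, backcrosses overlap the parental q distribution;
recovery around 70-85% of simulated backcrosses is the realistic ceiling
the tests encode, and the F1-only configuration exists precisely to avoid
uninterpretable backcross noise in sparse panels.

## The detection framework

Three routes, combined by `consensus_calls()`:

1. **General analysis** (`run_general_analysis()`): K = 2 on everyone,
   fixed threshold 0.8 — the literature's convention for *Felis* panels.
   Conservative rule: own-cluster mean q below the threshold. Relaxed
   rule: own-cluster 90% CrI lower bound below the threshold. The
   relaxed set contains the conservative set by construction.
2. **Resampling** (`run_resampling()`): 30 datasets each drawing 70
   domestic cats without replacement from the oversampled domestic pool
   (everyone else always included), so each pool member is included
   $30 \times 70 / 371 = 5.66$ times on average. Per dataset: fit,
   align, select reference parentals (q strictly above 0.9), simulate
   200 parentals per subspecies and 30 hybrids per class from the
   reference allele frequencies, fit the simulants *separately* (the
   closest literal reading of the protocol; a joint run is a flag away),
   and set the detection threshold at the lowest simulated-parental
   own-cluster q. Population rates are summarised by the mean and
   empirical 2.5/97.5 percentiles over datasets (the CI construction is
   unstated in the source protocol; percentiles are the assumption-free
   choice, a normal-approximation flag exists). An individual is called
   hybrid when detected in at least 15 samplings — an absolute count,
   per the protocol's wording, with a fractional mode available since
   domestic cats are sampled far fewer than 30 times. Datasets whose
   reference set comes out empty are skipped, with the denominator
   adjusted and the skip logged.
3. **EM classifier**, in F1-only and backcross configurations.

## Relatedness and space

`ml_relatedness()` maximises the pairwise likelihood
$\prod_\ell (k_0 S_0 + k_1 S_1 + k_2 S_2)$ over the IBD-coefficient
simplex by deterministic grid search (coarse step 0.02, local refinement
to 0.001), with $r = k_2 + k_1/2$. Population allele frequencies exclude
the focal pair by default (leave-pair-out, reduces upward bias in small
samples; full-sample mode available, falling back automatically when
exclusion zeroes a pair-private allele). The genetic-feasibility
constraint $k_1^2 \ge 4 k_0 k_2$ is not imposed by default. Genotyping
error is not modelled in the likelihood: consensus genotypes are taken as
true, a known limitation for the noisiest samples.

`pair_distances()` averages Euclidean distances over all cross-pairs of
two individuals' sampling locations. `distance_model()` fits OLS of
distance on relatedness within each sex stratum and pooled with the pair
sex class as covariate (both are reported rather than asserting one as
canonical), and offers a Mantel-style permutation p (permuting individual
identities) because pairs sharing an individual are not independent.

## Problem sizes and numerical choices

The test suite and the analysis scripts run the samplers at reduced but
structurally faithful sizes — typically 40-200 individuals, 22 loci,
chains of 300-1,500 retained iterations, 3-10 seeds per property — sizes
chosen so the full workflow re-runs comfortably on a laptop while keeping
every assertion at the study's marker resolution and differentiation.
Permutation tests use 99-199 permutations in tests and 999-1,000 in the
analysis scripts. Dirichlet draws guard against gamma underflow; EM adds
a 1e-6 pseudocount per allele so no observed allele is assigned zero
frequency; permutation p-values are never zero by the plus-one rule.

## Known limitations

Single-chain MCMC without cross-chain convergence diagnostics (the trend
check is a heuristic); the correlated model's fixed ancestral vector is a
simplification; no AMOVA, no migration-rate estimation, no
mitochondrial/Y markers — direction-of-gene-flow questions are out of
scope; relatedness assumes error-free consensus genotypes; the EM
classifier assumes linkage equilibrium within pools, as do all methods
here.
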