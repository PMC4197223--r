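---
title: "Models and methods behind popgenpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgenpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popgenpipe implements the analysis graph of a genome-wide SNP-chip survey
of structured livestock populations. This vignette records the models, the
parameter choices, and the numerical decisions, so that every default can
be traced to a reason rather than an accident.

## The data model

All stages operate on a `genotype_dataset`: an n × m matrix of B-allele
dosages (0/1/2, `NA` for a missing call), a variant table (chromosome,
identifier, genetic and physical position, two allele labels), and a
sample sheet with population labels. Dosage coding is conventional, and the
pipeline is invariant to it: flipping which allele is "B" maps d to 2 − d
and leaves r², heterozygosity, F, FST and all distances unchanged (this is
tested end to end). PLINK text and binary dialects are both supported; for
binary files the B allele is the second BIM allele column, while text files
carry no allele ordering, so the reader assigns the two observed alleles
alphabetically — round-trips are exact for the binary dialect always, and
for text whenever `alleleA` sorts before `alleleB` (our writers emit "A"/"B"
labels, which satisfy this).

## Quality control

Markers pass five filters in a fixed order: unmapped, non-autosomal
(sheep autosomes 1–26 by default), call frequency ≥ 0.95, MAF ≥ 0.05, and
exact Hardy–Weinberg p > 0.001. The order matters only for the attrition
report, and fixing it (the order PLINK-centred workflows conventionally
use) makes that report reproducible. Two decisions were genuinely open:

* **Exact versus asymptotic HWE.** The exact conditional test is used
  (all heterozygote counts compatible with the allele counts enumerated,
  two-sided by probability mass, no mid-p), because chip QC at MAF bounds
  routinely visits counts where the chi-square approximation is poor. The
  implementation is validated against a brute-force enumeration oracle for
  every configuration with n ≤ 20.
* **Per-population versus pooled HWE.** Per-population is the default:
  pooling structured samples manufactures Wahlund-style heterozygote
  deficits and would discard perfectly good markers. A locus is dropped if
  it fails in any population present; `hwe_per_population = FALSE` pools.

One contract subtlety: a "no-op" threshold set must be the identity, so
placing chromosome code 0 in the retained-chromosome set disables the
structural unmapped filter.

## Linkage disequilibrium

r² is computed from maximum-likelihood two-locus haplotype frequencies
under random mating, the double-heterozygote phase ambiguity resolved by
EM. The EM iterates to a log-likelihood change below 1e-10 (cap 1,000
iterations) — far tighter than the 1e-3 agreement we demand against an
independent grid-search oracle, and cheap because the estimator is
vectorised over all pairs of a chromosome at once via their 3 × 3 genotype
count tables. Tables dominated by double heterozygotes have a saddle at
linkage equilibrium, so three deterministic starts are run (the
equilibrium point of the observed margins plus the two phase-pure corners)
and the best likelihood kept; this removes initialisation sensitivity
without randomness. A locus fixed in the analysed subgroup has no defined
r²: such pairs return `NA`, are excluded from every mean, and are counted —
never conflated with r² = 0.

Summaries follow chip-survey conventions: adjacent-pair tables per
chromosome with a genome-wide row pooled over pairs (not a mean of
chromosome means); all within-chromosome pairs up to 50 Mb; decay bins at
0–50 kb, 50–100 kb, 100–200 kb, 200–500 kb, 0.5–1 Mb, 1–2 Mb, > 2 Mb; and
sliding 1 Mb windows advanced by 50 kb for the N_e trajectory. VIF pruning
reproduces the `--indep` idea: within sliding windows of 50 SNPs, remove
the highest-VIF SNP (ties: later map position, for determinism) until all
VIFs = 1/(1 − R²) sit at or below the threshold; 50/5/2 is used before
structure analyses and 50/10/1.5 before diversity indices. Missing dosages
are mean-imputed only inside the pruning regressions.

## Effective population size

Sved's relation N_e = (1/4c)(1/r̄² − 1) converts the mean r² of pairs c
Morgans apart into the effective size of the population about t = 1/(2c)
generations ago. Two silent constants had to be fixed:

* **Map conversion.** 1 cM per Mb, the standard chip assumption when no
  linkage map is supplied; under it the 1 Mb sliding bin probes t = 50.
* **Sample-size correction.** Estimated r² exceeds its population value by
  roughly 1/(2n) for n sampled individuals. The plain formula is the
  default (matching how the relation is usually quoted); passing
  `correct_sample_size = TRUE` subtracts 1/(2n) first, and the recovery
  tests use the correction, since without it N_e is biased downward at
  survey sample sizes.

## Diversity and inbreeding

Per-SNP MAF, observed heterozygosity, and expected heterozygosity 2p(1−p)
are reported as plain sample quantities. The individual inbreeding
coefficient is the method-of-moments excess-homozygosity statistic
F = (O − E)/(N − E); inside E the per-locus expected heterozygosity
carries the unbiased n/(n−1) factor (the PLINK `--het` convention), while
reported He stays the plain 2p(1−p) — the two serve different purposes
(an estimator versus a descriptive index). F is negative for individuals
less homozygous than the sample average; that is a feature of the
statistic, not an error state.

## Structure

Allele sharing A_s counts IBS2 loci plus half the IBS1 loci over the
mutually typed loci of a pair; heterozygote–heterozygote pairs share both
alleles and count as IBS2. The printed formula "IBS2 + 0.5*IBS1/N" is read
as (IBS2 + 0.5·IBS1)/N — the only parsing that keeps A_s in [0, 1]. MDS of
D = 1 − A_s is classical Torgerson scaling (double-centre the squared
distances, eigendecompose, scale eigenvectors by √λ), which on this D is
numerically the samples' PCA; axis signs are fixed by making each
component's largest-magnitude loading positive, and negative eigenvalues
(non-Euclidean D) are reported but never used for coordinates.

The admixture model is the standard binomial mixture: genotype g_ij ~
Binomial(2, Σ_k q_ik p_kj). It is maximised by EM (the FRAPPE-style
updates) rather than quasi-Newton block relaxation: slower per digit of
likelihood, but simple, monotone by construction (asserted per iteration
in the tests), and entirely adequate at survey scale. Convergence is
ΔlogL < 1e-6 (cap 2,000 iterations), three random starts by default with
the best likelihood kept; P is clipped to [1e-6, 1 − 1e-6] each iteration
to keep the likelihood finite; missing cells are skipped in every sum.
K = 1 is handled in closed form. Cross-validation for K masks cells, not
individuals: the non-missing genotype cells are partitioned into 5 folds,
each fold in turn set missing, the model refit (one start per fold — the
refits dominate runtime), and masked cells scored by mean binomial
deviance of ĝ = 2QP; ties in the error go to the smaller K. Recovery is
always judged after aligning cluster labels by the best permutation, since
the likelihood is label-invariant.

## Differentiation and networks

Pairwise FST is the Weir–Cockerham 1984 θ in its biallelic two-population
form: per-locus variance components a (between populations), b (between
individuals within), c (within individuals, the heterozygosity term),
combined across loci as Σa / Σ(a+b+c) — a ratio of sums, never a mean of
per-locus ratios. Negative per-locus components are kept; loci monomorphic
across both populations, or with fewer than two typed individuals in
either, are excluded. Note one estimator property the tests respect: if
two samples happen to have identical genotype counts, θ̂ is not zero but
about −1/(2(n−1)) — conditioning on equal counts pins the between-group
variance below its sampling expectation.

NeighborNet generalises neighbor-joining to split networks. The
agglomeration keeps clusters as paths of at most two active nodes, selects
the cluster pair by the NJ Q-criterion on average distances and then the
node pair within them (clusters exploded into singletons), and collapses
3-node paths by the 2/3–1/3 distance reduction, expanding the reductions
in reverse once a single path remains and closes into the circular
ordering. Ties break to the lowest-index pair, making the whole
construction deterministic. Split weights are then fitted by non-negative
least squares (Lawson–Hanson, via pracma) of the circular split system
against the distances, and zero-weight splits (≤ 1e-9) dropped. For a
tree-additive matrix this returns exactly the tree's splits with branch
lengths; for a circularly decomposable matrix the recovery is exact by
construction, which is what the ordering tests verify (on arbitrary noisy
matrices no agglomerative ordering can promise the global NNLS optimum).
The network is built from FST distances directly, without an
FST/(1 − FST) linearisation — the convention when networks are drawn
straight from pairwise FST tables. A bundled 10-breed FST matrix
(`sheep_breed_fst()`) serves as the worked example: its MDS and network
agree that Chios is the most divergent breed and Pinzirita the least.

## The synthetic generators — what they do and do not emulate

The generators give every stage a dataset with known truth:

* **Balding–Nichols** draws ancestral frequencies Uniform(0.05, 0.95),
  population frequencies Beta(p(1−F)/F, (1−p)(1−F)/F), genotypes
  Binomial(2, ·) — unlinked loci, HWE within populations. Expected
  pairwise θ between drifts F₁, F₂ is ≈ (F₁+F₂)/2, recorded in the truth.
  Defaults (2 chromosomes in the fast tier; the `sheep50k_preset()` gives
  26 autosomes × ~1,700 SNPs, 71/71/77 individuals, F of 4–6%) were chosen
  to mirror a 50K-chip breed survey: ~60 kb marker spacing, mean MAF near
  0.29, FST in the few-percent range.
* **simulate_admixed** draws genotypes Binomial(2, Σ q p) from a true Q —
  the admixture model's own generative process.
* **Wright–Fisher** simulates 2N_e haplotypes per discrete generation with
  Poisson crossovers on a Morgan map from linkage-equilibrium uniform
  starts, so terminal LD is the drift–recombination equilibrium of a known
  N_e. Loci fixed by drift stay in the output for QC to remove, as in real
  data. Recovery runs use 8 chromosomes × 600 loci, 400 generations at
  N_e = 100, 70 sampled individuals — enough surviving loci (~600) and
  window pairs (~700 at the 1 Mb bin) for the Sved inversion to be judged,
  while a full run stays under a minute.

What they do **not** emulate: genotyping error and missingness patterns,
ascertainment bias of chip SNP selection, mutation, selection, overlapping
generations, demographic change, linked structure in the Balding–Nichols
breeds (its loci are unlinked, so its r² sits at the 1/(2n) sampling
background — the analysis scripts say so explicitly), or sex chromosomes.
Passing recovery tests therefore demonstrates correctness of the
estimators under their own model assumptions, not robustness to the full
messiness of real chip data.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed; the pipeline writes a
manifest of parameters and MD5 checksums, and reruns with the same seed
are byte-identical (tested). Test-suite problem sizes are deliberately
modest — two-chromosome cohorts, hundreds of loci, tens of individuals for
unit properties; 5,000 loci × 140 samples for FST recovery and the
8-chromosome Wright–Fisher cohort for N_e recovery — sizes at which each
statistical claim is already decidable at the stated tolerance.

## Known limitations

* Haplotype estimation is strictly two-locus; no phasing, no D′-block
  structure, no LD heatmaps.
* The admixture model ignores LD (as its reference implementations do);
  feeding it unpruned data inflates effective information.
* Sved inversion inherits the approximations of the underlying relation:
  at 50K-chip scale, bin means mix distances, conditioning on segregating
  loci biases r² slightly upward, and the recovered N_e is accordingly a
  band, not a point — the recovery tests accept ±25%.
* The IBS distance loop is O(n² m); at a few hundred samples it is
  seconds, but it is not written for biobank n.
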