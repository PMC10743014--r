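---
title: "Promoter haplotype analysis with promhap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter haplotype analysis with promhap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promhap)
```

# The problem

Case–control resequencing studies of gene promoters genotype a handful
of SNPs in a short amplicon and ask whether the *combination* of
alleles along each chromosome — the haplotype — carries disease signal
that single-site tests miss. promhap implements the full haplotype-level
toolchain for such panels in a two-group (control/patient) setting:
phasing unphased diploid genotypes, per-locus Hardy–Weinberg and
differentiation tests, pairwise linkage disequilibrium, AMOVA-style
group divergence, median-joining haplotype networks, a cumulative
mutation-burden statistic, and position-weight-matrix scanning of the
per-haplotype promoter sequences.

The bundled panels describe the human ATG16L1 promoter (four SNPs:
rs1816753, rs12476635, rs74599577, rs77820970 on chromosome 2) and the
ATG5 promoter (rs510432 and rs506027 on chromosome 6), the two
autophagy-gene promoters studied in sporadic Parkinson's disease
cohorts. ATG5 is transcribed from the minus strand, so its panel is
ordered along the sequenced fragment rather than by ascending genomic
coordinate; this is why the two ATG5 haplotypes print as TG and CA.

# The synthetic cohort generator

Because individual-level genotypes from such studies are not freely
redistributable, `promoter_cohort_spec()` encodes the *statistical
structure* of a reference case–control cohort — 28 controls and 56
patients — and `generate_cohort()` draws synthetic individuals from it:
each individual receives two haplotypes i.i.d. from its group's
frequency vector (Hardy–Weinberg random union; the study populations
tested consistent with HWE, so no inbreeding parameter is modelled),
the unordered per-locus allele pairs are recorded, and phase is
discarded. A single integer seed drives all draws.

The ATG16L1 control haplotype frequencies (0.250, 0.625, 0.125 for
hap1–hap3, zero for hap4–hap7) are the unique solution of the observed
control allele frequencies. The patient allele frequencies constrain
but do not determine the seven patient haplotype frequencies (four
linear constraints, six free parameters); the bundled vector
(0.142, 0.537, 0.101, 0.106, 0.024, 0.045, 0.045) satisfies all four
constraints to within 0.001 while keeping the expected count of every
patient-only haplotype at n = 56 at two copies or more, so that the
rarest haplotypes remain recoverable by phasing at the study's sample
size. The ATG5 system has exactly two haplotypes, TG and CA, at
0.518/0.482 (control) and 0.536/0.464 (patient).

What the generator deliberately does **not** emulate: genotyping error,
de-novo mutation, recombination within the amplicon (the observed
reticulation is a property of the fixed haplotype set itself),
population substructure, and covariates such as age or sex. Tests that
pass on this generator therefore demonstrate correctness of the
statistical machinery under clean HWE sampling, not robustness to the
artefacts of real Sanger data.

A caveat worth recording: the published patient allele counts are not
integral for 2n = 112 chromosomes, which suggests per-locus missing
data in the original study; the spec treats the published frequencies
as exact. One visible consequence is in linkage disequilibrium: with
exact expected counts the near-singleton rs74599577 allele (three
copies, all on the locus-4 T background) is Bonferroni-significant by
Fisher's test, an artifact of rare-allele nesting; the no-significant-LD
property of the reference study is reproduced for the pairs among the
three common SNPs.

# Haplotype phasing

`em_phase()` implements maximum-likelihood haplotype frequency
estimation by expectation–maximization (Excoffier–Slatkin gene
counting). For an individual heterozygous at *h* loci there are
2^(h−1) compatible haplotype pairs; the E-step weights pair (a, b) by
2·f_a·f_b (or f_a² for a homozygous pair), the M-step re-estimates
frequencies from expected counts. Identical multilocus genotypes are
collapsed into classes first, so cost scales with the number of
distinct genotypes, not individuals.

Numerical choices:

* **Convergence**: |Δ log-likelihood| < 1e-8, at most 1000 iterations.
  The log-likelihood is asserted non-decreasing in the test suite.
* **Restarts**: 20 by default. The first restart starts from the exact
  uniform frequency vector (so a one-restart call is deterministic);
  the rest perturb it uniformly in [0.5, 1.5] before renormalising.
  With ≤4 biallelic SNPs the likelihood surface is small and restarts
  agree almost always; they guard against the rare saddle.
* **Tie-breaking**: when two phase resolutions of an individual are
  exactly equiprobable, the lexicographically smaller haplotype pair is
  chosen, deterministically.
* **Missing data**: individuals with any missing genotype are excluded
  from phasing (with a warning). With at most four loci per panel,
  imputation would add machinery without adding information.
* **Reporting rule**: a haplotype is *reported* when its estimated
  frequency is at least 1/(4N) — half an expected single copy among 2N
  chromosomes — **and** it enters at least one individual's most-likely
  pair. The second condition matters: maximum likelihood can leave
  trace mass (frequencies of order 0.005–0.02) on alternative phase
  resolutions that no individual's best reconstruction uses; Bayesian
  phasing tools shrink these away via the coalescent prior, and
  haplotype counts reported from reconstructed individuals ignore
  them. The rule in force is recorded in the result's `pruning` field.

The substitution of EM for Bayesian coalescent-informed phasing is a
deliberate design choice: at four biallelic SNPs and n = 84 the two
approaches agree in practice, EM is fully deterministic given the
restart seed, and its likelihood can be verified against exhaustive
enumeration. On that verification: enumerating all joint phase
assignments and scoring the observed-data likelihood at each
assignment's empirical frequencies yields a *lower bound* on the EM
optimum — the continuous MLE occasionally exceeds every integral
candidate — so the invariant tested is EM ≥ bound, with equality on
instances where the MLE is integral.

# Per-locus statistics

`hwe_exact()` enumerates Levene's conditional distribution of the
heterozygote count given the allele counts and returns the standard
two-sided exact p-value (sum of probabilities of all configurations no
more probable than the observed one, ties included). The test suite
checks it against an independent oracle that counts perfect matchings
of allele copies, for every table with total ≤ 20.

`diff_test()` measures group differentiation at a locus. For the 2×2
allelic table the exact two-sided Fisher probability is returned
directly (Monte-Carlo SE = 0). For genotypic tables the p-value is
estimated by permuting group labels across individuals — the table's
conditional (multivariate hypergeometric) probability serves as the
ordering statistic — with 100,000 permutations by default and
SE = sqrt(p(1−p)/n_mc). This replaces a Markov-chain exact test with a
plain label permutation targeting the same null distribution, which is
easier to verify: the permutation version is checked for type-I
calibration (rejection rate within [0.02, 0.08] at α = 0.05 across
null simulations) in the acceptance suite.

`allele_chisq()` is the Pearson chi-square without continuity
correction (df = 1), and `bonferroni()` applies the p < α/m rule.

# Linkage disequilibrium

`pairwise_ld()` computes, per locus pair, the classical
haplotype-frequency statistics on the pool of best-pair phased
chromosomes: D = p_AB − p_A·p_B with A, B the major alleles (ties
toward the alphabetically first allele), D′ = D/D_max with the usual
frequency-constrained maximum, r = D/√(p_A p_a p_B p_b), chi² = 2N·r²,
and a two-tailed Fisher exact p from the 2×2 haplotype-count table,
Bonferroni-corrected over all pairs. Under the major-allele convention
the statistics are invariant to renaming alleles in the input; the
sign of D refers to the role assignment, not the labels. Pairs
involving a monomorphic locus are flagged not applicable rather than
forced to zero. Using best-pair haplotypes (rather than posterior
expected counts) mirrors how LD is normally run downstream of phasing;
a composite-LD path that bypasses phasing is out of scope.

# Group divergence

`amova_fst()` decomposes the variance of the 2N haplotype observations
into among- and within-group components from sums of squared
inter-haplotype distances (the matrix entries are treated as squared
distances). The identity matrix yields the conventional frequency-only
Fst; the Hamming matrix yields the distance-weighted ΦST built on mean
pairwise nucleotide differences. Variance components follow the
standard two-level AMOVA estimator; negative components are reported
as computed, with a flag, rather than truncated — for literally
identical group compositions the among-group sum of squares is exactly
zero and the unbiased estimator is therefore slightly negative, which
the tests assert explicitly.

`fst_test()` permutes whole individuals between groups (keeping each
individual's two haplotypes together, preserving within-individual
dependence), includes the observed arrangement in the p-value
(p ≥ 1/(n_perm+1)), and defaults to 10,000 seeded permutations.

# The haplotype network

`median_joining()` builds the minimum spanning network — retaining
*all* links co-minimal within ε of the weight at which components
join, never arbitrarily dropping ties, which is precisely what
produces reticulations such as the four-cycle among hap1, hap2, hap4
and hap6 in the ATG16L1 panel — then adds majority-per-site median
vectors for mutually linked triplets whose connection cost is within ε
of the best candidate, iterating until stable, and finally prunes
median vectors lying on no shortest path between observed haplotypes.
ε defaults to 0. All sites are weighted equally. With ε = 0 and a
unique minimum spanning tree the output is that tree, verified in the
suite against exhaustive spanning-tree enumeration.

`reticulations()` returns a fundamental cycle basis (one cycle per
non-tree edge) with, per cycle, the loci whose state changes on two or
more of its edges. A cycle is reported as a cycle: whether it reflects
recombination or recurrent mutation is not decidable from the graph,
and the package does not claim a mechanism.

# Cumulative mutation burden

The burden of a diploid genotype under a reference design is the sum
over its two (best-pair) haplotypes of Hamming distances to the
reference haplotype — the wild type (hap1 design) or the most frequent
haplotype (hap2 design). `burden_test()` compares groups with a
two-sided t-test, choosing the Welch unequal-variance form when
Levene's test (mean-centred, the common default) rejects homogeneity
at 0.05, and recording the branch taken. When the pooled within-group
variance is zero the t statistic degenerates: equal means give t = 0,
p = 1; unequal means fall back to the exact permutation distribution
of the mean difference over all group-label reassignments. The
closed-form expectation 2·Σ f_i·d(hap_i, ref) per group
(`expected_burden()`) anchors the simulation tests. Burdens use each
individual's best-pair assignment; posterior-weighted burden is out of
scope.

# Promoter motif scanning

`pwm_scores()` scores sequence windows against a JASPAR position
frequency matrix by log2 odds with background-split pseudocounts
(default total pseudocount 0.8, uniform background); the reverse
strand is scored on the reverse complement with coordinates mapped
back. `tfbs_delta()` rebuilds each haplotype's promoter sequence,
scans within a window of each SNP (default: motif length + 10 on each
side), and merges haplotypes with identical local sequence into allele
groups — a biallelic site yields at most two rows. The numeric scores
of proprietary web scanners are not reproducible from published
summaries; the package implements standard PSSM scoring and treats
published score tables as qualitative structure only. No score
threshold is applied by default: the best hit per group is always
reported.

# Problem sizes in the test suite

The suite runs at sizes chosen to finish in well under a minute while
leaving no statistical check underpowered: phasing consistency and
allele-frequency recovery use cohorts of 5,000 diploids; calibration
checks use 500 null replicates with 400 Monte-Carlo permutations each;
exhaustive oracles (phase enumeration, HWE tables, spanning trees,
label reassignments) run at the largest sizes where enumeration is
exact (≤5 individuals × 3 SNPs, tables with total ≤ 20, 5-node
graphs, 8 labels).

# Known limitations

* Two groups only; no hierarchical (three-level) AMOVA.
* Phasing excludes incomplete individuals rather than imputing.
* LD, divergence and burden all consume best-pair phase assignments;
  phase uncertainty is summarised by the per-individual posterior but
  not propagated into downstream tests.
* The burden comparison has no covariate adjustment.
* Published t-statistics, group burden means, and permutation p-values
  of the reference study depend on its individual-level genotypes,
  which are not available; the package reproduces the study's
  *qualitative* findings (haplotype counts, architecture, reticulation,
  significance directions) and validates the machinery against
  closed-form and enumeration oracles instead.
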