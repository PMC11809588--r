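---
title: "Models and design choices in phylodiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in phylodiag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phylodiag diagnoses two distinct failure modes of phylogenomic inference —
systematic bias in the gene sample, and genuine biological conflict between
gene trees and the species tree (incomplete lineage sorting, introgression,
hemiplasy) — and complements them with a likelihood toolkit for discrete
morphology on a molecular backbone. This vignette records the models, the
tunable parameters, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The synthetic data generator

Every stage is exercised against simulated data, so the generator is
first-class, tested code.

**Species trees** are forward-time Yule trees: from two lineages, each
lineage splits at rate λ (default 1 per coalescent unit), and one further
exponential waiting time is appended after the (n−1)-th split so pendant
branches are never zero. The expected root height is
(1/λ)·Σ_{k=2..n} 1/k, which the tests check directly. Branch lengths are
tagged as coalescent units.

**Gene trees** follow the multispecies coalescent with one haploid lineage
sampled per species — matching a design with one transcriptome per species
after de-duplication. Within each population, lineage pairs coalesce at
rate 1 per pair; populations merge at species-tree nodes. Introgression is
modelled as a single instantaneous pulse: viewed backward in time, each
lineage in the recipient population jumps to the donor population with
probability γ at the pulse time. This matches the detection model of the
D-statistic family; continuous migration is deliberately out of scope. The
binding calibration is the rooted-triplet discordance fraction
(2/3)·e^(−t) for an internal branch of t coalescent units.

**Sequences** evolve under the symmetric k-state model (k = 4 for DNA,
k = 20 for amino acids — the Poisson model). The closed forms this admits
(e.g. the Jukes–Cantor expected p-distance ¾(1−e^(−4d/3))) anchor the
tests; empirical profile mixtures are out of scope. **Morphological
characters** evolve under the same symmetric model (Mk) with per-character
gamma rate multipliers, and the true node states are recorded so
ancestral-state recovery can be scored. **Missingness** is injected by
thinning taxa from genes (or blanking cells) to exact per-taxon targets,
emulating the skewed occupancy of transcriptome sets in which the sparsest
taxa appear in fewer than 20 alignments.

Simulation study conditions used by the binding tests, chosen once as
realistic for this kind of data and then frozen: quartet species trees with
split times 1/2/3 coalescent units (so the focal internal branch is 1 CU);
μ = 0.01 per site per CU for the D-statistic loci (2,000–2,200 loci of 200
sites, giving ≈5×10⁴ biallelic informative sites per matrix); morphology on
trees rescaled to unit height with base rate 0.5 expected changes per
character per tree height and shape-1.5 gamma rate heterogeneity — a slow,
morphology-like regime in which characters retain phylogenetic signal.

## Gene-property filtering

Five per-orthogroup properties drive matrix construction: occupancy
(fraction of the study taxa present), total gene-tree length (the
substitution-rate proxy; the tree, not the alignment, carries the rate
signal), saturation, RCFV, and mean patristic distance (a long-branch
indicator). Ranking keeps the best K with ties broken lexicographically by
gene id, so subsets are deterministic and nested in K.

Saturation is defined as 1 − b, where b is the least-squares slope
*through the origin* of pairwise uncorrected p-distances on pairwise
patristic distances. The through-origin form is a modelling choice: a pair
at patristic distance zero has p-distance zero by construction, so a free
intercept would only absorb noise. Pairs missing from either the alignment
or the tree are skipped and counted. RCFV is computed on the declared
alphabet only, with gaps and unknowns excluded from the frequencies; a
taxon with no scored residue is an error rather than a silent zero.

## Patterson's D and its calibration

For the assumed topology (((P1,P2),P3),O), a site is informative when all
four residues are scored and exactly two states occur; the outgroup state
is ancestral. D = (ABBA − BABA)/(ABBA + BABA). The standard error comes
from a delete-one jackknife over contiguous column blocks (default 1,000
columns; the trailing remainder merges into the last block — the default is
ours, since the convention the workflow follows delegates the block size to
the implementation). Significance uses the |z| ≥ 3 convention, exposed as
a parameter. For amino-acid matrices, "biallelic" means exactly two
amino-acid states with no similarity grouping — the simplest faithful
extension of the SNP definition.

Two properties are binding: under the null (no pulse, 1-CU internal
branch) the mean D over replicate matrices is within ±0.02 of zero with a
false-positive rate below 5%, and a γ = 0.3 pulse is detected with the
correct sign in ≥90% of replicates at ≈5×10⁴ informative sites.

## The five-taxon D-FOIL-style system

On the symmetric topology ((P1,P2),(P3,P4),O) with the (P1,P2) split the
younger, the package counts the sixteen biallelic patterns of derived/
ancestral states and forms four statistics from the cross-pair sharing
patterns BABA (P1,P3), ABBA (P2,P3), BAAB (P1,P4) and ABAB (P2,P4):

- DFO = (BABA − ABAB)/(BABA + ABAB)
- DIL = (ABBA − BAAB)/(ABBA + BAAB)
- DFI = (BABA + BAAB − ABBA − ABAB)/total — which first-pair taxon
- DOL = (BABA + ABBA − BAAB − ABAB)/total — which second-pair taxon

Because P1/P2 and P3/P4 are exchangeable under the null, each statistic has
expectation zero without gene flow. The exact relabelling symmetries —
swapping P1/P2 exchanges DFO with DIL, negates DFI and fixes DOL; swapping
P3/P4 maps DFO to −DIL, negates DOL and fixes DFI — are asserted in the
tests on fixed data. Each statistic is tested by a two-sided binomial test
of its left against right totals (α = 0.01 per statistic), and the (DFI,
DOL) sign pair maps to a class: (+,+) P1↔P3, (−,+) P2↔P3, (+,−) P1↔P4,
(−,−) P2↔P4, (0,+)/(0,−) gene flow involving the (P1,P2) ancestral
lineage, all-zero none. This membership and signature table is our
reconstruction from the design constraints of the original five-taxon
system (null balance plus pair-discriminating symmetry), and the class
table was verified by coalescent simulation of all eight directed pulse
scenarios; direction of transfer within a pair (donor versus recipient) is
deliberately not claimed, because it rests on second-order pattern
asymmetries we chose not to over-interpret. Matrices with fewer than 100
informative sites (configurable) return "insufficient data".

## Hemiplasy risk factor

For a focal internal branch of length t coalescent units, each replicate
simulates the local rooted-triplet genealogy (the two descendant lineages
coalesce within the branch with probability 1−e^(−t); otherwise all three
lineages coalesce above it, with topology uniform), then considers a binary
trait mutating at rate μ per coalescent unit with state toggling. A
replicate whose polarized trait pattern groups a non-clade is *conflicting*;
it is *hemiplastic* when a single mutation on a discordant genealogy
produced it and *homoplastic* when two or more mutations did. HRF is the
hemiplastic fraction of conflicting replicates, reported over the
seven-rate grid 0.0001, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1.

Two numerical choices matter. First, summary-coalescent species trees
carry no terminal branch lengths in coalescent units, so the pendant
length of the flanking lineages is an explicit parameter (default 1 CU)
rather than a hidden guess. Second, the default estimator integrates the
Poisson mutation placement analytically given each simulated genealogy
(per-branch odd-parity probabilities (1−e^(−2μl))/2), which estimates the
same quantity as raw mutation sampling but with far lower variance — at
μ = 10⁻⁴ the expected number of conflicting replicates in 10⁵ draws is only
a handful, so the raw estimator cannot resolve the grid. The raw sampled
estimator is retained (`method = "sampled"`) and the tests check that the
two agree within Monte-Carlo error. Across a branch's μ grid the same
genealogy replicates are reused (common random numbers), so profiles are
smooth and monotone decreasing in μ, as the tests assert.

## The Mk engine

Likelihoods use Felsenstein pruning with a uniform 1/k root prior,
characters batched as matrices and per-node rescaling for stability.
Gamma rate variation uses equal-probability categories represented by
their means (four categories by default); the Lewis variable-characters
correction divides the category-averaged likelihood by one minus the
summed category-averaged likelihoods of the k constant patterns — i.e. the
correction is applied after category averaging, the standard composition.
Missing and inapplicable cells contribute all-ones partials; the distinct
treatment of inapplicability belongs to the distance module. Parsimony is
generalized Sankoff dynamic programming: unit costs for unordered
characters, |i−j| ladder costs for ordered ones (the ladder spans the full
range between the observed extremes, so a character observed only as 0 and
2 costs two steps). Everything is validated against exhaustive enumeration
over all ancestral assignments on ≤5-leaf fixtures to 10⁻¹⁰.

Marginal ancestral states use the standard inside–outside pass; with gamma,
per-category marginals are combined with the categories' posterior
weights. The ascertainment term cancels from these conditional
probabilities, so none is applied. A state is reported resolved where its
marginal exceeds the threshold (default 0.69, following the protocol the
package reproduces; the threshold is exposed).

## Morphology toolkit choices

**MORD** rescales Gower dissimilarities to [0,1]: for each pair, over the
characters where both taxa are scored, |a−b| divided by the character's
observed state range for ordered characters and an inequality indicator for
unordered ones, averaged. Inapplicable cells are treated as non-comparable
(excluded pairwise); the flag exists because published descriptions of the
convention are ambiguous, and exclusion is the conservative reading.
Pairs with no comparable character are flagged undefined rather than
silently zero.

**Implied weighting** scores each character as f = k/(k + es) with
concavity k = 3 by default and es the parsimony steps beyond the minimum
conceivable on the matrix. **Weight calibration** for placement computes
implied weights on the guide tree and rescales them to mean 1 — an
explicit, testable stand-in for the undocumented internal calibration of
the placement tool the protocol used, with the same intent: prioritize
characters consistent with the molecular hypothesis. **k-means
partitioning** of the homoplasy scores runs k = 1..10 with 25 restarts and
picks the k with the largest second difference of the total within-cluster
sum of squares (the published criterion names only "comparing the total
sum squared"; the elbow rule is ours, and an explicit k can override it).

**Placement** attaches the query at each edge's midpoint with a pendant
branch optimized over [10⁻⁸, 10] by golden-section/parabolic search; the
score is the weighted sum of per-character corrected log-likelihoods
(Γ₄ + Lewis by default). Attachment-point optimization along the edge is
deliberately omitted: morphological matrices carry little signal for
within-edge position, and midpoint attachment keeps scoring O(edges ×
characters). Reference trees without branch lengths get unit lengths with
a notice. The assigned group is the label of the clade below the best
edge (majority label with alphabetical tie-break when the clade is mixed).
Partials in this path are kept unscaled, which is safe for
morphology-scale problems (≲ a few hundred tips, k ≤ 10) but would
underflow on very large trees.

**Rate-shift tests** fit one rate multiplier per partition block of
branches and/or characters by maximizing the Mk likelihood (box-constrained
quasi-Newton on log rates; the first character-block rate is pinned to 1
when both partition types are free, for identifiability), and compare
schemes by AIC weight w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2). Missing cells are
uncertainty over all states; inapplicable cells are treated as missing.

**Molecular distances** from the most complete genes use the closed-form
symmetric-model (Poisson) ML distance −((k−1)/k)·log(1 − k p/(k−1)) on the
sites both sequences score, or delegate to `phangorn::dist.ml` for
empirical amino-acid models such as LG. Saturated pairs (p beyond the
model's plateau) are flagged rather than truncated.

## What the simulations do and do not show

The generator reproduces the features the diagnostics are sensitive to —
coalescent discordance, pulse introgression, rate heterogeneity, skewed
occupancy, missing morphology — under symmetric substitution models with
i.i.d. sites and no alignment error. Passing tests therefore demonstrate
correctness of the statistics and calibration under the stated models, not
robustness to compositional attraction, alignment artefacts, model
misspecification or correlated characters, all of which real transcriptome
and morphology data contain. The problem sizes used by the binding tests
(e.g. 100–200 replicate matrices of 2,000 loci, 10⁵ Monte-Carlo
genealogies, 20-taxon placement fixtures) were chosen as the smallest at
which the closed-form expectations are sharp relative to Monte-Carlo
error.

## Known limitations

Gene flow is a single pulse, not continuous migration; D-FOIL direction
polarization is not attempted; the Mk engine has no asymmetric or
ordered-rate variants and no tree search; the placement scorer does not
optimize attachment position within an edge; HRF assumes the
infinite-sites-like binary trait of its definition. These follow the scope
of the analysis layer the package implements.
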