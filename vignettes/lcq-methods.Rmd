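---
title: "Models and methods in lcq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lcq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcq)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
establish. It states no empirical result that the test suite does not
itself compute.

## The line-cross setting

Two founder lines, A and B, are crossed to produce F1 individuals, and
F1 × F1 (F2) or F1 × founder (backcross, BC) matings produce the mapping
generation. When the lines are inbred, every line-A allele is identical
across founders and QTL mapping reduces to tracking *line origin*. With
outbred founders two complications arise: markers are only partially
informative about line origin, and a QTL may *segregate within a line*
(frequency of the increasing allele `f_A` strictly between 0 and 1), in
which case a line-origin contrast has little or no mean effect and a
variance-component formulation is needed. `lcq` implements both routes.

## Line-origin hidden Markov model

For each offspring the hidden state at a locus is the ordered pair of
founder-line origins of its paternal and maternal gamete —
(AA, AB, BA, BB) for an F2; for a BC the founder parent's gamete origin
is fixed, leaving two states. The two gametes recombine independently,
so the transition matrix between loci at distance `d` cM is the
Kronecker product of two 2-state chains with switch probability given by
the Haldane map function `r = (1 − exp(−2d/100))/2`. The same map
function drives the simulator's crossover process (Poisson, rate 1 per
100 cM, no interference), so the HMM is exactly matched to the
generative model; crossover interference (Kosambi and relatives) is
deliberately out of scope because the simulator/HMM pair would no longer
be mutually consistent.

Emissions require the distribution of the allele carried on each F1
parent's line-A-derived and line-B-derived homolog. These are inferred
per marker (`infer_f1_homolog_dists`): founder genotypes force the phase
where possible; otherwise the parent-conditional transmission
distribution applies, falling back to line allele frequencies estimated
from the founders (`estimate_line_freqs`, counting estimator with a 0.5
pseudocount per observed allele so no emission is ever exactly zero).
The F1's own genotype always constrains the pair of homolog alleles;
a non-Mendelian conflict yields a finding and the marker is treated as
missing for that F1. This two-layer factorisation (phase inference, then
per-offspring chains) is exact for inbred lines and a principled
approximation for outbred pedigrees; its marginals are verified against
exhaustive enumeration over all ordered origin sequences on every test
instance with few markers, which is the strongest statement the package
makes about correctness of the chain algebra.

Emissions are mixed with a uniform genotyping-error component,
`(1 − ε)P + εU` with `ε = 0.001` by default — enough to absorb isolated
Mendelian conflicts without modelling an error process. Grid positions
(step `Δ` cM, chromosome end always included) are silent states.
Numerical stability is by per-locus rescaling of the forward and
backward vectors; a 1,000-marker chromosome stays finite.

On a sex chromosome only homogametic-sex offspring are processed
(a dosage model for the heterogametic sex is out of scope); the
simulator likewise only produces autosomes, so the sex-chromosome path
is exercised with hand-built fixtures.

Note one identifiability fact visible in the output: with symmetric
parental information the ordered heterozygous states AB and BA are
indistinguishable and receive equal posterior mass. All downstream
predictors use sums or differences that are invariant to this symmetry.

## Least-squares scan

At each grid position the trait is regressed on
`a = P(AA) − P(BB)` and `d = P(AB) + P(BA)` (Haley–Knott), plus
covariates, and compared with the covariates-only null by an F test
(2 numerator df for F2, 1 for BC). Missing phenotypes are dropped
listwise; predictors are never missing by construction. A perfect fit
(zero residual sum of squares) is reported as a capped statistic
(`F = 1e12`, flagged `perfect_fit`) rather than infinity; rank-deficient
genetic blocks (e.g. a constant dominance column) are reduced with a df
adjustment and flagged. The two-locus scan adds the four products
(a₁a₂, a₁d₂, d₁a₂, d₁d₂) and tests them with a 4-df F test on a coarser
pair grid (default 5 cM) excluding same-chromosome pairs closer than
20 cM — a collinearity guard, since nearby positions carry nearly
identical predictors.

Genome-wide significance uses the permutation scheme of shuffling trait
values across analysed individuals while keeping all predictors fixed,
recording the genome-wide maximum statistic, and taking empirical
quantiles (type-7). Permuting rows of the phenotype only preserves the
genotype-probability structure exactly. We permute across all analysed
individuals; within-family permutation would also be defensible when
family effects are present, but the package's simulated worlds have
none. For sex-chromosome scans the permutation is within the
homogametic subset, which is the analysed set.

## NOIA orthogonal effects

The statistical formulation of the natural and orthogonal interactions
model defines, for genotype frequencies `(p11, p12, p22)` (2, 1, 0
copies of the line-A allele), a 3×3 design whose additive column is
`(−p12 − 2 p22, 1 − p12 − 2 p22, 2 − p12 − 2 p22)` and whose dominance
column is `(−2 p12 p22, 4 p11 p22, −2 p11 p12)/D`,
`D = p11 + p22 − (p11 − p22)²`. The frequency-weighted Gram matrix of
this design is diagonal, which is what makes the estimates orthogonal:
dropping or adding the dominance term does not move the additive
estimate at the reference frequencies. When `D = 0` (fewer than three
genotype classes) the dominance scale does not exist and the design
degenerates to 3×2 with a flag. At F2 frequencies (1/4, 1/2, 1/4) the
scales reduce to the classical (−1, 0, 1) and (−1/2, 1/2, −1/2). Note
the sign convention: the additive scale *rises* towards the g22 class
(zero copies of the line-A allele), so a trait that increases with
line-A dosage has a negative NOIA `alpha`, the mirror image of the
scan's `a` coding.

Effects are estimated by regressing the trait on each individual's
*expected* scale values (posterior genotype probabilities times the
design); whether the original implementations use this or a
full-information method is not documented, and the regression contract
is the testable choice. The default reference population is the sample
(mean genotype probabilities), where orthogonality holds exactly;
`F2` and user-supplied frequencies are alternatives. Change of
reference is the linear map `E₂ = S₂⁻¹S₁E₁`, which preserves genotypic
values exactly; multi-locus maps use Kronecker products of per-locus
designs under an explicit linkage-equilibrium assumption (≤ 4 loci).

## MCIBD and the FIA scan

The locus IBD matrix Π has entries
`Π_ij = E[# IBD pairs among the four (allele of i, allele of j) pairs]/2`
— the additive-relationship scale, diagonal `1 + F_i`. Founders are
assumed non-inbred and mutually unrelated, so each founder homolog gets
a unique label. Each Monte-Carlo iteration samples (i) every offspring's
ordered origin state at the position from its posterior, (ii) for every
F1 homolog, which of the corresponding founder's two homologs it copies
— a 2-state chain with Haldane transitions, conditioned on founder/F1
marker genotypes where informative and uniform otherwise — then
propagates labels and counts sharing. Because a single position is
evaluated at a time and offspring chains are conditionally independent
given the F1 homolog distributions, sampling each offspring's state from
its single-locus marginal is exact; the shared segregation indicators
(one draw per F1 homolog per iteration) carry the between-individual
dependence that makes Π more than a product of marginals. The averaged
matrix is symmetrised and negative eigenvalues are clipped at zero.
Defaults: 200 samples per position; the segregation-chain emissions
treat the stored founder allele-pair order as the phase, exact for
homozygous or uniquely-tagged founders and uniform (hence harmless)
otherwise. The estimator is validated against exhaustive descent
enumeration on a toy pedigree and against realised founder labels from
the simulator.

The variance model is `y = Xβ + g + e`, `g ~ N(0, σ²_g Π)`,
`e ~ N(0, σ²_e I)`, fitted by REML profiled over `λ = σ²_g/σ²_e` with a
one-dimensional search (tolerance 1e-6, boundary `λ = 0` allowed, flat
profiles flagged as boundary) on the spectral decomposition of Π.
Significance uses the standardised score
`U = (r'Πr/σ̂² − tr(MΠ)) / sqrt(2 tr((MΠ)²))` with `M` the null
projection; all inferential weight rests on permutation of the trait
values with the genome-wide maximum score, never on the normal
approximation. A single locus component is fitted; a polygenic
background component is a known omission.

The fixed-versus-segregating comparison is a REML log-likelihood ratio
between Π from MCIBD and the line-cross matrix Π_LC implied by fixation
(all line-A alleles mutually IBD; entries from per-gamete line-origin
marginals, diagonal `1 + P(AA) + P(BB)`). The design choice that
matters: `fia_scan` augments the fixed effects with the position's
Haley–Knott predictors before computing this LR. The fixation
hypothesis is a statement about the *mean* (line origin determines the
genetic value), so it belongs in X; with covariates-only X the LR is
systematically negative under true fixation because the unmodelled
line-origin mean signal is better absorbed by Π_LC than by the finer
founder-level Π — simulation during development showed exactly this.
With the predictors in X the LR concentrates near zero under fixation
and goes positive under within-line segregation, which is the behaviour
the test suite asserts. The exported `segregation_lr` takes X from the
caller, so both conventions are available.

## The simulator as a stated world

`simulate_cross` draws founder genotypes from one of three marker
models — `line_private` (fixed line differences: the inbred-lines
idealisation), `shared` (two alleles at frequencies `p_A`/`p_B` in the
two lines: realistic partially informative SNPs), `founder_unique`
(every founder homolog privately tagged: descent fully observable, used
for truth-mode IBD checks) — then simulates meiosis with Poisson
crossovers and records every individual's two homologs as
founder-homolog segment lists. QTL effects follow the usual
(−a, d, +a) genotype coding with per-line allele frequencies
`(f_A, f_B)`; pairwise epistasis adds the four product terms; the
phenotype adds an optional sex effect and Gaussian noise (default
residual SD 1, so effects are in residual-SD units). Default design:
2 founders per line, 4 F1s, offspring allocated round-robin to F1
couples — small full-sib families, as in real line crosses. Genotype
observation error is off by default; when on, a corrupted genotype is a
uniform draw over the marker's allele pairs.

What a green test establishes is therefore conditional on this world:
no genotyping-error process in the default tests, no crossover
interference, no polygenic background, no family environmental effects,
founders unrelated. The acceptance experiments state their own
parameters (e.g. type-I calibration at n = 200 with 20 markers over
100 cM; localisation at n = 500 with a = 0.5 SD; FIA power at n = 400,
`f_A = 0.5`, a = 1 SD — the effect size chosen for the power contrast is
1 residual SD, a moderate QTL, fixed before any results were inspected).

## Numerical choices and degenerate inputs

* Probabilities are renormalised per locus; posterior vectors sum to 1
  within 1e-9.
* `F = 1e12` is the perfect-fit sentinel; output files never contain
  infinities.
* The REML search interval is `λ ∈ [0, 1e4]`; a profile improvement
  below 1e-6 over the boundary returns `λ = 0` flagged `boundary`
  (this also covers `Π ∝ I`, where `λ` is unidentifiable).
* PSD repair clips negative eigenvalues at zero; post-repair minimum
  eigenvalues are ≥ −1e-8.
* Ties in `which.max` resolve to the first (leftmost) position.
* Generation labels are inferred structurally when absent (no parents →
  founder; founder×founder across lines → F1; F1×F1 → F2; F1×founder →
  BC); pedigrees are topologically sorted on load; founder lines are
  two-coloured from the mating graph when unlabelled, anchoring each
  component's first founder to line A (ambiguous only when components
  are disconnected *and* unlabelled).

## Known limitations

Deep (advanced intercross) pedigrees, more than two founder lines,
composite-interval or multi-QTL models, bootstrap confidence intervals
for QTL location, FDR-style multiplicity control, genotyping-error-rate
estimation and a heterogametic-sex dosage model are all out of scope.
The `.gen` reader implements a documented simplified dialect, not a
bit-exact CRI-MAP clone.
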