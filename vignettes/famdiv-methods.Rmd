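---
title: "Methods: models, estimators and design choices in famdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in famdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

famdiv studies how a tandemly duplicated gene family — the motivating case is
the CEACAM/PSG cluster on human chromosome 19 — diverges, both across species
(tandem duplication versus whole-genome duplication) and within humans
(population differentiation of SNPs and copy-number variants). This vignette
is the package's account of the science behind each stage: the models, their
assumptions, the tunable parameters, and the choices made where the
methodology was genuinely open.

## Synteny-based duplication classification

**Model.** Orthology of single-copy *marker* genes (e.g. TGFB1, ATP1A3,
TOMM40, APOE around the CEACAM/PSG locus) is taken as input; no sequence
comparison is performed. `find_blocks()` chains query-species markers, sorted
by position, into syntenic blocks: consecutive markers join one block when
they share a query chromosome, their reference partners share a reference
chromosome, and the query gap is at most `max_gap`. Chains shorter than
`min_markers` are dropped. A reference marker with orthologs on two query
chromosomes (TOMM40a/TOMM40b-style duplicated anchors) seeds two blocks over
the same reference region — the signature of a duplicated block.

`classify_duplicates()` then applies rules in a fixed precedence:

1. family genes chained transitively within `tandem_gap` on one chromosome
   form a **tandem** call;
2. single genes in two blocks that share reference markers but occupy
   different query chromosomes are paired as **wgd_coortholog**;
3. a lone gene in exactly one block is a **singleton**;
4. genes in no block, or ambiguously in several overlapping blocks, are
   **unresolved** (with a warning — never a silent tie-break).

**Parameters.** `tandem_gap` defaults to 500 kb: published locus maps place
tandem family members tens to a few hundred kb apart, and "neighbouring" has
no published quantification, so the default is permissive and is echoed in
every run's metadata sidecar. `min_markers = 2` and `max_gap = 2 Mb` reflect
marker densities of real locus maps (2–8 markers over ~10 Mb). A tandem
array inside a duplicated block keeps its tandem label; the block pairing is
recorded as evidence, so WGD ancestry of whole arrays remains visible without
double-assigning genes.

**Assumptions and limits.** Strand is carried but ignored; inversions and
translocations inside a block are invisible to the chaining; classification
reports evidence, not certainty — no confidence score is computed because
none is defined for this kind of curated-map inference.

## Per-SNP F_ST and empirical brackets

**Estimator.** `fst_scan()` implements the Weir–Cockerham (1984) unbiased
estimator from the a/b/c variance components (among populations, among
individuals within populations, within individuals), computed from
per-population allele frequencies, sample sizes and observed
heterozygosities: `theta = a/(a+b+c)`. Missing genotypes are dropped per
population; a SNP monomorphic across the retained populations, or with fewer
than two informative populations, is *undefined* — flagged `NA`, not zero —
and excluded from ranking. Negative estimates at weakly differentiated SNPs
are expected and kept.

`fst_global()` provides the aggregate over a SNP set as the standard ratio
of sums, `sum(a)/sum(a+b+c)`. The mean of per-SNP ratio estimates is *not*
used as an aggregate: it carries a systematic downward Jensen bias that grows
with differentiation (about −15% at F = 0.2 with three populations of 60),
whereas the ratio of sums recovers the generating F within a few percent.
Per-SNP estimates remain the ranking statistic, since selection scans rank
individual SNPs.

**Brackets.** `rank_brackets()` computes percentile ranks over all defined
estimates in the supplied SNP set — the ranking universe is a run-level
choice (chromosome-wide or genome-wide), not hard-coded. A bracket of q%
flags the `floor(n*q/100)` largest values; ties with the cut value are
promoted into the better bracket, so bracket membership is monotone
(top-1 ⊆ top-5 ⊆ top-10 ⊆ top-15). Tie promotion is the conservative choice:
a tie never decides against a SNP.

**Enrichment and density.** `family_enrichment()` contrasts each family's
fraction of flagged genes with a conserved background by a 2×2 chi-squared
test without Yates correction; when no gene is flagged anywhere the test is
degenerate and p = 1 is reported by convention. `snp_density()` summarises
per-gene synonymous/nonsynonymous SNP counts as means ± SEM
(SEM = sd/sqrt(n)), compares means by Welch's t-test (robust to the unequal
variances of family versus background counts) and the fractions of genes
with ≥ 1 nonsynonymous SNP by chi-squared. No multiple-testing correction is
applied: the outputs are raw bracket memberships and single contrasts, to be
interpreted as such.

## Linkage disequilibrium

`ld_r2()` estimates two-locus haplotype frequencies from unphased diploid
genotypes by maximum likelihood. Every genotype combination except the
double heterozygote determines its two haplotypes; the cis/trans split of
double heterozygotes is resolved by EM, initialised at linkage equilibrium,
with tolerance 1e-10 on the frequency change and a 1000-iteration cap
(non-convergence is an error naming the cap, not a silent result).
`r^2 = D^2 / (pA(1-pA) pB(1-pB))`, clamped into [0, 1]; denominators below
1e-12 (monomorphic pairs after pairwise deletion of missing data) are
undefined. `ld_blocks()` defines a block as a maximal run of consecutive,
position-ordered SNPs in which *every adjacent pair* has r² at or above the
threshold (default 0.8). This adjacency-chain rule is a deliberate
simplification of confidence-interval-based block finding: it
operationalises an r²-threshold definition directly and is trivially
auditable. Missing adjacent estimates break a chain.

## CNV calculus

The copy-number model is a signed event calculus: starting from an explicit
per-gene diploid baseline, each loss event removes and each gain event adds
one copy of every gene the CNV overlaps, so a homozygous (event count 2)
loss over five genes removes ten gene copies. With an 11-gene family
baseline of 22 copies, homozygosity for a five-gene loss gives 12 and
homozygosity for a four-gene gain gives 30 — the package reproduces this
arithmetic exactly. Multi-copy amplifications per event are out of scope;
records of type `both` cannot be genotyped without a per-individual
direction and are rejected rather than guessed. Copy numbers are floored at
zero with a warning.

`copy_number_range()` enumerates all `3^k` genotype combinations (capped at
k = 12 CNVs) because CNVs overlapping shared genes make per-CNV greedy
bounds wrong; the flooring also makes the total non-additive near zero, and
enumeration is exact in both respects. Frequency and length thresholds are
strict inequalities ("larger than 500 bp", "frequency higher than 1%"), and
a CNV with no frequency information is flagged *unknown*, never treated as
rare. The family baseline is always an explicit input — whether a
potentially pseudogenised member is counted in the family is a judgement the
caller must make, not the package.

## Synthetic data: what it emulates, and what it does not

`simulate_genotype_panel()` draws per-SNP ancestral frequencies (by default
uniform on 0.05–0.95, mimicking a common-SNP genotyping panel), then
population frequencies from the Balding–Nichols beta model
`Beta(p(1-F)/F, (1-p)(1-F)/F)`, so that the among-population variance is
`F·p(1-p)`, and finally diploid genotypes as Binomial(2, p_k).
Balding–Nichols is the standard F_ST-parameterised stand-in when no
demographic model is specified. Defaults — three populations of 60
individuals, F = 0.10 — describe HapMap-II-scale panels of continental
populations. Per-gene SNP counts are Poisson with family-specific means; the
defaults (nonsynonymous 8.3 per family gene versus 3.8 per background gene,
synonymous 4.2 versus 3.6) are the observed chromosome-19 coding-SNP
densities for this family, so the generator reproduces the density contrast
the analyses are designed to detect.

The generator deliberately does **not** emulate: SNP ascertainment bias of
historical SNP databases (so published per-gene averages are a parameter
choice here, not a replication target), linkage disequilibrium decay (LD
tests use directly constructed haplotype configurations instead), mutation
on genealogies (no coalescent), or CNV–SNP correlation. Passing tests on
simulated panels therefore demonstrate parameter recovery and internal
consistency — not that real data would give the published values.

`simulate_gene_landscape()` writes marker-anchored landscapes with known
truth labels (tandem arrays of ≥ 2 genes 50 kb apart, WGD fragment pairs
carrying duplicated marker orthologs, singleton blocks), each archetype on
its own chromosome pair; classifier recovery on 20 seeded landscapes is the
acceptance property for the synteny module. All generators run under a
single master seed with derived sub-streams, restore the caller's RNG state,
and are bit-reproducible.

## Numerical and interface choices

- Coordinates are 0-based half-open everywhere internally; GFF3's 1-based
  closed convention is converted at the I/O boundary only, and the
  conversion is an involution (tested by byte-identical write–read–write).
- Genotypes are stored as counts of the non-reference allele;
  ancestral/derived polarity is a separate per-SNP flag, never a recoding.
- Overlap queries share one half-open primitive: touching intervals do not
  overlap.
- Missing data policy: pairwise deletion for LD, per-population deletion for
  F_ST, never imputation.
- The pipeline writes plain TSV outputs with JSON metadata sidecars
  (parameters, seed, package version, input checksums) instead of using a
  workflow engine, so a run is inspectable and diffable; identical
  configuration and seed give a byte-identical output tree, and the report
  contains only numbers read back from stage outputs.

## Problem sizes used by the test suite

The packaged checks size their simulations to be decisive yet quick: F_ST
parameter recovery uses 5,000 SNPs across 3 × 60 individuals at
F ∈ {0.02, 0.05, 0.10, 0.20} with three seeds each (relative error under
10%, observed ~3%); the density power check uses 200 genes over 100 seeds;
classifier recovery uses 20 landscapes; enumeration bounds are checked
against 10,000 sampled CNV genotype profiles; the end-to-end determinism
check runs the pipeline twice at 200–400 SNPs. These sizes are the package's
own calibration choices and are stated here so they can be scaled up
deliberately rather than discovered in test code.

## Known limitations

Synteny chaining has no inversion model and one gap parameter; the LD module
phases only SNP pairs (no multi-SNP haplotypes or extended-haplotype
statistics); the CNV calculus assumes one copy gained/lost per event per
overlapped gene; enrichment contrasts are unadjusted single tests; and the
synthetic data's idealisations mean quantitative agreement with published
population-scale tables is out of reach by design — worked examples on
published count structures, parameter recovery, and internal invariants are
the supported evidence.
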