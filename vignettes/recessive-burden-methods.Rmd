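---
title: "Methods: recessive collapsing, Firth burden testing and cohort structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive collapsing, Firth burden testing and cohort structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(recburden)
```

# Overview

`recburden` tests whether cases of a binary phenotype are enriched in rare
*recessive* genotypes — homozygous, compound heterozygous or hemizygous —
over a pre-specified candidate gene panel, relative to controls drawn from
the same (structured) population. The motivating application is inborn
errors of type I interferon immunity in children with COVID-19 pneumonia,
where the candidate panel comprises the 15 loci with known recessive,
biochemically complete defects of type I IFN induction or response, of
which only *TLR7* is X-linked.

The pipeline is deliberately stage-structured, because each stage answers a
different threat to validity:

| stage | threat addressed |
|---|---|
| genotype/site QC | sequencing artefacts mimicking rare genotypes |
| candidate selection | benign variation diluting the carrier definition |
| recessive collapsing | genotype-to-mechanism mapping, cis/trans phase |
| PCA covariates | ancestry-driven confounding of carrier frequency |
| kinship filtering | pseudo-replication from related individuals |
| ROH consanguinity | excess homozygosity as both confounder and covariate of interest |
| Firth burden test | separation (zero carrier cells) breaking ordinary logistic ML |

# Models and procedures

## Genotype and site quality control

A genotype is set missing iff depth `< 8`, genotype quality `< 20`, or —
for *heterozygous* diploid calls only — the minor-read ratio
`min(ref, alt)/(ref + alt) < 0.20`. All three bounds are strict, so a call
at exactly DP 8 / GQ 20 / ratio 0.20 survives. The ratio rule is restricted
to heterozygotes because for a homozygous or hemizygous call the
least-covered allele is expected near zero coverage and the rule would
reject essentially every good call; hemizygous calls are marked in the data
model (`hemi` column) precisely so the filter can honour this. A
heterozygous call with no usable allele depths is set missing under its own
log reason rather than silently retained.

Sites are then dropped if masked (low-complexity/decoy BED), multiallelic
with more than 4 ALT alleles at the locus (counted before biallelic
splitting, so the rule is well defined), more than 10% missing after
genotype filtering, or spanning more than 15 nt. Both filters are
idempotent and monotone in their thresholds; tests assert both properties.

## Candidate variant classes

The primary analysis set is: consequence in {missense, pLOF, essential
splice}, population MAF `< 1e-4`, and CADD strictly greater than the
gene-specific mutation significance cutoff (MSC). "Strictly greater" is the
verbatim reading of the rule; a config flag (`msc_strict = FALSE`) switches
to `>=` for sensitivity analysis. Three companion sets support secondary
and calibration analyses: pLOF within the primary set; pLOF with no MAF or
CADD restriction; and rare synonymous variants (negative control — a
well-calibrated covariate-adjusted test should find nothing there).
Essential-splice status is taken from the annotation input; the package
does not recompute consequences.

## Recessive collapsing

Per sample per gene, in priority order: homozygous (any qualifying site at
dosage 2), homozygous deletion (from precomputed CNV calls overlapping a
panel gene, treated as a pLOF homozygous mechanism), hemizygous (male,
X-linked gene, dosage 1), compound heterozygous (two or more distinct
qualifying heterozygous sites). With genotyped parents, a compound
heterozygote is *confirmed* when some site pair is established in trans
(each parent carries exactly one of the pair) and *discarded* when every
pair is established in cis; otherwise it stays *potential* and counts as a
carrier — without parental data one cannot phase, and excluding potential
compound heterozygotes would bias the carrier count downward
asymmetrically in consanguineous versus outbred families. One call per
sample-gene is emitted (the strongest mechanism); carrier status is "has at
least one call in the set", which is what the burden test consumes.

Male X heterozygous diploid calls are biologically inconsistent; the loader
sets them missing and counts them in an anomaly log rather than letting
them create hemizygous carriers. Pseudo-autosomal regions are out of model
(the only X-linked panel gene is non-PAR).

## Ancestry, kinship, consanguinity

**PCA.** Common well-called sites (MAF > 0.01, call rate > 0.99) are
mean-imputed, centred by `2p` and scaled by `sqrt(2p(1-p))`; scores are
projections on the top right-singular directions, computed through the
sample-by-sample cross-product (exact, and cheap when SNPs outnumber
samples). The first five PCs are the default burden-test covariates.

**Kinship.** The KING-robust between-family estimator
`phi = (N_both_het - 2 N_opp_hom) / (N_het_i + N_het_j)` over sites
non-missing in both samples, with degrees at the standard thresholds
(0.354 / 0.177 / 0.0884 / 0.0442). The estimator is exactly 0.5 for
duplicates and requires no allele-frequency estimates, which is what makes
it robust in structured cohorts: unrelated cross-population pairs come out
*negative* (around −0.11 at F~ST~ 0.1), never crossing the relatedness
threshold. The unrelated subset removes one sample per related pair by
greedy maximum-degree elimination; ties prefer removing controls, then
non-carriers, then the lexicographically larger ID. The preference order
keeps analysis power and makes the retained set deterministic.

**ROH.** A PLINK-style scan: windows of 50 consecutive SNVs whose span is
at most 1,000 kb are called homozygous if they contain at most 1
heterozygote and 5 missing calls; an SNV is in a run if at least 5% of the
valid windows covering it are homozygous; maximal runs with at least 100
SNVs and 1,000 kb are reported. Only the window size (1,000 kb / 50 SNVs)
is a published setting; the secondary parameters follow the scanning
tool's conventional defaults and are all exposed in `filter_config()`. The
homozygosity rate divides total run length by the *mapped* autosomal
extent (per-chromosome max − min SNV position): exome maps have no
calibrated genome length, and this denominator is deterministic and
testable. Samples above 1% are flagged as born to consanguineous parents.

## Firth-penalized burden test

The burden test is a logistic regression of case status on the carrier
indicator plus covariates, maximizing the Jeffreys-penalized likelihood

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det\!\big(X^\top W X\big),
\qquad W = \mathrm{diag}(\pi_i(1-\pi_i)),$$

by Newton steps on the modified score
$U_r^* = \sum_i (y_i - \pi_i + h_i(\tfrac12 - \pi_i))x_{ir}$, with
step-halving on any penalized-likelihood decrease and convergence when the
largest coefficient update falls below 1e-8 (at most 100 iterations). The
penalty removes the O(1/n) bias of ML and keeps estimates finite under
complete separation — the situation that actually occurs here, since
several variant sets have zero carrier controls. On an
intercept-plus-indicator design the estimator coincides with adding 0.5 to
every cell of the 2×2 table, which provides a closed-form oracle used
throughout the tests; a brute-force grid maximizer of $\ell^*$ provides a
second, derivative-free oracle.

Inference is by penalized likelihood-ratio test — the tested coefficient
is fixed at zero, the others re-maximized, with the penalty always
evaluated on the full design — against chi-squared with 1 df, matching the
"likelihood ratio" wording of the reference methodology; Wald statistics
are available via `tidy(fit, wald = TRUE)`. Confidence bounds are profile
penalized-likelihood roots found by bisection to coefficient tolerance
1e-6, with a Wald fallback (and a warning) if a bound cannot be bracketed.
A constant carrier indicator yields p = 1 with a warning rather than an
error, so pipeline runs on carrier-free sets do not crash.

Type-I error of the covariate-adjusted test is checked by simulation: 200
null cohorts with two-population structure, ancestry-biased carrier
planting and ancestry-biased case sampling (so the unadjusted test is
confounded); the adjusted rejection rate at α = 0.05 must stay within
[0.02, 0.10].

## Population recessive genotype frequency

For qualifying allele frequencies $q_1,\dots,q_k$ at one gene, the
cumulative MAF is $Q=\sum q_i$ and the random-mating recessive genotype
frequency is $Q^2$ (autosomal; homozygotes plus compound heterozygotes) or
$mQ + (1-m)Q^2$ (X-linked, male fraction $m$). $\sum q_i$ is used rather
than $1-\prod(1-q_i)$: at the frequencies involved the difference is below
1e-8 and the sum is the conventional reporting scale. Panel aggregates add
per-gene figures (rare-event additivity); a forward simulation of 10⁷
random-mating individuals serves as the independent oracle. gnomAD
extraction is out of scope — the module consumes a table of allele
frequencies.

# The synthetic cohort generator

`simulate_cohort()` emulates exactly the statistical structure the
analysis assumes, not sequencing reality:

- **Population structure**: subpopulation allele frequencies follow a
  Balding–Nichols law around ancestral frequencies drawn U(0.05, 0.5);
  genotypes are Hardy–Weinberg within subpopulation. Per-group population
  weights create ancestry-outcome confounding on demand.
- **Scaled genome**: 22 autosomes × 13 Mb (plus an X of the same length).
  The scale-down keeps the *published* ROH window (1,000 kb, 50 SNVs)
  satisfiable at simulation-sized SNP counts — at the default fixture
  density (~18 kb between SNVs) a 50-SNV window spans ~0.9 Mb, inside the
  1,000-kb cap, exactly as in a dense exome map.
- **Consanguinity**: autozygous blocks overlaid on flagged samples. The
  total autozygous length is made *equal* to F × (mapped extent) — blocks
  of equal length at random non-overlapping positions — rather than
  random with mean F. This satisfies "expected fraction = F" exactly and
  is a variance-reduction choice: the >1% consanguinity flag then has a
  deterministic truth value per sample, which the exact fixture
  reproduction requires. Above F = 0.4 the generator switches to one long
  block per chromosome.
- **Planted carriers**: requested per gene/mechanism/group (optionally
  per population); compound heterozygotes receive two distinct qualifying
  sites; hemizygous plants are validated to be male and X-linked.
  Background alternate alleles at panel variants are heterozygous only, at
  most one qualifying site per gene per sample, and never given to males
  on X — so the generator *cannot* create spontaneous recessive genotypes
  and the truth table is exhaustive. This is what makes
  "precision = recall = 1" a meaningful exact test rather than a
  statistical statement.
- **Relatives**: sibling pairs and parent-offspring trios are generated by
  per-SNP independent transmission from simulated parental haplotypes.
  This gives the correct expected kinship for the KING estimator (which is
  a per-site method) without modelling linkage. Trio parents carry the
  planted compound-het alleles in trans.
- **QC noise** (optional): negative-binomial depth, Gaussian GQ, binomial
  het allele balance, uniform missingness — enough to exercise every
  filter reason, with no attempt at error-mode realism.

What passing tests therefore do **not** show: robustness to LD (none is
simulated; PCA and ROH behave more smoothly on real data), to annotation
error (consequences and CADD are taken as given), to batch effects between
sequencing platforms, or to genuinely random autozygosity totals.

## The fixture cohort

`pediatric_cohort_fixture()` instantiates the published cohort layout:
112 patients (78 boys; 25/15/72 moderate/severe/critical), 1,224 controls
(306 male), 12 deleterious-genotype patients (1 STAT2 compound het, 3 TYK2
homozygotes, 7 TLR7 hemizygotes, 1 IFNAR1 homozygous deletion with the
published severity grades), 3 neutral-genotype controls, 26/75
consanguineous patients/controls (F = 0.0625), and four related patient
pairs planted as full siblings. The two related pairs beyond the TLR7
carrier pairs are not characterized in the source; the fixture makes them
non-carrier *critical* pairs — the unique assignment under which the
unrelated denominators (108 patients, 70 critical) and all carrier
percentages are reproduced simultaneously. The STAT2 patient has no
genotyped parents, so collapsing reports the compound heterozygote as
*potential* — matching how that carrier was counted. The fixture is
noise-free by design: quality filters must pass everything, making the
printed proportions a deterministic function of the layout.

# Numerical and design choices

- **Rounding**: reported percentages use round-half-up at one decimal
  (two for the sub-1% control carrier percentage), reproducing the printed
  values 10.7 / 0.25 / 9.3 / 23.2 / 6.1 / 9.0 / 4.6 / 5.7 and ratio 2.3.
- **Variant identity**: `(chrom, pos, ref, alt)` after trailing/leading
  base trimming; multiallelic rows split with per-allele depths; the
  pre-split ALT count feeds the >4-allele filter.
- **BED convention**: `[s, e)` half-open masks 1-based positions
  `s+1..e`; property-tested against a per-base oracle.
- **Multiple calls per gene**: a sample homozygous at one site and
  heterozygous at others yields one call (strongest mechanism), since
  carrier status, not call multiplicity, enters the test.
- **Fisher tests** (consanguinity-by-status, carrier-by-consanguinity) are
  two-sided by the hypergeometric point-probability rule — the default
  convention of standard software; the observed-probability comparison
  uses a 1e-7 relative tolerance to absorb floating-point ties.
- **Determinism**: every stochastic stage derives its seed from the run
  seed and a stage label (`derive_seed()`), so inserting a stage never
  shifts another stage's stream; all derived seeds stay below 2³¹.
- **Problem sizes**: the fixture uses 16,000 background SNVs (kinship SE
  ~0.004, far from the 0.0442 threshold; ROH density ~18 kb); calibration
  uses 200 replicates of 300 samples × 400 SNVs; kinship classification
  uses 100 pairs per relationship at 5,000 SNVs; the population-frequency
  oracle simulates 10⁷ individuals. These sizes were chosen so each check
  is decisively powered while the whole suite stays interactive.

# Known limitations

- No linkage disequilibrium or recombination-based segment sharing;
  kinship degrees beyond the third are not distinguishable by design.
- Compound-het confirmation uses trios only; population-based statistical
  phasing and read-backed phasing are out of scope.
- The covariate-adjusted headline statistics of the motivating study
  (e.g. OR 26.6 with CI 7.3–96.6) depend on the raw genotype-level data,
  which are not deposited; the package asserts instead the closed-form
  unadjusted OR on the printed counts (~43.4), which falls inside that
  published interval.
- Population-specific or inbreeding-adjusted genotype frequencies are not
  modelled in the Hardy–Weinberg module.
- The dominant-model screen over the wider immune-gene list reported
  negative in the motivating study is intentionally not implemented.
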