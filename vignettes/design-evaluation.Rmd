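---
title: "Evaluating tagging, coverage and power for sequencing-era association studies"
author: "tagpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating tagging, coverage and power for sequencing-era association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagpower)
```

## The problem

Genome-wide association studies built on genotyping arrays rest on two
assumptions: that a catalogue of variants discovered in a reference cohort
covers the variation segregating in new samples, and that linkage
disequilibrium (LD) lets a modest tag-SNP set stand in for everything else.
Both assumptions hold well for common variants (minor allele frequency,
MAF > 5%) and degrade badly for low-frequency variants
(0.5% < MAF ≤ 5%): low-frequency alleles are young, sit on few haplotypes,
show weak r² with their neighbours, and keep appearing as new individuals
are sequenced. This package quantifies those degradations on any phased
haplotype panel — LD spectra by frequency class, tag-SNP yield and
untaggable fractions, fixed-array coverage under discovery ascertainment,
and case-control mapping power under explicit disease models — so that
array-based and sequencing-based designs can be compared like for like.

Throughout, variants are classified as *rare* (MAF ≤ 0.5%),
*low frequency* (0.5% < MAF ≤ 5%) and *common* (MAF > 5%), with both
boundaries inclusive on the rarer side.

## The substrate: phased haplotype panels

Every stage consumes a `haplotype_panel`: a 0/1 matrix with one row per
chromosome (rows 2k−1, 2k belong to sample k) and one column per biallelic
SNP, with variants sorted by (chrom, pos) and every column polymorphic.
Panels are read from phased VCF (`read_phased_vcf()`, backed by
VariantAnnotation) or IMPUTE-style hap/legend pairs; gene regions come from
BED (0-based half-open; a variant at 1-based position `pos` belongs to a
region iff `start < pos <= end`); array content is a two-column (chrom, pos)
TSV manifest.

Deliberate strictness at the boundary:

* unphased (`/`) or missing (`.`) genotypes are errors, not candidates for
  phasing or imputation — both are out of scope here, and silently guessing
  phase would corrupt every downstream r²;
* multiallelic and non-SNP records are rejected;
* monomorphic columns are *dropped with a logged count* rather than kept or
  refused: r² is undefined at zero variance, and fixed-content arrays
  routinely carry sites that are monomorphic in a new cohort. The same rule
  reapplies after sample subsetting.

## The synthetic-data generator

`generate_panel()` / `generate_gene_panels()` produce panels with two
properties the evaluation needs: a realistic allele-frequency spectrum and
block-structured LD that decays with distance. It is a stylized copying
model, not a coalescent simulator — controllable, fast, and sufficient to
exercise tagging, coverage and power; a coalescent backend could be swapped
in behind the same `haplotype_panel` contract.

**Frequencies first.** Minor-allele counts are drawn i.i.d. from the target
folded site-frequency spectrum and imposed exactly, so the empirical
spectrum matches the target by construction regardless of the copying
dynamics. Under the standard neutral model (constant population size,
random mating) the unfolded spectrum is ∝ 1/i; folding onto minor counts
i = 1..⌊n/2⌋ gives weights 1/i + 1/(n−i), and 1/i at i = n/2 for even n
(`expected_folded_sfs()`). Uniform and user-supplied spectra are also
available.

**Placement second.** Each region is tiled into blocks. A block has
`founders_per_block` founder lineages; every chromosome copies one founder
label per block, switching to a random founder between adjacent variants
with probability `switch_rate ×` distance. Carrier sets are then placed on
this mosaic with an *age–frequency* split:

* **Old variants** (count above one founder's share of chromosomes) fill
  whole founder clusters, in a cyclic founder order fixed per block,
  starting at a rotation that itself persists along the chromosome, with a
  block-stable within-founder order. Nearby old variants therefore carry
  nested unions of the same clusters — strong common–common LD inside
  blocks, decaying as labels and rotations switch.
* **Young variants** (count within one founder's share) are recent
  mutations placed on uniformly random chromosomes, independent of the
  mosaic — low-frequency/low-frequency and low-frequency/common LD stay
  weak, and the residual strong-LD fraction among rare pairs is the
  unavoidable singleton-collision rate (two singletons on the same
  chromosome have r² = 1).

This split is what reproduces, structurally rather than by luck of the
seed, the canonical qualitative pattern: strong LD is concentrated in
common–common pairs; low-frequency variants are untaggable roughly twice as
often as common ones; an ascertained array covers common variation almost
fully and low-frequency variation poorly; and the proportion of
low-frequency variants among discovered sites rises as the cohort grows.

**Defaults** (units in basepairs unless noted): chromosome mode 1 Mb with
55 samples (a typical phased reference-panel size) and 3,000 variants;
genes mode 382 disjoint genes of 5 kb carrying 2,254 variants among 55
samples, emulating an exome-pilot shape; 50 kb blocks with 10 founders
each; switch rate 1e-5 per bp (runs of shared haplotype structure on the
50 kb scale, largely decorrelated by 200 kb). A single seed drives all
randomness; output is byte-identical under a fixed seed.
`founders_per_block = 1` is rejected at configuration time: a single
lineage leaves the copying structure with no polymorphic information.

**What a green test does *not* establish.** The generator has no
demography, selection, recombination maps, gene conversion or sequencing
error; rare-variant haplotype clustering is understated (young variants are
fully independent of the mosaic); frequencies are exact draws, so
frequency-estimation noise is absent. Results on synthetic panels validate
the *machinery* and the *direction* of effects, not population-genetic
magnitudes.

`ascertain_discovery_panel()` models a chip frozen by a discovery cohort:
its manifest is exactly the set of sites polymorphic within the discovery
subsample. An empty discovery set is a legitimate empty manifest.

## LD analysis

r² is computed from phased gamete frequencies:
D = p_AB − p_A p_B and r² = D² / (p_A(1−p_A) p_B(1−p_B)) — equal to the
squared Pearson correlation of the two 0/1 columns, symmetric and invariant
to allele relabeling. Haplotype r² (not genotype composite LD) is used
because the substrate is phased.

`pairwise_ld_profile()` counts every unordered in-scope pair exactly once
(window on the same chromosome, or same gene region) and summarizes r² into
five fixed intervals: [0, 0.2), [0.2, 0.4), [0.4, 0.6), [0.6, 0.8),
[0.8, 1]. The bins are left-closed with a closed top bin so that the two
named thresholds — 0.2 ("weak") and 0.8 ("strong") — fall on edges and
r² = 0.8 counts as strong. Strata are cc / rc / rr over
{common, low-frequency}; pairs involving rare variants are reported in
separate `rare_*` strata when requested and excluded from the three-stratum
default, which mirrors how such figures are conventionally drawn.

`dosage_r2()` is the imputation-accuracy metric (squared correlation
between true genotypes and imputed dosages), provided as a reusable metric
only — imputation itself is out of scope. Constant dosages return 0 (an
uninformative imputation), constant truth is a domain error.

## Tag SNP selection

`greedy_select_tags()` implements greedy pairwise tagging: among remaining
SNPs, select the one whose number of remaining in-scope neighbours at
r² ≥ t is largest; it becomes a tag, its neighbours its bin; remove the bin
and repeat. Decisions the algorithm statement leaves open, fixed here:

* "exceeding the threshold" is r² ≥ t (ties included), consistent with the
  ≥ 0.8 strong-LD convention;
* ties on the neighbour count break to the lowest (chrom, pos) —
  determinism;
* neighbour counts are recomputed each round against the remaining SNPs,
  not frozen at the start;
* a SNP with zero qualifying neighbours goes to `untaggable`, not into a
  size-one bin labelled "tag" — this keeps the three-way partition
  (tag / tagged / untaggable) aligned with how tagging yield is usually
  plotted. `find_untaggable()` gives the same set order-independently (the
  zero-degree SNPs of the r² graph).

Note a consequence: the *number of bins* alone is not monotone in the
threshold (tightening t can move whole bins into `untaggable`); the
genotyping burden — bins plus untaggable SNPs, i.e. assays needed to
observe everything — is the monotone quantity, and is what the tests
check.

## Coverage

A target SNP is covered at threshold t iff its own site is on the array
(direct typing, r² = 1 by convention) or some array site within the window
(default 200 kb, the widest tagging scope) has r² ≥ t with it. Array sites
absent from the target panel — or monomorphic in its samples — capture
nothing: that is precisely the ascertainment failure mode. Whether direct
typing should count is arguably convention; near-total common-variant
coverage by dense catalogues implies it should, so `count_direct = TRUE` is
the default with a documented switch. Reports stratify by the target SNP's
MAF category; `coverage_curve()` sweeps thresholds (coverage is
non-increasing in t, non-decreasing under array inclusion).

## Disease models and power

A `disease_model` is (kind, K, γ₁, γ₂) with penetrances f₁ = γ₁f₀,
f₂ = γ₂f₀ and f₀ = K / (P₀ + γ₁P₁ + γ₂P₂) under HWE genotype probabilities
P = ((1−p)², 2p(1−p), p²), so Σ f_g P_g = K to machine precision
(`solve_penetrance()`; f₂ > 1 is an explicit infeasibility error). Model
kinds constrain the risks: dominant γ₁ = γ₂, additive γ₂ = 2γ₁ − 1,
multiplicative γ₂ = γ₁², recessive γ₁ = 1. Conventional defaults:
K = 0.01; homozygous risks 1.4 / 1.8 for common variants (the squares of a
surveyed median 1.183 and mean 1.5 per-allele risk, `rr_from_survey()`),
and for low-frequency variants 1.8 (dominant/additive/multiplicative) or
3.2 (recessive); α = 0.05; arm sizes 3,000 or 5,000 ("n = 5000" means
5,000 cases *and* 5,000 controls). The risk allele is the allele coded 1.

**Simulation.** `simulate_case_control()` forms individuals by drawing two
chromosomes uniformly with replacement from the panel and assigning status
by the penetrance of the causal genotype. The literal implementation is
rejection sampling (accept a draw as a case with probability f_g); since
the acceptance probability depends on the pair only through its causal
genotype g, conditioning on acceptance factorizes: the case law is *draw g
from the Bayes-inverted case distribution, then a uniform pair given g*.
The default `method = "stratified"` implements that identity exactly —
same distribution, no 1/K ≈ 100-fold waste — and `method = "rejection"`
remains available; the tests check both against the closed-form conditional
law.

**The test.** `chi2_2df_test()` is the Pearson chi-square on the 2×3
case/control × genotype table. Genotype columns with zero total are dropped
and df reduced to (columns − 1): with rare homozygotes the three-column
table is frequently unobservable, and this keeps the statistic defined
without inventing data. Replicates whose table degenerates below two
columns count as non-rejections.

**Power.** `estimate_power()` tests, per replicate, a single SNP at
uncorrected α: the causal SNP (`all_snps` — with the causal typed, it is
the best single test), the best-r² proxy among other panel SNPs
(`exclude_causal`), or among array sites (`panel_restricted`); r² ties
break to the lowest position, and an empty proxy set yields power 0 with a
warning — the power-side analogue of untaggability. Because the chi-square
depends on the data only through genotype *counts* at the tested SNP, the
replicate counts are drawn directly from the exact two-locus case/control
distributions induced by pair resampling (enumerate the 4×4 haplotype-pair
combinations); this is distribution-identical to materializing individuals
and makes 10,000-replicate calibration runs cheap. Default 1,000
replicates (Monte-Carlo SE ≈ 0.007 at power 0.95); `mc_se =
√(p̂(1−p̂)/R)` is always reported. `aggregate_power_by_maf()` averages
estimates over causal-MAF bins (default width 0.01).

**Analytic oracle.** `analytic_power()` gives the asymptotic power of the
direct 2-df test: noncentrality λ = n₁n₂/(n₁+n₂) · Σ_g (p₁g − p₂g)²/p̄_g
with p̄ the arm-weighted mean cell probability, power = upper tail of
χ²(2, λ) at the central critical value. Under the null λ = 0 and power = α
exactly. **Known limitation:** the approximation assumes adequately
populated cells. At MAF ≤ 0.02 (and for recessive models up to MAF 0.05)
with a few thousand samples per arm, the expected homozygote counts fall
below ~2; there the finite-sample test — including the zero-column df
reduction — and the asymptotic formula genuinely part ways, by a few
percentage points and with model-dependent sign (the recessive signal lives
in a column that is often entirely absent, so simulation falls *below* the
asymptotic value). The acceptance suite runs the full model × MAF × n
grid and deliberately leaves the sparse-cell cells red rather than widening
the tolerance; the oracle should not be trusted as ground truth in that
regime, for exactly the reason fixed arrays should not be trusted to map
rare recessives.

## Numerical choices and degenerate inputs

* r² is clamped to [0, 1] against floating-point overshoot; coverage
  compares with a 1e-12 slack at the threshold so r² values that are
  exactly t pass on every platform.
* MAF category boundaries are inclusive (≤ 0.005 rare, ≤ 0.05 low); the
  classifier rejects values outside [0, 0.5] beyond 1e-12.
* Penetrance/prevalence consistency in `case_control_genotype_freqs()` is
  enforced at 1e-9.
* Empty panels, empty manifests, empty discovery sets and empty r² strata
  are all legal and return empty/NA results; zero-variance columns,
  constant truth in `dosage_r2()`, and sub-2-column chi-square tables are
  errors.
* All tie-breaks (tag selection, proxy choice) resolve to the lowest
  (chrom, pos) for determinism.

## Pipeline

`run_pipeline()` executes simulate → ld → tag → coverage → power from one
JSON configuration with a global seed; `validate_config()` returns
field-level findings before anything runs. Outputs are TSVs with a
commented header naming units and conventions, plus `run_manifest.tsv`
with md5 digests of every output and of the configuration; identical
config + seed reproduces every byte. The `inst/cli/tagpower` script exposes
the stages as subcommands.

## Known limitations

* No imputation, phasing, genotype likelihoods, indels or multiallelics.
* Single-marker tagging and testing only: no multimarker/haplotype tags, no
  burden or collapsing tests, no covariates or stratification control.
* The generator's caveats above; in particular, panels of ~55 samples
  contain no rare-class (MAF ≤ 0.5%) variants at all — the rare stratum
  machinery is exercised only at larger sample sizes.
* The analytic power oracle is asymptotic; see the sparse-cell discussion.
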