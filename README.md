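# tagpower

Design evaluation for association studies in the sequencing era: given a
phased haplotype panel, how much of its variation can a tag-SNP set or a
fixed genotyping array capture, and how much power does each design retain
for mapping causal variants — especially **low-frequency** ones
(0.5% < MAF ≤ 5%), where linkage disequilibrium is weak and fixed arrays
struggle?

The package is aimed at statistical geneticists and study designers who want
to compare *genotype-a-catalogue* designs (tag SNPs, fixed chips ascertained
from a discovery cohort) against *sequence-everything* designs, on real
phased VCF panels or on built-in synthetic panels that emulate
chromosome-scale and exome-style data.

## What it computes

- **LD profiles.** Pairwise LD on phased haplotypes, measured by the squared
  correlation r² = D² / (p_A(1−p_A) p_B(1−p_B)) with D = p_AB − p_A p_B,
  within inter-marker windows (50/100/200 kb) or within genes, summarized as
  proportions over five r² intervals and stratified by MAF-category pair:
  common–common (cc), low-frequency–common (rc), low-frequency–low-frequency
  (rr). r² ≥ 0.8 is the conventional "strong LD" threshold.
- **Tag SNP selection.** Greedy pairwise tagging: repeatedly pick the SNP
  with the most in-scope neighbours at r² ≥ t, form a bin, remove it, until
  none remain. SNPs with no qualifying partner are *untaggable*.
- **Array coverage.** The proportion of a cohort's SNPs captured by a fixed
  marker set, directly (the site is on the array) or indirectly (r² ≥ t with
  an array site within the window), per MAF category. Arrays can be
  *ascertained* from a discovery subsample, reproducing the blind spot fixed
  chips have for variants discovered only in new samples.
- **Power.** Case-control power of the 2-df genotypic chi-square test under
  dominant / additive / multiplicative / recessive disease models
  parameterized by prevalence K and genotype relative risks γ₁ = f₁/f₀,
  γ₂ = f₂/f₀ (penetrances solved from K and γ under HWE). Monte-Carlo
  simulation by chromosome resampling from the panel, testing the causal SNP
  itself, its best proxy, or its best on-array proxy; plus a noncentral
  chi-square analytic oracle with λ = n₁n₂/(n₁+n₂) · Σ_g (p₁g−p₂g)²/p̄_g.
- **Synthetic panels.** Neutral folded site-frequency spectrum (∝ 1/i,
  folded) imposed on a founder-copying mosaic with block-structured,
  distance-decaying LD; deterministic under a seed.

## Worked example

```r
library(tagpower)

cfg   <- sim_config(seed = 11, n_samples = 55, n_variants = 1500,
                    region_length = 5e5)
panel <- generate_panel(cfg)

pairwise_ld_profile(panel, window = 200000)
#>   window    scope stratum n_pairs [0,0.2) [0.2,0.4) [0.4,0.6) [0.6,0.8) [0.8,1]
#> 1  2e+05 distance      cc  238337   0.945  0.023903  1.72e-02  1.00e-02 0.00376
#> 2  2e+05 distance      rc  351655   1.000  0.000284  2.84e-06  0.00e+00 0.00000
#> 3  2e+05 distance      rr  129175   0.986  0.008918  3.76e-03  4.64e-05 0.00172

tag_summary(greedy_select_tags(panel, threshold = 0.8), panel)
#>        category   n prop_tag prop_tagged prop_untaggable
#> 1        common 867    0.151       0.464           0.385
#> 2 low_frequency 633    0.120       0.221           0.659

chip <- ascertain_discovery_panel(panel, panel$sample_ids[1:10], name = "chip")
coverage_at_threshold(panel, chip, 0.8)
#>        category n_target n_covered proportion
#> 1        common      867       825      0.952
#> 2 low_frequency      633       213      0.336
#> 3       overall     1500      1038      0.692

dm <- disease_model("dominant", rr_hom = 1.8)   # K = 0.01, gamma1 = gamma2 = 1.8
power_mc_direct(dm, risk_allele_freq = 0.05, n_cases = 5000, n_controls = 5000,
                replicates = 1000, seed = 1)$power
#> [1] 1
```

Reading the numbers: strong LD (r² ≥ 0.8) is several-fold more common among
common–common pairs (0.38%) than among low-frequency pairs (0.17%) and
essentially absent between low-frequency and common SNPs — which is why
two-thirds of the low-frequency SNPs are untaggable at r² ≥ 0.8 (vs 39% of
common SNPs), and why a chip ascertained from 10 discovery samples covers
95% of the common but only 34% of the low-frequency variation. A saturated
dominant signal at MAF 5% (γ = 1.8, 5,000 cases + 5,000 controls) is
detected in every replicate: power 1.000.

## Pipeline CLI

All five stages run from one JSON config (see `validate_config()` /
`run_pipeline()`), or via the `inst/cli/tagpower` script:

```sh
tagpower run --config config.json          # simulate -> ld -> tag -> coverage -> power
tagpower validate config.json
```

Outputs are TSVs with commented headers plus a `run_manifest.tsv` of md5
digests; reruns with the same config and seed are byte-identical.

## Documentation

`vignettes/design-evaluation.Rmd` describes the models, the synthetic-data
generator and its limits, all numerical choices, and the open design
decisions.
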