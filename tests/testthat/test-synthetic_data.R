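test_that("expected_folded_sfs folds the neutral 1/i spectrum", {
  expect_equal(expected_folded_sfs(2), 1)
  # n=4: weights (1 + 1/3, 1/2) -> (8/11, 3/11)
  expect_equal(expected_folded_sfs(4), c(8, 3) / 11)
  # n=6: weights (1 + 1/5, 1/2 + 1/4, 1/3)
  w <- c(1.2, 0.75, 1 / 3)
  expect_equal(expected_folded_sfs(6), w / sum(w), tolerance = 1e-12)
  expect_equal(round(expected_folded_sfs(6), 4), c(0.5255, 0.3285, 0.1460))
  expect_error(expected_folded_sfs(1), ">= 2")
  for (n in c(5, 10, 11, 200)) expect_equal(sum(expected_folded_sfs(n)), 1)
})

test_that("sim_config validates its domain", {
  expect_error(sim_config(n_samples = 0), "positive count")
  expect_error(sim_config(switch_rate = 2), "switch_rate")
  expect_error(sim_config(founders_per_block = 1), "monomorphic")
  expect_error(sim_config(n_variants = 200, region_length = 100), "shorter")
  expect_error(sim_config(sfs = "zipf"), "unknown sfs")
})

test_that("generate_panel is deterministic and satisfies panel invariants", {
  cfg <- sim_config(seed = 4, n_samples = 20, n_variants = 150, region_length = 1e5)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$variants, p2$variants)
  expect_silent(validate_panel(p1))
  expect_true(all(p1$variants$maf > 0 & p1$variants$maf <= 0.5))
  p3 <- generate_panel(sim_config(seed = 5, n_samples = 20, n_variants = 150,
                                  region_length = 1e5))
  expect_false(identical(p1$haplotypes, p3$haplotypes))
})

test_that("empirical folded SFS matches its target (chi-square GOF)", {
  cfg <- sim_config(seed = 8, n_samples = 500, n_variants = 5000, region_length = 1e6)
  p <- generate_panel(cfg)
  n_chrom <- 1000L
  counts <- round(p$variants$maf * n_chrom)
  obs <- tabulate(counts, nbins = n_chrom %/% 2L)
  expp <- expected_folded_sfs(n_chrom) * length(counts)
  kmax <- max(which(expp >= 5))
  obs_p <- c(obs[1:kmax], sum(obs[-(1:kmax)]))
  exp_p <- c(expp[1:kmax], sum(expp[-(1:kmax)]))
  pval <- stats::chisq.test(obs_p, p = exp_p / sum(exp_p))$p.value
  expect_gt(pval, 0.001)
})

test_that("uniform and custom SFS options are honoured", {
  cfg <- sim_config(seed = 3, n_samples = 10, n_variants = 400,
                    region_length = 1e5, sfs = "uniform")
  p <- generate_panel(cfg)
  expect_gt(mean(p$variants$maf > 0.25), 0.3)  # uniform puts mass on high counts
  custom <- c(1, rep(0, 9))  # singletons only (n_chrom = 20)
  p2 <- generate_panel(sim_config(seed = 3, n_samples = 10, n_variants = 100,
                                  region_length = 1e5, sfs = custom))
  expect_true(all(round(p2$variants$maf * 20) == 1))
})

test_that("gene mode partitions variants into disjoint regions", {
  cfg <- sim_config(seed = 6, n_samples = 15, n_variants = 60, mode = "genes",
                    n_genes = 10)
  gp <- generate_gene_panels(cfg)
  expect_equal(nrow(gp$regions), 10L)
  v <- gp$panel$variants
  hits <- sapply(seq_len(nrow(v)), function(i)
    sum(v$pos[i] > gp$regions$start & v$pos[i] <= gp$regions$end))
  expect_true(all(hits == 1L))  # every variant in exactly one region
  expect_equal(mean(table(findInterval(v$pos, gp$regions$start))), 60 / 10,
               tolerance = 0.35)
  # n_genes = 1 reduces to a single region holding everything
  gp1 <- generate_gene_panels(sim_config(seed = 6, n_samples = 15, n_variants = 40,
                                         mode = "genes", n_genes = 1))
  expect_equal(nrow(gp1$regions), 1L)
  expect_true(all(gp1$panel$variants$pos <= gp1$regions$end))
})

test_that("exome-shaped default (382 genes, 2254 SNPs, 55 samples) round-trips", {
  cfg <- sim_config(seed = 9, n_samples = 55, n_variants = 2254, mode = "genes",
                    n_genes = 382)
  gp <- generate_gene_panels(cfg)
  expect_equal(n_variants(gp$panel), 2254L)
  expect_equal(n_samples(gp$panel), 55L)
  f <- tempfile(fileext = ".vcf")
  write_phased_vcf(gp$panel, f)
  p2 <- read_phased_vcf(f)
  expect_identical(p2$haplotypes, gp$panel$haplotypes)
})

test_that("discovery ascertainment is exact and monotone in the cohort", {
  p <- generate_panel(sim_config(seed = 12, n_samples = 50, n_variants = 400,
                                 region_length = 2e5))
  all_m <- ascertain_discovery_panel(p, p$sample_ids)
  expect_equal(nrow(all_m$sites), n_variants(p))
  expect_equal(nrow(ascertain_discovery_panel(p, character(0))$sites), 0L)
  sizes <- sapply(c(5, 10, 20, 35, 50), function(k)
    nrow(ascertain_discovery_panel(p, p$sample_ids[1:k])$sites))
  expect_true(all(diff(sizes) >= 0))
  # a variant carried only outside the discovery set is excluded
  carriers <- which(p$haplotypes[, 1] == 1L)
  outside <- setdiff(seq_len(n_samples(p)), unique((carriers + 1L) %/% 2L))
  m <- ascertain_discovery_panel(p, p$sample_ids[outside])
  expect_false(paste(p$variants$chrom[1], p$variants$pos[1]) %in%
               paste(m$sites$chrom, m$sites$pos))
})

test_that("mosaic LD: within-block r2 exceeds between-block r2", {
  p <- generate_panel(sim_config(seed = 15, n_samples = 55, n_variants = 600,
                                 region_length = 3e5))
  pr <- ld_pairs(p, window = 200000)
  li <- match(pr$left, p$variants$id)
  ri <- match(pr$right, p$variants$id)
  blk <- (p$variants$pos - 1L) %/% 50000L
  same <- blk[li] == blk[ri]
  expect_gt(mean(pr$r2[same]), mean(pr$r2[!same]))
})

test_that("low-frequency proportion among discovered sites grows with cohort size", {
  p <- generate_panel(sim_config(seed = 16, n_samples = 200, n_variants = 2000,
                                 region_length = 5e5))
  prop_low <- sapply(c(15, 55, 200), function(s) {
    sp <- quiet(subset_panel(p, samples = p$sample_ids[1:s]))
    mean(sp$variants$category != "common")
  })
  expect_true(all(diff(prop_low) > 0))
})
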