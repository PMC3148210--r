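test_that("compute_maf counts minor alleles and is relabeling-invariant", {
  expect_equal(compute_maf(c(0, 0, 0, 1)), 0.25)
  expect_equal(compute_maf(c(1, 1, 1, 0)), 0.25)  # minor allele is reference
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_error(compute_maf(integer(0)), "empty")
  set.seed(1)
  for (k in 1:20) {
    x <- rbinom(30, 1, runif(1))
    expect_equal(compute_maf(x), compute_maf(1L - x))
  }
})

test_that("classify_maf_category uses inclusive boundaries and partitions [0, 0.5]", {
  expect_equal(classify_maf_category(0.05), "low_frequency")
  expect_equal(classify_maf_category(0.005), "rare")
  expect_equal(classify_maf_category(0.06), "common")
  expect_equal(classify_maf_category(0), "rare")
  expect_error(classify_maf_category(0.6), "\\[0, 0.5\\]")
  expect_error(classify_maf_category(-0.1), "\\[0, 0.5\\]")
  grid <- seq(0, 0.5, by = 0.001)
  cats <- classify_maf_category(grid)
  expect_true(all(cats %in% c("common", "low_frequency", "rare")))
  # each value lands in exactly one class, consistent with the boundaries
  expect_identical(cats == "rare", grid <= 0.005)
  expect_identical(cats == "low_frequency", grid > 0.005 & grid <= 0.05)
})

test_that("read_phased_vcf parses phased biallelic SNPs and annotates maf", {
  path <- write_vcf_lines(c(vcf_header(),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"))
  p <- read_phased_vcf(path)
  expect_equal(n_variants(p), 1L)
  expect_equal(nrow(p$haplotypes), 4L)
  expect_equal(sum(p$haplotypes), 3L)
  expect_equal(p$variants$maf, 0.25)
  expect_equal(p$variants$category, "common")
  expect_equal(p$sample_ids, c("s1", "s2"))
})

test_that("read_phased_vcf rejects unphased, missing and multiallelic records", {
  unph <- write_vcf_lines(c(vcf_header(),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1"))
  expect_error(read_phased_vcf(unph), "unphased")
  miss <- write_vcf_lines(c(vcf_header(),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t.|.\t1|1"))
  expect_error(read_phased_vcf(miss), "missing")
  multi <- write_vcf_lines(c(vcf_header(),
    "chr1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t1|2"))
  expect_error(read_phased_vcf(multi), "multiallelic")
})

test_that("monomorphic records are dropped with a log message", {
  path <- write_vcf_lines(c(vcf_header(),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|0\t0|0",
    "chr1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0"))
  expect_message(p <- read_phased_vcf(path), "1 monomorphic")
  expect_equal(n_variants(p), 1L)
  expect_equal(p$variants$id, "rs2")
})

test_that("VCF round trip is the identity on haplotypes and positions", {
  p <- random_small_panel(12L, 30L)
  f <- tempfile(fileext = ".vcf")
  write_phased_vcf(p, f)
  p2 <- read_phased_vcf(f)
  expect_identical(p2$haplotypes, p$haplotypes)
  expect_identical(p2$variants$pos, p$variants$pos)
  expect_identical(p2$variants$id, p$variants$id)
  expect_identical(p2$sample_ids, p$sample_ids)
  # header-only degenerate file
  empty <- quiet(subset_panel(p, variants = character(0)))
  f2 <- tempfile(fileext = ".vcf")
  write_phased_vcf(empty, f2)
  p3 <- read_phased_vcf(f2)
  expect_equal(n_variants(p3), 0L)
  expect_equal(p3$sample_ids, p$sample_ids)
})

test_that("hap/legend dialect round trips", {
  p <- random_small_panel(10L, 15L)
  hp <- tempfile(); lp <- tempfile()
  write_hap_legend(p, hp, lp)
  p2 <- read_hap_legend(hp, lp, chrom = "chr1", sample_ids = p$sample_ids)
  expect_identical(p2$haplotypes, p$haplotypes)
  expect_identical(p2$variants$pos, p$variants$pos)
})

test_that("subset_panel keeps order, recomputes maf and drops new monomorphics", {
  p <- random_small_panel(16L, 20L)
  expect_identical(subset_panel(p, variants = p$variants$id)$haplotypes, p$haplotypes)
  # empty manifest intersection -> empty panel
  man <- array_manifest("chrX", 1L)
  expect_equal(n_variants(subset_panel(p, manifest = man)), 0L)
  # 4-sample toy with hand-recomputed maf after dropping half the samples
  cols <- list(ones_at(8, c(1, 5, 7)),   # sample pairs: (1,2) (3,4) (5,6) (7,8)
               ones_at(8, c(7, 8)))
  toy <- toy_panel(cols)
  sub <- quiet(subset_panel(toy, samples = c("sample1", "sample2")))
  # rows kept: haplotypes 1:4; col1 has one carrier -> maf 1/4; col2 monomorphic
  expect_equal(n_variants(sub), 1L)
  expect_equal(sub$variants$maf, 0.25)
  expect_error(subset_panel(toy, samples = "nope"), "unknown sample")
})

test_that("gene regions round trip through BED with half-open membership", {
  reg <- data.frame(name = c("gA", "gB"), chrom = "chr1",
                    start = c(100L, 500L), end = c(200L, 600L))
  f <- tempfile(fileext = ".bed")
  write_gene_regions(reg, f)
  reg2 <- read_gene_regions(f)
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
  expect_equal(reg2$name, reg$name)
  # membership: start < pos <= end (1-based pos)
  p <- toy_panel(list(ones_at(4, 1), ones_at(4, 2), ones_at(4, 3)),
                 pos = c(100L, 101L, 200L))
  sub <- quiet(subset_panel(p, regions = reg2[1, ]))
  expect_equal(sub$variants$pos, c(101L, 200L))
})

test_that("array manifest io and duplicate rejection", {
  m <- array_manifest(c("chr1", "chr1"), c(10L, 20L), name = "chip")
  f <- tempfile(fileext = ".tsv")
  write_array_manifest(m, f)
  m2 <- read_array_manifest(f, name = "chip")
  expect_equal(m2$sites, m$sites)
  expect_error(array_manifest(c("chr1", "chr1"), c(10L, 10L)), "duplicate")
})
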