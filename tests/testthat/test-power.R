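dom18 <- function() disease_model("dominant", rr_hom = 1.8)

test_that("disease_model enforces the model-kind relationships", {
  expect_equal(disease_model("additive", rr_hom = 1.8)$rr_het, 1.4)
  expect_equal(disease_model("multiplicative", rr_hom = 1.8)$rr_het, sqrt(1.8))
  expect_equal(disease_model("recessive", rr_hom = 3.2)$rr_het, 1)
  expect_equal(dom18()$rr_het, 1.8)
  expect_error(disease_model("additive", rr_hom = 1.8, rr_het = 1.6), "inconsistent")
  expect_error(disease_model("dominant", rr_hom = 1.8, prevalence = 0), "prevalence")
})

test_that("hwe_genotype_freqs", {
  expect_equal(unname(hwe_genotype_freqs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(hwe_genotype_freqs(0.05)), c(0.9025, 0.095, 0.0025))
  expect_equal(unname(hwe_genotype_freqs(0)), c(1, 0, 0))
})

test_that("solve_penetrance closed form, prevalence identity and infeasibility", {
  pen <- solve_penetrance(dom18(), 0.05)
  expect_equal(unname(pen), c(0.01 / 1.078, 1.8 * 0.01 / 1.078, 1.8 * 0.01 / 1.078))
  expect_equal(round(unname(pen), 6), c(0.009276, 0.016698, 0.016698))
  # null model: f = K everywhere
  null <- disease_model("dominant", rr_hom = 1)
  expect_equal(unname(solve_penetrance(null, 0.3)), rep(0.01, 3))
  # prevalence identity across a grid
  set.seed(7)
  for (k in 1:10) {
    dm <- disease_model(sample(c("dominant", "additive", "multiplicative", "recessive"), 1),
                        rr_hom = runif(1, 1, 3), prevalence = runif(1, 0.001, 0.2))
    p <- runif(1, 0.01, 0.6)
    pen <- solve_penetrance(dm, p)
    expect_equal(sum(pen * hwe_genotype_freqs(p)), dm$prevalence, tolerance = 1e-14)
  }
  expect_error(solve_penetrance(disease_model("recessive", rr_hom = 3.2, prevalence = 0.5), 0.5),
               "infeasible")
})

test_that("case/control genotype frequencies by Bayes inversion", {
  geno <- hwe_genotype_freqs(0.05)
  pen <- solve_penetrance(dom18(), 0.05)
  arms <- case_control_genotype_freqs(pen, geno, 0.01)
  expect_equal(round(arms$case, 4), c(0.8372, 0.1586, 0.0042))
  expect_equal(sum(arms$case), 1, tolerance = 1e-12)
  expect_equal(sum(arms$control), 1, tolerance = 1e-12)
  # null model: both arms reproduce the genotype distribution
  pen0 <- solve_penetrance(disease_model("additive", rr_hom = 1), 0.2)
  arms0 <- case_control_genotype_freqs(pen0, hwe_genotype_freqs(0.2), 0.01)
  expect_equal(arms0$case, unname(hwe_genotype_freqs(0.2)))
  expect_equal(arms0$control, unname(hwe_genotype_freqs(0.2)))
  expect_error(case_control_genotype_freqs(pen, geno, 0.4), "inconsistent")
})

test_that("chi2_2df_test agrees with chisq.test and drops empty columns", {
  eq <- chi2_2df_test(c(30, 20, 10), c(30, 20, 10))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  ct <- suppressWarnings(stats::chisq.test(rbind(c(50, 40, 10), c(70, 25, 5)), correct = FALSE))
  me <- chi2_2df_test(c(50, 40, 10), c(70, 25, 5))
  expect_equal(me$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(me$df, 2L)
  expect_equal(me$p_value, ct$p.value, tolerance = 1e-12)
  # zero homozygote column -> 2x2 table with 1 df
  me2 <- chi2_2df_test(c(60, 40, 0), c(70, 30, 0))
  ct2 <- suppressWarnings(stats::chisq.test(rbind(c(60, 40), c(70, 30)), correct = FALSE))
  expect_equal(me2$df, 1L)
  expect_equal(me2$statistic, unname(ct2$statistic), tolerance = 1e-12)
  expect_error(chi2_2df_test(c(10, 0, 0), c(20, 0, 0)), "degenerate")
  # vectorized batch path equals the scalar test
  set.seed(11)
  for (k in 1:20) {
    cs <- rmultinom(1, 200, c(0.5, 0.4, 0.1))[, 1]
    cn <- rmultinom(1, 300, c(0.6, 0.3, 0.1))[, 1]
    expect_equal(tagpower:::.chi2_batch(cbind(cs), cbind(cn)),
                 chi2_2df_test(cs, cn)$p_value, tolerance = 1e-12)
  }
})

test_that("simulate_case_control is deterministic and matches the conditional law", {
  p <- generate_panel(sim_config(seed = 5, n_samples = 55, n_variants = 300,
                                 region_length = 2e5))
  v <- p$variants
  cid <- v$id[which.min(abs(v$maf - 0.05))]
  hap <- p$haplotypes[, match(cid, v$id)]
  s1 <- simulate_case_control(p, cid, dom18(), 400, 400, seed = 3)
  s2 <- simulate_case_control(p, cid, dom18(), 400, 400, seed = 3)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_equal(dim(s1$genotypes), c(800L, 300L))
  expect_equal(s1$status, rep(c(1L, 0L), each = 400))

  # null model: case genotypes at the causal match HWE resampling of the pool
  null <- disease_model("dominant", rr_hom = 1)
  sn <- simulate_case_control(p, cid, null, 3000, 3000, seed = 8)
  pf <- mean(hap)
  expected <- c((1 - pf)^2, 2 * pf * (1 - pf), pf^2)
  gof <- stats::chisq.test(tabulate(sn$genotypes[sn$status == 1, cid] + 1L, 3L),
                           p = expected)
  expect_gt(gof$p.value, 0.001)

  # dominant model: empirical case triple within 3 binomial SE of the exact law
  pen <- solve_penetrance(dom18(), pf)
  two <- tagpower:::.two_locus_arm_freqs(hap, hap, pen)
  sd_ <- simulate_case_control(p, cid, dom18(), 5000, 5000, seed = 9)
  emp <- tabulate(sd_$genotypes[sd_$status == 1, cid] + 1L, 3L) / 5000
  expect_true(all(abs(emp - two$case) <= 3 * sqrt(two$case * (1 - two$case) / 5000) + 1e-9))

  # literal rejection sampling agrees with the stratified sampler's law
  sr <- simulate_case_control(p, cid, dom18(), 600, 600, seed = 10, method = "rejection")
  empr <- tabulate(sr$genotypes[sr$status == 1, cid] + 1L, 3L) / 600
  expect_true(all(abs(empr - two$case) <= 3 * sqrt(two$case * (1 - two$case) / 600) + 1e-9))
})

test_that("estimate_power: proxy choice, null calibration and analytic agreement", {
  p <- generate_panel(sim_config(seed = 5, n_samples = 55, n_variants = 300,
                                 region_length = 2e5))
  v <- p$variants
  cid <- v$id[which.min(abs(v$maf - 0.05))]
  pf <- mean(p$haplotypes[, match(cid, v$id)])

  # null calibration
  null <- disease_model("dominant", rr_hom = 1)
  e0 <- estimate_power(p, cid, null, replicates = 2000, seed = 6)
  expect_lt(abs(e0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  # direct power matches the analytic oracle at the pool frequency
  e1 <- estimate_power(p, cid, dom18(), replicates = 2000, seed = 6)
  pa <- analytic_power(dom18(), pf)
  expect_lt(abs(e1$power - pa), 3 * max(e1$mc_se, sqrt(pa * (1 - pa) / 2000)) + 1e-6)

  # exclude_causal picks the best-r2 proxy; with a duplicated causal the
  # proxy is perfect and power matches the direct test
  pdup <- toy_panel(list(ones_at(40, 1:5), ones_at(40, 1:5), ones_at(40, c(2, 8, 9))),
                    pos = c(1000L, 2000L, 3000L), ids = c("c1", "c2", "x"))
  dm <- disease_model("additive", rr_hom = 1.8)
  ed <- estimate_power(pdup, "c1", dm, n_cases = 2000, n_controls = 2000,
                       replicates = 500, mode = "exclude_causal", seed = 4)
  expect_equal(ed$tested, "c2")
  ea <- estimate_power(pdup, "c1", dm, n_cases = 2000, n_controls = 2000,
                       replicates = 500, mode = "all_snps", seed = 4)
  expect_equal(ed$power, ea$power)

  # empty proxy set: power 0 with a warning
  none <- array_manifest("chr9", 1L, name = "none")
  expect_warning(
    ez <- estimate_power(pdup, "c1", dm, replicates = 100, mode = "panel_restricted",
                         manifest = none, seed = 2),
    "uncapturable")
  expect_equal(ez$power, 0)
})

test_that("analytic_power: null equals alpha and power grows with n", {
  null <- disease_model("multiplicative", rr_hom = 1)
  expect_equal(analytic_power(null, 0.1, 1000, 1000, alpha = 0.05), 0.05, tolerance = 1e-12)
  dm <- disease_model("additive", rr_hom = 1.4)
  pw <- sapply(c(500, 1000, 2000, 4000), function(n) analytic_power(dm, 0.1, n, n))
  expect_true(all(diff(pw) > 0))
})

test_that("aggregate_power_by_maf averages within bins and rejects mixed sets", {
  p <- toy_panel(list(ones_at(40, 1:2), ones_at(40, 1:3), ones_at(40, 1:20)),
                 ids = c("v1", "v2", "v3"))  # mafs 0.05, 0.075, 0.5
  dm <- disease_model("additive", rr_hom = 1.8)
  mk <- function(id, power) {
    structure(list(causal = id, tested = id, mode = "all_snps", model = dm,
                   n_cases = 100L, n_controls = 100L, alpha = 0.05,
                   replicates = 10L, power = power, mc_se = 0),
              class = "power_estimate")
  }
  tab <- aggregate_power_by_maf(list(mk("v1", 0.2), mk("v2", 0.4), mk("v3", 0.9)), p)
  expect_equal(tab$mean_power[tab$maf_lo == 0.05], 0.2)
  expect_equal(tab$mean_power[tab$maf_lo == 0.07], 0.4)
  expect_equal(tab$mean_power[tab$maf_lo == 0.5], 0.9)
  two_same <- aggregate_power_by_maf(list(mk("v1", 0.2), mk("v1", 0.4)), p)
  expect_equal(two_same$mean_power, 0.3)
  bad <- mk("v1", 0.5); bad$mode <- "exclude_causal"
  expect_error(aggregate_power_by_maf(list(mk("v2", 0.2), bad), p), "heterogeneous")
})

test_that("rr_from_survey squares the surveyed relative risks", {
  rr <- rr_from_survey(1.5, 1.183)
  expect_equal(unname(rr["mean_sq"]), 2.25)
  expect_equal(unname(rr["median_sq"]), 1.183^2)
})
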