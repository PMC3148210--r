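# Disease-model power engine: penetrances solved from prevalence and
# genotype relative risks, case-control simulation by chromosome resampling,
# the 2-df Pearson chi-square test, Monte-Carlo power for direct / proxy /
# panel-restricted testing, and a noncentral chi-square analytic oracle.

.model_kinds <- c("dominant", "additive", "multiplicative", "recessive")

#' Define a disease model (prevalence + genotype relative risks)
#'
#' The genotype relative risks are gamma1 = f1/f0 (one risk-allele copy) and
#' gamma2 = f2/f0 (two copies).  The model kind fixes their relationship:
#' dominant gamma1 = gamma2, additive gamma2 = 2 gamma1 - 1, multiplicative
#' gamma2 = gamma1^2, recessive gamma1 = 1.  When `rr_het` is omitted it is
#' derived from `rr_hom` under the model kind.
#'
#' @param kind one of `"dominant"`, `"additive"`, `"multiplicative"`,
#'   `"recessive"`.
#' @param rr_hom homozygous genotype relative risk gamma2.  Conventional
#'   defaults used throughout: 1.4 or 1.8 for common variants; for low
#'   frequency variants 1.8 (dominant/additive/multiplicative) and 3.2
#'   (recessive).
#' @param prevalence population disease prevalence K in (0, 1); default 0.01.
#' @param rr_het optional heterozygous relative risk gamma1; if supplied it
#'   must satisfy the model-kind relationship.
#' @return a `disease_model` list with fields `kind`, `prevalence`, `rr_het`,
#'   `rr_hom`.
#' @export
disease_model <- function(kind = .model_kinds, rr_hom, prevalence = 0.01,
                          rr_het = NULL) {
  kind <- match.arg(kind)
  if (prevalence <= 0 || prevalence >= 1) stopf("disease_model: prevalence must lie in (0, 1)")
  if (rr_hom <= 0) stopf("disease_model: rr_hom must be positive")
  derived <- switch(kind,
    dominant = rr_hom,
    additive = (rr_hom + 1) / 2,
    multiplicative = sqrt(rr_hom),
    recessive = 1
  )
  if (is.null(rr_het)) {
    rr_het <- derived
  } else if (abs(rr_het - derived) > 1e-6) {
    stopf("disease_model: rr_het = %g inconsistent with %s model (expected %g)",
          rr_het, kind, derived)
  }
  structure(list(kind = kind, prevalence = prevalence,
                 rr_het = rr_het, rr_hom = rr_hom),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("disease_model: %s, K = %g, gamma1 = %g, gamma2 = %g\n",
              x$kind, x$prevalence, x$rr_het, x$rr_hom))
  invisible(x)
}

#' Hardy-Weinberg genotype probabilities
#'
#' @param risk_allele_freq risk allele frequency p in \[0, 1\].
#' @return probabilities of carrying 0, 1, 2 risk alleles:
#'   `((1-p)^2, 2p(1-p), p^2)`.
#' @export
hwe_genotype_freqs <- function(risk_allele_freq) {
  p <- risk_allele_freq
  if (p < 0 || p > 1) stopf("hwe_genotype_freqs: frequency outside [0, 1]")
  c(g0 = (1 - p)^2, g1 = 2 * p * (1 - p), g2 = p^2)
}

#' Solve penetrances from prevalence and genotype relative risks
#'
#' Under HWE at the risk-allele frequency, the baseline penetrance is
#' `f0 = K / (P0 + gamma1 P1 + gamma2 P2)` and `f1 = gamma1 f0`,
#' `f2 = gamma2 f0`, so that the population prevalence identity
#' `sum(f_g P_g) = K` holds to machine precision.
#'
#' @param model a [disease_model()].
#' @param risk_allele_freq risk allele frequency in (0, 1).
#' @return named numeric `c(f0, f1, f2)`.
#' @export
solve_penetrance <- function(model, risk_allele_freq) {
  if (!inherits(model, "disease_model")) stopf("solve_penetrance: need a disease_model")
  P <- hwe_genotype_freqs(risk_allele_freq)
  f0 <- model$prevalence / sum(P * c(1, model$rr_het, model$rr_hom))
  pen <- c(f0 = f0, f1 = model$rr_het * f0, f2 = model$rr_hom * f0)
  if (any(pen > 1)) {
    stopf("solve_penetrance: infeasible model (f2 = %.4f > 1 at K = %g, gamma1 = %g, gamma2 = %g, p = %g)",
          pen[["f2"]], model$prevalence, model$rr_het, model$rr_hom, risk_allele_freq)
  }
  pen
}

#' Case and control genotype distributions by Bayes inversion
#'
#' `case_g = f_g P_g / K` and `control_g = (1 - f_g) P_g / (1 - K)`.
#'
#' @param pen penetrance triple from [solve_penetrance()].
#' @param geno genotype probability triple (e.g. [hwe_genotype_freqs()]).
#' @param K population prevalence consistent with `pen` and `geno`.
#' @return list with unit-sum numeric triples `case` and `control`.
#' @export
case_control_genotype_freqs <- function(pen, geno, K) {
  if (abs(sum(pen * geno) - K) > 1e-9) {
    stopf("case_control_genotype_freqs: inconsistent inputs (sum f_g P_g = %.6g != K = %g)",
          sum(pen * geno), K)
  }
  list(case = as.numeric(pen * geno / K),
       control = as.numeric((1 - pen) * geno / (1 - K)))
}

# Exact case/control genotype distributions at a marker, for individuals
# formed from two iid uniform draws from a finite chromosome pool, accepted
# by penetrance at the causal site.  hapA = causal column, hapB = marker
# column (may be the same).  Returns the marker triples and the pool
# prevalence implied by the causal-genotype distribution.
.two_locus_arm_freqs <- function(hapA, hapB, pen) {
  n <- length(hapA)
  q <- numeric(4L)  # haplotype freqs: 00, 01, 10, 11 (causal, marker)
  q[1L] <- sum(hapA == 0L & hapB == 0L) / n
  q[2L] <- sum(hapA == 0L & hapB == 1L) / n
  q[3L] <- sum(hapA == 1L & hapB == 0L) / n
  q[4L] <- sum(hapA == 1L & hapB == 1L) / n
  a_of <- c(0L, 0L, 1L, 1L)
  b_of <- c(0L, 1L, 0L, 1L)
  J <- matrix(0, 3L, 3L)  # P(gA, gB) for two iid chromosomes
  for (h1 in 1:4) for (h2 in 1:4) {
    gA <- a_of[h1] + a_of[h2]
    gB <- b_of[h1] + b_of[h2]
    J[gA + 1L, gB + 1L] <- J[gA + 1L, gB + 1L] + q[h1] * q[h2]
  }
  K_pool <- sum(pen * rowSums(J))
  list(case = colSums(J * pen) / K_pool,
       control = colSums(J * (1 - pen)) / (1 - K_pool),
       K_pool = K_pool, causal_geno = rowSums(J))
}

#' Pearson chi-square association test on a 2x3 case/control table
#'
#' Genotype columns with zero total are dropped and the degrees of freedom
#' reduced to (remaining columns - 1), keeping the statistic defined when
#' rare homozygotes are absent.  With all three columns populated this is the
#' usual 2-df genotypic test.
#'
#' @param case_counts,control_counts genotype count triples (g = 0, 1, 2).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi2_2df_test <- function(case_counts, control_counts) {
  if (length(case_counts) != 3L || length(control_counts) != 3L) {
    stopf("chi2_2df_test: genotype count triples required")
  }
  O <- rbind(case = case_counts, control = control_counts)
  keep <- colSums(O) > 0
  if (sum(keep) < 2L) stopf("chi2_2df_test: degenerate table (fewer than two nonzero genotype columns)")
  O <- O[, keep, drop = FALSE]
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- ncol(O) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Vectorized chi-square over replicate count matrices (3 x R each).
# Returns p-values; NA marks degenerate replicates (fewer than 2 nonzero
# genotype columns), which callers count as non-rejections.
.chi2_batch <- function(caseM, ctrlM) {
  n1 <- colSums(caseM)
  n2 <- colSums(ctrlM)
  N <- n1 + n2
  coltot <- caseM + ctrlM                      # 3 x R
  Ecase <- sweep(coltot, 2L, n1 / N, `*`)
  Ectrl <- sweep(coltot, 2L, n2 / N, `*`)
  term <- function(O, E) {
    x <- (O - E)^2 / E
    x[E == 0] <- 0
    x
  }
  stat <- colSums(term(caseM, Ecase)) + colSums(term(ctrlM, Ectrl))
  df <- colSums(coltot > 0) - 1L
  p <- rep(NA_real_, length(stat))
  ok <- df >= 1L
  p[ok] <- stats::pchisq(stat[ok], df[ok], lower.tail = FALSE)
  p
}

#' Simulate a case-control panel by resampling chromosomes
#'
#' Individuals are formed by drawing two chromosomes uniformly with
#' replacement from the panel's haplotype pool; disease status follows the
#' penetrance of the individual's genotype at the causal site (solved from
#' the model at the pool's causal risk-allele frequency; the risk allele is
#' the allele coded 1).  The default `"stratified"` method draws each
#' individual's causal genotype from the exact case (or control) conditional
#' distribution and then a uniform chromosome pair conditional on that
#' genotype, which is distribution-identical to `"rejection"` (accept a
#' uniform pair as a case with probability `f_g`) because acceptance depends
#' on the pair only through its causal genotype.
#'
#' @param panel a [haplotype_panel()].
#' @param causal variant id of the causal SNP (must be polymorphic).
#' @param model a [disease_model()].
#' @param n_cases,n_controls arm sizes.
#' @param seed integer seed (deterministic output).
#' @param method `"stratified"` (default, exact and fast) or `"rejection"`
#'   (literal accept/reject resampling; bounded attempt budget).
#' @return list with `genotypes` (individuals x variants, cases first),
#'   `status` (1 = case), `causal`, `penetrance`.
#' @export
simulate_case_control <- function(panel, causal, model, n_cases, n_controls,
                                  seed = 1L, method = c("stratified", "rejection")) {
  validate_panel(panel)
  method <- match.arg(method)
  ci <- match(causal, panel$variants$id)
  if (is.na(ci)) stopf("simulate_case_control: causal variant '%s' not in panel", causal)
  H <- panel$haplotypes
  hapA <- H[, ci]
  p_pool <- mean(hapA)
  pen <- solve_penetrance(model, p_pool)
  set.seed(seed)
  two <- .two_locus_arm_freqs(hapA, hapA, pen)
  ones <- which(hapA == 1L)
  zeros <- which(hapA == 0L)

  draw_pairs_strat <- function(n, probs) {
    g <- sample.int(3L, n, replace = TRUE, prob = probs) - 1L
    i <- integer(n); j <- integer(n)
    s0 <- g == 0L; s1 <- g == 1L; s2 <- g == 2L
    if (any(s0)) { i[s0] <- sample(zeros, sum(s0), replace = TRUE)
                   j[s0] <- sample(zeros, sum(s0), replace = TRUE) }
    if (any(s1)) { first_one <- stats::runif(sum(s1)) < 0.5
                   io <- sample(ones, sum(s1), replace = TRUE)
                   iz <- sample(zeros, sum(s1), replace = TRUE)
                   i[s1] <- ifelse(first_one, io, iz)
                   j[s1] <- ifelse(first_one, iz, io) }
    if (any(s2)) { i[s2] <- sample(ones, sum(s2), replace = TRUE)
                   j[s2] <- sample(ones, sum(s2), replace = TRUE) }
    cbind(i, j)
  }

  draw_pairs_reject <- function(n, accept_prob) {
    got_i <- integer(0); got_j <- integer(0)
    budget <- 1000L * n + 10000L
    nr <- nrow(H)
    while (length(got_i) < n) {
      batch <- max(1000L, 2L * (n - length(got_i)))
      if (budget <= 0L) stopf("simulate_case_control: rejection budget exhausted (acceptance probability too small)")
      budget <- budget - batch
      i <- sample.int(nr, batch, replace = TRUE)
      j <- sample.int(nr, batch, replace = TRUE)
      g <- hapA[i] + hapA[j]
      acc <- stats::runif(batch) < accept_prob[g + 1L]
      got_i <- c(got_i, i[acc]); got_j <- c(got_j, j[acc])
    }
    cbind(got_i[seq_len(n)], got_j[seq_len(n)])
  }

  pairs <- if (method == "stratified") {
    rbind(draw_pairs_strat(n_cases, two$case),
          draw_pairs_strat(n_controls, two$control))
  } else {
    rbind(draw_pairs_reject(n_cases, pen),
          draw_pairs_reject(n_controls, 1 - pen))
  }
  geno <- H[pairs[, 1L], , drop = FALSE] + H[pairs[, 2L], , drop = FALSE]
  colnames(geno) <- panel$variants$id
  list(genotypes = geno,
       status = rep(c(1L, 0L), c(n_cases, n_controls)),
       causal = causal, penetrance = pen)
}

# tested-SNP choice for estimate_power: returns the column index, or NA when
# no eligible proxy exists.
.choose_tested_snp <- function(panel, ci, mode, manifest) {
  v <- panel$variants
  if (mode == "all_snps") return(ci)
  cand <- if (mode == "exclude_causal") {
    setdiff(seq_len(nrow(v)), ci)
  } else {
    if (is.null(manifest)) stopf("estimate_power: mode='panel_restricted' requires a manifest")
    which(paste(v$chrom, v$pos) %in% paste(manifest$sites$chrom, manifest$sites$pos))
  }
  if (length(cand) == 0L) return(NA_integer_)
  H <- panel$haplotypes
  Z <- scale(H)
  r2 <- (colSums(Z[, ci] * Z[, cand, drop = FALSE]) / (nrow(H) - 1))^2
  best <- r2 >= max(r2) - 1e-12
  cand[best][which.min(v$pos[cand[best]])]  # ties by lowest position
}

#' Monte-Carlo power of the genotypic chi-square test on a panel
#'
#' For each replicate a case-control study of the configured size is drawn by
#' chromosome resampling from the panel (see [simulate_case_control()]); the
#' tested SNP is the causal SNP itself (`all_snps`), its best-r^2 proxy among
#' the other panel SNPs (`exclude_causal`), or its best proxy among the array
#' manifest's sites (`panel_restricted`).  Power is the fraction of
#' replicates with chi-square p <= alpha at the tested SNP.  Replicate
#' genotype counts at the tested SNP are drawn from the exact conditional
#' distributions implied by the resampling scheme (counts are sufficient for
#' the test), so large replicate numbers stay fast.
#'
#' @inheritParams simulate_case_control
#' @param alpha significance level (default 0.05).
#' @param replicates Monte-Carlo replicates (default 1000).
#' @param mode `"all_snps"`, `"exclude_causal"` or `"panel_restricted"`.
#' @param manifest an [array_manifest()] (panel_restricted mode).
#' @return a `power_estimate`: list with `causal`, `tested`, `mode`, `model`,
#'   `n_cases`, `n_controls`, `alpha`, `replicates`, `power`, `mc_se`.
#'   Degenerate replicate tables (fewer than two populated genotype columns)
#'   count as non-rejections; an empty proxy set yields power 0 with a warning.
#' @export
estimate_power <- function(panel, causal, model, n_cases = 5000L,
                           n_controls = 5000L, alpha = 0.05,
                           replicates = 1000L,
                           mode = c("all_snps", "exclude_causal", "panel_restricted"),
                           manifest = NULL, seed = 1L) {
  validate_panel(panel)
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stopf("estimate_power: alpha must lie in (0, 1)")
  ci <- match(causal, panel$variants$id)
  if (is.na(ci)) stopf("estimate_power: causal variant '%s' not in panel", causal)
  ti <- .choose_tested_snp(panel, ci, mode, manifest)
  out <- list(causal = causal, tested = NA_character_, mode = mode,
              model = model, n_cases = n_cases, n_controls = n_controls,
              alpha = alpha, replicates = as.integer(replicates))
  if (is.na(ti)) {
    warning("estimate_power: no eligible tested SNP; the causal signal is uncapturable, power = 0")
    out$power <- 0
    out$mc_se <- 0
    class(out) <- "power_estimate"
    return(out)
  }
  hapA <- panel$haplotypes[, ci]
  hapB <- panel$haplotypes[, ti]
  pen <- solve_penetrance(model, mean(hapA))
  freqs <- .two_locus_arm_freqs(hapA, hapB, pen)
  set.seed(seed)
  caseM <- stats::rmultinom(replicates, n_cases, freqs$case)
  ctrlM <- stats::rmultinom(replicates, n_controls, freqs$control)
  p <- .chi2_batch(caseM, ctrlM)
  pw <- mean(!is.na(p) & p <= alpha)
  out$tested <- panel$variants$id[ti]
  out$power <- pw
  out$mc_se <- sqrt(pw * (1 - pw) / replicates)
  class(out) <- "power_estimate"
  out
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power_estimate: %s model, causal %s, tested %s (%s), n = %d+%d\n  power = %.3f (mc_se %.4f, %d replicates, alpha %g)\n",
              x$model$kind, x$causal, x$tested, x$mode, x$n_cases,
              x$n_controls, x$power, x$mc_se, x$replicates, x$alpha))
  invisible(x)
}

#' @export
as.data.frame.power_estimate <- function(x, ...) {
  data.frame(causal = x$causal, tested = x$tested, mode = x$mode,
             model = x$model$kind, rr_het = x$model$rr_het,
             rr_hom = x$model$rr_hom, prevalence = x$model$prevalence,
             n_cases = x$n_cases, n_controls = x$n_controls, alpha = x$alpha,
             replicates = x$replicates, power = x$power, mc_se = x$mc_se,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo power of the direct genotypic test under HWE
#'
#' Idealized-population variant of [estimate_power()]: genotypes follow HWE
#' at the given risk-allele frequency (no finite haplotype pool, no LD);
#' replicate case/control genotype counts are multinomial draws from the
#' Bayes-inverted case and control distributions.
#'
#' @param model a [disease_model()].
#' @param risk_allele_freq risk allele frequency in (0, 1).
#' @param n_cases,n_controls arm sizes.
#' @param alpha significance level.
#' @param replicates Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list with `power`, `mc_se`, `replicates`.
#' @export
power_mc_direct <- function(model, risk_allele_freq, n_cases = 5000L,
                            n_controls = 5000L, alpha = 0.05,
                            replicates = 1000L, seed = 1L) {
  geno <- hwe_genotype_freqs(risk_allele_freq)
  pen <- solve_penetrance(model, risk_allele_freq)
  arms <- case_control_genotype_freqs(pen, geno, model$prevalence)
  set.seed(seed)
  caseM <- stats::rmultinom(replicates, n_cases, arms$case)
  ctrlM <- stats::rmultinom(replicates, n_controls, arms$control)
  p <- .chi2_batch(caseM, ctrlM)
  pw <- mean(!is.na(p) & p <= alpha)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / replicates),
       replicates = as.integer(replicates))
}

#' Analytic power of the direct 2-df test (noncentral chi-square)
#'
#' Noncentrality `lambda = n1 n2 / (n1 + n2) * sum_g (case_g - control_g)^2 /
#' pbar_g`, with `pbar_g` the arm-size-weighted mean cell probability; power
#' is the upper tail of the noncentral chi-square (2 df, lambda) at the
#' central 2-df critical value.
#'
#' @inheritParams power_mc_direct
#' @return power in \[0, 1\]; equals `alpha` under the null.
#' @export
analytic_power <- function(model, risk_allele_freq, n_cases = 5000L,
                           n_controls = 5000L, alpha = 0.05) {
  geno <- hwe_genotype_freqs(risk_allele_freq)
  pen <- solve_penetrance(model, risk_allele_freq)
  arms <- case_control_genotype_freqs(pen, geno, model$prevalence)
  n1 <- n_cases; n2 <- n_controls
  pbar <- (n1 * arms$case + n2 * arms$control) / (n1 + n2)
  lambda <- n1 * n2 / (n1 + n2) * sum((arms$case - arms$control)^2 / pbar)
  crit <- stats::qchisq(1 - alpha, df = 2)
  stats::pchisq(crit, df = 2, ncp = lambda, lower.tail = FALSE)
}

#' Average power across causal SNPs by MAF bin
#'
#' @param estimates list of `power_estimate` objects (or a data.frame from
#'   rbinding their [as.data.frame()] rows) sharing model, arm sizes, alpha
#'   and mode.
#' @param panel the source [haplotype_panel()] (supplies causal MAFs).
#' @param bin_width MAF bin width (default 0.01).
#' @return data.frame: `maf_lo`, `maf_hi`, `n`, `mean_power`; bins with no
#'   causal SNPs are omitted.
#' @export
aggregate_power_by_maf <- function(estimates, panel, bin_width = 0.01) {
  df <- if (is.data.frame(estimates)) estimates else
    do.call(rbind, lapply(estimates, as.data.frame))
  homo <- c("mode", "model", "rr_het", "rr_hom", "prevalence",
            "n_cases", "n_controls", "alpha")
  for (f in homo) {
    if (length(unique(df[[f]])) > 1L) {
      stopf("aggregate_power_by_maf: heterogeneous estimates (field '%s')", f)
    }
  }
  maf <- panel$variants$maf[match(df$causal, panel$variants$id)]
  if (anyNA(maf)) stopf("aggregate_power_by_maf: causal SNP not found in panel")
  bin <- floor(maf / bin_width)
  agg <- stats::aggregate(df$power, by = list(bin = bin), FUN = mean)
  nn <- as.vector(table(bin)[as.character(agg$bin)])
  data.frame(maf_lo = agg$bin * bin_width, maf_hi = (agg$bin + 1) * bin_width,
             n = nn, mean_power = agg$x)
}

#' Relative-risk default candidates from a GWAS-catalog style survey
#'
#' Squares the surveyed mean and median per-allele relative risks to obtain
#' homozygous relative-risk candidates (the per-allele risk acts twice in a
#' homozygote under a multiplicative composition).  With the surveyed values
#' 1.5 (mean) and 1.183 (median) this yields 2.25 and ~1.4, the source of the
#' conventional 1.4 / 1.8 defaults for common variants.
#'
#' @param mean_rr,median_rr surveyed mean and median per-allele relative risks.
#' @return named numeric: `mean_rr`, `median_rr`, `mean_sq`, `median_sq`.
#' @export
rr_from_survey <- function(mean_rr = 1.5, median_rr = 1.183) {
  c(mean_rr = mean_rr, median_rr = median_rr,
    mean_sq = mean_rr^2, median_sq = median_rr^2)
}
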