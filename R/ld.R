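# Pairwise r^2 on phased haplotypes, windowed/gene-scoped pair enumeration,
# five-interval LD profiles stratified by MAF-category pair, and the
# imputation-accuracy (dosage r^2) metric.

.r2_bin_breaks <- c(0, 0.2, 0.4, 0.6, 0.8)
.r2_bin_names <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)", "[0.8,1]")
.paper_strata <- c("cc", "rc", "rr")

#' Squared correlation (r^2) between two haplotype columns
#'
#' Computed from phased gamete counts: with allele frequencies `pA`, `pB` and
#' haplotype frequency `pAB`, `D = pAB - pA pB` and
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))`.  On 0/1 columns this equals the
#' squared Pearson correlation; it is symmetric and invariant to allele
#' relabeling at either site.
#'
#' @param colA,colB 0/1 vectors of equal length, both polymorphic.
#' @return r^2 in \[0, 1\].
#' @export
compute_r2 <- function(colA, colB) {
  if (length(colA) != length(colB)) stopf("compute_r2: unequal lengths")
  pA <- mean(colA)
  pB <- mean(colB)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stopf("compute_r2: zero-variance column (monomorphic sites must be excluded)")
  }
  D <- mean(colA * colB) - pA * pB
  min(1, D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# category-pair label: paper strata use c = common, r = low_frequency
# (cc / rc / rr); pairs involving rare variants go to extra strata.
.category_pair <- function(catA, catB) {
  a <- pmin(catA, catB)  # alphabetical: common < low_frequency < rare
  b <- pmax(catA, catB)
  key <- paste(a, b)
  out <- rep(NA_character_, length(key))
  out[key == "common common"] <- "cc"
  out[key == "common low_frequency"] <- "rc"
  out[key == "low_frequency low_frequency"] <- "rr"
  out[key == "common rare"] <- "rare_common"
  out[key == "low_frequency rare"] <- "rare_lowfreq"
  out[key == "rare rare"] <- "rare_rare"
  out
}

# Enumerate in-scope unordered pairs with their r^2. Internal core shared by
# the profile, tagging and coverage stages; returns integer column indices.
.ld_pair_table <- function(panel, window = NULL, scope = c("distance", "gene"),
                           regions = NULL) {
  scope <- match.arg(scope)
  v <- panel$variants
  H <- panel$haplotypes
  n <- nrow(H)
  m <- ncol(H)
  li <- integer(0); ri <- integer(0)
  if (scope == "distance") {
    if (is.null(window) || window <= 0) stopf("ld pairs: window must be > 0")
    for (ch in unique(v$chrom)) {
      idx <- which(v$chrom == ch)
      p <- v$pos[idx]
      hi <- findInterval(p + window, p)
      for (k in seq_along(idx)) {
        if (hi[k] > k) {
          li <- c(li, rep(idx[k], hi[k] - k))
          ri <- c(ri, idx[(k + 1L):hi[k]])
        }
      }
    }
  } else {
    if (is.null(regions)) stopf("ld pairs: scope='gene' requires regions")
    for (g in seq_len(nrow(regions))) {
      idx <- which(v$chrom == regions$chrom[g] &
                   v$pos > regions$start[g] & v$pos <= regions$end[g])
      if (length(idx) >= 2L) {
        cmb <- utils::combn(idx, 2L)
        li <- c(li, cmb[1L, ])
        ri <- c(ri, cmb[2L, ])
      }
    }
  }
  if (length(li) == 0L) {
    return(data.frame(li = integer(0), ri = integer(0), distance = integer(0),
                      r2 = numeric(0)))
  }
  # vectorized r^2 through standardized columns, chunked to bound memory
  Z <- scale(H)
  r2 <- numeric(length(li))
  chunk <- 50000L
  for (s in seq(1L, length(li), by = chunk)) {
    e <- min(s + chunk - 1L, length(li))
    r2[s:e] <- pmin(1, (colSums(Z[, li[s:e], drop = FALSE] *
                                Z[, ri[s:e], drop = FALSE]) / (n - 1))^2)
  }
  data.frame(li = li, ri = ri, distance = abs(v$pos[ri] - v$pos[li]), r2 = r2)
}

#' Enumerate in-scope SNP pairs with r^2 and MAF-category strata
#'
#' Every unordered pair within the inter-marker window (same chromosome) or
#' within the same gene region contributes exactly once.
#'
#' @param panel a [haplotype_panel()].
#' @param window inter-marker distance in basepairs (distance scope).
#' @param scope `"distance"` or `"gene"`.
#' @param regions gene regions (required for gene scope).
#' @return data.frame: `left`, `right` (variant ids), `distance`, `r2`,
#'   `category_pair` (`cc`/`rc`/`rr` for the common/low-frequency strata,
#'   `rare_*` for pairs involving rare variants).
#' @export
ld_pairs <- function(panel, window = NULL, scope = c("distance", "gene"),
                     regions = NULL) {
  validate_panel(panel)
  scope <- match.arg(scope)
  tab <- .ld_pair_table(panel, window, scope, regions)
  v <- panel$variants
  data.frame(
    left = v$id[tab$li], right = v$id[tab$ri],
    distance = tab$distance, r2 = tab$r2,
    category_pair = .category_pair(v$category[tab$li], v$category[tab$ri]),
    stringsAsFactors = FALSE
  )
}

#' Proportions of r^2 values in five fixed intervals
#'
#' Bins are left-closed at 0.2 steps with the top bin closed:
#' \[0,0.2), \[0.2,0.4), \[0.4,0.6), \[0.6,0.8), \[0.8,1\]; the named
#' thresholds 0.2 and 0.8 (weak / strong LD) fall on bin edges.
#'
#' @param r2_values nonempty numeric vector in \[0, 1\].
#' @return named vector of five proportions summing to 1.
#' @export
bin_r2_proportions <- function(r2_values) {
  if (length(r2_values) == 0L) stopf("bin_r2_proportions: empty input")
  if (any(r2_values < 0 | r2_values > 1)) stopf("bin_r2_proportions: r2 outside [0, 1]")
  bin <- findInterval(r2_values, .r2_bin_breaks)
  out <- tabulate(bin, nbins = 5L) / length(r2_values)
  names(out) <- .r2_bin_names
  out
}

#' Five-interval LD profile stratified by MAF-category pair
#'
#' @inheritParams ld_pairs
#' @param strata `"paper"` restricts to the cc / rc / rr strata (pairs
#'   involving rare variants are excluded, as in the three-stratum figures);
#'   `"all"` adds the `rare_*` strata.
#' @return data.frame with one row per stratum: `window`, `scope`, `stratum`,
#'   `n_pairs` and the five bin proportions (NA when `n_pairs` is 0).
#' @export
pairwise_ld_profile <- function(panel, window = NULL,
                                scope = c("distance", "gene"), regions = NULL,
                                strata = c("paper", "all")) {
  scope <- match.arg(scope)
  strata <- match.arg(strata)
  pairs <- ld_pairs(panel, window, scope, regions)
  levels <- if (strata == "paper") .paper_strata else
    c(.paper_strata, "rare_common", "rare_lowfreq", "rare_rare")
  out <- lapply(levels, function(s) {
    r2 <- pairs$r2[pairs$category_pair == s]
    props <- if (length(r2)) bin_r2_proportions(r2) else
      stats::setNames(rep(NA_real_, 5L), .r2_bin_names)
    cbind(data.frame(window = if (scope == "distance") window else NA_integer_,
                     scope = scope, stratum = s, n_pairs = length(r2),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(props), check.names = FALSE))
  })
  do.call(rbind, out)
}

#' Dosage r^2: squared correlation between true and imputed genotypes
#'
#' The standard imputation-accuracy metric: the squared Pearson correlation
#' between true genotypes (0/1/2) and imputed dosages.  Constant dosages give
#' 0 (no information); constant truth is a domain error.
#'
#' @param true_genotypes integer vector in \{0,1,2\}, length >= 2, not all equal.
#' @param imputed_dosages numeric vector of the same length.
#' @return squared correlation in \[0, 1\].
#' @export
dosage_r2 <- function(true_genotypes, imputed_dosages) {
  if (length(true_genotypes) != length(imputed_dosages)) stopf("dosage_r2: unequal lengths")
  if (length(true_genotypes) < 2L) stopf("dosage_r2: need length >= 2")
  if (stats::var(true_genotypes) == 0) stopf("dosage_r2: constant true genotypes")
  if (stats::var(imputed_dosages) == 0) return(0)
  stats::cor(true_genotypes, imputed_dosages)^2
}
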