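# Synthetic phased panels: neutral folded site-frequency spectrum imposed on
# a founder-copying mosaic, giving block-structured LD with distance decay.
# The generator stands in for chromosome-scale (low-coverage-like) and short
# multi-gene (exome-like) panels so every downstream stage is testable
# without external data.

#' Simulation configuration
#'
#' Defaults emulate the shapes this package is exercised on: chromosome mode
#' is a 1 Mb region with 55 samples (a typical phased reference-panel size);
#' genes mode is 382 genes carrying 2,254 SNPs.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_samples number of diploid samples (2 chromosomes each).
#' @param n_variants number of polymorphic sites to place.
#' @param region_length simulated region length in basepairs (chromosome mode).
#' @param mode `"chromosome"` or `"genes"`.
#' @param n_genes number of disjoint gene regions (genes mode).
#' @param gene_span length of each gene region in basepairs.
#' @param gene_gap gap between consecutive gene regions in basepairs.
#' @param block_length haplotype-block length in basepairs; founder copying is
#'   independent across blocks.
#' @param founders_per_block number of founder lineages per block (>= 2).
#' @param switch_rate per-basepair probability that a chromosome switches
#'   founder lineage between adjacent variants (distance-scaled).
#' @param sfs `"neutral_folded"` (proportional to 1/i, folded), `"uniform"`,
#'   or a numeric weight vector over minor-allele counts `1..n_chromosomes/2`.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L, n_samples = 55L, n_variants = 3000L,
                       region_length = 1e6, mode = c("chromosome", "genes"),
                       n_genes = 382L, gene_span = 5000L, gene_gap = 50000L,
                       block_length = 50000L, founders_per_block = 10L,
                       switch_rate = 1e-5, sfs = "neutral_folded") {
  mode <- match.arg(mode)
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              region_length = as.integer(region_length), mode = mode,
              n_genes = as.integer(n_genes), gene_span = as.integer(gene_span),
              gene_gap = as.integer(gene_gap),
              block_length = as.integer(block_length),
              founders_per_block = as.integer(founders_per_block),
              switch_rate = switch_rate, sfs = sfs)
  class(cfg) <- "sim_config"
  counts <- c("n_samples", "n_variants", "region_length", "n_genes",
              "gene_span", "gene_gap", "block_length")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) stopf("sim_config: %s must be a positive count", f)
  }
  if (cfg$switch_rate < 0 || cfg$switch_rate > 1) {
    stopf("sim_config: switch_rate must lie in [0, 1]")
  }
  if (cfg$founders_per_block < 2L) {
    stopf("sim_config: founders_per_block must be >= 2; a single founder lineage leaves every column monomorphic of copying structure (no polymorphism survives)")
  }
  if (cfg$mode == "chromosome" && cfg$region_length < cfg$n_variants) {
    stopf("sim_config: region shorter than n_variants (cannot place distinct positions)")
  }
  if (cfg$mode == "genes") {
    per_gene_max <- cfg$gene_span
    if (cfg$n_variants > cfg$n_genes * per_gene_max) {
      stopf("sim_config: too many variants for %d genes of %d bp", cfg$n_genes, cfg$gene_span)
    }
  }
  if (is.character(cfg$sfs)) {
    if (!cfg$sfs %in% c("neutral_folded", "uniform")) stopf("sim_config: unknown sfs '%s'", cfg$sfs)
  } else if (!is.numeric(cfg$sfs) || any(cfg$sfs < 0) || sum(cfg$sfs) <= 0) {
    stopf("sim_config: custom sfs must be a nonnegative numeric weight vector")
  }
  cfg
}

#' Expected folded site-frequency spectrum under the standard neutral model
#'
#' Under the constant-size, random-mating neutral model the unfolded spectrum
#' is proportional to 1/i; folding onto minor-allele counts `i = 1..floor(n/2)`
#' gives weights `1/i + 1/(n-i)` (and `1/i` at `i = n/2` for even `n`).
#'
#' @param n_chromosomes sample size in chromosomes (>= 2).
#' @return vector of proportions over minor-allele counts, summing to 1.
#' @export
expected_folded_sfs <- function(n_chromosomes) {
  n <- as.integer(n_chromosomes)
  if (is.na(n) || n < 2L) stopf("expected_folded_sfs: need n_chromosomes >= 2")
  i <- seq_len(n %/% 2L)
  w <- 1 / i + 1 / (n - i)
  if (n %% 2L == 0L) w[length(w)] <- 1 / i[length(i)]
  w / sum(w)
}

.sfs_weights <- function(cfg, n_chrom) {
  kmax <- n_chrom %/% 2L
  if (is.numeric(cfg$sfs)) {
    if (length(cfg$sfs) != kmax) {
      stopf("custom sfs length %d != floor(n_chromosomes/2) = %d", length(cfg$sfs), kmax)
    }
    return(cfg$sfs / sum(cfg$sfs))
  }
  if (cfg$sfs == "uniform") return(rep(1 / kmax, kmax))
  expected_folded_sfs(n_chrom)
}

# Founder-label mosaic for one segment: label matrix (n_chrom x n_pos);
# adjacent variants share a label unless a distance-scaled switch occurs.
.founder_labels <- function(pos, n_chrom, n_founders, switch_rate) {
  k <- length(pos)
  L <- matrix(0L, nrow = n_chrom, ncol = k)
  L[, 1L] <- sample.int(n_founders, n_chrom, replace = TRUE)
  if (k > 1L) {
    for (j in 2L:k) {
      p_sw <- min(1, switch_rate * (pos[j] - pos[j - 1L]))
      sw <- stats::runif(n_chrom) < p_sw
      L[, j] <- L[, j - 1L]
      if (any(sw)) L[sw, j] <- sample.int(n_founders, sum(sw), replace = TRUE)
    }
  }
  L
}

# Per-variant rotation of the block's cyclic founder order; persistent along
# the chromosome with the same distance-scaled switching as the labels.
.rotation_path <- function(pos, n_founders, switch_rate) {
  k <- length(pos)
  rot <- integer(k)
  rot[1L] <- sample.int(n_founders, 1L)
  if (k > 1L) {
    for (j in 2L:k) {
      p_sw <- min(1, switch_rate * (pos[j] - pos[j - 1L]))
      rot[j] <- if (stats::runif(1L) < p_sw) sample.int(n_founders, 1L) else rot[j - 1L]
    }
  }
  rot
}

# Impose an exact minor-allele count per column, with carriers clustered by
# founder lineage.  Each block fixes a cyclic founder order and a
# per-chromosome base score; chromosomes are filled founder-by-founder until
# the target count is reached, so frequencies follow the configured SFS
# exactly.  Placement mirrors the age-frequency correlation of neutral
# variation: an "old" variant (count spanning more than one founder's share)
# uses a rotation that persists along the chromosome and the block's fixed
# within-founder order, so nearby old variants carry nested unions of the
# same founder clusters -- strong within-block LD between common variants.
# A "young" variant (count within a single founder's share) is a recent
# mutation placed on chromosomes drawn at random, independent of the mosaic,
# so low-frequency/low-frequency and low-frequency/common LD stay weak.
# Label and rotation switching both decay with inter-marker distance.
.segment_haplotypes <- function(pos, n_chrom, cfg, sfs_w) {
  k <- length(pos)
  F_ <- cfg$founders_per_block
  H <- matrix(0L, nrow = n_chrom, ncol = k)
  if (k == 0L) return(H)
  block <- (pos - 1L) %/% cfg$block_length
  counts <- sample.int(length(sfs_w), k, replace = TRUE, prob = sfs_w)
  cluster_share <- n_chrom / F_
  for (b in unique(block)) {
    idx <- which(block == b)
    L <- .founder_labels(pos[idx], n_chrom, F_, cfg$switch_rate)
    cyc <- sample.int(F_)               # block-level cyclic founder order
    rot <- .rotation_path(pos[idx], F_, cfg$switch_rate)
    base_score <- stats::runif(n_chrom)  # block-stable within-founder order
    for (jj in seq_along(idx)) {
      m <- counts[idx[jj]]
      if (m <= cluster_share) {
        H[sample.int(n_chrom, m), idx[jj]] <- 1L
      } else {
        prio <- cyc[((seq_len(F_) + rot[jj] - 2L) %% F_) + 1L]
        ord <- order(match(L[, jj], prio), base_score)
        H[ord[seq_len(m)], idx[jj]] <- 1L
      }
    }
  }
  H
}

#' Generate a chromosome-scale synthetic haplotype panel
#'
#' Positions are sampled uniformly without replacement over the region, minor
#' allele counts are drawn from the configured folded spectrum, and carriers
#' are placed on a founder-copying mosaic (see `sim_config`), which yields
#' high within-block r\eqn{^2} decaying with inter-marker distance and
#' independence across blocks.  Output is byte-identical under a fixed seed.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()].
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "sim_config")) stopf("generate_panel: need a sim_config")
  if (config$mode != "chromosome") stopf("generate_panel: config mode must be 'chromosome' (use generate_gene_panels for genes mode)")
  set.seed(config$seed)
  n_chrom <- 2L * config$n_samples
  sfs_w <- .sfs_weights(config, n_chrom)
  pos <- sort(sample.int(config$region_length, config$n_variants))
  H <- .segment_haplotypes(pos, n_chrom, config, sfs_w)
  haplotype_panel(H, chrom = rep("chr1", length(pos)), pos = pos,
                  id = sprintf("snp%05d", seq_along(pos)),
                  sample_ids = sprintf("sim%03d", seq_len(config$n_samples)),
                  drop_monomorphic = FALSE)
}

#' Generate a multi-gene synthetic panel with its gene regions
#'
#' Emulates an exome-style panel: `n_genes` disjoint regions laid end to end
#' (span `gene_span`, gap `gene_gap`), variants distributed near-evenly across
#' genes, and founder copying independent between genes.
#'
#' @param config a [sim_config()] with `mode = "genes"`.
#' @return list with elements `panel` (a [haplotype_panel()]) and `regions`
#'   (gene-region data.frame, BED 0-based half-open).
#' @export
generate_gene_panels <- function(config) {
  if (!inherits(config, "sim_config")) stopf("generate_gene_panels: need a sim_config")
  if (config$mode != "genes") stopf("generate_gene_panels: config mode must be 'genes'")
  set.seed(config$seed)
  n_chrom <- 2L * config$n_samples
  sfs_w <- .sfs_weights(config, n_chrom)
  G <- config$n_genes
  starts1 <- 1L + (seq_len(G) - 1L) * (config$gene_span + config$gene_gap)  # 1-based first bp
  ends1 <- starts1 + config$gene_span - 1L
  # near-even allocation of variants to genes
  base <- config$n_variants %/% G
  alloc <- rep(base, G)
  rem <- config$n_variants - base * G
  if (rem > 0L) {
    extra <- sample.int(G, rem)
    alloc[extra] <- alloc[extra] + 1L
  }
  pos <- integer(0)
  gene_of <- integer(0)
  for (g in seq_len(G)) {
    if (alloc[g] == 0L) next
    pg <- sort(sample.int(config$gene_span, alloc[g])) + starts1[g] - 1L
    pos <- c(pos, pg)
    gene_of <- c(gene_of, rep(g, alloc[g]))
  }
  H <- matrix(0L, nrow = n_chrom, ncol = length(pos))
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    H[, idx] <- .segment_haplotypes(pos[idx], n_chrom, config, sfs_w)
  }
  panel <- haplotype_panel(H, chrom = rep("chr1", length(pos)), pos = pos,
                           id = sprintf("snp%05d", seq_along(pos)),
                           sample_ids = sprintf("sim%03d", seq_len(config$n_samples)),
                           drop_monomorphic = FALSE)
  regions <- data.frame(name = sprintf("gene%04d", seq_len(G)),
                        chrom = "chr1", start = starts1 - 1L, end = ends1,
                        stringsAsFactors = FALSE)
  if (G > 1L && any(starts1[-1L] <= ends1[-G])) {
    stopf("generate_gene_panels: internal error, overlapping regions")
  }
  list(panel = panel, regions = regions)
}

#' Ascertain a fixed-content array from a discovery subsample
#'
#' Models a chip whose content is frozen by a finite discovery cohort: the
#' manifest contains exactly the panel sites that are polymorphic within the
#' discovery samples.  Variants carried only by individuals outside the
#' discovery set are invisible to the chip.
#'
#' @param panel a [haplotype_panel()].
#' @param discovery_sample_ids subset of `panel$sample_ids` (may be empty,
#'   giving an empty manifest).
#' @param name manifest name.
#' @return an [array_manifest()].
#' @export
ascertain_discovery_panel <- function(panel, discovery_sample_ids, name = "discovery") {
  validate_panel(panel)
  unknown <- setdiff(discovery_sample_ids, panel$sample_ids)
  if (length(unknown)) stopf("ascertain_discovery_panel: unknown sample id(s): %s",
                             paste(utils::head(unknown, 3), collapse = ", "))
  if (length(discovery_sample_ids) == 0L) {
    return(array_manifest(character(0), integer(0), name = name))
  }
  si <- which(panel$sample_ids %in% discovery_sample_ids)
  rows <- as.vector(rbind(2L * si - 1L, 2L * si))
  cs <- colSums(panel$haplotypes[rows, , drop = FALSE])
  poly <- cs > 0L & cs < length(rows)
  array_manifest(panel$variants$chrom[poly], panel$variants$pos[poly], name = name)
}
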