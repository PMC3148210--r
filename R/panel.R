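# HaplotypePanel: the phased substrate of every downstream stage.
# variants: data.frame(id, chrom, pos, ref, alt, maf, category) sorted by (chrom, pos)
# haplotypes: integer matrix in {0,1}, one row per chromosome, one column per variant;
#   rows 2k-1, 2k belong to sample k.

.maf_categories <- c("common", "low_frequency", "rare")

#' Minor allele frequency of a haplotype column
#'
#' @param column vector of 0/1 allele indicators (one entry per chromosome).
#' @return `min(f, 1 - f)` where `f` is the alternate-allele frequency.
#' @examples
#' compute_maf(c(0, 0, 0, 1)) # 0.25
#' @export
compute_maf <- function(column) {
  if (length(column) == 0L) stopf("compute_maf: empty column")
  if (anyNA(column) || !all(column %in% c(0L, 1L))) {
    stopf("compute_maf: column must be 0/1 with no missing values")
  }
  f <- mean(column)
  min(f, 1 - f)
}

#' Classify a minor allele frequency into common / low-frequency / rare
#'
#' Boundaries follow the conventions used throughout the package:
#' rare when MAF <= 0.5%, low frequency when 0.5% < MAF <= 5%,
#' common when MAF > 5%.  Both boundaries are inclusive on the
#' lower-frequency side.
#'
#' @param maf numeric vector of minor allele frequencies in \[0, 0.5\].
#' @return character vector with values `"common"`, `"low_frequency"`, `"rare"`.
#' @export
classify_maf_category <- function(maf) {
  if (anyNA(maf) || any(maf < -1e-12) || any(maf > 0.5 + 1e-12)) {
    stopf("classify_maf_category: maf must lie in [0, 0.5]")
  }
  out <- rep("common", length(maf))
  out[maf <= 0.05] <- "low_frequency"
  out[maf <= 0.005] <- "rare"
  out
}

#' Construct a phased haplotype panel
#'
#' @param haplotypes matrix of 0/1 alleles, one row per chromosome (two
#'   consecutive rows per sample), one column per variant.
#' @param chrom,pos,id,ref,alt per-variant annotation vectors. `pos` is 1-based.
#' @param sample_ids one id per sample (`nrow(haplotypes)/2` of them).
#' @param drop_monomorphic drop zero-variance columns (with a logged count)
#'   instead of failing validation.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, chrom, pos, id = NULL, ref = NULL,
                            alt = NULL, sample_ids = NULL,
                            drop_monomorphic = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  dimnames(haplotypes) <- NULL
  m <- ncol(haplotypes)
  n <- nrow(haplotypes)
  if (n %% 2L != 0L) stopf("haplotype_panel: row count must be even (two chromosomes per sample)")
  if (length(chrom) != m || length(pos) != m) {
    stopf("haplotype_panel: variant annotation length does not match column count")
  }
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n %/% 2L))
  if (length(sample_ids) != n %/% 2L) stopf("haplotype_panel: need one sample id per pair of rows")
  if (anyDuplicated(sample_ids)) stopf("haplotype_panel: duplicate sample ids")

  ord <- variant_order(chrom, pos)
  if (m > 0L && anyDuplicated(paste(chrom, pos))) {
    stopf("haplotype_panel: duplicate (chrom, pos) forbidden")
  }
  haplotypes <- haplotypes[, ord, drop = FALSE]
  variants <- data.frame(
    id = as.character(id)[ord], chrom = chrom[ord], pos = pos[ord],
    ref = as.character(ref)[ord], alt = as.character(alt)[ord],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(variants$id)) stopf("haplotype_panel: duplicate variant ids")

  panel <- structure(
    list(variants = variants, haplotypes = haplotypes, sample_ids = sample_ids),
    class = "haplotype_panel"
  )
  panel <- .refresh_maf(panel, drop_monomorphic = drop_monomorphic,
                        context = "haplotype_panel")
  validate_panel(panel)
}

# recompute maf/category; optionally drop monomorphic columns with a log line
.refresh_maf <- function(panel, drop_monomorphic = TRUE, context = "panel") {
  H <- panel$haplotypes
  m <- ncol(H)
  if (m == 0L) {
    panel$variants$maf <- numeric(0)
    panel$variants$category <- character(0)
    return(panel)
  }
  f <- colMeans(H)
  mono <- f == 0 | f == 1
  if (any(mono)) {
    if (!drop_monomorphic) stopf("%s: %d monomorphic column(s)", context, sum(mono))
    tp_log("info", sprintf("%s: removed %d monomorphic column(s)", context, sum(mono)))
    H <- H[, !mono, drop = FALSE]
    panel$haplotypes <- H
    panel$variants <- panel$variants[!mono, , drop = FALSE]
    rownames(panel$variants) <- NULL
    f <- f[!mono]
  }
  panel$variants$maf <- pmin(f, 1 - f)
  panel$variants$category <- classify_maf_category(panel$variants$maf)
  panel
}

#' Validate a haplotype panel against its invariants
#'
#' Checks column/annotation agreement, even row count, polymorphism of every
#' column, strict (chrom, pos) sorting and the maf/category annotations.
#'
#' @param panel a `haplotype_panel`.
#' @return the panel, invisibly usable in pipelines; errors on violation.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "haplotype_panel")) stopf("not a haplotype_panel")
  v <- panel$variants
  H <- panel$haplotypes
  if (ncol(H) != nrow(v)) stopf("panel: column count != variant count")
  if (nrow(H) %% 2L != 0L) stopf("panel: odd haplotype row count")
  if (length(panel$sample_ids) != nrow(H) %/% 2L) stopf("panel: sample id count mismatch")
  if (ncol(H) > 0L) {
    cs <- colSums(H)
    if (any(cs == 0L | cs == nrow(H))) stopf("panel: monomorphic column present")
    ord <- variant_order(v$chrom, v$pos)
    if (!identical(ord, seq_len(nrow(v)))) stopf("panel: variants not sorted by (chrom, pos)")
    if (anyDuplicated(paste(v$chrom, v$pos))) stopf("panel: duplicate (chrom, pos)")
    if (max(abs(v$maf - pmin(colMeans(H), 1 - colMeans(H)))) > 1e-12) {
      stopf("panel: stale maf annotation")
    }
  }
  panel
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d variants x %d chromosomes (%d samples)\n",
              ncol(x$haplotypes), nrow(x$haplotypes), length(x$sample_ids)))
  if (ncol(x$haplotypes) > 0L) {
    tab <- table(factor(x$variants$category, levels = .maf_categories))
    cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of variants / samples in a panel
#' @param panel a `haplotype_panel`.
#' @export
n_variants <- function(panel) ncol(panel$haplotypes)

#' @rdname n_variants
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Subset a panel by variants, samples, gene regions, or an array manifest
#'
#' Ordering of retained variants is preserved.  After sample subsetting the
#' MAF and category annotations are recomputed on the retained chromosomes and
#' columns that became monomorphic are dropped with a logged count.
#'
#' @param panel a `haplotype_panel`.
#' @param variants character vector of variant ids to keep.
#' @param samples character vector of sample ids to keep.
#' @param regions a gene-region data.frame (see [read_gene_regions()]); a
#'   variant at 1-based position `pos` belongs to a region iff
#'   `start < pos <= end` (BED half-open convention).
#' @param manifest an [array_manifest()]; keeps variants whose (chrom, pos)
#'   is on the manifest.
#' @return a new `haplotype_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL,
                         regions = NULL, manifest = NULL) {
  validate_panel(panel)
  v <- panel$variants
  keep <- rep(TRUE, nrow(v))
  if (!is.null(variants)) {
    unknown <- setdiff(variants, v$id)
    if (length(unknown)) stopf("subset_panel: unknown variant id(s): %s",
                               paste(utils::head(unknown, 3), collapse = ", "))
    keep <- keep & v$id %in% variants
  }
  if (!is.null(regions)) {
    inr <- rep(FALSE, nrow(v))
    for (k in seq_len(nrow(regions))) {
      inr <- inr | (v$chrom == regions$chrom[k] &
                    v$pos > regions$start[k] & v$pos <= regions$end[k])
    }
    keep <- keep & inr
  }
  if (!is.null(manifest)) {
    keep <- keep & paste(v$chrom, v$pos) %in% paste(manifest$sites$chrom, manifest$sites$pos)
  }
  rows <- seq_len(nrow(panel$haplotypes))
  sample_ids <- panel$sample_ids
  if (!is.null(samples)) {
    unknown <- setdiff(samples, panel$sample_ids)
    if (length(unknown)) stopf("subset_panel: unknown sample id(s): %s",
                               paste(utils::head(unknown, 3), collapse = ", "))
    si <- which(panel$sample_ids %in% samples)
    rows <- as.vector(rbind(2L * si - 1L, 2L * si))
    sample_ids <- panel$sample_ids[si]
  }
  out <- structure(
    list(variants = v[keep, , drop = FALSE],
         haplotypes = panel$haplotypes[rows, keep, drop = FALSE],
         sample_ids = sample_ids),
    class = "haplotype_panel"
  )
  rownames(out$variants) <- NULL
  out <- .refresh_maf(out, drop_monomorphic = TRUE, context = "subset_panel")
  validate_panel(out)
}
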