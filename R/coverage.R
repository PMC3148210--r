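# Coverage of a target panel by a fixed marker set: a target SNP is covered
# directly (its own site is on the array) or indirectly (some array site
# within the window has r^2 >= threshold with it).  Array sites absent from
# the target panel, or monomorphic in its samples, capture nothing.

#' Coverage of a target panel by a fixed tag set at one r^2 threshold
#'
#' @param target a [haplotype_panel()] (the cohort being evaluated).
#' @param tags an [array_manifest()] (the fixed marker set).
#' @param threshold r^2 threshold in (0, 1].
#' @param window maximal distance for indirect capture, in basepairs
#'   (default 200 kb, the widest tagging window used here).
#' @param count_direct should a target SNP whose own site is on the array
#'   count as covered (r^2 = 1 by convention)?  Default TRUE: arrays genotype
#'   their own content.
#' @return a `coverage_report` data.frame with one row per MAF category plus
#'   an `overall` row: `category`, `n_target`, `n_covered`, `proportion`;
#'   attributes `threshold` and `tag_set_name`.
#' @export
coverage_at_threshold <- function(target, tags, threshold, window = 200000L,
                                  count_direct = TRUE) {
  validate_panel(target)
  if (!inherits(tags, "array_manifest")) stopf("coverage: tags must be an array_manifest")
  if (threshold <= 0 || threshold > 1) stopf("coverage: threshold must lie in (0, 1]")
  if (window <= 0) stopf("coverage: window must be > 0")
  v <- target$variants
  m <- nrow(v)
  on_array <- paste(v$chrom, v$pos) %in% paste(tags$sites$chrom, tags$sites$pos)
  covered <- if (count_direct) on_array else rep(FALSE, m)
  tag_idx <- which(on_array)  # array sites present (and so polymorphic) in target
  if (length(tag_idx) > 0L && m > 0L) {
    H <- target$haplotypes
    Z <- scale(H)
    n <- nrow(H)
    for (i in which(!covered)) {
      cand <- tag_idx[v$chrom[tag_idx] == v$chrom[i] &
                      abs(v$pos[tag_idx] - v$pos[i]) <= window &
                      tag_idx != i]
      if (length(cand) == 0L) next
      r2 <- (colSums(Z[, i] * Z[, cand, drop = FALSE]) / (n - 1))^2
      if (any(r2 >= threshold - 1e-12)) covered[i] <- TRUE
    }
  }
  cats <- intersect(.maf_categories, unique(v$category))
  rows <- lapply(cats, function(cc) {
    sel <- v$category == cc
    data.frame(category = cc, n_target = sum(sel), n_covered = sum(covered[sel]),
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- data.frame(category = "overall", n_target = m,
                                          n_covered = sum(covered),
                                          stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$proportion <- ifelse(out$n_target > 0L, out$n_covered / out$n_target, NA_real_)
  attr(out, "threshold") <- threshold
  attr(out, "tag_set_name") <- tags$name
  class(out) <- c("coverage_report", class(out))
  out
}

#' Coverage across a sweep of r^2 thresholds
#'
#' @inheritParams coverage_at_threshold
#' @param thresholds numeric vector of thresholds, sorted ascending.
#' @return data.frame stacking one [coverage_at_threshold()] report per
#'   threshold, with a leading `threshold` column.  Proportions are
#'   non-increasing in the threshold.
#' @export
coverage_curve <- function(target, tags, thresholds, window = 200000L,
                           count_direct = TRUE) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stopf("coverage_curve: thresholds must be sorted strictly ascending")
  }
  out <- lapply(thresholds, function(th) {
    rep_ <- coverage_at_threshold(target, tags, th, window, count_direct)
    cbind(data.frame(threshold = th), as.data.frame(rep_))
  })
  do.call(rbind, out)
}
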