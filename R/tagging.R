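# Greedy pairwise tag-SNP selection with bins, plus untaggable-SNP
# detection, at distance or gene scope.  "Exceeding the threshold" is
# implemented as r^2 >= threshold throughout (ties included), matching the
# >= 0.8 strong-LD convention.

# adjacency lists over in-scope edges with r^2 >= threshold
.tag_adjacency <- function(panel, threshold, scope, window, regions) {
  if (threshold <= 0 || threshold > 1) stopf("tagging: threshold must lie in (0, 1]")
  tab <- .ld_pair_table(panel, window, scope, regions)
  keep <- tab$r2 >= threshold
  m <- n_variants(panel)
  ends <- c(tab$li[keep], tab$ri[keep])
  nbrs <- c(tab$ri[keep], tab$li[keep])
  unname(split(nbrs, factor(ends, levels = seq_len(m))))
}

#' Greedy tag-SNP selection
#'
#' Iteratively selects, among the remaining SNPs, the one with the maximal
#' number of remaining in-scope neighbours at `r^2 >= threshold`; that SNP
#' becomes a tag and together with those neighbours forms a bin, all of which
#' are removed before the next round.  Neighbour counts are recomputed against
#' the remaining SNPs each round.  SNPs with zero qualifying neighbours at
#' selection time are untaggable (not size-one bins).  Ties on the maximal
#' count are broken by lowest (chrom, pos).
#'
#' @param panel a [haplotype_panel()].
#' @param threshold r^2 threshold in (0, 1].
#' @param scope `"distance"` (inter-marker window) or `"gene"` (same region).
#' @param window window in basepairs (distance scope); default 200 kb.
#' @param regions gene regions (gene scope).
#' @return a `tag_assignment`: list with `threshold`, `scope`, `window`,
#'   `bins` (list of `list(tag=, tagged=)`), `untaggable` (ids), and
#'   `variant_ids` for consistency checks.  Every panel variant appears
#'   exactly once across tags, tagged members and untaggable.
#' @export
greedy_select_tags <- function(panel, threshold, scope = c("distance", "gene"),
                               window = 200000L, regions = NULL) {
  validate_panel(panel)
  scope <- match.arg(scope)
  adj <- .tag_adjacency(panel, threshold, scope, window, regions)
  m <- n_variants(panel)
  ids <- panel$variants$id
  remaining <- rep(TRUE, m)
  bins <- list()
  untaggable <- character(0)
  while (any(remaining)) {
    rem_idx <- which(remaining)
    deg <- vapply(rem_idx, function(i) sum(remaining[adj[[i]]]), integer(1L))
    zero <- rem_idx[deg == 0L]
    if (length(zero)) {
      untaggable <- c(untaggable, ids[zero])
      remaining[zero] <- FALSE
      rem_idx <- rem_idx[deg > 0L]
      deg <- deg[deg > 0L]
    }
    if (length(rem_idx) == 0L) break
    tag <- rem_idx[which.max(deg)]  # variants sorted by (chrom, pos): first max wins
    members <- adj[[tag]][remaining[adj[[tag]]]]
    bins[[length(bins) + 1L]] <- list(tag = ids[tag], tagged = sort(ids[members]))
    remaining[c(tag, members)] <- FALSE
  }
  structure(list(threshold = threshold, scope = scope,
                 window = if (scope == "distance") window else NA_integer_,
                 bins = bins, untaggable = untaggable, variant_ids = ids),
            class = "tag_assignment")
}

#' @export
print.tag_assignment <- function(x, ...) {
  cat(sprintf("tag_assignment: %d bins, %d untaggable of %d SNPs (r2 >= %g, %s scope)\n",
              length(x$bins), length(x$untaggable), length(x$variant_ids),
              x$threshold, x$scope))
  invisible(x)
}

#' Untaggable SNPs at a threshold
#'
#' Exactly the variants with no in-scope partner at `r^2 >= threshold`;
#' independent of any greedy selection order.
#'
#' @inheritParams greedy_select_tags
#' @return character vector of variant ids.
#' @export
find_untaggable <- function(panel, threshold, scope = c("distance", "gene"),
                            window = 200000L, regions = NULL) {
  validate_panel(panel)
  scope <- match.arg(scope)
  if (scope == "gene" && is.null(regions)) stopf("find_untaggable: scope='gene' requires regions")
  adj <- .tag_adjacency(panel, threshold, scope, window, regions)
  deg <- lengths(adj)
  panel$variants$id[deg == 0L]
}

#' Tag / tagged / untaggable proportions per MAF category
#'
#' @param assignment a `tag_assignment` produced from `panel`.
#' @param panel the originating [haplotype_panel()].
#' @return data.frame with one row per MAF category present in the panel:
#'   `category`, `n`, `prop_tag`, `prop_tagged`, `prop_untaggable`
#'   (rows sum to 1).
#' @export
tag_summary <- function(assignment, panel) {
  if (!inherits(assignment, "tag_assignment")) stopf("tag_summary: need a tag_assignment")
  validate_panel(panel)
  if (!setequal(assignment$variant_ids, panel$variants$id)) {
    stopf("tag_summary: assignment does not match panel variants")
  }
  status <- stats::setNames(rep(NA_character_, n_variants(panel)), panel$variants$id)
  for (b in assignment$bins) {
    status[b$tag] <- "tag"
    status[b$tagged] <- "tagged"
  }
  status[assignment$untaggable] <- "untaggable"
  if (anyNA(status)) stopf("tag_summary: assignment does not partition the panel")
  cat_ <- panel$variants$category
  cats <- intersect(.maf_categories, unique(cat_))
  out <- do.call(rbind, lapply(cats, function(cc) {
    s <- status[cat_ == cc]
    data.frame(category = cc, n = length(s),
               prop_tag = mean(s == "tag"),
               prop_tagged = mean(s == "tagged"),
               prop_untaggable = mean(s == "untaggable"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
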