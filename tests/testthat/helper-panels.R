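# Fixtures are built in code; no data files.

quiet <- function(expr) {
  old <- options(tagpower.loglevel = "warn")
  on.exit(options(old))
  expr
}

# panel from explicit haplotype columns (list of 0/1 vectors)
toy_panel <- function(cols, pos = NULL, chrom = NULL, ids = NULL) {
  H <- do.call(cbind, cols)
  m <- ncol(H)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  quiet(haplotype_panel(H, chrom = chrom, pos = pos, id = ids))
}

# column of given length with ones at `at`
ones_at <- function(n, at) {
  x <- integer(n)
  x[at] <- 1L
  x
}

# panel whose columns are all copies of one polymorphic column
dup_panel <- function(n_hap = 8L, n_var = 4L, spacing = 1000L) {
  base <- ones_at(n_hap, seq_len(n_hap %/% 2L))
  toy_panel(rep(list(base), n_var), pos = seq_len(n_var) * spacing)
}

# random small polymorphic panel (each column redrawn until polymorphic)
random_small_panel <- function(n_hap, n_var, spacing = 1000L) {
  n_hap <- 2L * ((as.integer(n_hap) + 1L) %/% 2L)  # even row count
  cols <- lapply(seq_len(n_var), function(j) {
    repeat {
      x <- stats::rbinom(n_hap, 1L, stats::runif(1, 0.1, 0.9))
      if (sum(x) > 0L && sum(x) < n_hap) return(x)
    }
  })
  toy_panel(cols, pos = seq_len(n_var) * spacing)
}

# independent r^2 oracle: squared Pearson correlation (compute_r2 uses the
# gamete-frequency formula)
r2_cor_oracle <- function(a, b) stats::cor(a, b)^2

# brute-force zero-degree (untaggable) oracle over all in-scope pairs
untaggable_oracle <- function(panel, threshold, window) {
  v <- panel$variants
  m <- nrow(v)
  deg <- integer(m)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (v$chrom[i] == v$chrom[j] && abs(v$pos[i] - v$pos[j]) <= window &&
          compute_r2(panel$haplotypes[, i], panel$haplotypes[, j]) >= threshold) {
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
  }
  v$id[deg == 0L]
}

# brute-force minimum tag cover (dominating set over the r^2 graph restricted
# to SNPs that have at least one in-scope partner); returns minimal size
min_tag_cover_oracle <- function(panel, threshold, window) {
  v <- panel$variants
  m <- nrow(v)
  A <- matrix(FALSE, m, m)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (v$chrom[i] == v$chrom[j] && abs(v$pos[i] - v$pos[j]) <= window &&
          compute_r2(panel$haplotypes[, i], panel$haplotypes[, j]) >= threshold) {
        A[i, j] <- A[j, i] <- TRUE
      }
    }
  }
  coverable <- which(rowSums(A) > 0L)
  if (length(coverable) == 0L) return(0L)
  for (size in seq_along(coverable)) {
    subsets <- utils::combn(coverable, size, simplify = FALSE)
    for (T_ in subsets) {
      dominated <- union(T_, which(apply(A[, T_, drop = FALSE], 1L, any)))
      if (all(coverable %in% dominated)) return(size)
    }
  }
  length(coverable)
}

# flat tag-assignment certificate: every tagged member has an in-scope
# r^2 >= threshold edge to its tag, and the three-way partition is exact
check_tag_certificate <- function(assignment, panel) {
  v <- panel$variants
  seen <- character(0)
  for (b in assignment$bins) {
    seen <- c(seen, b$tag, b$tagged)
    ti <- match(b$tag, v$id)
    for (mem in b$tagged) {
      mi <- match(mem, v$id)
      expect_true(v$chrom[ti] == v$chrom[mi] &&
                  abs(v$pos[ti] - v$pos[mi]) <= assignment$window)
      expect_gte(compute_r2(panel$haplotypes[, ti], panel$haplotypes[, mi]),
                 assignment$threshold)
    }
  }
  seen <- c(seen, assignment$untaggable)
  expect_setequal(seen, v$id)
  expect_equal(anyDuplicated(seen), 0L)
}

write_vcf_lines <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
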