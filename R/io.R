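# Readers and writers for the standard interchange formats:
# phased VCF (via VariantAnnotation), IMPUTE-style hap/legend, BED gene
# regions (via rtracklayer), and two-column array manifests.

#' Read a phased VCF into a haplotype panel
#'
#' Strict contract: every record must be a biallelic SNP with fully phased
#' ("|") and non-missing GT fields.  Monomorphic records are removed with a
#' logged count; unphased, missing or multiallelic records are errors (no
#' imputation, no phasing is attempted here).
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return a [haplotype_panel()].
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stopf("read_phased_vcf: no such file: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("read_phased_vcf: VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ids <- names(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altl)
  if (any(nalt != 1L)) {
    bad <- which(nalt != 1L)[1L]
    stopf("read_phased_vcf: multiallelic record at %s:%d", chrom[bad], pos[bad])
  }
  alts <- as.character(unlist(altl))
  snp <- nchar(refs) == 1L & nchar(alts) == 1L
  if (length(snp) && !all(snp)) {
    bad <- which(!snp)[1L]
    stopf("read_phased_vcf: non-SNP record at %s:%d", chrom[bad], pos[bad])
  }
  samples <- colnames(gt)
  if (length(gt)) {
    miss <- matrix(grepl(".", gt, fixed = TRUE), nrow = nrow(gt))
    if (any(miss)) {
      bad <- which(miss, arr.ind = TRUE)[1L, ]
      stopf("read_phased_vcf: missing genotype at %s:%d (sample %s); missing GTs are rejected, not imputed",
            chrom[bad[1L]], pos[bad[1L]], samples[bad[2L]])
    }
    unph <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
    if (any(unph)) {
      bad <- which(unph, arr.ind = TRUE)[1L, ]
      stopf("read_phased_vcf: unphased genotype at %s:%d (sample %s); all GTs must use '|'",
            chrom[bad[1L]], pos[bad[1L]], samples[bad[2L]])
    }
    ok <- matrix(gt %in% c("0|0", "0|1", "1|0", "1|1"), nrow = nrow(gt))
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1L, ]
      stopf("read_phased_vcf: malformed GT '%s' at %s:%d",
            gt[bad[1L], bad[2L]], chrom[bad[1L]], pos[bad[1L]])
    }
  }
  nvar <- nrow(gt)
  nsamp <- ncol(gt)
  H <- matrix(0L, nrow = 2L * nsamp, ncol = nvar)
  if (nvar > 0L && nsamp > 0L) {
    a1 <- matrix(as.integer(substring(gt, 1L, 1L)), nrow = nvar)
    a2 <- matrix(as.integer(substring(gt, 3L, 3L)), nrow = nvar)
    H[seq(1L, 2L * nsamp, by = 2L), ] <- t(a1)
    H[seq(2L, 2L * nsamp, by = 2L), ] <- t(a2)
  }
  if (is.null(ids) || anyDuplicated(ids)) ids <- paste0(chrom, ":", pos)
  haplotype_panel(H, chrom = chrom, pos = pos, id = ids, ref = refs, alt = alts,
                  sample_ids = samples, drop_monomorphic = TRUE)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCFv4.2 file with phased GT fields; the round trip through
#' [read_phased_vcf()] reproduces the haplotype matrix and positions exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  validate_panel(panel)
  v <- panel$variants
  H <- panel$haplotypes
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    stopf("write_phased_vcf: cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tagpower",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  if (nrow(v) > 0L) {
    ns <- length(panel$sample_ids)
    odd <- H[seq(1L, 2L * ns, by = 2L), , drop = FALSE]
    evn <- H[seq(2L, 2L * ns, by = 2L), , drop = FALSE]
    gts <- matrix(paste0(t(odd), "|", t(evn)), nrow = nrow(v))  # variant x sample
    lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                   sep = "\t")
    if (ns > 0L) {
      lines <- paste(lines, apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read / write IMPUTE-style hap + legend files
#'
#' Secondary dialect: the legend is whitespace-delimited with header
#' `id position a0 a1`; the hap file has one row per variant and one 0/1
#' column per haplotype.
#'
#' @param hap_path,legend_path file paths.
#' @param chrom chromosome name to assign (the legend format carries none).
#' @param sample_ids optional sample ids (defaults to `sample1..k`).
#' @return a [haplotype_panel()].
#' @export
read_hap_legend <- function(hap_path, legend_path, chrom = "1", sample_ids = NULL) {
  leg <- utils::read.table(legend_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("id", "position", "a0", "a1")
  if (!all(need %in% names(leg))) stopf("read_hap_legend: legend must have columns %s",
                                        paste(need, collapse = " "))
  hap <- as.matrix(utils::read.table(hap_path, header = FALSE))
  if (nrow(hap) != nrow(leg)) stopf("read_hap_legend: hap rows != legend rows")
  if (ncol(hap) %% 2L != 0L) stopf("read_hap_legend: odd haplotype count")
  haplotype_panel(t(hap), chrom = rep(chrom, nrow(leg)), pos = leg$position,
                  id = leg$id, ref = leg$a0, alt = leg$a1,
                  sample_ids = sample_ids, drop_monomorphic = TRUE)
}

#' @rdname read_hap_legend
#' @param panel a [haplotype_panel()] to write.
#' @export
write_hap_legend <- function(panel, hap_path, legend_path) {
  validate_panel(panel)
  v <- panel$variants
  utils::write.table(
    data.frame(id = v$id, position = v$pos, a0 = v$ref, a1 = v$alt),
    legend_path, quote = FALSE, row.names = FALSE
  )
  utils::write.table(t(panel$haplotypes), hap_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(hap_path)
}

#' Read gene regions from a BED file
#'
#' BED is 0-based half-open; coordinates are kept in that convention and a
#' variant at 1-based position `pos` belongs to a region iff
#' `start < pos <= end`.
#'
#' @param path BED file (3+ columns; column 4 supplies names when present).
#' @return data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
read_gene_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("region", seq_along(gr))
  out <- data.frame(
    name = as.character(nm),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # back to BED 0-based
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  bad <- out$start >= out$end
  if (any(bad)) stopf("read_gene_regions: empty region '%s'", out$name[which(bad)[1L]])
  out
}

#' @rdname read_gene_regions
#' @param regions gene-region data.frame to write.
#' @export
write_gene_regions <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Array manifest: a named set of genotyped sites
#'
#' @param chrom,pos parallel vectors of sites (1-based positions).
#' @param name manifest name (e.g. the chip it emulates).
#' @return object of class `array_manifest` with a `sites` data.frame.
#' @export
array_manifest <- function(chrom, pos, name = "array") {
  sites <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(paste(sites$chrom, sites$pos))) stopf("array_manifest: duplicate sites")
  sites <- sites[variant_order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(name = name, sites = sites), class = "array_manifest")
}

#' @export
print.array_manifest <- function(x, ...) {
  cat(sprintf("array_manifest '%s': %d sites\n", x$name, nrow(x$sites)))
  invisible(x)
}

#' Read / write an array manifest as two-column TSV (chrom, pos)
#'
#' @param path TSV path; lines starting with `#` are ignored.
#' @param name manifest name.
#' @export
read_array_manifest <- function(path, name = basename(path)) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (!all(c("chrom", "pos") %in% names(dt))) {
    stopf("read_array_manifest: need columns chrom, pos")
  }
  array_manifest(dt$chrom, dt$pos, name = name)
}

#' @rdname read_array_manifest
#' @param manifest an [array_manifest()] to write.
#' @export
write_array_manifest <- function(manifest, path) {
  data.table::fwrite(manifest$sites, path, sep = "\t")
  invisible(path)
}
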