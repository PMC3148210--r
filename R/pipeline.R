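# One-config orchestration of the five stages:
# simulate -> ld -> tag -> coverage -> power.
# Config is JSON; all tabular outputs are TSV with a commented header line
# naming units/conventions; reruns with the same config and seed are
# byte-identical.

.pipeline_stages <- c("simulate", "ld", "tag", "coverage", "power")

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- tryCatch(jsonlite::read_json(config, simplifyVector = TRUE),
                       error = function(e) stopf("config parse error: %s", conditionMessage(e)))
  }
  if (!is.list(config)) stopf("config must be a JSON object")
  config
}

#' Validate a pipeline run configuration
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @return character vector of findings (field + violation); empty when the
#'   config is runnable.
#' @export
validate_config <- function(config) {
  cfg <- .read_config(config)
  findings <- character(0)
  add <- function(msg) findings <<- c(findings, msg)
  stages <- cfg$stages %||% .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) add(sprintf("stages: unknown stage(s) %s", paste(bad, collapse = ", ")))
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) add("seed: integer seed required")
  if (is.null(cfg$outdir) || !is.character(cfg$outdir)) add("outdir: output directory required")
  sim <- cfg$simulate
  if ("simulate" %in% stages) {
    ok <- tryCatch({ do.call(sim_config, c(list(seed = cfg$seed %||% 1L),
                                           sim[setdiff(names(sim), c("discovery_samples"))])); TRUE },
                   error = function(e) { add(sprintf("simulate: %s", conditionMessage(e))); FALSE })
    ds <- sim$discovery_samples
    if (ok && !is.null(ds) && (!is.numeric(ds) || ds < 0 || (!is.null(sim$n_samples) && ds > sim$n_samples))) {
      add("simulate.discovery_samples: must be a count <= n_samples")
    }
  }
  num_in <- function(x, lo, hi) is.numeric(x) && all(x > lo & x <= hi)
  if ("ld" %in% stages) {
    w <- cfg$ld$windows %||% c(50000, 100000, 200000)
    if (!is.numeric(w) || any(w <= 0)) add("ld.windows: windows must be positive basepair counts")
  }
  if ("tag" %in% stages) {
    th <- cfg$tag$threshold %||% 0.8
    if (!num_in(th, 0, 1)) add("tag.threshold: r2 threshold must lie in (0, 1]")
    if (!is.null(cfg$tag$window) && cfg$tag$window <= 0) add("tag.window: must be > 0")
  }
  if ("coverage" %in% stages) {
    th <- cfg$coverage$thresholds %||% c(0.2, 0.5, 0.8)
    if (!num_in(th, 0, 1)) add("coverage.thresholds: r2 thresholds must lie in (0, 1]")
    if (is.unsorted(th, strictly = TRUE)) add("coverage.thresholds: must be strictly ascending")
  }
  if ("power" %in% stages) {
    pw <- cfg$power
    if (!is.null(pw$n_cases) && pw$n_cases <= 0) add("power.n_cases: must be a positive count")
    if (!is.null(pw$n_controls) && pw$n_controls <= 0) add("power.n_controls: must be a positive count")
    if (!is.null(pw$alpha) && !num_in(pw$alpha, 0, 0.999999)) add("power.alpha: must lie in (0, 1)")
    if (!is.null(pw$replicates) && pw$replicates <= 0) add("power.replicates: must be a positive count")
    kind <- pw$model %||% "additive"
    if (!kind %in% .model_kinds) add(sprintf("power.model: unknown model '%s'", kind))
    if (!is.null(pw$rr_hom) && pw$rr_hom <= 0) add("power.rr_hom: must be positive")
  }
  findings
}

.write_tsv <- function(df, path, comment) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(x)
      if (is.numeric(x)) formatC(x, digits = 15, format = "g") else as.character(x)),
      list(sep = "\t")))
    writeLines(body, con)
  }
  invisible(path)
}

#' Run the evaluation pipeline from one configuration
#'
#' Stages run in dependency order; downstream stages read the panel / regions
#' / manifest written by `simulate` (or paths supplied under `inputs`).
#' Every output is listed in `run_manifest.tsv` together with its md5 digest
#' and the config hash; rerunning with the same config and seed reproduces
#' the outputs byte for byte.
#'
#' @param config path to a JSON config file, or an equivalent list.  Fields:
#'   `seed`, `outdir`, `stages` (subset of simulate/ld/tag/coverage/power),
#'   and per-stage parameter blocks (`simulate`, `ld`, `tag`, `coverage`,
#'   `power`) mirroring the module function arguments.
#' @param outdir optional override of the config's output directory.
#' @return invisibly, a data.frame manifest of written files (paths + md5).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- .read_config(config)
  findings <- validate_config(cfg)
  if (length(findings)) {
    stopf("invalid config:\n%s", paste(" -", findings, collapse = "\n"))
  }
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% .pipeline_stages
  seed <- as.integer(cfg$seed)

  paths <- list(vcf = file.path(outdir, "panel.vcf"),
                bed = file.path(outdir, "genes.bed"),
                manifest = file.path(outdir, "array_manifest.tsv"))
  if (!is.null(cfg$inputs$vcf)) paths$vcf <- cfg$inputs$vcf
  if (!is.null(cfg$inputs$bed)) paths$bed <- cfg$inputs$bed
  if (!is.null(cfg$inputs$manifest)) paths$manifest <- cfg$inputs$manifest
  written <- character(0)
  note <- function(p) written <<- c(written, p)

  panel <- NULL; regions <- NULL; manifest <- NULL
  need_panel <- function(stage) {
    if (!is.null(panel)) return(invisible(NULL))
    if (!file.exists(paths$vcf)) {
      stopf("stage '%s': missing upstream panel VCF '%s' (run 'simulate' first or set inputs$vcf)",
            stage, paths$vcf)
    }
    panel <<- read_phased_vcf(paths$vcf)
    if (file.exists(paths$bed)) regions <<- read_gene_regions(paths$bed)
    invisible(NULL)
  }

  if ("simulate" %in% stages) {
    tp_log("info", "stage simulate")
    sim <- cfg$simulate
    sc_args <- sim[setdiff(names(sim), "discovery_samples")]
    sc <- do.call(sim_config, c(list(seed = seed), sc_args))
    if (sc$mode == "genes") {
      gp <- generate_gene_panels(sc)
      panel <- gp$panel
      regions <- gp$regions
      write_gene_regions(regions, paths$bed); note(paths$bed)
    } else {
      panel <- generate_panel(sc)
    }
    write_phased_vcf(panel, paths$vcf); note(paths$vcf)
    n_disc <- as.integer(sim$discovery_samples %||% max(1L, sc$n_samples %/% 2L))
    set.seed(seed + 1L)
    disc <- sample(panel$sample_ids, n_disc)
    manifest <- ascertain_discovery_panel(panel, disc, name = "discovery_array")
    write_array_manifest(manifest, paths$manifest); note(paths$manifest)
  }

  if ("ld" %in% stages) {
    tp_log("info", "stage ld")
    need_panel("ld")
    ldc <- cfg$ld
    scope <- ldc$scope %||% "distance"
    prof <- if (scope == "gene") {
      if (is.null(regions)) stopf("stage 'ld': gene scope needs regions (genes.bed missing)")
      pairwise_ld_profile(panel, scope = "gene", regions = regions,
                          strata = ldc$strata %||% "paper")
    } else {
      do.call(rbind, lapply(ldc$windows %||% c(50000, 100000, 200000), function(w)
        pairwise_ld_profile(panel, window = w, scope = "distance",
                            strata = ldc$strata %||% "paper")))
    }
    f <- file.path(outdir, "ld_profile.tsv")
    .write_tsv(prof, f, "LD profile; window in bp; proportions over r2 bins [0,0.2) ... [0.8,1]")
    note(f)
  }

  if ("tag" %in% stages) {
    tp_log("info", "stage tag")
    need_panel("tag")
    tc <- cfg$tag
    scope <- tc$scope %||% "distance"
    if (scope == "gene" && is.null(regions)) stopf("stage 'tag': gene scope needs regions (genes.bed missing)")
    ta <- greedy_select_tags(panel, threshold = tc$threshold %||% 0.8,
                             scope = scope, window = tc$window %||% 200000L,
                             regions = regions)
    bins_df <- do.call(rbind, lapply(ta$bins, function(b)
      data.frame(tag = b$tag, member = c(b$tag, b$tagged),
                 role = c("tag", rep("tagged", length(b$tagged))),
                 stringsAsFactors = FALSE)))
    if (is.null(bins_df)) bins_df <- data.frame(tag = character(0), member = character(0),
                                                role = character(0))
    f1 <- file.path(outdir, "tag_bins.tsv")
    .write_tsv(bins_df, f1, sprintf("tag bins at r2 >= %g, %s scope", ta$threshold, ta$scope))
    f2 <- file.path(outdir, "untaggable.tsv")
    .write_tsv(data.frame(id = ta$untaggable), f2, "untaggable SNP ids")
    f3 <- file.path(outdir, "tag_summary.tsv")
    .write_tsv(tag_summary(ta, panel), f3, "per-MAF-category tag/tagged/untaggable proportions")
    note(f1); note(f2); note(f3)
  }

  if ("coverage" %in% stages) {
    tp_log("info", "stage coverage")
    need_panel("coverage")
    if (is.null(manifest)) {
      if (!file.exists(paths$manifest)) {
        stopf("stage 'coverage': missing upstream array manifest '%s'", paths$manifest)
      }
      manifest <- read_array_manifest(paths$manifest)
    }
    cc <- cfg$coverage
    cv <- coverage_curve(panel, manifest, thresholds = cc$thresholds %||% c(0.2, 0.5, 0.8),
                         window = cc$window %||% 200000L)
    f <- file.path(outdir, "coverage.tsv")
    .write_tsv(cv, f, "coverage by MAF category across r2 thresholds (window in bp)")
    note(f)
  }

  if ("power" %in% stages) {
    tp_log("info", "stage power")
    need_panel("power")
    pw <- cfg$power
    if (is.null(manifest) && file.exists(paths$manifest)) {
      manifest <- read_array_manifest(paths$manifest)
    }
    model <- disease_model(pw$model %||% "additive", rr_hom = pw$rr_hom %||% 1.8,
                           prevalence = pw$prevalence %||% 0.01)
    modes <- pw$modes %||% "all_snps"
    n_causal <- as.integer(pw$n_causal %||% min(20L, n_variants(panel)))
    set.seed(seed + 2L)
    causal_ids <- sample(panel$variants$id, n_causal)
    rows <- list()
    ests <- list()
    for (md in modes) {
      for (cid in causal_ids) {
        est <- suppressWarnings(estimate_power(
          panel, cid, model, n_cases = pw$n_cases %||% 5000L,
          n_controls = pw$n_controls %||% 5000L, alpha = pw$alpha %||% 0.05,
          replicates = pw$replicates %||% 1000L, mode = md,
          manifest = manifest, seed = seed + 100L + length(rows)))
        rows[[length(rows) + 1L]] <- as.data.frame(est)
        if (md == modes[[1L]]) ests[[length(ests) + 1L]] <- est
      }
    }
    f1 <- file.path(outdir, "power.tsv")
    .write_tsv(do.call(rbind, rows), f1, "Monte-Carlo power per causal SNP / mode")
    f2 <- file.path(outdir, "power_by_maf.tsv")
    .write_tsv(aggregate_power_by_maf(ests, panel), f2,
               sprintf("mean power by causal MAF bin (mode %s)", modes[[1L]]))
    note(f1); note(f2)
  }

  cfg_min <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tmp <- tempfile()
  writeLines(cfg_min, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  man <- data.frame(file = basename(written),
                    md5 = unname(tools::md5sum(written)),
                    config_md5 = cfg_hash, stringsAsFactors = FALSE)
  .write_tsv(man, file.path(outdir, "run_manifest.tsv"),
             "output digests for this run")
  invisible(man)
}

#' Command-line entry point
#'
#' Subcommands: `run` (all configured stages), `simulate`, `ld`, `tag`,
#' `coverage`, `power` (single stage), and `validate`.  All but `validate`
#' take `--config <path>` and an optional `--outdir <dir>`;
#' `validate <path>` prints findings.  Install target `inst/cli/tagpower`
#' wraps this function for `Rscript`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status, invisibly (0 on success).
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: tagpower <run|simulate|ld|tag|coverage|power> --config cfg.json [--outdir dir]\n       tagpower validate cfg.json"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]
  rest <- args[-1L]
  getopt <- function(flag) {
    i <- which(rest == flag)
    if (length(i) == 1L && i < length(rest)) rest[[i + 1L]] else NULL
  }
  if (cmd == "validate") {
    path <- if (length(rest)) rest[[1L]] else getopt("--config")
    if (is.null(path)) { message(usage); return(invisible(1L)) }
    findings <- tryCatch(validate_config(path), error = function(e) conditionMessage(e))
    if (length(findings) == 0L) {
      message("config OK")
      return(invisible(0L))
    }
    message(paste(findings, collapse = "\n"))
    return(invisible(1L))
  }
  if (!cmd %in% .pipeline_stages && cmd != "run") { message(usage); return(invisible(1L)) }
  cfg_path <- getopt("--config")
  if (is.null(cfg_path)) { message(usage); return(invisible(1L)) }
  cfg <- .read_config(cfg_path)
  if (cmd != "run") cfg$stages <- cmd
  status <- tryCatch({ run_pipeline(cfg, outdir = getopt("--outdir")); 0L },
                     error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
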