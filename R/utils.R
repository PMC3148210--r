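#' @keywords internal
"_PACKAGE"

# logging: levels debug < info < warn; controlled by options(tagpower.loglevel=)
.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

tp_log <- function(level, ...) {
  thr <- getOption("tagpower.loglevel", "info")
  if (.log_levels[[level]] >= .log_levels[[thr]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sorted-by-(chrom,pos) order for variant tables
variant_order <- function(chrom, pos) order(chrom, pos, method = "radix")
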