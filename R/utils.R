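#' @title Internal helpers
#' @name ubnexus-internals
#' @keywords internal
NULL

# stop() wrapper that tags the failing stage for pipeline error reporting
ub_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

assert_that <- function(cond, stage, msg) {
  if (!isTRUE(cond)) ub_stop(stage, msg)
  invisible(TRUE)
}

#' Write a data frame as TSV
#'
#' Header row, tab-delimited, '.' decimal, no quoting, no row names.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Deterministic per-stream seed expansion.  A single global seed maps to one
# substream seed per named stream via fixed offsets, so adding a stream never
# perturbs the draws of existing ones.  Offsets are part of the contract.
.stream_offsets <- c(
  ub_peptides     = 101L,
  spectral_counts = 211L,
  guide_counts    = 307L,
  lfq_matrix      = 401L,
  splicing_counts = 503L,
  nucleus_images  = 601L
)

stream_seed <- function(seed, stream) {
  offs <- .stream_offsets[[stream]]
  if (is.null(offs)) ub_stop("sim", "unknown stream: ", stream)
  as.integer((as.numeric(seed) * 1009 + offs) %% .Machine$integer.max)
}

# Benjamini-Hochberg q-values; thin wrapper kept so every module adjusts
# p-values through one audited call site.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
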