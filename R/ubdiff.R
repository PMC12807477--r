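#' Per-site log2 fold changes of diGly peptide intensities
#'
#' For every site row, replicate intensities are collapsed by arithmetic
#' mean within each condition and the fold change computed as
#' `log2((mean_KO + pc) / (mean_WT + pc))`.
#'
#' @param table diGly peptide table with `protein_id`, `site_position` and
#'   per-replicate intensity columns.
#' @param ko_cols,wt_cols names (or indices) of the KO and WT intensity
#'   columns; by default columns prefixed `KO_` and `WT_`.
#' @param pseudocount intensity pseudocount guarding zero means
#'   (default 1).
#' @param threshold absolute log2FC filter (default 0.5).
#' @return data frame (one row per site): protein_id, site_position,
#'   log2fc, passes_filter (`|log2fc| >= threshold`), lost_ub
#'   (`log2fc <= -threshold`).
#' @export
site_log2fc <- function(table, ko_cols = NULL, wt_cols = NULL,
                        pseudocount = 1, threshold = 0.5) {
  if (is.null(ko_cols)) ko_cols <- grep("^KO_", names(table), value = TRUE)
  if (is.null(wt_cols)) wt_cols <- grep("^WT_", names(table), value = TRUE)
  assert_that(length(ko_cols) >= 1 && length(wt_cols) >= 1, "ubdiff",
              "both condition groups must be present")
  assert_that(pseudocount >= 0, "ubdiff", "pseudocount must be >= 0")
  ko <- rowMeans(as.matrix(table[ko_cols]))
  wt <- rowMeans(as.matrix(table[wt_cols]))
  if (pseudocount == 0 && any(ko == 0 & wt == 0))
    ub_stop("ubdiff", "all-zero site row with pseudocount 0: ratio undefined")
  fc <- log2((ko + pseudocount) / (wt + pseudocount))
  data.frame(protein_id = table$protein_id,
             site_position = table$site_position,
             log2fc = fc,
             passes_filter = abs(fc) >= threshold,
             lost_ub = fc <= -threshold,
             stringsAsFactors = FALSE)
}

#' Flag proteins that lose ubiquitylation
#'
#' A protein is flagged when at least one of its diGly sites has
#' `log2fc <= -threshold` (i.e. the site intensity drops on ligase loss).
#'
#' @param results output of [site_log2fc()].
#' @param threshold absolute log2FC threshold (default 0.5).
#' @return data frame: protein_id, lost_ub, min_site_log2fc, n_sites.
#' @export
flag_lost_ub <- function(results, threshold = 0.5) {
  sp <- split(results$log2fc, results$protein_id)
  data.frame(protein_id = names(sp),
             lost_ub = vapply(sp, function(x) any(x <= -threshold), logical(1)),
             min_site_log2fc = vapply(sp, min, numeric(1)),
             n_sites = lengths(sp),
             stringsAsFactors = FALSE, row.names = NULL)
}
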