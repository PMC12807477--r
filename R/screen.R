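#' Counts-per-million normalization
#'
#' Scales each sample column of a guide-count matrix to a total of 1e6.
#'
#' @param counts numeric matrix (guides x samples) or data frame of count
#'   columns.
#' @return matrix of CPM values.
#' @export
cpm_normalize <- function(counts) {
  m <- as.matrix(counts)
  tot <- colSums(m)
  assert_that(all(tot > 0), "screen", "zero-total count column")
  sweep(m, 2, tot, "/") * 1e6
}

#' Per-guide log2 fold change, day 10 vs day 0
#'
#' `log2((day10 + pc) / (day0 + pc))`, element-wise; replicate columns can
#' be averaged afterwards or supplied pre-averaged.
#'
#' @param day10,day0 numeric vectors/matrices of (normalized) counts.
#' @param pseudocount added to both (default 1).
#' @return log2 fold changes with the shape of the inputs.
#' @export
guide_log2fc <- function(day10, day0, pseudocount = 1) {
  log2((day10 + pseudocount) / (day0 + pseudocount))
}

# Average per-guide log2FC (day10 vs day0) across replicates in one
# context, from the wide count table produced by gen_guide_counts().
context_guide_fc <- function(table, context, pseudocount = 1,
                             normalize = TRUE) {
  cols <- grep(sprintf("^%s\\.", context), names(table), value = TRUE)
  assert_that(length(cols) > 0, "screen",
              paste0("no count columns for context ", context))
  counts <- as.matrix(table[cols])
  if (normalize) counts <- cpm_normalize(counts)
  d0 <- grep("\\.day0\\.", cols)
  d10 <- grep("\\.day10\\.", cols)
  fc <- guide_log2fc(counts[, d10, drop = FALSE], counts[, d0, drop = FALSE],
                     pseudocount)
  rowMeans(fc)
}

#' Gene-level context-dependence test
#'
#' For one gene, matched per-guide log2 fold changes from the two contexts
#' are compared by a two-tailed paired t-test.  A gene whose paired
#' differences have zero variance is reported with `p = 1` and a
#' `degenerate` flag rather than an error.
#'
#' @param fc_ctrl,fc_fbxo11 per-guide log2FC vectors, same guides in the
#'   same order, length >= 2.
#' @return one-row data frame: median FC per context, mean paired
#'   difference, t, p_value, degenerate.
#' @export
gene_context_test <- function(fc_ctrl, fc_fbxo11) {
  assert_that(length(fc_ctrl) == length(fc_fbxo11) && length(fc_ctrl) >= 2,
              "screen", "need matched guide FCs, n >= 2")
  d <- fc_fbxo11 - fc_ctrl
  if (stats::sd(d) == 0) {
    return(data.frame(median_ctrl = stats::median(fc_ctrl),
                      median_fbxo11 = stats::median(fc_fbxo11),
                      mean_diff = mean(d), t = NA_real_, p_value = 1,
                      degenerate = TRUE))
  }
  tt <- stats::t.test(fc_fbxo11, fc_ctrl, paired = TRUE)
  data.frame(median_ctrl = stats::median(fc_ctrl),
             median_fbxo11 = stats::median(fc_fbxo11),
             mean_diff = mean(d), t = unname(tt$statistic),
             p_value = tt$p.value, degenerate = FALSE)
}

#' Screen-wide gene classification
#'
#' Computes replicate-averaged per-guide log2 fold changes in each context,
#' runs the paired context test per gene, adjusts p-values by
#' Benjamini-Hochberg across genes, and classifies each significant gene by
#' the context with the larger absolute median FC and the sign of that
#' median: `enriched_sgCTRL`, `enriched_sgFBXO11`, `depleted_sgCTRL`,
#' `depleted_sgFBXO11`, or `none`.
#'
#' @param table wide guide-count table (`guide_id`, `gene_id`, count
#'   columns `<context>.<timepoint>.r<k>`).
#' @param alpha significance level (default 0.05).
#' @param use_q gate the class on the BH-adjusted q-value (default `TRUE`);
#'   set `FALSE` to gate on raw p.
#' @param pseudocount CPM pseudocount for the guide FCs.
#' @return data frame per gene: medians, mean_diff, t, p_value, q_value,
#'   class.
#' @export
screen_gene_results <- function(table, alpha = 0.05, use_q = TRUE,
                                pseudocount = 1) {
  fc_ctrl <- context_guide_fc(table, "sgCTRL", pseudocount)
  fc_fbx <- context_guide_fc(table, "sgFBXO11", pseudocount)
  genes <- unique(table$gene_id)
  rows <- lapply(genes, function(g) {
    i <- table$gene_id == g
    cbind(gene_id = g, gene_context_test(fc_ctrl[i], fc_fbx[i]))
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  crit <- if (use_q) res$q_value else res$p_value
  sel_fbx <- abs(res$median_fbxo11) >= abs(res$median_ctrl)
  ctx <- ifelse(sel_fbx, "sgFBXO11", "sgCTRL")
  med <- ifelse(sel_fbx, res$median_fbxo11, res$median_ctrl)
  res$class <- ifelse(crit < alpha & !res$degenerate,
                      paste0(ifelse(med > 0, "enriched_", "depleted_"), ctx),
                      "none")
  res$class[crit < alpha & med == 0] <- "none"
  rownames(res) <- NULL
  res
}
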