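#' Preprocess an LFQ quantity matrix
#'
#' log2 transform, presence filtering (a protein is kept only if it is
#' quantified in at least `min_presence_fraction` of the samples of at
#' least one group), and per-sample median centering.  Missing values stay
#' missing; nothing is imputed.
#'
#' @param matrix proteins x samples quantity matrix (values > 0 or `NA`).
#' @param groups named character vector mapping sample -> group label.
#' @param min_presence_fraction minimum fraction of quantified samples
#'   within a group (default 0.5).
#' @return filtered, centered log2 matrix.
#' @export
preprocess_lfq <- function(matrix, groups, min_presence_fraction = 0.5) {
  assert_that(all(colnames(matrix) %in% names(groups)), "proteome",
              "group labels must cover all sample columns")
  lm <- log2(matrix)
  keep <- vapply(seq_len(nrow(lm)), function(i) {
    any(vapply(unique(groups), function(g) {
      v <- lm[i, names(groups)[groups == g], drop = TRUE]
      mean(!is.na(v)) >= min_presence_fraction
    }, logical(1)))
  }, logical(1))
  lm <- lm[keep, , drop = FALSE]
  med <- apply(lm, 2, stats::median, na.rm = TRUE)
  sweep(lm, 2, med, "-")
}

#' Differential protein abundance, Welch t-test
#'
#' Per-protein two-sided Welch t-test on available (non-missing) log2
#' values, group-1 vs group-2; Benjamini-Hochberg q across tested
#' proteins.  A protein with fewer than 2 values in either group is
#' skipped with a recorded reason.  Significance follows the volcano
#' convention `p < p_cutoff` and `|log2FC| > fc_cutoff`.
#'
#' @param matrix log2 quantity matrix (e.g. from [preprocess_lfq()]).
#' @param groups named group vector; the first of `levels` is the
#'   numerator of the fold change.
#' @param levels character(2): numerator and denominator group labels
#'   (default the two group values, disease first if present).
#' @param p_cutoff,fc_cutoff volcano cutoffs (defaults 0.05, 0.5).
#' @return data frame: protein_id, log2fc, t, p_value, q_value,
#'   significant, skipped, skip_reason.
#' @export
differential_proteins <- function(matrix, groups, levels = NULL,
                                  p_cutoff = 0.05, fc_cutoff = 0.5) {
  gl <- unique(groups[colnames(matrix)])
  if (is.null(levels))
    levels <- if ("disease" %in% gl) c("disease", setdiff(gl, "disease")[1])
  else gl[1:2]
  s1 <- colnames(matrix)[groups[colnames(matrix)] == levels[1]]
  s2 <- colnames(matrix)[groups[colnames(matrix)] == levels[2]]
  res <- lapply(rownames(matrix), function(pid) {
    x <- matrix[pid, s1]; y <- matrix[pid, s2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(protein_id = pid, log2fc = NA_real_, t = NA_real_,
                        p_value = NA_real_, skipped = TRUE,
                        skip_reason = "fewer than 2 values in a group",
                        stringsAsFactors = FALSE))
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(protein_id = pid, log2fc = mean(x) - mean(y),
               t = unname(tt$statistic), p_value = tt$p.value,
               skipped = FALSE, skip_reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  tested <- !out$skipped
  out$q_value[tested] <- bh_adjust(out$p_value[tested])
  out$significant <- tested & out$p_value < p_cutoff &
    abs(out$log2fc) > fc_cutoff
  out
}

#' PCA on the most variable proteins
#'
#' Selects the top `fraction` of proteins by variance (computed on
#' available values), centers rows, and runs singular-value PCA on the
#' complete-case submatrix.
#'
#' @param matrix log2 quantity matrix.
#' @param fraction fraction of proteins to keep (default 0.5).
#' @param scale. unit-scale rows before PCA (default `FALSE`).
#' @return list: scores (samples x PC), loadings, var_explained, selected
#'   (protein ids used).
#' @export
top_variable_pca <- function(matrix, fraction = 0.5, scale. = FALSE) {
  v <- apply(matrix, 1, stats::var, na.rm = TRUE)
  n_keep <- max(2L, floor(nrow(matrix) * fraction))
  sel <- names(sort(v, decreasing = TRUE))[seq_len(n_keep)]
  sub <- matrix[sel, , drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  assert_that(nrow(sub) >= 2, "proteome", "too few complete rows for PCA")
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
       selected = sel)
}

#' Hierarchical clustering of samples and proteins
#'
#' Takes the `top_n` proteins ranked by differential-abundance p-value,
#' z-scores each protein row, and clusters both samples and proteins with
#' correlation distance (`1 - Pearson r`) and average linkage.  Row
#' clusters are cut at `k_rows` to emulate numbered heatmap clusters.
#'
#' @param matrix log2 quantity matrix.
#' @param de output of [differential_proteins()] used for ranking; `NULL`
#'   ranks by row variance instead.
#' @param top_n number of proteins (default 400).
#' @param k_rows number of row clusters to cut (default 8).
#' @return list: sample_hclust, row_hclust, row_clusters (named integer),
#'   sample_clusters at k = 2, proteins (ids used).
#' @export
hierarchical_cluster <- function(matrix, de = NULL, top_n = 400, k_rows = 8) {
  if (!is.null(de)) {
    ranked <- de$protein_id[order(de$p_value)]
    ranked <- ranked[ranked %in% rownames(matrix)]
  } else {
    ranked <- names(sort(apply(matrix, 1, stats::var, na.rm = TRUE),
                         decreasing = TRUE))
  }
  sel <- ranked[seq_len(min(top_n, length(ranked)))]
  sub <- matrix[sel, , drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  zs <- t(scale(t(sub)))
  zs <- zs[apply(zs, 1, function(x) all(is.finite(x))), , drop = FALSE]
  cor_dist <- function(m) stats::as.dist(1 - stats::cor(t(m)))
  hs <- stats::hclust(cor_dist(t(zs)), method = "average")
  hr <- stats::hclust(cor_dist(zs), method = "average")
  list(sample_hclust = hs, row_hclust = hr,
       row_clusters = stats::cutree(hr, k = min(k_rows, nrow(zs))),
       sample_clusters = stats::cutree(hs, k = 2),
       proteins = rownames(zs))
}

#' Project differential fold changes onto an interaction network
#'
#' Attaches each node's log2FC as a vertex attribute; nodes absent from
#' the differential results are flagged (`measured = FALSE`), never
#' dropped.  The summary is the mean log2FC over measured nodes.
#'
#' @param de output of [differential_proteins()].
#' @param network an [igraph::graph] with node names in the protein id
#'   namespace.
#' @return list: network (annotated graph), mean_log2fc, n_measured,
#'   n_missing.
#' @export
project_onto_network <- function(de, network) {
  nodes <- igraph::V(network)$name
  i <- match(nodes, de$protein_id)
  fc <- ifelse(is.na(i), NA_real_, de$log2fc[i])
  g <- igraph::set_vertex_attr(network, "log2fc", value = fc)
  g <- igraph::set_vertex_attr(g, "measured", value = !is.na(fc))
  list(network = g, mean_log2fc = mean(fc, na.rm = TRUE),
       n_measured = sum(!is.na(fc)), n_missing = sum(is.na(fc)))
}

#' Fold-change correlation between two omic layers
#'
#' Pearson and Spearman correlation of matched fold changes after an inner
#' join on id.
#'
#' @param proteome_fc,transcriptome_fc named numeric vectors of log2 fold
#'   changes (names are ids).
#' @return list: pearson, spearman, n_matched.
#' @export
fc_correlation <- function(proteome_fc, transcriptome_fc) {
  ids <- intersect(names(proteome_fc), names(transcriptome_fc))
  x <- proteome_fc[ids]; y <- transcriptome_fc[ids]
  ok <- is.finite(x) & is.finite(y)
  list(pearson = if (sum(ok) >= 3) stats::cor(x[ok], y[ok]) else NA_real_,
       spearman = if (sum(ok) >= 3)
         stats::cor(x[ok], y[ok], method = "spearman") else NA_real_,
       n_matched = sum(ok))
}
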