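#' G-test of IP vs IgG spectral counts
#'
#' Likelihood-ratio goodness-of-fit test of a protein's counts in the bait
#' IP and IgG control runs against expected counts proportional to the run
#' depths: `e_i = T_i * (c_ip + c_igg) / (T_ip + T_igg)`, then
#' `G = 2 * sum(c_i * log(c_i / e_i))` with zero-count terms contributing
#' 0, referred to a chi-square with 1 df.  No continuity or Williams
#' correction is applied.  All arguments are vectorized over proteins.
#'
#' @param c_ip,c_igg observed spectral counts.
#' @param t_ip,t_igg total run depths (column sums).
#' @return data frame with columns `G` and `p_value`.
#' @export
g_test <- function(c_ip, c_igg, t_ip, t_igg) {
  assert_that(all(t_ip + t_igg > 0), "ip_enrichment", "zero grand total")
  assert_that(all(c_ip <= t_ip) && all(c_igg <= t_igg), "ip_enrichment",
              "counts exceed totals")
  tot <- c_ip + c_igg
  e_ip <- t_ip * tot / (t_ip + t_igg)
  e_igg <- t_igg * tot / (t_ip + t_igg)
  term <- function(c, e) ifelse(c == 0, 0, c * log(c / e))
  g <- 2 * (term(c_ip, e_ip) + term(c_igg, e_igg))
  g <- pmax(g, 0)
  data.frame(G = g, p_value = stats::pchisq(g, df = 1, lower.tail = FALSE))
}

#' Fold enrichment of IP over IgG proportions
#'
#' `((c_ip + pc) / T_ip) / ((c_igg + pc) / T_igg)`.  The pseudocount keeps
#' the ratio finite for proteins absent from the IgG run; it is applied
#' here only, never in the G statistic.
#'
#' @inheritParams g_test
#' @param pseudocount count pseudocount (default 0.5).
#' @return numeric fold-enrichment vector.
#' @export
fold_enrichment <- function(c_ip, c_igg, t_ip, t_igg, pseudocount = 0.5) {
  ((c_ip + pseudocount) / t_ip) / ((c_igg + pseudocount) / t_igg)
}

#' Call bait-specific interactors
#'
#' Applies the G-test and fold enrichment to every protein of a
#' spectral-count table and marks the "significance box":
#' `p < p_cutoff` and `fold_enrichment > fc_cutoff`.
#'
#' @param table data frame with `protein_id`, `count_ip`, `count_igg`;
#'   totals are computed as column sums.
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param fc_cutoff fold-enrichment cutoff (default 1.5).
#' @param adjust apply Benjamini-Hochberg correction and gate the box on
#'   the adjusted value instead of raw p (default `FALSE`, following the
#'   raw-p convention of the enrichment scatter).
#' @return data frame sorted by decreasing G: protein_id, count_ip,
#'   count_igg, G, p_value, q_value, fold_enrichment, in_box.
#' @export
call_interactors <- function(table, p_cutoff = 0.05, fc_cutoff = 1.5,
                             adjust = FALSE) {
  if (nrow(table) == 0)
    return(data.frame(protein_id = character(), count_ip = integer(),
                      count_igg = integer(), G = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      fold_enrichment = numeric(), in_box = logical()))
  t_ip <- sum(table$count_ip); t_igg <- sum(table$count_igg)
  gt <- g_test(table$count_ip, table$count_igg, t_ip, t_igg)
  fe <- fold_enrichment(table$count_ip, table$count_igg, t_ip, t_igg)
  q <- bh_adjust(gt$p_value)
  crit_p <- if (adjust) q else gt$p_value
  out <- data.frame(protein_id = table$protein_id,
                    count_ip = table$count_ip, count_igg = table$count_igg,
                    G = gt$G, p_value = gt$p_value, q_value = q,
                    fold_enrichment = fe,
                    in_box = crit_p < p_cutoff & fe > fc_cutoff,
                    stringsAsFactors = FALSE)
  out[order(-out$G), , drop = FALSE]
}

#' Assemble the confidence-filtered interaction network
#'
#' Drops edges below the confidence cutoff, restricts nodes to the
#' whitelist (typically the in-box interactors plus the bait), and removes
#' self-loops.
#'
#' @param edge_table data frame: node_a, node_b, confidence in [0, 1].
#' @param confidence_cutoff minimum edge confidence (default 0.7, the
#'   "medium confidence" convention).
#' @param node_whitelist character vector of allowed node ids; `NULL`
#'   keeps all nodes.
#' @return an undirected [igraph::graph] with edge attribute `confidence`.
#' @export
assemble_network <- function(edge_table, confidence_cutoff = 0.7,
                             node_whitelist = NULL) {
  stopifnot(all(c("node_a", "node_b", "confidence") %in% names(edge_table)))
  keep <- edge_table$confidence >= confidence_cutoff &
    edge_table$node_a != edge_table$node_b
  if (!is.null(node_whitelist))
    keep <- keep & edge_table$node_a %in% node_whitelist &
      edge_table$node_b %in% node_whitelist
  ed <- edge_table[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[c("node_a", "node_b", "confidence")], directed = FALSE,
    vertices = if (is.null(node_whitelist)) NULL else
      unique(c(node_whitelist, ed$node_a, ed$node_b)))
  igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
}
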