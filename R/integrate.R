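#' Build per-protein evidence profiles
#'
#' Outer-joins the three evidence streams on protein/gene id (after an
#' optional explicit id mapping) and records, per protein: whether it lost
#' ubiquitylation, whether it is an in-box interactor, and whether its
#' screen class is context dependent, together with the supporting
#' numbers.  Evidence absent from a stream is `FALSE` with the missingness
#' recorded, never an error; ids present in the mapping but in no stream
#' are reported in the `unmapped` attribute.
#'
#' @param ub_results output of [flag_lost_ub()].
#' @param interaction_calls output of [call_interactors()].
#' @param screen_results output of [screen_gene_results()].
#' @param id_map optional data frame (from_id, to_id) harmonizing gene ids
#'   of the screen stream into the protein id namespace; default identity.
#' @return data frame of evidence profiles, one row per protein id.
#' @export
build_profiles <- function(ub_results, interaction_calls, screen_results,
                           id_map = NULL) {
  map_id <- function(ids) {
    if (is.null(id_map)) return(ids)
    i <- match(ids, id_map$from_id)
    out <- ifelse(is.na(i), ids, id_map$to_id[i])
    out
  }
  screen_ids <- map_id(screen_results$gene_id)
  all_ids <- sort(unique(c(ub_results$protein_id,
                           interaction_calls$protein_id, screen_ids)))
  iu <- match(all_ids, ub_results$protein_id)
  ii <- match(all_ids, interaction_calls$protein_id)
  is <- match(all_ids, screen_ids)
  prof <- data.frame(
    protein_id = all_ids,
    lost_ub = !is.na(iu) & ub_results$lost_ub[iu],
    interactor = !is.na(ii) & interaction_calls$in_box[ii],
    screen_dependent = !is.na(is) & screen_results$class[is] != "none",
    in_ub_stream = !is.na(iu), in_ip_stream = !is.na(ii),
    in_screen_stream = !is.na(is),
    min_site_log2fc = ifelse(is.na(iu), NA_real_,
                             ub_results$min_site_log2fc[iu]),
    G = ifelse(is.na(ii), NA_real_, interaction_calls$G[ii]),
    ip_p = ifelse(is.na(ii), NA_real_, interaction_calls$p_value[ii]),
    screen_diff = ifelse(is.na(is), NA_real_, screen_results$mean_diff[is]),
    screen_q = ifelse(is.na(is), NA_real_, screen_results$q_value[is]),
    stringsAsFactors = FALSE)
  if (!is.null(id_map))
    attr(prof, "unmapped") <- setdiff(id_map$from_id, screen_results$gene_id)
  prof
}

#' Nominate candidate substrates
#'
#' A protein is nominated iff all three evidence booleans are true (lost
#' ubiquitylation AND in-box interactor AND context-dependent screen hit).
#' Nominations are ranked by a composite score: the sum of per-stream
#' z-scores of `-min_site_log2fc`, `G`, and `|screen mean difference|`
#' (each standardized over the proteins carrying that stream).
#'
#' @param profiles output of [build_profiles()].
#' @return `profiles` with added `nominated` and `rank_score`, sorted with
#'   nominated proteins first by decreasing score.
#' @export
nominate <- function(profiles) {
  z <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(ifelse(is.na(x), 0, 0))
    out <- (x - mean(x, na.rm = TRUE)) / s
    ifelse(is.na(out), 0, out)
  }
  score <- z(-profiles$min_site_log2fc) + z(profiles$G) +
    z(abs(profiles$screen_diff))
  out <- profiles
  out$nominated <- profiles$lost_ub & profiles$interactor &
    profiles$screen_dependent
  out$rank_score <- score
  out[order(-out$nominated, -out$rank_score), , drop = FALSE]
}
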