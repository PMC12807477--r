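#' Percent spliced in (PSI)
#'
#' Default `PSI = I / (I + S)`; with `length_normalize`, junction counts
#' are first divided by the inclusion/skipping form lengths:
#' `(I/lI) / (I/lI + S/lS)`.  Undefined (NA) when `I + S = 0`.
#'
#' @param I,S inclusion and skipping junction counts (vectorized).
#' @param lI,lS form lengths (default 1), used only when normalizing.
#' @param length_normalize logical (default `FALSE`).
#' @return PSI values in [0, 1] or `NA`.
#' @export
compute_psi <- function(I, S, lI = 1, lS = 1, length_normalize = FALSE) {
  if (length_normalize) {
    a <- I / lI; b <- S / lS
  } else {
    a <- I; b <- S
  }
  ifelse(I + S == 0, NA_real_, a / (a + b))
}

# Binomial log-likelihood ratio test of pooled inclusion proportions
# between two groups (H0: shared proportion); chi-square 1 df.
binom_lrt <- function(i1, n1, i2, n2) {
  ll <- function(i, n, p) {
    out <- 0
    if (i > 0) out <- out + i * log(p)
    if (n - i > 0) out <- out + (n - i) * log(1 - p)
    out
  }
  p0 <- (i1 + i2) / (n1 + n2)
  p1 <- i1 / n1; p2 <- i2 / n2
  lr <- 2 * (ll(i1, n1, p1) + ll(i2, n2, p2) - ll(i1, n1, p0) - ll(i2, n2, p0))
  lr <- max(lr, 0)
  c(stat = lr, p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Per-event group difference test on splice-event junction counts
#'
#' Inclusion counts are pooled within each group; a two-sided binomial
#' likelihood-ratio test compares the pooled inclusion proportions, and
#' the inclusion-level difference `dPSI` is the difference of mean
#' per-sample PSIs (group1 - group2).  q-values by Benjamini-Hochberg
#' across events.  Events whose PSI is undefined in every sample of a
#' group are skipped with a recorded reason.
#'
#' @param table splice-event table (`event_id`, `event_type`, `inc_*` /
#'   `skip_*` sample columns) as produced by [gen_splicing_counts()].
#' @param groups named character vector sample -> group label; group order
#'   follows `sort(unique(groups))` unless `levels` given.
#' @param levels character(2) giving (group1, group2).
#' @param length_normalize passed to [compute_psi()].
#' @return data frame: event_id, event_type, psi1, psi2, delta_psi, stat,
#'   p_value, q_value, skipped, skip_reason.
#' @export
event_test <- function(table, groups, levels = NULL,
                       length_normalize = FALSE) {
  samples <- names(groups)
  if (is.null(levels)) levels <- sort(unique(groups))
  s1 <- samples[groups == levels[1]]; s2 <- samples[groups == levels[2]]
  inc <- as.matrix(table[paste0("inc_", samples)])
  skip <- as.matrix(table[paste0("skip_", samples)])
  colnames(inc) <- samples; colnames(skip) <- samples
  res <- lapply(seq_len(nrow(table)), function(e) {
    base <- data.frame(event_id = table$event_id[e],
                       event_type = table$event_type[e],
                       stringsAsFactors = FALSE)
    psi <- compute_psi(inc[e, ], skip[e, ], table$len_inc[e],
                       table$len_skip[e], length_normalize)
    p1 <- psi[s1]; p2 <- psi[s2]
    if (all(is.na(p1)) || all(is.na(p2)))
      return(cbind(base, psi1 = NA_real_, psi2 = NA_real_,
                   delta_psi = NA_real_, stat = NA_real_, p_value = NA_real_,
                   skipped = TRUE,
                   skip_reason = "PSI undefined in all samples of a group"))
    lrt <- binom_lrt(sum(inc[e, s1]), sum(inc[e, s1]) + sum(skip[e, s1]),
                     sum(inc[e, s2]), sum(inc[e, s2]) + sum(skip[e, s2]))
    cbind(base, psi1 = mean(p1, na.rm = TRUE), psi2 = mean(p2, na.rm = TRUE),
          delta_psi = mean(p1, na.rm = TRUE) - mean(p2, na.rm = TRUE),
          stat = lrt[["stat"]], p_value = lrt[["p"]], skipped = FALSE,
          skip_reason = "")
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  tested <- !out$skipped
  out$q_value[tested] <- bh_adjust(out$p_value[tested])
  out
}

#' Filter significant splice events
#'
#' The event filter: `q < fdr_cutoff`, `p < p_cutoff` and
#' `|dPSI| > dpsi_cutoff` (defaults 0.05 / 0.05 / 0.15).
#'
#' @param results output of [event_test()].
#' @param fdr_cutoff,p_cutoff,dpsi_cutoff thresholds.
#' @return list: results (with `passes` column), passing (event ids),
#'   counts_by_type (named integer per event type).
#' @export
filter_events <- function(results, fdr_cutoff = 0.05, p_cutoff = 0.05,
                          dpsi_cutoff = 0.15) {
  pass <- !results$skipped & !is.na(results$q_value) &
    results$q_value < fdr_cutoff & results$p_value < p_cutoff &
    abs(results$delta_psi) > dpsi_cutoff
  results$passes <- pass
  counts <- table(factor(results$event_type[pass],
                         levels = sort(unique(results$event_type))))
  list(results = results, passing = results$event_id[pass],
       counts_by_type = stats::setNames(as.integer(counts), names(counts)))
}

#' Expression quartile sample groups
#'
#' Assigns samples at or above the 75th percentile of one gene's
#' expression to the high group and at or below the 25th percentile to the
#' low group; the middle half is unassigned.  Percentile ranks use
#' midranks for ties; an all-equal vector yields empty groups with a
#' degenerate flag.
#'
#' @param expression named numeric vector (sample -> expression).
#' @return list: high, low (sample id vectors), degenerate.
#' @export
quartile_groups <- function(expression) {
  if (length(unique(expression)) == 1)
    return(list(high = character(), low = character(), degenerate = TRUE))
  n <- length(expression)
  pct <- (rank(expression, ties.method = "average") - 0.5) / n
  list(high = names(expression)[pct >= 0.75],
       low = names(expression)[pct <= 0.25],
       degenerate = FALSE)
}
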