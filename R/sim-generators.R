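#' Planted-truth universe shared by all synthetic streams
#'
#' Deterministically (from the global seed alone) selects the shared
#' protein/gene id sets: the full-evidence "substrate" proteins planted in
#' all three nomination streams, the stream-specific planted sets, and the
#' screen library genes (which, as in the targeted screen design, cover the
#' differentially ubiquitylated proteins).
#'
#' @param cfg a [sim_config()].
#' @return list of id vectors.
#' @keywords internal
sim_universe <- function(cfg) {
  ids <- protein_ids(cfg$n_proteins)
  ub_ids <- ids[seq_len(min(cfg$ub$n_ub_proteins, cfg$n_proteins))]
  set.seed(stream_seed(cfg$seed, "ub_peptides") + 7L)
  substrates <- sort(sample(ub_ids, cfg$n_substrates))
  ub_extra <- sample(setdiff(ub_ids, substrates),
                     max(0L, cfg$ub$n_planted - cfg$n_substrates))
  ub_planted <- sort(c(substrates, ub_extra))
  # stream-specific interactors are drawn outside the ubiquitylome gene
  # space, so the full-evidence (triple-planted) set is exactly `substrates`
  ip_pool <- setdiff(ids, ub_ids)
  if (length(ip_pool) < cfg$ip$n_planted - cfg$n_substrates)
    ip_pool <- setdiff(ids, substrates)
  ip_extra <- sample(ip_pool, max(0L, cfg$ip$n_planted - cfg$n_substrates))
  ip_planted <- sort(c(substrates, ip_extra))
  n_lib <- min(cfg$screen$n_genes, length(ub_ids))
  lib_extra <- sample(setdiff(ub_ids, ub_planted),
                      max(0L, n_lib - length(ub_planted)))
  screen_genes <- sort(c(ub_planted, lib_extra))
  ctx_extra <- sample(setdiff(screen_genes, substrates),
                      max(0L, cfg$screen$n_planted - cfg$n_substrates))
  ctx_genes <- sort(c(substrates, ctx_extra))
  ctx_sign <- stats::setNames(sample(c(-1, 1), length(ctx_genes), replace = TRUE),
                              ctx_genes)
  ctx_sign[substrates] <- 1  # substrates modelled as enriched on ligase loss
  list(ids = ids, ub_ids = ub_ids, substrates = substrates,
       ub_planted = ub_planted, ip_planted = ip_planted,
       screen_genes = screen_genes, ctx_genes = ctx_genes,
       ctx_sign = ctx_sign)
}

#' Simulate a diGly-site peptide intensity table
#'
#' KO vs WT intensities for `n_sites` ubiquitylation sites.  Planted
#' proteins have all their sites shifted so that the KO/WT mean intensity
#' ratio is `2^-effect`; null sites have ratio 1.  Replicate noise is
#' log-normal (`noise_sd` on the log2 scale); `noise_sd = 0` forces exact
#' ratios.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (data frame: protein_id, site_position,
#'   peptide_key, KO_*/WT_* intensity columns) and `truth`
#'   (planted_lost_ub_proteins, effect).
#' @export
gen_ub_peptides <- function(cfg) {
  stopifnot(inherits(cfg, "ub_sim_config"))
  uni <- sim_universe(cfg)
  p <- cfg$ub
  set.seed(stream_seed(cfg$seed, "ub_peptides"))
  n_prot <- length(uni$ub_ids)
  # every protein gets one site, remaining sites spread at random
  protein <- c(uni$ub_ids,
               sample(uni$ub_ids, max(0L, p$n_sites - n_prot), replace = TRUE))
  protein <- protein[seq_len(p$n_sites)]
  pos <- integer(p$n_sites)
  for (pr in unique(protein)) {
    i <- which(protein == pr)
    pos[i] <- sort(sample(5:600, length(i)))
  }
  planted <- protein %in% uni$ub_planted
  base <- stats::rnorm(p$n_sites, mean = 25, sd = 2)
  r <- p$n_replicates
  wt <- matrix(2^(base + stats::rnorm(p$n_sites * r, 0, p$noise_sd)),
               ncol = r)
  ko <- matrix(2^(base - ifelse(planted, p$effect, 0) +
                    stats::rnorm(p$n_sites * r, 0, p$noise_sd)), ncol = r)
  colnames(wt) <- paste0("WT_", seq_len(r))
  colnames(ko) <- paste0("KO_", seq_len(r))
  tab <- data.frame(protein_id = protein, site_position = pos,
                    peptide_key = sprintf("%s_K%d", protein, pos),
                    ko, wt, stringsAsFactors = FALSE)
  list(table = tab,
       truth = list(planted_lost_ub_proteins = uni$ub_planted,
                    effect = p$effect))
}

#' Simulate an IP vs IgG spectral-count table
#'
#' Total counts for each run are drawn as a single multinomial over
#' proteins.  Baseline protein weights are log-normal; planted interactors
#' have IP proportion equal to `fold` times their IgG proportion (before
#' renormalization).
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (protein_id, count_ip, count_igg) and `truth`.
#' @export
gen_spectral_counts <- function(cfg) {
  stopifnot(inherits(cfg, "ub_sim_config"))
  uni <- sim_universe(cfg)
  p <- cfg$ip
  assert_that(p$fold >= 1, "gen_spectral_counts",
              "planted interactor fold must be >= 1")
  set.seed(stream_seed(cfg$seed, "spectral_counts"))
  n <- cfg$n_proteins
  w <- stats::rlnorm(n, 0, p$base_sd)
  planted <- uni$ids %in% uni$ip_planted
  prop_igg <- w / sum(w)
  w_ip <- w * ifelse(planted, p$fold, 1)
  prop_ip <- w_ip / sum(w_ip)
  tab <- data.frame(
    protein_id = uni$ids,
    count_ip  = as.integer(stats::rmultinom(1, p$total_ip, prop_ip)),
    count_igg = as.integer(stats::rmultinom(1, p$total_igg, prop_igg)),
    stringsAsFactors = FALSE)
  list(table = tab,
       truth = list(planted_interactors = uni$ip_planted, fold = p$fold))
}

#' Simulate a CRISPR screen guide-count matrix
#'
#' Negative-binomial counts (variance `mu + dispersion * mu^2`) for every
#' guide at day 0 and day 10 in two contexts (`sgCTRL`, `sgFBXO11`) with
#' replicates.  Context-dependent genes receive their day-10 effect (signed
#' log2 shift) in the `sgFBXO11` context only.  `dispersion = 0` makes
#' counts deterministic (rounded means).
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (guide_id, gene_id and one count column per
#'   `<context>.<timepoint>.r<rep>`) and `truth`.
#' @export
gen_guide_counts <- function(cfg) {
  stopifnot(inherits(cfg, "ub_sim_config"))
  uni <- sim_universe(cfg)
  p <- cfg$screen
  set.seed(stream_seed(cfg$seed, "guide_counts"))
  genes <- uni$screen_genes
  g <- p$guides_per_gene
  gene_id <- rep(genes, each = g)
  guide_id <- sprintf("%s_g%d", gene_id, rep(seq_len(g), length(genes)))
  n <- length(guide_id)
  # library representation varies between guides but not across columns
  mu0 <- if (p$dispersion == 0) rep(p$depth, n) else
    p$depth * 2^stats::rnorm(n, 0, 0.25)
  eff <- stats::setNames(rep(0, length(genes)), genes)
  eff[uni$ctx_genes] <- p$effect * uni$ctx_sign[uni$ctx_genes]
  eff_guide <- eff[gene_id]
  draw <- function(mu) {
    if (p$dispersion == 0) as.integer(round(mu))
    else as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / p$dispersion))
  }
  cols <- list()
  for (ctx in c("sgCTRL", "sgFBXO11")) {
    for (tp in c("day0", "day10")) {
      for (rep_i in seq_len(p$n_replicates)) {
        mu <- mu0
        if (tp == "day10" && ctx == "sgFBXO11") mu <- mu0 * 2^eff_guide
        cols[[sprintf("%s.%s.r%d", ctx, tp, rep_i)]] <- draw(mu)
      }
    }
  }
  tab <- data.frame(guide_id = guide_id, gene_id = gene_id,
                    cols, stringsAsFactors = FALSE, check.names = FALSE)
  list(table = tab,
       truth = list(planted_context_genes =
                      data.frame(gene_id = uni$ctx_genes,
                                 effect = unname(eff[uni$ctx_genes]),
                                 stringsAsFactors = FALSE)))
}

#' Simulate a two-group LFQ protein quantity matrix
#'
#' Log-normal quantities for the full protein universe over
#' disease and healthy sample columns.  Proteins in the node set of the
#' supplied interaction network are shifted in the disease group by
#' `lfq$network_effect` (log2); values are then masked missing (absent,
#' encoded `NA`) completely at random at `lfq$missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @param network an [igraph::graph] or character vector of node ids; if
#'   `NULL`, the planted interactor set is used.
#' @return list with `matrix` (proteins x samples, `NA` = absent),
#'   `groups` (named character vector: sample -> "disease"/"healthy") and
#'   `truth` (planted_de_proteins with true log2FC).
#' @export
gen_lfq_matrix <- function(cfg, network = NULL) {
  stopifnot(inherits(cfg, "ub_sim_config"))
  uni <- sim_universe(cfg)
  p <- cfg$lfq
  nodes <- if (is.null(network)) uni$ip_planted
  else if (inherits(network, "igraph")) igraph::V(network)$name
  else as.character(network)
  nodes <- intersect(nodes, uni$ids)
  set.seed(stream_seed(cfg$seed, "lfq_matrix"))
  n <- cfg$n_proteins
  samples <- c(sprintf("D%02d", seq_len(p$n_disease)),
               sprintf("H%02d", seq_len(p$n_healthy)))
  groups <- stats::setNames(rep(c("disease", "healthy"),
                                c(p$n_disease, p$n_healthy)), samples)
  base <- stats::rnorm(n, p$base_mean, p$base_sd)
  shift <- ifelse(uni$ids %in% nodes, p$network_effect, 0)
  m <- matrix(NA_real_, n, length(samples),
              dimnames = list(uni$ids, samples))
  for (j in seq_along(samples)) {
    mu <- base + if (groups[j] == "disease") shift else 0
    m[, j] <- 2^(mu + stats::rnorm(n, 0, p$noise_sd))
  }
  if (p$missing_rate > 0)
    m[matrix(stats::runif(length(m)) < p$missing_rate, nrow(m))] <- NA
  list(matrix = m, groups = groups,
       truth = list(planted_de_proteins =
                      data.frame(protein_id = nodes,
                                 log2fc = rep(p$network_effect, length(nodes)),
                                 stringsAsFactors = FALSE)))
}

#' Simulate a pre-scored interaction edge table
#'
#' Confidence-scored undirected edges among a node set (ring backbone plus
#' random chords), emulating an externally supplied interaction database
#' export.  Planted edges get high confidence; a fringe of decoy edges to
#' outside nodes gets low confidence.
#'
#' @param cfg a [sim_config()].
#' @param nodes character vector of node ids; default planted interactors.
#' @return data frame (node_a, node_b, confidence).
#' @export
gen_edge_table <- function(cfg, nodes = NULL) {
  stopifnot(inherits(cfg, "ub_sim_config"))
  uni <- sim_universe(cfg)
  if (is.null(nodes)) nodes <- uni$ip_planted
  set.seed(stream_seed(cfg$seed, "spectral_counts") + 13L)
  k <- length(nodes)
  ring <- data.frame(node_a = nodes, node_b = nodes[c(2:k, 1)])
  n_chord <- max(1L, k)
  chord <- t(replicate(n_chord, sample(nodes, 2)))
  core <- unique(rbind(ring, data.frame(node_a = chord[, 1], node_b = chord[, 2])))
  core$confidence <- round(stats::runif(nrow(core), 0.75, 0.99), 3)
  out <- setdiff(uni$ids, nodes)
  fringe <- data.frame(node_a = sample(nodes, k, replace = TRUE),
                       node_b = sample(out, k),
                       confidence = round(stats::runif(k, 0.15, 0.6), 3))
  rbind(core, fringe)
}

#' Simulate a splice-event junction-count table
#'
#' Inclusion (`I`) and skipping (`S`) junction counts per event per sample,
#' binomial at fixed per-event depth.  Planted events have group-1 PSI
#' shifted by `splice$delta_psi` relative to group 2.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (event rows; `inc_*` / `skip_*` sample
#'   columns; lengths), `groups`, and `truth`.
#' @export
gen_splicing_counts <- function(cfg) {
  stopifnot(inherits(cfg, "ub_sim_config"))
  uni <- sim_universe(cfg)
  p <- cfg$splice
  set.seed(stream_seed(cfg$seed, "splicing_counts"))
  types <- sample(c("SE", "RI", "A3SS", "A5SS", "MXE"), p$n_events,
                  replace = TRUE, prob = c(0.5, 0.15, 0.125, 0.125, 0.1))
  event_id <- sprintf("E%04d", seq_len(p$n_events))
  gene <- sample(uni$ids, p$n_events, replace = TRUE)
  planted <- seq_len(p$n_events) %in% sample(p$n_events, p$n_planted)
  psi2 <- stats::runif(p$n_events, 0.25, 0.75)            # group-2 (control)
  psi1 <- pmin(0.98, pmax(0.02, psi2 + ifelse(planted, p$delta_psi, 0)))
  samples <- c(sprintf("G1_s%d", seq_len(p$n_group1)),
               sprintf("G2_s%d", seq_len(p$n_group2)))
  groups <- stats::setNames(rep(c("group1", "group2"),
                                c(p$n_group1, p$n_group2)), samples)
  inc <- matrix(0L, p$n_events, length(samples),
                dimnames = list(event_id, samples))
  for (j in seq_along(samples)) {
    psi <- if (groups[j] == "group1") psi1 else psi2
    inc[, j] <- stats::rbinom(p$n_events, p$depth, psi)
  }
  skip <- p$depth - inc
  tab <- data.frame(event_id = event_id, gene = gene, event_type = types,
                    len_inc = p$len_inc, len_skip = p$len_skip,
                    stringsAsFactors = FALSE)
  incd <- as.data.frame(inc); names(incd) <- paste0("inc_", samples)
  skipd <- as.data.frame(skip); names(skipd) <- paste0("skip_", samples)
  tab <- cbind(tab, incd, skipd)
  rownames(tab) <- NULL
  list(table = tab, groups = groups,
       truth = list(planted_splice_events =
                      data.frame(event_id = event_id[planted],
                                 delta_psi = psi1[planted] - psi2[planted],
                                 stringsAsFactors = FALSE)))
}
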