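#' Pipeline run configuration
#'
#' Collects every stage threshold (with the pipeline's standard defaults),
#' the simulation configuration, the permutation count, and the output
#' directory into one serializable object.
#'
#' @param seed global seed; flows into the simulation and the GSEA
#'   permutation stream.
#' @param outdir output directory (created if missing).
#' @param ub_threshold site |log2FC| cutoff (default 0.5).
#' @param ip_p,ip_fc interactor box cutoffs (defaults 0.05, 1.5).
#' @param network_confidence edge confidence cutoff (default 0.7).
#' @param screen_alpha screen significance level (default 0.05).
#' @param de_p,de_fc proteome volcano cutoffs (defaults 0.05, 0.5).
#' @param splice_fdr,splice_p,splice_dpsi splice-event filter (defaults
#'   0.05, 0.05, 0.15).
#' @param n_perm GSEA permutations (default 1000).
#' @param sim named list of overrides forwarded to [sim_config()].
#' @return list of class `ub_run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("ubnexus_run_"),
                       ub_threshold = 0.5, ip_p = 0.05, ip_fc = 1.5,
                       network_confidence = 0.7, screen_alpha = 0.05,
                       de_p = 0.05, de_fc = 0.5, splice_fdr = 0.05,
                       splice_p = 0.05, splice_dpsi = 0.15,
                       n_perm = 1000L, sim = list()) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              ub_threshold = ub_threshold, ip_p = ip_p, ip_fc = ip_fc,
              network_confidence = network_confidence,
              screen_alpha = screen_alpha, de_p = de_p, de_fc = de_fc,
              splice_fdr = splice_fdr, splice_p = splice_p,
              splice_dpsi = splice_dpsi, n_perm = as.integer(n_perm),
              sim = sim)
  ok <- function(x, lo, hi) is.numeric(x) && x >= lo && x <= hi
  assert_that(ok(ub_threshold, 0, Inf) && ok(ip_p, 0, 1) &&
                ok(network_confidence, 0, 1) && ok(screen_alpha, 0, 1) &&
                ok(de_p, 0, 1) && ok(splice_fdr, 0, 1) &&
                ok(splice_p, 0, 1) && ok(splice_dpsi, 0, 1),
              "run_config", "threshold out of range")
  class(cfg) <- "ub_run_config"
  cfg
}

#' Run the full pipeline on synthetic data
#'
#' Generates every input stream (seeded from the run configuration),
#' writes them in their standard on-disk formats, executes all analysis
#' stages in dependency order, and returns (and writes) a machine-readable
#' run report.  Any stage failure halts with a stage-tagged error.
#' Rerunning with the same configuration and seed reproduces a
#' byte-identical report.
#'
#' @param cfg a [run_config()].
#' @return list of class `ub_run_report` (also written as `report.json`
#'   and `report.txt` under `cfg$outdir`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "ub_run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  ind <- file.path(cfg$outdir, "inputs")
  dir.create(ind, showWarnings = FALSE)
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))

  # --- synthetic inputs ------------------------------------------------
  ub <- gen_ub_peptides(scfg)
  ip <- gen_spectral_counts(scfg)
  edges <- gen_edge_table(scfg)
  screen <- gen_guide_counts(scfg)
  splice <- gen_splicing_counts(scfg)
  img_ctrl <- gen_nucleus_images(scfg, "control")
  img_low <- gen_nucleus_images(scfg, "low")
  write_tsv(ub$table, file.path(ind, "ub_peptides.tsv"))
  write_tsv(ip$table, file.path(ind, "spectral_counts.tsv"))
  write_tsv(edges, file.path(ind, "interaction_edges.tsv"))
  write_tsv(screen$table, file.path(ind, "guide_counts.tsv"))
  write_tsv(splice$table, file.path(ind, "splice_events.tsv"))
  write_nucleus_tiff(img_ctrl$images[[1]],
                     file.path(ind, "nucleus_control_example.tif"))
  write_nucleus_tiff(img_low$images[[1]],
                     file.path(ind, "nucleus_low_example.tif"))

  # --- substrate nomination stages ------------------------------------
  sites <- site_log2fc(ub$table, threshold = cfg$ub_threshold)
  lost <- flag_lost_ub(sites, threshold = cfg$ub_threshold)
  calls <- call_interactors(ip$table, p_cutoff = cfg$ip_p,
                            fc_cutoff = cfg$ip_fc)
  in_box <- calls$protein_id[calls$in_box]
  net <- assemble_network(edges, confidence_cutoff = cfg$network_confidence,
                          node_whitelist = in_box)
  genes <- screen_gene_results(screen$table, alpha = cfg$screen_alpha)
  prof <- build_profiles(lost, calls, genes)
  nom <- nominate(prof)
  write_tsv(sites, file.path(cfg$outdir, "ub_sites.tsv"))
  write_tsv(calls, file.path(cfg$outdir, "interaction_calls.tsv"))
  write_tsv(genes, file.path(cfg$outdir, "screen_genes.tsv"))
  write_tsv(nom, file.path(cfg$outdir, "nominations.tsv"))

  # --- proteome stage --------------------------------------------------
  net_nodes <- igraph::V(net)$name
  lfq <- gen_lfq_matrix(scfg, network = net_nodes)
  lmat <- preprocess_lfq(lfq$matrix, lfq$groups)
  de <- differential_proteins(lmat, lfq$groups, p_cutoff = cfg$de_p,
                              fc_cutoff = cfg$de_fc)
  clus <- hierarchical_cluster(lmat, de)
  proj <- project_onto_network(de, net)
  ranking <- stats::setNames(de$t[!de$skipped], de$protein_id[!de$skipped])
  gsea <- gsea_custom_set(ranking, net_nodes, n_perm = cfg$n_perm,
                          seed = cfg$seed)
  write_tsv(de, file.path(cfg$outdir, "proteome_de.tsv"))

  # --- splicing stage --------------------------------------------------
  ev <- event_test(splice$table, splice$groups)
  flt <- filter_events(ev, cfg$splice_fdr, cfg$splice_p, cfg$splice_dpsi)
  write_tsv(flt$results, file.path(cfg$outdir, "splice_results.tsv"))

  # --- imaging stage ---------------------------------------------------
  quant <- function(stream) {
    res <- lapply(stream$images, quantify_nucleus_image)
    list(nuclei = do.call(rbind, lapply(res, `[[`, "nuclei")),
         objects = do.call(rbind, lapply(res, `[[`, "objects")))
  }
  q_ctrl <- quant(img_ctrl); q_low <- quant(img_low)

  # --- report ----------------------------------------------------------
  files <- list.files(ind, full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  report <- list(
    parameters = unclass(cfg)[setdiff(names(cfg), "outdir")],
    input_checksums = as.list(sums),
    counts = list(
      sites_flagged = sum(sites$lost_ub),
      proteins_lost_ub = sum(lost$lost_ub),
      interactors_called = length(in_box),
      network_nodes = length(net_nodes),
      network_edges = igraph::ecount(net),
      genes_classified = sum(genes$class != "none"),
      proteins_significant = sum(de$significant, na.rm = TRUE),
      events_passing = length(flt$passing),
      nuclei_quantified = nrow(q_ctrl$nuclei) + nrow(q_low$nuclei)
    ),
    proteome = list(network_mean_log2fc = proj$mean_log2fc,
                    gsea_es = gsea$es, gsea_nes = gsea$nes,
                    gsea_p = gsea$p_value),
    imaging = list(
      mean_objects_control = mean(q_ctrl$nuclei$n_objects),
      mean_objects_low = mean(q_low$nuclei$n_objects),
      median_circ_control = stats::median(q_ctrl$objects$circularity),
      median_circ_low = stats::median(q_low$objects$circularity),
      median_ar_control = stats::median(q_ctrl$objects$aspect_ratio),
      median_ar_low = stats::median(q_low$objects$aspect_ratio)
    ),
    nominated = nom$protein_id[nom$nominated],
    truth = list(substrates = sim_universe(scfg)$substrates)
  )
  class(report) <- "ub_run_report"
  jsonlite::write_json(unclass(report), file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report), file.path(cfg$outdir, "report.txt"))
  report
}

format_report <- function(report) {
  c("ubnexus run report",
    sprintf("seed: %d", report$parameters$seed),
    "counts:",
    sprintf("  %-22s %s", names(report$counts), unlist(report$counts)),
    sprintf("interactome GSEA: ES=%.4f NES=%.4f p=%.4g",
            report$proteome$gsea_es, report$proteome$gsea_nes,
            report$proteome$gsea_p),
    sprintf("network mean log2FC: %.4f", report$proteome$network_mean_log2fc),
    sprintf("nominated substrates: %s",
            paste(report$nominated, collapse = ", ")))
}

#' @export
print.ub_run_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
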