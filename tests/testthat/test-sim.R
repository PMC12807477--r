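test_that("configuration validates fields and round-trips through JSON", {
  expect_error(sim_config(ip = list(fold = 0.5)), "fold")
  expect_error(sim_config(lfq = list(noise_sd = -1)), "noise")
  expect_error(sim_config(bogus = 1), "unknown field")
  cfg <- tiny_sim(seed = 42)
  path <- tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$ub$n_sites, cfg$ub$n_sites)
  expect_equal(cfg2$image$conditions$low$n_objects,
               cfg$image$conditions$low$n_objects)
})

test_that("same config and seed give bit-identical streams", {
  cfg <- tiny_sim(seed = 7)
  for (gen in list(gen_ub_peptides, gen_spectral_counts, gen_guide_counts,
                   gen_splicing_counts)) {
    expect_identical(gen(cfg), gen(cfg))
  }
  expect_identical(gen_lfq_matrix(cfg), gen_lfq_matrix(cfg))
  expect_identical(gen_nucleus_images(cfg, "low"),
                   gen_nucleus_images(cfg, "low"))
  # and a different seed actually changes the draws
  expect_false(identical(gen_ub_peptides(cfg)$table,
                         gen_ub_peptides(tiny_sim(seed = 8))$table))
})

test_that("planted truth ids are a subset of emitted table ids", {
  cfg <- tiny_sim(seed = 3)
  ub <- gen_ub_peptides(cfg)
  expect_true(all(ub$truth$planted_lost_ub_proteins %in% ub$table$protein_id))
  ip <- gen_spectral_counts(cfg)
  expect_true(all(ip$truth$planted_interactors %in% ip$table$protein_id))
  sc <- gen_guide_counts(cfg)
  expect_true(all(sc$truth$planted_context_genes$gene_id %in% sc$table$gene_id))
  sp <- gen_splicing_counts(cfg)
  expect_true(all(sp$truth$planted_splice_events$event_id %in% sp$table$event_id))
  lf <- gen_lfq_matrix(cfg)
  expect_true(all(lf$truth$planted_de_proteins$protein_id %in%
                    rownames(lf$matrix)))
  expect_true(all(is.finite(sp$truth$planted_splice_events$delta_psi)))
})

test_that("zero-noise forcing pins diGly fold changes exactly", {
  cfg <- tiny_sim(seed = 1)
  cfg$ub$noise_sd <- 0; cfg$ub$effect <- 1
  ub <- gen_ub_peptides(cfg)
  res <- site_log2fc(ub$table, pseudocount = 0)
  planted <- res$protein_id %in% ub$truth$planted_lost_ub_proteins
  expect_equal(unique(res$log2fc[planted]), -1)
  expect_equal(unique(res$log2fc[!planted]), 0)
  cfg$ub$effect <- 0
  res0 <- site_log2fc(gen_ub_peptides(cfg)$table, pseudocount = 0)
  expect_equal(res0$log2fc, rep(0, nrow(res0)))
})

test_that("null diGly sites have mean log2FC within 3 SE of zero", {
  cfg <- sim_config(seed = 11)
  ub <- gen_ub_peptides(cfg)
  res <- site_log2fc(ub$table, pseudocount = 0)
  null_fc <- res$log2fc[!res$protein_id %in% ub$truth$planted_lost_ub_proteins]
  se <- stats::sd(null_fc) / sqrt(length(null_fc))
  expect_lt(abs(mean(null_fc)), 3 * se)
})

test_that("spectral counts conserve the configured totals", {
  cfg <- tiny_sim(seed = 5)
  tab <- gen_spectral_counts(cfg)$table
  expect_identical(sum(tab$count_ip), as.integer(cfg$ip$total_ip))
  expect_identical(sum(tab$count_igg), as.integer(cfg$ip$total_igg))
})

test_that("guide counts honour zero-dispersion and zero-noise forcing", {
  sc <- gen_guide_counts(sim_config(seed = 2, n_proteins = 60L,
                                    n_substrates = 0L,
                                    screen = list(dispersion = 0,
                                                  n_planted = 0L,
                                                  n_genes = 20L)))
  fc <- ubnexus:::context_guide_fc
  expect_equal(unname(fc(sc$table, "sgCTRL")), rep(0, nrow(sc$table)))
  expect_equal(unname(fc(sc$table, "sgFBXO11")), rep(0, nrow(sc$table)))
  # with a planted effect and no dispersion, raw-count FC difference
  # recovers the planted effect (up to integer rounding of the means)
  cfg2 <- sim_config(seed = 2, n_proteins = 60L,
                     screen = list(dispersion = 0, n_planted = 4L,
                                   n_genes = 20L, effect = 1.5))
  sc2 <- gen_guide_counts(cfg2)
  fc_c <- fc(sc2$table, "sgCTRL", normalize = FALSE)
  fc_f <- fc(sc2$table, "sgFBXO11", normalize = FALSE)
  truth <- sc2$truth$planted_context_genes
  for (k in seq_len(nrow(truth))) {
    i <- sc2$table$gene_id == truth$gene_id[k]
    expect_equal(mean(fc_f[i] - fc_c[i]), truth$effect[k], tolerance = 0.02)
  }
})

test_that("LFQ zero-noise shift and missingness rate behave as configured", {
  cfg <- sim_config(seed = 4, n_proteins = 100L,
                    lfq = list(noise_sd = 0, missing_rate = 0))
  lf <- gen_lfq_matrix(cfg, network = c("P0001", "P0002"))
  lm <- log2(lf$matrix)
  d <- rowMeans(lm[, lf$groups == "disease"]) -
    rowMeans(lm[, lf$groups == "healthy"])
  expect_equal(unname(d[c("P0001", "P0002")]), rep(cfg$lfq$network_effect, 2))
  expect_equal(unname(d["P0050"]), 0)
  cfg2 <- sim_config(seed = 4, n_proteins = 400L,
                     lfq = list(missing_rate = 0.2))
  lf2 <- gen_lfq_matrix(cfg2)
  rate <- mean(is.na(lf2$matrix))
  n <- length(lf2$matrix)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("group-label permutation destroys the planted proteome signal", {
  cfg <- sim_config(seed = 6)
  lf <- gen_lfq_matrix(cfg)
  lm <- preprocess_lfq(lf$matrix, lf$groups)
  set.seed(61)
  rates <- vapply(1:5, function(i) {
    g <- stats::setNames(sample(lf$groups), names(lf$groups))
    de <- differential_proteins(lm, g)
    mean(de$p_value[!de$skipped] < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
  # unpermuted labels, by contrast, recover the planted proteins
  de0 <- differential_proteins(lm, lf$groups)
  planted <- lf$truth$planted_de_proteins$protein_id
  hit <- de0$significant[match(planted, de0$protein_id)]
  expect_gt(mean(hit, na.rm = TRUE), 0.8)
})

test_that("planted PSI levels are recovered at depth and edge cases hold", {
  expect_equal(compute_psi(0, 10), 0)
  expect_true(is.na(compute_psi(0, 0)))
  cfg <- sim_config(seed = 9, splice = list(depth = 20000L, n_planted = 0L))
  sp <- gen_splicing_counts(cfg)
  inc <- as.matrix(sp$table[paste0("inc_", names(sp$groups))])
  skip <- as.matrix(sp$table[paste0("skip_", names(sp$groups))])
  psi <- compute_psi(inc, skip)
  # at very deep coverage the empirical PSI approaches the planted value;
  # planted values are uniform on [0.25, 0.75] so compare per-event spread
  expect_lt(max(apply(psi, 1, stats::sd)), 0.02)
})

test_that("synthetic nuclei contain the planted number of bright objects", {
  cfg <- sim_config(seed = 10, image = list(n_nuclei = 3L, noise_sd = 0))
  im <- gen_nucleus_images(cfg, "control")
  for (i in seq_along(im$images)) {
    img <- im$images[[i]]
    rois <- segment_nuclei(img$dapi, min_area = 200)
    expect_length(rois, 1)
    bm <- bright_mask(img$npm1, rois[[1]])
    sh <- object_shapes(bm$bright, min_area = 10)
    expect_identical(nrow(sh),
                     im$truth$planted_objects_per_nucleus[[i]]$n_objects)
  }
})

test_that("TIFF round trip preserves channel content to 16-bit precision", {
  cfg <- sim_config(seed = 12, image = list(n_nuclei = 1L))
  img <- gen_nucleus_images(cfg, "low")$images[[1]]
  path <- tempfile(fileext = ".tif")
  write_nucleus_tiff(img, path)
  back <- read_nucleus_tiff(path)
  expect_lt(max(abs(back$npm1 - img$npm1)), 1e-4)
  expect_lt(max(abs(back$dapi - img$dapi)), 1e-4)
})
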