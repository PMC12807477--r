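#' Simulation configuration
#'
#' Builds the configuration object consumed by every synthetic-data
#' generator.  Defaults describe one coherent study: a shared namespace of
#' `n_proteins` protein/gene ids in which a small set of "substrate"
#' proteins carries evidence in all three nomination streams (lost
#' ubiquitylation, physical interaction, context-dependent screen effect),
#' while each stream additionally has its own stream-specific planted
#' positives.  Sample sizes mirror the study design the pipeline targets:
#' 3 replicates per condition for the diGly ubiquitylome, 6 guides per gene
#' in 2 screen replicates, and a 13-disease vs 6-healthy LFQ proteome.
#'
#' Randomness is controlled by a single global `seed` that is expanded
#' deterministically into one substream seed per generator (fixed offsets),
#' so regenerating one stream never perturbs another.
#'
#' @param seed integer global seed.
#' @param ... named overrides for any top-level block (`ub`, `ip`, `screen`,
#'   `lfq`, `splice`, `image`) or scalar field (`n_proteins`,
#'   `n_substrates`); block overrides are merged field-wise into defaults.
#' @return a list of class `ub_sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed         = as.integer(seed),
    n_proteins   = 800L,   # shared protein/gene id universe
    n_substrates = 2L,     # full-evidence proteins planted in all 3 streams
    ub = list(
      n_sites      = 1000L, # diGly sites, spread over the first 200 proteins
      n_ub_proteins = 200L,
      n_planted    = 20L,   # proteins that lose ubiquitylation on KO
      effect       = 2,     # log2 drop of KO/WT intensity at planted sites
      noise_sd     = 0.3,   # replicate log2 intensity noise
      n_replicates = 3L
    ),
    ip = list(
      total_ip   = 20000L,  # spectral-count depth of the bait IP run
      total_igg  = 20000L,  # and of the IgG control run
      n_planted  = 25L,     # true interactors
      fold       = 8,       # IP/IgG proportion ratio for true interactors
      base_sd    = 0.5      # log-normal spread of baseline protein weights
    ),
    screen = list(
      n_genes      = 100L,  # library genes (subset of the universe)
      guides_per_gene = 6L,
      n_replicates = 2L,
      depth        = 500,   # mean day-0 guide count
      dispersion   = 0.05,  # NB dispersion (var = mu + disp * mu^2)
      n_planted    = 10L,   # context-dependent genes
      effect       = 1.5    # log2 day10 shift, applied in sgFBXO11 only
    ),
    lfq = list(
      n_disease    = 13L,
      n_healthy    = 6L,
      base_mean    = 20,    # mean log2 quantity
      base_sd      = 2,     # between-protein spread of baseline log2 level
      noise_sd     = 0.5,   # within-group replicate log2 noise
      network_effect = -1,  # log2 shift applied to network-node proteins
      missing_rate = 0.1
    ),
    splice = list(
      n_events   = 200L,
      n_group1   = 8L,      # e.g. low-expression disease samples
      n_group2   = 8L,      # healthy controls
      depth      = 100L,    # junction reads per event per sample
      n_planted  = 20L,
      delta_psi  = 0.3,
      len_inc    = 2L,
      len_skip   = 1L
    ),
    image = list(
      width   = 192L, height = 192L,
      nucleus_axes = c(70, 55),   # nucleus ellipse semi-axes, px
      n_nuclei = 20L,             # images per condition
      noise_sd = 0.02,            # Gaussian noise on [0,1] intensities
      conditions = list(
        # control-like: few, larger, elongated bright objects
        control = list(n_objects = 3L, object_axes = c(14, 7)),
        # knockdown-like: more, smaller, rounder objects
        low     = list(n_objects = 6L, object_axes = c(8, 7))
      )
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) ub_stop("sim_config", "unknown field: ", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "ub_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk <- function(cond, what) assert_that(cond, "sim_config", what)
  chk(num1(cfg$seed), "seed must be a single integer")
  chk(num1(cfg$n_proteins) && cfg$n_proteins >= 1, "n_proteins >= 1")
  chk(cfg$n_substrates >= 0 && cfg$n_substrates <= cfg$n_proteins,
      "n_substrates in [0, n_proteins]")
  chk(cfg$ub$n_replicates >= 2, "ub: >= 2 replicates per condition required")
  chk(cfg$ub$noise_sd >= 0 && cfg$lfq$noise_sd >= 0 && cfg$image$noise_sd >= 0,
      "noise scales must be >= 0")
  chk(cfg$ip$fold >= 1, "ip: planted interactor fold must be >= 1")
  chk(cfg$screen$dispersion >= 0, "screen: dispersion must be >= 0")
  chk(cfg$screen$guides_per_gene >= 2, "screen: >= 2 guides per gene")
  chk(cfg$lfq$missing_rate >= 0 && cfg$lfq$missing_rate < 1,
      "lfq: missing_rate in [0, 1)")
  chk(cfg$splice$delta_psi >= 0 && cfg$splice$delta_psi <= 1,
      "splice: delta_psi in [0, 1]")
  counts <- c(cfg$ub$n_sites, cfg$ip$total_ip, cfg$screen$n_genes,
              cfg$lfq$n_disease, cfg$lfq$n_healthy, cfg$splice$n_events,
              cfg$image$n_nuclei)
  chk(all(counts >= 1), "all counts must be >= 1")
  invisible(cfg)
}

#' Serialize / restore a simulation configuration
#'
#' @param cfg a `ub_sim_config`.
#' @param path JSON file path.
#' @return `read_sim_config` returns a validated `ub_sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, c(list(seed = raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}

# ids shared by all streams
protein_ids <- function(n) sprintf("P%04d", seq_len(n))
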