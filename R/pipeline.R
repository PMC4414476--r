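#' Pipeline configuration
#'
#' Either `vcf` (plus `populations`, and optionally `pedigree_file`,
#' `types_file`) or `simulate` must be supplied.
#'
#' @param out_dir output directory for artifacts.
#' @param simulate optional [sim_config()] for synthetic input.
#' @param vcf optional phased VCF path.
#' @param populations named vector sample -> population (VCF input).
#' @param pedigree_file optional pedigree CSV (id, sire, dam, breed).
#' @param types_file optional type-class CSV (animal_id, type).
#' @param focal focal breed label (defaults to the simulated one).
#' @param qc a [qc_thresholds()] object.
#' @param max_gap,block_size block construction parameters.
#' @param ar_g optional rarefaction depth override.
#' @param deluge list of [great_deluge()] parameters.
#' @param selection list of [select_nucleus()] thresholds.
#' @param seed master seed; per-stage seeds are derived from it by a
#'   stable string hash so stages are reproducible in isolation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, vcf = NULL,
                            populations = NULL, pedigree_file = NULL,
                            types_file = NULL, focal = NULL,
                            qc = qc_thresholds(), max_gap = 50000,
                            block_size = 4, ar_g = NULL,
                            deluge = list(max_iter = 20000),
                            selection = list(max_foreign = 0.125,
                                             max_rel = 0.25,
                                             max_self = 1.05, sd_mult = 2),
                            seed = 1L) {
  if (is.null(simulate) && is.null(vcf))
    stop("either a simulation config or a VCF path is required")
  structure(list(out_dir = out_dir, simulate = simulate, vcf = vcf,
                 populations = populations, pedigree_file = pedigree_file,
                 types_file = types_file, focal = focal, qc = qc,
                 max_gap = max_gap, block_size = block_size, ar_g = ar_g,
                 deluge = deluge, selection = selection,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# stable per-stage child seed: polynomial string hash folded into [0, 2^28)
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 268435456
  as.integer((h + seed) %% 268435456)
}

#' Run the haplotype-block analysis pipeline end to end
#'
#' Stages, in order: input (simulate or read VCF) -> SNP QC -> block
#' construction and encoding -> diversity table -> pairwise G_ST / D_EST /
#' D_A / D_PS matrices (CSV plus PHYLIP and NEXUS) -> genomic relationship
#' matrix -> 2D embedding -> nucleus selection -> evidence correlations.
#' A manifest JSON records the package version, seed, and per-stage sizes.
#' Any stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()] object.
#' @return invisibly, a list with the main in-memory results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(cfg$out_dir, f)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(package = "hapdiv",
                   version = as.character(utils::packageVersion("hapdiv")),
                   seed = cfg$seed, stages = list())

  ## input
  res <- run_stage("input", {
    if (!is.null(cfg$simulate)) {
      sim_cfg <- cfg$simulate
      sim_cfg$seed <- stage_seed(cfg$seed, "simulate")
      sim <- simulate_panel(sim_cfg)
      if (is.null(cfg$focal)) cfg$focal <- sim_cfg$focal_breed
      list(panel = sim$panel, haps = sim$haplotypes,
           pedigree = sim$pedigree, types = sim$types, truth = sim$truth)
    } else {
      inp <- read_phased_vcf(cfg$vcf, cfg$populations)
      ped <- if (!is.null(cfg$pedigree_file))
        utils::read.csv(cfg$pedigree_file, stringsAsFactors = FALSE)
      typ <- if (!is.null(cfg$types_file))
        utils::read.csv(cfg$types_file, stringsAsFactors = FALSE)
      list(panel = inp$panel, haps = inp$haplotypes,
           pedigree = ped, types = typ, truth = NULL)
    }
  })
  manifest$stages$input <- list(n_snps = nrow(res$panel),
                                n_animals = length(res$haps$animal_id))

  ## QC
  run_stage("qc", {
    res$fpanel <- filter_snps(res$panel, res$haps, thresholds = cfg$qc)
    res$fhaps <- subset_haplotypes(res$haps, res$fpanel)
    utils::write.csv(attr(res$fpanel, "qc_log"), art("qc_log.csv"),
                     row.names = FALSE)
  })
  manifest$stages$qc <- list(n_snps_kept = nrow(res$fpanel))

  ## blocks
  run_stage("blocks", {
    res$blocks <- build_blocks(res$fpanel, cfg$max_gap, cfg$block_size)
    res$ba <- encode_block_alleles(res$fhaps, res$blocks)
    bed <- data.frame(chrom = res$blocks$chrom,
                      start = res$blocks$start - 1L, end = res$blocks$end)
    utils::write.table(bed, art("blocks.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.csv(data.frame(block = seq_len(nrow(res$blocks)),
                                snp_id = apply(res$blocks$idx, 1, function(i)
                                  paste(res$fpanel$snp_id[i], collapse = ";"))),
                     art("block_snps.csv"), row.names = FALSE)
  })
  manifest$stages$blocks <- list(n_blocks = nrow(res$blocks))

  ## diversity
  run_stage("diversity", {
    res$ac <- tally_alleles(res$ba)
    res$diversity <- summarize_diversity(res$ba, res$fhaps, g = cfg$ar_g)
    utils::write.csv(res$diversity, art("diversity.csv"), row.names = FALSE)
  })
  manifest$stages$diversity <- list(n_pops = length(res$ac$pops),
                                    rarefaction_g = attr(res$diversity, "g"))

  ## distances
  run_stage("distances", {
    res$gst <- gst_pairwise(res$ac)
    res$dest <- dest_pairwise(res$ac)
    res$da <- nei_da(block_frequencies(res$ac))
    res$dps <- dps_individuals(res$ba)
    for (nm in c("gst", "dest", "da", "dps")) {
      utils::write.csv(res[[nm]], art(paste0(nm, ".csv")))
      export_distance(res[[nm]], art(paste0(nm, ".phy")), "phylip")
      export_distance(res[[nm]], art(paste0(nm, ".nex")), "nexus")
    }
  })
  manifest$stages$distances <- list(n_pairs = sum(upper.tri(res$gst)))

  ## relationships
  run_stage("grm", {
    res$G <- genomic_relationship(res$fhaps)
    utils::write.csv(res$G, art("grm.csv"))
  })
  manifest$stages$grm <- list(n_animals = nrow(res$G))

  ## embedding
  run_stage("embed", {
    del <- cfg$deluge
    res$embedding <- do.call(great_deluge, c(
      list(m = res$dps, seed = stage_seed(cfg$seed, "embed")), del))
    utils::write.csv(data.frame(animal_id = res$ba$animal_id,
                                population = res$ba$population,
                                x = res$embedding$coords[, 1],
                                y = res$embedding$coords[, 2]),
                     art("embedding.csv"), row.names = FALSE)
  })
  manifest$stages$embed <- list(start_cor = res$embedding$start_cor,
                                final_cor = res$embedding$final_cor)

  ## selection
  run_stage("select", {
    pops <- stats::setNames(res$ba$population, res$ba$animal_id)
    ff <- NULL
    if (!is.null(res$pedigree)) {
      comp <- pedigree_breed_composition(res$pedigree, cfg$focal)
      focal_frac <- comp$fractions[, cfg$focal]
      ff <- 1 - focal_frac[names(pops)[pops == cfg$focal]]
      names(ff) <- names(pops)[pops == cfg$focal]
    } else {
      ff <- stats::setNames(rep(0, sum(pops == cfg$focal)),
                            names(pops)[pops == cfg$focal])
    }
    res$selection <- select_nucleus(res$G, pops, cfg$focal, ff,
                                    cfg$selection)
    utils::write.csv(res$selection$report, art("selection.csv"),
                     row.names = FALSE)
  })
  manifest$stages$select <- list(
    n_focal = nrow(res$selection$report),
    n_nucleus = length(res$selection$nucleus))

  ## evidence correlations
  run_stage("correlate", {
    if (!is.null(res$types)) {
      rep_df <- res$selection$report
      src <- names(which.max(colMeans(
        rep_df[, setdiff(colnames(rep_df),
                         c("animal_id", "foreign_fraction", "self_rel",
                           "max_rel_focal", "status", "stage", "reason")),
               drop = FALSE])))
      refs <- unique(res$ba$population)
      refs <- setdiff(refs, cfg$focal)
      adm <- supervised_admixture(res$fhaps, c(cfg$focal, src),
                                  rep_df$animal_id)
      typ <- res$types$type[match(rep_df$animal_id, res$types$animal_id)]
      res$correlations <- correlate_evidence(
        typ, rep_df$foreign_fraction, rep_df[[src]], adm[, src])
      utils::write.csv(res$correlations, art("correlations.csv"))
    }
  })
  manifest$stages$correlate <- list(done = !is.null(res$correlations))

  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
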