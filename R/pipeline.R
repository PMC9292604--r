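## Orchestration: a single structured config drives simulate -> filter ->
## diversity -> dstat -> topoweight -> smc -> hpsmc -> dating, with one
## global seed deriving per-stage seeds and a machine-readable run report.

pkgVersion <- function() {
  as.character(utils::packageVersion("ChelonScan"))
}

paramDigest <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", as.integer(h))
}

defaultRunConfig <- function() {
  list(
    seed = 1L,
    outdir = "chelonscan_run",
    stages = list(simulate = TRUE, filter = TRUE, diversity = TRUE,
                  dstat = TRUE, topoweight = TRUE, smc = TRUE,
                  hpsmc = FALSE, date = TRUE),
    demography = "default_turtle",
    layout = list(n_scaffolds = 4, scaffold_length = 5e6,
                  mito_length = 16000, mito_ne_scale = 0.25,
                  mito_migration = TRUE),
    mask = list(gap_fraction = 0.1, mean_gap = 500),
    filter = list(radius = 5, indel_qual_min = 60),
    diversity = list(window_size = 1e5, min_depth = 5),
    dstat = list(outgroup = "DC", block_size = 1e6, min_sites = 100),
    topoweight = list(outgroup = "DC", size_snps = 50, min_snps = 45,
                      smooth_span = 1e6),
    smc = list(bin_size = 100, pattern = "4+25*2+4+6", t_max = 15,
               max_iters = 15, bootstrap_reps = 0),
    hpsmc = list(pair = c("HH", "LL"), bin_size = 10, pattern = "1+7*2+1",
                 t_max = 15, grid_from = 10, grid_to = 15, grid_step = 1),
    date = list())
}

#' Validate and default-expand a pipeline configuration
#'
#' Accepts a nested list or the path of a YAML file, fills in every default
#' (the defaults are the filter thresholds, window sizes, SNP-window rules,
#' bin sizes and atomic-interval patterns used throughout the package), and
#' reports all problems at once. Re-validating an expanded config is the
#' identity.
#'
#' @param config list or YAML path.
#' @return Fully expanded, validated config list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultRunConfig(), config)
  errs <- character()
  if (is.null(cfg$seed)) errs <- c(errs, "a seed is required")
  for (f in c("vcf", "mask_bed")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      errs <- c(errs, sprintf("%s file does not exist: %s", f, cfg[[f]]))
  }
  if (!cfg$stages$simulate && is.null(cfg$vcf))
    errs <- c(errs, "with simulation disabled a vcf input is required")
  model <- tryCatch(
    if (identical(cfg$demography, "default_turtle")) defaultTurtleModel()
    else buildDemography(cfg$demography),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
  if (!is.null(model)) {
    pops <- model@populations$name
    for (og in c(cfg$dstat$outgroup, cfg$topoweight$outgroup))
      if (!og %in% pops)
        errs <- c(errs, sprintf("unknown outgroup species: %s", og))
    if (cfg$stages$hpsmc && !all(cfg$hpsmc$pair %in% pops))
      errs <- c(errs, "hpsmc pair names unknown species")
  }
  if (length(errs)) stop("invalid config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  cfg$model <- model
  cfg
}

stageSeed <- function(cfg, stage) deriveSeed(cfg$seed, stage)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing every artifact
#' (VCF, BED, window tables, D table, weight tables, trajectories, dated
#' tree, truth record) under \code{cfg$outdir} with headers carrying the
#' package version, seed and a parameter digest. Rerunning with the same
#' config and seed reproduces the key outputs byte for byte.
#'
#' @param cfg validated config from \code{\link{validateConfig}}.
#' @param quiet suppress progress messages.
#' @return A run report: per-stage status and key outputs.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  cfg <- validateConfig(cfg)
  t0 <- Sys.time()
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  # digest the scientific parameters only, not paths
  digest <- paramDigest(cfg[setdiff(names(cfg),
                                    c("model", "outdir", "vcf", "mask_bed"))])
  hdr <- c(sprintf("ChelonScan %s", pkgVersion()),
           sprintf("seed=%d params=%s", cfg$seed, digest))
  report <- list(version = pkgVersion(), seed = cfg$seed,
                 param_digest = digest, stages = list(), outputs = list())
  say <- function(...) if (!quiet) message(sprintf(...))
  mark <- function(stage, status) {
    report$stages[[stage]] <<- status
    say("[%s] %s", stage, status)
  }

  gt <- mito <- mask <- truth <- NULL
  if (cfg$stages$simulate) {
    lay <- cfg$layout
    layout <- genomeLayout(lay$n_scaffolds, lay$scaffold_length,
                           lay$mito_length, lay$mito_ne_scale,
                           lay$mito_migration)
    sim <- simulateGenotypes(cfg$model, layout, 1,
                             seed = stageSeed(cfg, "simulate"))
    gt <- sim$genotypes; mito <- sim$mito; truth <- sim$truth
    mask <- degradeMask(sim$mask, cfg$mask$gap_fraction,
                        seed = stageSeed(cfg, "mask"),
                        mean_gap = cfg$mask$mean_gap)
    vcfPath <- file.path(cfg$outdir, "genotypes.vcf")
    writeGenotypeVcf(gt, vcfPath, header_extra = paste0("##", hdr))
    writeBedMask(mask, file.path(cfg$outdir, "callable.bed"))
    writeTruthRecord(truth, file.path(cfg$outdir, "truth.json"))
    report$outputs$vcf <- vcfPath
    mark("simulate", "ok")
  } else {
    gt <- readGenotypeVcf(cfg$vcf)
    mask <- if (!is.null(cfg$mask_bed))
      readBedMask(cfg$mask_bed, gt@scaffolds) else fullMask(gt@scaffolds)
    mark("simulate", "skipped (external input)")
  }

  if (cfg$stages$filter) {
    vcfPath <- report$outputs$vcf %||% cfg$vcf
    recs <- readVariantRecords(vcfPath)
    filt <- applyFilterChain(recs, radius = cfg$filter$radius,
                             indel_qual_min = cfg$filter$indel_qual_min)
    utils::write.table(
      filt[, c("scaffold", "pos", "ref", "alt", "FILTER")],
      file.path(cfg$outdir, "filter_annotations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    report$outputs$filter_kept <- sum(filt$keep)
    report$outputs$filter_total <- nrow(filt)
    mark("filter", "ok")
  } else mark("filter", "skipped")

  if (cfg$stages$diversity) {
    windows <- makeWindows(gt@scaffolds, cfg$diversity$window_size)
    hets <- lapply(gt@samples, function(s)
      windowedHeterozygosity(gt, s, mask, windows, cfg$diversity$min_depth))
    names(hets) <- gt@samples
    for (s in gt@samples)
      writeWindowStats(hets[[s]],
                       file.path(cfg$outdir,
                                 sprintf("heterozygosity_%s.tsv", s)), hdr)
    report$outputs$mean_het <- vapply(hets, function(h)
      sum(h$n_het) / sum(h$end - h$start), numeric(1))
    report$outputs$tstv <- tryCatch(tstvRatio(gt), error = function(e) NA)
    ibs <- ibsDistanceMatrix(gt, seed = stageSeed(cfg, "ibs"))
    utils::write.table(ibs, file.path(cfg$outdir, "ibs_distances.tsv"),
                       sep = "\t", quote = FALSE)
    report$outputs$ibs <- ibs
    mark("diversity", "ok")
  } else mark("diversity", "skipped")

  tree <- tryCatch(speciesTreeFromModel(cfg$model), error = function(e) NULL)

  if (cfg$stages$dstat) {
    if (is.null(tree)) {
      mark("dstat", "failed: no species tree")
    } else {
      dtab <- dstatScan(gt, tree, cfg$dstat$outgroup,
                        seed = stageSeed(cfg, "dstat"),
                        block_size = cfg$dstat$block_size,
                        min_sites = cfg$dstat$min_sites)
      writeWindowStats(dtab, file.path(cfg$outdir, "dstat.tsv"), hdr)
      report$outputs$dstat <- dtab
      mark("dstat", "ok")
    }
  } else mark("dstat", "skipped")

  if (cfg$stages$topoweight) {
    tw <- topologyWeightScan(gt, cfg$topoweight$outgroup,
                             cfg$topoweight$size_snps,
                             cfg$topoweight$min_snps)
    sm <- smoothWeights(tw, cfg$topoweight$smooth_span)
    writeWindowStats(tw, file.path(cfg$outdir, "topology_weights.tsv"), hdr)
    writeWindowStats(sm, file.path(cfg$outdir,
                                   "topology_weights_smoothed.tsv"), hdr)
    wCols <- grep("^w[0-9]+$", names(tw), value = TRUE)
    means <- colMeans(tw[, wCols, drop = FALSE])
    names(means) <- topologyStrings(attr(tw, "catalog"))
    report$outputs$topology_weight_means <- means
    mark("topoweight", "ok")
  } else mark("topoweight", "skipped")

  if (cfg$stages$smc) {
    sm <- cfg$smc
    who <- sm$samples %||% gt@samples
    cfgS <- smcConfig(bin_size = sm$bin_size, pattern = sm$pattern,
                      t_max = sm$t_max, max_iters = sm$max_iters)
    trajPaths <- character()
    for (s in who) {
      bins <- binarizeDiploid(gt, s, mask, sm$bin_size)
      tr <- tryCatch(fitSmc(bins, cfgS), error = function(e) e)
      if (inherits(tr, "error")) {
        mark("smc", sprintf("failed for %s: %s", s, conditionMessage(tr)))
        next
      }
      gtime <- cfg$model@generation_time[[g2pop(gt, s)]]
      tr <- scaleTrajectory(tr, cfg$model@mu, gtime)
      p <- file.path(cfg$outdir, sprintf("smc_%s.tsv", s))
      writeTrajectory(tr, p, hdr)
      trajPaths <- c(trajPaths, p)
      if (sm$bootstrap_reps > 0) {
        reps <- bootstrapSmc(bins, cfgS, n_reps = sm$bootstrap_reps,
                             seed = stageSeed(cfg, paste0("boot", s)))
        for (i in seq_along(reps))
          writeTrajectory(scaleTrajectory(reps[[i]], cfg$model@mu, gtime),
                          file.path(cfg$outdir,
                                    sprintf("smc_%s_boot%02d.tsv", s, i)),
                          hdr)
      }
    }
    report$outputs$smc_trajectories <- trajPaths
    mark("smc", "ok")
  } else mark("smc", "skipped")

  if (cfg$stages$hpsmc) {
    hp <- cfg$hpsmc
    gtime <- mean(vapply(hp$pair, function(p)
      cfg$model@generation_time[[p]], numeric(1)))
    res <- hpsmcRun(gt, hp$pair, mask,
                    smcConfig(bin_size = hp$bin_size, pattern = hp$pattern,
                              t_max = hp$t_max),
                    mu = cfg$model@mu, gen_time = gtime,
                    grid_range_ma = c(hp$grid_from, hp$grid_to),
                    grid_step_ma = hp$grid_step,
                    seed = stageSeed(cfg, "hpsmc"))
    report$outputs$hpsmc_bracket <- c(lower = res$bracket@lower,
                                      upper = res$bracket@upper)
    writeTrajectory(res$traj,
                    file.path(cfg$outdir,
                              sprintf("hpsmc_%s_%s.tsv", hp$pair[1],
                                      hp$pair[2])), hdr)
    mark("hpsmc", "ok")
  } else mark("hpsmc", "skipped")

  if (cfg$stages$date) {
    calAge <- cfg$date$calibration_age_ma
    if (is.null(calAge) && !is.null(truth)) {
      rootGen <- max(truth@divergence$time)
      calAge <- rootGen * mean(cfg$model@generation_time) / 1e6
    }
    if (is.null(calAge)) {
      mark("date", "skipped: no calibration age available")
    } else {
      d <- populationDistanceMatrix(gt)
      dated <- upgmaCalibratedAges(d, list(taxa = rownames(d),
                                           age = calAge))
      ape::write.tree(dated@tree, file.path(cfg$outdir, "dated_tree.nwk"))
      report$outputs$node_ages_ma <- dated@ages
      mark("date", "ok")
    }
  } else mark("date", "skipped")

  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report[setdiff(names(report), "outputs")],
                       file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

g2pop <- function(gt, s) gt@populations[[s]]
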