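## Synthetic genome generation. The coalescent-with-recombination engine is
## msprime, driven through the bundled script in inst/python; everything
## around it (scenario construction, parsing, masks, truth records,
## determinism) lives here.

pythonBinary <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin))
    stop("no python interpreter on PATH; the simulator backend needs one")
  bin
}

driverPath <- function() {
  p <- system.file("python", "msprime_driver.py", package = "ChelonScan")
  if (!nzchar(p)) stop("msprime driver script not found in package")
  p
}

# Run a list of scenario descriptions through the driver in one interpreter
# invocation; each scenario must carry an 'out' path.
runScenarios <- function(scenarios) {
  cfg <- tempfile(fileext = ".json")
  on.exit(unlink(cfg), add = TRUE)
  jsonlite::write_json(list(scenarios = scenarios), cfg,
                       auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(pythonBinary(), c(driverPath(), cfg),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0)
    stop("simulation backend failed:\n", paste(out, collapse = "\n"))
  invisible(out)
}

modelScenario <- function(model, samples, seed, ne_scale = 1,
                          disable_migration = FALSE, r = model@r,
                          kappa = 4.3) {
  list(
    seed = as.integer(seed), mu = model@mu, r = r, kappa = kappa,
    ne_scale = ne_scale, disable_migration = disable_migration,
    populations = apply(model@populations, 1, function(x)
      list(name = unname(x["name"]), ne = as.numeric(x["ne"])),
      simplify = FALSE),
    splits = if (nrow(model@splits)) lapply(seq_len(nrow(model@splits)),
      function(i) as.list(model@splits[i, ])) else list(),
    migrations = if (nrow(model@migrations)) lapply(
      seq_len(nrow(model@migrations)),
      function(i) as.list(model@migrations[i, ])) else list(),
    pulses = if (nrow(model@pulses)) lapply(seq_len(nrow(model@pulses)),
      function(i) as.list(model@pulses[i, ])) else list(),
    size_changes = if (nrow(model@size_changes)) lapply(
      seq_len(nrow(model@size_changes)),
      function(i) as.list(model@size_changes[i, ])) else list(),
    samples = samples)
}

readSimTsv <- function(path, sample_names, populations, ploidy, scaffolds) {
  n_hap <- length(sample_names) * ploidy
  empty <- data.frame(scaffold = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (!file.exists(path) || file.size(path) == 0) {
    sites <- empty
    hap <- matrix(integer(), nrow = 0, ncol = n_hap)
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = c(1, 3, 4, 5),
                                              integer = 2),
                            col.names = c("scaffold", "pos", "ref", "alt",
                                          "gts"))
    codes <- utf8ToInt(paste(dt$gts, collapse = ""))
    hap <- matrix(as.integer(codes - 48L), ncol = n_hap, byrow = TRUE)
    sites <- data.frame(scaffold = dt$scaffold, pos = dt$pos, ref = dt$ref,
                        alt = dt$alt, stringsAsFactors = FALSE)
    ord <- order(match(sites$scaffold, scaffolds$name), sites$pos)
    sites <- sites[ord, , drop = FALSE]
    hap <- hap[ord, , drop = FALSE]
    rownames(sites) <- NULL
  }
  new("GenotypeTable", samples = sample_names, populations = populations,
      ploidy = as.integer(ploidy), scaffolds = scaffolds, sites = sites,
      haplotypes = hap, phased = TRUE, qual = rep(NA_real_, nrow(sites)),
      depth = NULL)
}

#' Mask covering every base of a layout
#' @param layout a \linkS4class{GenomeLayout} or scaffold data.frame.
#' @return A \linkS4class{CallableMask} spanning all scaffolds.
#' @export
fullMask <- function(layout) {
  sc <- if (is(layout, "GenomeLayout")) layout@scaffolds else layout
  new("CallableMask",
      intervals = data.frame(scaffold = sc$name, start = 0, end = sc$length,
                             stringsAsFactors = FALSE),
      scaffolds = sc)
}

buildSimSpec <- function(model, layout, n_diploids_per_pop, seed, kappa) {
  pops <- model@populations$name
  if (n_diploids_per_pop == 1) {
    sample_names <- pops
    sample_pops <- stats::setNames(pops, pops)
  } else {
    sample_names <- as.vector(t(outer(pops, seq_len(n_diploids_per_pop),
                                      paste, sep = "_")))
    sample_pops <- stats::setNames(rep(pops, each = n_diploids_per_pop),
                                   sample_names)
  }
  sampleCfg <- function(ploidy) lapply(pops, function(p)
    list(population = p, n = n_diploids_per_pop, ploidy = ploidy))
  outNuc <- tempfile(fileext = ".tsv")
  scenarios <- list(c(
    modelScenario(model, sampleCfg(2L), seed = deriveSeed(seed, "nuclear"),
                  kappa = kappa),
    list(id = "nuclear", out = outNuc,
         scaffolds = lapply(seq_len(nrow(layout@scaffolds)), function(i)
           list(name = layout@scaffolds$name[i],
                length = layout@scaffolds$length[i])))))
  outMito <- NULL
  if (layout@mito_length > 0) {
    outMito <- tempfile(fileext = ".tsv")
    scenarios <- c(scenarios, list(c(
      modelScenario(model, sampleCfg(1L), seed = deriveSeed(seed, "mito"),
                    ne_scale = layout@mito_ne_scale,
                    disable_migration = !layout@mito_migration, r = 0,
                    kappa = kappa),
      list(id = "mito", out = outMito,
           scaffolds = list(list(name = "mito",
                                 length = layout@mito_length))))))
  }
  list(scenarios = scenarios, sample_names = sample_names,
       sample_pops = sample_pops, outNuc = outNuc, outMito = outMito,
       model = model, layout = layout, seed = seed)
}

collectSim <- function(spec) {
  layout <- spec$layout
  gt <- readSimTsv(spec$outNuc, spec$sample_names, spec$sample_pops, 2L,
                   layout@scaffolds)
  mito <- if (!is.null(spec$outMito))
    readSimTsv(spec$outMito, spec$sample_names, spec$sample_pops, 1L,
               data.frame(name = "mito", length = layout@mito_length,
                          stringsAsFactors = FALSE))
  else NULL
  list(genotypes = gt, mito = mito, mask = fullMask(layout),
       truth = truthRecord(spec$model, spec$seed))
}

#' Simulate many independent scenarios in one backend invocation
#'
#' Starting the simulation backend dominates run time for small genomes;
#' replicate studies (null calibrations, divergence grids) should therefore
#' be batched. Each spec is a list with elements \code{model},
#' \code{layout}, \code{seed} and optionally \code{n_diploids_per_pop}.
#'
#' @param specs list of scenario specs.
#' @param kappa HKY transition/transversion rate parameter.
#' @return List of simulation results as from \code{\link{simulateGenotypes}}.
#' @export
simulateGenotypesBatch <- function(specs, kappa = 4.3) {
  built <- lapply(specs, function(sp)
    buildSimSpec(sp$model, sp$layout, sp$n_diploids_per_pop %||% 1,
                 sp$seed, kappa))
  allScen <- unlist(lapply(built, `[[`, "scenarios"), recursive = FALSE)
  runScenarios(allScen)
  on.exit(unlink(vapply(allScen, `[[`, "", "out")), add = TRUE)
  lapply(built, collectSim)
}

#' Simulate multi-species diploid genomes under a demographic model
#'
#' Generates phased biallelic genotypes over the scaffolds of \code{layout}
#' under \code{model}, together with a full callable mask and the
#' ground-truth record. When the layout defines a mito-surrogate locus, a
#' haploid non-recombining locus is simulated with every population size
#' scaled by \code{mito_ne_scale} (default 1/4) and migration included or
#' not according to \code{mito_migration}.
#'
#' The same seed always reproduces the same output bit for bit.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param layout a \linkS4class{GenomeLayout}.
#' @param n_diploids_per_pop diploid individuals sampled per population.
#' @param seed integer seed.
#' @param kappa transition/transversion rate parameter of the HKY mutation
#'   model (4.3 gives a whole-genome Ts/Tv near 2.15).
#' @return list with elements \code{genotypes} (\linkS4class{GenotypeTable}),
#'   \code{mito} (haploid \linkS4class{GenotypeTable} or NULL), \code{mask}
#'   (\linkS4class{CallableMask}) and \code{truth}
#'   (\linkS4class{TruthRecord}).
#' @export
simulateGenotypes <- function(model, layout, n_diploids_per_pop = 1, seed,
                              kappa = 4.3) {
  stopifnot(is(model, "DemographicModel"), is(layout, "GenomeLayout"))
  if (nrow(layout@scaffolds) == 0 || sum(layout@scaffolds$length) <= 0)
    stop("zero-length genome")
  validObject(model); validObject(layout)
  simulateGenotypesBatch(list(list(model = model, layout = layout,
                                   n_diploids_per_pop = n_diploids_per_pop,
                                   seed = seed)), kappa = kappa)[[1]]
}

#' Simulate independent non-recombining loci
#'
#' Fast path for window-level calibration experiments: \code{n_loci}
#' independent loci of equal length, no within-locus recombination, one
#' haplotype (default) or diploid per population.
#'
#' @inheritParams simulateGenotypes
#' @param n_loci number of independent loci.
#' @param locus_length locus length in bp.
#' @param ploidy 1 (haploid samples) or 2.
#' @return A \linkS4class{GenotypeTable} with one scaffold per locus.
#' @export
simulateLoci <- function(model, n_loci, locus_length, ploidy = 1, seed,
                         kappa = 4.3) {
  stopifnot(is(model, "DemographicModel"), n_loci >= 1, locus_length > 0)
  pops <- model@populations$name
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  sc <- c(modelScenario(model,
                        lapply(pops, function(p)
                          list(population = p, n = 1L,
                               ploidy = as.integer(ploidy))),
                        seed = seed, r = 0, kappa = kappa),
          list(id = "loci", out = out, num_loci = as.integer(n_loci),
               locus_length = locus_length))
  runScenarios(list(sc))
  scaffolds <- data.frame(name = sprintf("locus_%d", seq_len(n_loci)),
                          length = rep(locus_length, n_loci),
                          stringsAsFactors = FALSE)
  gt <- readSimTsv(out, pops, stats::setNames(pops, pops),
                   as.integer(ploidy), scaffolds)
  # loci with no variants leave no trace in the TSV; keep the full scaffold
  # table so window counts stay interpretable
  gt
}

#' Punch random gaps into a callable mask
#'
#' Removes randomly placed gaps (exponentially distributed widths around
#' \code{mean_gap}) until the callable span has shrunk by
#' \code{gap_fraction}, within 1 percent. Emulates the callable-fraction
#' loss real data suffer from mappability and repeat filters (roughly 10
#' percent of selected scaffolds).
#'
#' @param mask a \linkS4class{CallableMask}.
#' @param gap_fraction fraction of callable span to remove, in [0, 1).
#' @param seed integer seed.
#' @param mean_gap mean gap width in bp.
#' @return A degraded \linkS4class{CallableMask}.
#' @export
degradeMask <- function(mask, gap_fraction, seed, mean_gap = 500) {
  stopifnot(is(mask, "CallableMask"))
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)")
  if (gap_fraction == 0) return(mask)
  span0 <- callableSpan(mask)
  target <- gap_fraction * span0
  iv <- mask@intervals
  withSeed(seed, {
    for (pass in 1:50) {
      removed <- span0 - sum(iv$end - iv$start)
      remaining <- target - removed
      if (remaining <= 0.005 * target) break
      width <- min(mean_gap, max(10, remaining))
      k <- max(1L, ceiling(remaining / width))
      # place gap starts uniformly over the genome coordinate space
      tot <- sum(mask@scaffolds$length)
      starts <- floor(stats::runif(k, 0, tot))
      widths <- pmax(1, round(stats::rexp(k, 1 / width)))
      cum <- cumsum(mask@scaffolds$length)
      scIdx <- findInterval(starts, c(0, cum), rightmost.closed = TRUE)
      offset <- c(0, cum)[scIdx]
      gaps <- data.frame(scaffold = mask@scaffolds$name[scIdx],
                         start = starts - offset,
                         end = pmin(starts - offset + widths,
                                    mask@scaffolds$length[scIdx]))
      newIv <- lapply(unique(iv$scaffold), function(sc) {
        cur <- iv[iv$scaffold == sc, , drop = FALSE]
        g <- gaps[gaps$scaffold == sc, , drop = FALSE]
        ir <- IRanges::IRanges(start = cur$start + 1, end = cur$end)
        if (nrow(g) > 0) {
          gr <- IRanges::IRanges(start = g$start + 1, end = g$end)
          ir <- IRanges::setdiff(ir, gr)
        }
        if (length(ir) == 0) return(NULL)
        data.frame(scaffold = sc, start = IRanges::start(ir) - 1,
                   end = IRanges::end(ir), stringsAsFactors = FALSE)
      })
      iv <- do.call(rbind, Filter(Negate(is.null), newIv))
      iv <- iv[order(match(iv$scaffold, mask@scaffolds$name), iv$start), ,
               drop = FALSE]
      rownames(iv) <- NULL
    }
  })
  new("CallableMask", intervals = iv, scaffolds = mask@scaffolds)
}

#' Randomize within-individual allele order
#'
#' Destroys phase by shuffling the order of the two alleles of each diploid
#' individual independently at every site (a fair coin per site and sample).
#' The unordered genotype at every site is preserved exactly.
#'
#' @param g a phased diploid \linkS4class{GenotypeTable}.
#' @param seed integer seed.
#' @return An unphased \linkS4class{GenotypeTable}.
#' @export
unphase <- function(g, seed) {
  stopifnot(is(g, "GenotypeTable"))
  if (g@ploidy != 2L) stop("unphase needs diploid input")
  if (!g@phased) stop("input is already unphased")
  hap <- g@haplotypes
  n <- nrow(hap)
  withSeed(seed, {
    for (i in seq_along(g@samples)) {
      cols <- c(2L * i - 1L, 2L * i)
      swap <- stats::runif(n) < 0.5
      if (any(swap)) {
        tmp <- hap[swap, cols[1]]
        hap[swap, cols[1]] <- hap[swap, cols[2]]
        hap[swap, cols[2]] <- tmp
      }
    }
  })
  out <- g
  out@haplotypes <- hap
  out@phased <- FALSE
  out
}
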