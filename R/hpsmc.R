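## hPSMC: pseudo-haploidize two genomes, build an artificial F1 "hybrid",
## fit its coalescent trajectory, and bracket the end of gene flow against
## a grid of clean-split simulations. Because the two pseudo-haploid
## genomes cannot coalesce more recently than the last gene flow between
## the species, the F1 trajectory shows an apparent Ne explosion at recent
## times whose position dates the cessation of gene flow rather than the
## species split.

#' Collapse a diploid sample to one random allele per position
#'
#' Homozygous sites keep their allele; heterozygous sites contribute one of
#' the two alleles with equal probability (seeded). Sites below the depth
#' or quality floor become missing. Tables without depth/quality
#' annotations (synthetic data) pass those floors.
#'
#' @param g a diploid \linkS4class{GenotypeTable}.
#' @param sample sample name.
#' @param min_depth minimum per-sample depth (default 5).
#' @param min_qual minimum site quality (default 30).
#' @param seed integer seed.
#' @return A \linkS4class{PseudoHaploid}.
#' @export
pseudoHaploidize <- function(g, sample, min_depth = 5, min_qual = 30,
                             seed = 1) {
  stopifnot(is(g, "GenotypeTable"), g@ploidy == 2L)
  cols <- sampleHaplotypeColumns(g, sample)
  h1 <- g@haplotypes[, cols[1]]
  h2 <- g@haplotypes[, cols[2]]
  n <- length(h1)
  allele <- withSeed(deriveSeed(seed, paste0("pseudohap:", sample)), {
    ifelse(h1 == h2, h1, ifelse(stats::runif(n) < 0.5, h1, h2))
  })
  missing <- rep(FALSE, n)
  if (!is.null(g@depth)) {
    dp <- g@depth[, match(sample, g@samples)]
    missing <- missing | is.na(dp) | dp < min_depth
  }
  qual <- g@qual
  missing <- missing | (!is.na(qual) & qual < min_qual)
  allele[missing] <- NA_integer_
  sites <- g@sites
  sites$allele <- as.integer(allele)
  new("PseudoHaploid", sample = sample, scaffolds = g@scaffolds,
      sites = sites, seed = as.integer(seed))
}

#' Combine two pseudo-haploids into an artificial F1 genotype track
#'
#' Positions called in both inputs become diploid genotypes (heterozygous
#' exactly where the alleles differ); positions missing in either are
#' dropped. Both inputs must share the same site coordinate system (come
#' from the same genotype table).
#'
#' @param a,b \linkS4class{PseudoHaploid} objects.
#' @return A diploid \linkS4class{GenotypeTable} with the single sample
#'   \code{"F1"}.
#' @export
makePseudoF1 <- function(a, b) {
  stopifnot(is(a, "PseudoHaploid"), is(b, "PseudoHaploid"))
  if (!identical(a@sites[, c("scaffold", "pos")],
                 b@sites[, c("scaffold", "pos")]))
    stop("disjoint coordinate systems: pseudo-haploids must share sites")
  ok <- !is.na(a@sites$allele) & !is.na(b@sites$allele)
  sites <- a@sites[ok, c("scaffold", "pos", "ref", "alt"), drop = FALSE]
  rownames(sites) <- NULL
  hap <- cbind(a@sites$allele[ok], b@sites$allele[ok])
  new("GenotypeTable", samples = "F1",
      populations = c(F1 = "F1"), ploidy = 2L, scaffolds = a@scaffolds,
      sites = sites, haplotypes = hap, phased = TRUE,
      qual = rep(NA_real_, nrow(sites)), depth = NULL)
}

#' Estimate the pre-divergence plateau Ne of an hPSMC trajectory
#'
#' Replaces the traditional by-eye reading of the old-time flat region with
#' an explicit rule: scanning from the oldest interval toward the present,
#' the rise onset is the oldest interval whose Ne reaches 1.5 times the
#' geometric mean of the three oldest intervals; the plateau is the
#' geometric mean of all intervals older than the onset. A trajectory that
#' rises throughout has no plateau and errors.
#'
#' @param traj a scaled \linkS4class{SmcTrajectory}.
#' @param rise_factor onset threshold relative to the old-time level.
#' @param tail_exclude number of oldest intervals excluded from the
#'   reading: the final open-ended interval absorbs the truncated
#'   coalescence tail and the one before it is weakly constrained, so both
#'   are unreliable (the usual practice of ignoring the oldest segments of
#'   a coalescent-HMM curve).
#' @return list with \code{plateau_ne} and \code{onset_years} (NA when no
#'   rise was detected).
#' @export
estimatePlateauNe <- function(traj, rise_factor = 1.5, tail_exclude = 2) {
  if (nrow(traj@scaled) == 0) stop("scale the trajectory first")
  ne <- traj@scaled$ne
  K <- length(ne)
  if (K < 4 + tail_exclude)
    stop("need >= ", 4 + tail_exclude, " parameter groups to read a plateau")
  ne <- ne[seq_len(K - tail_exclude)]
  K <- K - tail_exclude
  if (all(diff(ne) < 0)) # strictly rising toward the present everywhere
    stop("no plateau: trajectory rises across all intervals")
  ref <- geomMean(ne[(K - 2):K])
  hits <- which(ne >= rise_factor * ref) # index 1 = most recent
  if (length(hits) == 0)
    return(list(plateau_ne = geomMean(ne), onset_years = NA_real_))
  onset <- max(hits) # oldest interval reaching the threshold
  if (onset > K - 2)
    stop("no plateau: trajectory rises across the oldest intervals")
  list(plateau_ne = geomMean(ne[(onset + 1):K]),
       onset_years = traj@scaled$left_years[onset])
}

#' Simulate the clean-split divergence grid
#'
#' For each grid time T, a clean split (no migration) of an ancestral
#' population of size \code{plateau_ne} into two populations of the same
#' size, one diploid sampled per side; each side is pseudo-haploidized, the
#' pseudo-F1 built, and its trajectory fitted with the same configuration
#' as the empirical pair. All grid points run in one backend invocation.
#'
#' @param plateau_ne ancestral (pre-divergence) diploid Ne.
#' @param t_range_ma two divergence times in Ma (grid ends, inclusive).
#' @param step_ma grid step in Myr.
#' @param mu mutation rate per site per generation.
#' @param gen_time mean generation time of the pair, years.
#' @param layout \linkS4class{GenomeLayout} for the simulated genomes.
#' @param cfg \linkS4class{SmcConfig} shared with the empirical fit.
#' @param seed integer seed.
#' @param r recombination rate per site per generation.
#' @return list of lists with elements \code{T} (Ma) and \code{traj}
#'   (scaled \linkS4class{SmcTrajectory}).
#' @export
simulateDivergenceGrid <- function(plateau_ne, t_range_ma, step_ma = 1, mu,
                                   gen_time, layout, cfg, seed, r = 1e-8) {
  stopifnot(plateau_ne > 0, length(t_range_ma) == 2,
            t_range_ma[2] >= t_range_ma[1])
  grid <- seq(t_range_ma[1], t_range_ma[2], by = step_ma)
  if (length(grid) == 0) stop("empty grid")
  specs <- lapply(seq_along(grid), function(i) {
    Tgen <- grid[i] * 1e6 / gen_time
    model <- buildDemography(list(
      populations = list(list(name = "X", ne = plateau_ne),
                         list(name = "Y", ne = plateau_ne)),
      splits = list(list(time = Tgen, childA = "X", childB = "Y",
                         ancestral = "XY", ne = plateau_ne)),
      mu = mu, r = r, generation_time = gen_time))
    list(model = model, layout = layout,
         seed = deriveSeed(seed, "grid", i))
  })
  sims <- simulateGenotypesBatch(specs)
  lapply(seq_along(grid), function(i) {
    traj <- hpsmcFitPair(sims[[i]]$genotypes, c("X", "Y"), sims[[i]]$mask,
                         cfg, seed = deriveSeed(seed, "gridfit", i))
    list(T = grid[i], traj = scaleTrajectory(traj, mu, gen_time))
  })
}

#' Pseudo-haploidize a pair and fit the F1 trajectory
#'
#' @param g diploid \linkS4class{GenotypeTable} containing both samples.
#' @param pair character of length 2: sample names.
#' @param mask \linkS4class{CallableMask}.
#' @param cfg \linkS4class{SmcConfig} (10 bp bins by convention).
#' @param seed integer seed for the pseudo-haploid draws.
#' @param min_depth,min_qual pseudo-haploidization floors.
#' @return An unscaled \linkS4class{SmcTrajectory}.
#' @export
hpsmcFitPair <- function(g, pair, mask, cfg = smcConfig(bin_size = 10),
                         seed = 1, min_depth = 5, min_qual = 30) {
  stopifnot(length(pair) == 2)
  ph <- lapply(pair, function(s)
    pseudoHaploidize(g, s, min_depth, min_qual, seed))
  f1 <- makePseudoF1(ph[[1]], ph[[2]])
  bins <- binarizeDiploid(f1, "F1", mask, cfg@bin_size)
  fitSmc(bins, cfg)
}

# step-function lookup of Ne at time t (years) on a scaled trajectory
neAt <- function(scaled, t) {
  k <- findInterval(t, c(scaled$left_years, Inf), rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1), nrow(scaled))
  scaled$ne[k]
}

#' Bracket the end of gene flow against a divergence grid
#'
#' The comparison window is the set of empirical-trajectory group midpoints
#' whose Ne lies between \code{window_mult[1]} and \code{window_mult[2]}
#' times the plateau (the exponential-rise region). A grid curve is
#' "older" when its Ne exceeds the empirical curve at \code{frac} or more
#' of the window points, and "younger" when below at the same fraction;
#' the bracket is (largest younger T, smallest older T). Whether the grid
#' curves are ordered in T over the window is recorded in
#' \code{grid_monotone}.
#'
#' @param empirical scaled \linkS4class{SmcTrajectory} of the pair.
#' @param grid list from \code{\link{simulateDivergenceGrid}}.
#' @param plateau_ne plateau Ne.
#' @param pair species-pair labels for the report.
#' @param window_mult comparison window as multiples of the plateau.
#' @param frac dominance fraction for the older/younger call.
#' @return A \linkS4class{GeneFlowBracket}.
#' @export
bracketGeneFlowEnd <- function(empirical, grid, plateau_ne,
                               pair = c("A", "B"),
                               window_mult = c(1.5, 10), frac = 0.9) {
  stopifnot(length(grid) >= 2)
  sc <- empirical@scaled
  if (nrow(sc) == 0) stop("scale the empirical trajectory first")
  # the comparison window is the contiguous exponential-rise region: from
  # the foot of the Ne wall (where the curve last exceeds the upper band
  # edge) down to where it first re-enters the plateau; intervals older
  # than the plateau entry are excluded even if late-time drift pushes
  # them back above the lower band edge
  wall <- sc$ne > window_mult[2] * plateau_ne
  t_lo <- if (any(wall)) max(sc$right_years[wall]) else min(sc$left_years)
  belowBand <- sc$ne < window_mult[1] * plateau_ne &
    sc$right_years > t_lo
  t_hi <- if (any(belowBand)) min(sc$left_years[belowBand])
          else max(sc$right_years)
  if (t_hi <= t_lo)
    stop("empirical trajectory never enters the comparison window")
  # dense (log-spaced) evaluation grid across the window, so the
  # older/younger call does not hinge on a handful of interval midpoints
  tEval <- exp(seq(log(max(t_lo, 1)), log(t_hi), length.out = 64))
  neEmp <- neAt(sc, tEval)
  keep <- neEmp >= window_mult[1] * plateau_ne &
    neEmp <= window_mult[2] * plateau_ne
  if (!any(keep))
    stop("empirical trajectory never enters the comparison window")
  tEval <- tEval[keep]
  neEmp <- neEmp[keep]
  Ts <- vapply(grid, `[[`, numeric(1), "T")
  ord <- order(Ts)
  fracAbove <- vapply(grid[ord], function(gm)
    mean(neAt(gm$traj@scaled, tEval) > neEmp), numeric(1))
  fracBelow <- vapply(grid[ord], function(gm)
    mean(neAt(gm$traj@scaled, tEval) < neEmp), numeric(1))
  TsOrd <- Ts[ord]
  older <- fracAbove >= frac
  younger <- fracBelow >= frac
  unbounded <- character()
  lower <- if (any(younger)) max(TsOrd[younger]) else {
    unbounded <- c(unbounded, "below"); -Inf
  }
  upper <- if (any(older)) min(TsOrd[older]) else {
    unbounded <- c(unbounded, "above"); Inf
  }
  new("GeneFlowBracket", pair = pair, grid_times = TsOrd,
      lower = lower, upper = upper, unbounded = unbounded,
      plateau_ne = plateau_ne, window_years = range(tEval),
      grid_monotone = !is.unsorted(fracAbove))
}

#' Default per-pair TMRCA caps for pseudo-F1 fits
#'
#' Deeper pairs need a larger cap: 15 coalescent units for
#' hawksbill/loggerhead, 5 for hawksbill/green, 10 otherwise.
#'
#' @param a,b species codes (e.g. \code{"HH"}, \code{"LL"}).
#' @return t_max in coalescent units.
#' @export
hpsmcTmax <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "/")
  if (key == "HH/LL") return(15)
  if (key == "GG/HH") return(5)
  10
}

#' End-to-end hPSMC for one species pair
#'
#' Pseudo-haploidizes the pair, fits and scales the F1 trajectory, reads
#' (or accepts) the plateau Ne, simulates the divergence grid and brackets
#' the end of gene flow.
#'
#' @inheritParams hpsmcFitPair
#' @param mu,gen_time scaling parameters (generation time should be the
#'   mean of the two species).
#' @param grid_range_ma,grid_step_ma divergence grid in Ma.
#' @param grid_layout \linkS4class{GenomeLayout} for grid simulations.
#' @param plateau \code{"auto"} or a manual plateau Ne.
#' @return list with \code{traj}, \code{plateau}, \code{grid},
#'   \code{bracket}.
#' @export
hpsmcRun <- function(g, pair, mask, cfg = smcConfig(bin_size = 10), mu,
                     gen_time, grid_range_ma, grid_step_ma = 1,
                     grid_layout = NULL, plateau = "auto", seed = 1,
                     min_depth = 5, min_qual = 30) {
  traj <- scaleTrajectory(
    hpsmcFitPair(g, pair, mask, cfg, seed, min_depth, min_qual),
    mu, gen_time)
  plateau_ne <- if (identical(plateau, "auto"))
    estimatePlateauNe(traj)$plateau_ne else as.numeric(plateau)
  if (is.null(grid_layout))
    grid_layout <- new("GenomeLayout",
                       scaffolds = g@scaffolds, mito_length = 0,
                       mito_ne_scale = 0.25, mito_migration = TRUE)
  grid <- simulateDivergenceGrid(plateau_ne, grid_range_ma, grid_step_ma,
                                 mu, gen_time, grid_layout, cfg,
                                 seed = deriveSeed(seed, "hpsmc-grid"))
  bracket <- bracketGeneFlowEnd(traj, grid, plateau_ne, pair)
  list(traj = traj, plateau = plateau_ne, grid = grid, bracket = bracket)
}
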