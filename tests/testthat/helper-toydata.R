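# Shared fixtures, all built in code. Simulation results used by several
# test files are cached for the session so each backend scenario runs once.

.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, producer) {
  if (!exists(key, envir = .simCache)) assign(key, producer(), envir = .simCache)
  get(key, envir = .simCache)
}

# GenotypeTable from a haplotype matrix (sites x haplotypes, 0/1), two
# columns per diploid sample
makeToyGt <- function(hap, samples, positions = seq_len(nrow(hap)),
                      scaffold = "s1", scaffold_length = max(positions) + 10,
                      populations = NULL, ploidy = 2L,
                      ref = rep("A", nrow(hap)), alt = rep("G", nrow(hap)),
                      depth = NULL, qual = rep(NA_real_, nrow(hap))) {
  hap <- matrix(as.integer(hap), nrow = nrow(hap))
  if (is.null(populations)) populations <- stats::setNames(samples, samples)
  new("GenotypeTable", samples = samples, populations = populations,
      ploidy = as.integer(ploidy),
      scaffolds = data.frame(name = scaffold, length = scaffold_length,
                             stringsAsFactors = FALSE),
      sites = data.frame(scaffold = scaffold, pos = as.integer(positions),
                         ref = ref, alt = alt, stringsAsFactors = FALSE),
      haplotypes = hap, phased = TRUE, qual = qual, depth = depth)
}

makeToyMask <- function(intervals, scaffolds) {
  new("CallableMask", intervals = intervals, scaffolds = scaffolds)
}

# SmcTrajectory with a prescribed scaled Ne curve (most recent first), for
# plateau / bracketing unit tests
makeScaledTraj <- function(ne, left_years = NULL, right_years = NULL) {
  K <- length(ne)
  if (is.null(left_years)) {
    bounds <- 10^seq(4, 8, length.out = K + 1)
    left_years <- bounds[seq_len(K)]
    right_years <- bounds[seq_len(K) + 1]
    left_years[1] <- 0
  }
  tr <- new("SmcTrajectory", boundaries = seq(0, 15, length.out = K + 1),
            groups = seq_len(K), lambda = rep(1, K), theta = 0.01,
            rho = 0.01, bin_size = 10L, loglik = numeric(),
            scaled = data.frame(group = seq_len(K), left_years = left_years,
                                right_years = right_years, ne = ne))
  tr
}

# desk-scale five-species model used by the replicate suites: the sea
# turtle topology with split ages scaled to one quarter and matching
# ancestral-size scaling, low recombination to keep coalescent simulation
# cheap while leaving linkage far below the jackknife block size
calibrationModel <- function(pulses = list()) {
  defaultTurtleModel(ne = 25000, time_scale = 0.25, anc_scale = 0.25,
                     r = 4e-9, pulses = pulses)
}

skipIfNoBackend <- function() {
  ok <- tryCatch(nzchar(Sys.which("python")), error = function(e) FALSE)
  if (!ok) stop("no python interpreter available for the simulator backend")
  invisible(TRUE)
}
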