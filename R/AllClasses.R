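#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ChelonScan, .registration = TRUE
NULL

#' DemographicModel: species tree, sizes, migration and rates
#'
#' Records an isolation-with-migration demography: a set of extant
#' populations with diploid effective sizes, a sequence of population splits
#' (times in generations before present, increasing toward the past),
#' migration epochs and admixture pulses, per-site mutation and recombination
#' rates, and per-population generation times in years. This object is both
#' the input to the simulator and the ground-truth record against which
#' inference is checked.
#'
#' @slot populations data.frame with columns \code{name}, \code{ne} (diploid).
#' @slot splits data.frame with columns \code{time} (generations before
#'   present), \code{childA}, \code{childB}, \code{ancestral}, \code{ne}.
#' @slot migrations data.frame with columns \code{pop1}, \code{pop2},
#'   \code{rate} (per generation), \code{start}, \code{end} (generations
#'   before present, \code{start < end}), \code{direction} (one of
#'   \code{"both"}, \code{"1>2"}, \code{"2>1"}; forward-time donor first).
#' @slot pulses data.frame with columns \code{time}, \code{from}, \code{to},
#'   \code{fraction}: forward-time admixture pulses (donor \code{from}).
#' @slot size_changes data.frame with columns \code{pop}, \code{time},
#'   \code{ne}: stepwise population-size changes (the population takes size
#'   \code{ne} at times older than \code{time}).
#' @slot mu mutation rate per site per generation.
#' @slot r recombination rate per site per generation.
#' @slot generation_time named numeric, years per generation per population.
#' @export
setClass("DemographicModel",
  representation(populations = "data.frame", splits = "data.frame",
                 migrations = "data.frame", pulses = "data.frame",
                 size_changes = "data.frame",
                 mu = "numeric", r = "numeric",
                 generation_time = "numeric"),
  prototype(size_changes = data.frame(pop = character(), time = numeric(),
                                      ne = numeric(),
                                      stringsAsFactors = FALSE)))

setValidity("DemographicModel", function(object) {
  msg <- character()
  p <- object@populations
  if (nrow(p) < 1) msg <- c(msg, "at least one population required")
  if (anyDuplicated(p$name)) msg <- c(msg, "duplicate population names")
  if (any(p$ne <= 0)) msg <- c(msg, "population Ne must be > 0")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@r < 0) msg <- c(msg, "r must be >= 0")
  s <- object@splits
  if (nrow(s) > 0) {
    if (any(s$time <= 0)) msg <- c(msg, "split times must be > 0")
    if (any(s$ne <= 0)) msg <- c(msg, "ancestral Ne must be > 0")
    if (is.unsorted(s$time, strictly = TRUE))
      msg <- c(msg, "splits must be ordered with strictly increasing time")
  }
  m <- object@migrations
  if (nrow(m) > 0) {
    if (any(m$rate < 0)) msg <- c(msg, "migration rates must be >= 0")
    if (any(m$end <= m$start))
      msg <- c(msg, "migration epoch end must be > start (times increase into the past)")
  }
  # an epoch (or pulse) must not extend past the merge of its two populations
  mergeTime <- mergeTimeTable(object)
  if (nrow(m) > 0) {
    for (i in seq_len(nrow(m))) {
      tm <- pairMergeTime(mergeTime, object, m$pop1[i], m$pop2[i])
      if (is.na(tm))
        msg <- c(msg, sprintf("migration epoch names unknown population pair %s/%s",
                              m$pop1[i], m$pop2[i]))
      else if (m$end[i] > tm)
        msg <- c(msg, sprintf(
          "migration epoch between %s and %s extends to %g, past their merge at %g",
          m$pop1[i], m$pop2[i], m$end[i], tm))
    }
  }
  sz <- object@size_changes
  if (nrow(sz) > 0) {
    if (any(sz$ne <= 0)) msg <- c(msg, "size-change Ne must be > 0")
    if (any(sz$time <= 0)) msg <- c(msg, "size-change times must be > 0")
  }
  pu <- object@pulses
  if (nrow(pu) > 0) {
    if (any(pu$fraction <= 0 | pu$fraction >= 1))
      msg <- c(msg, "pulse fractions must be in (0,1)")
    for (i in seq_len(nrow(pu))) {
      tm <- pairMergeTime(mergeTime, object, pu$from[i], pu$to[i])
      if (is.na(tm) || pu$time[i] >= tm)
        msg <- c(msg, sprintf("pulse between %s and %s at %g is not before their merge",
                              pu$from[i], pu$to[i], pu$time[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' GenomeLayout: scaffold structure of a simulated genome
#'
#' @slot scaffolds data.frame with columns \code{name}, \code{length} (bp).
#' @slot mito_length length in bp of the haploid non-recombining
#'   mitochondrial-surrogate locus (0 disables it).
#' @slot mito_ne_scale factor applied to every population size for the mito
#'   locus (default 1/4: haploid and maternally inherited).
#' @slot mito_migration logical; whether migration epochs/pulses also apply
#'   to the mito locus (on by default so mitochondrial capture is possible).
#' @export
setClass("GenomeLayout",
  representation(scaffolds = "data.frame", mito_length = "numeric",
                 mito_ne_scale = "numeric", mito_migration = "logical"))

setValidity("GenomeLayout", function(object) {
  msg <- character()
  s <- object@scaffolds
  if (nrow(s) < 1) msg <- c(msg, "at least one scaffold required")
  if (any(s$length <= 0)) msg <- c(msg, "scaffold lengths must be > 0")
  if (anyDuplicated(s$name)) msg <- c(msg, "scaffold names must be unique")
  if (object@mito_length < 0) msg <- c(msg, "mito length must be >= 0")
  if (object@mito_ne_scale <= 0) msg <- c(msg, "mito Ne scale must be > 0")
  if (length(msg)) msg else TRUE
})

#' TruthRecord: simulation ground truth
#'
#' @slot model the \linkS4class{DemographicModel} echoed back.
#' @slot divergence data.frame (\code{pop1}, \code{pop2}, \code{time}):
#'   true split time per pair, generations before present.
#' @slot cessation data.frame (\code{pop1}, \code{pop2}, \code{time}): true
#'   end of gene flow per pair (equals the split time when there was none).
#' @slot seed integer seed used.
#' @export
setClass("TruthRecord",
  representation(model = "DemographicModel", divergence = "data.frame",
                 cessation = "data.frame", seed = "integer"))

setValidity("TruthRecord", function(object) {
  d <- object@divergence; ce <- object@cessation
  key <- function(x) paste(pmin(x$pop1, x$pop2), pmax(x$pop1, x$pop2))
  if (!identical(sort(key(d)), sort(key(ce))))
    return("divergence and cessation tables must cover the same pairs")
  m <- match(key(d), key(ce))
  if (any(ce$time[m] > d$time + 1e-9))
    return("gene-flow cessation cannot predate the split (cessation must be <= split time)")
  TRUE
})

#' GenotypeTable: phased biallelic haplotype matrix over scaffolds
#'
#' The central genotype container: biallelic sites with 1-based positions,
#' one row per site, one column per haplotype (two consecutive columns per
#' diploid sample, one for a haploid sample). Alleles are coded 0 (REF) and
#' 1 (ALT); REF is the ancestral allele for simulated data.
#'
#' @slot samples character sample names.
#' @slot populations named character mapping sample -> population/species.
#' @slot ploidy integer, 1 or 2 (all samples share it).
#' @slot scaffolds data.frame with columns \code{name}, \code{length}.
#' @slot sites data.frame with columns \code{scaffold}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (single bases).
#' @slot haplotypes integer matrix, sites x haplotypes, entries 0/1.
#' @slot phased logical; \code{FALSE} after \code{\link{unphase}}.
#' @slot qual numeric per-site quality (may be all NA).
#' @slot depth optional numeric matrix sites x samples of read depths
#'   (\code{NULL} means depth is unknown and depth filters pass).
#' @export
setClass("GenotypeTable",
  representation(samples = "character", populations = "character",
                 ploidy = "integer", scaffolds = "data.frame",
                 sites = "data.frame", haplotypes = "matrix",
                 phased = "logical", qual = "numeric",
                 depth = "ANY"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  n <- nrow(object@sites)
  if (nrow(object@haplotypes) != n)
    msg <- c(msg, "haplotype matrix and site table disagree on site count")
  if (ncol(object@haplotypes) != length(object@samples) * object@ploidy)
    msg <- c(msg, "haplotype matrix must have ploidy columns per sample")
  if (!all(object@samples %in% names(object@populations)))
    msg <- c(msg, "every sample needs a population assignment")
  if (n > 0) {
    if (!all(object@sites$scaffold %in% object@scaffolds$name))
      msg <- c(msg, "site on unknown scaffold")
    if (any(object@sites$pos < 1)) msg <- c(msg, "positions are 1-based (>= 1)")
    ord <- order(match(object@sites$scaffold, object@scaffolds$name),
                 object@sites$pos)
    if (!identical(ord, seq_len(n)))
      msg <- c(msg, "sites must be sorted by scaffold then position")
    dup <- duplicated(object@sites[, c("scaffold", "pos")])
    if (any(dup)) msg <- c(msg, "positions must be strictly increasing per scaffold")
    vals <- unique(as.vector(object@haplotypes))
    if (!all(vals %in% c(0L, 1L)))
      msg <- c(msg, "haplotype alleles must be 0/1 (biallelic)")
  }
  if (length(object@qual) != n) msg <- c(msg, "qual must have one entry per site")
  if (!is.null(object@depth) &&
      (nrow(object@depth) != n || ncol(object@depth) != length(object@samples)))
    msg <- c(msg, "depth matrix must be sites x samples")
  if (length(msg)) msg else TRUE
})

#' CallableMask: sorted half-open callable intervals per scaffold
#'
#' Intervals use BED conventions: 0-based, half-open \code{[start, end)}.
#'
#' @slot intervals data.frame with columns \code{scaffold}, \code{start},
#'   \code{end}, sorted and non-overlapping within scaffold.
#' @slot scaffolds data.frame with columns \code{name}, \code{length}.
#' @export
setClass("CallableMask",
  representation(intervals = "data.frame", scaffolds = "data.frame"))

setValidity("CallableMask", function(object) {
  msg <- character()
  iv <- object@intervals
  if (nrow(iv) > 0) {
    if (any(iv$end <= iv$start)) msg <- c(msg, "intervals need start < end")
    if (any(iv$start < 0)) msg <- c(msg, "intervals are 0-based (start >= 0)")
    if (!all(iv$scaffold %in% object@scaffolds$name))
      msg <- c(msg, "interval on unknown scaffold")
    for (sc in unique(iv$scaffold)) {
      sub <- iv[iv$scaffold == sc, , drop = FALSE]
      if (is.unsorted(sub$start, strictly = TRUE) ||
          any(sub$start[-1] < sub$end[-nrow(sub)]))
        msg <- c(msg, sprintf("intervals on %s must be sorted and non-overlapping", sc))
      len <- object@scaffolds$length[match(sc, object@scaffolds$name)]
      if (any(sub$end > len)) msg <- c(msg, sprintf("interval past end of %s", sc))
    }
  }
  if (length(msg)) msg else TRUE
})

#' DResult: Patterson's D for one trio
#'
#' @slot trio character of length 3: P1, P2, P3 sample names.
#' @slot outgroup character outgroup sample name.
#' @slot arrangement printed arrangement string, always
#'   \code{"(((P1,P2),P3),O)"} with D > 0 meaning excess P2-P3 sharing.
#' @slot nABBA,nBABA weighted pattern counts.
#' @slot D,SE,Z the statistic, weighted block-jackknife SE, and Z = D/SE.
#' @slot n_blocks number of jackknife blocks used.
#' @slot significant logical, |Z| > 3.
#' @export
setClass("DResult",
  representation(trio = "character", outgroup = "character",
                 arrangement = "character", nABBA = "numeric",
                 nBABA = "numeric", D = "numeric", SE = "numeric",
                 Z = "numeric", n_blocks = "integer", significant = "logical"))

setValidity("DResult", function(object) {
  if (!is.na(object@D) && (object@D < -1 - 1e-12 || object@D > 1 + 1e-12))
    return("D must lie in [-1, 1]")
  TRUE
})

#' TopologyCatalog: canonical rooted topologies for a fixed outgroup
#'
#' @slot ingroup character ingroup taxon names.
#' @slot outgroup character outgroup name.
#' @slot topologies character vector of canonical newick strings (ingroup
#'   rooted topologies), deterministic order.
#' @export
setClass("TopologyCatalog",
  representation(ingroup = "character", outgroup = "character",
                 topologies = "character"))

setValidity("TopologyCatalog", function(object) {
  k <- length(object@ingroup)
  expected <- if (k >= 2) prod(seq(2 * k - 3, 1, by = -2)) else 1
  if (length(object@topologies) != expected)
    return(sprintf("expected %d rooted topologies for %d ingroup taxa, got %d",
                   expected, k, length(object@topologies)))
  if (anyDuplicated(object@topologies)) return("canonical topologies must be unique")
  TRUE
})

#' SmcConfig: settings for the discretized coalescent HMM
#'
#' @slot bin_size bin width in bp.
#' @slot pattern atomic-interval pattern, e.g. \code{"4+25*2+4+6"}: a bare
#'   term \code{n} is one parameter group spanning n atomic intervals and
#'   \code{n*m} is n groups of m atomic intervals each.
#' @slot t_max upper bound on pairwise TMRCA, in coalescent units (2N0
#'   generations); the time grid is log-spaced on (0, t_max].
#' @slot theta_init,rho_init per-bin scaled mutation/recombination rates;
#'   \code{NA} means initialize from the observed heterozygous-bin fraction.
#' @slot rho_ratio when not NA, rho is initialized as
#'   \code{rho_ratio * theta} (use the recombination-to-mutation rate ratio
#'   r/mu when known); takes precedence over \code{rho_init}.
#' @slot max_iters,tol EM iteration cap and relative log-likelihood tolerance.
#' @slot mstep_maxit iteration cap for the inner M-step optimizer.
#' @slot min_bins floor on the number of non-missing bins required for a fit.
#' @export
setClass("SmcConfig",
  representation(bin_size = "integer", pattern = "character",
                 t_max = "numeric", theta_init = "numeric",
                 rho_init = "numeric", rho_ratio = "numeric",
                 max_iters = "integer",
                 tol = "numeric", mstep_maxit = "integer",
                 min_bins = "integer"))

setValidity("SmcConfig", function(object) {
  msg <- character()
  if (object@bin_size < 1) msg <- c(msg, "bin_size must be >= 1")
  if (object@t_max <= 0) msg <- c(msg, "t_max must be > 0")
  p <- tryCatch(parseIntervalPattern(object@pattern), error = function(e) NULL)
  if (is.null(p)) msg <- c(msg, "interval pattern does not parse")
  else if (p$n_atomic < 2) msg <- c(msg, "pattern must give >= 2 atomic intervals")
  if (length(msg)) msg else TRUE
})

#' BinSequence: per-scaffold observation symbols for the SMC HMM
#'
#' Symbols are integers: 0 = no heterozygote observed in the bin, 1 = at
#' least one heterozygote, 2 = missing (more than half the bin outside the
#' callable mask).
#'
#' @slot sequences named list of integer vectors, one per scaffold.
#' @slot bin_size bin width in bp.
#' @export
setClass("BinSequence",
  representation(sequences = "list", bin_size = "integer"))

setValidity("BinSequence", function(object) {
  for (s in object@sequences) {
    if (!all(s %in% c(0L, 1L, 2L)))
      return("bin symbols must be 0 (no-het), 1 (het) or 2 (missing)")
  }
  if (object@bin_size < 1) return("bin_size must be >= 1")
  TRUE
})

#' SmcTrajectory: fitted coalescence intensities on a discretized time grid
#'
#' @slot boundaries atomic interval boundaries in coalescent units, strictly
#'   increasing from 0 to t_max (length n_atomic + 1; the final atomic
#'   interval is open-ended for the prior but reported up to t_max).
#' @slot groups integer mapping atomic interval -> parameter group.
#' @slot lambda per-group coalescence intensity (relative rate; Ne = N0 /
#'   lambda).
#' @slot theta,rho fitted per-bin scaled rates.
#' @slot bin_size bin width in bp used for the fit.
#' @slot loglik per-iteration total log-likelihood trace.
#' @slot scaled data.frame with per-group \code{left_years},
#'   \code{right_years}, \code{ne} once \code{\link{scaleTrajectory}} has
#'   been applied (empty before).
#' @export
setClass("SmcTrajectory",
  representation(boundaries = "numeric", groups = "integer",
                 lambda = "numeric", theta = "numeric", rho = "numeric",
                 bin_size = "integer", loglik = "numeric",
                 scaled = "data.frame"))

setValidity("SmcTrajectory", function(object) {
  msg <- character()
  b <- object@boundaries
  if (is.unsorted(b, strictly = TRUE) || b[1] != 0)
    msg <- c(msg, "boundaries must increase strictly from 0")
  if (length(object@groups) != length(b) - 1)
    msg <- c(msg, "one group id per atomic interval required")
  if (any(object@lambda <= 0)) msg <- c(msg, "lambda must be > 0")
  if (max(object@groups) != length(object@lambda))
    msg <- c(msg, "lambda must have one entry per parameter group")
  if (length(msg)) msg else TRUE
})

#' PseudoHaploid: one randomly sampled allele per callable position
#'
#' Sparse representation: only variant positions are stored; all other
#' callable positions implicitly carry the reference allele.
#'
#' @slot sample source sample name.
#' @slot scaffolds data.frame with columns \code{name}, \code{length}.
#' @slot sites data.frame with columns \code{scaffold}, \code{pos},
#'   \code{allele} (0 = REF, 1 = ALT) for called variant positions, and
#'   missing positions listed with \code{allele = NA}.
#' @slot seed seed used for the random draws.
#' @export
setClass("PseudoHaploid",
  representation(sample = "character", scaffolds = "data.frame",
                 sites = "data.frame", seed = "integer"))

#' GeneFlowBracket: grid bracketing of the end of gene flow
#'
#' @slot pair the two species compared.
#' @slot grid_times grid divergence times evaluated (Ma).
#' @slot lower,upper bracketing times in Ma (\code{-Inf}/\code{Inf} when the
#'   empirical curve falls outside the grid; see \code{unbounded}).
#' @slot unbounded character flags, subset of \code{c("below", "above")}.
#' @slot plateau_ne pre-divergence plateau Ne used.
#' @slot window_years range of times (years) over which curves were compared.
#' @slot grid_monotone logical; whether grid curves were ordered in T over
#'   the comparison window.
#' @export
setClass("GeneFlowBracket",
  representation(pair = "character", grid_times = "numeric",
                 lower = "numeric", upper = "numeric",
                 unbounded = "character", plateau_ne = "numeric",
                 window_years = "numeric", grid_monotone = "logical"))

setValidity("GeneFlowBracket", function(object) {
  if (is.finite(object@lower) && is.finite(object@upper) &&
      object@lower >= object@upper)
    return("bracket lower bound must be below upper bound")
  TRUE
})

#' DatedTree: calibrated ultrametric tree with node ages in Ma
#'
#' @slot tree rooted ultrametric \code{phylo}; branch lengths in Ma.
#' @slot ages numeric node ages in Ma, named by internal node number.
#' @slot calibration list with \code{taxa} (clade used) and \code{age} (Ma).
#' @export
setClass("DatedTree",
  representation(tree = "ANY", ages = "numeric", calibration = "list"))

setValidity("DatedTree", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  TRUE
})

## ---- show methods ----

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel:", nrow(object@populations), "populations,",
      nrow(object@splits), "splits,", nrow(object@migrations),
      "migration epochs,", nrow(object@pulses), "pulses\n")
  cat("  mu =", object@mu, " r =", object@r, "\n")
  cat("  populations:", paste(object@populations$name, collapse = ", "), "\n")
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object@sites), "biallelic sites,",
      length(object@samples), "samples (ploidy", object@ploidy, "),",
      nrow(object@scaffolds), "scaffolds,",
      if (object@phased) "phased" else "unphased", "\n")
})

setMethod("show", "CallableMask", function(object) {
  cat("CallableMask:", nrow(object@intervals), "intervals,",
      format(callableSpan(object), big.mark = ","), "callable bp on",
      nrow(object@scaffolds), "scaffolds\n")
})

setMethod("show", "DResult", function(object) {
  cat(sprintf("DResult %s: D = %.4f, SE = %.4f, Z = %.2f (%s, %d blocks)\n",
              object@arrangement, object@D, object@SE, object@Z,
              if (object@significant) "|Z| > 3" else "n.s.", object@n_blocks))
})

setMethod("show", "TopologyCatalog", function(object) {
  cat("TopologyCatalog:", length(object@topologies),
      "rooted topologies on {", paste(object@ingroup, collapse = ", "),
      "} with outgroup", object@outgroup, "\n")
})

setMethod("show", "SmcTrajectory", function(object) {
  cat("SmcTrajectory:", length(object@lambda), "parameter groups over",
      length(object@boundaries) - 1, "atomic intervals; theta =",
      signif(object@theta, 4), "\n")
  if (nrow(object@scaled) > 0)
    cat("  scaled: Ne", paste(signif(range(object@scaled$ne), 3), collapse = " - "),
        "over", paste(signif(range(c(object@scaled$left_years,
                                     object@scaled$right_years)), 3),
                      collapse = " - "), "years\n")
})

setMethod("show", "GeneFlowBracket", function(object) {
  cat(sprintf("GeneFlowBracket %s-%s: [%s, %s] Ma (plateau Ne %.0f)%s\n",
              object@pair[1], object@pair[2],
              format(object@lower), format(object@upper), object@plateau_ne,
              if (length(object@unbounded))
                paste0(" [unbounded ", paste(object@unbounded, collapse = ","), "]")
              else ""))
})

## ---- accessors ----

#' @rdname GenotypeTable-class
#' @param object,x a \linkS4class{GenotypeTable} (or other container).
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' @rdname GenotypeTable-class
#' @export
setMethod("sampleNames", "GenotypeTable", function(object) object@samples)

#' @rdname GenotypeTable-class
#' @export
setGeneric("samplePopulations", function(object) standardGeneric("samplePopulations"))

#' @rdname GenotypeTable-class
#' @export
setMethod("samplePopulations", "GenotypeTable", function(object) object@populations)

#' @rdname GenotypeTable-class
#' @export
setGeneric("siteTable", function(object) standardGeneric("siteTable"))

#' @rdname GenotypeTable-class
#' @export
setMethod("siteTable", "GenotypeTable", function(object) object@sites)

#' @rdname GenotypeTable-class
#' @export
setGeneric("haplotypeMatrix", function(object) standardGeneric("haplotypeMatrix"))

#' @rdname GenotypeTable-class
#' @export
setMethod("haplotypeMatrix", "GenotypeTable", function(object) object@haplotypes)

#' @rdname GenotypeTable-class
#' @export
setGeneric("scaffoldTable", function(object) standardGeneric("scaffoldTable"))

#' @rdname GenotypeTable-class
#' @export
setMethod("scaffoldTable", "GenotypeTable", function(object) object@scaffolds)

#' @rdname CallableMask-class
#' @param object a \linkS4class{CallableMask}.
#' @export
setMethod("scaffoldTable", "CallableMask", function(object) object@scaffolds)

#' @rdname CallableMask-class
#' @export
setGeneric("maskIntervals", function(object) standardGeneric("maskIntervals"))

#' @rdname CallableMask-class
#' @export
setMethod("maskIntervals", "CallableMask", function(object) object@intervals)

#' Total callable span of a mask in bp
#' @param object a \linkS4class{CallableMask}.
#' @export
setGeneric("callableSpan", function(object) standardGeneric("callableSpan"))

#' @rdname callableSpan
#' @export
setMethod("callableSpan", "CallableMask", function(object) {
  if (nrow(object@intervals) == 0) return(0)
  sum(object@intervals$end - object@intervals$start)
})

#' @rdname TopologyCatalog-class
#' @param object a \linkS4class{TopologyCatalog}.
#' @export
setGeneric("topologyStrings", function(object) standardGeneric("topologyStrings"))

#' @rdname TopologyCatalog-class
#' @export
setMethod("topologyStrings", "TopologyCatalog", function(object) object@topologies)

#' Haplotype columns belonging to one sample
#' @param object a \linkS4class{GenotypeTable}.
#' @param sample sample name.
#' @return integer column indices into \code{haplotypeMatrix(object)}.
#' @export
sampleHaplotypeColumns <- function(object, sample) {
  i <- match(sample, object@samples)
  if (is.na(i)) stop("unknown sample: ", sample)
  if (object@ploidy == 1L) i else c(2L * i - 1L, 2L * i)
}
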