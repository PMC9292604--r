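## Windowed diversity statistics, identity-by-state distances and the
## distance-based strict-clock dating surrogate.

#' Windowed heterozygosity for one sample
#'
#' Counts heterozygous genotypes per window at sites passing the depth
#' floor, reported both per window length (the headline figure, matching
#' the convention of dividing by window size) and per callable bp (which
#' corrects for mask gaps and partial trailing windows).
#'
#' @param g a diploid \linkS4class{GenotypeTable}.
#' @param sample sample name.
#' @param mask a \linkS4class{CallableMask}.
#' @param windows window data.frame from \code{\link{makeWindows}}.
#' @param min_depth minimum per-sample depth for a site to contribute
#'   (ignored when the table carries no depth information).
#' @return data.frame: window columns plus \code{n_callable}, \code{n_het},
#'   \code{het_per_bp}, \code{het_per_callable}.
#' @export
windowedHeterozygosity <- function(g, sample, mask, windows, min_depth = 5) {
  stopifnot(is(g, "GenotypeTable"), g@ploidy == 2L)
  if (!sample %in% g@samples) stop("sample absent: ", sample)
  cols <- sampleHaplotypeColumns(g, sample)
  het <- g@haplotypes[, cols[1]] != g@haplotypes[, cols[2]]
  if (!is.null(g@depth)) {
    dp <- g@depth[, match(sample, g@samples)]
    het <- het & !is.na(dp) & dp >= min_depth
  }
  sites <- g@sites
  maskGr <- maskToGRanges(mask)
  winGr <- GenomicRanges::GRanges(
    windows$scaffold,
    IRanges::IRanges(start = windows$start + 1, end = windows$end))
  hits <- GenomicRanges::findOverlaps(winGr, maskGr)
  n_callable <- rep(0, nrow(windows))
  if (length(hits) > 0) {
    pieces <- GenomicRanges::pintersect(winGr[S4Vectors::queryHits(hits)],
                                        maskGr[S4Vectors::subjectHits(hits)])
    w <- tapply(GenomicRanges::width(pieces), S4Vectors::queryHits(hits), sum)
    n_callable[as.integer(names(w))] <- w
  }

  out <- windows
  out$n_callable <- n_callable
  out$n_sites <- 0L
  out$n_het <- 0L
  if (nrow(sites) > 0) {
    wIdx <- rep(NA_integer_, nrow(sites))
    for (sc in unique(windows$scaffold)) {
      sIdx <- which(sites$scaffold == sc)
      wRows <- which(windows$scaffold == sc)
      if (!length(sIdx) || !length(wRows)) next
      j <- findInterval(sites$pos[sIdx] - 1, windows$start[wRows])
      ok <- j >= 1 & sites$pos[sIdx] <= windows$end[wRows][pmax(j, 1)]
      wIdx[sIdx[ok]] <- wRows[j[ok]]
    }
    tab <- table(wIdx)
    out$n_sites[as.integer(names(tab))] <- as.integer(tab)
    tabh <- table(wIdx[het])
    out$n_het[as.integer(names(tabh))] <- as.integer(tabh)
  }
  out$het_per_bp <- out$n_het / (out$end - out$start)
  out$het_per_callable <- ifelse(out$n_callable > 0,
                                 out$n_het / out$n_callable, NA_real_)
  out
}

#' Transition / transversion ratio over sites
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#'
#' @param g a \linkS4class{GenotypeTable}.
#' @return The ratio nTs / nTv.
#' @export
tstvRatio <- function(g) {
  s <- g@sites
  if (nrow(s) == 0) stop("no sites")
  pair <- paste(pmin(s$ref, s$alt), pmax(s$ref, s$alt))
  ts <- pair %in% c("A G", "C T")
  nTv <- sum(!ts)
  if (nTv == 0) stop("undefined Ts/Tv: no transversions observed")
  sum(ts) / nTv
}

#' Identity-by-state distance matrix under a consensus approach
#'
#' Each sample is reduced to its consensus (majority) allele per site, with
#' heterozygote ties broken by a seeded fair coin; the distance between two
#' samples is the proportion of sites where their consensus alleles differ.
#'
#' @param g a \linkS4class{GenotypeTable} with at least two samples.
#' @param seed integer seed for tie-breaking.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = samples.
#' @export
ibsDistanceMatrix <- function(g, seed) {
  stopifnot(is(g, "GenotypeTable"))
  if (length(g@samples) < 2) stop("need >= 2 samples")
  n <- nrow(g@sites)
  if (n == 0) stop("no overlapping called sites")
  k <- length(g@samples)
  cons <- matrix(0L, nrow = n, ncol = k, dimnames = list(NULL, g@samples))
  withSeed(seed, {
    for (i in seq_len(k)) {
      if (g@ploidy == 1L) {
        cons[, i] <- g@haplotypes[, i]
      } else {
        cnt <- g@haplotypes[, 2L * i - 1L] + g@haplotypes[, 2L * i]
        cons[, i] <- ifelse(cnt == 2L, 1L,
                            ifelse(cnt == 0L, 0L,
                                   as.integer(stats::runif(n) < 0.5)))
      }
    }
  })
  d <- matrix(0, k, k, dimnames = list(g@samples, g@samples))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- mean(cons[, i] != cons[, j])
  }
  d
}

#' Generation time from life-history parameters
#'
#' Computed as age to maturity plus half the reproductive longevity.
#'
#' @param age_to_maturity years to sexual maturity.
#' @param reproductive_longevity reproductive lifespan in years.
#' @return Generation time in years.
#' @examples
#' generationTime(20, 8) # 24
#' @export
generationTime <- function(age_to_maturity, reproductive_longevity) {
  if (age_to_maturity < 0 || reproductive_longevity < 0)
    stop("life-history parameters must be >= 0")
  age_to_maturity + reproductive_longevity / 2
}

#' Jukes-Cantor corrected distance between two haplotypes
#'
#' The raw mismatch fraction p over the compared sites (differences at the
#' listed variant sites divided by \code{total_sites}, which defaults to the
#' variant-site count but should be the full compared sequence length for
#' per-bp distances) is corrected as \eqn{-\frac{3}{4}\log(1 - 4p/3)}.
#'
#' @param a,b equal-length 0/1 allele vectors.
#' @param total_sites number of compared sites (denominator for p).
#' @return Substitutions per site.
#' @export
jcDistance <- function(a, b, total_sites = length(a)) {
  stopifnot(length(a) == length(b), total_sites >= length(a))
  p <- sum(a != b) / total_sites
  jcCorrect(p)
}

#' @rdname jcDistance
#' @param p raw mismatch proportion.
#' @export
jcCorrect <- function(p) {
  if (any(p >= 0.75)) stop("Jukes-Cantor distance saturates at p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Mean between-population JC distances
#'
#' For every population pair, the average per-bp mismatch fraction over all
#' cross-population haplotype pairs (denominator \code{total_bp}), JC
#' corrected. Input sites are assumed biallelic with identical alleles at
#' all unlisted positions.
#'
#' @param g a \linkS4class{GenotypeTable}.
#' @param total_bp compared sequence length per haplotype (defaults to the
#'   summed scaffold lengths).
#' @return Symmetric matrix over populations.
#' @export
populationDistanceMatrix <- function(g, total_bp = sum(g@scaffolds$length)) {
  pops <- unique(g@populations[g@samples])
  k <- length(pops)
  hapPop <- rep(g@populations[g@samples], each = g@ploidy)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ci <- which(hapPop == pops[i]); cj <- which(hapPop == pops[j])
    diffs <- vapply(ci, function(a) vapply(cj, function(b)
      sum(g@haplotypes[, a] != g@haplotypes[, b]), numeric(1)),
      numeric(length(cj)))
    p <- mean(diffs) / total_bp
    d[i, j] <- d[j, i] <- jcCorrect(p)
  }
  d
}

#' UPGMA tree with a single linear age calibration
#'
#' Builds a UPGMA tree from a distance matrix and rescales all node heights
#' linearly so that the node defined by \code{calibration$taxa} has exactly
#' age \code{calibration$age} (Ma). Errors if the calibration taxa do not
#' form a clade of the UPGMA tree (no silent rescaling against a different
#' node).
#'
#' @param dist symmetric non-negative distance matrix with taxon dimnames.
#' @param calibration list with \code{taxa} (character) and \code{age} (Ma).
#' @return A \linkS4class{DatedTree}.
#' @export
upgmaCalibratedAges <- function(dist, calibration) {
  stopifnot(is.matrix(dist), isSymmetric(unname(dist)),
            all(dist >= 0), is.list(calibration))
  tree <- phangorn::upgma(stats::as.dist(dist))
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  rootHeight <- max(depths[seq_len(ntip)])
  heights <- rootHeight - depths # 0 at tips, height at internal nodes
  taxa <- calibration$taxa
  if (!all(taxa %in% tree$tip.label)) stop("calibration taxa not in tree")
  node <- if (length(taxa) == 1) match(taxa, tree$tip.label)
          else ape::getMRCA(tree, taxa)
  cladeTips <- tree$tip.label[unlist(phangorn::Descendants(tree, node,
                                                           "tips"))]
  if (!setequal(cladeTips, taxa))
    stop("calibration clade not recovered by UPGMA; refusing to rescale")
  h <- heights[node]
  if (h <= 0) stop("calibration node has zero height")
  f <- calibration$age / h
  tree$edge.length <- tree$edge.length * f
  ages <- heights[(ntip + 1):length(heights)] * f
  names(ages) <- as.character((ntip + 1):length(heights))
  new("DatedTree", tree = tree, ages = ages,
      calibration = list(taxa = taxa, age = calibration$age, node = node))
}

#' Age of the MRCA of a set of taxa in a dated tree
#' @param dated a \linkS4class{DatedTree}.
#' @param taxa character tip labels.
#' @return Age in Ma.
#' @export
datedNodeAge <- function(dated, taxa) {
  node <- if (length(taxa) == 1) match(taxa, dated@tree$tip.label)
          else ape::getMRCA(dated@tree, taxa)
  if (is.null(node) || is.na(node)) stop("taxa not found")
  if (node <= length(dated@tree$tip.label)) return(0)
  unname(dated@ages[as.character(node)])
}

#' Write per-window statistics as TSV
#' @param stats data.frame of window statistics.
#' @param path output path.
#' @param header_extra optional comment lines (prefixed with #).
#' @export
writeWindowStats <- function(stats, path, header_extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_extra)) writeLines(paste0("# ", header_extra), con)
  utils::write.table(stats, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
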