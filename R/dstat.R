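## Patterson's D (ABBA-BABA) from four single genomes, with a weighted
## delete-one block jackknife over large physical blocks and a scan over
## every trio consistent with a species tree.
##
## Arrangement convention, fixed and printed on every result:
## (((P1,P2),P3),O) with the derived state B defined relative to the
## outgroup allele; D = (nABBA - nBABA) / (nABBA + nBABA) > 0 means excess
## derived-allele sharing between P2 and P3.

#' Count ABBA / BABA patterns per genomic block
#'
#' One allele is sampled uniformly per diploid per site (seeded), matching
#' the single-read counting mode of genotype-free D estimators; sites where
#' the sampled outgroup allele matches neither pattern requirement are
#' ignored. Blocks are consecutive physical spans of \code{block_size} bp
#' per scaffold. Alternatively \code{weighted = TRUE} uses within-individual
#' allele frequencies instead of sampling.
#'
#' @param g a diploid \linkS4class{GenotypeTable}.
#' @param trio character of length 3: P1, P2, P3 sample names.
#' @param outgroup outgroup sample name.
#' @param seed integer seed for allele sampling.
#' @param block_size jackknife block span in bp.
#' @param weighted logical; use allele-frequency weights instead of sampled
#'   alleles.
#' @return data.frame with one row per block: \code{scaffold}, \code{start},
#'   \code{nABBA}, \code{nBABA}, \code{n_informative}.
#' @export
countPatterns <- function(g, trio, outgroup, seed, block_size = 5e6,
                          weighted = FALSE) {
  stopifnot(is(g, "GenotypeTable"), length(trio) == 3)
  ids <- c(trio, outgroup)
  if (anyDuplicated(ids)) stop("trio and outgroup must be distinct samples")
  if (weighted) {
    a <- sapply(ids, function(s) {
      cols <- sampleHaplotypeColumns(g, s)
      if (g@ploidy == 1L) g@haplotypes[, cols]
      else (g@haplotypes[, cols[1]] + g@haplotypes[, cols[2]]) / 2
    })
  } else {
    # draw one haplotype per diploid per site; choosing the haplotype (not
    # the allele value) keeps the draw invariant to REF/ALT relabelling
    a <- withSeed(deriveSeed(seed, paste(ids, collapse = ",")), {
      sapply(ids, function(s) {
        cols <- sampleHaplotypeColumns(g, s)
        if (g@ploidy == 1L) return(g@haplotypes[, cols])
        pick <- stats::runif(nrow(g@haplotypes)) < 0.5
        ifelse(pick, g@haplotypes[, cols[1]], g@haplotypes[, cols[2]])
      })
    })
  }
  # both polarizations of the classical frequency estimator; for sampled
  # 0/1 alleles this reduces to indicator counting of (A,B,B,A) / (B,A,B,A)
  # patterns with the derived state defined by the outgroup allele
  p1 <- a[, 1]; p2 <- a[, 2]; p3 <- a[, 3]; p4 <- a[, 4]
  abba <- (1 - p1) * p2 * p3 * (1 - p4) + p1 * (1 - p2) * (1 - p3) * p4
  baba <- p1 * (1 - p2) * p3 * (1 - p4) + (1 - p1) * p2 * (1 - p3) * p4

  blockId <- paste(g@sites$scaffold, floor((g@sites$pos - 1) / block_size))
  blocks <- unique(blockId)
  out <- data.frame(
    block = blocks,
    nABBA = as.numeric(tapply(abba, factor(blockId, blocks), sum)),
    nBABA = as.numeric(tapply(baba, factor(blockId, blocks), sum)),
    stringsAsFactors = FALSE)
  out$n_informative <- out$nABBA + out$nBABA
  out
}

#' Patterson's D from pattern counts
#' @param nABBA,nBABA pattern counts (weighted or integer).
#' @return D = (nABBA - nBABA) / (nABBA + nBABA).
#' @export
dStatistic <- function(nABBA, nBABA) {
  tot <- nABBA + nBABA
  if (tot <= 0) stop("D undefined: no informative sites")
  (nABBA - nBABA) / tot
}

#' Weighted delete-one block jackknife for D
#'
#' Blocks are weighted by their informative-site counts; the standard error
#' uses the weighted delete-one jackknife for unequal block sizes (Busing's
#' formulation), and Z = D / SE. Blocks with fewer than \code{min_sites}
#' informative sites are dropped first.
#'
#' @param blocks data.frame from \code{\link{countPatterns}}.
#' @param min_sites minimum informative sites for a block to enter.
#' @return list with \code{D}, \code{SE}, \code{Z}, \code{n_blocks},
#'   \code{nABBA}, \code{nBABA}, and \code{degenerate} (TRUE when all
#'   blocks agree exactly, forcing SE = 0).
#' @export
blockJackknife <- function(blocks, min_sites = 100) {
  b <- blocks[blocks$n_informative >= min_sites, , drop = FALSE]
  gN <- nrow(b)
  if (gN < 2) stop("need >= 2 blocks with informative sites")
  totA <- sum(b$nABBA); totB <- sum(b$nBABA)
  D <- dStatistic(totA, totB)
  n <- totA + totB
  m <- b$n_informative
  thetaMinus <- vapply(seq_len(gN), function(j)
    dStatistic(totA - b$nABBA[j], totB - b$nBABA[j]), numeric(1))
  h <- n / m
  # weighted jackknife estimate and variance (Busing et al. 1999)
  thetaJ <- gN * D - sum((1 - m / n) * thetaMinus)
  tau <- h * D - (h - 1) * thetaMinus
  v <- sum((tau - thetaJ)^2 / (h - 1)) / gN
  SE <- sqrt(v)
  degenerate <- SE == 0
  Z <- if (SE > 0) D / SE else if (D == 0) 0 else NaN
  list(D = D, SE = SE, Z = Z, n_blocks = gN, nABBA = totA, nBABA = totB,
       degenerate = degenerate)
}

#' D statistic with jackknife for one trio
#'
#' @inheritParams countPatterns
#' @param min_sites minimum informative sites per jackknife block.
#' @return A \linkS4class{DResult}.
#' @export
dstatTrio <- function(g, trio, outgroup, seed, block_size = 5e6,
                      min_sites = 100, weighted = FALSE) {
  counts <- countPatterns(g, trio, outgroup, seed, block_size, weighted)
  jk <- blockJackknife(counts, min_sites)
  new("DResult", trio = trio, outgroup = outgroup,
      arrangement = sprintf("(((%s,%s),%s),%s)", trio[1], trio[2], trio[3],
                            outgroup),
      nABBA = jk$nABBA, nBABA = jk$nBABA, D = jk$D, SE = jk$SE, Z = jk$Z,
      n_blocks = as.integer(jk$n_blocks),
      significant = is.finite(jk$Z) && abs(jk$Z) > 3)
}

# Trios (P1,P2,P3) consistent with a rooted species tree: (P1,P2) must be a
# cherry or nested pair relative to P3, i.e. MRCA(P1,P2) is a strict
# descendant of MRCA(P1,P2,P3). The outgroup is excluded from the trio.
consistentTrios <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not on tree")
  if (!ape::is.binary(tree))
    stop("species tree must be fully resolved (binary)")
  ingroup <- setdiff(tree$tip.label, outgroup)
  trios <- list()
  for (pair in utils::combn(ingroup, 2, simplify = FALSE)) {
    mrca12 <- ape::getMRCA(tree, pair)
    for (p3 in setdiff(ingroup, pair)) {
      mrca123 <- ape::getMRCA(tree, c(pair, p3))
      if (mrca12 != mrca123)
        trios[[length(trios) + 1]] <- c(pair, p3)
    }
  }
  trios
}

#' Scan all species-tree-consistent trios
#'
#' Enumerates every trio (P1, P2, P3) whose pair (P1, P2) forms a cherry or
#' nested pair relative to P3 on the rooted species tree, and computes D
#' with jackknife for each, polarizing with the fixed outgroup.
#'
#' @param g a diploid \linkS4class{GenotypeTable} (one sample per species).
#' @param species_tree rooted binary \code{phylo} whose tip labels are
#'   sample names (including the outgroup).
#' @param outgroup outgroup sample name.
#' @inheritParams dstatTrio
#' @return data.frame with one row per trio: arrangement, counts, D, SE, Z,
#'   block count and significance at |Z| > 3.
#' @export
dstatScan <- function(g, species_tree, outgroup, seed, block_size = 5e6,
                      min_sites = 100, weighted = FALSE) {
  trios <- consistentTrios(species_tree, outgroup)
  rows <- lapply(trios, function(tr) {
    r <- dstatTrio(g, tr, outgroup, seed, block_size, min_sites, weighted)
    data.frame(P1 = tr[1], P2 = tr[2], P3 = tr[3], outgroup = outgroup,
               arrangement = r@arrangement, nABBA = r@nABBA,
               nBABA = r@nBABA, D = r@D, SE = r@SE, Z = r@Z,
               n_blocks = r@n_blocks, significant = r@significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
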