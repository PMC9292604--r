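## Exact topology weighting: enumerate all rooted ingroup topologies,
## infer a neighbor-joining tree per 50-SNP window, and weight each window
## by iterating over every combination of one haplotype per species.

# nested-list tree utilities for topology enumeration
.addTaxon <- function(tree, taxon) {
  out <- list(list(tree, taxon))
  if (is.list(tree)) {
    for (i in 1:2) {
      for (sub in .addTaxon(tree[[i]], taxon)) {
        t2 <- tree
        t2[[i]] <- sub
        out[[length(out) + 1]] <- t2
      }
    }
  }
  out
}

.canonicalString <- function(tree) {
  if (!is.list(tree)) return(tree)
  kids <- sort(vapply(tree, .canonicalString, character(1)))
  paste0("(", paste(kids, collapse = ","), ")")
}

#' Enumerate all rooted binary topologies on the ingroup
#'
#' With a fixed outgroup, the distinct window outcomes are the rooted binary
#' topologies of the ingroup taxa: (2k-3)!! of them for k taxa (15 for
#' four, as for five sea turtle species rooted with the leatherback). Each
#' topology is stored in canonical form (leaf sets sorted lexicographically
#' at every node), in deterministic (sorted) order.
#'
#' @param ingroup character ingroup taxon names.
#' @param outgroup outgroup name.
#' @return A \linkS4class{TopologyCatalog}.
#' @examples
#' length(topologyStrings(enumerateTopologies(c("OL", "LL", "HH", "GG"),
#'                                            "DC"))) # 15
#' @export
enumerateTopologies <- function(ingroup, outgroup) {
  if (anyDuplicated(c(ingroup, outgroup))) stop("duplicate taxon names")
  if (length(ingroup) < 2) stop("need >= 2 ingroup taxa")
  trees <- list(ingroup[1])
  for (taxon in ingroup[-1]) {
    trees <- unlist(lapply(trees, .addTaxon, taxon = taxon),
                    recursive = FALSE)
  }
  canon <- sort(unique(vapply(trees, .canonicalString, character(1))))
  new("TopologyCatalog", ingroup = sort(ingroup), outgroup = outgroup,
      topologies = canon)
}

#' Remove SNPs private to the outgroup
#'
#' Sites where every ingroup haplotype carries the same allele and only the
#' outgroup carries the alternative contribute no information about
#' ingroup relationships and are removed before windowing.
#'
#' @param g a \linkS4class{GenotypeTable}.
#' @param outgroup outgroup sample name.
#' @return Filtered \linkS4class{GenotypeTable}.
#' @export
removeOutgroupPrivateSnps <- function(g, outgroup) {
  if (!outgroup %in% g@samples) stop("outgroup sample absent")
  ogCols <- sampleHaplotypeColumns(g, outgroup)
  inCols <- setdiff(seq_len(ncol(g@haplotypes)),
                    unlist(lapply(outgroup, sampleHaplotypeColumns,
                                  object = g)))
  hin <- g@haplotypes[, inCols, drop = FALSE]
  mono <- matrixStats_rowAlleleRange(hin) == 0
  og <- g@haplotypes[, ogCols, drop = FALSE]
  ogDiffers <- rowSums(og != hin[, 1]) > 0
  drop <- mono & ogDiffers
  subsetSites(g, !drop)
}

matrixStats_rowAlleleRange <- function(m) {
  if (ncol(m) == 0) return(rep(0L, nrow(m)))
  mx <- m[, 1]; mn <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) {
    mx <- pmax(mx, m[, j]); mn <- pmin(mn, m[, j])
  }
  mx - mn
}

subsetSites <- function(g, keep) {
  out <- g
  out@sites <- g@sites[keep, , drop = FALSE]
  rownames(out@sites) <- NULL
  out@haplotypes <- g@haplotypes[keep, , drop = FALSE]
  out@qual <- g@qual[keep]
  if (!is.null(g@depth)) out@depth <- g@depth[keep, , drop = FALSE]
  out
}

#' Split sites into fixed-size SNP windows
#'
#' Consecutive non-overlapping blocks of \code{size_snps} SNPs per
#' scaffold; a terminal block is kept only with at least \code{min_snps}
#' SNPs. The window midpoint is the mean of its first and last SNP
#' positions.
#'
#' @param g a \linkS4class{GenotypeTable}.
#' @param size_snps SNPs per window.
#' @param min_snps minimum SNPs for a terminal window to be kept.
#' @return data.frame with \code{scaffold}, \code{first_idx},
#'   \code{last_idx} (row indices into the site table), \code{n_snps},
#'   \code{midpoint}.
#' @export
windowSnpBlocks <- function(g, size_snps = 50, min_snps = 45) {
  sites <- g@sites
  out <- list()
  for (sc in unique(sites$scaffold)) {
    idx <- which(sites$scaffold == sc)
    n <- length(idx)
    if (n == 0) next
    starts <- seq(1, n, by = size_snps)
    for (s in starts) {
      e <- min(s + size_snps - 1, n)
      if (e - s + 1 < min_snps) next
      out[[length(out) + 1]] <- data.frame(
        scaffold = sc, first_idx = idx[s], last_idx = idx[e],
        n_snps = e - s + 1,
        midpoint = (sites$pos[idx[s]] + sites$pos[idx[e]]) / 2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), first_idx = integer(),
                      last_idx = integer(), n_snps = integer(),
                      midpoint = numeric()))
  do.call(rbind, out)
}

#' Infer a window tree by neighbor joining
#'
#' Pairwise mismatch fractions over the window's SNPs, Jukes-Cantor
#' corrected (clamped just below the p = 3/4 saturation point), then
#' neighbor joining. Rows are processed in sorted label order so ties break
#' deterministically.
#'
#' @param hap integer 0/1 matrix, SNPs x haplotypes, with haplotype labels
#'   as column names.
#' @return Unrooted \code{phylo} on the haplotype labels.
#' @export
inferWindowTree <- function(hap) {
  if (ncol(hap) < 4) stop("need >= 4 haplotypes")
  if (nrow(hap) < 1) stop("need >= 1 variable site")
  hap <- hap[, order(colnames(hap)), drop = FALSE]
  k <- ncol(hap)
  p <- matrix(0, k, k, dimnames = list(colnames(hap), colnames(hap)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p[i, j] <- p[j, i] <- mean(hap[, i] != hap[, j])
  }
  if (all(p == 0)) stop("all haplotypes identical: star window")
  d <- jcCorrect(pmin(p, 0.7499))
  ape::nj(stats::as.dist(d))
}

# canonical string of a rooted phylo, with tip labels translated through
# labelMap (haplotype -> species) when given
phyloCanonical <- function(tree, labelMap = NULL) {
  ntip <- length(tree$tip.label)
  labels <- tree$tip.label
  if (!is.null(labelMap)) labels <- unname(labelMap[labels])
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(labels[node])
    sub <- sort(vapply(kids[[as.character(node)]], rec, character(1)))
    paste0("(", paste(sub, collapse = ","), ")")
  }
  rec(ntip + 1L)
}

#' Exact topology weights for one window tree
#'
#' Iterates over every combination of one haplotype per species (the
#' "complete" weighting: 2^5 = 32 combinations for five diploid species),
#' prunes the window tree to that combination, roots it with the outgroup
#' haplotype, and tallies which catalog topology the induced ingroup tree
#' matches. Weights are counts normalized to sum to one.
#'
#' @param tree unrooted \code{phylo} on haplotype labels.
#' @param taxon_map named character haplotype label -> species.
#' @param catalog a \linkS4class{TopologyCatalog}.
#' @return Numeric weight vector, one entry per catalog topology.
#' @export
weightWindow <- function(tree, taxon_map, catalog) {
  species <- c(catalog@ingroup, catalog@outgroup)
  hapBySpecies <- lapply(species, function(sp)
    names(taxon_map)[taxon_map == sp])
  names(hapBySpecies) <- species
  missing <- species[lengths(hapBySpecies) == 0]
  if (length(missing)) stop("no haplotype for species: ",
                            paste(missing, collapse = ", "))
  absent <- setdiff(unlist(hapBySpecies), tree$tip.label)
  if (length(absent)) stop("haplotype missing from tree: ",
                           paste(absent, collapse = ", "))
  combos <- expand.grid(hapBySpecies, stringsAsFactors = FALSE)
  counts <- stats::setNames(numeric(length(catalog@topologies)),
                            catalog@topologies)
  for (i in seq_len(nrow(combos))) {
    tips <- unlist(combos[i, ])
    sub <- ape::keep.tip(tree, tips)
    ogHap <- combos[i, catalog@outgroup]
    rooted <- ape::root(sub, outgroup = ogHap, resolve.root = TRUE)
    rooted <- ape::drop.tip(rooted, ogHap)
    key <- phyloCanonical(rooted, taxon_map)
    if (!key %in% names(counts))
      stop("window tree induced a topology outside the catalog: ", key)
    counts[key] <- counts[key] + 1
  }
  counts / sum(counts)
}

#' Topology weights across all SNP windows
#'
#' Full scan: remove outgroup-private SNPs, cut 50-SNP windows, infer a
#' neighbor-joining tree per window and weight it exactly over the catalog.
#' Windows whose haplotypes are all identical are skipped.
#'
#' @param g a \linkS4class{GenotypeTable}; species assignments come from
#'   \code{samplePopulations(g)}.
#' @param outgroup outgroup sample name.
#' @param size_snps,min_snps window size parameters
#'   (\code{\link{windowSnpBlocks}}).
#' @param catalog optional precomputed \linkS4class{TopologyCatalog}.
#' @return data.frame with \code{scaffold}, \code{midpoint}, \code{n_snps}
#'   and one weight column per catalog topology (\code{w1}, \code{w2},
#'   ...); the catalog is attached as attribute \code{"catalog"}.
#' @export
topologyWeightScan <- function(g, outgroup, size_snps = 50, min_snps = 45,
                               catalog = NULL) {
  species <- unique(g@populations[g@samples])
  ogSpecies <- g@populations[[outgroup]]
  if (is.null(catalog))
    catalog <- enumerateTopologies(setdiff(species, ogSpecies), ogSpecies)
  g2 <- removeOutgroupPrivateSnps(g, outgroup)
  blocks <- windowSnpBlocks(g2, size_snps, min_snps)
  hapNames <- hapLabels(g2)
  taxon_map <- stats::setNames(
    g2@populations[rep(g2@samples, each = g2@ploidy)], hapNames)
  keep <- integer()
  wmat <- matrix(NA_real_, nrow(blocks), length(catalog@topologies))
  for (i in seq_len(nrow(blocks))) {
    idx <- blocks$first_idx[i]:blocks$last_idx[i]
    hap <- g2@haplotypes[idx, , drop = FALSE]
    colnames(hap) <- hapNames
    tr <- tryCatch(inferWindowTree(hap), error = function(e) NULL)
    if (is.null(tr)) next
    wmat[i, ] <- weightWindow(tr, taxon_map, catalog)
    keep <- c(keep, i)
  }
  out <- data.frame(scaffold = blocks$scaffold[keep],
                    midpoint = blocks$midpoint[keep],
                    n_snps = blocks$n_snps[keep],
                    stringsAsFactors = FALSE)
  wmat <- wmat[keep, , drop = FALSE]
  colnames(wmat) <- paste0("w", seq_along(catalog@topologies))
  out <- cbind(out, as.data.frame(wmat))
  rownames(out) <- NULL
  attr(out, "catalog") <- catalog
  out
}

hapLabels <- function(g) {
  if (g@ploidy == 1L) g@samples
  else as.vector(t(outer(g@samples, 1:2, paste, sep = "_")))
}

#' Smooth topology weights along the genome
#'
#' Locally weighted (tricube) linear fit of each topology's weight against
#' the window midpoint, with a fixed physical bandwidth (span, default 1
#' Mb), evaluated at the midpoints themselves; fitted values are clipped to
#' [0, 1] and renormalized across topologies at every point.
#'
#' @param weights data.frame from \code{\link{topologyWeightScan}}.
#' @param span_bp full smoothing span in bp (points within span/2 of the
#'   evaluation point enter the local fit).
#' @return data.frame of the same shape with smoothed weight columns.
#' @export
smoothWeights <- function(weights, span_bp = 1e6) {
  wCols <- grep("^w[0-9]+$", names(weights), value = TRUE)
  out <- weights
  h <- span_bp / 2
  for (sc in unique(weights$scaffold)) {
    rows <- which(weights$scaffold == sc)
    if (length(rows) < 2) next
    x <- weights$midpoint[rows]
    for (cn in wCols) {
      y <- weights[[cn]][rows]
      fitted <- vapply(x, function(x0) {
        u <- (x - x0) / h
        wts <- (1 - pmin(abs(u), 1)^3)^3
        use <- wts > 0
        if (sum(use) == 1) return(y[use])
        xm <- x[use] - x0
        ws <- wts[use]
        sw <- sum(ws); sx <- sum(ws * xm); sxx <- sum(ws * xm^2)
        sy <- sum(ws * y[use]); sxy <- sum(ws * xm * y[use])
        det <- sw * sxx - sx^2
        if (abs(det) < 1e-12 * max(1, sxx)) return(sy / sw)
        (sxx * sy - sx * sxy) / det # local linear intercept at x0
      }, numeric(1))
      out[[cn]][rows] <- pmin(pmax(fitted, 0), 1)
    }
    tot <- rowSums(out[rows, wCols, drop = FALSE])
    out[rows, wCols] <- out[rows, wCols, drop = FALSE] / tot
  }
  out
}
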