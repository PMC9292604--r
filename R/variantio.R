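## VCF / BED input and output plus the hard-filter chain. Coordinate
## conventions: VCF positions are 1-based inclusive; masks and windows are
## 0-based half-open (BED).

#' Default hard-filter thresholds
#'
#' GATK-style hard filters for single-genome resequencing panels: drop any
#' record that is not a biallelic SNP, has QUAL < 60, FS > 60, QD < 2,
#' MQ < 40, MQRankSum < -20 or ReadPosRankSum < -8. An absent INFO
#' annotation never fires its criterion (the upstream caller only emits
#' rank-sum annotations at heterozygous sites).
#'
#' @return Named list of thresholds.
#' @export
hardFilterDefaults <- function() {
  list(qual_min = 60, fs_max = 60, qd_min = 2, mq_min = 40,
       mqranksum_min = -20, readposranksum_min = -8)
}

#' Apply hard filters to variant records
#'
#' @param records data.frame as returned by \code{\link{readVariantRecords}}
#'   (columns \code{scaffold}, \code{pos}, \code{ref}, \code{alt},
#'   \code{qual}, \code{FS}, \code{QD}, \code{MQ}, \code{MQRankSum},
#'   \code{ReadPosRankSum}, \code{is_indel}).
#' @param thresholds list as from \code{\link{hardFilterDefaults}}.
#' @return \code{records} with added logical \code{keep} and character
#'   \code{reasons} (semicolon-separated names of every violated criterion,
#'   empty when kept).
#' @export
hardFilterRecords <- function(records, thresholds = hardFilterDefaults()) {
  th <- utils::modifyList(hardFilterDefaults(), thresholds)
  n <- nrow(records)
  reasons <- vector("list", n)
  add <- function(idx, reason) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], reason)
  }
  multi <- grepl(",", records$alt)
  notSnp <- records$is_indel | multi | records$alt == "." |
    nchar(records$ref) != 1 | (nchar(records$alt) != 1 & !multi)
  add(notSnp, "not biallelic SNP")
  fire <- function(x, cmp) !is.na(x) & cmp(x)
  add(fire(records$qual, function(x) x < th$qual_min),
      sprintf("QUAL<%g", th$qual_min))
  add(fire(records$FS, function(x) x > th$fs_max),
      sprintf("FS>%g", th$fs_max))
  add(fire(records$QD, function(x) x < th$qd_min),
      sprintf("QD<%g", th$qd_min))
  add(fire(records$MQ, function(x) x < th$mq_min),
      sprintf("MQ<%g", th$mq_min))
  add(fire(records$MQRankSum, function(x) x < th$mqranksum_min),
      sprintf("MQRankSum<%g", th$mqranksum_min))
  add(fire(records$ReadPosRankSum, function(x) x < th$readposranksum_min),
      sprintf("ReadPosRankSum<%g", th$readposranksum_min))
  records$keep <- lengths(reasons) == 0
  records$reasons <- vapply(reasons, function(r)
    paste(r, collapse = ";"), character(1))
  records
}

#' Exclude regions of aberrant coverage
#'
#' Returns the maximal half-open intervals of a per-base depth profile where
#' depth exceeds \code{upper_k} times the mean or falls below the mean
#' divided by \code{lower_k} (the symmetric-on-log-scale reading of a
#' "within 4x of average coverage" rule; both bounds configurable).
#'
#' @param depth numeric per-base depths for one scaffold (base 0 first).
#' @param mean_depth average depth; computed from \code{depth} by default.
#' @param upper_k,lower_k multipliers for the upper and lower bounds.
#' @return data.frame with 0-based half-open \code{start}, \code{end}.
#' @export
coverageFilter <- function(depth, mean_depth = mean(depth), upper_k = 4,
                           lower_k = 4) {
  if (length(depth) == 0) stop("empty depth profile")
  stopifnot(mean_depth > 0)
  bad <- depth > upper_k * mean_depth | depth < mean_depth / lower_k
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Drop SNPs close to confidently called indels
#'
#' A SNP is removed when it lies within \code{radius} bp of any indel whose
#' QUAL exceeds \code{indel_qual_min}.
#'
#' @param records sorted variant record data.frame (see
#'   \code{\link{hardFilterRecords}}).
#' @param radius proximity radius in bp (distance \code{<= radius} drops).
#' @param indel_qual_min minimum indel QUAL (strictly greater) for the indel
#'   to count.
#' @return \code{records} restricted to SNP rows, with logical \code{keep}
#'   and \code{reasons} columns reflecting indel proximity only.
#' @export
indelProximityFilter <- function(records, radius = 5, indel_qual_min = 60) {
  ord <- order(match(records$scaffold, unique(records$scaffold)), records$pos)
  if (!identical(ord, seq_len(nrow(records))))
    stop("records must be sorted by scaffold then position")
  snps <- records[!records$is_indel, , drop = FALSE]
  indels <- records[records$is_indel & !is.na(records$qual) &
                      records$qual > indel_qual_min, , drop = FALSE]
  keep <- rep(TRUE, nrow(snps))
  for (sc in unique(snps$scaffold)) {
    sIdx <- which(snps$scaffold == sc)
    ip <- indels$pos[indels$scaffold == sc]
    if (length(ip) == 0) next
    sp <- snps$pos[sIdx]
    near <- vapply(sp, function(p) any(abs(p - ip) <= radius), logical(1))
    keep[sIdx][near] <- FALSE
  }
  snps$keep <- keep
  snps$reasons <- ifelse(keep, "", "indel_proximity")
  rownames(snps) <- NULL
  snps
}

#' Run the full site-filter chain
#'
#' Hard filters plus indel proximity, annotating rather than deleting:
#' every record receives a \code{FILTER} string (\code{"PASS"} or the
#' semicolon-joined reasons). With \code{mode = "drop"} only passing
#' biallelic SNPs are returned. The kept set is independent of the order
#' the criteria are applied in.
#'
#' @inheritParams hardFilterRecords
#' @inheritParams indelProximityFilter
#' @param mode \code{"annotate"} (default) or \code{"drop"}.
#' @return Annotated (or filtered) record data.frame.
#' @export
applyFilterChain <- function(records, thresholds = hardFilterDefaults(),
                             radius = 5, indel_qual_min = 60,
                             mode = c("annotate", "drop")) {
  mode <- match.arg(mode)
  hard <- hardFilterRecords(records, thresholds)
  prox <- indelProximityFilter(records, radius, indel_qual_min)
  proxKey <- paste(prox$scaffold, prox$pos)
  key <- paste(hard$scaffold, hard$pos)
  m <- match(key, proxKey)
  proxDrop <- !is.na(m) & !prox$keep[ifelse(is.na(m), 1L, m)]
  reasons <- hard$reasons
  reasons <- ifelse(proxDrop,
                    ifelse(nzchar(reasons),
                           paste(reasons, "indel_proximity", sep = ";"),
                           "indel_proximity"),
                    reasons)
  hard$keep <- hard$keep & !proxDrop
  hard$reasons <- reasons
  hard$FILTER <- ifelse(hard$keep, "PASS", reasons)
  if (mode == "drop") hard[hard$keep, , drop = FALSE] else hard
}

#' Intersect callable masks
#'
#' Exact interval intersection across any number of masks; the result's
#' callable span can never exceed the smallest input span. Associative and
#' commutative.
#'
#' @param masks list of \linkS4class{CallableMask} objects.
#' @return A \linkS4class{CallableMask}.
#' @export
intersectMasks <- function(masks) {
  stopifnot(length(masks) >= 1)
  if (length(masks) == 1) return(masks[[1]])
  gr <- Reduce(function(a, b) GenomicRanges::intersect(a, b),
               lapply(masks, maskToGRanges))
  grangesToMask(gr, masks[[1]]@scaffolds)
}

#' @rdname CallableMask-class
#' @param mask a \linkS4class{CallableMask}.
#' @export
maskToGRanges <- function(mask) {
  iv <- mask@intervals
  GenomicRanges::GRanges(
    seqnames = iv$scaffold,
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end))
}

#' @rdname CallableMask-class
#' @param gr a GRanges of callable intervals (1-based).
#' @param scaffolds scaffold data.frame (\code{name}, \code{length}).
#' @export
grangesToMask <- function(gr, scaffolds) {
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  iv <- data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  iv <- iv[order(match(iv$scaffold, scaffolds$name), iv$start), ,
           drop = FALSE]
  rownames(iv) <- NULL
  new("CallableMask", intervals = iv, scaffolds = scaffolds)
}

#' Tile scaffolds into windows
#'
#' Non-overlapping windows \code{[0, size)}, \code{[size, 2 size)}, ...;
#' scaffolds shorter than \code{min_scaffold} are skipped entirely (the
#' recommended practice for coalescent-HMM input), and a trailing partial
#' window is kept but flagged so downstream statistics can normalize by
#' callable span instead of window size.
#'
#' @param layout a \linkS4class{GenomeLayout}, \linkS4class{CallableMask} or
#'   scaffold data.frame with \code{name}, \code{length}.
#' @param size window size in bp.
#' @param min_scaffold minimum scaffold length to include (default 0).
#' @return data.frame with \code{scaffold}, \code{start}, \code{end}
#'   (0-based half-open) and logical \code{partial}.
#' @export
makeWindows <- function(layout, size, min_scaffold = 0) {
  stopifnot(size > 0)
  sc <- if (is(layout, "GenomeLayout") || is(layout, "CallableMask"))
    scaffoldTable(layout) else layout
  out <- lapply(seq_len(nrow(sc)), function(i) {
    len <- sc$length[i]
    if (len < min_scaffold) return(NULL)
    starts <- seq(0, len - 1, by = size)
    ends <- pmin(starts + size, len)
    data.frame(scaffold = sc$name[i], start = starts, end = ends,
               partial = ends - starts < size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), partial = logical())
  rownames(out) <- NULL
  out
}

## ---- VCF ----

#' Write a GenotypeTable as VCF 4.2
#'
#' Positions 1-based; GT separated by \code{"|"} when phased and \code{"/"}
#' when unphased. Output is deterministic for a given table.
#'
#' @param g a \linkS4class{GenotypeTable}.
#' @param path output path.
#' @param header_extra optional character vector of extra \code{##} lines
#'   (e.g. seed and parameter digests).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(g, path, header_extra = character()) {
  stopifnot(is(g, "GenotypeTable"))
  sep <- if (g@phased) "|" else "/"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ChelonScan",
               header_extra,
               sprintf("##contig=<ID=%s,length=%d>", g@scaffolds$name,
                       as.integer(g@scaffolds$length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g@samples), collapse = "\t")), con)
  n <- nrow(g@sites)
  if (n > 0) {
    hap <- g@haplotypes
    gtCols <- vapply(seq_along(g@samples), function(i) {
      if (g@ploidy == 1L) as.character(hap[, i])
      else paste(hap[, 2L * i - 1L], hap[, 2L * i], sep = sep)
    }, character(n))
    gtCols <- matrix(gtCols, nrow = n)
    qual <- ifelse(is.na(g@qual), ".", format(g@qual, trim = TRUE))
    lines <- paste(g@sites$scaffold, g@sites$pos, ".", g@sites$ref,
                   g@sites$alt, qual, ".", ".", "GT",
                   apply(gtCols, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF into a GenotypeTable
#'
#' Parses GT fields of a biallelic-SNP VCF (as written by
#' \code{\link{writeGenotypeVcf}} or an upstream caller after filtering).
#' Records that are not biallelic SNPs or carry missing genotypes are
#' dropped.
#'
#' @param path VCF path.
#' @param populations optional named character sample -> population; defaults
#'   to each sample being its own population.
#' @return A \linkS4class{GenotypeTable}.
#' @export
readGenotypeVcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !grepl(",", fix$ALT)
  complete <- !apply(is.na(gt) | grepl("\\.", gt), 1, any)
  keep <- snp & complete
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  phased <- !any(grepl("/", gt))
  ploidy <- if (grepl("[|/]", gt[1])) 2L else 1L
  n <- nrow(fix)
  hap <- matrix(0L, nrow = n, ncol = length(samples) * ploidy)
  for (i in seq_along(samples)) {
    if (ploidy == 2L) {
      parts <- strsplit(gt[, i], "[|/]")
      hap[, 2L * i - 1L] <- as.integer(vapply(parts, `[`, "", 1L))
      hap[, 2L * i] <- as.integer(vapply(parts, `[`, "", 2L))
    } else {
      hap[, i] <- as.integer(gt[, i])
    }
  }
  # contig lengths from the header; fall back to max position seen
  meta <- v@meta
  contigLines <- grep("^##contig", meta, value = TRUE)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contigLines)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                          contigLines)))
  scaffoldNames <- unique(c(ids, fix$CHROM))
  scaffolds <- data.frame(name = scaffoldNames,
                          length = lens[match(scaffoldNames, ids)],
                          stringsAsFactors = FALSE)
  for (i in which(is.na(scaffolds$length))) {
    pmax <- suppressWarnings(max(as.numeric(
      fix$POS[fix$CHROM == scaffolds$name[i]])))
    scaffolds$length[i] <- if (is.finite(pmax)) pmax else 1
  }
  if (is.null(populations))
    populations <- stats::setNames(samples, samples)
  sites <- data.frame(scaffold = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ord <- order(match(sites$scaffold, scaffolds$name), sites$pos)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  new("GenotypeTable", samples = samples, populations = populations,
      ploidy = ploidy, scaffolds = scaffolds,
      sites = sites[ord, , drop = FALSE],
      haplotypes = hap[ord, , drop = FALSE],
      phased = phased, qual = qual[ord], depth = NULL)
}

#' Read raw variant records (with INFO annotations) from a VCF
#'
#' Used by the filter chain: keeps every record (SNPs, indels,
#' multiallelics) and pulls out QUAL plus the INFO annotations the hard
#' filters inspect. Absent annotations become NA.
#'
#' @param path VCF path.
#' @return data.frame with columns \code{scaffold}, \code{pos}, \code{ref},
#'   \code{alt}, \code{qual}, \code{FS}, \code{QD}, \code{MQ},
#'   \code{MQRankSum}, \code{ReadPosRankSum}, \code{is_indel}.
#' @export
readVariantRecords <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- function(tag) {
    x <- vcfR::extract.info(v, element = tag)
    suppressWarnings(as.numeric(x))
  }
  alt1 <- vapply(strsplit(fix$ALT, ","), `[`, "", 1L)
  data.frame(
    scaffold = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, qual = suppressWarnings(as.numeric(fix$QUAL)),
    FS = info("FS"), QD = info("QD"), MQ = info("MQ"),
    MQRankSum = info("MQRankSum"), ReadPosRankSum = info("ReadPosRankSum"),
    is_indel = nchar(fix$REF) > 1 |
      (nchar(alt1) > 1 & !grepl(",", fix$ALT) & alt1 != "."),
    stringsAsFactors = FALSE)
}

## ---- BED ----

#' Write a callable mask as BED (0-based half-open)
#' @param mask a \linkS4class{CallableMask}.
#' @param path output path.
#' @export
writeBedMask <- function(mask, path) {
  iv <- mask@intervals
  utils::write.table(
    data.frame(iv$scaffold, format(iv$start, scientific = FALSE, trim = TRUE),
               format(iv$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as a callable mask
#' @param path BED path (first three columns used).
#' @param scaffolds scaffold data.frame (\code{name}, \code{length});
#'   defaults to lengths implied by the intervals.
#' @return A \linkS4class{CallableMask}.
#' @export
readBedMask <- function(path, scaffolds = NULL) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  iv <- data.frame(scaffold = as.character(bed[[1]]),
                   start = as.numeric(bed[[2]]), end = as.numeric(bed[[3]]),
                   stringsAsFactors = FALSE)
  if (is.null(scaffolds)) {
    agg <- stats::aggregate(end ~ scaffold, data = iv, FUN = max)
    scaffolds <- data.frame(name = agg$scaffold, length = agg$end,
                            stringsAsFactors = FALSE)
  }
  iv <- iv[order(match(iv$scaffold, scaffolds$name), iv$start), ,
           drop = FALSE]
  rownames(iv) <- NULL
  new("CallableMask", intervals = iv, scaffolds = scaffolds)
}
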