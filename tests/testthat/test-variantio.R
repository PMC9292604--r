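toyRecords <- function() {
  readVariantRecords(system.file("extdata", "toy_filters.vcf",
                                 package = "ChelonScan"))
}

test_that("hard filters fire exactly on their thresholds", {
  rec <- data.frame(
    scaffold = "s", pos = c(10, 20, 30), ref = c("A", "C", "T"),
    alt = c("G", "T", "A,G"),
    qual = c(100, 100, 100), FS = c(1, NA, 1), QD = c(20, 1.5, 20),
    MQ = c(60, 60, 60), MQRankSum = c(0, NA, 0),
    ReadPosRankSum = c(0, 0, 0), is_indel = FALSE,
    stringsAsFactors = FALSE)
  out <- hardFilterRecords(rec)
  expect_true(out$keep[1])
  expect_false(out$keep[2]); expect_equal(out$reasons[2], "QD<2")
  expect_false(out$keep[3]); expect_equal(out$reasons[3], "not biallelic SNP")
})

test_that("absent INFO annotations never fire their criterion", {
  rec <- data.frame(scaffold = "s", pos = 1, ref = "A", alt = "G",
                    qual = 100, FS = NA, QD = NA, MQ = NA, MQRankSum = NA,
                    ReadPosRankSum = NA, is_indel = FALSE,
                    stringsAsFactors = FALSE)
  expect_true(hardFilterRecords(rec)$keep)
})

test_that("coverage filter matches a brute-force per-base scan", {
  expect_equal(nrow(coverageFilter(rep(10, 50), 10)), 0) # uniform = clean
  d <- rep(10, 300); d[101:200] <- 50 # a 100-bp run at 5x mean of the rest
  out <- coverageFilter(d, mean_depth = 10)
  expect_equal(out, data.frame(start = 100, end = 200))
  # random toy profile against an independent per-base oracle
  set.seed(42)
  depth <- sample(c(2, 10, 12, 50, 0), 1000, replace = TRUE,
                  prob = c(.05, .6, .25, .05, .05))
  m <- mean(depth)
  out <- coverageFilter(depth, m)
  bad <- depth > 4 * m | depth < m / 4
  expect_equal(sum(out$end - out$start), sum(bad))
  covered <- rep(FALSE, 1000)
  for (i in seq_len(nrow(out))) covered[(out$start[i] + 1):out$end[i]] <- TRUE
  expect_equal(covered, bad)
  expect_error(coverageFilter(numeric(0)), "empty")
})

test_that("indel proximity drops SNPs within the radius of confident indels", {
  rec <- data.frame(
    scaffold = "s", pos = c(100, 103, 106, 200, 202),
    ref = c("AT", "G", "C", "G", "T"), alt = c("A", "A", "T", "GA", "G"),
    qual = c(70, 100, 100, 50, 100),
    FS = NA, QD = NA, MQ = NA, MQRankSum = NA, ReadPosRankSum = NA,
    is_indel = c(TRUE, FALSE, FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  out <- indelProximityFilter(rec, radius = 5, indel_qual_min = 60)
  expect_false(out$keep[out$pos == 103]) # 3 bp from a QUAL-70 indel
  expect_true(out$keep[out$pos == 106])  # 6 bp away
  expect_true(out$keep[out$pos == 202])  # indel too low-quality to count
  expect_error(indelProximityFilter(rec[c(2, 1, 3:5), ]), "sorted")
})

test_that("the kept set does not depend on criterion order", {
  rec <- toyRecords()
  chain <- applyFilterChain(rec)
  # independent composition: proximity first, then hard filters
  prox <- indelProximityFilter(rec)
  hardOnProx <- hardFilterRecords(prox[prox$keep, ])
  keptAlt <- hardOnProx$pos[hardOnProx$keep]
  expect_setequal(chain$pos[chain$keep], keptAlt)
})

test_that("mask intersection equals a brute-force bitmap AND", {
  sc <- data.frame(name = "s1", length = 200, stringsAsFactors = FALSE)
  mk <- function(iv) makeToyMask(
    data.frame(scaffold = "s1", start = iv[, 1], end = iv[, 2]), sc)
  m1 <- mk(cbind(0, 100))
  m2 <- mk(cbind(50, 150))
  out <- intersectMasks(list(m1, m2))
  expect_equal(out@intervals$start, 50)
  expect_equal(out@intervals$end, 100)
  # idempotence
  self <- intersectMasks(list(m1, m1))
  expect_equal(self@intervals, m1@intervals)
  # three random masks vs bitmap oracle; associativity and commutativity
  set.seed(7)
  rmask <- function() {
    starts <- sort(sample(0:190, 5))
    ends <- pmin(starts + sample(3:25, 5, replace = TRUE), 200)
    keep <- c(TRUE, diff(starts) > 25) # crude non-overlap guarantee
    mk(cbind(starts, ends)[keep, , drop = FALSE])
  }
  bitmap <- function(m) {
    b <- rep(FALSE, 200)
    for (i in seq_len(nrow(m@intervals)))
      b[(m@intervals$start[i] + 1):m@intervals$end[i]] <- TRUE
    b
  }
  ms <- list(rmask(), rmask(), rmask())
  res <- intersectMasks(ms)
  expect_equal(bitmap(res), bitmap(ms[[1]]) & bitmap(ms[[2]]) & bitmap(ms[[3]]))
  resRev <- intersectMasks(rev(ms))
  expect_equal(resRev@intervals, res@intervals)
  resAssoc <- intersectMasks(list(intersectMasks(ms[1:2]), ms[[3]]))
  expect_equal(resAssoc@intervals, res@intervals)
  expect_lte(callableSpan(res), min(sapply(ms, callableSpan)))
})

test_that("window tiling respects size, minimum scaffold and partial flags", {
  sc <- data.frame(name = c("a", "b", "c"),
                   length = c(1e6, 499000, 1050000),
                   stringsAsFactors = FALSE)
  w <- makeWindows(sc, 1e5, min_scaffold = 5e5)
  expect_equal(sum(w$scaffold == "a"), 10)
  expect_false(any(w$partial[w$scaffold == "a"]))
  expect_equal(sum(w$scaffold == "b"), 0) # below the scaffold floor
  wc <- w[w$scaffold == "c", ]
  expect_equal(nrow(wc), 11)
  expect_equal(wc$end[11] - wc$start[11], 5e4)
  expect_true(wc$partial[11])
  expect_false(any(wc$partial[-11]))
})

test_that("VCF round-trip preserves the modelled fields", {
  hap <- rbind(c(0, 1, 0, 0), c(1, 1, 0, 1), c(0, 0, 1, 1))
  g <- makeToyGt(hap, c("X", "Y"), positions = c(10, 40, 90),
                 ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  path <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(g, path)
  g2 <- readGenotypeVcf(path)
  expect_equal(g2@samples, g@samples)
  expect_equal(g2@sites$pos, g@sites$pos)
  expect_equal(g2@sites$ref, g@sites$ref)
  expect_equal(g2@sites$alt, g@sites$alt)
  expect_equal(unname(g2@haplotypes), unname(g@haplotypes))
  expect_true(g2@phased)
  # and a second round trip is the identity
  path2 <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(g2, path2)
  expect_identical(readLines(path)[-(1:2)], readLines(path2)[-(1:2)])
})

test_that("BED masks round-trip with 0-based half-open coordinates", {
  sc <- data.frame(name = c("s1", "s2"), length = c(500, 300),
                   stringsAsFactors = FALSE)
  m <- makeToyMask(data.frame(scaffold = c("s1", "s1", "s2"),
                              start = c(0, 200, 50), end = c(100, 450, 300)),
                   sc)
  path <- tempfile(fileext = ".bed")
  writeBedMask(m, path)
  m2 <- readBedMask(path, sc)
  expect_equal(m2@intervals, m@intervals)
  expect_equal(callableSpan(m2), 100 + 250 + 250)
})
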