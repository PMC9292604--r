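test_that("rooted topology counts follow the double factorial", {
  expect_equal(length(topologyStrings(enumerateTopologies(c("a", "b"), "o"))), 1)
  expect_equal(length(topologyStrings(enumerateTopologies(c("a", "b", "c"), "o"))), 3)
  cat4 <- enumerateTopologies(c("OL", "LL", "HH", "GG"), "DC")
  expect_equal(length(topologyStrings(cat4)), 15)
  expect_equal(length(topologyStrings(
    enumerateTopologies(letters[1:5], "o"))), 105)
  # canonical strings are unique, deterministic and contain every taxon
  expect_false(anyDuplicated(topologyStrings(cat4)) > 0)
  expect_identical(topologyStrings(cat4),
                   topologyStrings(enumerateTopologies(c("GG", "HH", "LL", "OL"),
                                                       "DC")))
  for (s in topologyStrings(cat4))
    for (taxon in c("OL", "LL", "HH", "GG"))
      expect_equal(lengths(regmatches(s, gregexpr(taxon, s))), 1)
  expect_error(enumerateTopologies(c("a", "a", "b"), "o"), "duplicate")
})

test_that("outgroup-private SNPs are removed, ingroup variation retained", {
  # 12 sites: 4 outgroup-private, 8 with ingroup variation
  hap <- rbind(
    c(0, 0, 0, 0, 1, 1), c(0, 0, 0, 0, 1, 0), # og-private / og+ing? second has og het
    c(1, 1, 1, 1, 1, 1), c(0, 0, 0, 0, 0, 1),
    c(0, 1, 0, 0, 0, 0), c(1, 0, 1, 0, 0, 0),
    c(0, 0, 1, 1, 0, 0), c(1, 1, 0, 0, 1, 1),
    c(0, 0, 0, 0, 1, 1), c(0, 1, 1, 1, 1, 1),
    c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 0, 1))
  g <- makeToyGt(hap, c("A", "B", "O"), positions = 1:12)
  out <- removeOutgroupPrivateSnps(g, "O")
  # hand classification: ingroup columns are 1:4; private-to-outgroup rows
  # are those with ingroup monomorphic and any outgroup difference
  ing <- hap[, 1:4]; og <- hap[, 5:6]
  private <- apply(ing, 1, function(x) length(unique(x)) == 1) &
    sapply(1:12, function(i) any(og[i, ] != ing[i, 1]))
  expect_equal(nrow(siteTable(out)), sum(!private))
  expect_equal(siteTable(out)$pos, which(!private))
  # row 3 (all derived incl. outgroup) is monomorphic everywhere: kept
  expect_true(3 %in% siteTable(out)$pos)
})

test_that("SNP windows honour size and terminal minimum", {
  mkg <- function(n) makeToyGt(matrix(0L, n, 4), c("A", "B"),
                               positions = seq_len(n) * 10,
                               scaffold_length = n * 10 + 10)
  b149 <- windowSnpBlocks(mkg(149), 50, 45)
  expect_equal(nrow(b149), 3) # 50 + 50 + 49 (terminal kept: 49 >= 45)
  expect_equal(b149$n_snps, c(50, 50, 49))
  b144 <- windowSnpBlocks(mkg(144), 50, 45)
  expect_equal(nrow(b144), 2) # 44-SNP remainder dropped
  expect_equal(nrow(windowSnpBlocks(mkg(10), 50, 45)), 0)
  # midpoint is the mean of first and last SNP positions
  expect_equal(b149$midpoint[1], (10 + 500) / 2)
})

test_that("window trees recover clear topologies deterministically", {
  hap <- cbind(a1 = c(rep(1, 20), rep(0, 10), rep(0, 5)),
               a2 = c(rep(1, 20), rep(0, 10), rep(1, 5)),
               b1 = c(rep(0, 20), rep(1, 10), rep(0, 5)),
               o1 = rep(0, 35))
  tr <- inferWindowTree(hap)
  # a1/a2 form a cherry
  canon <- ChelonScan:::phyloCanonical(
    ape::root(tr, outgroup = "o1", resolve.root = TRUE))
  expect_true(grepl("\\(a1,a2\\)", canon))
  # permuting input column order changes nothing
  tr2 <- inferWindowTree(hap[, c(3, 1, 4, 2)])
  expect_equal(ChelonScan:::phyloCanonical(tr2), ChelonScan:::phyloCanonical(tr))
  # identical haplotype pairs give zero-length cherries but a defined tree
  hap2 <- cbind(x1 = c(1, 1, 0, 0), x2 = c(1, 1, 0, 0),
                y1 = c(0, 0, 1, 1), y2 = c(0, 0, 1, 1))
  expect_s3_class(inferWindowTree(hap2), "phylo")
  expect_error(inferWindowTree(hap2[, 1:3]), "4 haplotypes")
  expect_error(inferWindowTree(matrix(0L, 3, 4,
                                      dimnames = list(NULL, letters[1:4]))),
               "identical")
})

test_that("exact weighting matches a four-point-condition oracle", {
  # random 8-leaf tree: species A, B, C with two haplotypes each + outgroup
  set.seed(77)
  labels <- c("a1", "a2", "b1", "b2", "c1", "c2", "o1", "o2")
  taxon_map <- stats::setNames(c("A", "A", "B", "B", "C", "C", "O", "O"),
                               labels)
  catalog <- enumerateTopologies(c("A", "B", "C"), "O")
  for (rep in 1:5) {
    tree <- ape::rtree(8, tip.label = sample(labels))
    tree$edge.length <- rep(1, nrow(tree$edge))
    w <- weightWindow(tree, taxon_map, catalog)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
    # oracle: per combination, quartet split by the four-point condition on
    # topological path distances
    dd <- ape::cophenetic.phylo(tree)
    counts <- stats::setNames(numeric(3), topologyStrings(catalog))
    for (a in c("a1", "a2")) for (b in c("b1", "b2"))
      for (cc in c("c1", "c2")) for (o in c("o1", "o2")) {
        s_ab <- dd[a, b] + dd[cc, o]
        s_ac <- dd[a, cc] + dd[b, o]
        s_bc <- dd[b, cc] + dd[a, o]
        key <- c("((A,B),C)", "((A,C),B)", "((B,C),A)")[
          which.min(c(s_ab, s_ac, s_bc))]
        counts[key] <- counts[key] + 1
      }
    expect_equal(unname(w[names(counts)]), unname(counts / 16))
  }
})

test_that("weights put full mass on the topology of monophyletic species", {
  tree <- ape::read.tree(text = "(((a1,a2),((b1,b2),(c1,c2))),o1);")
  tree$edge.length <- rep(1, nrow(tree$edge))
  catalog <- enumerateTopologies(c("A", "B", "C"), "O")
  taxon_map <- stats::setNames(c("A", "A", "B", "B", "C", "C", "O"),
                               c("a1", "a2", "b1", "b2", "c1", "c2", "o1"))
  w <- weightWindow(ape::unroot(tree), taxon_map, catalog)
  expect_equal(unname(w["((B,C),A)"]), 1)
  expect_equal(sum(w), 1)
})

test_that("loess smoothing preserves constants, bounds and normalization", {
  const <- data.frame(scaffold = "s", midpoint = seq(5e4, 2e6, by = 1e5),
                      n_snps = 50, w1 = 0.6, w2 = 0.3, w3 = 0.1)
  sm <- smoothWeights(const, span_bp = 1e6)
  expect_equal(sm$w1, const$w1, tolerance = 1e-9)
  expect_equal(sm$w2, const$w2, tolerance = 1e-9)
  # step function: smooth monotone transition, clipped and renormalized
  step <- data.frame(scaffold = "s", midpoint = seq(5e4, 4e6, by = 1e5),
                     n_snps = 50)
  step$w1 <- as.numeric(step$midpoint > 2e6)
  step$w2 <- 1 - step$w1
  sm2 <- smoothWeights(step, span_bp = 1e6)
  expect_true(all(sm2$w1 >= 0 & sm2$w1 <= 1))
  expect_equal(sm2$w1 + sm2$w2, rep(1, nrow(step)))
  expect_true(all(diff(sm2$w1) > -1e-8)) # no oscillation after clipping
  # single window: identity
  one <- const[1, ]
  expect_equal(smoothWeights(one, 1e6), one)
})
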