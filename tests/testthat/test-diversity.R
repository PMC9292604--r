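test_that("windowed heterozygosity counts and normalizations are exact", {
  # 150 het sites in a fully callable 100-kb window, 50 in a half-callable one
  n <- 200
  hap <- cbind(rep(0L, n), rep(1L, n), rep(0L, n), rep(0L, n)) # S1 het, S2 hom
  pos <- c(seq(101, by = 13, length.out = 150),
           seq(100001, by = 7, length.out = 50))
  g <- makeToyGt(hap, c("S1", "S2"), positions = pos,
                 scaffold_length = 2e5)
  mask <- makeToyMask(data.frame(scaffold = "s1", start = c(0, 100000),
                                 end = c(100000, 150000)),
                      g@scaffolds)
  windows <- makeWindows(g@scaffolds, 1e5)
  out <- windowedHeterozygosity(g, "S1", mask, windows)
  expect_equal(out$n_het, c(150, 50))
  expect_equal(out$het_per_bp, c(1.5e-3, 5e-4))
  expect_equal(out$het_per_callable, c(1.5e-3, 1e-3))
  # conservation: window sums equal the genome-wide het count
  expect_equal(sum(out$n_het), 200)
  # the hom sample has no het anywhere
  out2 <- windowedHeterozygosity(g, "S2", mask, windows)
  expect_equal(sum(out2$n_het), 0)
  expect_error(windowedHeterozygosity(g, "nope", mask, windows), "absent")
})

test_that("depth floors drop low-coverage sites from het counts", {
  hap <- cbind(c(0L, 0L, 0L), c(1L, 1L, 1L), rep(0L, 3), rep(0L, 3))
  depth <- cbind(c(10, 4, 5), c(10, 10, 10))
  g <- makeToyGt(hap, c("S1", "S2"), positions = c(5, 10, 15),
                 scaffold_length = 100, depth = depth)
  mask <- fullMask(g@scaffolds)
  w <- makeWindows(g@scaffolds, 100)
  out <- windowedHeterozygosity(g, "S1", mask, w, min_depth = 5)
  expect_equal(out$n_het, 2) # the DP=4 site does not count
})

test_that("Ts/Tv classification matches hand enumeration", {
  # 21 transitions, 10 transversions -> 2.1
  ref <- c(rep("A", 11), rep("C", 10), rep("A", 6), rep("G", 4))
  alt <- c(rep("G", 11), rep("T", 10), rep("T", 6), rep("C", 4))
  g <- makeToyGt(matrix(0L, 31, 2), "S1", positions = 1:31,
                 ref = ref, alt = alt)
  expect_equal(tstvRatio(g), 2.1)
  # transitions only: undefined
  g2 <- makeToyGt(matrix(0L, 3, 2), "S1", positions = 1:3,
                  ref = c("A", "G", "C"), alt = c("G", "A", "T"))
  expect_error(tstvRatio(g2), "transversions")
  # random table vs per-site hand classification
  set.seed(9)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 60, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "x")
  g3 <- makeToyGt(matrix(0L, 60, 2), "S1", positions = 1:60,
                  ref = ref, alt = unname(alt))
  isTs <- paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
  expect_equal(tstvRatio(g3), sum(isTs) / sum(!isTs))
})

test_that("IBS distances match hand computation and metric axioms", {
  # all-homozygous genotypes: consensus is deterministic
  hom <- function(x) rep(x, each = 2)
  hap <- t(sapply(1:10, function(i)
    c(hom(as.integer(i > 5)), hom(0L), hom(1L))))
  g <- makeToyGt(hap, c("S1", "S2", "S3"), positions = 1:10)
  d <- ibsDistanceMatrix(g, seed = 1)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["S1", "S2"], 0.5)
  expect_equal(d["S1", "S3"], 0.5)
  expect_equal(d["S2", "S3"], 1) # differ at every consensus site
  expect_equal(d, t(d))
  # triangle inequality on a random table with heterozygotes
  set.seed(11)
  hap2 <- matrix(rbinom(40 * 8, 1, 0.4), 40, 8)
  g2 <- makeToyGt(hap2, paste0("T", 1:4), positions = 1:40)
  d2 <- ibsDistanceMatrix(g2, seed = 2)
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(d2[i, j], d2[i, k] + d2[k, j] + 1e-12)
  # seeded determinism
  expect_identical(d2, ibsDistanceMatrix(g2, seed = 2))
})

test_that("generation time is maturity plus half the reproductive span", {
  expect_equal(generationTime(20, 8), 24)
  expect_equal(generationTime(10, 10), 15)
  expect_equal(generationTime(0, 0), 0)
  expect_error(generationTime(-1, 5))
})

test_that("Jukes-Cantor correction matches its closed form", {
  expect_equal(jcDistance(c(0, 1, 1), c(0, 1, 1)), 0)
  # p = 0.1: -(3/4) log(1 - 4*0.1/3) = 0.1073256
  a <- c(rep(1, 1), rep(0, 9)); b <- rep(0, 10)
  expect_equal(jcDistance(a, b), 0.107326, tolerance = 1e-5)
  expect_error(jcCorrect(0.75), "saturat")
  expect_error(jcCorrect(0.9), "saturat")
})

test_that("UPGMA dating scales node heights through one calibration", {
  d <- matrix(c(0, 0.2, 0.4,
                0.2, 0, 0.4,
                0.4, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dated <- upgmaCalibratedAges(d, list(taxa = c("A", "B", "C"), age = 68.4))
  expect_equal(datedNodeAge(dated, c("A", "B", "C")), 68.4) # calibration exact
  expect_equal(datedNodeAge(dated, c("A", "B")), 34.2)      # 0.1/0.2 * 68.4
  # ultrametric within tolerance
  depths <- ape::node.depth.edgelength(dated@tree)
  tipDepths <- depths[seq_along(dated@tree$tip.label)]
  expect_lt(diff(range(tipDepths)), 1e-9 * max(tipDepths))
  # ages decrease root -> tips
  expect_gt(datedNodeAge(dated, c("A", "B", "C")), datedNodeAge(dated, c("A", "B")))
  # calibrating on a set that is not a UPGMA clade must fail loudly
  expect_error(upgmaCalibratedAges(d, list(taxa = c("A", "C"), age = 10)),
               "not recovered")
})
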