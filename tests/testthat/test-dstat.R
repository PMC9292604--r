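# helper: diploid table with homozygous genotypes so allele sampling is
# deterministic; rows give one allele per sample (P1, P2, P3, O)
homTrioGt <- function(patterns, block_size_positions = 1000) {
  hap <- do.call(rbind, lapply(patterns, function(p) rep(p, each = 2)))
  makeToyGt(hap, c("P1", "P2", "P3", "O"),
            positions = seq(100, by = block_size_positions,
                            length.out = length(patterns)),
            scaffold_length = 1000 * length(patterns) + 1000)
}

test_that("site patterns classify as ABBA/BABA by outgroup polarization", {
  g <- homTrioGt(list(
    c(0, 1, 1, 0),  # ABBA
    c(1, 0, 1, 0),  # BABA
    c(0, 0, 1, 0),  # AABA: neither
    c(1, 1, 1, 0),  # BBBA: neither
    c(0, 1, 1, 0),  # ABBA
    c(0, 1, 1, 1),  # relative to outgroup: B A A -> neither
    c(0, 1, 0, 1),  # relative to outgroup: B A B -> BABA
    c(1, 1, 0, 0))) # BBAA: neither
  counts <- countPatterns(g, c("P1", "P2", "P3"), "O", seed = 1,
                          block_size = 1e6)
  expect_equal(sum(counts$nABBA), 2)
  expect_equal(sum(counts$nBABA), 2)
})

test_that("D statistic arithmetic and degenerate input", {
  expect_equal(dStatistic(30, 10), 0.5)
  expect_equal(dStatistic(7, 7), 0)
  expect_error(dStatistic(0, 0), "undefined")
})

test_that("weighted block jackknife matches an independent computation", {
  # equal-weight blocks reduce to the classic delete-one jackknife
  blocks <- data.frame(block = c("b1", "b2", "b3"),
                       nABBA = c(30, 20, 25), nBABA = c(10, 20, 15))
  blocks$n_informative <- blocks$nABBA + blocks$nBABA
  jk <- blockJackknife(blocks, min_sites = 1)
  D <- (75 - 45) / 120
  thetaMinus <- c((75 - 30) - (45 - 10), (75 - 20) - (45 - 20),
                  (75 - 25) - (45 - 15)) / 80
  varClassic <- (3 - 1) / 3 * sum((thetaMinus - mean(thetaMinus))^2)
  expect_equal(jk$D, D)
  expect_equal(jk$SE, sqrt(varClassic))
  expect_equal(jk$Z, D / sqrt(varClassic))
  # unequal weights against a from-scratch implementation of the weighted
  # delete-one jackknife (pseudovalue form)
  b2 <- data.frame(block = c("b1", "b2", "b3", "b4"),
                   nABBA = c(300, 20, 75, 40), nBABA = c(200, 30, 50, 45))
  b2$n_informative <- b2$nABBA + b2$nBABA
  jk2 <- blockJackknife(b2, min_sites = 1)
  n <- sum(b2$n_informative); m <- b2$n_informative; gN <- 4
  th <- (sum(b2$nABBA) - sum(b2$nBABA)) / n
  thMinus <- sapply(1:4, function(j) {
    a <- sum(b2$nABBA[-j]); b <- sum(b2$nBABA[-j]); (a - b) / (a + b)
  })
  h <- n / m
  thJ <- gN * th - sum((1 - m / n) * thMinus)
  tau <- h * th - (h - 1) * thMinus
  expect_equal(jk2$SE, sqrt(sum((tau - thJ)^2 / (h - 1)) / gN))
  # identical blocks: SE = 0 flagged degenerate
  b3 <- data.frame(block = c("x", "y"), nABBA = c(10, 10), nBABA = c(10, 10))
  b3$n_informative <- 20
  jk3 <- blockJackknife(b3, min_sites = 1)
  expect_true(jk3$degenerate)
  expect_equal(jk3$SE, 0)
  expect_error(blockJackknife(b3[1, ], min_sites = 1), "blocks")
})

test_that("swapping P1 and P2 flips the sign of D exactly", {
  set.seed(21)
  pats <- lapply(1:400, function(i) {
    p <- rbinom(3, 1, 0.5); c(p, 0)
  })
  g <- homTrioGt(pats, block_size_positions = 100)
  r12 <- dstatTrio(g, c("P1", "P2", "P3"), "O", seed = 5,
                   block_size = 1e4, min_sites = 2)
  r21 <- dstatTrio(g, c("P2", "P1", "P3"), "O", seed = 5,
                   block_size = 1e4, min_sites = 2)
  expect_equal(r12@D, -r21@D)
  expect_equal(r12@SE, r21@SE)
})

test_that("D is invariant to which allele is labelled REF/ALT", {
  set.seed(31)
  hap <- matrix(rbinom(300 * 8, 1, 0.4), 300, 8)
  g <- makeToyGt(hap, c("P1", "P2", "P3", "O"), positions = seq_len(300) * 50,
                 scaffold_length = 20000)
  flip <- rbinom(300, 1, 0.5) == 1
  hap2 <- hap
  hap2[flip, ] <- 1L - hap2[flip, ]
  g2 <- makeToyGt(hap2, c("P1", "P2", "P3", "O"),
                  positions = seq_len(300) * 50, scaffold_length = 20000)
  c1 <- countPatterns(g, c("P1", "P2", "P3"), "O", seed = 3, block_size = 1e4)
  c2 <- countPatterns(g2, c("P1", "P2", "P3"), "O", seed = 3, block_size = 1e4)
  expect_equal(c1$nABBA, c2$nABBA)
  expect_equal(c1$nBABA, c2$nBABA)
})

test_that("trio enumeration follows the species tree", {
  tree <- speciesTreeFromModel(defaultTurtleModel())
  scanTrios <- ChelonScan:::consistentTrios(tree, "DC")
  lab <- sapply(scanTrios, function(t)
    sprintf("((%s,%s)%s)", sort(t[1:2])[1], sort(t[1:2])[2], t[3]))
  expect_setequal(lab, c("((LL,OL)HH)", "((LL,OL)GG)", "((HH,OL)GG)",
                         "((HH,LL)GG)"))
  # three ingroup taxa, fully pectinate: only the cherry pair has a valid P3
  t3 <- ape::read.tree(text = "(((A,B),C),O);")
  expect_equal(length(ChelonScan:::consistentTrios(t3, "O")), 1)
  # star tree rejected
  star <- ape::read.tree(text = "(A,B,C,O);")
  expect_error(ChelonScan:::consistentTrios(star, "O"), "binary")
})

test_that("re-polarizing with a second outgroup genome barely moves D", {
  skipIfNoBackend()
  sim <- cachedSim("calib2perPop", function() {
    simulateGenotypes(calibrationModel(),
                      genomeLayout(2, 5e6), 2, seed = 88)
  })
  g <- sim$genotypes
  r1 <- dstatTrio(g, c("OL_1", "LL_1", "HH_1"), "DC_1", seed = 6,
                  block_size = 1e6)
  r2 <- dstatTrio(g, c("OL_1", "LL_1", "HH_1"), "DC_2", seed = 6,
                  block_size = 1e6)
  expect_lt(abs(r1@D - r2@D), r1@SE)
  # neither outgroup produces a spurious signal on ILS-only data
  expect_lt(abs(r1@Z), 3)
  expect_lt(abs(r2@Z), 3)
})
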