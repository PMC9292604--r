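test_that("pseudo-haploidization keeps hom alleles and samples het ones", {
  # sample S1: 200 het sites and 100 hom-alt sites
  n <- 300
  hap <- cbind(c(rep(0L, 200), rep(1L, 100)), rep(1L, n),
               rep(0L, n), rep(0L, n))
  g <- makeToyGt(hap, c("S1", "S2"), positions = seq_len(n) * 10,
                 scaffold_length = 4000)
  ph <- pseudoHaploidize(g, "S1", seed = 4)
  expect_equal(ph@sites$allele[201:300], rep(1L, 100)) # hom sites forced
  picked <- ph@sites$allele[1:200]
  # binomial check: each allele drawn about half the time
  expect_gt(mean(picked), 0.5 - 4 * sqrt(0.25 / 200))
  expect_lt(mean(picked), 0.5 + 4 * sqrt(0.25 / 200))
  # determinism
  expect_identical(ph@sites, pseudoHaploidize(g, "S1", seed = 4)@sites)
  # depth floor: DP = 4 becomes missing
  depth <- cbind(rep(10, n), rep(10, n)); depth[5, 1] <- 4
  g2 <- makeToyGt(hap, c("S1", "S2"), positions = seq_len(n) * 10,
                  scaffold_length = 4000, depth = depth)
  ph2 <- pseudoHaploidize(g2, "S1", seed = 4)
  expect_true(is.na(ph2@sites$allele[5]))
  # quality floor
  qual <- rep(100, n); qual[7] <- 29
  g3 <- makeToyGt(hap, c("S1", "S2"), positions = seq_len(n) * 10,
                  scaffold_length = 4000, qual = qual)
  expect_true(is.na(pseudoHaploidize(g3, "S1", seed = 4)@sites$allele[7]))
})

test_that("pseudo-F1 heterozygosity marks exactly the differing positions", {
  n <- 20
  hap <- cbind(rep(0L, n), rep(0L, n), rep(1L, n), rep(1L, n))
  hap[1:3, 3:4] <- 0L # S2 matches S1 at positions 1-3
  g <- makeToyGt(hap, c("S1", "S2"), positions = seq_len(n) * 5,
                 scaffold_length = 200)
  a <- pseudoHaploidize(g, "S1", seed = 1)
  b <- pseudoHaploidize(g, "S2", seed = 1)
  f1 <- makePseudoF1(a, b)
  het <- f1@haplotypes[, 1] != f1@haplotypes[, 2]
  expect_equal(sum(het), n - 3)
  # a genome paired with itself has no heterozygosity
  self <- makePseudoF1(a, a)
  expect_equal(sum(self@haplotypes[, 1] != self@haplotypes[, 2]), 0)
  # positions missing in either input are dropped from the track
  depth <- cbind(rep(10, n), rep(10, n)); depth[c(4, 9, 15), 1] <- 2
  g2 <- makeToyGt(hap, c("S1", "S2"), positions = seq_len(n) * 5,
                  scaffold_length = 200, depth = depth)
  a2 <- pseudoHaploidize(g2, "S1", seed = 1)
  b2 <- pseudoHaploidize(g2, "S2", seed = 1)
  f2 <- makePseudoF1(a2, b2)
  expect_equal(nrow(f2@sites), 17)
  het2 <- f2@haplotypes[, 1] != f2@haplotypes[, 2]
  # 20 sites - 3 identical (positions 1-3) - 3 dropped differing sites
  expect_equal(sum(het2), 14)
})

test_that("plateau reading matches constructed trajectories", {
  # flat curve: plateau equals the level, no onset
  flat <- makeScaledTraj(rep(110000, 10))
  out <- estimatePlateauNe(flat)
  expect_equal(out$plateau_ne, 110000)
  expect_true(is.na(out$onset_years))
  # flat then rising 100x toward the present: plateau within 1 percent
  curve <- makeScaledTraj(c(1.1e7, 4e6, 1e6, 3e5, 9e4, 9.2e4, 8.8e4, 9.1e4,
                            9e4, 9e4))
  out2 <- estimatePlateauNe(curve)
  expect_equal(out2$plateau_ne, geomMean <- exp(mean(log(c(9e4, 9.2e4, 8.8e4,
                                                           9.1e4)))),
               tolerance = 0.01)
  expect_false(is.na(out2$onset_years))
  # strictly increasing: no plateau to read
  expect_error(estimatePlateauNe(makeScaledTraj(10^seq(7, 5, length.out = 10))),
               "plateau")
})

test_that("grid bracketing returns the neighbours of a grid member", {
  plateau <- 1e5
  mkCurve <- function(T_ma) {
    # rise begins around T_ma: recent intervals explode, old sit at the
    # plateau, with enough intervals that the transition is resolved
    K <- 24
    bounds <- 10^seq(5.5, 8, length.out = K + 1)
    left <- c(0, bounds[seq_len(K - 1)]); right <- bounds[seq_len(K)]
    mid <- sqrt(pmax(left, 1e4) * right)
    ne <- plateau * (1 + 1000 * exp(-(mid / (T_ma * 1e6))^1.5))
    makeScaledTraj(ne, left, right)
  }
  grid <- lapply(10:15, function(T) list(T = T, traj = mkCurve(T)))
  emp <- mkCurve(12)
  br <- bracketGeneFlowEnd(emp, grid, plateau, c("A", "B"))
  expect_equal(br@lower, 11)
  expect_equal(br@upper, 13)
  expect_true(br@grid_monotone)
  expect_length(br@unbounded, 0)
  # an empirical curve younger than the whole grid is flagged unbounded
  brLow <- bracketGeneFlowEnd(mkCurve(5), grid, plateau, c("A", "B"))
  expect_equal(brLow@lower, -Inf)
  expect_true("below" %in% brLow@unbounded)
})

test_that("re-polarizing against another reference leaves the F1 track unchanged", {
  set.seed(13)
  n <- 500
  hap <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
  g <- makeToyGt(hap, c("S1", "S2"), positions = seq_len(n) * 20,
                 scaffold_length = n * 20 + 10)
  flip <- rbinom(n, 1, 0.5) == 1
  hap2 <- hap; hap2[flip, ] <- 1L - hap2[flip, ]
  g2 <- makeToyGt(hap2, c("S1", "S2"), positions = seq_len(n) * 20,
                  scaffold_length = n * 20 + 10)
  mask <- fullMask(g@scaffolds)
  mkBins <- function(gt) {
    a <- pseudoHaploidize(gt, "S1", seed = 2)
    b <- pseudoHaploidize(gt, "S2", seed = 3)
    binarizeDiploid(makePseudoF1(a, b), "F1", mask, 10)
  }
  expect_identical(mkBins(g)@sequences, mkBins(g2)@sequences)
})

test_that("a within-population pseudo-F1 shows no divergence wall", {
  skipIfNoBackend()
  model <- buildDemography(list(
    populations = list(list(name = "A", ne = 20000)),
    mu = 7.9e-9, r = 2e-9, generation_time = 1))
  sim <- simulateGenotypes(model, genomeLayout(3, 2e6), 2, seed = 63)
  cfg <- smcConfig(bin_size = 10, pattern = "1+7*2+1", t_max = 15,
                   max_iters = 10, rho_ratio = 2e-9 / 7.9e-9)
  traj <- scaleTrajectory(
    hpsmcFitPair(sim$genotypes, c("A_1", "A_2"), sim$mask, cfg, seed = 2),
    7.9e-9, 1)
  ne <- traj@scaled$ne
  # the two most recent intervals of a pseudo-haploid fit are unconstrained
  # (hardly any coalescence mass) and excluded from quantitative reads; a
  # divergence wall would keep Ne at hundreds of times the background far
  # beyond them, which is what must not appear here
  mids <- geomMean(ne[4:7])
  expect_lt(max(ne[3:7]) / mids, 10)
  # and the curve tracks the true population size through the mid intervals
  expect_lt(abs(log(mids / 20000)), log(2))
})
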