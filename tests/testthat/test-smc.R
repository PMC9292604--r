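test_that("interval patterns parse into atomic intervals and groups", {
  p <- parseIntervalPattern("4+25*2+4+6")
  expect_equal(p$n_atomic, 64)
  expect_equal(max(p$groups), 28)
  expect_equal(as.integer(table(p$groups))[1], 4)
  p2 <- parseIntervalPattern("1*4")
  expect_equal(p2$n_atomic, 4)
  expect_equal(max(p2$groups), 1)
  p3 <- parseIntervalPattern("4*1")
  expect_equal(p3$n_atomic, 4)
  expect_equal(max(p3$groups), 4)
  expect_error(parseIntervalPattern("0+2"), "positive")
  expect_error(parseIntervalPattern("2++2"), "malformed")
})

test_that("binarization maps differences and mask gaps to symbols", {
  sc <- data.frame(name = "s", length = 200, stringsAsFactors = FALSE)
  full <- fullMask(sc)
  # identical haplotypes: all no-het
  b0 <- binSequenceFromPositions(list(), sc, full, 50)
  expect_equal(b0@sequences$s, rep(0L, 4))
  # single difference at position p marks exactly bin floor((p-1)/bin)
  for (p in c(1, 50, 51, 200)) {
    b <- binSequenceFromPositions(list(s = p), sc, full, 50)
    expect_equal(which(b@sequences$s == 1L) - 1, floor((p - 1) / 50))
  }
  # 200-bp pair, 3 diffs, 60-bp mask gap: hand-derived symbols
  mask <- makeToyMask(data.frame(scaffold = "s", start = c(0, 160),
                                 end = c(100, 200)), sc)
  b <- binSequenceFromPositions(list(s = c(10, 60, 190)), sc, mask, 50)
  # bin3 [100,150) fully gapped -> missing; bin4 has 40/50 callable -> kept
  expect_equal(b@sequences$s, c(1L, 1L, 2L, 1L))
})

test_that("model matrices satisfy stochasticity and prior normalization", {
  b <- smcTimeBoundaries(16, 15)
  expect_equal(b[1], 0)
  expect_true(all(diff(b) > 0))
  for (lam in list(rep(1, 16), exp(seq(-2, 2, length.out = 16)))) {
    m <- ChelonScan:::.smcModel(b, lam, 0.05, 0.06)
    expect_equal(sum(m$prior), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(m$P)), rep(1, 16), tolerance = 1e-12)
    expect_true(all(m$ehet > 0 & m$ehet < 1))
    expect_true(all(diff(m$tbar) > 0))
  }
})

test_that("forward likelihood equals exhaustive path enumeration", {
  b3 <- smcTimeBoundaries(3, 4)
  m3 <- ChelonScan:::.smcModel(b3, c(0.7, 1.3, 1.1), 0.2, 0.3)
  obs <- c(0L, 1L, 0L, 2L, 1L, 0L, 0L, 1L, 2L, 0L)
  es <- ChelonScan:::.smcEstep(list(obs), m3$P, m3$prior, m3$ehet, TRUE)
  emit <- function(o, j) {
    if (o == 1) m3$ehet[j] else if (o == 0) 1 - m3$ehet[j] else 1
  }
  paths <- expand.grid(rep(list(1:3), length(obs)))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    p <- as.integer(paths[i, ])
    v <- m3$prior[p[1]] * emit(obs[1], p[1])
    for (t in 2:length(obs)) v <- v * m3$P[p[t - 1], p[t]] * emit(obs[t], p[t])
    tot <- tot + v
  }
  expect_equal(es$loglik, log(tot), tolerance = 1e-8)
  # forward and backward recursions agree
  expect_equal(es$loglik_backward, es$loglik,
               tolerance = 1e-8 * abs(es$loglik))
  # posterior bookkeeping: transitions count B-1, emissions count B
  expect_equal(sum(es$xi), length(obs) - 1, tolerance = 1e-9)
  expect_equal(sum(es$gamma1), 1, tolerance = 1e-12)
  expect_equal(sum(es$het) + sum(es$hom), sum(obs != 2L), tolerance = 1e-9)
})

test_that("an all-missing block only propagates Markov dynamics", {
  b <- smcTimeBoundaries(4, 6)
  m <- ChelonScan:::.smcModel(b, c(0.8, 1, 1.4, 0.9), 0.1, 0.2)
  left <- c(0L, 1L, 0L)
  right <- c(1L, 0L, 0L)
  k <- 5
  obs <- c(left, rep(2L, k), right)
  es <- ChelonScan:::.smcEstep(list(obs), m$P, m$prior, m$ehet, FALSE)
  # manual forward: run the left flank, bridge with P^(k+1), run the right
  emitv <- function(o) if (o == 1) m$ehet else 1 - m$ehet
  a <- m$prior * emitv(left[1]); ll <- log(sum(a)); a <- a / sum(a)
  for (o in left[-1]) {
    a <- as.vector(t(m$P) %*% a) * emitv(o); ll <- ll + log(sum(a)); a <- a / sum(a)
  }
  bridge <- Reduce(`%*%`, replicate(k + 1, m$P, simplify = FALSE))
  a <- as.vector(t(bridge) %*% a) * emitv(right[1])
  ll <- ll + log(sum(a)); a <- a / sum(a)
  for (o in right[-1]) {
    a <- as.vector(t(m$P) %*% a) * emitv(o); ll <- ll + log(sum(a)); a <- a / sum(a)
  }
  expect_equal(es$loglik, ll, tolerance = 1e-10)
})

test_that("EM increases the log-likelihood monotonically", {
  set.seed(5)
  obs <- list(as.integer(rbinom(3000, 1, 0.08)),
              as.integer(rbinom(2000, 1, 0.02)))
  obs[[1]][sample(3000, 100)] <- 2L
  bs <- new("BinSequence", sequences = list(s1 = obs[[1]], s2 = obs[[2]]),
            bin_size = 100L)
  cfg <- smcConfig(bin_size = 100, pattern = "2+4*2+2", t_max = 10,
                   max_iters = 8, tol = 0, min_bins = 1000)
  tr <- fitSmc(bs, cfg)
  expect_true(all(diff(tr@loglik) > -1e-6 * abs(tr@loglik[1])))
  expect_s4_class(tr, "SmcTrajectory")
  # degenerate input: no heterozygous bin at all
  bs0 <- new("BinSequence", sequences = list(s = rep(0L, 20000)),
             bin_size = 100L)
  expect_error(fitSmc(bs0, cfg), "degenerate")
})

test_that("trajectory scaling follows N0 = theta/(4 mu bin) exactly", {
  mu <- 1e-8; bin <- 100L
  tr <- new("SmcTrajectory", boundaries = c(0, 0.5, 1, 2, 4),
            groups = 1:4, lambda = c(2, 1, 0.5, 1), theta = 4 * mu * 100 * 10000,
            rho = 0.01, bin_size = bin, loglik = numeric(),
            scaled = data.frame())
  s1 <- scaleTrajectory(tr, mu, gen_time = 1)
  expect_equal(smcN0(s1, mu), 10000)
  # times in generations are 2 N0 t_coal
  expect_equal(s1@scaled$left_years, c(0, 0.5, 1, 2) * 2 * 10000)
  expect_equal(s1@scaled$ne, 10000 / tr@lambda)
  # doubling the generation time doubles years, leaves Ne unchanged
  s2 <- scaleTrajectory(tr, mu, gen_time = 2)
  expect_equal(s2@scaled$left_years, 2 * s1@scaled$left_years)
  expect_equal(s2@scaled$ne, s1@scaled$ne)
  # round trip: lambda recovered exactly from the scaled curve
  expect_equal(smcN0(s1, mu) / s1@scaled$ne, tr@lambda)
})

test_that("bootstrap replicates are seeded and identity without resampling", {
  set.seed(8)
  obs <- as.integer(rbinom(12000, 1, 0.05))
  bs <- new("BinSequence", sequences = list(s = obs), bin_size = 100L)
  cfg <- smcConfig(bin_size = 100, pattern = "2+3*2+2", t_max = 10,
                   max_iters = 4, min_bins = 1000)
  fit <- fitSmc(bs, cfg)
  ident <- bootstrapSmc(bs, cfg, n_reps = 1, segment_bp = 2e5, seed = 1,
                        resample = FALSE)
  expect_equal(ident[[1]]@lambda, fit@lambda)
  r1 <- bootstrapSmc(bs, cfg, n_reps = 2, segment_bp = 2e5, seed = 9)
  r2 <- bootstrapSmc(bs, cfg, n_reps = 2, segment_bp = 2e5, seed = 9)
  expect_equal(lapply(r1, function(x) x@lambda),
               lapply(r2, function(x) x@lambda))
  expect_error(bootstrapSmc(bs, cfg, segment_bp = 1e9), "longer")
})

test_that("a tenfold bottleneck is recovered at the right epoch", {
  skipIfNoBackend()
  # diploid Ne 20000 with a drop to 2000 between 10k and 30k generations
  model <- buildDemography(list(
    populations = list(list(name = "A", ne = 20000)),
    size_changes = list(list(pop = "A", time = 10000, ne = 2000),
                        list(pop = "A", time = 30000, ne = 20000)),
    mu = 7.9e-9, r = 1e-8, generation_time = 1))
  sim <- simulateGenotypes(model, genomeLayout(5, 1e7), 1, seed = 11)
  bins <- binarizeDiploid(sim$genotypes, "A", sim$mask, 100)
  cfg <- smcConfig(bin_size = 100, pattern = "14*1", t_max = 8,
                   max_iters = 25, tol = 1e-7, rho_ratio = 1e-8 / 7.9e-9)
  tr <- scaleTrajectory(fitSmc(bins, cfg), 7.9e-9, 1)
  k <- which.min(tr@scaled$ne)
  # dip depth within a factor two of truth ...
  expect_lt(tr@scaled$ne[k], 2 * 2000)
  expect_gt(tr@scaled$ne[k], 2000 / 2)
  # ... and located inside the true epoch
  expect_gt(tr@scaled$right_years[k], 10000)
  expect_lt(tr@scaled$left_years[k], 30000)
})

test_that("the bootstrap envelope covers constant-Ne truth in mid intervals", {
  skipIfNoBackend()
  sim <- cachedSim("constNe1e4", function() {
    m <- buildDemography(list(
      populations = list(list(name = "A", ne = 10000)),
      mu = 7.9e-9, r = 1e-8, generation_time = 1))
    simulateGenotypes(m, genomeLayout(10, 1e6), 1, seed = 101)
  })
  bins <- binarizeDiploid(sim$genotypes, "A", sim$mask, 100)
  cfg <- smcConfig(bin_size = 100, pattern = "2+6*2+2", t_max = 15,
                   max_iters = 8, rho_ratio = 1e-8 / 7.9e-9)
  reps <- bootstrapSmc(bins, cfg, n_reps = 20, segment_bp = 1e6, seed = 14)
  nes <- sapply(reps, function(r) scaleTrajectory(r, 7.9e-9, 1)@scaled$ne)
  tr <- reps[[1]]
  nG <- max(tr@groups)
  left <- sapply(seq_len(nG), function(g) tr@boundaries[min(which(tr@groups == g))])
  right <- sapply(seq_len(nG), function(g) tr@boundaries[max(which(tr@groups == g)) + 1])
  mid <- left >= 0.2 & right <= 2
  covered <- apply(nes[mid, , drop = FALSE], 1, function(x)
    min(x) <= 10000 && max(x) >= 10000)
  expect_gte(mean(covered), 0.8)
})
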