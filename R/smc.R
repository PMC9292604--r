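## PSMC'-style coalescent HMM: configuration, binarization, EM fitting,
## real-unit scaling and bootstrap. The numerical core (transition matrix
## construction and the forward-backward E-step) is compiled code; the
## M-step maximizes the expected complete-data log-likelihood over grouped
## log-intensities and log-theta with L-BFGS-B, which makes every EM
## iteration a generalized EM step with a non-decreasing observed
## log-likelihood.

#' Parse an atomic-interval pattern
#'
#' Grammar: \code{term(+term)*} with \code{term = n} (one parameter group
#' spanning n atomic intervals) or \code{n*m} (n groups of m atomic
#' intervals each). The classic \code{"4+25*2+4+6"} gives 64 atomic
#' intervals in 28 groups.
#'
#' @param pattern pattern string.
#' @return list with \code{n_atomic} and \code{groups} (integer vector
#'   mapping atomic interval to parameter group).
#' @examples
#' parseIntervalPattern("4+25*2+4+6")
#' @export
parseIntervalPattern <- function(pattern) {
  if (!grepl("^[0-9]+(\\*[0-9]+)?(\\+[0-9]+(\\*[0-9]+)?)*$", pattern))
    stop("malformed interval pattern: ", pattern)
  groups <- integer()
  gid <- 0L
  for (term in strsplit(pattern, "+", fixed = TRUE)[[1]]) {
    parts <- as.integer(strsplit(term, "*", fixed = TRUE)[[1]])
    if (any(parts == 0)) stop("pattern terms must be positive: ", term)
    if (length(parts) == 1) {
      gid <- gid + 1L
      groups <- c(groups, rep(gid, parts))
    } else {
      for (i in seq_len(parts[1])) {
        gid <- gid + 1L
        groups <- c(groups, rep(gid, parts[2]))
      }
    }
  }
  list(n_atomic = length(groups), groups = groups)
}

#' SMC configuration constructor
#'
#' @param bin_size bin width in bp (100 for within-species diploid runs; 10
#'   for pseudo-F1 runs, where divergence would saturate wider bins).
#' @param pattern atomic-interval pattern (see
#'   \code{\link{parseIntervalPattern}}).
#' @param t_max TMRCA upper bound in coalescent units.
#' @param theta_init,rho_init initial per-bin rates (NA = derive from data;
#'   rho is fixed after initialization).
#' @param rho_ratio when not NA, initialize rho as \code{rho_ratio * theta};
#'   use r/mu when the recombination-to-mutation rate ratio is known.
#' @param max_iters,tol,mstep_maxit,min_bins EM controls.
#' @return An \linkS4class{SmcConfig}.
#' @export
smcConfig <- function(bin_size = 100, pattern = "4+25*2+4+6", t_max = 15,
                      theta_init = NA_real_, rho_init = NA_real_,
                      rho_ratio = NA_real_,
                      max_iters = 20, tol = 1e-5, mstep_maxit = 30,
                      min_bins = 10000) {
  new("SmcConfig", bin_size = as.integer(bin_size), pattern = pattern,
      t_max = t_max, theta_init = theta_init, rho_init = rho_init,
      rho_ratio = rho_ratio,
      max_iters = as.integer(max_iters), tol = tol,
      mstep_maxit = as.integer(mstep_maxit), min_bins = as.integer(min_bins))
}

#' Log-spaced time grid boundaries
#'
#' Lower boundaries of n atomic intervals on (0, t_max], using the PSMC
#' spacing T_j = 0.1 (exp(j/n log(1 + 10 t_max)) - 1), which concentrates
#' intervals at recent times.
#'
#' @param n number of atomic intervals.
#' @param t_max upper TMRCA bound (coalescent units).
#' @return Numeric vector of n lower boundaries starting at 0.
#' @export
smcTimeBoundaries <- function(n, t_max) {
  j <- 0:(n - 1)
  0.1 * (exp(j / n * log(1 + 10 * t_max)) - 1)
}

#' Binarize heterozygosity tracks into HMM observation symbols
#'
#' A bin is \code{het} (1) when at least one listed difference position
#' falls in it, \code{missing} (2) when more than half its bases fall
#' outside the callable mask, else \code{no-het} (0).
#'
#' @param positions named list (per scaffold) of 1-based positions carrying
#'   a heterozygote/difference.
#' @param scaffolds scaffold data.frame (\code{name}, \code{length}).
#' @param mask a \linkS4class{CallableMask}.
#' @param bin_size bin width in bp.
#' @return A \linkS4class{BinSequence}.
#' @export
binSequenceFromPositions <- function(positions, scaffolds, mask, bin_size) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  seqs <- list()
  for (i in seq_len(nrow(scaffolds))) {
    sc <- scaffolds$name[i]
    nb <- ceiling(scaffolds$length[i] / bin_size)
    callable <- numeric(nb)
    iv <- mask@intervals[mask@intervals$scaffold == sc, , drop = FALSE]
    for (k in seq_len(nrow(iv))) {
      s <- iv$start[k]; e <- iv$end[k]
      b0 <- floor(s / bin_size); b1 <- floor((e - 1) / bin_size)
      if (b0 == b1) {
        callable[b0 + 1] <- callable[b0 + 1] + (e - s)
      } else {
        callable[b0 + 1] <- callable[b0 + 1] + ((b0 + 1) * bin_size - s)
        callable[b1 + 1] <- callable[b1 + 1] + (e - b1 * bin_size)
        if (b1 > b0 + 1)
          callable[(b0 + 2):b1] <- callable[(b0 + 2):b1] + bin_size
      }
    }
    obs <- integer(nb)
    pos <- positions[[sc]]
    if (!is.null(pos) && length(pos) > 0)
      obs[unique(floor((pos - 1) / bin_size)) + 1] <- 1L
    # trailing partial bin judged against its own width
    widths <- rep(bin_size, nb)
    widths[nb] <- scaffolds$length[i] - (nb - 1) * bin_size
    obs[callable <= 0.5 * widths] <- 2L
    seqs[[sc]] <- obs
  }
  new("BinSequence", sequences = seqs, bin_size = as.integer(bin_size))
}

#' Binarize one diploid sample's heterozygosity track
#'
#' Phase-free: only the positions of heterozygous genotypes matter, so
#' phased and unphased input give identical bin sequences.
#'
#' @param g a diploid \linkS4class{GenotypeTable}.
#' @param sample sample name.
#' @inheritParams binSequenceFromPositions
#' @return A \linkS4class{BinSequence}.
#' @export
binarizeDiploid <- function(g, sample, mask, bin_size = 100) {
  cols <- sampleHaplotypeColumns(g, sample)
  het <- g@haplotypes[, cols[1]] != g@haplotypes[, cols[2]]
  positions <- split(g@sites$pos[het], g@sites$scaffold[het])
  binSequenceFromPositions(positions, g@scaffolds, mask, bin_size)
}

nonMissingBins <- function(bs) sum(vapply(bs@sequences, function(s)
  sum(s != 2L), numeric(1)))

#' Fit the coalescent HMM by EM
#'
#' Baum-Welch with per-parameter-group coalescence intensities. theta is
#' initialized from the genome-wide heterozygous-bin fraction and
#' re-estimated each iteration; rho is fixed after initialization. The
#' total log-likelihood is non-decreasing across iterations and the fit is
#' deterministic given its inputs.
#'
#' @param seqs a \linkS4class{BinSequence}.
#' @param cfg an \linkS4class{SmcConfig}.
#' @param verbose print per-iteration log-likelihoods.
#' @return An \linkS4class{SmcTrajectory} (unscaled; see
#'   \code{\link{scaleTrajectory}}).
#' @export
fitSmc <- function(seqs, cfg = smcConfig(), verbose = FALSE) {
  stopifnot(is(seqs, "BinSequence"), is(cfg, "SmcConfig"))
  if (seqs@bin_size != cfg@bin_size)
    stop("bin size of sequences and config disagree")
  obs <- unname(seqs@sequences)
  nOk <- nonMissingBins(seqs)
  if (nOk < cfg@min_bins)
    stop("too few non-missing bins for a stable fit: ", nOk)
  nHet <- sum(vapply(obs, function(s) sum(s == 1L), numeric(1)))
  if (nHet == 0) stop("degenerate input: no heterozygous bins at all")

  pat <- parseIntervalPattern(cfg@pattern)
  n <- pat$n_atomic
  groups <- pat$groups
  nG <- max(groups)
  bounds <- smcTimeBoundaries(n, cfg@t_max)

  h <- nHet / nOk
  theta <- if (is.na(cfg@theta_init)) -log(1 - h) else cfg@theta_init
  rho <- if (!is.na(cfg@rho_ratio)) cfg@rho_ratio * theta
         else if (is.na(cfg@rho_init)) theta else cfg@rho_init
  lambdaG <- rep(1, nG)

  Qfun <- function(par, es) {
    lam <- exp(par[groups])
    th <- exp(par[nG + 1])
    m <- .smcModel(bounds, lam, rho, th)
    P <- pmax(m$P, 1e-300)
    prior <- pmax(m$prior, 1e-300)
    e <- pmin(pmax(m$ehet, 1e-300), 1 - 1e-12)
    sum(es$xi * log(P)) + sum(es$gamma1 * log(prior)) +
      sum(es$het * log(e)) + sum(es$hom * log1p(-e))
  }

  llTrace <- numeric()
  for (it in seq_len(cfg@max_iters)) {
    m <- .smcModel(bounds, lambdaG[groups], rho, theta)
    es <- .smcEstep(obs, m$P, m$prior, m$ehet, TRUE)
    llTrace <- c(llTrace, es$loglik)
    if (verbose) message(sprintf("EM iter %d: loglik %.4f", it, es$loglik))
    if (it > 1 &&
        (llTrace[it] - llTrace[it - 1]) < cfg@tol * abs(llTrace[it - 1]))
      break
    if (it == cfg@max_iters) break
    par0 <- c(log(lambdaG), log(theta))
    q0 <- Qfun(par0, es)
    opt <- stats::optim(par0, Qfun, es = es, method = "L-BFGS-B",
                        lower = rep(c(-7, log(theta) - 3), c(nG, 1)),
                        upper = rep(c(7, log(theta) + 3), c(nG, 1)),
                        control = list(fnscale = -1,
                                       maxit = cfg@mstep_maxit))
    if (opt$value > q0) { # generalized EM: only accept improvements of Q
      lambdaG <- exp(opt$par[seq_len(nG)])
      theta <- exp(opt$par[nG + 1])
    }
  }

  new("SmcTrajectory", boundaries = c(bounds, cfg@t_max),
      groups = groups, lambda = lambdaG, theta = theta, rho = rho,
      bin_size = cfg@bin_size, loglik = llTrace,
      scaled = data.frame())
}

#' Scale a trajectory to years and diploid Ne
#'
#' The fitted per-bin theta fixes the reference size N0 = theta / (4 mu
#' bin_size); interval boundaries (coalescent units of 2 N0 generations)
#' become years through the generation time, and each group's Ne is N0 /
#' lambda.
#'
#' @param traj an \linkS4class{SmcTrajectory}.
#' @param mu mutation rate per site per generation.
#' @param gen_time generation time in years.
#' @return The trajectory with its \code{scaled} table filled in.
#' @export
scaleTrajectory <- function(traj, mu, gen_time) {
  stopifnot(mu > 0, gen_time > 0)
  if (traj@theta <= 0) stop("zero theta: cannot scale")
  n0 <- traj@theta / (4 * mu * traj@bin_size)
  nG <- max(traj@groups)
  left <- vapply(seq_len(nG), function(g)
    traj@boundaries[min(which(traj@groups == g))], numeric(1))
  right <- vapply(seq_len(nG), function(g)
    traj@boundaries[max(which(traj@groups == g)) + 1], numeric(1))
  out <- traj
  out@scaled <- data.frame(
    group = seq_len(nG),
    left_years = left * 2 * n0 * gen_time,
    right_years = right * 2 * n0 * gen_time,
    ne = n0 / traj@lambda)
  out
}

#' Reference size N0 implied by a fitted trajectory
#' @param traj an \linkS4class{SmcTrajectory}.
#' @param mu mutation rate per site per generation.
#' @return Diploid N0.
#' @export
smcN0 <- function(traj, mu) traj@theta / (4 * mu * traj@bin_size)

#' Block bootstrap over fixed-length genome segments
#'
#' Resamples the binarized genome with replacement in segments of
#' \code{segment_bp} until the original total length is reached, refits
#' each replicate, and returns the list of trajectories. Seeded and
#' deterministic. \code{resample = FALSE} refits the original data
#' (identity replicates).
#'
#' @inheritParams fitSmc
#' @param n_reps number of replicates.
#' @param segment_bp segment length in bp.
#' @param seed integer seed.
#' @param resample logical.
#' @return List of \linkS4class{SmcTrajectory} objects.
#' @export
bootstrapSmc <- function(seqs, cfg = smcConfig(), n_reps = 20,
                         segment_bp = 5e6, seed = 1, resample = TRUE) {
  stopifnot(n_reps >= 1)
  segBins <- max(1L, as.integer(segment_bp / seqs@bin_size))
  segments <- list()
  for (s in seqs@sequences) {
    starts <- seq(1, length(s), by = segBins)
    for (st in starts)
      segments[[length(segments) + 1]] <-
        s[st:min(st + segBins - 1, length(s))]
  }
  if (length(segments) == 0) stop("no segments: segment longer than genome?")
  totalBins <- sum(lengths(seqs@sequences))
  if (segBins > totalBins) stop("segment longer than the genome")
  lapply(seq_len(n_reps), function(r) {
    reseq <- if (!resample) seqs else withSeed(deriveSeed(seed, "boot", r), {
      picked <- list()
      tot <- 0
      while (tot < totalBins) {
        k <- sample.int(length(segments), 1)
        picked[[length(picked) + 1]] <- segments[[k]]
        tot <- tot + length(segments[[k]])
      }
      names(picked) <- sprintf("seg_%d", seq_along(picked))
      new("BinSequence", sequences = picked, bin_size = seqs@bin_size)
    })
    fitSmc(reseq, cfg)
  })
}

#' Write a scaled trajectory as TSV
#' @param traj a scaled \linkS4class{SmcTrajectory}.
#' @param path output path.
#' @param header_extra optional comment lines.
#' @export
writeTrajectory <- function(traj, path, header_extra = character()) {
  if (nrow(traj@scaled) == 0) stop("scale the trajectory first")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_extra)) writeLines(paste0("# ", header_extra), con)
  utils::write.table(traj@scaled[, c("left_years", "right_years", "ne")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
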