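#' Derive a reproducible stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from a single
#' global seed plus a stage label, so that one integer reproduces a whole run
#' while stages stay statistically independent of each other.
#'
#' @param seed Integer global seed.
#' @param stage Character label of the stage (e.g. \code{"dstat"}).
#' @param index Optional replicate index mixed into the hash.
#' @return A positive integer seed below 2^31.
#' @export
deriveSeed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(paste0(stage, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  val <- (as.numeric(seed) %% 2147483647) * 48271 + h
  as.integer(val %% 2147483629) + 1L
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so package internals never
#' perturb user-level random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Expected SNP accumulation since a bottleneck
#'
#' Back-of-envelope bound on the number of new heterozygous sites expected to
#' accumulate on a diploid genome since a bottleneck: two lineages each
#' mutating at rate \code{mu} per site per generation over
#' \code{years / generation_time} generations, expressed per \code{span_bp}
#' base pairs.
#'
#' @param mu Mutation rate per site per generation.
#' @param years Time since the bottleneck, in years.
#' @param generation_time Generation time in years.
#' @param span_bp Window size in base pairs the count is expressed over.
#' @return Expected SNP count per \code{span_bp}.
#' @examples
#' snpAccumulation(7.9e-9, 200000, 24, 10000)
#' @export
snpAccumulation <- function(mu, years, generation_time, span_bp = 10000) {
  stopifnot(mu >= 0, years >= 0, generation_time > 0, span_bp > 0)
  2 * mu * (years / generation_time) * span_bp
}

geomMean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
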