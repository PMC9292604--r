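## Model construction and interrogation for isolation-with-migration
## demographies. Times are generations before present and increase into the
## past; population sizes are diploid Ne.

# Existence windows for every population name (extant and ancestral):
# t0 = creation time (0 for extant), t1 = time it merges into an ancestor
# (Inf for the final root population).
popWindows <- function(model) {
  s <- model@splits
  nm <- c(model@populations$name, s$ancestral)
  t0 <- c(rep(0, nrow(model@populations)), s$time)
  t1 <- rep(Inf, length(nm))
  for (i in seq_len(nrow(s))) {
    for (child in c(s$childA[i], s$childB[i])) {
      j <- match(child, nm)
      if (!is.na(j)) t1[j] <- s$time[i]
    }
  }
  data.frame(name = nm, t0 = t0, t1 = t1, stringsAsFactors = FALSE)
}

# Chain of (time, container) pairs a population's lineage passes through.
ancestorChain <- function(model, name) {
  s <- model@splits
  w <- popWindows(model)
  if (!name %in% w$name) return(NULL)
  chain <- data.frame(time = w$t0[match(name, w$name)], container = name,
                      stringsAsFactors = FALSE)
  cur <- name
  repeat {
    i <- which(s$childA == cur | s$childB == cur)
    if (length(i) == 0) break
    i <- i[which.min(s$time[i])]
    cur <- s$ancestral[i]
    chain <- rbind(chain, data.frame(time = s$time[i], container = cur))
  }
  chain
}

mergeTimeTable <- function(model) popWindows(model)

# Time at which the lineages of two population names find a common
# container; NA if either name is unknown.
pairMergeTime <- function(windows, model, a, b) {
  if (!(a %in% windows$name) || !(b %in% windows$name)) return(NA_real_)
  if (a == b) return(0)
  ca <- ancestorChain(model, a)
  cb <- ancestorChain(model, b)
  common <- intersect(ca$container, cb$container)
  if (length(common) == 0) return(Inf)
  min(vapply(common, function(cc) {
    max(ca$time[match(cc, ca$container)], cb$time[match(cc, cb$container)])
  }, numeric(1)))
}

#' Build and validate a demographic model
#'
#' Accepts a structured configuration (a nested list, or the path of a YAML
#' file with the same structure) describing populations, splits, migration
#' epochs and admixture pulses, and returns a validated
#' \linkS4class{DemographicModel}. Split times may be given directly in
#' generations (\code{time}) or as ages in Ma (\code{age_ma}), which are
#' converted using \code{generation_time} (years).
#'
#' @param config nested list or YAML file path with entries
#'   \code{populations} (list of \code{list(name, ne)}), \code{splits},
#'   \code{migrations}, \code{pulses}, \code{mu}, \code{r} and
#'   \code{generation_time} (single number or named per population).
#' @return A \linkS4class{DemographicModel}.
#' @examples
#' m <- buildDemography(list(
#'   populations = list(list(name = "A", ne = 10000),
#'                      list(name = "B", ne = 10000)),
#'   splits = list(list(time = 10000, childA = "A", childB = "B",
#'                      ancestral = "AB", ne = 10000)),
#'   mu = 7.9e-9, r = 1e-8, generation_time = 24))
#' @export
buildDemography <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$populations) || length(config$populations) == 0)
    stop("config must name at least one population")

  pops <- do.call(rbind, lapply(config$populations, function(p)
    data.frame(name = as.character(p$name), ne = as.numeric(p$ne),
               stringsAsFactors = FALSE)))

  gt <- config$generation_time %||% 1
  if (is.null(names(gt)) || length(gt) == 1L) {
    gtv <- stats::setNames(rep(as.numeric(gt)[1], nrow(pops)), pops$name)
  } else {
    gtv <- unlist(gt)
    missing <- setdiff(pops$name, names(gtv))
    if (length(missing)) stop("no generation time for: ",
                              paste(missing, collapse = ", "))
    gtv <- gtv[pops$name]
  }

  cvtTime <- function(entry) {
    if (!is.null(entry$time)) return(as.numeric(entry$time))
    if (!is.null(entry$age_ma)) {
      g <- if (!is.null(entry$generation_time)) as.numeric(entry$generation_time)
           else mean(gtv)
      return(entry$age_ma * 1e6 / g)
    }
    stop("split/epoch needs a 'time' (generations) or 'age_ma'")
  }

  splits <- if (length(config$splits %||% list()) == 0)
    data.frame(time = numeric(), childA = character(), childB = character(),
               ancestral = character(), ne = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, lapply(config$splits, function(s)
    data.frame(time = cvtTime(s), childA = as.character(s$childA),
               childB = as.character(s$childB),
               ancestral = as.character(s$ancestral), ne = as.numeric(s$ne),
               stringsAsFactors = FALSE)))
  splits <- splits[order(splits$time), , drop = FALSE]
  rownames(splits) <- NULL

  migrations <- if (length(config$migrations %||% list()) == 0)
    data.frame(pop1 = character(), pop2 = character(), rate = numeric(),
               start = numeric(), end = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, lapply(config$migrations, function(m)
    data.frame(pop1 = as.character(m$pop1), pop2 = as.character(m$pop2),
               rate = as.numeric(m$rate), start = as.numeric(m$start),
               end = as.numeric(m$end),
               direction = as.character(m$direction %||% "both"),
               stringsAsFactors = FALSE)))

  pulses <- if (length(config$pulses %||% list()) == 0)
    data.frame(time = numeric(), from = character(), to = character(),
               fraction = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, lapply(config$pulses, function(p)
    data.frame(time = as.numeric(p$time), from = as.character(p$from),
               to = as.character(p$to), fraction = as.numeric(p$fraction),
               stringsAsFactors = FALSE)))

  size_changes <- if (length(config$size_changes %||% list()) == 0)
    data.frame(pop = character(), time = numeric(), ne = numeric(),
               stringsAsFactors = FALSE)
  else do.call(rbind, lapply(config$size_changes, function(s)
    data.frame(pop = as.character(s$pop), time = cvtTime(s),
               ne = as.numeric(s$ne), stringsAsFactors = FALSE)))

  model <- new("DemographicModel", populations = pops, splits = splits,
               migrations = migrations, pulses = pulses,
               size_changes = size_changes,
               mu = as.numeric(config$mu %||% 7.9e-9),
               r = as.numeric(config$r %||% 1e-8),
               generation_time = gtv)

  # referenced names must exist and epochs must respect existence windows
  w <- popWindows(model)
  refs <- c(splits$childA, splits$childB, migrations$pop1, migrations$pop2,
            pulses$from, pulses$to, size_changes$pop)
  unknown <- setdiff(refs, w$name)
  if (length(unknown)) stop("unknown population(s): ",
                            paste(unique(unknown), collapse = ", "))
  for (i in seq_len(nrow(migrations))) {
    t1 <- min(w$t1[match(migrations$pop1[i], w$name)],
              w$t1[match(migrations$pop2[i], w$name)])
    if (migrations$end[i] > t1)
      stop(sprintf("migration epoch %s-%s extends past a merge at %g generations",
                   migrations$pop1[i], migrations$pop2[i], t1))
  }
  model
}

#' Default five-species sea-turtle demographic model
#'
#' A desk-scale isolation-with-migration truth model for the five globally
#' distributed sea turtle species: olive ridley (OL), loggerhead (LL),
#' hawksbill (HH), green (GG) and leatherback (DC, the outgroup). Split ages
#' follow nuclear strict-clock dates (15.5, 18.3, 40.5 and 76.5 Ma),
#' ancestral sizes the pre-divergence plateaus inferred from pseudo-F1
#' trajectories (roughly 1.1-2.1e5), a 24-year generation time, mutation
#' rate 7.9e-9 per site per generation and recombination rate 1e-8.
#'
#' @param ne diploid Ne of each extant species.
#' @param migrations,pulses optional epoch/pulse lists as in
#'   \code{\link{buildDemography}}.
#' @param time_scale multiplier on all split ages: \code{time_scale < 1}
#'   gives a shallower history with the same topology and relative node
#'   depths, convenient for replicate-heavy calibration studies where the
#'   full 76.5 Ma history would dominate run time.
#' @param anc_scale multiplier on the ancestral population sizes.
#' @param mu,r mutation and recombination rates per site per generation.
#' @return A \linkS4class{DemographicModel}.
#' @export
defaultTurtleModel <- function(ne = 50000, migrations = list(),
                               pulses = list(), time_scale = 1,
                               anc_scale = 1, mu = 7.9e-9, r = 1e-8) {
  buildDemography(list(
    populations = list(
      list(name = "OL", ne = ne), list(name = "LL", ne = ne),
      list(name = "HH", ne = ne), list(name = "GG", ne = ne),
      list(name = "DC", ne = ne)),
    splits = list(
      list(age_ma = 15.5 * time_scale, childA = "OL", childB = "LL",
           ancestral = "ancOLLL", ne = 110000 * anc_scale),
      list(age_ma = 18.3 * time_scale, childA = "ancOLLL", childB = "HH",
           ancestral = "ancCarettini", ne = 115000 * anc_scale),
      list(age_ma = 40.5 * time_scale, childA = "ancCarettini",
           childB = "GG", ancestral = "ancCheloniidae",
           ne = 200000 * anc_scale),
      list(age_ma = 76.5 * time_scale, childA = "ancCheloniidae",
           childB = "DC", ancestral = "ancChelonioidea",
           ne = 200000 * anc_scale)),
    migrations = migrations, pulses = pulses,
    mu = mu, r = r, generation_time = 24))
}

#' Default genome layout
#'
#' @param n_scaffolds,scaffold_length scaffold count and length in bp.
#' @param mito_length mito-surrogate locus length (bp); 0 disables.
#' @param mito_ne_scale Ne scaling for the mito locus (default 1/4).
#' @param mito_migration whether migration also applies to the mito locus.
#' @return A \linkS4class{GenomeLayout}.
#' @export
genomeLayout <- function(n_scaffolds = 4, scaffold_length = 5e6,
                         mito_length = 0, mito_ne_scale = 0.25,
                         mito_migration = TRUE) {
  new("GenomeLayout",
      scaffolds = data.frame(
        name = sprintf("scaffold_%d", seq_len(n_scaffolds)),
        length = rep(as.numeric(scaffold_length), n_scaffolds),
        stringsAsFactors = FALSE),
      mito_length = as.numeric(mito_length),
      mito_ne_scale = mito_ne_scale, mito_migration = mito_migration)
}

#' Rooted species tree implied by a model's splits
#'
#' @param model a \linkS4class{DemographicModel} whose splits join all
#'   populations into one root.
#' @return A rooted binary \code{phylo} with the extant populations as tips.
#' @export
speciesTreeFromModel <- function(model) {
  s <- model@splits
  if (nrow(s) == 0) stop("model has no splits: no tree to build")
  nk <- stats::setNames(as.list(model@populations$name),
                        model@populations$name)
  for (i in seq_len(nrow(s))) {
    nk[[s$ancestral[i]]] <- paste0("(", nk[[s$childA[i]]], ",",
                                   nk[[s$childB[i]]], ")")
  }
  root <- s$ancestral[nrow(s)]
  ape::read.tree(text = paste0(nk[[root]], ";"))
}

#' Ground-truth divergence and gene-flow cessation times
#'
#' Builds the \linkS4class{TruthRecord} for a model: for every pair of
#' extant populations, the true split time and the true end of gene flow
#' (the most recent time any migration epoch or pulse connected their
#' lineages; equal to the split time when there was none).
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param seed the simulation seed to echo.
#' @return A \linkS4class{TruthRecord}.
#' @export
truthRecord <- function(model, seed = NA_integer_) {
  pops <- model@populations$name
  w <- popWindows(model)
  if (length(pops) < 2) {
    empty <- data.frame(pop1 = character(), pop2 = character(),
                        time = numeric(), stringsAsFactors = FALSE)
    return(new("TruthRecord", model = model, divergence = empty,
               cessation = empty, seed = as.integer(seed)))
  }
  pairs <- utils::combn(pops, 2)
  div <- ces <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tdiv <- pairMergeTime(w, model, a, b)
    ca <- ancestorChain(model, a)$container
    cb <- ancestorChain(model, b)$container
    flowTimes <- numeric()
    m <- model@migrations
    for (i in seq_len(nrow(m))) {
      x <- m$pop1[i]; y <- m$pop2[i]
      if ((x %in% ca && y %in% cb) || (x %in% cb && y %in% ca))
        if (m$start[i] < tdiv) flowTimes <- c(flowTimes, m$start[i])
    }
    pu <- model@pulses
    for (i in seq_len(nrow(pu))) {
      x <- pu$from[i]; y <- pu$to[i]
      if ((x %in% ca && y %in% cb) || (x %in% cb && y %in% ca))
        if (pu$time[i] < tdiv) flowTimes <- c(flowTimes, pu$time[i])
    }
    div[k] <- tdiv
    ces[k] <- if (length(flowTimes)) min(flowTimes) else tdiv
  }
  new("TruthRecord", model = model,
      divergence = data.frame(pop1 = pairs[1, ], pop2 = pairs[2, ],
                              time = div, stringsAsFactors = FALSE),
      cessation = data.frame(pop1 = pairs[1, ], pop2 = pairs[2, ],
                             time = ces, stringsAsFactors = FALSE),
      seed = as.integer(seed))
}

#' Write a truth record as JSON
#' @param truth a \linkS4class{TruthRecord}.
#' @param path output file path.
#' @export
writeTruthRecord <- function(truth, path) {
  jsonlite::write_json(list(
    seed = truth@seed,
    mu = truth@model@mu, r = truth@model@r,
    populations = truth@model@populations,
    splits = truth@model@splits,
    migrations = truth@model@migrations,
    pulses = truth@model@pulses,
    generation_time = as.list(truth@model@generation_time),
    divergence = truth@divergence,
    cessation = truth@cessation), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
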