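# R-side driver for the compiled Wright-Fisher simulator.

optModeCode <- function(mode) match(mode, c("none", "instant", "gradual")) - 1L

# list handed to the C++ core; shiftGen is absolute (optimum applies for
# generations strictly greater than it)
asCppConfig <- function(config, shiftGen = config@burnIn) {
  list(N = config@N, L = config@L, bufferLen = config@bufferLen,
       geneLen = config@geneLen, mu = config@mu, rec = config@rec,
       fracNeutral = config@fracNeutral,
       fracDeleterious = config@fracDeleterious,
       fracTrait = config@fracTrait, selfing = config@selfing,
       nTraits = config@nTraits, effectSd = config@effectSd,
       Vs = config@Vs, sDel = config@sDel, hDel = config@hDel,
       optMode = optModeCode(config@optMode), shiftGen = as.integer(shiftGen))
}

asCppPop <- function(pop) {
  mut <- pop@mutations
  sub <- pop@substitutions
  list(haplotypes = pop@haplotypes,
       mutations = list(id = as.integer(mut$id),
                        position = as.integer(mut$position),
                        class = classToCode(mut$class),
                        origin = as.integer(mut$origin)),
       effects = pop@effects,
       substitutions = list(id = as.integer(sub$id),
                            position = as.integer(sub$position),
                            class = classToCode(sub$class),
                            origin = as.integer(sub$origin),
                            fixed = as.integer(sub$fixed)),
       subEffects = pop@subEffects,
       generation = pop@generation)
}

fromCppPop <- function(cpop, config) {
  mut <- cpop$mutations
  sub <- cpop$substitutions
  new("Population",
      haplotypes = cpop$haplotypes,
      mutations = data.frame(id = mut$id, position = mut$position,
                             class = codeToClass(mut$class),
                             origin = mut$origin),
      effects = cpop$effects,
      substitutions = data.frame(id = sub$id, position = sub$position,
                                 class = codeToClass(sub$class),
                                 origin = sub$origin, fixed = sub$fixed),
      subEffects = cpop$subEffects,
      generation = as.integer(cpop$generation),
      optimum = cpop$optimum,
      zSub = cpop$zSub,
      nSubDel = as.integer(cpop$nSubDel),
      config = config)
}

#' Optimum trajectory
#'
#' Per-trait optimum at a generation: 0 through the burn-in, then (in
#' instant mode) \eqn{1/\sqrt{n}} on every trait from the generation after
#' the shift, or (gradual mode) a linear ramp in 100 equal increments of
#' \eqn{1/(100\sqrt n)}.  The \eqn{1/\sqrt n} magnitude makes the initial
#' fitness drop identical for every pleiotropy degree, since per-trait
#' effect variance scales as \eqn{1/n}.
#'
#' @param generation generation(s), with the shift occurring after
#'   `config@burnIn`
#' @param config a [SimulationConfig-class]
#' @return the per-trait optimum value at each generation
#' @examples
#' cfg <- simulationConfig(N = 100, burnIn = 1000, optMode = "gradual")
#' optimumAt(c(1000, 1050, 1200), cfg)
#' @export
optimumAt <- function(generation, config) {
  cpp_optimum_at(as.integer(generation), asCppConfig(config))
}

statsColumnNames <- function(n) {
  per <- function(stem) paste0(stem, seq_len(n))
  c("gen", "meanFitness", "varFitness", "inbreedingDepression",
    "segTrait", "segNeutral", "segDeleterious", "fHat",
    per("meanZ"), per("VG"), per("Vg"), per("VI"), per("CLD"))
}

#' Run the forward simulator
#'
#' Executes `generations` generations of Wright-Fisher reproduction with
#' viability selection, partial selfing and the configured optimum
#' schedule, starting from a mutation-free population (or from `init`).
#' Summary statistics (mean/variance of fitness, optional
#' inbreeding-depression assay, segregating-site counts, excess
#' homozygosity, and the per-trait variance decomposition VG/Vg/VI/CLD)
#' are recorded every `statsIntervalPre` generations up to the shift and
#' every `statsIntervalPost` afterwards; full population snapshots are
#' taken at `snapshotGens` (default: the generation of the shift and 40,
#' 300 and 1000 generations after it, clamped to the run length).
#'
#' Determinism: all randomness comes from R's RNG, so `set.seed()` before
#' the call makes the run reproducible bit-for-bit.
#'
#' @param config a [SimulationConfig-class]
#' @param generations total generations (default burn-in + post-shift)
#' @param init optional starting [Population-class] (its generation counter
#'   carries on)
#' @param statsGens explicit statistics generations, overriding the cadence
#' @param snapshotGens generations at which to keep full snapshots
#' @param idStream record the inbreeding-depression assay at every
#'   statistics generation (two cohorts of `idSize` offspring)
#' @param idSize cohort size for the assay
#' @param maxPopGenome resource guard: error if N * L exceeds this
#' @return a [SimulationResult-class]
#' @examples
#' cfg <- deskConfig(N = 50, L = 50e3, burnIn = 100, postGens = 20,
#'                   statsIntervalPre = 50, statsIntervalPost = 10)
#' set.seed(1)
#' res <- runSimulation(cfg)
#' tail(simStats(res))
#' @export
runSimulation <- function(config, generations = config@burnIn + config@postGens,
                          init = NULL, statsGens = NULL, snapshotGens = NULL,
                          idStream = FALSE, idSize = 500L,
                          maxPopGenome = 2e12) {
  stopifnot(is(config, "SimulationConfig"))
  if (as.double(config@N) * config@L > maxPopGenome)
    stop("N * L exceeds the configured resource budget (maxPopGenome)")
  g0 <- if (is.null(init)) 0L else init@generation
  gEnd <- g0 + as.integer(generations)
  shift <- config@burnIn
  if (is.null(statsGens)) {
    pre <- seq(g0, min(shift, gEnd), by = max(1L, config@statsIntervalPre))
    post <- if (gEnd > shift)
      seq(shift, gEnd, by = max(1L, config@statsIntervalPost)) else integer()
    statsGens <- sort(unique(c(pre, post, shift, gEnd)))
    statsGens <- statsGens[statsGens >= g0 & statsGens <= gEnd]
  }
  if (is.null(snapshotGens)) {
    snapshotGens <- unique(pmin(c(shift, shift + c(40L, 300L, 1000L)), gEnd))
    snapshotGens <- snapshotGens[snapshotGens >= g0]
  }
  res <- cpp_simulate(asCppConfig(config),
                      if (is.null(init)) NULL else asCppPop(init),
                      as.integer(generations),
                      as.integer(statsGens), as.integer(snapshotGens),
                      idStream, as.integer(idSize))
  stats <- as.data.frame(res$stats)
  names(stats) <- statsColumnNames(config@nTraits)
  new("SimulationResult", stats = stats,
      snapshots = lapply(res$snapshots, fromCppPop, config = config),
      final = fromCppPop(res$final, config), config = config)
}

#' Advance a population by one (or more) generations
#'
#' @param pop a [Population-class]
#' @param generations number of generations
#' @return the advanced [Population-class]
#' @export
nextGeneration <- function(pop, generations = 1L) {
  res <- cpp_simulate(asCppConfig(pop@config, shiftGenOf(pop)), asCppPop(pop),
                      as.integer(generations), integer(), integer(),
                      FALSE, 0L)
  fromCppPop(res$final, pop@config)
}

# populations advanced from a snapshot keep the config's absolute schedule
shiftGenOf <- function(pop) pop@config@burnIn

#' Individual fitness components
#'
#' Trait values (additive over mutations, homozygotes counting twice, plus
#' twice the summed effects of fixed substitutions) and the resulting
#' fitness \eqn{w = w_q w_d} with
#' \eqn{w_q = \exp(-\tfrac12\sum_i (z_i - z_{0,i})^2 / V_s)} and
#' \eqn{w_d = (1-h|s|)^{n_{het}} (1-|s|)^{n_{hom}}} over deleterious sites.
#'
#' @param pop a [Population-class]
#' @return data.frame with fitness `w` and one `z` column per trait;
#'   attribute `optimum` holds the per-trait optimum used
#' @export
individualFitness <- function(pop) {
  res <- cpp_individual_fitness(asCppPop(pop), asCppConfig(pop@config,
                                                           shiftGenOf(pop)))
  out <- data.frame(w = res$w)
  z <- res$z
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  out <- cbind(out, as.data.frame(z))
  attr(out, "optimum") <- res$optimum
  out
}

#' Draw one meiotic product from a parent
#'
#' Poisson-distributed crossovers at rate `rec * (L-1)` per meiosis,
#' alternating parental haplotypes between breakpoints, plus (if `mutate`)
#' Poisson(`mu * L`) new mutations at uniform positions, classed by region
#' (buffer: neutral; gene: the configured class split).  A new mutation
#' landing on an occupied site is discarded.
#'
#' @param pop a [Population-class]
#' @param parent parent index (1..N)
#' @param mutate add new mutations?
#' @return list with `inherited` (rows of the parent population's mutation
#'   table) and `newPositions`, `newClasses`, `newEffects` for de-novo
#'   mutations
#' @export
makeGamete <- function(pop, parent, mutate = TRUE) {
  res <- cpp_make_gamete(asCppPop(pop), asCppConfig(pop@config,
                                                    shiftGenOf(pop)),
                         as.integer(parent), mutate)
  res$newClasses <- codeToClass(res$newClasses)
  res
}
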