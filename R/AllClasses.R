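# S4 containers for the two-locus engine, the multi-locus theory and the
# forward simulator.

hapNames <- c("ab", "Ab", "aB", "AB")

#' Two-locus model parameters
#'
#' Scaled parameters of the two-locus stabilising-selection model under
#' partial selfing.  Effects and distances are scaled by \eqn{\sqrt{V_s}}:
#' \eqn{\gamma_A = \alpha_A/\sqrt{V_s}}, \eqn{d_0 = z_0/\sqrt{V_s}}, so the
#' Gaussian fitness of a genotype with \eqn{n_A, n_B} mutant alleles is
#' \eqn{\exp(-(\gamma_A n_A + \gamma_B n_B - d_0)^2/2)}.
#'
#' @slot gammaA,gammaB scaled allelic effects (dimensionless)
#' @slot r recombination fraction in \[0, 0.5\]
#' @slot sigma selfing fraction in \[0, 1\]
#' @slot F inbreeding coefficient in \[0, 1\]; defaults to the neutral
#'   equilibrium value \eqn{\sigma/(2-\sigma)}
#' @slot d0 scaled distance of the (wildtype) phenotype to the optimum
#' @export
setClass("TwoLocusParams",
         representation(gammaA = "numeric", gammaB = "numeric", r = "numeric",
                        sigma = "numeric", F = "numeric", d0 = "numeric"),
         validity = function(object) {
           msg <- character()
           if (object@r < 0 || object@r > 0.5)
             msg <- c(msg, "r must lie in [0, 0.5]")
           if (object@sigma < 0 || object@sigma > 1)
             msg <- c(msg, "sigma must lie in [0, 1]")
           if (object@F < 0 || object@F > 1)
             msg <- c(msg, "F must lie in [0, 1]")
           if (length(msg)) msg else TRUE
         })

#' @param gammaA,gammaB scaled allelic effects
#' @param r recombination fraction
#' @param sigma selfing fraction
#' @param F inbreeding coefficient; `NULL` for \eqn{\sigma/(2-\sigma)}
#' @param d0 scaled distance to the optimum
#' @return a `TwoLocusParams` object
#' @examples
#' twoLocusParams(gammaA = 0.1, gammaB = 0.1, r = 0.5, sigma = 0.9)
#' @rdname TwoLocusParams-class
#' @export
twoLocusParams <- function(gammaA = 0, gammaB = 0, r = 0.5, sigma = 0,
                           F = NULL, d0 = 0) {
  if (is.null(F)) F <- sigma / (2 - sigma)
  new("TwoLocusParams", gammaA = gammaA, gammaB = gammaB, r = r,
      sigma = sigma, F = F, d0 = d0)
}

#' Two-locus haplotype state
#'
#' Frequencies of the four haplotypes ab, Ab, aB, AB.  A 4x4 matrix of
#' ordered genotype frequencies may be attached (slot `G`); the exact
#' recursion keeps it so that departures from the inbreeding-coefficient
#' approximation are carried between generations.
#'
#' @slot x haplotype frequencies (ab, Ab, aB, AB), summing to one
#' @slot G 4x4 ordered genotype frequency matrix, or a 0x0 matrix if unset
#' @export
setClass("TwoLocusState",
         representation(x = "numeric", G = "matrix"),
         validity = function(object) {
           msg <- character()
           if (length(object@x) != 4)
             msg <- c(msg, "x must have length 4")
           else {
             if (abs(sum(object@x) - 1) > 1e-8)
               msg <- c(msg, "haplotype frequencies must sum to 1")
             if (any(object@x < -1e-12) || any(object@x > 1 + 1e-12))
               msg <- c(msg, "haplotype frequencies must lie in [0, 1]")
           }
           if (nrow(object@G) > 0) {
             if (!all(dim(object@G) == c(4, 4)))
               msg <- c(msg, "G must be 4x4")
             else if (abs(sum(object@G) - 1) > 1e-8)
               msg <- c(msg, "genotype frequencies must sum to 1")
           }
           if (length(msg)) msg else TRUE
         })

#' @param x haplotype frequencies (ab, Ab, aB, AB); alternatively give
#'   `pA`, `pB` and `delta`
#' @param pA,pB allele frequencies of A and B
#' @param delta linkage disequilibrium \eqn{\delta}
#' @return a `TwoLocusState`
#' @examples
#' twoLocusState(pA = 0.01, pB = 0.01, delta = 0)
#' @rdname TwoLocusState-class
#' @export
twoLocusState <- function(x = NULL, pA = NULL, pB = NULL, delta = 0) {
  if (is.null(x)) {
    qA <- 1 - pA; qB <- 1 - pB
    x <- c(qA * qB + delta, pA * qB - delta, qA * pB - delta,
           pA * pB + delta)
  }
  x <- setNames(as.numeric(x), hapNames)
  new("TwoLocusState", x = x, G = matrix(numeric(0), 0, 0))
}

#' @param state a `TwoLocusState`
#' @return `alleleFreqA`/`alleleFreqB`: allele frequencies; `ld`: the
#'   linkage disequilibrium \eqn{\delta = x_4 - p_A p_B}
#' @rdname TwoLocusState-class
#' @export
alleleFreqA <- function(state) unname(state@x[2] + state@x[4])

#' @rdname TwoLocusState-class
#' @export
alleleFreqB <- function(state) unname(state@x[3] + state@x[4])

#' @rdname TwoLocusState-class
#' @export
ld <- function(state) unname(state@x[4] - alleleFreqA(state) * alleleFreqB(state))

setMethod("show", "TwoLocusState", function(object) {
  cat("TwoLocusState\n")
  print(round(object@x, 6))
  cat(sprintf("pA = %.6g, pB = %.6g, delta = %.6g%s\n",
              alleleFreqA(object), alleleFreqB(object), ld(object),
              if (nrow(object@G)) " (genotype table attached)" else ""))
})

setMethod("show", "TwoLocusParams", function(object) {
  cat(sprintf(paste0("TwoLocusParams: gammaA = %g, gammaB = %g, r = %g, ",
                     "sigma = %g, F = %g, d0 = %g\n"),
              object@gammaA, object@gammaB, object@r, object@sigma,
              object@F, object@d0))
})

#' Multi-locus trait architecture
#'
#' Per-locus allelic effects \eqn{\alpha_i}, background-association
#' coefficients \eqn{\beta_i} (variables of the model, supplied here as
#' inputs; typically opposite in sign to \eqn{\alpha_i}), per-locus
#' mutation rates \eqn{u_i}, the stabilising-selection variance \eqn{V_s}
#' and the inbreeding coefficient \eqn{F}.
#'
#' @slot alpha,beta,u numeric vectors of equal length
#' @slot Vs,F numeric scalars
#' @export
setClass("TraitArchitecture",
         representation(alpha = "numeric", beta = "numeric", u = "numeric",
                        Vs = "numeric", F = "numeric"),
         validity = function(object) {
           msg <- character()
           n <- length(object@alpha)
           if (length(object@beta) != n || length(object@u) != n)
             msg <- c(msg, "alpha, beta and u must have equal length")
           if (object@Vs <= 0) msg <- c(msg, "Vs must be positive")
           if (object@F < 0 || object@F > 1)
             msg <- c(msg, "F must lie in [0, 1]")
           if (any(object@u < 0)) msg <- c(msg, "mutation rates must be >= 0")
           if (length(msg)) msg else TRUE
         })

#' @param alpha allelic effects
#' @param beta background-association coefficients (recycled)
#' @param u per-locus mutation rates (recycled)
#' @param Vs stabilising-selection variance
#' @param F inbreeding coefficient
#' @return a `TraitArchitecture`
#' @examples
#' traitArchitecture(alpha = 0.25, u = 1e-5)
#' @rdname TraitArchitecture-class
#' @export
traitArchitecture <- function(alpha, beta = 0, u, Vs = 1, F = 0) {
  n <- length(alpha)
  new("TraitArchitecture", alpha = as.numeric(alpha),
      beta = rep_len(as.numeric(beta), n), u = rep_len(as.numeric(u), n),
      Vs = Vs, F = F)
}

#' @param arch a `TraitArchitecture`
#' @return `totalMutationRate`: the total trait mutation rate
#'   \eqn{U = \sum_i u_i}
#' @rdname TraitArchitecture-class
#' @export
totalMutationRate <- function(arch) sum(arch@u)

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf(paste0("TraitArchitecture: %d loci, U = %g, Vs = %g, F = %g\n"),
              length(object@alpha), sum(object@u), object@Vs, object@F))
})

#' Forward-simulation configuration
#'
#' Parameters of the Wright-Fisher forward simulator.  The defaults are the
#' full-scale study conditions: N = 5000 diploids, a 25 Mb genome of
#' alternating 4000 bp neutral buffers and 1000 bp genes, per-bp mutation
#' rate 4e-8 and recombination rate 1.98e-7, gene mutations split 25%
#' neutral / 65% deleterious / 10% trait, trait-effect s.d. 0.25 (variance
#' split across `nTraits`), Vs = 1, deleterious mutations with |s| = 0.02
#' and h = 0.2, a 10N-generation burn-in and 1001 post-shift generations.
#' Use [deskConfig()] for a proportionally scaled desk-top preset.
#'
#' @slot N diploid population size
#' @slot L genome length (bp)
#' @slot bufferLen,geneLen neutral-buffer and gene region sizes (bp)
#' @slot mu per-bp per-gamete mutation rate
#' @slot rec per-bp recombination rate
#' @slot fracNeutral,fracDeleterious,fracTrait gene-mutation class split
#' @slot selfing selfing fraction sigma
#' @slot nTraits pleiotropy degree n
#' @slot effectSd total trait-effect s.d. (per-trait variance effectSd^2/n)
#' @slot Vs stabilising-selection variance
#' @slot sDel,hDel deleterious selection magnitude and dominance; sDel = 0
#'   disables deleterious fitness effects
#' @slot optMode `"none"`, `"instant"` or `"gradual"`
#' @slot burnIn,postGens generation counts (shift happens after `burnIn`)
#' @slot statsIntervalPre,statsIntervalPost statistics cadence before and
#'   after the shift
#' @export
setClass("SimulationConfig",
         representation(N = "integer", L = "numeric", bufferLen = "integer",
                        geneLen = "integer", mu = "numeric", rec = "numeric",
                        fracNeutral = "numeric", fracDeleterious = "numeric",
                        fracTrait = "numeric", selfing = "numeric",
                        nTraits = "integer", effectSd = "numeric",
                        Vs = "numeric", sDel = "numeric", hDel = "numeric",
                        optMode = "character", burnIn = "integer",
                        postGens = "integer", statsIntervalPre = "integer",
                        statsIntervalPost = "integer"),
         validity = function(object) {
           msg <- character()
           fr <- c(object@fracNeutral, object@fracDeleterious, object@fracTrait)
           if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
             msg <- c(msg, "gene-mutation class fractions must be >= 0 and sum to 1")
           if (object@selfing < 0 || object@selfing > 1)
             msg <- c(msg, "selfing must lie in [0, 1]")
           if (!object@optMode %in% c("none", "instant", "gradual"))
             msg <- c(msg, "optMode must be one of none/instant/gradual")
           if (object@N < 1 || object@L < 1)
             msg <- c(msg, "N and L must be positive")
           if (object@mu < 0 || object@rec < 0)
             msg <- c(msg, "mu and rec must be >= 0")
           if (object@Vs <= 0) msg <- c(msg, "Vs must be positive")
           if (length(msg)) msg else TRUE
         })

#' @param N,L,bufferLen,geneLen,mu,rec,fracNeutral,fracDeleterious,fracTrait
#'   see slots
#' @param selfing,nTraits,effectSd,Vs,sDel,hDel,optMode see slots
#' @param burnIn generations before the shift (default 10N)
#' @param postGens generations after the shift
#' @param statsIntervalPre,statsIntervalPost statistics cadence
#' @return a `SimulationConfig`
#' @examples
#' cfg <- simulationConfig(N = 100, L = 50e3, burnIn = 200, postGens = 50)
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(N = 5000, L = 25e6, bufferLen = 4000,
                             geneLen = 1000, mu = 4e-8, rec = 1.98e-7,
                             fracNeutral = 0.25, fracDeleterious = 0.65,
                             fracTrait = 0.10, selfing = 0, nTraits = 1,
                             effectSd = 0.25, Vs = 1, sDel = 0.02,
                             hDel = 0.2, optMode = "instant",
                             burnIn = 10L * N, postGens = 1001L,
                             statsIntervalPre = 500L,
                             statsIntervalPost = 10L) {
  new("SimulationConfig", N = as.integer(N), L = as.numeric(L),
      bufferLen = as.integer(bufferLen), geneLen = as.integer(geneLen),
      mu = mu, rec = rec, fracNeutral = fracNeutral,
      fracDeleterious = fracDeleterious, fracTrait = fracTrait,
      selfing = selfing, nTraits = as.integer(nTraits),
      effectSd = effectSd, Vs = Vs, sDel = abs(sDel), hDel = hDel,
      optMode = optMode, burnIn = as.integer(burnIn),
      postGens = as.integer(postGens),
      statsIntervalPre = as.integer(statsIntervalPre),
      statsIntervalPost = as.integer(statsIntervalPost))
}

#' Desk-scale simulation preset
#'
#' Shrinks the genome while preserving the buffer/gene proportions and the
#' per-genome mutation and recombination input: `mu` and `rec` are scaled
#' up by the same factor the genome is scaled down, so the total trait
#' mutation rate per gamete, \eqn{U_t}, and the mean number of crossovers
#' per meiosis match the full-scale values.  `rateScale` additionally
#' multiplies both rates (e.g. `rateScale = 0.1` for the 10-fold-reduced
#' validation setting with \eqn{U_t = 0.002}).
#'
#' @param N diploid population size
#' @param L genome length in bp
#' @param rateScale joint multiplier on mu and rec
#' @param ... further arguments passed to [simulationConfig()]
#' @return a `SimulationConfig`
#' @examples
#' deskConfig(N = 200, L = 250e3, selfing = 0.999)
#' @export
deskConfig <- function(N = 200, L = 250e3, rateScale = 1, ...) {
  genomeScale <- 25e6 / L
  simulationConfig(N = N, L = L, mu = 4e-8 * genomeScale * rateScale,
                   rec = 1.98e-7 * genomeScale * rateScale, ...)
}

setMethod("show", "SimulationConfig", function(object) {
  ut <- traitMutationRate(object)
  cat(sprintf("SimulationConfig: N = %d, L = %g bp, selfing = %g, n = %d\n",
              object@N, object@L, object@selfing, object@nTraits))
  cat(sprintf("  mu = %g, rec = %g, U_t = %g (%g trait mutations/generation",
              object@mu, object@rec, ut, 2 * object@N * ut))
  cat(sprintf(" over 2N gametes)\n  optimum: %s after %d generations; %d post-shift\n",
              object@optMode, object@burnIn, object@postGens))
})

#' Trait mutation rate implied by a configuration
#'
#' The per-gamete (haploid genome) trait mutation rate
#' \eqn{U_t = \mu L f_{gene} f_{trait}}, where \eqn{f_{gene}} is the gene
#' fraction of the genome.  The population-level input per generation is
#' \eqn{2 N U_t} over the 2N transmitted gametes (both conventions are
#' printed by `show()` since per-diploid counting halves the number).
#'
#' @param config a [SimulationConfig-class]
#' @return the per-gamete trait mutation rate
#' @export
traitMutationRate <- function(config) {
  period <- config@bufferLen + config@geneLen
  geneFrac <- if (period > 0) config@geneLen / period else 0
  config@mu * config@L * geneFrac * config@fracTrait
}

#' Simulated population
#'
#' A diploid population as 2N sparse haplotypes (vectors of row indices
#' into the mutation table), plus a ledger of fixed substitutions whose
#' trait contribution (`zSub`, twice the summed effects) every individual
#' carries.
#'
#' @slot haplotypes list of 2N integer vectors (rows of `mutations`)
#' @slot mutations data.frame with columns id, position, class, origin
#' @slot effects numeric matrix (segregating mutations x traits)
#' @slot substitutions data.frame with columns id, position, class, origin,
#'   fixed
#' @slot subEffects effects of fixed mutations
#' @slot generation current generation
#' @slot optimum per-trait optimum at `generation`
#' @slot zSub per-trait substitution contribution to every trait value
#' @slot nSubDel number of fixed deleterious mutations
#' @slot config the [SimulationConfig-class] that produced the population
#' @export
setClass("Population",
         representation(haplotypes = "list", mutations = "data.frame",
                        effects = "matrix", substitutions = "data.frame",
                        subEffects = "matrix", generation = "integer",
                        optimum = "numeric", zSub = "numeric",
                        nSubDel = "integer", config = "SimulationConfig"),
         validity = function(object) {
           msg <- character()
           if (length(object@haplotypes) != 2 * object@config@N)
             msg <- c(msg, "need exactly 2N haplotypes")
           m <- nrow(object@mutations)
           refs <- unlist(object@haplotypes, use.names = FALSE)
           if (length(refs) && (min(refs) < 1 || max(refs) > m))
             msg <- c(msg, "haplotypes refer to unknown mutation rows")
           if (nrow(object@effects) != m)
             msg <- c(msg, "effects must have one row per mutation")
           if (length(msg)) msg else TRUE
         })

setMethod("show", "Population", function(object) {
  cls <- table(factor(object@mutations$class, levels = MUT_CLASSES))
  cat(sprintf("Population: N = %d diploids at generation %d\n",
              object@config@N, object@generation))
  cat(sprintf("  segregating: %d neutral, %d trait, %d deleterious; %d fixed\n",
              cls[["neutral"]], cls[["trait"]], cls[["deleterious"]],
              nrow(object@substitutions)))
})

#' @param pop a `Population`
#' @return `mutationTable`: the segregating-mutation data.frame with the
#'   per-trait effects bound as columns; `substitutionTable`: the same for
#'   the fixed-substitution ledger; `alleleFrequencies`: derived-allele
#'   frequencies of all segregating mutations
#' @rdname Population-class
#' @export
mutationTable <- function(pop) {
  eff <- pop@effects
  colnames(eff) <- paste0("effect", seq_len(ncol(eff)))
  cbind(pop@mutations, as.data.frame(eff))
}

#' @rdname Population-class
#' @export
substitutionTable <- function(pop) {
  eff <- pop@subEffects
  colnames(eff) <- paste0("effect", seq_len(ncol(eff)))
  cbind(pop@substitutions, as.data.frame(eff))
}

#' @rdname Population-class
#' @export
alleleFrequencies <- function(pop) {
  m <- nrow(pop@mutations)
  cnt <- tabulate(unlist(pop@haplotypes, use.names = FALSE), nbins = m)
  cnt / (2 * pop@config@N)
}

#' Simulation result
#'
#' Time series of summary statistics, population snapshots at designated
#' timepoints, and the final population.
#'
#' @slot stats data.frame statistics stream (one row per recorded
#'   generation)
#' @slot snapshots list of [Population-class] snapshots
#' @slot final the final [Population-class]
#' @slot config the [SimulationConfig-class]
#' @export
setClass("SimulationResult",
         representation(stats = "data.frame", snapshots = "list",
                        final = "Population", config = "SimulationConfig"))

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d statistics rows, %d snapshots, final generation %d\n",
              nrow(object@stats), length(object@snapshots),
              object@final@generation))
})

#' @param x a `SimulationResult`
#' @return `simStats`: the statistics data.frame; `snapshots`: the list of
#'   snapshot populations; `finalPopulation`: the final population
#' @rdname SimulationResult-class
#' @export
simStats <- function(x) x@stats

#' @rdname SimulationResult-class
#' @export
snapshots <- function(x) x@snapshots

#' @rdname SimulationResult-class
#' @export
finalPopulation <- function(x) x@final
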