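# Exact two-locus genotype recursion under partial selfing and Gaussian
# stabilising selection, plus the closed-form approximations for LD and
# allele-frequency dynamics that it serves as the oracle for.

# haplotype index -> allele indicators; 1 ab, 2 Ab, 3 aB, 4 AB
hapA <- c(0L, 1L, 0L, 1L)
hapB <- c(0L, 0L, 1L, 1L)

#' Genotype frequencies from haplotype frequencies
#'
#' Builds the 4x4 table of ordered genotype frequencies from haplotype
#' frequencies using the inbreeding-coefficient approximation:
#' \eqn{g_{ii} = x_i^2 + F x_i(1-x_i)} on the diagonal and, for the
#' unordered heterozygous genotype formed by haplotypes i and j,
#' \eqn{g_{ij} = 2 x_i x_j (1-F)} (stored as two ordered entries of
#' \eqn{x_i x_j (1-F)} each).  This shortcut ignores recombination during
#' self-fertilisation; the exact recursion ([exactGenerationStep()]) does
#' not rely on it once a genotype table is attached to the state.
#'
#' @param state a [TwoLocusState-class]
#' @param F inbreeding coefficient in \[0, 1\]
#' @return a 4x4 matrix of ordered genotype frequencies summing to one
#' @examples
#' s <- twoLocusState(pA = 0.5, pB = 0, delta = 0)
#' genotypesFromHaplotypes(s, F = 1)
#' @export
genotypesFromHaplotypes <- function(state, F) {
  stopifnot(is(state, "TwoLocusState"), F >= 0, F <= 1)
  x <- state@x
  G <- (1 - F) * outer(x, x)
  diag(G) <- x^2 + F * x * (1 - x)
  dimnames(G) <- list(hapNames, hapNames)
  G
}

# Gaussian fitness of each ordered genotype given scaled effects and the
# scaled distance d0: w = exp(-(gammaA*nA + gammaB*nB - d0)^2 / 2)
genotypeFitness <- function(params) {
  nA <- outer(hapA, hapA, "+")
  nB <- outer(hapB, hapB, "+")
  z <- params@gammaA * nA + params@gammaB * nB - params@d0
  exp(-z^2 / 2)
}

# Gamete distribution of every ordered genotype: a 4x4x4 array M with
# M[i, j, k] = P(gamete k | parent carries haplotypes i, j).
# Non-recombinant products i and j each have probability (1-r)/2;
# recombinants (A_i, B_j) and (A_j, B_i) each r/2.
meiosisArray <- function(r) {
  M <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) {
    rec1 <- 1L + hapA[i] + 2L * hapB[j]
    rec2 <- 1L + hapA[j] + 2L * hapB[i]
    g <- numeric(4)
    g[i] <- g[i] + (1 - r) / 2
    g[j] <- g[j] + (1 - r) / 2
    g[rec1] <- g[rec1] + r / 2
    g[rec2] <- g[rec2] + r / 2
    M[i, j, ] <- g
  }
  M
}

#' Exact two-locus generation step
#'
#' One full generation of the deterministic (infinite-population)
#' two-locus recursion: each ordered genotype is weighted by its Gaussian
#' fitness, then an offspring is produced by selfing a fitness-sampled
#' parent with probability `sigma` (two independent meioses of the same
#' parent, so recombination during self-fertilisation is modelled
#' explicitly) and otherwise by the union of two independent
#' fitness-sampled gametes.
#'
#' If `state` carries no genotype table, one is constructed from the
#' haplotype frequencies via [genotypesFromHaplotypes()] with `params@F`;
#' on output the state carries the exact next-generation genotype table, so
#' iterating the step never re-applies the approximation.
#'
#' @param state a [TwoLocusState-class]
#' @param params a [TwoLocusParams-class]
#' @return the next-generation [TwoLocusState-class]; attribute
#'   `meanFitness` holds the parental mean fitness
#' @examples
#' st <- twoLocusState(pA = 0.05, pB = 0.05, delta = 0)
#' pr <- twoLocusParams(gammaA = 0.1, gammaB = 0.1, r = 0.1, sigma = 0.9)
#' exactGenerationStep(st, pr)
#' @export
exactGenerationStep <- function(state, params) {
  stopifnot(is(state, "TwoLocusState"), is(params, "TwoLocusParams"))
  G <- if (nrow(state@G)) state@G else genotypesFromHaplotypes(state, params@F)
  w <- genotypeFitness(params)
  wbar <- sum(G * w)
  Gw <- G * w / wbar
  M <- meiosisArray(params@r)
  # gamete pool over all fitness-weighted parents
  y <- vapply(1:4, function(k) sum(Gw * M[, , k]), numeric(1))
  Gnext <- (1 - params@sigma) * outer(y, y)
  if (params@sigma > 0) {
    for (i in 1:4) for (j in 1:4) {
      if (Gw[i, j] > 0) {
        m <- M[i, j, ]
        Gnext <- Gnext + params@sigma * Gw[i, j] * outer(m, m)
      }
    }
  }
  dimnames(Gnext) <- list(hapNames, hapNames)
  out <- new("TwoLocusState", x = setNames(rowSums(Gnext), hapNames),
             G = Gnext)
  attr(out, "meanFitness") <- wbar
  out
}

#' Iterate the exact two-locus recursion
#'
#' @param state starting [TwoLocusState-class]
#' @param params a [TwoLocusParams-class]
#' @param generations number of generations to iterate
#' @param every record one row every `every` generations
#' @return a data.frame with columns t, pA, pB, delta, meanFitness
#' @examples
#' st <- twoLocusState(pA = 0.05, pB = 0.05, delta = 0)
#' pr <- twoLocusParams(gammaA = 0.1, gammaB = 0.1, r = 0.5)
#' tail(twoLocusTrajectory(st, pr, 100))
#' @export
twoLocusTrajectory <- function(state, params, generations, every = 1L) {
  rows <- seq(0L, generations, by = every)
  out <- data.frame(t = rows, pA = NA_real_, pB = NA_real_,
                    delta = NA_real_, meanFitness = NA_real_)
  k <- 1L
  for (t in 0:generations) {
    if (t %% every == 0L) {
      out$pA[k] <- alleleFreqA(state)
      out$pB[k] <- alleleFreqB(state)
      out$delta[k] <- ld(state)
      out$meanFitness[k] <- meanFitnessTwoLocus(state, params)
      k <- k + 1L
    }
    if (t < generations) state <- exactGenerationStep(state, params)
  }
  out
}

#' Mean fitness of a two-locus population
#'
#' @inheritParams directionalCoefficients
#' @return the genotype-frequency-weighted mean Gaussian fitness
#' @export
meanFitnessTwoLocus <- function(state, params) {
  G <- if (nrow(state@G)) state@G else genotypesFromHaplotypes(state, params@F)
  sum(G * genotypeFitness(params))
}

#' Composite coefficients of the directional-phase approximations
#'
#' \eqn{\Gamma = (1+3F)(\gamma_A+\gamma_B)^2 + (1-F) r (2-(\gamma_A+\gamma_B)^2)}
#' governs the per-generation breakdown of LD at the optimum, and
#' \eqn{\kappa = d_0(\gamma_A(q_A-p_A) + \gamma_B(q_B-p_B))} the build-up
#' of LD under directional selection.
#'
#' @param state a [TwoLocusState-class]
#' @param params a [TwoLocusParams-class]
#' @return list with elements `kappa` and `Gamma`
#' @export
directionalCoefficients <- function(state, params) {
  g <- params@gammaA + params@gammaB
  Gamma <- (1 + 3 * params@F) * g^2 + (1 - params@F) * params@r * (2 - g^2)
  pA <- alleleFreqA(state); pB <- alleleFreqB(state)
  kappa <- params@d0 * (params@gammaA * (1 - 2 * pA) +
                        params@gammaB * (1 - 2 * pB))
  list(kappa = kappa, Gamma = Gamma)
}

#' Per-generation LD change at the optimum (closed form)
#'
#' Weak-selection, rare-allele approximation at \eqn{d_0 = 0}:
#' \deqn{\Delta\delta = -(1+3F) p_A p_B \gamma_A \gamma_B - (\delta/2)\Gamma.}
#' Selection generates negative LD between alleles whose effects point the
#' same way (\eqn{\gamma_A\gamma_B > 0}) and positive LD otherwise.
#'
#' @inheritParams directionalCoefficients
#' @return the predicted one-generation change in \eqn{\delta}
#' @examples
#' st <- twoLocusState(pA = 0.01, pB = 0.01, delta = 0)
#' deltaLdAtOptimum(st, twoLocusParams(gammaA = 0.1, gammaB = 0.1))
#' @export
deltaLdAtOptimum <- function(state, params) {
  co <- directionalCoefficients(state, params)
  -(1 + 3 * params@F) * alleleFreqA(state) * alleleFreqB(state) *
    params@gammaA * params@gammaB - ld(state) / 2 * co$Gamma
}

#' Critical recombination fraction for selfing to amplify negative LD
#'
#' Selfing increases the magnitude of selection-generated LD
#' (\eqn{\partial\Gamma/\partial F > 0}) iff the recombination fraction is
#' below \eqn{3 s^2/(2 - s^2)} with \eqn{s = \gamma_A + \gamma_B}.
#'
#' @param gammaA,gammaB scaled allelic effects with \eqn{(\gamma_A+\gamma_B)^2 < 2}
#' @return the critical recombination fraction
#' @examples
#' gammaThreshold(0.1, 0.1)
#' @export
gammaThreshold <- function(gammaA, gammaB) {
  s2 <- (gammaA + gammaB)^2
  if (s2 >= 2) stop("(gammaA + gammaB)^2 must be below 2")
  3 * s2 / (2 - s2)
}

#' Quasi-linkage-equilibrium LD
#'
#' The quasi-steady LD reached when recombination is fast relative to
#' selection (\eqn{\gamma_A, \gamma_B \ll r(1-F)}):
#' \deqn{\delta_{QLE} \approx -\frac{(1+3F)\gamma_A\gamma_B}{(1-F) r} p_A p_B.}
#'
#' @inheritParams directionalCoefficients
#' @return the QLE value of \eqn{\delta}
#' @examples
#' st <- twoLocusState(pA = 0.1, pB = 0.1, delta = 0)
#' qleLd(st, twoLocusParams(gammaA = 0.1, gammaB = 0.1, r = 0.5))
#' @export
qleLd <- function(state, params) {
  if (params@F >= 1 || params@r <= 0)
    stop("QLE is undefined for F = 1 or r = 0")
  -(1 + 3 * params@F) * params@gammaA * params@gammaB /
    ((1 - params@F) * params@r) * alleleFreqA(state) * alleleFreqB(state)
}

#' Directional-phase allele-frequency change (closed form)
#'
#' For \eqn{\gamma \ll d_0} (directional regime),
#' \deqn{\Delta p_A = d_0 (1+F)(\gamma_A p_A(1-p_A) + \delta\gamma_B),}
#' and symmetrically for locus B.  Negative LD with an aligned partner
#' locus (\eqn{\delta\gamma_B} opposing \eqn{\gamma_A}) slows the spread.
#'
#' @inheritParams directionalCoefficients
#' @param locus `"A"` or `"B"`
#' @return the predicted one-generation allele-frequency change
#' @export
alleleChangeDirectional <- function(state, params, locus = c("A", "B")) {
  locus <- match.arg(locus)
  d <- ld(state)
  if (locus == "A") {
    p <- alleleFreqA(state)
    params@d0 * (1 + params@F) * (params@gammaA * p * (1 - p) + d * params@gammaB)
  } else {
    p <- alleleFreqB(state)
    params@d0 * (1 + params@F) * (params@gammaB * p * (1 - p) + d * params@gammaA)
  }
}

#' Directional-phase LD change (closed form)
#'
#' \deqn{\Delta\delta \approx \delta(\kappa(1+F) - (1-F) r)} with
#' \eqn{\kappa} from [directionalCoefficients()]: selfing amplifies the LD
#' term through \eqn{1+F} while damping its breakdown by recombination.
#'
#' @inheritParams directionalCoefficients
#' @return the predicted one-generation change in \eqn{\delta}
#' @export
ldChangeDirectional <- function(state, params) {
  co <- directionalCoefficients(state, params)
  ld(state) * (co$kappa * (1 + params@F) - (1 - params@F) * params@r)
}
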