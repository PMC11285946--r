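# Effective-parameter rescaling: what mutation and recombination rates an
# outcrossing population needs to mimic a partially selfing one.

#' Neutral-equilibrium inbreeding coefficient
#'
#' \eqn{F = \sigma/(2-\sigma)} for selfing fraction \eqn{\sigma}.
#'
#' @param sigma selfing fraction in \[0, 1\]
#' @return the inbreeding coefficient
#' @examples
#' inbreedingF(0.999)
#' @export
inbreedingF <- function(sigma) {
  stopifnot(all(sigma >= 0 & sigma <= 1))
  sigma / (2 - sigma)
}

#' Joint two-locus identity-by-descent probability
#'
#' \eqn{\Phi = \sigma(2+\sigma) / ((4-\sigma)(2-\sigma))}, the probability
#' of joint identity-by-descent at two loci, evaluated at recombination
#' fraction 1/2 (the whole-genome rescaling uses the mean number of
#' crossovers per meiosis, so the free-recombination value is the relevant
#' one).
#'
#' @inheritParams inbreedingF
#' @return the joint identity-by-descent probability
#' @examples
#' jointIbdPhi(0.999)
#' @export
jointIbdPhi <- function(sigma) {
  stopifnot(all(sigma >= 0 & sigma <= 1))
  sigma * (2 + sigma) / ((4 - sigma) * (2 - sigma))
}

#' Effective mutation and recombination rates under selfing
#'
#' Selfing reduces the effective population size by \eqn{1+F}, hence the
#' net mutation input: \eqn{\mu_{eff} = \mu/(1+F)}.  The effective
#' recombination rate shrinks with homozygosity:
#' \eqn{r_{eff} = r(1 - 2F + \Phi)}.  An outcrossing population run at
#' these rates mimics the drift and linkage regime of a selfing one.
#'
#' @param mu per-bp mutation rate
#' @param rec per-bp recombination rate
#' @param sigma selfing fraction
#' @return a one-row data.frame with columns sigma, F, Phi, muEff, recEff
#' @examples
#' effectiveRates(4e-8, 1.98e-7, 0.999)
#' @export
effectiveRates <- function(mu, rec, sigma) {
  F <- inbreedingF(sigma)
  Phi <- jointIbdPhi(sigma)
  data.frame(sigma = sigma, F = F, Phi = Phi,
             muEff = mu / (1 + F),
             recEff = rec * (1 - 2 * F + Phi))
}
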