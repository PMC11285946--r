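# Closed-form multi-locus predictions with background-association
# coefficients beta_i: per-locus dynamics, equilibrium frequencies and the
# equilibrium decomposition of the genetic variance.

#' Per-locus allele-frequency change in a multi-locus background
#'
#' At distance D from the optimum, the change in the derived-allele
#' frequency at locus i is
#' \deqn{\Delta x_i = \frac{(1+F)}{V_s}(\alpha_i+\beta_i) D\, x_i(1-x_i)
#'   - \frac{(1+3F)}{V_s}(\alpha_i+\beta_i)^2
#'     \Big(1-\frac{D^2}{2V_s}\Big) x_i(1-x_i)\Big(\tfrac12-x_i\Big).}
#' The first (directional) term is amplified by homozygosity through
#' \eqn{1+F}; the second (stabilising) term purges minor alleles and is
#' amplified through \eqn{1+3F}.  The background association \eqn{\beta_i}
#' simply shifts the effective allelic effect to \eqn{\alpha_i+\beta_i}.
#'
#' @param x derived-allele frequencies (vectorised over loci)
#' @param arch a [TraitArchitecture-class]
#' @param D distance of the mean phenotype from the optimum (trait units)
#' @return per-locus frequency change per generation
#' @examples
#' arch <- traitArchitecture(alpha = 0.25, u = 1e-5)
#' alleleChange(0.1, arch, D = 0)
#' @export
alleleChange <- function(x, arch, D) {
  ab <- arch@alpha + arch@beta
  Vs <- arch@Vs; F <- arch@F
  (1 + F) / Vs * ab * D * x * (1 - x) -
    (1 + 3 * F) / Vs * ab^2 * (1 - D^2 / (2 * Vs)) * x * (1 - x) * (0.5 - x)
}

#' Change in the distance to the optimum
#'
#' \deqn{\Delta D = -\frac{1}{V_s}\big((1+F) V_g + C_{LD}\big) D
#'   + \frac{(1+3F)}{V_s}\Big(1-\frac{D^2}{2V_s}\Big)
#'     (\mu_3 + 2\nu_{2,1} + \nu_{1,2}),}
#' where \eqn{V_g} is the genic variance, \eqn{C_{LD}} the LD covariance
#' and \eqn{\mu_3, \nu_{2,1}, \nu_{1,2}} third-order central moments.
#' These quantities are variables of the model, not parameters; supply
#' them measured from a population (e.g. via [varianceDecomposition()]).
#'
#' @param arch a [TraitArchitecture-class] (supplies Vs and F)
#' @param D distance of the mean phenotype from the optimum
#' @param Vg genic variance
#' @param CLD linkage-disequilibrium covariance
#' @param mu3,nu21,nu12 third-order central moments (default 0)
#' @return the per-generation change in D
#' @examples
#' arch <- traitArchitecture(alpha = 0.25, u = 1e-5)
#' distanceChange(arch, D = 0.5, Vg = 0.08, CLD = 0)
#' @export
distanceChange <- function(arch, D, Vg, CLD, mu3 = 0, nu21 = 0, nu12 = 0) {
  Vs <- arch@Vs; F <- arch@F
  -((1 + F) * Vg + CLD) * D / Vs +
    (1 + 3 * F) / Vs * (1 - D^2 / (2 * Vs)) * (mu3 + 2 * nu21 + nu12)
}

#' Equilibrium derived-allele frequency at mutation-selection balance
#'
#' At the optimum (D = 0), rare-allele mutation-selection balance gives
#' \deqn{x_i(0) = \frac{u_i V_s}{(1+3F)(\alpha_i+\beta_i(0))^2},}
#' the house-of-cards frequency \eqn{u V_s/\alpha^2} when associations are
#' neglected and \eqn{F = 0}.  Selfing purges rare alleles (the
#' \eqn{1+3F} factor) while negative associations (\eqn{\beta_i} opposing
#' \eqn{\alpha_i}) weaken that purging.
#'
#' @param arch a [TraitArchitecture-class]
#' @return per-locus equilibrium frequencies
#' @examples
#' equilibriumFrequency(traitArchitecture(alpha = 0.25, u = 1e-5))
#' @export
equilibriumFrequency <- function(arch) {
  ab <- arch@alpha + arch@beta
  if (any(ab == 0))
    stop("alpha + beta = 0 at some locus: effectively neutral, no balance")
  arch@u * arch@Vs / ((1 + 3 * arch@F) * ab^2)
}

#' Equilibrium genetic-variance components
#'
#' At mutation-selection balance at the optimum, with total trait mutation
#' rate \eqn{U = \sum_i u_i} and loci averaged:
#' \deqn{V_G = 4UV_s\frac{1+F}{1+3F}\overline{\frac{\alpha_i}{\alpha_i+\beta_i}},\quad
#'   V_g = \frac{4UV_s}{1+3F}\overline{\frac{\alpha_i^2}{(\alpha_i+\beta_i)^2}},\quad
#'   V_I = F\,V_g,\quad
#'   C_{LD} = 4UV_s\frac{1+F}{1+3F}\overline{\frac{\alpha_i\beta_i}{(\alpha_i+\beta_i)^2}}.}
#' The identity \eqn{V_G = V_g + V_I + C_{LD}} holds algebraically for any
#' architecture.  With no associations (\eqn{\beta_i = 0}) and no selfing
#' this collapses to the house-of-cards genic variance \eqn{V_g = 4UV_s}.
#'
#' @param arch a [TraitArchitecture-class]
#' @return a one-row data.frame with columns VG, Vg, VI, CLD
#' @examples
#' # house of cards: U = 0.02, Vs = 1, outcrossing, no associations
#' equilibriumVarianceComponents(
#'   traitArchitecture(alpha = 0.25, u = 0.02, Vs = 1, F = 0))
#' @export
equilibriumVarianceComponents <- function(arch) {
  ab <- arch@alpha + arch@beta
  if (any(ab == 0))
    stop("alpha + beta = 0 at some locus: components are degenerate")
  U <- sum(arch@u); Vs <- arch@Vs; F <- arch@F
  base <- 4 * U * Vs / (1 + 3 * F)
  Vg <- base * mean(arch@alpha^2 / ab^2)
  VI <- F * Vg
  CLD <- base * (1 + F) * mean(arch@alpha * arch@beta / ab^2)
  VG <- base * (1 + F) * mean(arch@alpha / ab)
  data.frame(VG = VG, Vg = Vg, VI = VI, CLD = CLD)
}

#' Empirical background-association coefficients
#'
#' Estimates, for every segregating trait mutation, the mean background
#' deviation associated with carrying the derived allele.  For mutation j
#' with effect \eqn{a_j} (on `trait`), the haploid background of a gamete
#' is its summed trait value excluding locus j; writing
#' \eqn{\bar g_{A,j}} for its mean over carrier gametes and \eqn{\bar g_j}
#' for the overall mean, the diploid association is estimated as
#' \deqn{\hat\beta_{A,j} = (1+\hat F)(\bar g_{A,j} - \bar g_j),}
#' since the co-transmitted homolog resembles the focal gamete with
#' probability \eqn{\hat F} (the population's excess homozygosity, see
#' [excessHomozygosity()]).  The locus-level coefficient is
#' \eqn{\hat\beta_j = \hat\beta_{A,j}/(1-x_j)}.
#'
#' @param pop a [Population-class]
#' @param trait trait index
#' @return data.frame with columns id, position, freq, alpha, betaA, beta
#' @export
estimateBeta <- function(pop, trait = 1L) {
  cls <- pop@mutations$class
  keep <- which(cls == "trait")
  m <- nrow(pop@mutations)
  a <- pop@effects[, trait]
  # haploid trait value of every gamete
  hv <- vapply(pop@haplotypes,
               function(h) sum(a[h]), numeric(1))
  Fhat <- max(0, min(1, excessHomozygosity(pop)))
  H <- length(pop@haplotypes)
  carrier <- matrix(FALSE, H, length(keep))
  rowsOf <- match(seq_len(m), keep)
  for (h in seq_len(H)) {
    r <- rowsOf[pop@haplotypes[[h]]]
    carrier[h, r[!is.na(r)]] <- TRUE
  }
  out <- data.frame(id = pop@mutations$id[keep],
                    position = pop@mutations$position[keep],
                    freq = colSums(carrier) / H,
                    alpha = a[keep], betaA = NA_real_, beta = NA_real_)
  for (k in seq_along(keep)) {
    aj <- a[keep[k]]
    bg <- hv - aj * carrier[, k]      # background excludes the focal locus
    gA <- mean(bg[carrier[, k]])
    out$betaA[k] <- (1 + Fhat) * (gA - mean(bg))
    out$beta[k] <- out$betaA[k] / (1 - out$freq[k])
  }
  out
}
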