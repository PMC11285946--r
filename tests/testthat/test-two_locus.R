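# Exact two-locus recursion and its closed-form approximations.

test_that("genotype table from haplotype frequencies follows the F-model", {
  # fixed haplotype: the single homozygote has frequency 1
  s <- twoLocusState(x = c(1, 0, 0, 0))
  G <- genotypesFromHaplotypes(s, F = 0.5)
  expect_equal(G[1, 1], 1)
  expect_equal(sum(G) - G[1, 1], 0)

  # Hardy-Weinberg at F = 0: unordered heterozygote frequency 2 x1 x2
  s <- twoLocusState(x = c(0.5, 0.5, 0, 0))
  G <- genotypesFromHaplotypes(s, F = 0)
  expect_equal(G[1, 1], 0.25)
  expect_equal(G[1, 2] + G[2, 1], 0.5)
  expect_equal(G[2, 2], 0.25)

  # full inbreeding: heterozygotes vanish
  G <- genotypesFromHaplotypes(s, F = 1)
  expect_equal(G[1, 1], 0.5)
  expect_equal(G[2, 2], 0.5)
  expect_equal(G[1, 2] + G[2, 1], 0)

  expect_equal(sum(genotypesFromHaplotypes(
    twoLocusState(pA = 0.3, pB = 0.2, delta = 0.01), F = 0.7)), 1)
  expect_error(twoLocusState(x = c(0.7, 0.5, -0.1, -0.1)))
})

test_that("exact step conserves frequencies and decays neutral LD as (1-r)", {
  st <- twoLocusState(pA = 0.5, pB = 0.5, delta = 0.1)
  pr <- twoLocusParams(gammaA = 0, gammaB = 0, r = 0.5, sigma = 0)
  s2 <- exactGenerationStep(st, pr)
  expect_equal(ld(s2), 0.05, tolerance = 1e-12)
  pr2 <- twoLocusParams(r = 0.2, sigma = 0)
  expect_equal(ld(exactGenerationStep(st, pr2)), 0.08, tolerance = 1e-12)

  # frequency conservation under selection and selfing
  set.seed(7)
  for (k in 1:20) {
    st <- twoLocusState(pA = runif(1, 0.01, 0.99), pB = runif(1, 0.01, 0.99))
    pr <- twoLocusParams(gammaA = runif(1, -0.3, 0.3),
                         gammaB = runif(1, -0.3, 0.3),
                         r = runif(1, 0, 0.5), sigma = runif(1),
                         d0 = runif(1, -1, 1))
    for (g in 1:5) {
      st <- exactGenerationStep(st, pr)
      expect_lt(abs(sum(st@x) - 1), 1e-12)
      expect_lt(abs(sum(st@G) - 1), 1e-12)
    }
  }
})

test_that("neutral oracle converges to F = sigma/(2-sigma) for all selfing rates", {
  hetA <- function(G) {
    # one-locus heterozygosity at A from the ordered genotype table
    isA <- c(FALSE, TRUE, FALSE, TRUE)
    sum(G[outer(isA, isA, xor)])
  }
  for (sigma in c(0, 0.5, 0.9, 0.99, 0.999)) {
    pr <- twoLocusParams(r = 0.2, sigma = sigma)
    st <- twoLocusState(pA = 0.5, pB = 0.5, delta = 0)
    st@G <- genotypesFromHaplotypes(st, F = 0)   # start fully outbred
    Fprev <- -1
    for (g in 1:20000) {
      st <- exactGenerationStep(st, pr)
      Fhat <- 1 - hetA(st@G) / (2 * alleleFreqA(st) * (1 - alleleFreqA(st)))
      if (abs(Fhat - Fprev) < 1e-13) break
      Fprev <- Fhat
    }
    expect_equal(Fhat, sigma / (2 - sigma), tolerance = 1e-6)
  }
})

test_that("LD change at the optimum matches the closed form to O(zeta^3)", {
  # direct evaluations
  st <- twoLocusState(pA = 0.01, pB = 0.01, delta = 0)
  expect_equal(deltaLdAtOptimum(st, twoLocusParams(0.1, 0.1)), -1e-6)
  expect_equal(deltaLdAtOptimum(st, twoLocusParams(0, 0.1)), 0)
  expect_gt(deltaLdAtOptimum(st, twoLocusParams(-0.1, 0.1)), 0)

  # error against the exact oracle shrinks at least as zeta^2.5 as the
  # scaled effects and frequencies shrink jointly
  zetas <- 2^-(0:4)
  for (sigma in c(0, 0.5, 0.9)) {
    errs <- vapply(zetas, function(z) {
      st <- twoLocusState(pA = 0.05 * z, pB = 0.05 * z, delta = 0)
      pr <- twoLocusParams(gammaA = 0.05 * z, gammaB = 0.05 * z, r = 0.3,
                           sigma = sigma, d0 = 0)
      abs((ld(exactGenerationStep(st, pr)) - ld(st)) -
            deltaLdAtOptimum(st, pr))
    }, numeric(1))
    slope <- coef(lm(log(errs) ~ log(zetas)))[2]
    expect_gt(slope, 2.5)
  }

  # sign structure: generated LD negative iff effects are aligned
  for (gB in c(0.08, -0.08)) {
    st <- twoLocusState(pA = 0.03, pB = 0.03, delta = 0)
    pr <- twoLocusParams(gammaA = 0.08, gammaB = gB, r = 0.3, sigma = 0.5)
    oracle <- ld(exactGenerationStep(st, pr)) - ld(st)
    form <- deltaLdAtOptimum(st, pr)
    expect_equal(sign(oracle), -sign(0.08 * gB))
    expect_equal(sign(form), sign(oracle))
  }
})

test_that("critical recombination threshold for selfing to amplify LD", {
  expect_equal(gammaThreshold(0.1, 0.1), 0.12 / 1.96)
  expect_equal(gammaThreshold(0, 0), 0)
  expect_error(gammaThreshold(1, 0.5))
  # at r = 0 the derivative of Gamma in F is positive for any effect size
  g <- 0.2
  dGamma <- 3 * (2 * g)^2 - 0 * (2 - (2 * g)^2)
  expect_gt(dGamma, 0)
})

test_that("QLE LD formula and oracle agree in the fast-recombination regime", {
  st <- twoLocusState(pA = 0.1, pB = 0.1, delta = 0)
  expect_equal(qleLd(st, twoLocusParams(0.1, 0.1, r = 0.5)), -2e-4)
  expect_gt(qleLd(st, twoLocusParams(-0.1, 0.1, r = 0.5)), 0)
  expect_error(qleLd(st, twoLocusParams(0.1, 0.1, r = 0)))
  expect_error(qleLd(st, twoLocusParams(0.1, 0.1, r = 0.5, F = 1)))

  # iterated oracle: long-run delta/(pA pB) within 10% of the QLE ratio.
  # Grid avoids jointly high selfing and recombination, where the
  # F-approximation underlying the closed form is known to degrade.
  grid <- expand.grid(sigma = c(0, 0.5), r = c(0.2, 0.5), g = c(0.02, 0.05))
  grid <- grid[!(grid$sigma == 0.5 & grid$r == 0.5), ]
  for (k in seq_len(nrow(grid))) {
    pr <- twoLocusParams(gammaA = grid$g[k], gammaB = grid$g[k],
                         r = grid$r[k], sigma = grid$sigma[k], d0 = 0)
    st <- twoLocusState(pA = 0.05, pB = 0.05, delta = 0)
    for (i in 1:400) st <- exactGenerationStep(st, pr)
    obs <- ld(st) / (alleleFreqA(st) * alleleFreqB(st))
    pred <- qleLd(st, pr) / (alleleFreqA(st) * alleleFreqB(st))
    expect_equal(obs, pred, tolerance = 0.1)
  }
})

test_that("directional-phase allele-change approximation", {
  st <- twoLocusState(pA = 0.5, pB = 0.5, delta = 0)
  pr <- twoLocusParams(gammaA = 0.1, gammaB = 0, d0 = 0.1)
  expect_equal(alleleChangeDirectional(st, pr, "A"), 0.0025)
  # boundaries are fixed points
  for (p in c(0, 1))
    expect_equal(alleleChangeDirectional(
      twoLocusState(pA = p, pB = 0.5, delta = 0), pr, "A"), 0)
  # negative LD between aligned alleles slows the spread
  pr2 <- twoLocusParams(gammaA = 0.05, gammaB = 0.05, d0 = 0.5, r = 0.3)
  stLd <- twoLocusState(pA = 0.1, pB = 0.1, delta = -0.005)
  st0 <- twoLocusState(pA = 0.1, pB = 0.1, delta = 0)
  expect_lt(alleleChangeDirectional(stLd, pr2, "A"),
            alleleChangeDirectional(st0, pr2, "A"))

  # one-step oracle agreement for weak effects (gamma << d0)
  for (sigma in c(0, 0.5, 0.9)) for (d0 in c(0.3, 0.5)) {
    pr3 <- twoLocusParams(gammaA = 0.02, gammaB = 0.02, r = 0.3,
                          sigma = sigma, d0 = d0)
    st3 <- twoLocusState(pA = 0.05, pB = 0.08, delta = -0.002)
    dpOracle <- alleleFreqA(exactGenerationStep(st3, pr3)) - alleleFreqA(st3)
    expect_equal(alleleChangeDirectional(st3, pr3, "A"), dpOracle,
                 tolerance = 0.1)
  }
})

test_that("directional-phase LD-change approximation", {
  pr <- twoLocusParams(gammaA = 0.1, gammaB = 0.1, r = 0.3, sigma = 0.5,
                       d0 = 0.5)
  # kappa vanishes at p = 1/2, leaving pure recombination decay
  st <- twoLocusState(pA = 0.5, pB = 0.5, delta = 0.01)
  expect_equal(directionalCoefficients(st, pr)$kappa, 0)
  expect_equal(ldChangeDirectional(st, pr),
               -0.01 * (1 - pr@F) * pr@r)
  expect_equal(ldChangeDirectional(
    twoLocusState(pA = 0.2, pB = 0.2, delta = 0), pr), 0)
  # F = 1: no recombination decay, pure 2*delta*kappa
  pr1 <- twoLocusParams(gammaA = 0.1, gammaB = 0.1, r = 0.3, sigma = 1,
                        F = 1, d0 = 0.5)
  st1 <- twoLocusState(pA = 0.2, pB = 0.2, delta = -0.004)
  k <- directionalCoefficients(st1, pr1)$kappa
  expect_equal(ldChangeDirectional(st1, pr1), 2 * -0.004 * k)

  # one-step oracle agreement in the directional regime
  for (sigma in c(0, 0.5, 0.9)) for (g in c(0.02, 0.05)) {
    pr3 <- twoLocusParams(gammaA = g, gammaB = g, r = 0.3, sigma = sigma,
                          d0 = 0.3)
    st3 <- twoLocusState(pA = 0.05, pB = 0.08, delta = -0.002)
    ddOracle <- ld(exactGenerationStep(st3, pr3)) - ld(st3)
    expect_equal(ldChangeDirectional(st3, pr3), ddOracle, tolerance = 0.1)
  }
})

test_that("trajectory emitter records the generation series", {
  st <- twoLocusState(pA = 0.05, pB = 0.05, delta = 0)
  pr <- twoLocusParams(gammaA = 0.1, gammaB = 0.1, r = 0.5, d0 = 0.5)
  tr <- twoLocusTrajectory(st, pr, 20, every = 5)
  expect_equal(tr$t, seq(0, 20, by = 5))
  expect_equal(tr$pA[1], 0.05)
  expect_true(all(diff(tr$pA) > 0))   # directional phase: A spreads
  expect_true(all(tr$meanFitness > 0 & tr$meanFitness <= 1))
})
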