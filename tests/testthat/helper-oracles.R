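# Independent reference computations used as oracles in the tests.

# contingency-table LD statistics for one pair of 0/1 haplotype vectors
refPairLd <- function(a, b) {
  pA <- mean(a); pB <- mean(b)
  p11 <- mean(a == 1 & b == 1)
  D <- p11 - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       dprime = if (dmax > 0) abs(D) / dmax else 0)
}

# single-locus population with exact genotype counts (n0, n1, n2) for a
# trait or deleterious mutation of effect `a`
countPopulation <- function(n0, n1, n2, a = 0.5, class = "trait",
                            sDel = 0) {
  N <- n0 + n1 + n2
  cfg <- simulationConfig(N = N, L = 10000, bufferLen = 4000,
                          geneLen = 1000, mu = 0, rec = 0, sDel = sDel,
                          optMode = "none", burnIn = 0L, postGens = 0L)
  h <- replicate(2L * N, integer(), simplify = FALSE)
  i <- 0L
  for (k in seq_len(n2)) { i <- i + 1L; h[[2 * i - 1]] <- 1L; h[[2 * i]] <- 1L }
  for (k in seq_len(n1)) { i <- i + 1L; h[[2 * i - 1]] <- 1L }
  selfpoly:::newPopulation(h, positions = 4500L, classes = class,
                           effects = if (class == "trait") a else 0,
                           config = cfg)
}

# two-haplotype-class population (each individual gets haplotype drawn
# from rows hapRows with exact counts) -- used to build LD fixtures
pairHapSample <- function(hapMat, positions, L = 50e3) {
  # hapMat: sites x haplotypes 0/1 matrix
  structure(list(geno = hapMat, id = seq_len(nrow(hapMat)),
                 position = as.integer(positions),
                 class = rep("trait", nrow(hapMat)),
                 origin = rep(0L, nrow(hapMat)),
                 effects = matrix(0.5, nrow(hapMat), 1),
                 freq = rowMeans(hapMat),
                 display = seq_len(nrow(hapMat)),
                 individuals = seq_len(ncol(hapMat) / 2),
                 generation = 0L, L = L),
            class = "HaplotypeSample")
}
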