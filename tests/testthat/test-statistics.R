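# Variance decomposition, inbreeding depression, LD machinery, haplotype
# sampling and allele trajectories.

test_that("variance decomposition reproduces hand-computed fixtures", {
  vd <- varianceDecomposition(makeFixture("hwe_single_locus"))
  expect_equal(vd$Vg, 0.125)
  expect_equal(vd$VI, 0)
  expect_equal(vd$CLD, 0, tolerance = 1e-10)
  expect_equal(vd$VG, 0.125)

  vd <- varianceDecomposition(makeFixture("inbred_single_locus"))
  expect_equal(vd$Vg, 0.125)
  expect_equal(vd$VI, 0.125)      # = F * Vg at F = 1
  expect_equal(vd$VG, 0.25)
  expect_equal(vd$CLD, 0, tolerance = 1e-10)

  vd <- varianceDecomposition(makeFixture("negative_ld_pair"))
  expect_equal(vd$VG, 0)          # every gamete carries the same value
  expect_equal(vd$Vg, 0.25)
  expect_equal(vd$VI, 0)
  expect_equal(vd$CLD, -0.25)

  expect_error(varianceDecomposition(makeFixture("hwe_single_locus"),
                                     individuals = integer()))
})

test_that("variance identity holds and VI/Vg recovers F at the single locus", {
  # identity on simulated populations, against the in-run C++ stream
  cfg <- deskConfig(N = 60, L = 50e3, selfing = 0.9, burnIn = 300,
                    postGens = 0, sDel = 0)
  set.seed(5)
  res <- runSimulation(cfg, generations = 300,
                       statsGens = 300L, snapshotGens = 300L)
  vd <- varianceDecomposition(snapshots(res)[[1]])
  expect_equal(vd$VG, vd$Vg + vd$VI + vd$CLD, tolerance = 1e-10)
  st <- simStats(res)
  expect_equal(vd$VG, st$VG1, tolerance = 1e-8)
  expect_equal(vd$Vg, st$Vg1, tolerance = 1e-8)
  expect_equal(vd$VI, st$VI1, tolerance = 1e-8)
  expect_equal(vd$meanZ, st$meanZ1, tolerance = 1e-8)
  expect_equal(vd$meanFitness, st$meanFitness, tolerance = 1e-8)

  # single-locus F-model with exact genotype counts: VI = 2 F p q a^2
  for (Fv in c(0.2, 0.5, 1)) for (p in c(0.3, 0.5)) {
    q <- 1 - p
    n1 <- round(200 * 2 * p * q * (1 - Fv))
    n2 <- round(200 * (p^2 + Fv * p * q))
    pop <- countPopulation(200 - n1 - n2, n1, n2, a = 0.5)
    vd <- varianceDecomposition(pop)
    pexact <- (n1 / 2 + n2) / 200
    expect_equal(vd$Vg, 2 * pexact * (1 - pexact) * 0.25)
    if (n1 / 200 == 2 * p * q * (1 - Fv) && pexact == p)
      expect_equal(vd$VI / vd$Vg, Fv)
  }
})

test_that("excess homozygosity reads F from genotype proportions", {
  expect_equal(excessHomozygosity(makeFixture("hwe_single_locus")), 0)
  expect_equal(excessHomozygosity(makeFixture("inbred_single_locus")), 1)
  pop <- countPopulation(75, 50, 75, a = 0.5)  # F = 0.5 at p = 0.5
  expect_equal(excessHomozygosity(pop), 0.5)
})

test_that("inbreeding depression matches closed-form cohort expectations", {
  # no segregating selected variation: identical cohorts in expectation
  quiet <- countPopulation(100, 0, 0, a = 0.5)
  expect_equal(inbreedingDepression(quiet, nOffspring = 200), 0)

  # every individual heterozygous for one partially recessive deleterious
  # site: selfed and outcrossed offspring have the same 1:2:1 genotype
  # distribution, so inbreeding depression vanishes in expectation
  allHet <- countPopulation(0, 400, 0, class = "deleterious", sDel = 0.02)
  set.seed(2)
  idHet <- mean(replicate(8, inbreedingDepression(allHet, 4000)))
  expect_equal(idHet, 0, tolerance = 3e-4)

  # deleterious allele at Hardy-Weinberg p = 0.5: selfing exposes
  # homozygotes.  Closed form with fitness-weighted parent sampling:
  w <- c(1, 1 - 0.2 * 0.02, 1 - 0.02)           # w0, w1, w2
  f <- c(0.25, 0.5, 0.25)
  pw <- f * w / sum(f * w)
  wS <- sum(pw * c(w[1], sum(c(0.25, 0.5, 0.25) * w), w[3]))
  pgam <- sum(pw * c(0, 0.5, 1))                 # derived-gamete frequency
  wO <- sum(c((1 - pgam)^2, 2 * pgam * (1 - pgam), pgam^2) * w)
  idExact <- 1 - wS / wO
  hwPop <- countPopulation(100, 200, 100, class = "deleterious",
                           sDel = 0.02)
  set.seed(3)
  idObs <- mean(replicate(8, inbreedingDepression(hwPop, 4000)))
  expect_gt(idExact, 0)
  expect_equal(idObs, idExact, tolerance = 0.15)
})

test_that("pairwise LD matches hand computation and a contingency oracle", {
  # haplotypes AB x4, Ab x1, aB x1, ab x4
  A <- c(rep(1, 5), rep(0, 5))
  B <- c(rep(1, 4), 0, 1, rep(0, 4))
  samp <- pairHapSample(rbind(A, B), positions = c(0, 30e3))
  tab <- ldMatrix(samp, maf = 0.1, minDist = 1e3)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$D, 0.15)
  expect_equal(tab$r2, 0.36)
  expect_equal(tab$dprime, 0.6)

  # perfect coupling and near-independence
  full <- pairHapSample(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)),
                        positions = c(0, 30e3))
  tabF <- ldMatrix(full, minDist = 1e3)
  expect_equal(tabF$r2, 1)
  expect_equal(tabF$dprime, 1)

  set.seed(11)
  H <- 400
  ind <- rbind(sample(0:1, H, TRUE), sample(0:1, H, TRUE))
  tabI <- ldMatrix(pairHapSample(ind, c(0, 30e3)), minDist = 1e3)
  expect_lt(tabI$r2, 0.03)

  # random matrices against the contingency-table oracle
  set.seed(12)
  for (k in 1:10) {
    M <- matrix(rbinom(5 * 40, 1, runif(1, 0.2, 0.8)), 5, 40)
    tab <- ldMatrix(pairHapSample(M, seq(0, 8e4, by = 2e4)),
                    maf = 0.1, minDist = 1e3)
    for (r in seq_len(nrow(tab))) {
      ref <- refPairLd(M[tab$idA[r], ], M[tab$idB[r], ])
      expect_equal(tab$r2[r], ref$r2)
      expect_equal(tab$dprime[r], ref$dprime)
      expect_equal(tab$D[r], ref$D)
    }
  }
})

test_that("LD filters: MAF cutoff and greedy distance thinning", {
  # four SNPs; second violates spacing, fourth (freq 0.05) violates MAF
  M <- rbind(rep(c(1, 0), 10),
             rep(c(1, 1, 0, 0), 5),
             rep(c(0, 1), 10),
             c(1, rep(0, 19)))
  samp <- pairHapSample(M, positions = c(0, 3e5, 6e5, 11e5), L = 25e6)
  tab <- ldMatrix(samp, maf = 0.1, minDist = 5e5)
  expect_equal(sort(unique(c(tab$posA, tab$posB))), c(0, 6e5))
  # minDist defaults to L / 50 = 0.5 Mb here
  tabDefault <- ldMatrix(samp, maf = 0.1)
  expect_equal(tabDefault$posA, tab$posA)
  # a single surviving SNP yields an empty table with a warning
  expect_warning(empty <- ldMatrix(samp, maf = 0.1, minDist = 2e6))
  expect_equal(nrow(empty), 0)
})

test_that("LD decay binning, down-sampling and replicate dropping", {
  mkTab <- function(dists, r2 = 0.5) {
    structure(data.frame(idA = 1, idB = 2, posA = 0, posB = dists,
                         dist = dists, D = 0.1, r2 = r2, dprime = 0.8),
              L = 25e6)
  }
  # bins with 12 / 30 / 50 entries all down-sample to 12
  d <- c(runif(12, 0, 0.5e6), runif(30, 0.5e6, 1e6), runif(50, 1e6, 1.5e6))
  set.seed(4)
  dec <- ldDecay(mkTab(d), binWidth = 0.5e6, maxDist = 12.5e6)
  expect_equal(dec$perReplicate$n, c(12, 12, 12))
  expect_equal(dec$dropped, integer(0))

  # sparsest bin below 10 entries: the replicate is omitted
  d2 <- c(runif(9, 0, 0.5e6), runif(30, 0.5e6, 1e6))
  expect_warning(dec2 <- ldDecay(mkTab(d2), binWidth = 0.5e6,
                                 maxDist = 12.5e6))
  expect_equal(dec2$dropped, 1L)

  # pairs beyond half the genome are excluded before binning
  d3 <- c(runif(15, 0, 0.5e6), rep(13e6, 40))
  dec3 <- ldDecay(mkTab(d3), binWidth = 0.5e6, maxDist = 12.5e6)
  expect_equal(nrow(dec3$perReplicate), 1)
  expect_equal(dec3$perReplicate$n, 15)

  # two replicates: cross-replicate mean averages matching bins
  set.seed(6)
  dec4 <- ldDecay(list(mkTab(runif(40, 0, 1e6), r2 = 0.2),
                       mkTab(runif(40, 0, 1e6), r2 = 0.6)),
                  binWidth = 0.5e6, maxDist = 12.5e6)
  expect_equal(dec4$mean$meanR2, rep(0.4, nrow(dec4$mean)))
})

test_that("haplotype sampling thins with trait-variant priority", {
  cfg <- simulationConfig(N = 60, L = 1e6, bufferLen = 4000, geneLen = 1000,
                          mu = 0, rec = 0, sDel = 0, optMode = "none",
                          burnIn = 0L, postGens = 0L)
  buildPop <- function(nTrait, nNeutral, nFixedTrait = 0) {
    m <- nTrait + nNeutral + nFixedTrait
    pos <- sort(sample.int(1e6, m))
    cls <- c(rep("trait", nTrait), rep("neutral", nNeutral),
             rep("trait", nFixedTrait))
    h <- replicate(120, integer(), simplify = FALSE)
    for (j in seq_len(nTrait + nNeutral)) {
      carriers <- sample.int(120, sample(2:100, 1))
      for (k in carriers) h[[k]] <- sort(c(h[[k]], j))
    }
    if (nFixedTrait > 0)
      for (j in (m - nFixedTrait + 1):m)
        for (k in seq_len(120)) h[[k]] <- sort(c(h[[k]], j))
    selfpoly:::newPopulation(h, pos, cls, effects = 0.1, config = cfg)
  }
  set.seed(21)
  # more trait variants than space: thinned to exactly 100 trait rows
  samp <- haplotypeSample(buildPop(150, 30), nInd = 60)
  expect_equal(length(samp$display), 100)
  expect_true(all(samp$class[samp$display] == "trait"))

  # 80 segregating trait variants: all kept, background fills to 100
  samp2 <- haplotypeSample(buildPop(80, 60), nInd = 60)
  expect_equal(length(samp2$display), 100)
  expect_equal(sum(samp2$class[samp2$display] == "trait"), 80)

  # trait mutations fixed in the sample are never displayed
  samp3 <- haplotypeSample(buildPop(20, 10, nFixedTrait = 5), nInd = 60)
  shown <- samp3$freq[samp3$display]
  expect_true(all(!(samp3$class[samp3$display] == "trait" & shown == 1)))

  # requesting more individuals than exist warns and samples everyone
  expect_warning(samp4 <- haplotypeSample(buildPop(5, 5), nInd = 100))
  expect_equal(ncol(samp4$geno), 120)
})

test_that("allele trajectories track pre-shift variants through the ledger", {
  cfg <- simulationConfig(N = 10, L = 1e6, bufferLen = 4000, geneLen = 1000,
                          mu = 0, rec = 0, sDel = 0, optMode = "none",
                          burnIn = 0L, postGens = 0L)
  hap <- function(rows) replicate(20, integer(), simplify = FALSE) |>
    (\(h) { for (r in names(rows)) h[[as.integer(r)]] <- rows[[r]]; h })()
  # reference snapshot: trait mutations 1 (rare) and 2 (common)
  ref <- selfpoly:::newPopulation(
    hap(list(`1` = c(1L, 2L), `2` = 2L, `3` = 2L, `4` = 2L)),
    positions = c(4100L, 4500L), classes = c("trait", "trait"),
    effects = c(0.3, -0.2), config = cfg)
  # later snapshot: mutation 1 lost, mutation 2 fixed (in the ledger),
  # and a new mutation (id 7) that must be excluded
  later <- selfpoly:::newPopulation(
    hap(list(`5` = 1L)), positions = 9400L, classes = "trait",
    effects = 0.1, config = cfg, generation = 40L)
  later@mutations$id <- 7L
  later@substitutions <- data.frame(id = 2L, position = 4500L,
                                    class = "trait", origin = 0L,
                                    fixed = 25L)
  later@subEffects <- matrix(-0.2, 1, 1)
  tr <- alleleTrajectories(list(ref, later))
  expect_equal(tr$id, c(1L, 2L))
  expect_equal(tr$freq_0, c(1 / 20, 4 / 20))
  expect_equal(tr$freq_40, c(0, 1))
})

test_that("VCF output round-trips through an independent reader", {
  set.seed(31)
  pop <- makeFixture("random_small")
  samp <- haplotypeSample(pop, nInd = 20)
  path <- file.path(tempdir(), "sample.vcf")
  writeVcf(samp, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(samp$geno))
  expect_equal(as.integer(v@fix[, "POS"]), samp$position + 1L)
  gt <- vcfR::extract.gt(v, return.alleles = FALSE)
  # reconstruct the phased matrix and compare
  rebuilt <- do.call(cbind, lapply(seq_len(ncol(gt)), function(k) {
    parts <- strsplit(gt[, k], "|", fixed = TRUE)
    cbind(as.integer(vapply(parts, `[`, "", 1)),
          as.integer(vapply(parts, `[`, "", 2)))
  }))
  expect_equal(unname(rebuilt), unname(samp$geno))

  # the package's own reader recovers the annotations too
  back <- readVcfSample(path)
  expect_equal(back$geno, unname(samp$geno))
  expect_equal(back$position, samp$position)
  expect_equal(back$class, samp$class)
  expect_equal(back$origin, samp$origin)
  expect_equal(back$effects, unname(samp$effects), tolerance = 1e-6)
  expect_equal(back$L, samp$L)
})
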