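# Downstream measurements on simulated populations: variance
# decomposition, inbreeding depression, LD matrices and decay curves,
# haplotype sampling and allele-frequency trajectories.

# per-mutation genotype counts (het/hom individuals) over a set of
# individuals; returns frequencies f0, f1, f2 and derived-allele p
genotypeCounts <- function(pop, individuals = NULL) {
  N <- pop@config@N
  if (is.null(individuals)) individuals <- seq_len(N)
  nI <- length(individuals)
  m <- nrow(pop@mutations)
  hapIdx <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  haps <- pop@haplotypes[hapIdx]
  ids <- unlist(haps, use.names = FALSE)
  if (m == 0L || length(ids) == 0L) {
    z <- numeric(m)
    return(list(f0 = z + 1, f1 = z, f2 = z, p = z, n = nI))
  }
  ind <- rep(rep(seq_len(nI), each = 2L), lengths(haps))
  cnt <- tabulate(ids + m * (ind - 1L), nbins = m * nI)
  dim(cnt) <- c(m, nI)
  f1 <- rowSums(cnt == 1L) / nI
  f2 <- rowSums(cnt == 2L) / nI
  list(f0 = 1 - f1 - f2, f1 = f1, f2 = f2, p = f1 / 2 + f2, n = nI)
}

#' Excess homozygosity
#'
#' The inbreeding coefficient estimated from genotype frequencies:
#' \eqn{\hat F = 1 - \sum_j f_{1,j} / \sum_j 2 p_j (1 - p_j)} over
#' segregating sites of every class.  At neutral equilibrium under partial
#' selfing its expectation is \eqn{\sigma/(2-\sigma)}.
#'
#' @param pop a [Population-class]
#' @param individuals subset of individuals (default: all)
#' @return the excess-homozygosity estimate (NA with no segregating sites)
#' @export
excessHomozygosity <- function(pop, individuals = NULL) {
  gc <- genotypeCounts(pop, individuals)
  seg <- gc$p > 0 & gc$p < 1
  hexp <- sum(2 * gc$p[seg] * (1 - gc$p[seg]))
  if (hexp == 0) return(NA_real_)
  1 - sum(gc$f1[seg]) / hexp
}

#' Variance decomposition of trait values
#'
#' Decomposes, per trait, the genetic variance \eqn{V_G} (the realised
#' variance of individual trait values, so cross-locus covariances are
#' captured) into the genic variance
#' \eqn{V_g = \sum_j 2 p_j(1-p_j) a_j^2}, the inbreeding covariance
#' \eqn{V_I = \sum_j (2 f_{2,j} f_{0,j} - \tfrac12 f_{1,j}^2) a_j^2}
#' (zero at Hardy-Weinberg proportions; \eqn{2Fpq a^2} under the
#' single-locus F-model), and the linkage-disequilibrium covariance
#' \eqn{C_{LD} = V_G - V_g - V_I}.
#'
#' @param pop a [Population-class]
#' @param individuals subset of individuals (default: all)
#' @return a data.frame with one row per trait: trait, meanZ, VG, Vg, VI,
#'   CLD, meanFitness, varFitness, generation
#' @examples
#' varianceDecomposition(makeFixture("negative_ld_pair"))
#' @export
varianceDecomposition <- function(pop, individuals = NULL) {
  N <- pop@config@N
  if (is.null(individuals)) individuals <- seq_len(N)
  if (length(individuals) == 0L) stop("empty sample")
  nt <- pop@config@nTraits
  gc <- genotypeCounts(pop, individuals)
  # individual trait values: additive over both haplotypes + substitutions
  hapIdx <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  haps <- pop@haplotypes[hapIdx]
  ids <- unlist(haps, use.names = FALSE)
  z <- matrix(rep(pop@zSub, each = length(individuals)),
              length(individuals), nt)
  if (length(ids)) {
    ind <- rep(rep(seq_along(individuals), each = 2L), lengths(haps))
    zi <- rowsum(pop@effects[ids, , drop = FALSE], group = ind)
    z[as.integer(rownames(zi)), ] <- z[as.integer(rownames(zi)), ] +
      unname(zi)
  }
  isTrait <- pop@mutations$class == "trait"
  w <- individualFitness(pop)$w[individuals]
  out <- data.frame(trait = seq_len(nt), meanZ = NA_real_, VG = NA_real_,
                    Vg = NA_real_, VI = NA_real_, CLD = NA_real_,
                    meanFitness = mean(w),
                    varFitness = mean((w - mean(w))^2),
                    generation = pop@generation)
  for (t in seq_len(nt)) {
    a2 <- pop@effects[, t]^2
    out$meanZ[t] <- mean(z[, t])
    out$VG[t] <- mean((z[, t] - out$meanZ[t])^2)
    out$Vg[t] <- sum((2 * gc$p * (1 - gc$p) * a2)[isTrait])
    out$VI[t] <- sum(((2 * gc$f2 * gc$f0 - 0.5 * gc$f1^2) * a2)[isTrait])
    out$CLD[t] <- out$VG[t] - out$Vg[t] - out$VI[t]
  }
  out
}

#' Inbreeding depression
#'
#' Produces two cohorts of offspring from fitness-sampled parents of the
#' source population -- one by obligate selfing, one by obligate
#' outcrossing -- with mutation disabled, and returns
#' \eqn{1 - \bar w_S / \bar w_O}.  The cohorts are discarded.
#'
#' @param pop a [Population-class]
#' @param nOffspring cohort size (default 500)
#' @return the inbreeding-depression estimate
#' @export
inbreedingDepression <- function(pop, nOffspring = 500L) {
  cpop <- asCppPop(pop)
  ccfg <- asCppConfig(pop@config, shiftGenOf(pop))
  wS <- mean(cpp_cohort_fitness(cpop, ccfg, as.integer(nOffspring), TRUE))
  wO <- mean(cpp_cohort_fitness(cpop, ccfg, as.integer(nOffspring), FALSE))
  if (wO == 0) stop("outcrossed cohort has zero mean fitness")
  1 - wS / wO
}

#' Sample phased haplotypes from a population
#'
#' Draws `nInd` random individuals and returns their phased 0/1 genotype
#' matrix over the mutations segregating within the sample, together with
#' positions, classes and effects.  For plotting, `display` indexes up to
#' `thin` rows: trait mutations fixed within the sample are excluded, then
#' segregating trait variants are prioritised and background (neutral or
#' deleterious) mutations fill the remaining space.
#'
#' @param pop a [Population-class]
#' @param nInd number of individuals to sample (default 50; capped at N
#'   with a warning)
#' @param thin maximum number of rows indexed by `display`
#' @return an object of class `HaplotypeSample`: a list with elements
#'   `geno` (sites x 2*nInd matrix), `id`, `position`, `class`, `origin`,
#'   `effects`, `freq` (within-sample), `display`, `individuals`,
#'   `generation` and `L`
#' @export
haplotypeSample <- function(pop, nInd = 50L, thin = 100L) {
  N <- pop@config@N
  if (N < nInd) {
    warning("population smaller than requested sample; sampling all ", N,
            " individuals")
    nInd <- N
  }
  individuals <- sort(sample.int(N, nInd))
  hapIdx <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  m <- nrow(pop@mutations)
  H <- 2L * nInd
  geno <- matrix(0L, m, H)
  for (k in seq_len(H)) geno[pop@haplotypes[[hapIdx[k]]], k] <- 1L
  present <- rowSums(geno) > 0L
  geno <- geno[present, , drop = FALSE]
  mut <- pop@mutations[present, , drop = FALSE]
  eff <- pop@effects[present, , drop = FALSE]
  freq <- rowSums(geno) / H
  ord <- order(mut$position)
  geno <- geno[ord, , drop = FALSE]
  mut <- mut[ord, , drop = FALSE]
  eff <- eff[ord, , drop = FALSE]
  freq <- freq[ord]

  isTrait <- mut$class == "trait"
  segTrait <- which(isTrait & freq < 1)
  background <- which(!isTrait)
  if (length(segTrait) > thin) {
    display <- sort(sample(segTrait, thin))
  } else {
    fill <- min(thin - length(segTrait), length(background))
    extra <- if (fill > 0) sample(background, fill) else integer()
    display <- sort(c(segTrait, extra))
  }
  structure(list(geno = geno, id = mut$id, position = mut$position,
                 class = mut$class, origin = mut$origin, effects = eff,
                 freq = freq, display = display,
                 individuals = individuals, generation = pop@generation,
                 L = pop@config@L),
            class = "HaplotypeSample")
}

#' Pairwise linkage disequilibrium table
#'
#' Filters the sampled SNPs to minor allele frequency >= `maf`, thins them
#' greedily left-to-right so retained variants are at least `minDist`
#' apart (the first SNP is kept, then each next SNP at least `minDist`
#' beyond the last retained one), and returns \eqn{r^2} (squared allelic
#' correlation) and \eqn{|D'|} (D normalised by its frequency-given bound)
#' for every retained pair.
#'
#' `minDist` defaults to L/50, the genome fraction corresponding to
#' 0.5 Mb on the full-scale 25 Mb genome, so desk-scale runs retain the
#' same fraction of sites.
#'
#' @param x a `HaplotypeSample` (see [haplotypeSample()])
#' @param maf minor-allele-frequency threshold (inclusive)
#' @param minDist minimum distance between retained SNPs (bp)
#' @return a data.frame (`LDTable`) with columns idA, idB, posA, posB,
#'   dist, D, r2, dprime; zero rows (with a warning) if fewer than two
#'   SNPs survive the filters
#' @examples
#' set.seed(1)
#' cfg <- deskConfig(N = 50, L = 50e3, burnIn = 200, postGens = 0)
#' pop <- finalPopulation(runSimulation(cfg, generations = 200))
#' ld <- ldMatrix(haplotypeSample(pop, 25))
#' @export
ldMatrix <- function(x, maf = 0.1, minDist = NULL) {
  stopifnot(inherits(x, "HaplotypeSample"))
  if (is.null(minDist)) minDist <- x$L / 50
  p <- rowMeans(x$geno)
  keep <- which(pmin(p, 1 - p) >= maf)
  if (length(keep)) {          # greedy thinning on position-ordered SNPs
    kept <- keep[1]
    last <- x$position[keep[1]]
    for (k in keep[-1]) {
      if (x$position[k] >= last + minDist) {
        kept <- c(kept, k)
        last <- x$position[k]
      }
    }
    keep <- kept
  }
  if (length(keep) < 2) {
    warning("fewer than two SNPs retained; returning an empty LD table")
    return(data.frame(idA = integer(), idB = integer(), posA = integer(),
                      posB = integer(), dist = numeric(), D = numeric(),
                      r2 = numeric(), dprime = numeric()))
  }
  G <- x$geno[keep, , drop = FALSE]
  H <- ncol(G)
  p <- rowMeans(G)
  P11 <- tcrossprod(G) / H
  D <- P11 - outer(p, p)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  d <- D[pairs]
  dmax <- ifelse(d > 0,
                 pmin(p[i] * (1 - p[j]), (1 - p[i]) * p[j]),
                 pmin(p[i] * p[j], (1 - p[i]) * (1 - p[j])))
  out <- data.frame(idA = x$id[keep][i], idB = x$id[keep][j],
                    posA = x$position[keep][i], posB = x$position[keep][j],
                    dist = abs(x$position[keep][j] - x$position[keep][i]),
                    D = d,
                    r2 = d^2 / (p[i] * (1 - p[i]) * p[j] * (1 - p[j])),
                    dprime = ifelse(dmax > 0, abs(d) / dmax, 0))
  attr(out, "L") <- x$L
  out
}

#' Binned LD-decay curves across replicates
#'
#' Bins each replicate's pairwise distances into `binWidth`-wide bins up
#' to `maxDist` (defaults: L/50 and L/2, matching 0.5 Mb bins capped at
#' 12.5 Mb on the full-scale genome), randomly down-samples every bin to
#' the smallest bin count so each distance contributes equally, and drops
#' a replicate entirely when that smallest count is below `minBinCount`.
#'
#' @param tables one LD table (see [ldMatrix()]) or a list of them
#' @param binWidth bin width in bp
#' @param maxDist maximum pair distance considered
#' @param minBinCount minimum per-bin pair count for a replicate to be kept
#' @return list with `perReplicate` (replicate, binMid, n, meanR2,
#'   meanDprime), `mean` (cross-replicate means per bin) and `dropped`
#'   (indices of omitted replicates); empty with a warning if every
#'   replicate is dropped
#' @export
ldDecay <- function(tables, binWidth = NULL, maxDist = NULL,
                    minBinCount = 10L) {
  if (is.data.frame(tables)) tables <- list(tables)
  L <- attr(tables[[1]], "L")
  if (is.null(binWidth)) binWidth <- if (is.null(L)) stop("binWidth needed") else L / 50
  if (is.null(maxDist)) maxDist <- if (is.null(L)) stop("maxDist needed") else L / 2
  per <- list()
  dropped <- integer()
  for (rep in seq_along(tables)) {
    tab <- tables[[rep]]
    tab <- tab[tab$dist < maxDist, , drop = FALSE]
    if (nrow(tab) == 0) { dropped <- c(dropped, rep); next }
    bin <- floor(tab$dist / binWidth)
    counts <- table(bin)
    minc <- min(counts)
    if (minc < minBinCount) { dropped <- c(dropped, rep); next }
    rows <- unlist(lapply(split(seq_len(nrow(tab)), bin), function(idx) {
      if (length(idx) > minc) sample(idx, minc) else idx
    }), use.names = FALSE)
    tab <- tab[rows, , drop = FALSE]
    bin <- floor(tab$dist / binWidth)
    agg <- do.call(rbind, lapply(split(tab, bin), function(b)
      data.frame(binMid = (floor(b$dist[1] / binWidth) + 0.5) * binWidth,
                 n = nrow(b), meanR2 = mean(b$r2),
                 meanDprime = mean(b$dprime))))
    agg$replicate <- rep
    per[[length(per) + 1]] <- agg
  }
  if (!length(per)) {
    warning("all replicates dropped by the minimum-bin-count rule")
    return(list(perReplicate = data.frame(), mean = data.frame(),
                dropped = dropped))
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  mids <- sort(unique(per$binMid))
  avg <- do.call(rbind, lapply(mids, function(mid) {
    b <- per[per$binMid == mid, ]
    data.frame(binMid = mid, nReplicates = nrow(b), meanR2 = mean(b$meanR2),
               meanDprime = mean(b$meanDprime))
  }))
  list(perReplicate = per[, c("replicate", "binMid", "n", "meanR2",
                              "meanDprime")],
       mean = avg, dropped = dropped)
}

#' Trait-allele frequency trajectories across snapshots
#'
#' Tracks, over a series of whole-population snapshots, every trait
#' mutation segregating in the first (reference, typically pre-shift)
#' snapshot; mutations arising later are excluded.  A mutation absent from
#' a later snapshot is read from that snapshot's substitutions ledger
#' (frequency 1 if it fixed by then, 0 if it was lost).
#'
#' @param snaps list of [Population-class] snapshots in time order
#' @return data.frame with id, position, meanEffect and one `freq_<gen>`
#'   column per snapshot
#' @export
alleleTrajectories <- function(snaps) {
  stopifnot(length(snaps) >= 1)
  ref <- snaps[[1]]
  isTrait <- ref@mutations$class == "trait"
  ids <- ref@mutations$id[isTrait]
  out <- data.frame(id = ids, position = ref@mutations$position[isTrait],
                    meanEffect = rowMeans(ref@effects[isTrait, ,
                                                      drop = FALSE]))
  for (s in snaps) {
    freq <- alleleFrequencies(s)
    f <- freq[match(ids, s@mutations$id)]
    missing <- is.na(f)
    if (any(missing)) {
      fixedBy <- s@substitutions$fixed[match(ids[missing],
                                             s@substitutions$id)]
      f[missing] <- ifelse(!is.na(fixedBy) & fixedBy <= s@generation, 1, 0)
    }
    out[[paste0("freq_", s@generation)]] <- f
  }
  out
}
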