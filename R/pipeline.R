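# Orchestration: experiment grids over parameter combinations, seeded
# replicates with a manifest, and deterministic fixture populations with
# analytically known variance components.

#' Build an experiment grid
#'
#' Expands `vary` (named lists of values for [simulationConfig()]
#' arguments, e.g. `list(selfing = c(0, 0.999), sDel = c(0, 0.02))`) into
#' the full factorial grid times `replicates`, assigning every
#' (configuration, replicate) pair a distinct seed derived
#' deterministically from `seed`.
#'
#' @param config base [SimulationConfig-class]
#' @param vary named list of parameter values to cross
#' @param replicates replicates per parameter combination
#' @param seed top-level seed from which run seeds are derived
#' @return an `ExperimentGrid`: a data.frame of runs (label, replicate,
#'   seed, varied parameters) with the per-run configs in attribute
#'   `configs`
#' @export
experimentGrid <- function(config, vary = list(), replicates = 1L,
                           seed = 1L) {
  combos <- if (length(vary)) expand.grid(vary, KEEP.OUT.ATTRS = FALSE)
            else data.frame(row.names = 1)
  nC <- max(1L, nrow(combos))
  runs <- expand.grid(combo = seq_len(nC), replicate = seq_len(replicates))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nrow(runs))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  configs <- vector("list", nrow(runs))
  labels <- character(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    cfg <- config
    ci <- runs$combo[k]
    if (ncol(combos)) {
      for (nm in names(combos)) slot(cfg, nm) <- combos[[nm]][ci]
      labels[k] <- paste(paste0(names(combos), "=",
                                unlist(combos[ci, , drop = FALSE])),
                         collapse = ",")
    } else labels[k] <- "base"
    validObject(cfg)
    configs[[k]] <- cfg
  }
  out <- data.frame(label = labels, replicate = runs$replicate,
                    seed = seeds)
  if (ncol(combos)) out <- cbind(out, combos[runs$combo, , drop = FALSE])
  rownames(out) <- NULL
  structure(out, configs = configs, class = c("ExperimentGrid",
                                              "data.frame"))
}

#' Run an experiment grid
#'
#' Runs every (configuration, replicate) entry of the grid under its own
#' seed and writes, per run, the statistics stream
#' (`<run>/stats.tsv`), the substitutions ledger
#' (`<run>/substitutions.tsv`) and one VCF haplotype sample per snapshot
#' timepoint (`<run>/sample_gen<g>.vcf`), plus a top-level `manifest.tsv`
#' recording label, seed and status.  A failing run is recorded in the
#' manifest and the experiment continues.
#'
#' @param grid an `ExperimentGrid` from [experimentGrid()]
#' @param outDir output directory (created if needed)
#' @param nSample individuals per VCF haplotype sample
#' @param ... further arguments passed to [runSimulation()]
#' @return the manifest data.frame, invisibly
#' @export
runExperiment <- function(grid, outDir, nSample = 50L, ...) {
  stopifnot(inherits(grid, "ExperimentGrid"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  configs <- attr(grid, "configs")
  manifest <- cbind(as.data.frame(grid), status = "ok", error = "")
  for (k in seq_len(nrow(grid))) {
    runDir <- file.path(outDir, sprintf("run%03d", k))
    dir.create(runDir, showWarnings = FALSE)
    status <- tryCatch({
      set.seed(grid$seed[k])
      res <- runSimulation(configs[[k]], ...)
      write.table(simStats(res), file.path(runDir, "stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(substitutionTable(finalPopulation(res)),
                  file.path(runDir, "substitutions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      for (snap in snapshots(res)) {
        samp <- haplotypeSample(snap, min(nSample, configs[[k]]@N))
        writeVcf(samp, file.path(runDir, sprintf("sample_gen%d.vcf",
                                                 snap@generation)))
      }
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    if (status != "ok") {
      manifest$status[k] <- "failed"
      manifest$error[k] <- status
    }
  }
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# bare-hands Population builder used by the fixtures
newPopulation <- function(haplotypes, positions, classes, effects, config,
                          generation = 0L, origin = 0L) {
  m <- length(positions)
  effects <- matrix(effects, nrow = m, ncol = config@nTraits)
  new("Population", haplotypes = haplotypes,
      mutations = data.frame(id = seq_len(m), position = as.integer(positions),
                             class = classes,
                             origin = rep_len(as.integer(origin), m)),
      effects = effects,
      substitutions = data.frame(id = integer(), position = integer(),
                                 class = character(), origin = integer(),
                                 fixed = integer()),
      subEffects = matrix(numeric(), 0, config@nTraits),
      generation = as.integer(generation),
      optimum = numeric(config@nTraits), zSub = numeric(config@nTraits),
      nSubDel = 0L, config = config)
}

#' Deterministic fixture populations
#'
#' Small populations with analytically known variance components, for
#' testing the statistics machinery:
#' \describe{
#'   \item{hwe_single_locus}{one trait locus (a = 0.5, p = 0.5) at exact
#'     Hardy-Weinberg proportions: Vg = VG = 0.125, VI = CLD = 0.}
#'   \item{inbred_single_locus}{the same locus fully inbred
#'     (f0 = f2 = 0.5): Vg = VI = 0.125, VG = 0.25, CLD = 0.}
#'   \item{negative_ld_pair}{two loci (a = 0.5 each) in complete negative
#'     LD (haplotypes Ab, aB at 0.5 each, outbred): every gamete carries
#'     value 0.5, so VG = 0, Vg = 0.25, VI = 0, CLD = -0.25.}
#'   \item{random_small}{a short seeded desk-scale simulation (uses the
#'     current RNG state).}
#' }
#'
#' @param kind one of the fixture names above
#' @param N diploid size of the constructed fixtures (multiple of 4)
#' @return a [Population-class]
#' @export
makeFixture <- function(kind = c("hwe_single_locus", "inbred_single_locus",
                                 "negative_ld_pair", "random_small"),
                        N = 100L) {
  kind <- match.arg(kind)
  stopifnot(N %% 4 == 0)
  cfg <- simulationConfig(N = N, L = 10000, bufferLen = 4000,
                          geneLen = 1000, mu = 0, rec = 0, sDel = 0,
                          optMode = "none", burnIn = 0L, postGens = 0L)
  emptyHap <- replicate(2L * N, integer(), simplify = FALSE)
  hap <- function(assign) {       # assign: list of haplotype-index -> rows
    h <- emptyHap
    for (nm in names(assign)) h[[as.integer(nm)]] <- assign[[nm]]
    h
  }
  switch(kind,
    hwe_single_locus = {
      # N/4 homozygotes, N/2 heterozygotes (first haplotype), N/4 wildtype
      h <- emptyHap
      for (i in seq_len(N / 4)) { h[[2 * i - 1]] <- 1L; h[[2 * i]] <- 1L }
      for (i in (N / 4 + 1):(3 * N / 4)) h[[2 * i - 1]] <- 1L
      newPopulation(h, positions = 4500L, classes = "trait",
                    effects = 0.5, config = cfg)
    },
    inbred_single_locus = {
      h <- emptyHap
      for (i in seq_len(N / 2)) { h[[2 * i - 1]] <- 1L; h[[2 * i]] <- 1L }
      newPopulation(h, positions = 4500L, classes = "trait",
                    effects = 0.5, config = cfg)
    },
    negative_ld_pair = {
      # haplotypes Ab and aB at 0.5 each; genotypes at exact random-union
      # proportions: N/4 Ab/Ab, N/2 Ab/aB, N/4 aB/aB
      h <- emptyHap
      for (i in seq_len(N)) {
        h[[2 * i - 1]] <- if (i <= 3 * N / 4) 1L else 2L
        h[[2 * i]] <- if (i <= N / 4) 1L else 2L
      }
      newPopulation(h, positions = c(4200L, 4800L),
                    classes = c("trait", "trait"),
                    effects = c(0.5, 0.5), config = cfg)
    },
    random_small = {
      small <- deskConfig(N = 48, L = 50e3, burnIn = 200L, postGens = 0L,
                          sDel = 0, optMode = "none")
      finalPopulation(runSimulation(small, generations = 200L))
    })
}
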