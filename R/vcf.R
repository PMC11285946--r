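# Plain-text VCF output for haplotype samples: one record per segregating
# mutation, phased GT fields, INFO carrying the mutation class and the
# per-trait effects.

#' Write a haplotype sample as VCF
#'
#' Emits a minimal phased VCF 4.2 file with one record per mutation in the
#' sample.  INFO fields: `CLASS` (neutral/trait/deleterious), `ORIGIN`
#' (generation of appearance) and `EFF` (comma-separated per-trait
#' effects).  Positions are written 1-based.
#'
#' @param x a `HaplotypeSample` (see [haplotypeSample()])
#' @param file output path
#' @return the file path, invisibly
#' @export
writeVcf <- function(x, file) {
  stopifnot(inherits(x, "HaplotypeSample"))
  nInd <- ncol(x$geno) / 2
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=1,length=%d>", as.integer(x$L)),
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Mutation class\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=Integer,Description=\"Origin generation\">",
    "##INFO=<ID=EFF,Number=.,Type=Float,Description=\"Per-trait effects\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("i", seq_len(nInd))), collapse = "\t")), con)
  if (nrow(x$geno)) {
    gt <- matrix("", nrow(x$geno), nInd)
    for (k in seq_len(nInd))
      gt[, k] <- paste0(x$geno[, 2 * k - 1], "|", x$geno[, 2 * k])
    info <- sprintf("CLASS=%s;ORIGIN=%d;EFF=%s", x$class, x$origin,
                    apply(x$effects, 1, function(e)
                      paste(signif(e, 8), collapse = ",")))
    body <- cbind("1", x$position + 1L, x$id, "A", "T", ".", "PASS", info,
                  "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a haplotype-sample VCF
#'
#' Parses a phased VCF written by [writeVcf()] back into a
#' `HaplotypeSample`, recovering positions, classes, origins and
#' per-trait effects from the INFO column.
#'
#' @param file path to a VCF produced by [writeVcf()]
#' @return a `HaplotypeSample`
#' @export
readVcfSample <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  L <- as.numeric(sub(".*length=([0-9]+).*", "\\1",
                      grep("##contig", hdr, value = TRUE)[1]))
  if (!length(body)) {
    return(structure(list(geno = matrix(0L, 0, 0), id = integer(),
                          position = integer(), class = character(),
                          origin = integer(),
                          effects = matrix(numeric(), 0, 1),
                          freq = numeric(), display = integer(),
                          individuals = integer(), generation = NA_integer_,
                          L = L), class = "HaplotypeSample"))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  m <- length(f)
  nInd <- length(f[[1]]) - 9L
  info <- vapply(f, `[`, "", 8)
  grab <- function(key) sub(paste0(".*", key, "=([^;]*).*"), "\\1", info)
  effs <- strsplit(grab("EFF"), ",", fixed = TRUE)
  geno <- matrix(0L, m, 2L * nInd)
  for (r in seq_len(m)) {
    gt <- unlist(strsplit(f[[r]][10:(9 + nInd)], "|", fixed = TRUE))
    geno[r, ] <- as.integer(gt)
  }
  structure(list(geno = geno,
                 id = as.integer(vapply(f, `[`, "", 3)),
                 position = as.integer(vapply(f, `[`, "", 2)) - 1L,
                 class = grab("CLASS"),
                 origin = as.integer(grab("ORIGIN")),
                 effects = do.call(rbind, lapply(effs, as.numeric)),
                 freq = rowMeans(geno), display = seq_len(m),
                 individuals = seq_len(nInd), generation = NA_integer_,
                 L = L),
            class = "HaplotypeSample")
}
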