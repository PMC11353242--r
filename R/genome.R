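#' Genome model for the simulators and binning
#'
#' A genome model is the coordinate frame shared by the copy-number
#' simulator, the binned read-count simulator and the profiling stage:
#' chromosome names and lengths in bp, a bin size, and the base (modal)
#' ploidy of the cell line. Coordinates are 0-based, half-open throughout
#' the package; conversion to other conventions happens only at file
#' boundaries.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer-ish vector of chromosome lengths in bp, all > 0.
#' @param bin_size bin width in bp; every chromosome must hold at least one
#'   bin.
#' @param ploidy base ploidy (integer >= 1), the copy number of an
#'   unaltered locus.
#' @return An object of class `genome_model`: a list with `chrom`, `length`
#'   (named), `bin_size`, `ploidy`.
#' @examples
#' g <- genome_model(c("chr1", "chr2"), c(5e6, 3e6), bin_size = 1e6)
#' genome_bins(g)
#' @export
genome_model <- function(chrom, length, bin_size = 1e6, ploidy = 2L) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length))
    stop("`chrom` and `length` must have equal length")
  length <- as.double(length)
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  bin_size <- as.double(bin_size)
  if (bin_size <= 0 || any(length < bin_size))
    stop("`bin_size` must be positive and give >= 1 bin per chromosome")
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) stop("`ploidy` must be an integer >= 1")
  structure(
    list(chrom = as.character(chrom),
         length = stats::setNames(length, as.character(chrom)),
         bin_size = bin_size, ploidy = ploidy),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mbp, %.2g bp bins, ploidy %d\n",
              length(x$chrom), sum(x$length) / 1e6, x$bin_size, x$ploidy))
  invisible(x)
}

#' Toy 22-autosome genome
#'
#' The default evaluation genome: 22 autosomes with lengths proportional to
#' the human hg38 autosomes but rescaled to a 720 Mbp total (the magnitude
#' of a whole-genome difference comparison at desk scale), rounded to whole
#' Mbp so the default 1 Mbp bins tile every chromosome exactly. chr1 absorbs
#' the rounding remainder so the total is exactly 720 Mbp.
#'
#' @param bin_size bin width in bp (default 1 Mbp).
#' @param ploidy base ploidy; presets used in examples are 5 for a highly
#'   aneuploid line (~107 chromosomes) and 2 for a near-diploid line (~52).
#' @return A `genome_model`.
#' @examples
#' g <- toy_genome()
#' sum(g$length) / 1e6  # 720
#' @export
toy_genome <- function(bin_size = 1e6, ploidy = 2L) {
  # hg38 autosome lengths, Mbp
  hg38 <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35, 145.14,
            138.39, 133.80, 135.09, 133.28, 114.36, 107.04, 101.99, 90.34,
            83.26, 80.37, 58.62, 64.44, 46.71, 50.82)
  mb <- round(hg38 * 720 / sum(hg38))
  mb[1] <- mb[1] + (720 - sum(mb))
  genome_model(paste0("chr", 1:22), mb * 1e6, bin_size = bin_size,
               ploidy = ploidy)
}

#' Enumerate the bins of a genome model
#'
#' @param genome a `genome_model`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open); the last bin of a chromosome may be short.
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  out <- lapply(genome$chrom, function(ch) {
    len <- genome$length[[ch]]
    starts <- seq(0, len - 1, by = genome$bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + genome$bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
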