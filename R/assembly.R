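#' Construct a genome assembly
#'
#' A thin constructor around [GenomeInfoDb::Seqinfo] that pins the chromosome
#' universe every other function in the package validates coordinates against.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#'   Names are the chromosome identifiers, values must be positive.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' asm <- genome_assembly(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_assembly <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("chromosome names must be unique")
  }
  len <- as.integer(chrom_lengths)
  if (anyNA(len) || any(len <= 0)) {
    stop("every chromosome length must be a positive integer")
  }
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_lengths), seqlengths = len)
}

#' @noRd
assembly_lengths <- function(assembly) {
  stats::setNames(GenomeInfoDb::seqlengths(assembly),
                  GenomeInfoDb::seqnames(assembly))
}

# Validate that a GRanges fits inside an assembly; error names the offender.
#' @noRd
check_in_assembly <- function(gr, assembly, what = "interval") {
  lens <- assembly_lengths(assembly)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- !(chr %in% names(lens))
  if (any(bad)) {
    stop(sprintf("%s on unknown chromosome '%s'", what, chr[which(bad)[1]]))
  }
  over <- GenomicRanges::end(gr) > lens[chr] | GenomicRanges::start(gr) < 1L
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("%s %s:%d-%d exceeds chromosome bounds", what, chr[i],
                 GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
  }
  invisible(gr)
}

# Attach assembly seqinfo to a GRanges (keeping only assembly chromosomes).
#' @noRd
with_assembly <- function(gr, assembly) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(assembly)
  GenomeInfoDb::seqinfo(gr) <- assembly
  gr
}
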