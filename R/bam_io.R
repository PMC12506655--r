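#' Import reads from an indexed BAM file
#'
#' Reads alignments into the package's \code{\link{read_set}}
#' representation, keeping CIGAR strings so per-site base lookup is
#' alignment-aware. When a panel is supplied only alignments overlapping
#' panel sites are fetched (the BAM must be indexed); otherwise the whole
#' file is read.
#'
#' @param bam path to a coordinate-sorted BAM.
#' @param panel optional \code{\link{snp_panel}} restricting the fetch.
#' @param individual sample identifier to attach (default: BAM basename).
#' @param include_duplicates keep reads flagged as PCR/optical duplicates
#'   (default TRUE: they are not collapsed at this stage, but can be
#'   excluded here).
#' @return A \code{\link{read_set}} (secondary/supplementary and unmapped
#'   records excluded).
#' @export
read_bam_reads <- function(bam, panel = NULL, individual = NULL,
                           include_duplicates = TRUE) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  if (is.null(individual))
    individual <- sub("\\.bam$", "", basename(bam))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (include_duplicates) NA else FALSE)
  what <- c("qname", "rname", "pos", "strand", "seq", "qual", "mapq",
            "cigar")
  if (!is.null(panel)) {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("BAM index (.bai) not found for ", bam,
           "; index the file first")
    which <- GenomicRanges::GRanges(panel$chrom,
                                    IRanges::IRanges(panel$pos, panel$pos))
    param <- Rsamtools::ScanBamParam(flag = flag, what = what,
                                     which = which)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  x <- lapply(stats::setNames(what, what), function(w)
    do.call(c, lapply(unname(res), `[[`, w)))
  if (length(x$qname) == 0) return(empty_read_set())
  rs <- read_set(read_id = x$qname, individual = individual,
                 chrom = as.character(x$rname), start = x$pos,
                 seq = as.character(x$seq), qual = as.character(x$qual),
                 mapq = x$mapq, strand = as.character(x$strand),
                 cigar = as.character(x$cigar))
  # overlapping fetch windows can return a record once per window
  rs <- rs[!duplicated(rs$read_id), , drop = FALSE]
  as_read_set(rs)
}

#' Pile up panel-site observations directly from a BAM
#'
#' Convenience wrapper: \code{\link{read_bam_reads}} followed by
#' \code{\link{pileup_reads}}.
#'
#' @inheritParams read_bam_reads
#' @param min_mapq,min_baseq quality thresholds (default 30).
#' @return Observation table (see \code{\link{pileup_reads}}).
#' @export
observations_from_bam <- function(bam, panel, individual = NULL,
                                  min_mapq = 30, min_baseq = 30,
                                  include_duplicates = TRUE) {
  reads <- read_bam_reads(bam, panel, individual,
                          include_duplicates = include_duplicates)
  pileup_reads(reads, panel, min_mapq = min_mapq, min_baseq = min_baseq)
}

#' Write a read set as SAM text (optionally converting to BAM)
#'
#' Intended for exporting simulated reads so external tools (or
#' \code{\link{read_bam_reads}}) can consume them. Alignments are written
#' ungapped unless a CIGAR is present.
#'
#' @param reads a \code{\link{read_set}}.
#' @param path output path; ".sam" writes text, ".bam" additionally sorts,
#'   converts and indexes via Rsamtools.
#' @param ref_lengths named integer vector of reference sequence lengths
#'   for the header.
#' @return The output path.
#' @export
write_sam_reads <- function(reads, path, ref_lengths) {
  sam <- sub("\\.bam$", ".sam", path)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  flagv <- ifelse(reads$strand == "-", 16L, 0L)
  cig <- ifelse(is.na(reads$cigar), paste0(nchar(reads$seq), "M"),
                reads$cigar)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$read_id, flagv, reads$chrom, reads$start,
                  reads$mapq, cig, reads$seq, reads$qual)
  writeLines(c(hdr, body), sam)
  if (grepl("\\.bam$", path)) {
    tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    Rsamtools::sortBam(tmp, sub("\\.bam$", "", path))
    Rsamtools::indexBam(path)
    unlink(c(sam, tmp))
  }
  invisible(path)
}
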