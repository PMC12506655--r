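#' Construct an in-memory read set
#'
#' The package's working representation of aligned reads: one row per
#' alignment, with the stored sequence and base qualities in reference
#' orientation (as in a BAM record). In-process simulated reads are ungapped
#' (\code{cigar = NA} means an all-match alignment of \code{nchar(seq)});
#' reads imported from BAM keep their CIGAR so per-site offsets are computed
#' alignment-aware.
#'
#' @param read_id unique read identifiers.
#' @param individual sample identifier per read.
#' @param chrom,start mapped reference name and 1-based leftmost position;
#'   \code{NA} for unmapped reads.
#' @param seq sequence strings (reference orientation).
#' @param qual phred+33 quality strings, same lengths as \code{seq}.
#' @param mapq integer mapping qualities.
#' @param strand "+" or "-" (affects FASTQ export only).
#' @param is_modified logical; \code{TRUE} for allele-flipped copies.
#' @param flip_chrom,flip_pos for flipped copies, the panel site the read was
#'   modified at; \code{NA} otherwise.
#' @param cigar CIGAR strings or \code{NA} for ungapped alignments.
#' @return data.frame of class \code{read_set}.
#' @export
read_set <- function(read_id, individual, chrom, start, seq, qual, mapq,
                     strand = "+", is_modified = FALSE,
                     flip_chrom = NA_character_, flip_pos = NA_integer_,
                     cigar = NA_character_) {
  n <- length(read_id)
  rs <- data.frame(read_id = as.character(read_id),
                   individual = rep_len(as.character(individual), n),
                   chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   seq = as.character(seq),
                   qual = as.character(qual),
                   mapq = rep_len(as.integer(mapq), n),
                   strand = rep_len(as.character(strand), n),
                   is_modified = rep_len(as.logical(is_modified), n),
                   flip_chrom = rep_len(as.character(flip_chrom), n),
                   flip_pos = rep_len(as.integer(flip_pos), n),
                   cigar = rep_len(as.character(cigar), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(rs$read_id))
    stop("duplicate read_id in read set")
  bad <- !is.na(rs$seq) & !is.na(rs$qual) & nchar(rs$seq) != nchar(rs$qual)
  if (any(bad))
    stop("seq/qual length mismatch for read(s): ",
         paste(utils::head(rs$read_id[bad], 5), collapse = ", "))
  class(rs) <- c("read_set", "data.frame")
  rs
}

empty_read_set <- function() {
  read_set(character(), character(), character(), integer(),
           character(), character(), integer())
}

as_read_set <- function(df) {
  class(df) <- c("read_set", "data.frame")
  rownames(df) <- NULL
  df
}

# Reference-space end of each alignment.
read_end <- function(reads) {
  w <- ifelse(is.na(reads$cigar),
              nchar(reads$seq),
              GenomicAlignments::cigarWidthAlongReferenceSpace(
                ifelse(is.na(reads$cigar), "1M", reads$cigar)))
  reads$start + as.integer(w) - 1L
}

# 1-based offset into the stored (query-space) sequence of reference
# position `pos`, or NA when pos falls in a deletion/ref-skip. Vectorised
# over reads; `pos` recycled.
query_offset_at <- function(reads, pos) {
  n <- nrow(reads)
  pos <- rep_len(as.integer(pos), n)
  off <- pos - reads$start + 1L
  gapped <- !is.na(reads$cigar) & grepl("[DNIS]", reads$cigar)
  if (any(gapped)) {
    idx <- which(gapped)
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      reads$cigar[idx], ops = c("M", "=", "X"))
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
      reads$cigar[idx], ops = c("M", "=", "X"))
    for (k in seq_along(idx)) {
      i <- idx[k]
      rel <- pos[i] - reads$start[i] + 1L  # position in reference space of aln
      rs <- IRanges::start(rr[[k]]); re <- IRanges::end(rr[[k]])
      hit <- which(rel >= rs & rel <= re)
      off[i] <- if (length(hit) == 1)
        IRanges::start(qr[[k]])[hit] + (rel - rs[hit]) else NA_integer_
    }
  }
  len <- nchar(reads$seq)
  off[!is.na(off) & (off < 1L | off > len)] <- NA_integer_
  off
}

#' Pile up read bases at panel sites
#'
#' Produces one observation row per (read, covered panel site): the aligned
#' base, its phred base quality and the read's mapping quality. This is the
#' per-site evidence all genotype-likelihood and calling functions consume.
#'
#' @param reads a \code{\link{read_set}}.
#' @param panel a \code{\link{snp_panel}}.
#' @param min_mapq,min_baseq observations from reads below \code{min_mapq} or
#'   bases below \code{min_baseq} are dropped. Defaults keep everything;
#'   callers apply their own thresholds.
#' @return data.frame with columns \code{individual}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{read_id}, \code{base},
#'   \code{baseq}, \code{mapq}, \code{is_modified}.
#' @export
pileup_reads <- function(reads, panel, min_mapq = 0, min_baseq = 0) {
  stopifnot(inherits(panel, "snp_panel"))
  empty <- data.frame(individual = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      read_id = character(), base = character(),
                      baseq = integer(), mapq = integer(),
                      is_modified = logical(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0 || nrow(panel) == 0) return(empty)
  reads <- reads[!is.na(reads$start) & reads$mapq >= min_mapq, , drop = FALSE]
  if (nrow(reads) == 0) return(empty)
  hits <- overlap_read_sites(reads, panel)
  if (nrow(hits) == 0) return(empty)
  r <- reads[hits$read, , drop = FALSE]
  p <- panel[hits$site, , drop = FALSE]
  off <- query_offset_at(r, p$pos)
  ok <- !is.na(off)
  r <- r[ok, , drop = FALSE]; p <- p[ok, , drop = FALSE]; off <- off[ok]
  base <- substr(r$seq, off, off)
  baseq <- utf8ToInt_at(r$qual, off) - 33L
  out <- data.frame(individual = r$individual, chrom = p$chrom, pos = p$pos,
                    ref = p$ref, alt = p$alt, read_id = r$read_id,
                    base = base, baseq = baseq, mapq = r$mapq,
                    is_modified = r$is_modified, stringsAsFactors = FALSE)
  out <- out[out$baseq >= min_baseq, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# (read index, site index) pairs where the alignment spans the site.
overlap_read_sites <- function(reads, panel) {
  q <- IRanges::IRanges(reads$start, read_end(reads))
  s <- IRanges::IRanges(panel$pos, panel$pos)
  ov <- IRanges::findOverlaps(q, s)
  read <- S4Vectors::queryHits(ov)
  site <- S4Vectors::subjectHits(ov)
  same <- reads$chrom[read] == panel$chrom[site]
  data.frame(read = read[same], site = site[same])
}

# phred char at position `at` of each string, as integer code.
utf8ToInt_at <- function(x, at) {
  vapply(substr(x, at, at), function(ch)
    if (nzchar(ch)) utf8ToInt(ch) else NA_integer_, integer(1), USE.NAMES = FALSE)
}

#' Export reads as FASTQ
#'
#' Minus-strand reads are reverse-complemented (with reversed qualities) so
#' the FASTQ records are in sequencing orientation, ready for remapping.
#'
#' @param reads a \code{\link{read_set}}.
#' @param path output FASTQ path.
#' @export
write_fastq_reads <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  quals <- Biostrings::BStringSet(reads$qual)
  rev <- which(reads$strand == "-")
  if (length(rev)) {
    seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
    quals[rev] <- Biostrings::BStringSet(
      vapply(strsplit(reads$qual[rev], ""), function(ch)
        paste(rev(ch), collapse = ""), character(1)))
  }
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}
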