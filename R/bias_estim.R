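#' Flip the allele a read carries at a panel SNP
#'
#' Returns a copy of each read whose aligned base at the site is swapped
#' ref <-> alt, leaving sequence context, base qualities and alignment
#' untouched. Reads whose aligned base matches neither allele, or whose
#' alignment has a deletion/ref-skip at the site, yield no record. This is
#' the elementary step of the flip-remap procedure: if the aligner treated
#' both alleles equally, every flipped copy would map back to where its
#' original did.
#'
#' @param reads a \code{\link{read_set}} whose alignments span \code{site$pos}.
#' @param site a single-row data.frame with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (one \code{\link{snp_panel}} row).
#' @return A \code{\link{read_set}} of flipped copies (possibly empty), with
#'   \code{is_modified = TRUE}, \code{flip_chrom}/\code{flip_pos} set, and
#'   read ids suffixed with the site and flip direction.
#' @export
flip_read_at_snp <- function(reads, site) {
  stopifnot(nrow(site) == 1)
  if (nrow(reads) == 0) return(empty_read_set())
  spans <- reads$chrom == site$chrom &
    reads$start <= site$pos & read_end(reads) >= site$pos
  reads <- reads[spans, , drop = FALSE]
  if (nrow(reads) == 0) return(empty_read_set())
  off <- query_offset_at(reads, site$pos)
  base <- ifelse(is.na(off), NA, substr(reads$seq, off, off))
  keep <- !is.na(base) & (base == site$ref | base == site$alt)
  reads <- reads[keep, , drop = FALSE]
  off <- off[keep]; base <- base[keep]
  if (nrow(reads) == 0) return(empty_read_set())
  newbase <- ifelse(base == site$ref, site$alt, site$ref)
  dirn <- ifelse(base == site$ref, "ra", "ar")
  out <- reads
  substr(out$seq, off, off) <- newbase
  out$read_id <- paste0(reads$read_id, "_flip_", site$chrom, "_", site$pos,
                        "_", dirn)
  if (any(out$read_id %in% reads$read_id))
    stop("flipped read name collides with an existing read name")
  out$is_modified <- TRUE
  out$flip_chrom <- site$chrom
  out$flip_pos <- as.integer(site$pos)
  as_read_set(out)
}

#' Extract panel-site observations and build allele-flipped read copies
#'
#' For every read overlapping a panel SNP with mapping quality and base
#' quality passing the thresholds and an aligned base matching one of the two
#' alleles, emits the original observation and one independently flipped copy
#' per (read, site) pair. A read overlapping k panel SNPs yields k flipped
#' copies, each modified at exactly one site.
#'
#' @param reads a \code{\link{read_set}} of original alignments.
#' @param panel a \code{\link{snp_panel}}.
#' @param min_mapq,min_baseq retention thresholds (default 30, the
#'   conventional cutoffs for ancient-DNA pipelines).
#' @return list with \code{observations} (original-read observations at panel
#'   sites whose base matches ref or alt; see \code{\link{pileup_reads}}) and
#'   \code{flipped} (a \code{\link{read_set}} of modified copies).
#' @export
extract_and_flip <- function(reads, panel, min_mapq = 30, min_baseq = 30) {
  stopifnot(inherits(panel, "snp_panel"))
  obs <- pileup_reads(reads, panel, min_mapq = min_mapq,
                      min_baseq = min_baseq)
  obs <- obs[!obs$is_modified & (obs$base == obs$ref | obs$base == obs$alt), ,
             drop = FALSE]
  if (nrow(obs) == 0)
    return(list(observations = obs, flipped = empty_read_set()))
  r <- reads[match(obs$read_id, reads$read_id), , drop = FALSE]
  off <- query_offset_at(r, obs$pos)
  flip_to <- ifelse(obs$base == obs$ref, obs$alt, obs$ref)
  dirn <- ifelse(obs$base == obs$ref, "ra", "ar")
  out <- r
  substr(out$seq, off, off) <- flip_to
  out$read_id <- paste0(r$read_id, "_flip_", obs$chrom, "_", obs$pos,
                        "_", dirn)
  if (any(out$read_id %in% reads$read_id))
    stop("flipped read name collides with an existing read name")
  out$is_modified <- TRUE
  out$flip_chrom <- obs$chrom
  out$flip_pos <- obs$pos
  list(observations = obs, flipped = as_read_set(out))
}

#' Per-site reference-read proportion r from originals plus remapped flips
#'
#' Counts, per individual and site, the retained original observations and
#' the flipped copies that remapped back to the site, and computes
#' \eqn{r = n_{ref} / n_{total}}. A flipped copy counts only if it mapped to
#' the same chromosome with an alignment covering the site position, mapping
#' quality at least \code{min_mapq}, and an aligned base equal to ref or alt;
#' copies lost, moved or degraded by the mapper are excluded from both
#' counts, which is exactly what moves r away from 0.5. Without mapping bias
#' r = 0.5 at every covered site; reference bias gives r > 0.5, alternative
#' bias r < 0.5.
#'
#' @param observations original-read observations (from
#'   \code{\link{extract_and_flip}}).
#' @param remapped a \code{\link{read_set}} of remapped flipped copies (the
#'   mapper's output).
#' @param panel a \code{\link{snp_panel}}.
#' @param min_mapq retention threshold for remapped copies.
#' @return A bias table: data.frame of class \code{site_bias} with columns
#'   \code{individual}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{n_total}, \code{n_ref}, \code{r}, \code{low_evidence}. Sites with
#'   no retained reads for an individual get r = 0.5 with
#'   \code{low_evidence = TRUE}. One row per individual (seen in the inputs)
#'   and panel site.
#' @export
compute_site_bias <- function(observations, remapped, panel, min_mapq = 30) {
  stopifnot(inherits(panel, "snp_panel"))
  individuals <- sort(unique(c(observations$individual,
                               remapped$individual)))
  if (length(individuals) == 0) individuals <- NA_character_
  flip_obs <- retained_flip_observations(remapped, panel, min_mapq)
  all_obs <- rbind(
    observations[, c("individual", "chrom", "pos", "ref", "base")],
    flip_obs[, c("individual", "chrom", "pos", "ref", "base")])
  key_p <- paste(panel$chrom, panel$pos)
  grid <- expand.grid(site = seq_len(nrow(panel)),
                      individual = individuals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- factor(paste(all_obs$individual, all_obs$chrom, all_obs$pos),
              levels = paste(grid$individual, key_p[grid$site]))
  n_total <- as.integer(tapply(rep(1L, nrow(all_obs)), g, sum, default = 0L))
  n_ref <- as.integer(tapply(all_obs$base == all_obs$ref, g, sum,
                             default = 0L))
  r <- ifelse(n_total > 0, n_ref / n_total, 0.5)
  out <- data.frame(individual = grid$individual,
                    chrom = panel$chrom[grid$site],
                    pos = panel$pos[grid$site],
                    ref = panel$ref[grid$site],
                    alt = panel$alt[grid$site],
                    n_total = n_total, n_ref = n_ref, r = r,
                    low_evidence = n_total == 0L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_bias", "data.frame")
  out
}

# Observations of remapped flipped copies, retained only at their own flip
# site (same chromosome, alignment covering the site, mapq and allele check).
retained_flip_observations <- function(remapped, panel, min_mapq) {
  if (nrow(remapped) == 0)
    return(data.frame(individual = character(), chrom = character(),
                      pos = integer(), ref = character(), base = character(),
                      stringsAsFactors = FALSE))
  obs <- pileup_reads(remapped, panel, min_mapq = min_mapq, min_baseq = 0)
  r <- remapped[match(obs$read_id, remapped$read_id), , drop = FALSE]
  at_own_site <- obs$chrom == r$flip_chrom & obs$pos == r$flip_pos
  obs <- obs[at_own_site & (obs$base == obs$ref | obs$base == obs$alt), ,
             drop = FALSE]
  obs[, c("individual", "chrom", "pos", "ref", "base")]
}

#' Run the full flip-remap bias quantification
#'
#' Extracts reads at panel sites, builds allele-flipped copies, remaps them
#' through the supplied mapper adapter and summarises the per-individual,
#' per-site reference-read proportion r.
#'
#' @param reads a \code{\link{read_set}} of original alignments (possibly for
#'   several individuals).
#' @param panel a \code{\link{snp_panel}}.
#' @param mapper a mapper adapter: a function taking and returning a
#'   \code{\link{read_set}} (see \code{\link{identity_mapper}},
#'   \code{\link{biased_mapper}}, \code{\link{bwa_mapper}}).
#' @param min_mapq,min_baseq quality thresholds (default 30).
#' @return A \code{site_bias} table (see \code{\link{compute_site_bias}}).
#' @export
run_flip_remap <- function(reads, panel, mapper = identity_mapper(),
                           min_mapq = 30, min_baseq = 30) {
  ef <- extract_and_flip(reads, panel, min_mapq = min_mapq,
                         min_baseq = min_baseq)
  remapped <- tryCatch(mapper(ef$flipped),
                       error = function(e) stop("mapper failed during ",
                                                "flip-remap: ",
                                                conditionMessage(e)))
  compute_site_bias(ef$observations, remapped, panel, min_mapq = min_mapq)
}

#' Identity mapper adapter
#'
#' Returns every read at its original coordinates with full mapping quality:
#' the no-mapping-bias reference point, under which the flip-remap procedure
#' yields r = 0.5 at every covered site.
#'
#' @return A mapper function: \code{read_set -> read_set}.
#' @export
identity_mapper <- function() {
  function(reads) {
    reads$mapq <- rep(60L, nrow(reads))
    reads
  }
}

#' Write / read a bias table TSV
#'
#' Columns: INDIVIDUAL CHROM POS REF ALT N_TOTAL N_REF R FLAG.
#'
#' @param bias a \code{site_bias} table.
#' @param path file path.
#' @export
write_bias_table <- function(bias, path) {
  out <- data.frame(INDIVIDUAL = bias$individual, CHROM = bias$chrom,
                    POS = bias$pos, REF = bias$ref, ALT = bias$alt,
                    N_TOTAL = bias$n_total, N_REF = bias$n_ref,
                    R = sprintf("%.6g", bias$r),
                    FLAG = ifelse(bias$low_evidence, "LOW_EVIDENCE", "."))
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(individual = as.character(x$INDIVIDUAL), chrom = as.character(x$CHROM),
                    pos = as.integer(x$POS), ref = x$REF, alt = x$ALT,
                    n_total = as.integer(x$N_TOTAL),
                    n_ref = as.integer(x$N_REF), r = as.numeric(x$R),
                    low_evidence = x$FLAG == "LOW_EVIDENCE",
                    stringsAsFactors = FALSE)
  class(out) <- c("site_bias", "data.frame")
  out
}

#' bwa aln mapper adapter
#'
#' Shells out to \code{bwa aln}/\code{bwa samse} with the parameters commonly
#' used for short, degraded fragments (\code{-l 16500} to disable seeding,
#' \code{-n 0.01}, \code{-o 2}), so flipped copies are remapped with the same
#' settings as a typical ancient-DNA pipeline. Requires \code{bwa} and
#' \code{samtools} on the PATH.
#'
#' @param reference path to the reference FASTA (indexed on first use).
#' @param args character vector of \code{bwa aln} arguments.
#' @return A mapper function: \code{read_set -> read_set}. Reads that fail to
#'   map are dropped; mapped reads carry bwa's coordinates, CIGAR and mapping
#'   quality.
#' @export
bwa_mapper <- function(reference,
                       args = c("-l", "16500", "-n", "0.01", "-o", "2")) {
  if (Sys.which("bwa") == "" || Sys.which("samtools") == "")
    stop("bwa_mapper requires 'bwa' and 'samtools' on the PATH")
  if (!file.exists(reference))
    stop("reference FASTA not found: ", reference)
  force(args)
  function(reads) {
    if (nrow(reads) == 0) return(reads)
    if (!file.exists(paste0(reference, ".bwt"))) {
      rc <- system2("bwa", c("index", shQuote(reference)),
                    stdout = FALSE, stderr = FALSE)
      if (rc != 0) stop("bwa index failed for ", reference)
    }
    fq <- tempfile(fileext = ".fq")
    sai <- tempfile(fileext = ".sai")
    bam <- tempfile(fileext = ".bam")
    on.exit(unlink(c(fq, sai, bam, paste0(bam, ".bai"))), add = TRUE)
    write_fastq_reads(reads, fq)
    rc <- system2("bwa", c("aln", args, shQuote(reference), shQuote(fq)),
                  stdout = sai, stderr = FALSE)
    if (rc != 0) stop("bwa aln failed")
    cmd <- paste("bwa samse", shQuote(reference), shQuote(sai), shQuote(fq),
                 "| samtools sort -o", shQuote(bam), "-",
                 "&& samtools index", shQuote(bam))
    rc <- system(cmd, ignore.stderr = TRUE)
    if (rc != 0) stop("bwa samse / samtools sort failed")
    mapped <- read_bam_reads(bam, individual = reads$individual[1])
    # re-attach per-read metadata by name
    i <- match(mapped$read_id, reads$read_id)
    mapped <- mapped[!is.na(i), , drop = FALSE]
    i <- i[!is.na(i)]
    mapped$individual <- reads$individual[i]
    mapped$is_modified <- reads$is_modified[i]
    mapped$flip_chrom <- reads$flip_chrom[i]
    mapped$flip_pos <- reads$flip_pos[i]
    as_read_set(mapped)
  }
}
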