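#' Pseudohaploid calls by random read draw
#'
#' The standard low-coverage ancient-DNA genotyping shortcut: at each panel
#' site, sample a single read uniformly among those passing the base- and
#' mapping-quality thresholds and carrying one of the two panel alleles, and
#' report its allele as a haploid call. Sites without an eligible read are
#' missing. Independent of any genotype-likelihood machinery (and of r) by
#' construction.
#'
#' @param observations pileup table (see \code{\link{pileup_reads}});
#'   modified reads are ignored.
#' @param panel a \code{\link{snp_panel}}.
#' @param individuals individuals to call; defaults to those observed.
#' @param min_baseq minimum base quality (default 30).
#' @param min_mapq minimum mapping quality (default 30).
#' @param seed RNG seed for the draw; fixed seed plus fixed input order give
#'   identical calls.
#' @return data.frame with one row per individual x panel site:
#'   \code{individual}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{allele} ("ref"/"alt"/NA), \code{base}, and a \code{seed}
#'   attribute recording the draw.
#' @export
call_pseudohaploid <- function(observations, panel, individuals = NULL,
                               min_baseq = 30, min_mapq = 30, seed = 1) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is.null(individuals))
    individuals <- sort(unique(observations$individual))
  obs <- observations[!observations$is_modified &
                        observations$baseq >= min_baseq &
                        observations$mapq >= min_mapq &
                        (observations$base == observations$ref |
                           observations$base == observations$alt), ,
                      drop = FALSE]
  key_p <- paste(panel$chrom, panel$pos)
  grid <- expand.grid(site = seq_len(nrow(panel)), individual = individuals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lev <- paste(grid$individual, key_p[grid$site])
  picked_base <- rep(NA_character_, nrow(grid))
  if (nrow(obs) > 0) {
    g <- factor(paste(obs$individual, obs$chrom, obs$pos), levels = lev)
    keep <- !is.na(g)
    obs <- obs[keep, , drop = FALSE]
    g <- g[keep]
    # uniform draw per group: random key, keep the max per group
    u <- withr::with_seed(seed, stats::runif(nrow(obs)))
    ord <- order(as.integer(g), u)
    last <- !duplicated(as.integer(g)[ord], fromLast = TRUE)
    sel <- ord[last]
    picked_base[as.integer(g)[sel]] <- obs$base[sel]
  }
  out <- data.frame(individual = grid$individual,
                    chrom = panel$chrom[grid$site],
                    pos = panel$pos[grid$site],
                    ref = panel$ref[grid$site],
                    alt = panel$alt[grid$site],
                    base = picked_base,
                    stringsAsFactors = FALSE)
  out$allele <- ifelse(is.na(out$base), NA_character_,
                       ifelse(out$base == out$ref, "ref", "alt"))
  out <- out[order(out$individual, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Reference-allele frequency from pseudohaploid calls
#'
#' @param calls pseudohaploid call table (one population), from
#'   \code{\link{call_pseudohaploid}}.
#' @return data.frame per site with \code{f_ref} = ref calls / non-missing
#'   calls, \code{n_called}, and \code{all_missing} flagging sites where no
#'   individual was called (there \code{f_ref} is NA).
#' @export
af_from_pseudohaploid <- function(calls) {
  key <- unique(paste(calls$chrom, calls$pos))
  g <- factor(paste(calls$chrom, calls$pos), levels = key)
  n_called <- as.integer(tapply(!is.na(calls$allele), g, sum, default = 0L))
  n_ref <- as.integer(tapply(!is.na(calls$allele) & calls$allele == "ref",
                             g, sum, default = 0L))
  first <- !duplicated(g)
  data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
             f_ref = ifelse(n_called > 0, n_ref / n_called, NA_real_),
             n_called = n_called, all_missing = n_called == 0L,
             row.names = NULL)
}

#' Read pseudohaploid calls back from tped/tfam files
#'
#' Inverse of \code{\link{write_tped}} for panels of biallelic SNPs:
#' duplicated haploid genotypes become calls, "0 0" becomes missing.
#'
#' @param tped,tfam file paths.
#' @param panel a \code{\link{snp_panel}} supplying the ref/alt orientation.
#' @return A pseudohaploid call table (see \code{\link{call_pseudohaploid}}).
#' @export
read_tped_calls <- function(tped, tfam, panel) {
  fam <- utils::read.table(tfam, stringsAsFactors = FALSE)
  individuals <- fam[[2]]
  x <- utils::read.table(tped, stringsAsFactors = FALSE)
  chrom <- as.character(x[[1]])
  pos <- as.integer(x[[4]])
  idx <- match(paste(chrom, pos), paste(panel$chrom, panel$pos))
  if (anyNA(idx)) stop("tped contains sites absent from the panel")
  out <- do.call(rbind, lapply(seq_along(individuals), function(i) {
    a1 <- as.character(x[[3 + 2 * i]])
    base <- ifelse(a1 == "0", NA_character_, a1)
    data.frame(individual = individuals[i], chrom = chrom, pos = pos,
               ref = panel$ref[idx], alt = panel$alt[idx], base = base,
               allele = ifelse(is.na(base), NA_character_,
                               ifelse(base == panel$ref[idx], "ref",
                                      "alt")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write pseudohaploid calls as transposed-Plink text (tped/tfam)
#'
#' The haploid allele is duplicated into a homozygous diploid genotype (the
#' haploToPlink convention); missing calls become "0 0".
#'
#' @param calls pseudohaploid call table.
#' @param prefix output path prefix; writes \code{prefix.tped} and
#'   \code{prefix.tfam}.
#' @export
write_tped <- function(calls, prefix) {
  individuals <- unique(calls$individual)
  key <- paste(calls$chrom, calls$pos)
  sites <- unique(key)
  geno <- matrix("0 0", nrow = length(sites), ncol = length(individuals))
  si <- match(key, sites)
  ii <- match(calls$individual, individuals)
  ok <- !is.na(calls$base)
  geno[cbind(si[ok], ii[ok])] <- paste(calls$base[ok], calls$base[ok])
  first <- !duplicated(key)
  tped <- cbind(calls$chrom[first],
                paste0(calls$chrom[first], "_", calls$pos[first]),
                "0", calls$pos[first],
                geno)
  utils::write.table(tped, paste0(prefix, ".tped"), quote = FALSE,
                     sep = " ", row.names = FALSE, col.names = FALSE)
  tfam <- data.frame(fam = individuals, ind = individuals, pat = 0, mat = 0,
                     sex = 0, pheno = -9)
  utils::write.table(tfam, paste0(prefix, ".tfam"), quote = FALSE,
                     sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
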