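#' Phred score to error probability
#'
#' @param q non-negative phred-scaled base quality.
#' @return \code{10^(-q/10)}.
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) stop("phred quality must be >= 0")
  10^(-q / 10)
}

#' Probability of an observed base given a true allele
#'
#' The standard direct genotype-likelihood error model: an observed base
#' equals the true allele with probability 1 - e, and each of the three other
#' bases with probability e/3.
#'
#' @param b observed base(s).
#' @param a true allele(s).
#' @param e sequencing-error probability in (0, 1].
#' @return \code{1 - e} where \code{b == a}, else \code{e/3}.
#' @export
base_prob <- function(b, a, e) {
  ifelse(b == a, 1 - e, e / 3)
}

# Log-space per-site triplet computation shared by gl_default/gl_corrected.
# bases/errs: observations at one site; returns unnormalised log-likelihoods.
gl_log_triplet <- function(bases, errs, ref, alt, r) {
  p_ref <- base_prob(bases, ref, errs)
  p_alt <- base_prob(bases, alt, errs)
  c(l_rr = sum(log(p_ref)),
    l_ra = sum(log(r * p_ref + (1 - r) * p_alt)),
    l_aa = sum(log(p_alt)))
}

#' Default genotype likelihoods at one site
#'
#' Direct genotype likelihood for a biallelic site: the probability of the
#' observed bases given each genotype, with per-read error probabilities from
#' the phred base qualities. The heterozygote term averages the two alleles
#' with equal weight, i.e. assumes reads sample both alleles evenly --
#' precisely the assumption mapping bias violates.
#'
#' @param bases observed bases at the site (one per read).
#' @param quals phred base qualities (same length).
#' @param ref,alt the site's two alleles.
#' @return Named numeric: normalized likelihoods \code{l_rr}, \code{l_ra},
#'   \code{l_aa} summing to 1; \code{(1/3, 1/3, 1/3)} for zero reads.
#' @export
gl_default <- function(bases, quals, ref, alt) {
  gl_corrected(bases, quals, ref, alt, r = 0.5, clamp = c(0, 1))
}

#' Bias-corrected genotype likelihoods at one site
#'
#' Replaces the equal-weight heterozygote term by a mixture weighted with the
#' empirically measured reference-read proportion r of the flip-remap
#' procedure: each read observes the reference allele with probability r and
#' the alternative allele with probability 1 - r. Homozygote likelihoods are
#' unchanged. With r = 0.5 this reduces exactly to \code{\link{gl_default}}.
#'
#' @inheritParams gl_default
#' @param r reference-read proportion in [0, 1].
#' @param clamp lower/upper clamping bounds applied to r before use, so a
#'   finite flip-remap sample with r-hat of exactly 0 or 1 never zeroes the
#'   heterozygote likelihood. Default \code{c(0.001, 0.999)}.
#' @return Named numeric triplet as in \code{\link{gl_default}}.
#' @export
gl_corrected <- function(bases, quals, ref, alt, r,
                         clamp = c(0.001, 0.999)) {
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  r <- min(max(r, clamp[1]), clamp[2])
  if (length(bases) == 0)
    return(c(l_rr = 1 / 3, l_ra = 1 / 3, l_aa = 1 / 3))
  errs <- phred_to_error(quals)
  normalize_gl(gl_log_triplet(bases, errs, ref, alt, r), log_input = TRUE)
}

#' Normalize a genotype-likelihood triplet
#'
#' Scales the three likelihoods to sum to 1. With \code{log_input = TRUE}
#' the values are unnormalised log-likelihoods; the maximum is subtracted
#' before exponentiation so deep sites never underflow.
#'
#' @param t numeric length-3 triplet (RR, RA, AA).
#' @param log_input are values on the log scale?
#' @return Normalized numeric triplet summing to 1.
#' @export
normalize_gl <- function(t, log_input = FALSE) {
  if (log_input) {
    t <- exp(t - max(t))
  } else {
    if (any(t < 0)) stop("likelihoods must be non-negative")
    if (max(t) == 0) stop("all-zero likelihood triplet cannot be normalized")
  }
  out <- t / sum(t)
  names(out) <- c("l_rr", "l_ra", "l_aa")
  out
}

#' Genotype likelihoods for all individuals and panel sites
#'
#' Vectorised computation of default or bias-corrected genotype likelihoods
#' from a pileup observation table. In corrected mode each individual x site
#' uses that individual's own flip-remap ratio r; sites whose bias record is
#' low-evidence (no retained reads in the flip-remap) fall back to r = 0.5,
#' i.e. the default model.
#'
#' @param observations pileup table (see \code{\link{pileup_reads}});
#'   modified reads are ignored.
#' @param panel a \code{\link{snp_panel}}.
#' @param individuals individuals to compute GLs for; defaults to those
#'   present in \code{observations}.
#' @param bias a \code{site_bias} table (required for
#'   \code{mode = "corrected"}).
#' @param mode \code{"default"} or \code{"corrected"}.
#' @param min_baseq bases below this quality are excluded (default 30).
#' @param min_mapq observations from reads below this mapping quality are
#'   excluded (default 30).
#' @param clamp r clamping bounds, see \code{\link{gl_corrected}}.
#' @return data.frame of class \code{gl_set}: one row per individual x site
#'   with normalized \code{l_rr}, \code{l_ra}, \code{l_aa}, \code{n_reads},
#'   \code{mode} and \code{r_used}. Individual-sites without usable reads get
#'   the uninformative triplet (1/3, 1/3, 1/3).
#' @export
compute_gl <- function(observations, panel, individuals = NULL, bias = NULL,
                       mode = c("default", "corrected"), min_baseq = 30,
                       min_mapq = 30, clamp = c(0.001, 0.999)) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "snp_panel"))
  if (mode == "corrected" && is.null(bias))
    stop("corrected mode requires a bias table")
  if (is.null(individuals))
    individuals <- sort(unique(observations$individual))
  obs <- observations[!observations$is_modified &
                        observations$baseq >= min_baseq &
                        observations$mapq >= min_mapq, , drop = FALSE]
  key_p <- paste(panel$chrom, panel$pos)
  grid <- expand.grid(site = seq_len(nrow(panel)), individual = individuals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lev <- paste(grid$individual, key_p[grid$site])
  # r per individual x site
  r_used <- rep(0.5, nrow(grid))
  if (mode == "corrected") {
    bkey <- paste(bias$individual, bias$chrom, bias$pos)
    bi <- match(lev, bkey)
    found <- !is.na(bi)
    r_raw <- ifelse(bias$low_evidence[bi[found]], 0.5, bias$r[bi[found]])
    r_used[found] <- pmin(pmax(r_raw, clamp[1]), clamp[2])
  }
  n <- nrow(obs)
  if (n > 0) {
    g <- factor(paste(obs$individual, obs$chrom, obs$pos), levels = lev)
    keep <- !is.na(g)
    obs <- obs[keep, , drop = FALSE]
    g <- g[keep]
    e <- phred_to_error(obs$baseq)
    lp_ref <- log(base_prob(obs$base, obs$ref, e))
    lp_alt <- log(base_prob(obs$base, obs$alt, e))
    r_obs <- r_used[as.integer(g)]
    lp_het <- log(r_obs * exp(lp_ref) + (1 - r_obs) * exp(lp_alt))
    ll_rr <- as.numeric(tapply(lp_ref, g, sum, default = 0))
    ll_ra <- as.numeric(tapply(lp_het, g, sum, default = 0))
    ll_aa <- as.numeric(tapply(lp_alt, g, sum, default = 0))
    n_reads <- as.integer(tapply(rep(1L, length(g)), g, sum, default = 0L))
  } else {
    ll_rr <- ll_ra <- ll_aa <- rep(0, nrow(grid))
    n_reads <- rep(0L, nrow(grid))
  }
  m <- pmax(ll_rr, ll_ra, ll_aa)
  e_rr <- exp(ll_rr - m); e_ra <- exp(ll_ra - m); e_aa <- exp(ll_aa - m)
  s <- e_rr + e_ra + e_aa
  out <- data.frame(individual = grid$individual,
                    chrom = panel$chrom[grid$site],
                    pos = panel$pos[grid$site],
                    ref = panel$ref[grid$site],
                    alt = panel$alt[grid$site],
                    l_rr = e_rr / s, l_ra = e_ra / s, l_aa = e_aa / s,
                    n_reads = n_reads, mode = mode, r_used = r_used,
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gl_set", "data.frame")
  out
}

beagle_allele_code <- function(a) {
  c(A = 0L, C = 1L, G = 2L, T = 3L)[a]
}

#' Write genotype likelihoods in Beagle GL format
#'
#' Text table with one row per marker: \code{marker allele1 allele2} followed
#' by three normalized likelihood columns (homRef, het, homAlt) per
#' individual. Markers are coded \code{chrom_pos}; alleles 0=A, 1=C, 2=G,
#' 3=T. Missing data is the uninformative (1/3, 1/3, 1/3) triplet.
#'
#' @param gl a \code{gl_set} from \code{\link{compute_gl}}; every individual
#'   must cover the same sites in the same order.
#' @param path output path (".gz" suffix gzips).
#' @export
write_beagle <- function(gl, path) {
  individuals <- unique(gl$individual)
  key <- paste0(gl$chrom, "_", gl$pos)
  sites <- unique(key)
  if (nrow(gl) != length(individuals) * length(sites))
    stop("ragged gl_set: every individual must cover the same sites")
  if (nrow(gl) == 0) {
    writeLines("marker\tallele1\tallele2", path)
    return(invisible(path))
  }
  first <- gl[gl$individual == individuals[1], , drop = FALSE]
  cols <- list(marker = paste0(first$chrom, "_", first$pos),
               allele1 = beagle_allele_code(first$ref),
               allele2 = beagle_allele_code(first$alt))
  for (ind in individuals) {
    sub <- gl[gl$individual == ind, , drop = FALSE]
    if (!identical(paste0(sub$chrom, "_", sub$pos), cols$marker))
      stop("ragged gl_set: site order differs for individual ", ind)
    cols[[paste0(ind, ".rr")]] <- sprintf("%.6g", sub$l_rr)
    cols[[paste0(ind, ".ra")]] <- sprintf("%.6g", sub$l_ra)
    cols[[paste0(ind, ".aa")]] <- sprintf("%.6g", sub$l_aa)
  }
  header <- c("marker", "allele1", "allele2",
              rep(individuals, each = 3))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (length(cols$marker))
    writeLines(do.call(paste, c(unname(cols), sep = "\t")), con)
  invisible(path)
}

#' Read a Beagle GL file
#'
#' @param path Beagle GL file written by \code{\link{write_beagle}} (or
#'   ANGSD-compatible).
#' @return A \code{gl_set} data.frame.
#' @export
read_beagle <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, skip = 1)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  individuals <- unique(hdr[-(1:3)])
  if (length(hdr) != 3 + 3 * length(individuals))
    stop("malformed Beagle header")
  mk <- strsplit(x[[1]], "_")
  pos <- vapply(mk, function(p) p[length(p)], character(1))
  chrom <- mapply(function(p) paste(p[-length(p)], collapse = "_"), mk)
  dec <- c("A", "C", "G", "T")
  out <- do.call(rbind, lapply(seq_along(individuals), function(i) {
    j <- 3 + (i - 1) * 3
    data.frame(individual = individuals[i], chrom = chrom,
               pos = as.integer(pos),
               ref = dec[x[[2]] + 1], alt = dec[x[[3]] + 1],
               l_rr = as.numeric(x[[j + 1]]), l_ra = as.numeric(x[[j + 2]]),
               l_aa = as.numeric(x[[j + 3]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("gl_set", "data.frame")
  out
}
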