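#' Simulation scenario parameters
#'
#' Bundles every parameter of the synthetic-data generator. The demographic
#' layout is an outgroup S1, two sources S2 and S3 and a target T, with the
#' deepest split at \code{t123} generations, the S3 split at
#' \code{0.5 * t123}, the T/S2 split at \code{0.2 * t123}, and a single
#' admixture pulse of proportion \code{f} from S3 into T \code{pulse_age}
#' generations ago. Per-branch drift follows the Balding-Nichols model with
#' \code{F = 1 - exp(-t / (2 Ne))}. Sites are ascertained at sample minor
#' allele frequency >= \code{maf_min} in S1 and are exclusively
#' transversions on a random ancestral sequence of GC content \code{gc}.
#'
#' @param t123 deepest split, in generations (default 50000, a
#'   between-(sub)species divergence).
#' @param Ne effective population size along every branch (default 10000).
#' @param f admixture pulse proportion from S3 into T, in [0, 1].
#' @param pulse_age pulse age in generations (default 50; the pulse is
#'   applied to population frequencies, recent enough that post-pulse drift
#'   is negligible).
#' @param n_ind diploid individuals per population (default 21).
#' @param n_ind_target diploid individuals in T (defaults to \code{n_ind}).
#' @param n_sites target number of ascertained panel SNPs (default 2000).
#' @param depth mean sequencing coverage; per-site read counts are
#'   Poisson(\code{depth}) (default 2.0).
#' @param frag_loc log-normal location of fragment lengths; \code{NULL}
#'   (default) draws one per individual uniformly from [3.3, 3.8], giving
#'   mean fragment lengths between ~27 and ~46 bp.
#' @param frag_scale log-normal scale (default 0.2).
#' @param frag_min minimum fragment length; shorter draws are rejected
#'   (default 30).
#' @param gc ancestral sequence GC content (default 0.41).
#' @param beta alt-read loss probability of the parametric biased mapper:
#'   every mapping event drops a read carrying the alternative allele at its
#'   focal panel site with probability \code{beta}; 0 means no mapping bias.
#' @param error_q phred base quality assigned to every simulated base
#'   (default 30, i.e. error rate 0.001).
#' @param site_spacing distance between panel sites on the reference, in bp
#'   (default 150, larger than any plausible fragment under the length
#'   model, so each read covers exactly one panel site).
#' @param maf_min ascertainment minor-allele-frequency cutoff in the S1
#'   sample (default 0.1).
#' @param ref_source population the reference genome haplotype is sampled
#'   from ("S2", "S3" or "S1"). The default "S2" is the ingroup case --
#'   a reference from one of the admixture sources, the setting where
#'   mapping bias matters most; "S1" gives an outgroup reference whose
#'   alleles are nearly uncorrelated with the studied populations.
#'   Irrelevant when \code{beta = 0}.
#' @param seed integer seed making the whole bundle reproducible.
#' @return list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(t123 = 50000, Ne = 10000, f = 0.1, pulse_age = 50,
                         n_ind = 21, n_ind_target = n_ind, n_sites = 2000,
                         depth = 2.0, frag_loc = NULL, frag_scale = 0.2,
                         frag_min = 30, gc = 0.41, beta = 0, error_q = 30,
                         site_spacing = 150, maf_min = 0.1,
                         ref_source = c("S2", "S3", "S1"), seed = 1) {
  ref_source <- match.arg(ref_source)
  stopifnot(f >= 0, f <= 1, beta >= 0, beta <= 1, gc > 0, gc < 1,
            frag_scale > 0, frag_min > 0, t123 > 0, Ne > 0, depth > 0,
            n_ind >= 1, n_ind_target >= 1, n_sites >= 1, error_q >= 0)
  if (!is.null(frag_loc) && frag_loc <= 0) stop("frag_loc must be positive")
  structure(list(t123 = t123, t23 = 0.5 * t123, t_ts2 = 0.2 * t123,
                 Ne = Ne, f = f, pulse_age = pulse_age, n_ind = n_ind,
                 n_ind_target = n_ind_target, n_sites = n_sites,
                 depth = depth, frag_loc = frag_loc,
                 frag_scale = frag_scale, frag_min = frag_min, gc = gc,
                 beta = beta, error_q = error_q,
                 site_spacing = site_spacing, maf_min = maf_min,
                 ref_source = ref_source, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Random ancestral sequence with fixed GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#' The default gc of 0.41 matches a typical mammalian genome.
#'
#' @param length sequence length in bp.
#' @param gc GC content in (0, 1).
#' @param seed RNG seed.
#' @return A single character string of length \code{length}.
#' @export
simulate_ancestral_sequence <- function(length, gc = 0.41, seed = 1) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  bases <- withr::with_seed(seed, sample(c("G", "C", "A", "T"), length,
                                         replace = TRUE,
                                         prob = c(gc / 2, gc / 2,
                                                  (1 - gc) / 2,
                                                  (1 - gc) / 2)))
  paste(bases, collapse = "")
}

# One Balding-Nichols drift step: child frequency given parent frequency p
# and branch length t generations. F = 0 returns p unchanged; frequencies
# already fixed (0/1) stay fixed.
bn_drift <- function(p, t, Ne) {
  F <- 1 - exp(-t / (2 * Ne))
  if (F <= 0) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  out <- p
  seg <- p > 0 & p < 1
  out[seg] <- stats::rbeta(sum(seg), a[seg], b[seg])
  out
}

#' Simulate per-population allele frequencies under the drift model
#'
#' Draws an ancestral reference-allele frequency per site from a symmetric
#' Beta(0.5, 0.5) spectrum truncated to (0.05, 0.95), then applies
#' Balding-Nichols drift along each branch of the (S1,((S2,T),S3)) topology.
#' T's pre-pulse frequency drifts independently along the S2-lineage
#' terminal branch; the admixture pulse then sets
#' \code{p_T = f * p_S3 + (1 - f) * p_T_pre}.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param n_sites number of candidate sites to draw (defaults to
#'   \code{scenario$n_sites}; callers typically oversample before
#'   ascertainment).
#' @param seed RNG seed (defaults to \code{scenario$seed}).
#' @param spectrum ancestral-spectrum sampler: \code{function(n)} returning
#'   frequencies.
#' @return data.frame with per-site true frequencies \code{p_anc},
#'   \code{p_s1}, \code{p_s2}, \code{p_s3}, \code{p_t_pre}, \code{p_t}.
#' @export
simulate_frequencies <- function(scenario, n_sites = scenario$n_sites,
                                 seed = scenario$seed,
                                 spectrum = ancestral_spectrum) {
  withr::with_seed(seed, {
    p0 <- spectrum(n_sites)
    Ne <- scenario$Ne
    # branch lengths in generations
    p_s1 <- bn_drift(p0, scenario$t123, Ne)
    p_a23 <- bn_drift(p0, scenario$t123 - scenario$t23, Ne)
    p_s3 <- bn_drift(p_a23, scenario$t23, Ne)
    p_a2t <- bn_drift(p_a23, scenario$t23 - scenario$t_ts2, Ne)
    p_s2 <- bn_drift(p_a2t, scenario$t_ts2, Ne)
    p_t_pre <- bn_drift(p_a2t, scenario$t_ts2, Ne)
    p_t <- scenario$f * p_s3 + (1 - scenario$f) * p_t_pre
    data.frame(p_anc = p0, p_s1 = p_s1, p_s2 = p_s2, p_s3 = p_s3,
               p_t_pre = p_t_pre, p_t = p_t)
  })
}

# Default ancestral allele-frequency spectrum: Beta(0.5, 0.5) truncated.
ancestral_spectrum <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rbeta(2 * (n - length(out)) + 10, 0.5, 0.5)
    out <- c(out, x[x > 0.05 & x < 0.95])
  }
  out[seq_len(n)]
}

#' Simulate diploid genotypes from population frequencies
#'
#' Ref-allele dosages are Binomial(2, p) per individual and site (HWE within
#' populations), independent across sites.
#'
#' @param freqs frequency table from \code{\link{simulate_frequencies}}.
#' @param scenario a \code{\link{sim_scenario}}.
#' @param seed RNG seed.
#' @return list of class \code{sim_truth}: \code{freqs}, \code{genotypes}
#'   (list of sites x individuals dosage matrices for S1, S2, S3, T) and
#'   \code{admixture} (the true pulse proportion, shared by all T
#'   individuals).
#' @export
simulate_genotypes <- function(freqs, scenario, seed = scenario$seed + 1) {
  n_sites <- nrow(freqs)
  withr::with_seed(seed, {
    draw <- function(p, n_ind) {
      matrix(stats::rbinom(n_sites * n_ind, 2, rep(p, n_ind)),
             nrow = n_sites, ncol = n_ind)
    }
    genotypes <- list(S1 = draw(freqs$p_s1, scenario$n_ind),
                      S2 = draw(freqs$p_s2, scenario$n_ind),
                      S3 = draw(freqs$p_s3, scenario$n_ind),
                      T = draw(freqs$p_t, scenario$n_ind_target))
  })
  structure(list(freqs = freqs, genotypes = genotypes,
                 admixture = rep(scenario$f, scenario$n_ind_target)),
            class = "sim_truth")
}

#' Ascertain sites on outgroup sample MAF and thin
#'
#' Mimics SNP discovery in the outgroup: keeps sites whose minor allele
#' frequency in the S1 genotype sample (2 x n_ind chromosomes) is at least
#' \code{maf_min}, then thins uniformly at random to \code{n_keep} sites.
#'
#' @param truth a \code{sim_truth} from \code{\link{simulate_genotypes}}.
#' @param maf_min ascertainment cutoff (default 0.1).
#' @param n_keep number of sites to retain after thinning.
#' @param seed RNG seed for the thinning.
#' @return The \code{sim_truth} restricted to the ascertained sites (with a
#'   warning if fewer than \code{n_keep} survive; error if none do).
#' @export
ascertain_sites <- function(truth, maf_min = 0.1, n_keep, seed = 1) {
  S1 <- truth$genotypes$S1
  p_hat <- rowSums(S1) / (2 * ncol(S1))
  pass <- which(pmin(p_hat, 1 - p_hat) >= maf_min)
  if (length(pass) == 0)
    stop("no sites survived ascertainment; increase n_sites")
  if (length(pass) < n_keep) {
    warning("only ", length(pass), " sites survived ascertainment ",
            "(requested ", n_keep, ")")
    keep <- pass
  } else {
    keep <- sort(withr::with_seed(seed, sample(pass, n_keep)))
  }
  subset_truth(truth, keep)
}

# Re-express truth in reference-allele units once the reference haplotype is
# chosen: genotype dosages become ref-allele dosages and f_* columns give
# ref-allele frequencies (p_* stay in ancestral-allele units).
reorient_truth <- function(truth, ref_is_anc) {
  fr <- truth$freqs
  flip <- function(p) ifelse(ref_is_anc, p, 1 - p)
  fr$ref_is_ancestral <- ref_is_anc
  fr$f_s1 <- flip(fr$p_s1); fr$f_s2 <- flip(fr$p_s2)
  fr$f_s3 <- flip(fr$p_s3); fr$f_t_pre <- flip(fr$p_t_pre)
  fr$f_t <- flip(fr$p_t)
  genotypes <- lapply(truth$genotypes, function(g) {
    g[!ref_is_anc, ] <- 2L - g[!ref_is_anc, ]
    g
  })
  structure(list(freqs = fr, genotypes = genotypes,
                 admixture = truth$admixture),
            class = "sim_truth")
}

subset_truth <- function(truth, idx) {
  structure(list(freqs = truth$freqs[idx, , drop = FALSE],
                 genotypes = lapply(truth$genotypes,
                                    function(g) g[idx, , drop = FALSE]),
                 admixture = truth$admixture),
            class = "sim_truth")
}

#' Simulate ancient-DNA-like fragment lengths
#'
#' Log-normal lengths with rejection of fragments below \code{frag_min}.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param n number of fragments.
#' @param seed RNG seed.
#' @param frag_loc log-normal location; defaults to the scenario's value or,
#'   when that is NULL, a single draw from U(3.3, 3.8) (the per-individual
#'   convention).
#' @return Integer vector of \code{n} fragment lengths, all
#'   \code{>= frag_min}.
#' @export
simulate_fragments <- function(scenario, n, seed = 1,
                               frag_loc = scenario$frag_loc) {
  withr::with_seed(seed, {
    if (is.null(frag_loc)) frag_loc <- stats::runif(1, 3.3, 3.8)
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rlnorm(2 * (n - length(out)) + 10, frag_loc,
                         scenario$frag_scale)
      out <- c(out, x[x >= scenario$frag_min])
    }
    as.integer(round(out[seq_len(n)]))
  })
}

#' Simulate mapped sequencing reads at panel sites
#'
#' For each individual and panel site the read count is
#' Poisson(\code{depth}); each read is a fragment of the reference around
#' the site (log-normal length, uniform placement subject to covering the
#' site), carries one of the individual's two allele copies at the site
#' (uniformly), and every base is flipped to one of the three other bases
#' with the error probability implied by \code{error_q}. Reads are returned
#' as already-placed alignments (mapq 60); pass them through a mapper
#' adapter to impose mapping bias.
#'
#' @param genotypes sites x individuals dosage matrix for one population.
#' @param panel a \code{\link{snp_panel}} (rows aligned with
#'   \code{genotypes}).
#' @param ref_seq reference chromosome sequence (single string).
#' @param scenario a \code{\link{sim_scenario}}.
#' @param individuals individual identifiers (column names).
#' @param seed RNG seed.
#' @return A \code{\link{read_set}}.
#' @export
simulate_reads <- function(genotypes, panel, ref_seq, scenario, individuals,
                           seed = 1) {
  stopifnot(nrow(genotypes) == nrow(panel),
            length(individuals) == ncol(genotypes))
  chrom_len <- nchar(ref_seq)
  n_sites <- nrow(panel)
  n_ind <- ncol(genotypes)
  withr::with_seed(seed, {
    frag_locs <- if (is.null(scenario$frag_loc))
      stats::runif(n_ind, 3.3, 3.8) else rep(scenario$frag_loc, n_ind)
    counts <- stats::rpois(n_sites * n_ind, scenario$depth)
    site_i <- rep(rep(seq_len(n_sites), n_ind), counts)
    ind_i <- rep(rep(seq_len(n_ind), each = n_sites), counts)
    n_reads <- length(site_i)
    if (n_reads == 0) return(empty_read_set())
    # fragment lengths per read (per-individual location), truncated >= min
    len <- numeric(n_reads)
    for (i in seq_len(n_ind)) {
      sel <- which(ind_i == i)
      if (!length(sel)) next
      out <- numeric(0)
      while (length(out) < length(sel)) {
        x <- stats::rlnorm(2 * (length(sel) - length(out)) + 10,
                           frag_locs[i], scenario$frag_scale)
        out <- c(out, x[x >= scenario$frag_min])
      }
      len[sel] <- round(out[seq_along(sel)])
    }
    pos <- panel$pos[site_i]
    start <- pos - floor(stats::runif(n_reads) * len)  # covers the site
    start <- pmax(1L, pmin(as.integer(start), pos))
    end <- pmin(chrom_len, start + as.integer(len) - 1L)
    start <- pmax(1L, pmin(start, end))
    seqs <- substring(ref_seq, start, end)
    # allele carried at the focal site: one of the two copies, uniformly
    dose <- genotypes[cbind(site_i, ind_i)]
    carries_ref <- stats::runif(n_reads) < dose / 2
    allele <- ifelse(carries_ref, panel$ref[site_i], panel$alt[site_i])
    off <- pos - start + 1L
    substr(seqs, off, off) <- allele
    # sequencing errors: per-read error-base count, then per-base placement
    e <- phred_to_error(scenario$error_q)
    n_err <- stats::rbinom(n_reads, nchar(seqs), e)
    for (j in which(n_err > 0)) {
      at <- sample.int(nchar(seqs[j]), n_err[j])
      for (k in at) {
        cur <- substr(seqs[j], k, k)
        substr(seqs[j], k, k) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                        1)
      }
    }
    qual <- vapply(nchar(seqs), function(w)
      strrep(intToUtf8(scenario$error_q + 33L), w), character(1))
    read_set(read_id = sprintf("%s_s%d_r%d", individuals[ind_i], site_i,
                               seq_len(n_reads)),
             individual = individuals[ind_i], chrom = panel$chrom[site_i],
             start = start, seq = seqs, qual = qual, mapq = 60L)
  })
}

#' Parametric biased mapper adapter
#'
#' A stand-in for aligner-induced reference bias: every read whose aligned
#' base at its focal panel site equals the alternative allele is dropped
#' independently with probability \code{beta}; reads carrying the reference
#' allele (or neither allele) are always retained. \code{beta = 0} is the
#' identity mapper. The focal site of an original read is the (single) panel
#' site it covers; for a flipped copy it is the site it was flipped at.
#'
#' @param beta alt-read loss probability in [0, 1].
#' @param panel a \code{\link{snp_panel}} (used to locate focal sites of
#'   original reads).
#' @return A mapper function: \code{read_set -> read_set} (retained reads,
#'   mapq 60, original coordinates). Uses the caller's RNG stream; seed the
#'   session (or wrap with \code{withr::with_seed}) for determinism.
#' @export
biased_mapper <- function(beta, panel) {
  stopifnot(beta >= 0, beta <= 1)
  force(panel)
  function(reads) {
    if (nrow(reads) == 0 || beta == 0) return(identity_mapper()(reads))
    # focal site per read
    fchrom <- reads$flip_chrom
    fpos <- reads$flip_pos
    unflipped <- is.na(fpos)
    if (any(unflipped)) {
      hits <- overlap_read_sites(reads[unflipped, , drop = FALSE], panel)
      first <- !duplicated(hits$read)
      idx <- which(unflipped)[hits$read[first]]
      fchrom[idx] <- panel$chrom[hits$site[first]]
      fpos[idx] <- panel$pos[hits$site[first]]
    }
    off <- query_offset_at(reads, ifelse(is.na(fpos), reads$start, fpos))
    base <- substr(reads$seq, off, off)
    si <- match(paste(fchrom, fpos), paste(panel$chrom, panel$pos))
    is_alt <- !is.na(si) & !is.na(base) & base == panel$alt[si]
    drop <- is_alt & stats::runif(nrow(reads)) < beta
    out <- reads[!drop, , drop = FALSE]
    out$mapq <- rep(60L, nrow(out))
    as_read_set(out)
  }
}

#' Generate a complete, self-consistent simulation bundle
#'
#' Runs the whole generative pipeline: drift-model frequencies, outgroup
#' ascertainment and thinning, a transversion-only panel, HWE genotypes,
#' aDNA-like reads, mapping through the (possibly biased) parametric mapper,
#' flip-remap bias estimation, default and corrected genotype likelihoods
#' and pseudohaploid calls, with all truth recorded. The reference genome is
#' the ancestral sequence with one sampled S1 haplotype's alleles substituted
#' at panel sites, so the reference allele is usually -- not always -- the
#' ancestral/major one, as with real reference genomes; truth tables carry
#' both ancestral-allele (\code{p_*}) and reference-allele (\code{f_*})
#' frequencies, and genotype dosages count reference alleles. Fully
#' reproducible from the scenario's seed.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param outdir optional directory; when given, panel, truth tables, bias
#'   tables, Beagle GL files and pseudohaploid calls are written as text.
#' @param populations populations to simulate reads for (default all four).
#' @param oversample candidate-site multiplier before ascertainment
#'   (default 25; under the default drift scales only a few percent of
#'   candidate sites reach 10\% minor allele frequency in the S1 sample).
#' @return list of class \code{scenario_bundle}: \code{scenario},
#'   \code{panel}, \code{ref_seq}, \code{truth}, \code{reads} (mapped,
#'   post-bias), \code{observations}, \code{bias}, \code{gl_default},
#'   \code{gl_corrected}, \code{calls}, \code{individuals} (per-population
#'   id lists).
#' @export
generate_scenario_bundle <- function(scenario, outdir = NULL,
                                     populations = c("S1", "S2", "S3", "T"),
                                     oversample = 25) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n_cand <- oversample * scenario$n_sites
  freqs <- simulate_frequencies(scenario, n_sites = n_cand,
                                seed = scenario$seed)
  truth <- simulate_genotypes(freqs, scenario, seed = scenario$seed + 1)
  truth <- ascertain_sites(truth, maf_min = scenario$maf_min,
                           n_keep = scenario$n_sites,
                           seed = scenario$seed + 2)
  n_sites <- nrow(truth$freqs)
  # ancestral chromosome; the polymorphism is (ancestral, derived) with the
  # derived allele a transversion partner of the ancestral base
  chrom_len <- (n_sites + 1) * scenario$site_spacing
  anc_seq <- simulate_ancestral_sequence(chrom_len, gc = scenario$gc,
                                         seed = scenario$seed + 3)
  pos <- scenario$site_spacing * seq_len(n_sites)
  anc_allele <- substring(anc_seq, pos, pos)
  tv_partner <- list(A = c("C", "T"), C = c("A", "G"),
                     G = c("C", "T"), T = c("A", "G"))
  der_allele <- withr::with_seed(scenario$seed + 4, vapply(
    anc_allele, function(b) sample(tv_partner[[b]], 1), character(1),
    USE.NAMES = FALSE))
  # reference genome = one haplotype sampled from ref_source, so the
  # reference allele is usually (not always) that population's major allele
  p_refpop <- truth$freqs[[c(S1 = "p_s1", S2 = "p_s2",
                             S3 = "p_s3")[scenario$ref_source]]]
  ref_is_anc <- withr::with_seed(
    scenario$seed + 5, stats::rbinom(n_sites, 1, p_refpop) == 1)
  ref_allele <- ifelse(ref_is_anc, anc_allele, der_allele)
  alt_allele <- ifelse(ref_is_anc, der_allele, anc_allele)
  ref_seq <- anc_seq
  substr_at <- pos[!ref_is_anc]
  for (j in substr_at)
    substr(ref_seq, j, j) <- der_allele[match(j, pos)]
  panel <- snp_panel("sim1", pos, ref_allele, alt_allele,
                     transversions_only = TRUE)
  truth <- reorient_truth(truth, ref_is_anc)
  individuals <- lapply(stats::setNames(populations, populations),
                        function(p) {
                          n <- if (p == "T") scenario$n_ind_target else
                            scenario$n_ind
                          sprintf("%s_%02d", p, seq_len(n))
                        })
  mapper <- biased_mapper(scenario$beta, panel)
  reads_l <- list(); bias_l <- list()
  for (k in seq_along(populations)) {
    p <- populations[k]
    raw <- simulate_reads(truth$genotypes[[p]], panel, ref_seq, scenario,
                          individuals[[p]], seed = scenario$seed + 10 + k)
    mapped <- withr::with_seed(scenario$seed + 20 + k, mapper(raw))
    reads_l[[p]] <- mapped
    bias_l[[p]] <- withr::with_seed(
      scenario$seed + 30 + k,
      run_flip_remap(mapped, panel, mapper, min_mapq = 30, min_baseq = 30))
  }
  reads <- as_read_set(do.call(rbind, unname(reads_l)))
  bias <- do.call(rbind, unname(bias_l))
  class(bias) <- c("site_bias", "data.frame")
  observations <- pileup_reads(reads, panel)
  all_inds <- unlist(individuals, use.names = FALSE)
  gl_default <- compute_gl(observations, panel, individuals = all_inds,
                           mode = "default")
  gl_corrected <- compute_gl(observations, panel, individuals = all_inds,
                             bias = bias, mode = "corrected")
  calls <- call_pseudohaploid(observations, panel, individuals = all_inds,
                              seed = scenario$seed + 40)
  bundle <- structure(list(scenario = scenario, panel = panel,
                           ref_seq = ref_seq, truth = truth, reads = reads,
                           observations = observations, bias = bias,
                           gl_default = gl_default,
                           gl_corrected = gl_corrected, calls = calls,
                           individuals = individuals),
                      class = "scenario_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# Serialise a bundle's text artefacts.
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_snp_panel(bundle$panel, file.path(outdir, "panel.tsv"))
  tf <- bundle$truth$freqs
  tf[] <- lapply(tf, function(x) if (is.double(x)) round(x, 6) else x)
  utils::write.table(
    cbind(chrom = bundle$panel$chrom, pos = bundle$panel$pos,
          ref = bundle$panel$ref, alt = bundle$panel$alt, tf),
    file.path(outdir, "truth_frequencies.tsv"), quote = FALSE, sep = "\t",
    row.names = FALSE)
  utils::write.table(
    data.frame(individual = bundle$individuals$T,
               admixture = bundle$truth$admixture),
    file.path(outdir, "truth_admixture.tsv"), quote = FALSE, sep = "\t",
    row.names = FALSE)
  write_bias_table(bundle$bias, file.path(outdir, "bias.tsv"))
  write_beagle(bundle$gl_default, file.path(outdir, "gl_default.beagle"))
  write_beagle(bundle$gl_corrected, file.path(outdir, "gl_corrected.beagle"))
  write_tped(bundle$calls, file.path(outdir, "pseudohaploid"))
  fa <- file.path(outdir, "reference.fa")
  writeLines(c(">sim1", bundle$ref_seq), fa)
  invisible(outdir)
}
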