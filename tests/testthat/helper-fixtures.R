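# Shared fixtures and independent oracles used across the test files.

# A small panel with mixed transversion pairs.
tiny_panel <- function(n = 3, chrom = "chr1", spacing = 100) {
  pairs <- list(c("A", "C"), c("G", "T"), c("C", "A"), c("T", "G"))
  idx <- rep_len(seq_along(pairs), n)
  snp_panel(chrom, spacing * seq_len(n),
            vapply(pairs[idx], `[`, "", 1), vapply(pairs[idx], `[`, "", 2))
}

# Hand-built ungapped reads around a single position.
mk_reads <- function(bases, start, q = 30, individual = "ind1",
                     chrom = "chr1", mapq = 60, prefix = "r") {
  n <- length(bases)
  read_set(read_id = paste0(prefix, seq_len(n)), individual = individual,
           chrom = chrom, start = start, seq = bases,
           qual = strrep(intToUtf8(q + 33), nchar(bases[1])), mapq = mapq)
}

# Reads covering one panel site at a given offset within a context sequence.
mk_site_reads <- function(site, alleles, flank = 10, q = 30,
                          individual = "ind1", prefix = "r") {
  ctx <- strrep("T", flank)
  seqs <- paste0(ctx, alleles, ctx)
  read_set(read_id = paste0(prefix, seq_along(alleles)),
           individual = individual, chrom = site$chrom,
           start = site$pos - flank, seq = seqs,
           qual = strrep(intToUtf8(q + 33), 2 * flank + 1), mapq = 60)
}

# Independent scalar oracle for the genotype-likelihood triplet: direct
# product form, no log-space tricks, no shared code with the package path.
gl_oracle <- function(bases, quals, ref, alt, r = 0.5) {
  if (length(bases) == 0) return(c(1 / 3, 1 / 3, 1 / 3))
  l <- c(1, 1, 1)
  for (i in seq_along(bases)) {
    e <- 10^(-quals[i] / 10)
    pr <- if (bases[i] == ref) 1 - e else e / 3
    pa <- if (bases[i] == alt) 1 - e else e / 3
    l[1] <- l[1] * pr
    l[2] <- l[2] * (r * pr + (1 - r) * pa)
    l[3] <- l[3] * pa
  }
  l / sum(l)
}

# Random observation fixture for one site: list(bases, quals, ref, alt).
random_site_obs <- function() {
  alleles <- sample(c("A", "C", "G", "T"), 2)
  n <- sample(0:8, 1)
  bases <- sample(c(alleles, "G", "N"), n, replace = TRUE,
                  prob = c(0.45, 0.45, 0.05, 0.05))
  list(bases = bases, quals = sample(c(2, 20, 30, 37), n, replace = TRUE),
       ref = alleles[1], alt = alleles[2])
}

# Grid-search oracle for the per-site allele frequency MLE.
grid_af_oracle <- function(l_rr, l_ra, l_aa, grid = seq(0, 1, by = 0.001)) {
  ll <- vapply(grid, function(f)
    sum(log(l_rr * f^2 + l_ra * 2 * f * (1 - f) + l_aa * (1 - f)^2)),
    numeric(1))
  grid[which.max(ll)]
}

# Grid-search oracle for the K=2 supervised admixture proportion.
grid_admix_oracle <- function(l_rr, l_ra, l_aa, f1, f2,
                              grid = seq(0, 1, by = 0.001)) {
  eps <- 1e-6
  f1 <- pmin(pmax(f1, eps), 1 - eps)
  f2 <- pmin(pmax(f2, eps), 1 - eps)
  ll <- vapply(grid, function(q) {
    p <- q * f1 + (1 - q) * f2
    sum(log(l_rr * p^2 + l_ra * 2 * p * (1 - p) + l_aa * (1 - p)^2))
  }, numeric(1))
  grid[which.max(ll)]
}

# gl_set data.frame builder from likelihood matrices (sites x individuals).
mk_gl_set <- function(l_rr, l_ra, l_aa, individuals = NULL) {
  l_rr <- as.matrix(l_rr); l_ra <- as.matrix(l_ra); l_aa <- as.matrix(l_aa)
  n_sites <- nrow(l_rr); n_ind <- ncol(l_rr)
  if (is.null(individuals)) individuals <- sprintf("i%02d", seq_len(n_ind))
  out <- data.frame(
    individual = rep(individuals, each = n_sites),
    chrom = "chr1", pos = rep(100 * seq_len(n_sites), n_ind),
    ref = "A", alt = "C",
    l_rr = as.vector(l_rr), l_ra = as.vector(l_ra), l_aa = as.vector(l_aa),
    n_reads = 1L, mode = "default", r_used = 0.5,
    stringsAsFactors = FALSE)
  s <- out$l_rr + out$l_ra + out$l_aa
  out$l_rr <- out$l_rr / s; out$l_ra <- out$l_ra / s; out$l_aa <- out$l_aa / s
  class(out) <- c("gl_set", "data.frame")
  out
}

# Certainty GL rows for a given dosage (2 = hom ref).
certain_gl <- function(dosage) {
  rbind("2" = c(1, 0, 0), "1" = c(0, 1, 0), "0" = c(0, 0, 1))[
    as.character(dosage), , drop = FALSE]
}
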