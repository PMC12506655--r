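test_that("ancestral sequence composition matches the target GC content", {
  n <- 1e5
  s <- simulate_ancestral_sequence(n, gc = 0.41, seed = 43)
  counts <- table(strsplit(s, "")[[1]])
  gc <- sum(counts[c("G", "C")]) / n
  se_gc <- sqrt(0.41 * 0.59 / n)
  expect_lt(abs(gc - 0.41), 3 * se_gc)
  se_g <- sqrt(0.205 * 0.795 / n)
  expect_lt(abs(counts[["G"]] / n - 0.205), 3 * se_g)
  # gc = 0 degenerates to an A/T sequence (sampling prob 0 for G/C)
  s0 <- simulate_ancestral_sequence(1000, gc = 1e-12, seed = 1)
  expect_false(grepl("[GC]", s0))
  # deterministic under a fixed seed
  expect_identical(simulate_ancestral_sequence(500, seed = 5),
                   simulate_ancestral_sequence(500, seed = 5))
})

test_that("Balding-Nichols drift has the right first two moments", {
  p <- 0.3
  Ne <- 10000
  for (F_target in c(0.01, 0.1)) {
    t <- -2 * Ne * log(1 - F_target)
    withr::with_seed(47, {
      child <- biasgl:::bn_drift(rep(p, 2e5), t, Ne)
    })
    expect_lt(abs(mean(child) - p), 0.005)
    expect_lt(abs(var(child - p) / (F_target * p * (1 - p)) - 1), 0.1)
  }
  # no time, no drift; fixed frequencies stay fixed
  expect_equal(biasgl:::bn_drift(c(0.2, 0.8), 0, Ne), c(0.2, 0.8))
  expect_equal(biasgl:::bn_drift(c(0, 1), 5000, Ne), c(0, 1))
})

test_that("admixture pulse mixes frequencies at the stated proportion", {
  sc1 <- sim_scenario(f = 1, n_sites = 500, seed = 53)
  fr1 <- simulate_frequencies(sc1)
  expect_equal(fr1$p_t, fr1$p_s3)
  sc0 <- sim_scenario(f = 0, n_sites = 500, seed = 53)
  fr0 <- simulate_frequencies(sc0)
  expect_equal(fr0$p_t, fr0$p_t_pre)
  sc5 <- sim_scenario(f = 0.25, n_sites = 500, seed = 53)
  fr5 <- simulate_frequencies(sc5)
  expect_equal(fr5$p_t, 0.25 * fr5$p_s3 + 0.75 * fr5$p_t_pre)
})

test_that("genotype simulation draws HWE dosages", {
  sc <- sim_scenario(n_ind = 100, n_ind_target = 100, seed = 59)
  fr <- data.frame(p_anc = 0.5, p_s1 = 0, p_s2 = 1, p_s3 = 0.5,
                   p_t_pre = 0.5, p_t = 0.5)
  fr <- fr[rep(1, 100), ]
  tr <- simulate_genotypes(fr, sc, seed = 61)
  expect_true(all(tr$genotypes$S1 == 0))
  expect_true(all(tr$genotypes$S2 == 2))
  m <- mean(tr$genotypes$S3)
  expect_lt(abs(m - 1), 3 * sqrt(0.5 / (100 * 100)))
  expect_equal(tr$admixture, rep(sc$f, 100))
})

test_that("ascertainment filters on outgroup sample MAF and thins", {
  sc <- sim_scenario(n_ind = 5, seed = 67)
  fr <- data.frame(p_anc = rep(0.5, 4), p_s1 = 0, p_s2 = 0.5, p_s3 = 0.5,
                   p_t_pre = 0.5, p_t = 0.5)
  tr <- simulate_genotypes(fr, sc, seed = 67)
  # hand-set S1 sample dosages: MAFs 0, 0.1, 0.3, 0.5
  tr$genotypes$S1 <- rbind(rep(0, 5), c(1, 0, 0, 0, 0), c(2, 1, 0, 0, 0),
                           c(2, 2, 1, 0, 0))
  expect_warning(ascertain_sites(tr, maf_min = 0.1, n_keep = 10, seed = 3),
                 "survived")
  asc <- suppressWarnings(ascertain_sites(tr, maf_min = 0.1, n_keep = 10,
                                          seed = 3))
  expect_equal(nrow(asc$freqs), 3)
  expect_error(ascertain_sites(tr, maf_min = 0.6, n_keep = 1, seed = 3),
               "no sites")
  # thinning is deterministic under the seed
  a1 <- suppressWarnings(ascertain_sites(tr, 0.1, 2, seed = 5))
  a2 <- suppressWarnings(ascertain_sites(tr, 0.1, 2, seed = 5))
  expect_identical(a1$freqs, a2$freqs)
})

test_that("fragment lengths are truncated log-normal with plausible means", {
  sc <- sim_scenario(frag_scale = 0.2, frag_min = 30)
  short <- simulate_fragments(sc, 5000, seed = 71, frag_loc = 3.3)
  long <- simulate_fragments(sc, 5000, seed = 73, frag_loc = 3.8)
  expect_true(all(short >= 30) && all(long >= 30))
  # untruncated means are exp(loc + scale^2/2) ~ 27.7 and 45.6; truncation
  # at 30 bp pulls the short-fragment mean up
  expect_gt(mean(short), 30)
  expect_lt(mean(short), 40)
  expect_lt(abs(mean(long) - exp(3.8 + 0.02)), 2)
  expect_identical(simulate_fragments(sc, 100, seed = 9),
                   simulate_fragments(sc, 100, seed = 9))
})

test_that("read simulation honours depth, genotypes and the error model", {
  p <- tiny_panel(50, spacing = 200)
  sc <- sim_scenario(depth = 2, error_q = 1000, seed = 79)
  ref_seq <- simulate_ancestral_sequence(200 * 51, seed = 79)
  # make the reference agree with the panel ref alleles
  for (i in seq_len(nrow(p))) substr(ref_seq, p$pos[i], p$pos[i]) <- p$ref[i]
  n_ind <- 20
  geno <- matrix(2L, nrow(p), n_ind)
  reads <- simulate_reads(geno, p, ref_seq, sc, sprintf("i%02d", 1:n_ind),
                          seed = 83)
  n_cells <- nrow(p) * n_ind
  expect_lt(abs(nrow(reads) / n_cells - 2), 3 * sqrt(2 / n_cells))
  obs <- pileup_reads(reads, p)
  # error-free hom-ref reads all carry the reference base
  expect_true(all(obs$base == obs$ref))
  # heterozygous genotypes yield balanced alleles without error
  geno1 <- matrix(1L, nrow(p), n_ind)
  r1 <- simulate_reads(geno1, p, ref_seq, sc, sprintf("i%02d", 1:n_ind),
                       seed = 89)
  o1 <- pileup_reads(r1, p)
  fr <- mean(o1$base == o1$ref)
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / nrow(o1)))
})

test_that("scenario bundles are reproducible and internally consistent", {
  sc <- sim_scenario(n_sites = 60, n_ind = 4, n_ind_target = 3, f = 0.3,
                     beta = 0.2, depth = 1.5, seed = 97)
  b1 <- generate_scenario_bundle(sc)
  b2 <- generate_scenario_bundle(sc)
  expect_identical(b1$bias, b2$bias)
  expect_identical(b1$gl_corrected, b2$gl_corrected)
  expect_identical(b1$calls, b2$calls)
  # panel is transversions-only and within the reference
  expect_false(any(is_transition(b1$panel$ref, b1$panel$alt)))
  expect_true(all(b1$panel$pos <= nchar(b1$ref_seq)))
  # the reference sequence carries the panel ref allele at every site
  expect_equal(substring(b1$ref_seq, b1$panel$pos, b1$panel$pos),
               b1$panel$ref)
  # truth records the pulse proportion for every target individual
  expect_equal(b1$truth$admixture, rep(0.3, 3))
  # ref-allele truth columns are consistent reorientations
  fr <- b1$truth$freqs
  expect_equal(fr$f_t, ifelse(fr$ref_is_ancestral, fr$p_t, 1 - fr$p_t))
  # serialized bundles are byte-identical under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  biasgl:::write_bundle(b1, d1)
  biasgl:::write_bundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(sim_scenario(f = 1.2))
  expect_error(sim_scenario(beta = -0.1))
  expect_error(sim_scenario(gc = 0))
  sc <- sim_scenario(t123 = 40000)
  expect_equal(sc$t23, 20000)
  expect_equal(sc$t_ts2, 8000)
})
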