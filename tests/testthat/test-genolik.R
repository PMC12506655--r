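test_that("phred conversion and base probabilities follow the error model", {
  expect_equal(phred_to_error(c(30, 0, 20)), c(0.001, 1, 0.01))
  expect_error(phred_to_error(-1), ">= 0")
  expect_equal(base_prob("A", "A", 0.01), 0.99)
  expect_equal(base_prob("C", "A", 0.01), 0.01 / 3)
  # N never matches an allele, so it always takes the mismatch branch
  expect_equal(base_prob("N", "A", 0.3), 0.1)
})

test_that("single-read likelihood triplet matches the hand-computed values", {
  # one read carrying the reference allele at Q20
  t <- gl_default("A", 20, ref = "A", alt = "C")
  raw <- c(0.99, 0.4966667, 0.0033333)
  expect_equal(unname(t), raw / sum(raw), tolerance = 1e-6)
  expect_equal(unname(t), c(0.6644295, 0.3333333, 0.0022371),
               tolerance = 1e-6)
  # zero reads: empty product, uniform triplet
  expect_equal(unname(gl_default(character(), numeric(), "A", "C")),
               rep(1 / 3, 3))
  # two high-quality discordant reads pin the heterozygote
  t2 <- gl_default(c("A", "C"), c(100, 100), "A", "C")
  expect_equal(unname(t2), c(0, 1, 0), tolerance = 1e-8)
})

test_that("corrected heterozygote term weighs alleles by r", {
  # r = 0.6, one ref read at Q20: raw het likelihood 0.6*0.99 + 0.4*0.01/3
  t <- gl_corrected("A", 20, "A", "C", r = 0.6)
  expect_equal(unname(t["l_ra"] / t["l_rr"]), 0.5953333 / 0.99,
               tolerance = 1e-6)
  # r at the upper clamp: heterozygote nearly indistinguishable from hom-ref
  t1 <- gl_corrected("A", 100, "A", "C", r = 1.0)
  expect_equal(unname(t1["l_ra"] / t1["l_rr"]), 0.999, tolerance = 1e-6)
  expect_error(gl_corrected("A", 20, "A", "C", r = 1.5), "\\[0, 1\\]")
})

test_that("r = 0.5 correction reproduces the default likelihood exactly", {
  withr::with_seed(42, {
    for (i in 1:500) {
      o <- random_site_obs()
      d <- gl_default(o$bases, o$quals, o$ref, o$alt)
      c5 <- gl_corrected(o$bases, o$quals, o$ref, o$alt, r = 0.5)
      expect_identical(d, c5)
      expect_equal(unname(d), gl_oracle(o$bases, o$quals, o$ref, o$alt),
                   tolerance = 1e-12)
    }
  })
})

test_that("heterozygote likelihood is monotone in r for concordant reads", {
  rs <- seq(0.1, 0.9, by = 0.1)
  all_ref <- vapply(rs, function(r)
    gl_corrected(rep("A", 3), rep(20, 3), "A", "C", r)[["l_ra"]], numeric(1))
  all_alt <- vapply(rs, function(r)
    gl_corrected(rep("C", 3), rep(20, 3), "A", "C", r)[["l_ra"]], numeric(1))
  expect_true(all(diff(all_ref) > 0))
  expect_true(all(diff(all_alt) < 0))
})

test_that("allele swap with r -> 1 - r mirrors the triplet", {
  withr::with_seed(7, {
    for (i in 1:50) {
      o <- random_site_obs()
      r <- runif(1)
      a <- gl_corrected(o$bases, o$quals, o$ref, o$alt, r)
      b <- gl_corrected(o$bases, o$quals, o$alt, o$ref, 1 - r)
      expect_equal(unname(a), unname(b[c("l_aa", "l_ra", "l_rr")]),
                   tolerance = 1e-12)
    }
  })
})

test_that("log-space accumulation survives 1,000 reads without underflow", {
  t <- gl_default(rep(c("A", "C"), 500), rep(30, 1000), "A", "C")
  expect_true(all(is.finite(t)))
  expect_equal(unname(t), c(0, 1, 0), tolerance = 1e-10)
  # matches the scalar-product oracle on a depth where products still work
  o <- list(bases = rep(c("A", "C", "A"), 4), quals = rep(30, 12))
  expect_equal(unname(gl_default(o$bases, o$quals, "A", "C")),
               gl_oracle(o$bases, o$quals, "A", "C"), tolerance = 1e-12)
})

test_that("normalization handles degenerate triplets", {
  expect_equal(unname(normalize_gl(c(1, 1, 1))), rep(1 / 3, 3))
  expect_equal(unname(normalize_gl(c(0, 0.25, 0))), c(0, 1, 0))
  expect_error(normalize_gl(c(0, 0, 0)), "all-zero")
})

test_that("vectorised GL computation agrees with the scalar path", {
  p <- tiny_panel(2)
  obs <- rbind(
    pileup_reads(mk_site_reads(p[1, ], c("A", "A", "C"), prefix = "a"), p),
    pileup_reads(mk_site_reads(p[2, ], c("T", "G"), prefix = "b"), p))
  bias <- compute_site_bias(obs, empty_read_set(), p)
  bias$r <- c(0.7, 0.5)
  bias$low_evidence <- FALSE
  gl <- compute_gl(obs, p, bias = bias, mode = "corrected")
  expect_equal(unname(unlist(gl[1, c("l_rr", "l_ra", "l_aa")])),
               unname(gl_corrected(c("A", "A", "C"), rep(30, 3), "A", "C",
                                   r = 0.7)),
               tolerance = 1e-12)
  expect_equal(gl$r_used, c(0.7, 0.5))
  # low-evidence bias records fall back to the default model
  bias$low_evidence <- c(TRUE, TRUE)
  gl2 <- compute_gl(obs, p, bias = bias, mode = "corrected")
  gl0 <- compute_gl(obs, p, mode = "default")
  expect_equal(gl2[, c("l_rr", "l_ra", "l_aa")],
               gl0[, c("l_rr", "l_ra", "l_aa")])
})

test_that("Beagle serialization round-trips and codes alleles 0-3", {
  p <- tiny_panel(2)
  obs <- rbind(
    pileup_reads(mk_site_reads(p[1, ], c("A", "C"), prefix = "a"), p),
    pileup_reads(mk_site_reads(p[2, ], "G", prefix = "b"), p),
    pileup_reads(mk_site_reads(p[1, ], "A", individual = "ind2",
                               prefix = "c"), p))
  gl <- compute_gl(obs, p, individuals = c("ind1", "ind2"))
  f <- withr::local_tempfile(fileext = ".beagle")
  write_beagle(gl, f)
  lines <- readLines(f)
  expect_equal(lines[1],
               "marker\tallele1\tallele2\tind1\tind1\tind1\tind2\tind2\tind2")
  row1 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(row1[1:3], c("chr1_100", "0", "1"))  # A=0, C=1
  back <- read_beagle(f)
  expect_equal(back$l_ra, gl$l_ra, tolerance = 1e-5)
  # ind2 has no reads at site 2: missing triplet is three equal values
  miss <- back[back$individual == "ind2" & back$pos == 200, ]
  expect_equal(miss$l_rr, 1 / 3, tolerance = 1e-5)
  # ragged input is rejected
  expect_error(write_beagle(gl[-1, ], f), "ragged")
  # empty gl_set gives a header-only file
  write_beagle(gl[0, ], f)
  expect_equal(length(readLines(f)), 1)
})
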