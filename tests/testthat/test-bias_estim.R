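test_that("allele flipping swaps ref<->alt and leaves the rest untouched", {
  p <- tiny_panel(1)  # chr1:100 A/C
  reads <- mk_reads(c("TTATT", "TTCTT", "TTGTT"), start = 98)
  f_ref <- flip_read_at_snp(reads[1, ], p[1, ])
  expect_equal(f_ref$seq, "TTCTT")
  expect_equal(f_ref$qual, reads$qual[1])
  expect_true(f_ref$is_modified)
  expect_equal(f_ref$flip_pos, 100L)
  f_alt <- flip_read_at_snp(reads[2, ], p[1, ])
  expect_equal(f_alt$seq, "TTATT")
  # a base matching neither allele yields no record
  expect_equal(nrow(flip_read_at_snp(reads[3, ], p[1, ])), 0)
  # alignment not spanning the site yields no record
  far <- mk_reads("AAAAA", start = 300, prefix = "far")
  expect_equal(nrow(flip_read_at_snp(far, p[1, ])), 0)
})

test_that("a deletion at the site position yields no flipped record", {
  p <- tiny_panel(1)
  del <- read_set("d1", "ind1", "chr1", 97L, "AAAA", "IIII", 60L,
                  cigar = "2M2D2M")  # covers 97-102, deletion at 99-100
  expect_equal(nrow(flip_read_at_snp(del, p[1, ])), 0)
  expect_equal(nrow(pileup_reads(del, p)), 0)
})

test_that("a read spanning two panel SNPs yields one flip per site", {
  p <- snp_panel("chr1", c(100, 104), c("A", "G"), c("C", "T"))
  rd <- mk_reads("TTATTGTT", start = 98)  # ref A at 100, alt T at 104
  ef <- extract_and_flip(rd, p, min_mapq = 30, min_baseq = 0)
  expect_equal(nrow(ef$flipped), 2)
  expect_equal(ef$flipped$flip_pos, c(100L, 104L))
  # each copy is modified at exactly its own site
  expect_equal(ef$flipped$seq, c("TTCTTGTT", "TTATTGGT"))
})

test_that("extraction applies the mapping-quality threshold", {
  p <- tiny_panel(1)
  reads <- mk_reads(c("TTATT", "TTCTT"), start = 98)
  reads$mapq <- c(29L, 30L)
  ef <- extract_and_flip(reads, p, min_mapq = 30, min_baseq = 0)
  expect_equal(nrow(ef$observations), 1)
  expect_equal(ef$observations$read_id, "r2")
  # three passing reads over one SNP give three flipped records
  r3 <- mk_reads(c("TTATT", "TTCTT", "TTATT"), start = 98, prefix = "q")
  expect_equal(nrow(extract_and_flip(r3, p)$flipped), 3)
})

test_that("site bias counting matches the enumerated examples", {
  p <- tiny_panel(1)
  orig <- mk_site_reads(p[1, ], c("A", "A", "C"))
  ef <- extract_and_flip(orig, p)
  # complete retention forces balance: 3 ref among 6
  b <- compute_site_bias(ef$observations, identity_mapper()(ef$flipped), p)
  expect_equal(b$n_total, 6L)
  expect_equal(b$n_ref, 3L)
  expect_equal(b$r, 0.5)
  # losing one flipped-to-alt copy of a ref read: 3 ref among 5, r = 0.6
  lost <- identity_mapper()(ef$flipped)
  stopifnot(substr(lost$seq[1], 11, 11) == "C")  # the flip of ref read r1
  lost <- lost[-1, ]
  b2 <- compute_site_bias(ef$observations, as_read_set(lost), p)
  expect_equal(b2$n_total, 5L)
  expect_equal(b2$n_ref, 3L)
  expect_equal(b2$r, 0.6)
  # no reads at all: documented fallback r = 0.5 with the low-evidence flag
  b3 <- compute_site_bias(ef$observations[0, ], empty_read_set(), p)
  expect_equal(b3$r, 0.5)
  expect_true(b3$low_evidence)
})

test_that("flipped copies only count at their own site with good mapping", {
  p <- tiny_panel(1)
  orig <- mk_site_reads(p[1, ], c("A", "A"))
  ef <- extract_and_flip(orig, p)
  # remapped with low quality: excluded, r driven by originals only
  low <- ef$flipped
  low$mapq <- 20L
  b <- compute_site_bias(ef$observations, low, p, min_mapq = 30)
  expect_equal(b$n_total, 2L)
  expect_equal(b$r, 1.0)
  # remapped to another position: excluded as well
  moved <- identity_mapper()(ef$flipped)
  moved$start <- moved$start + 500L
  b2 <- compute_site_bias(ef$observations, moved, p)
  expect_equal(b2$n_total, 2L)
})

test_that("identity-mapper flip-remap gives r = 0.5 at every covered site", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      p <- tiny_panel(sample(2:5, 1))
      reads <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
        n <- sample(0:6, 1)
        if (n == 0) return(empty_read_set())
        alle <- sample(c(p$ref[i], p$alt[i], "N"), n, replace = TRUE,
                       prob = c(0.5, 0.4, 0.1))
        mk_site_reads(p[i, ], alle, prefix = sprintf("x%d_%d_", rep, i))
      }))
      b <- run_flip_remap(as_read_set(reads), p, identity_mapper())
      covered <- b[!b$low_evidence, ]
      expect_true(all(covered$r == 0.5))
      expect_true(all(covered$n_ref * 2 == covered$n_total))
    }
  })
})

test_that("relabeling ref<->alt complements r under the same retention", {
  p <- tiny_panel(1)
  p_swap <- snp_panel(p$chrom, p$pos, p$alt, p$ref)
  orig <- mk_site_reads(p[1, ], c("A", "A", "A", "C", "C"))
  # deterministic lossy mapper: drops flips of a fixed set of originals
  drop_mapper <- function(victims) {
    function(reads) {
      keep <- !sub("_flip_.*$", "", reads$read_id) %in% victims
      identity_mapper()(reads[keep, , drop = FALSE])
    }
  }
  m <- drop_mapper(c("r1", "r2"))
  b1 <- run_flip_remap(orig, p, m)
  b2 <- run_flip_remap(orig, p_swap, m)
  expect_equal(b1$r + b2$r, 1)
  expect_false(b1$r == 0.5)
})

test_that("the biased mapper drives r toward its retained-read expectation", {
  p <- tiny_panel(20, spacing = 200)
  # reference-homozygous individual: originals all carry ref
  mk_all_ref <- function() do.call(rbind, lapply(seq_len(nrow(p)),
    function(i) mk_site_reads(p[i, ], rep(p$ref[i], 10),
                              prefix = paste0("s", i, "_"))))
  for (beta in c(0, 0.2, 0.5)) {
    b <- withr::with_seed(100 + beta * 10,
      run_flip_remap(as_read_set(mk_all_ref()), p, biased_mapper(beta, p)))
    pooled <- sum(b$n_ref) / sum(b$n_total)
    n_orig <- sum(b$n_ref)
    se <- if (beta == 0) 0 else
      sqrt(beta * (1 - beta) / n_orig) / (2 - beta)^2
    expect_lt(abs(pooled - 1 / (2 - beta)), 3 * se + 1e-12)
  }
  # beta = 1: every flipped (alt) copy lost, r = 1 at all-ref sites
  b1 <- withr::with_seed(5,
    run_flip_remap(as_read_set(mk_all_ref()), p, biased_mapper(1, p)))
  expect_true(all(b1$r == 1))
})

test_that("flip-remap on an empty panel returns an empty table", {
  empty <- snp_panel(character(), integer(), character(), character())
  b <- run_flip_remap(empty_read_set(), empty, identity_mapper())
  expect_equal(nrow(b), 0)
})

test_that("bias tables round-trip through the TSV format", {
  p <- tiny_panel(2)
  orig <- rbind(mk_site_reads(p[1, ], c("A", "C"), prefix = "a"),
                mk_site_reads(p[2, ], "G", prefix = "b"))
  b <- run_flip_remap(as_read_set(orig), p, identity_mapper())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bias_table(b, f)
  back <- read_bias_table(f)
  expect_equal(back$r, b$r, tolerance = 1e-6)
  expect_equal(back$n_total, b$n_total)
  expect_equal(back$low_evidence, b$low_evidence)
})
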