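# biasgl — mapping-bias-corrected genotype likelihoods

Short-read aligners prefer reads that match the reference genome: a read
carrying a non-reference allele has more mismatches, scores lower, and is
more often rejected or misplaced. Low-coverage samples — above all ancient
DNA, where fragments are short and degraded — therefore look systematically
more reference-like than they are, which biases allele-frequency estimates,
f-statistics and ancestry proportions. `biasgl` is for population
geneticists working with low- to medium-coverage BAMs at pre-ascertained
biallelic SNP panels who want to measure this bias per site and per
individual, and to carry the measurement into their genotype likelihoods
instead of discarding reads.

## The method

At a biallelic SNP ℓ with reference allele R and alternative allele A, the
standard ("direct") genotype likelihood for the observed bases
D = {b₁, …, bₙ} is

    P(D | G = A₁A₂) = ∏ᵢ [ P(bᵢ | A₁) + P(bᵢ | A₂) ] / 2
    P(b | X) = 1 − e   if b = X,   e/3 otherwise,   e = 10^(−Q/10)

The heterozygote term weighs both alleles equally — exactly the assumption
mapping bias violates. `biasgl` measures the violation empirically: every
read overlapping ℓ is copied, the copy's base at ℓ is swapped R ↔ A, and the
modified copies are remapped with the same mapper and settings. Counting
originals and retained remapped copies together gives the reference-read
proportion

    r = (reads carrying R) / (all retained original + modified reads)

which is exactly 0.5 when the mapper treats both alleles equally, > 0.5
under reference bias, < 0.5 under alternative bias. The heterozygote
likelihood is then recalibrated as

    P(D | G = RA) = ∏ᵢ [ r·P(bᵢ | R) + (1 − r)·P(bᵢ | A) ]

which reduces to the direct form at r = 0.5. Homozygote likelihoods are
unchanged. Downstream tools that consume Beagle-format genotype likelihoods
need no modification.

The package also implements the estimators used to evaluate the correction —
pseudohaploid calling by random read draw, maximum-likelihood allele
frequencies from genotype likelihoods under Hardy–Weinberg equilibrium,
per-site f2 differentiation, and supervised admixture-proportion EM — plus a
synthetic-data generator (drift-model population frequencies, outgroup
ascertainment, aDNA-like fragments, and a parametric biased mapper) so the
whole pipeline runs end to end without external data.

## Worked example

```r
library(biasgl)

# a small simulated cohort with moderate reference bias
scenario <- sim_scenario(t123 = 20000, n_sites = 500, n_ind = 21,
                         f = 0.1, depth = 2, beta = 0.3, seed = 42)
bundle <- generate_scenario_bundle(scenario, populations = c("S2", "S3", "T"))

# per-site, per-individual mapping bias measured by flip-remap
summary(bundle$bias$r[!bundle$bias$low_evidence])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.5000  0.5000  0.5000  0.6031  0.6667  1.0000

# allele frequencies in the target population, default vs corrected GLs
gl_t <- function(gl) gl[gl$individual %in% bundle$individuals$T, ]
f_default   <- estimate_af_ml(gl_t(bundle$gl_default))$f_ref
f_corrected <- estimate_af_ml(gl_t(bundle$gl_corrected))$f_ref
truth <- bundle$truth$freqs$f_t
cat(sprintf("mean error (default GL):   %+.4f\n", mean(f_default - truth)))
#> mean error (default GL):   +0.0170
cat(sprintf("mean error (corrected GL): %+.4f\n", mean(f_corrected - truth)))
#> mean error (corrected GL): +0.0072

# supervised admixture proportions of the target individuals
sources <- cbind(Tpre = bundle$truth$freqs$f_t_pre,
                 S3   = bundle$truth$freqs$f_s3)
fits <- lapply(bundle$individuals$T, function(ind) {
  gl <- bundle$gl_corrected
  estimate_admixture_em(gl[gl$individual == ind, ], sources)
})
round(mean_population_admixture(fits), 3)
#>  Tpre    S3
#> 0.891 0.109
```

With a 30% chance of losing each alternative-allele read, the median
flip-remap ratio is still 0.5 (most site-individuals are homozygous) but the
upper tail reaches 1.0; default genotype likelihoods overestimate the
reference-allele frequency by +0.017 on average, the corrected likelihoods
cut that error by more than half; and the supervised EM recovers the
simulated 10% admixture pulse as 10.9%.

On real data the entry points are `read_snp_panel()`,
`observations_from_bam()`, `run_flip_remap()` (with `bwa_mapper()`),
`compute_gl()` and `write_beagle()`; a thin command-line wrapper with the
same pipeline as subcommands lives in `inst/cli/biasgl.R`.

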