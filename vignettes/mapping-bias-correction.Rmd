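---
title: "Measuring and correcting mapping bias in genotype likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and correcting mapping bias in genotype likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasgl)
```

## The problem and the model

Aligning short reads to a linear reference genome favours reads that carry
the reference allele: a non-reference read has at least one extra mismatch,
a lower alignment score, and a higher chance of being rejected or placed
elsewhere. In low-coverage data, and especially in ancient DNA where
fragments are 30–50 bp, this inflates the apparent reference-allele content
of every downstream quantity. The effect is locus- and individual-specific —
it depends on the local sequence, the fragment lengths, and how far the
sample is from the reference — so a single genome-wide correction factor is
not enough.

`biasgl` works at a user-supplied panel of pre-ascertained biallelic SNPs
(the standard setting for ancient-DNA cohorts and capture arrays; the
package does not discover variants). At a panel site with reference allele
$R_\ell$ and alternative allele $A_\ell$, the direct genotype likelihood for
$n$ observed bases $b_{\ell i}$ with phred qualities $Q_{\ell i}$ is

$$P(D_\ell \mid G = A_1 A_2) = \prod_{i=1}^n
  \frac{P(b_{\ell i} \mid A_1) + P(b_{\ell i} \mid A_2)}{2},
\qquad
P(b \mid X) = \begin{cases} 1 - e & b = X \\ e/3 & b \ne X \end{cases},
\quad e = 10^{-Q/10}.$$

Its heterozygote term assumes each read is equally likely to sample either
allele. The package estimates how badly that assumption fails, per site and
individual, by the flip-remap procedure: every read overlapping the site is
copied with its base at the site swapped $R \leftrightarrow A$, the copies
are remapped with the same mapper and parameters, and the reference-read
proportion

$$r_\ell = \frac{\#\{\text{retained reads carrying } R_\ell\}}
               {\#\{\text{all retained original and modified reads}\}}$$

is recorded. A mapper indifferent to the allele returns every modified copy
to its origin and $r_\ell = 0.5$ exactly; copies that are lost, moved, or
degraded below the mapping-quality threshold push $r_\ell$ away from 0.5 —
above under reference bias, below under alternative bias. The heterozygote
likelihood is then replaced by

$$P(D_\ell \mid G = R_\ell A_\ell) = \prod_{i=1}^n
  \left[ r_\ell P(b_{\ell i} \mid R_\ell)
       + (1 - r_\ell) P(b_{\ell i} \mid A_\ell) \right],$$

which recovers the direct form at $r_\ell = 0.5$. Homozygote likelihoods are
left untouched: a homozygous site loses reads under bias but the surviving
reads still point at the right genotype, so the first-order damage is to
heterozygote calibration.

### Assumptions

* The panel is truly biallelic; bases matching neither allele are excluded
  from $r_\ell$ and enter the likelihood only through the mismatch term.
* $r_\ell$ measured from today's read set applies to the reads being
  evaluated — original and flipped reads go through the identical mapping
  pipeline, which is what makes the estimate empirical rather than modelled.
* Reads are independent given the genotype (no overlapping mate
  double-counting; mate-aware collapsing is out of scope).

## Conventions and key choices in the bias estimator

* **Per-site flipping.** A read overlapping $k$ panel SNPs yields $k$
  copies, each flipped at exactly one site. Joint flipping would couple
  neighbouring sites and make $r_\ell$ a haplotype property; per-site
  flipping keeps it a marginal, site-level quantity.
* **Retention rule.** A modified copy counts if it remaps to the same
  chromosome with an alignment *covering* the site at mapping quality ≥ 30.
  Requiring an identical start coordinate would wrongly discard soft-clipped
  remappings whose start shifts; allele recoverability at the site is what
  matters.
* **Naming.** Copies are named `<read>_flip_<chrom>_<pos>_<dir>` so they can
  be re-associated after an external remap with no side state; collisions
  with existing names are rejected.
* **Strand.** Flipping operates on the reference-oriented stored sequence;
  FASTQ export reverse-complements minus-strand reads, so an external mapper
  sees sequencing-orientation records.
* **Duplicates** are not collapsed at this stage (BAM import can exclude
  flagged duplicates on request).
* **Base qualities** enter at extraction (min 30 by default, matching the
  pseudohaploid convention); the $r_\ell$ denominator is not re-filtered on
  base quality after remapping.
* **Degenerate sites.** With no retained reads, $r_\ell$ falls back to 0.5
  with a `low_evidence` flag, and corrected likelihoods silently use the
  default model there — the conservative choice.
* **Clamping.** Before entering the corrected likelihood, $r$ is clamped to
  $[0.001, 0.999]$ (configurable): a ratio of exactly 0 or 1 estimated from
  a handful of reads is a sampling artefact, and letting it zero out the
  heterozygote likelihood would be absurd confidence.

## Numerical choices

* Likelihoods are accumulated in log space and normalized per site after
  subtracting the maximum; the plain product form underflows at depth.
* The frequency EM treats each individual's normalized triplet as the unit
  of evidence under a Hardy–Weinberg prior; the M-step sets $f$ to half the
  mean expected reference dosage. The admixture EM is the supervised
  mixture-of-clusters model with fixed source frequencies, updated through
  expected per-allele-copy ancestry assignments.
* Both EMs are initialized from the argmax of a 34-point likelihood scan.
  The per-site frequency likelihood is a polynomial of degree $2n$ and the
  admixture likelihood a high-degree polynomial in $q$; both can be
  multimodal for small samples, and EM only climbs within the basin it
  starts in. Flat (uninformative) inputs skip the scan and report the fixed
  initialization (0.5, or uniform $q$) with a flag.
* Convergence is declared at a parameter change below $10^{-6}$ within 200
  iterations by default; near-boundary optima converge sublinearly, and
  results carry a convergence flag. The oracle-agreement tests run the EMs
  to $10^{-8}$ with a larger iteration budget.
* Source frequencies are clamped to $(10^{-6}, 1 - 10^{-6})$ so fixed sites
  cannot produce infinite log-likelihoods.
* f2 comes in a plain mode, $(f_1 - f_2)^2$, and a small-sample mode that
  subtracts $h/(n-1)$ per population with $h = f(1-f)\,n/(n-1)$. Plain is
  the default and every comparison in the package uses the same mode on
  both sides.
* The pseudohaploid caller samples uniformly among reads passing base and
  mapping quality 30 whose base matches an allele; the draw is seeded and
  the seed recorded, so calls are reproducible. The post-hoc panel filter
  retains sites with missingness strictly below 50% and pooled minor allele
  frequency of at least 10%, computed from one pseudohaploid call per
  individual across all stated populations (the most natural reading of a
  pooled per-individual allele count).

## What the synthetic-data generator emulates

`sim_scenario()` / `generate_scenario_bundle()` reproduce the statistical
structure of a four-population admixture design at desk scale: an outgroup
S1, two sources S2 and S3, and a target T that receives a single admixture
pulse of proportion $f$ from S3 fifty generations ago. Split depths scale
off the deepest split $t_{123}$ (S3 splits at $0.5\,t_{123}$, T/S2 at
$0.2\,t_{123}$), with $N_e = 10{,}000$ on every branch.

* **Frequencies.** Instead of a coalescent, each branch applies
  Balding–Nichols drift with $F = 1 - e^{-t/(2N_e)}$ to an ancestral
  frequency drawn from Beta(0.5, 0.5) truncated to (0.05, 0.95). This
  preserves the topology, drift scales and ascertainment while running in
  seconds; what it gives up is linkage, which none of the site-wise
  estimators here use. T's pre-pulse lineage drifts independently of S2
  after their split; the pulse then mixes frequencies,
  $p_T = f\,p_{S3} + (1-f)\,p_{T,pre}$ — adequate for site-wise estimators,
  though it does not produce mosaic haplotypes.
* **Ascertainment.** Sites are kept when the minor allele frequency in the
  S1 genotype sample (2 × 21 chromosomes) is at least 10%, then thinned at
  random to the requested panel size. Under the default drift scales only a
  few percent of candidates pass, so candidates are oversampled 25×.
* **Sequence.** The ancestral chromosome is i.i.d. with GC content 0.41
  (mammalian-like); polymorphisms are exclusively transversions (the
  aDNA-panel convention, because deamination mimics transitions). The
  reference genome is one haplotype sampled from a chosen population
  (`ref_source`, default S2 — an ingroup reference, the setting where
  mapping bias matters; S1 gives an outgroup reference whose alleles are
  nearly uncorrelated with the studied populations). Truth tables carry
  frequencies in both ancestral-allele and reference-allele units.
* **Reads.** Per site and individual, read counts are Poisson(depth);
  fragment lengths are log-normal (per-individual location drawn from
  U(3.3, 3.8), scale 0.2, minimum 30 bp — mean fragment lengths of roughly
  27–46 bp); each read carries one of the two allele copies uniformly; every
  base errs with the probability implied by a single phred quality (default
  Q30). Panel spacing (150 bp) exceeds any plausible fragment length, so
  each simulated read covers exactly one panel site; multi-SNP behaviour is
  exercised with hand-built fixtures instead.
* **Mapping bias.** A parametric mapper drops each read whose base at its
  focal site equals the alternative allele with probability $\beta$, at
  every mapping event (initial mapping and remapping of flipped copies);
  $\beta = 0$ is the identity mapper. For a reference-homozygous
  site-individual each retained original contributes one reference read and
  an alt-flipped copy retained with probability $1-\beta$, so the pooled
  balance converges to $1/(2-\beta)$; at heterozygous sites alternative
  originals are already depleted before flipping and the expectation is
  closer to 0.5. The Monte-Carlo checks therefore condition on
  reference-homozygous genotypes and pool counts across sites (the per-site
  ratio at low depth is Jensen-biased upward). $\beta$ is a free dial: no
  particular value is claimed to equal the bias a real aligner induces on a
  real genome.

**What passing tests do and do not show.** The generator has no post-mortem
deamination, no indels or structural variation, no repeats, no
contamination, a single base-quality stratum, and free recombination
between panel sites. Tests against it demonstrate that the estimators are
correct under their own model and that the correction removes the bias the
parametric mapper injects; they do not quantify how large mapping bias is
for any real aligner, genome or damage profile.

## Study configurations used by the checks

Two divergence regimes appear in the tests, chosen once, on the scale the
phenomenon lives at:

* **Parameter recovery** (admixture without bias) uses the between-species
  default $t_{123} = 50{,}000$ generations, 2,000 sites, 20 target
  individuals at 2×. The supervised EM is given the *true mixing-component*
  frequencies — the target's pre-pulse lineage and S3. Handing it the
  sampled sister population S2 instead (the only option with real data)
  attenuates $\hat q$ toward $1/K$, because the target lineage drifts away
  from S2 after their split; that proxy-source bias is a property of the
  design, not an estimator defect, so the correctness check does not mix
  the two questions.
* **Bias-direction checks** reproduce an empirical pattern observed on
  human cohorts, so they run at the human-scale divergence
  $t_{123} = 20{,}000$ generations with the ingroup (S2-sourced) reference,
  $\beta = 0.3$, and the standard post-hoc site filter applied before
  measuring. "Truth" for the differentiation comparison is the sample
  allele frequency of the same individuals' true genotypes — the array
  analogue — since population-parameter frequencies differ from any
  21-individual sample by sampling variance that the genotype-likelihood
  estimates would be charged with twice. At between-species divergence the
  pattern is structurally absent: target frequencies sit at fixation under
  an ingroup reference (estimates can only move down), and an outgroup
  reference decorrelates the reference allele from the studied populations,
  removing the differentiation compression.

## Limitations

* $r_\ell$ from a handful of reads is noisy; the clamp and the low-evidence
  fallback bound, but do not remove, that noise. Sites with extreme
  measured bias are better treated with suspicion than with arithmetic.
* The correction targets heterozygote calibration only; it cannot restore
  reads the mapper never returned, and genome-wide quantities estimated
  from corrected likelihoods remain noisier at low depth.
* Damage-aware likelihoods (deamination-conditioned error terms) are a
  separate, complementary correction and out of scope here.
* The supervised admixture EM requires source frequencies from somewhere;
  with real data those are estimates, and their error propagates into
  $\hat q$ in ways the recovery checks (which use true frequencies)
  deliberately do not measure.
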